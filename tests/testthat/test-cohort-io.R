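# Abundance tables and empirical order parameters.

test_that("tables pass through, counts are closed, empty samples refused", {
  m <- matrix(c(0.5, 0.3, 0.2, 0.9, 0.1, 0), nrow = 3)
  tab <- abundance_table(m)
  expect_equal(colSums(tab$abundances), c(sample1 = 1, sample2 = 1))

  expect_warning(tab2 <- abundance_table(matrix(c(2, 3, 5), ncol = 1)),
                 "renormalized")
  expect_equal(as.vector(tab2$abundances), c(0.2, 0.3, 0.5))

  expect_error(abundance_table(matrix(c(1, 0, 0, 0), 2)), "empty sample")
  expect_error(abundance_table(matrix(c(-0.1, 1.1), 2, 1)), "negative")
  expect_error(abundance_table(m, species_ids = c("a", "a", "b")), "unique")
})

test_that("round trip through TSV and long tibbles preserves the table", {
  tab <- random_table(S = 10, R = 6, seed = 3)
  tmp <- tempfile(fileext = ".tsv")
  write_abundance_table(tab, tmp)
  back <- read_abundance_table(tmp, metadata = paste0(tmp, ".metadata.tsv"))
  expect_equal(back$abundances, tab$abundances, tolerance = 1e-12)
  expect_equal(back$cohort_labels, tab$cohort_labels)

  long <- as_tibble(tab)
  again <- as_abundance_table(long)
  expect_equal(again$abundances[tab$species_ids, tab$sample_ids],
               tab$abundances)
})

test_that("BIOM tables are read through the biomformat bridge", {
  m <- matrix(c(12, 6, 2, 18, 2, 0), nrow = 3,
              dimnames = list(paste0("sp", 1:3), paste0("s", 1:2)))
  tmp <- tempfile(fileext = ".biom")
  biomformat::write_biom(biomformat::make_biom(m), tmp)
  expect_warning(tab <- read_abundance_table(tmp, format = "biom"),
                 "renormalized")
  expect_equal(tab$abundances[, "s1"], c(sp1 = 0.6, sp2 = 0.3, sp3 = 0.1))
  expect_equal(colSums(tab$abundances), c(s1 = 1, s2 = 1))
})

test_that("order parameters reproduce the hand-computed two-sample example", {
  m <- matrix(c(0.5, 0.3, 0.2, 0.9, 0.1, 0), nrow = 3)
  op <- estimate_order_parameters(abundance_table(m))
  expect_equal(op$h, (1 / 3 + 1 / 2) / 2, tolerance = 1e-12)          # 0.416667
  expect_equal(op$q_d, (0.38 / 3 + 0.82 / 2) / 2, tolerance = 1e-12)  # 0.268333
  expect_equal(op$q_0, ((1 / 3)^2 + (1 / 2)^2) / 2, tolerance = 1e-12)
  expect_equal(op$K, (0.9 + 0.3 + 0.2) / 3, tolerance = 1e-12)        # 0.466667
  expect_equal(op$S_pool, 3L)
  expect_equal(op$R, 2L)

  # uniform single sample: h = 1/S, q_d = q_0 = 1/S^2
  u <- abundance_table(matrix(rep(0.2, 5), ncol = 1))
  opu <- estimate_order_parameters(u)
  expect_equal(opu$h, 1 / 5)
  expect_equal(opu$q_d, 1 / 25)
  expect_equal(opu$q_0, 1 / 25)
})

test_that("compositional identities and inequalities hold on random tables", {
  for (seed in 1:5) {
    tab <- random_table(S = 40, R = 15, seed = seed, zeros = 0.3)
    op <- estimate_order_parameters(tab)
    for (cc in op$cohort) {
      A <- tab$abundances[, tab$cohort_labels == cc, drop = FALSE]
      Sa <- colSums(A > 0)
      row <- op[op$cohort == cc, ]
      expect_equal(row$h, mean(1 / Sa), tolerance = 1e-14)
      expect_equal(row$q_0, mean(1 / Sa^2), tolerance = 1e-14)
      expect_true(row$q_d >= row$q_0)       # Cauchy-Schwarz within samples
      expect_true(row$K <= 1 && row$K >= row$h)
    }
  }
})

test_that("estimators are invariant to species and sample reordering", {
  tab <- random_table(S = 25, R = 10, seed = 9)
  set.seed(1)
  perm_s <- sample(25); perm_a <- sample(10)
  tab2 <- abundance_table(tab$abundances[perm_s, perm_a],
                          cohort_labels = tab$cohort_labels[perm_a],
                          normalize = FALSE)
  op1 <- estimate_order_parameters(tab)
  op2 <- estimate_order_parameters(tab2)
  op2 <- op2[match(op1$cohort, op2$cohort), ]
  expect_equal(op1[, c("h", "q_d", "q_0", "K")], op2[, c("h", "q_d", "q_0", "K")])
})

test_that("bootstrap degenerates correctly and is reproducible", {
  tab <- random_table(S = 20, R = 10, seed = 2)
  b1 <- bootstrap_order_parameters(tab, n_iter = 50, retain_fraction = 1,
                                   seed = 4)
  expect_true(all(b1$summary$sd == 0))      # no resampling at retain = 1
  obs <- estimate_order_parameters(tab)
  expect_equal(unique(b1$draws$h[b1$draws$cohort == "A"]),
               obs$h[obs$cohort == "A"])

  b2 <- bootstrap_order_parameters(tab, n_iter = 30, seed = 7)
  b3 <- bootstrap_order_parameters(tab, n_iter = 30, seed = 7)
  expect_identical(b2$draws, b3$draws)
  expect_error(bootstrap_order_parameters(tab, n_iter = 5,
                                          retain_fraction = 0.05),
               "zero")
})

test_that("bootstrap spread shrinks with the number of samples", {
  theta <- model_parameters(1, 0.5, 2e-3, 2e-4)
  big <- sample_cohort_stationary(theta, K = 0.05, S = 40, R = 200, seed = 21,
                                  compositional = FALSE)
  small_idx <- 1:50
  small <- abundance_table(big$abundances[, small_idx],
                           cohort_labels = rep("all", 50), normalize = FALSE)
  bb <- bootstrap_order_parameters(big, n_iter = 200, seed = 5)
  bs <- bootstrap_order_parameters(small, n_iter = 200, seed = 5)
  sd_big <- bb$summary$sd[bb$summary$parameter == "h"]
  sd_small <- bs$summary$sd[bs$summary$parameter == "h"]
  expect_lt(sd_big, sd_small)
})

test_that("label randomization preserves sizes and detects real separation", {
  tab <- random_table(S = 20, R = 12, seed = 6)
  expect_error(label_randomization_null(
    abundance_table(tab$abundances, cohort_labels = rep("x", 12),
                    normalize = FALSE)),
    "2 cohorts")

  nl <- label_randomization_null(tab, n_iter = 40, seed = 3)
  counts <- dplyr::count(nl$draws, iter, cohort)
  expect_true(all(counts$n == 1))           # every cohort present per iteration

  # two cohorts generated at clearly different parameters: observed h outside
  # the central 95% of the null
  tA <- sample_cohort_stationary(model_parameters(1, 0.3, 2e-3, 2e-4),
                                 K = 0.05, S = 60, R = 30, seed = 11,
                                 subsample_depth = 2000)
  tB <- sample_cohort_stationary(model_parameters(1, 0.3, 8e-3, 8e-4),
                                 K = 0.2, S = 60, R = 30, seed = 12,
                                 subsample_depth = 2000)
  comb <- abundance_table(cbind(tA$abundances, tB$abundances),
                          cohort_labels = rep(c("A", "B"), each = 30),
                          sample_ids = paste0("s", 1:60), normalize = FALSE)
  obs <- estimate_order_parameters(comb)
  dh_obs <- diff(obs$h)
  nl2 <- label_randomization_null(comb, n_iter = 200, seed = 8)
  dh_null <- nl2$draws |>
    tidyr::pivot_wider(id_cols = "iter", names_from = "cohort",
                       values_from = "h") |>
    dplyr::mutate(d = B - A)
  expect_true(dh_obs < stats::quantile(dh_null$d, 0.025) ||
                dh_obs > stats::quantile(dh_null$d, 0.975))
})
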