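Package: dglvr
Title: Disordered Lotka-Volterra Macroecology for Microbiome Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Macroecological analysis of cross-sectional microbiome cohorts
    through the replica-symmetric solution of the disordered generalized
    Lotka-Volterra model. Estimates compositional order parameters (mean
    abundance, self-overlap, overlap, carrying capacity) with bootstrap and
    label-permutation uncertainty, inverts the replica-symmetric
    self-consistency equations by multi-start moment matching to recover the
    effective ecological parameters (mean interaction strength, interaction
    heterogeneity, demographic noise, immigration), and computes stability
    diagnostics: the replicon eigenvalue, the mass term, the distance to the
    replica-symmetry-breaking line, and the niche-neutral ratio. Includes a
    stationary cavity sampler and an explicit Euler-Maruyama simulator for
    generating synthetic cohorts with the statistical structure the theory
    assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    biomformat
Config/testthat/edition: 3
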