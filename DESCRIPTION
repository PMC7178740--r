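Package: btindices
Title: Bayesian Posterior Significance and Effect-Size Indices for the
    Two-Sample t-Test
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the panel of Bayesian posterior indices of significance
    and effect size for the two-sample t-test under the
    Jeffreys-Zellner-Siow (JZS) model: the JZS Bayes factor, the 95% and
    full region of practical equivalence (ROPE), the probability of
    direction, the MAP-based p-value, and the e-value of the Full Bayesian
    Significance Test under flat and Cauchy reference densities, with
    Welch's p-value as the frequentist reference. Includes a deterministic
    grid representation of the posterior of the standardized effect size,
    a synthetic two-group data generator, and a Monte-Carlo engine that
    estimates type-I error rates and sensitivity of each index across
    sample sizes, Cauchy prior scales, and additive noise levels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
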