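Package: floatmix
Title: Gaussian Mixture Models for Floating Plastic Debris
Version: 0.1.0
Authors@R:
    person("floatmix", "developers", email = "floatmix@example.org", role = c("aut", "cre"))
Description: Latent class analysis of floating macro- and microplastic particles
    via finite mixtures of normal distributions over particle length and width.
    Provides constrained EM estimation (per-class variances with the length-width
    covariance held equal across classes), class enumeration by BIC, bootstrapped
    likelihood-ratio test, normalized entropy and average posterior classification
    probability, a combined six-class model with category-restricted membership,
    cluster-robust (sandwich) standard errors for haul-clustered sampling,
    three-step distal-outcome analysis of polymer composition, a synthetic particle
    generator parameterized from published fitted values, and a command-line
    pipeline covering screening, enumeration, joint fitting and auxiliary analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
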