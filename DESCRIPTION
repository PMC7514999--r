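Package: elgfit
Title: The Exponentiated Lindley-Geometric Lifetime Distribution
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Distribution functions, exact Lambert-W inverse-CDF sampling,
    series-based moments and entropies, maximum-likelihood and EM estimation
    with asymptotic inference and multicensoring support, and a
    model-comparison workflow (Gamma, Weibull, Lindley-geometric,
    Weibull-geometric competitors with AIC/BIC/AICc and Cramer-von Mises /
    Anderson-Darling statistics) for the three-parameter exponentiated
    Lindley-geometric family of lifetime distributions. Ships the two
    classical case-study data sets (bladder-cancer remission times and bank
    waiting times) used to benchmark parametric survival models.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
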