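Package: iatkit
Title: Scoring Algorithms and Robust Comparison Machinery for the
    Implicit Association Test
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes Implicit Association Test (IAT) scores under a
    fully crossed family of scoring algorithms defined by four
    parameters: extreme-latency treatment (none, fixed-value or
    statistical trimming/winsorizing, inverse trimming), error-latency
    treatment (ignore, exclude, recode with mean + 2SD or mean + 600 ms,
    separate), scoring formula (D, Gaussian-rank G, worst-performance
    rule, mini-differences and robust variants), and the practice/test
    distinction. Includes the named D presets and their improved
    variants, psychometric evaluation (split-half and test-retest
    reliability, convergent and predictive validity), rank-score
    composition, rank-based ANOVA-type tests with Box-approximated
    degrees of freedom, Tukey-type nonparametric contrasts on relative
    effects, the Patel-Hoel interaction test, significance T-graphs with
    transitive reduction, and a seeded ex-Gaussian IAT session simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    mvtnorm
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
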