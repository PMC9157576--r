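Package: hpncea
Title: Markov Cohort Cost-Effectiveness Analysis of Supplemental Home
    Parenteral Nutrition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Two-state (survive/die) Markov cohort model for the
    cost-effectiveness of supplemental home parenteral nutrition versus
    best-practice nutritional care in incurable gastrointestinal cancer,
    from the Chinese healthcare perspective.  Provides Weibull parametric
    survival fitted from digitized Kaplan-Meier curves, per-cycle
    transition probabilities, discounted cost and QALY accrual, primary
    and per-visit secondary incremental cost-effectiveness ratios, net
    monetary benefit and willingness-to-pay headroom, one-way
    deterministic (tornado) and probabilistic (Monte Carlo, CEAC)
    sensitivity analyses, and a synthetic-trial generator with known
    ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
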