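Package: punishMPT
Title: Multinomial Processing Tree Analysis of Cooperation and Costly Punishment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring cooperation and costly punishment in one-shot
    simultaneous Prisoner's Dilemma experiments with a multinomial processing
    tree (MPT) model. Simulates trial-level experiments with computer-controlled
    partners and agents driven by known latent parameters, aggregates trials
    into the model's eight-cell category tables, estimates the latent
    cooperation and punishment probabilities (C, P_Moral, P_Hypocritical,
    P_Antisocial, b) by minimum-G2 maximum likelihood with optional equality
    constraints across framing conditions, and provides likelihood-ratio
    goodness-of-fit tests, nested delta-G2 comparisons, Cohen's w effect sizes,
    and noncentral chi-square power and sensitivity analysis.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
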