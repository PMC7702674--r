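Package: skullconv
Title: Convergence of Skull-Roof Microanatomy in Fossorial Lepidosaurs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies convergent evolution of skull-roof microanatomy and
    morphology in burrowing (fossorial) lepidosaurs. Extracts bone compactness,
    local thickness, anteroposterior bone overlap and macroscopic skull traits
    from binary micro-CT cross-section masks; tests lifestyle signal with
    phylogenetically informed ANOVA (Pagel's lambda GLS whitening and
    residual-randomization permutations); reconstructs lifestyle history by
    stochastic character mapping under an Mk model and continuous traits by
    maximum likelihood; and measures convergence with univariate C1 and
    univariate/bivariate C5 indices against a Brownian-motion simulation null.
    Includes a synthetic-study generator (pure-birth trees, regime-switching
    Ornstein-Uhlenbeck traits, procedural cross-section masks) with full
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    EBImage,
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phytools,
    phangorn,
    withr,
    tiff,
    optparse
Config/testthat/edition: 3
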