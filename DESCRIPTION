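Package: onestepblend
Title: One-Step Blending Genomic Prediction from De-Regressed Proofs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Genomic prediction for populations in which the reference set
    is dominated by cows with moderately reliable de-regressed proofs (DRP).
    Builds pedigree (A), genomic (VanRaden method 1 G), moment-adjusted
    (G-beta-alpha) and hybrid (H) relationship matrices, fits the weighted
    single-random-effect mixed model by restricted maximum likelihood and
    Henderson's mixed model equations, and evaluates realized and
    theoretical prediction accuracy on validation cohorts.  Includes a
    gene-dropping population simulator that emulates a cow-reference
    dairy-cattle design (genotyped reference cows and progeny-tested
    sires, a younger genotyped validation cohort, and non-genotyped dams
    and paternal half-sisters carrying DRP).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
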