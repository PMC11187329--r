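Package: lipidmr
Title: Drug-Target Mendelian Randomization for Lipid-Lowering Therapies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-sample drug-target Mendelian randomization with cis-acting
    genetic instruments near the genes encoding lipid-lowering drug targets
    (HMGCR, PCSK9, NPC1L1, APOB, ANGPTL3, PPARA, APOC3, LDLR, LPL).
    Implements summary-statistic input/output and effect-allele
    harmonization, cis-window instrument selection with greedy LD clumping
    and F-statistic screening, Wald-ratio/IVW/MR-Egger causal estimation, a
    sensitivity battery (Cochran's Q and I-squared, Egger intercept test,
    MR-PRESSO global/outlier/distortion tests, leave-one-out, funnel data),
    a two-stage study design gated on a positive-control outcome, and a
    synthetic GWAS summary-statistic generator with known ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    metafor,
    withr
Config/testthat/edition: 3
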