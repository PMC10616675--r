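Package: decaychase
Title: Transcriptome-Wide mRNA Decay Analysis of Actinomycin-D Chase Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing transcription-shutoff (actinomycin D) chase
    RNA-seq experiments in LPS-stimulated macrophages. Converts gene-level
    counts to per-kilobase normalized expression, computes per-replicate
    percent-of-anchor decay curves, applies a biotype/expression/decay filter
    cascade, and runs a two-stage stabilization screen: consecutive-timepoint
    two-sample t tests followed by a mixed-design repeated-measures two-way
    ANOVA with Greenhouse-Geisser correction and Sidak-adjusted per-timepoint
    comparisons. Includes a scanner for AU-rich tristetraprolin (TTP) family
    binding sites in 3'-UTR sequences, differential-expression threshold and
    cross-tabulation helpers, induction time-course area-under-the-curve
    statistics, and negative-binomial simulators of chase experiments with
    known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    car,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
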