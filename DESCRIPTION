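Package: msapquant
Title: Relative Quantitative Analysis of MSAP Methylation Profiles
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Relative quantitative analysis of methylation-sensitive
    amplified polymorphism (MSAP) marker data. Band presence/absence
    patterns from parallel EcoRI/HpaII and EcoRI/MspI digests of control
    and stressed samples are reduced to four-bit codes, each code is
    explained by enumerating all admissible methylation states of the
    CCGG restriction site, and the resulting event weights quantify
    demethylation, de novo methylation, and preservation of methylated
    and non-methylated cytosines, globally and split by CG/CHG sequence
    context. Includes Ward hierarchical clustering and one-way ANOVA of
    the derived characteristics, tabular I/O for binary marker matrices,
    and a simulator of MSAP experiments with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, ape
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
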