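Package: meltSTR
Title: STR Genotype Prediction from High-Resolution Melt Curves
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Statistical genotyping of short tandem repeat (STR) loci from
    qPCR high-resolution melt (HRM) curves. Extracts fixed-length feature
    vectors from the negative first derivative of a melt curve (primary peak,
    shoulder peaks and a constant-temperature pad), classifies unknown samples
    against genotype standards by linear discriminant analysis or by
    PCA-based Gaussian cluster typing, and evaluates predictions with
    confusion matrices, homozygous/heterozygous accuracy splits, near-miss
    rates and geno-group collapsing. Includes a melt-curve simulator whose
    per-allele logistic melting transitions reproduce the peak-and-shoulder
    morphologies of closely related STR genotypes, and packaged confusion
    matrices from a published D5S818/D18S51 HRM genotyping study.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
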