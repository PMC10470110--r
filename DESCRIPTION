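Package: pentagen
Title: Compressed Genotype Matrix Algebra for Single-Step Genomic Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for genomic prediction with bit-packed genotype data.
    Reads and writes PLINK 1 binary genotype files, re-packs dosage matrices
    into a base-3 format that stores five SNPs per byte, and multiplies the
    (allele-frequency centered) genotype matrix or its transpose by narrow
    trait matrices through 243-entry lookup tables, with sparse correction of
    missing calls. The same kernels drive a matrix-free preconditioned
    conjugate gradient solver for single-step SNP BLUP mixed model equations,
    built on Henderson's sparse inverse of the pedigree relationship matrix.
    A seeded gene-dropping simulator generates pedigrees, genotypes and
    phenotypes for testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
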