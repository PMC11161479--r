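Package: wssgwas
Title: Weighted Single-Step GWAS with Maternal-Effects Animal Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for weighted single-step genome-wide association studies
    (WssGWAS) in livestock populations where many animals are phenotyped but
    only a small recent subset is genotyped.  Builds pedigree numerator
    relationship matrices and their sparse inverses with inbreeding, applies
    standard SNP quality control (call rate, minor allele frequency, exact
    Hardy-Weinberg test), constructs weighted VanRaden genomic relationship
    matrices blended with the pedigree submatrix, assembles the single-step
    H-inverse, solves maternal-effects animal-model mixed model equations,
    estimates variance components by restricted maximum likelihood
    (average-information with expectation-maximisation fallback), iteratively
    re-weights SNPs by the nonlinearA rule, and decomposes genetic variance
    into non-overlapping 1-Mb genomic windows.  Includes a gene-dropping
    simulator that generates pedigrees, genotypes, quantitative trait loci and
    phenotypes with the exact statistical structure the model assumes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
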