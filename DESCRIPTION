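Package: hlaimpute
Title: Imputation and Association Testing of HLA Alleles and Amino Acid
    Polymorphisms from MHC SNP Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to impute classical HLA alleles, amino acid polymorphisms
    and intragenic indels across the major histocompatibility complex (MHC,
    chr6:29-34 Mb) from SNP genotype data.  Classical HLA typings and
    per-allele protein sequences are recoded as binary presence/absence
    markers, merged with quality-controlled SNPs into a phased reference
    panel, and imputed into SNP-genotyped target samples with a
    Li-Stephens haplotype-copying hidden Markov model that yields posterior
    allele dosages, genotype posteriors, best-guess calls and phased
    haplotypes.  Includes the standard accuracy metrics for HLA imputation
    (dosage-based locus accuracy, Pearson r2, multi-allelic R2, genotype
    concordance), case/control association testing of imputed dosages with
    omnibus amino-acid-position tests and haplotype odds ratios, a
    synthetic MHC data generator with known truth, PLINK bed/bim/fam and
    phased-haplotype/VCF input-output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    MASS
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
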