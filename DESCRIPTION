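Package: reversionscan
Title: Detection of BRCA1/2 Reversion Mutations and Homologous
    Recombination Deficiency Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects somatic reversion mutations that restore the open
    reading frame of a truncated BRCA1/2 allele: candidate somatic indels
    within a codon window of the germline lesion are phased in cis by
    spanning read pairs or, for encompassing deletions, by
    loss-of-wild-type inference from allele-specific copy number, and
    tested for reading-frame restoration by translation.  Also quantifies
    the homologous recombination deficiency phenotype through genomic scar
    scores (large-scale transitions, HRD-LOH, telomeric allelic
    imbalance), maximum-likelihood mutational-signature deconvolution,
    zygosity inference from purity and copy number, and cohort prevalence
    statistics, with a synthetic-cohort generator carrying planted ground
    truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
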