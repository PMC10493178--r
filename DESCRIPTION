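Package: vcfcohort
Title: Cohort-Level Summarization, Annotation and Mutational Signatures for VCF Variant Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Non-interactive toolkit for summarizing cohorts of variant call
    format (VCF) files. Reads single- or multi-sample VCFs into normalized,
    classified variant records organized as replicated sample groups;
    annotates variants to genes and genomic feature categories (exonic,
    splicing, UTR, intronic, up/downstream, intergenic) directly from GTF or
    GFF3 gene models; computes deterministic cohort summary tables (variant
    totals, replicate overlap regions, base substitution spectra, indel
    length distributions, per-window genome density, feature distributions,
    high-frequency and cancer driver gene tallies); and performs mutational
    signature analysis natively, building SBS96 trinucleotide count matrices
    from an indexed reference FASTA, extracting de novo signatures by
    Kullback-Leibler non-negative matrix factorization, refitting exposures
    against a reference catalog, and matching signatures by cosine
    similarity. A synthetic fixture generator produces toy genomes, gene
    models, driver lists, signature catalogs and replicated VCF cohorts with
    manifest-recorded planted truth so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    Rsamtools,
    rtracklayer,
    pracma,
    ggplot2,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
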