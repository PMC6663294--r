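Package: gbminit
Title: Expression-Dependent De Novo CHG Methylation and the Origin of Gene Body Methylation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream whole-genome bisulfite sequencing analysis of
    chromomethylase-induced de novo gene body methylation. Implements binomial
    per-cytosine methylation calling against a chloroplast non-conversion
    control, strand-aware trinucleotide context partitioning (CWG/CCG, CWA),
    a differential methylation site/region stage with size and percent-change
    filters, a CHG-gain gene classifier and its characterization statistics,
    transgenerational retention-ratio analysis of newly methylated cytosines,
    a random-gene background CG estimator, exact enrichment tests (log-space
    hypergeometric, two-sided Fisher, exact Wilcoxon), expression fold-change
    classification and delta-delta-Ct, binned methylation and ChIP metaplots
    with peak merging and density filtering, and a seeded synthetic-study
    generator (genome, annotations, generational methylome series with
    expression-dependent gain and post-silencing retention, allc emission under
    a Poisson coverage / bisulfite non-conversion read model) so every stage
    runs without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    methods,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
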