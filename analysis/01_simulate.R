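#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study.
#
# Emits, under results/sim/: the reference genome (FASTA), gene/repeat
# annotations (BED), one allc table per sample (wild type + six
# generations), the per-gene truth table, and the expression / qPCR / ChIP
# inputs used by later stages.

suppressPackageStartupMessages({
  library(gbminit)
  library(data.table)
})

seed <- as.integer(Sys.getenv("GBMINIT_SEED", "1"))
out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = seed)
sim <- simulate_study(cfg)

Biostrings::writeXStringSet(sim$reference$genome, file.path(out, "genome.fa"))
feats <- sim$reference$features
for (cls in c("gene", "repeat")) {
  sub <- feats[feats$feature_class == cls]
  bed <- data.table(
    chrom = as.character(GenomicRanges::seqnames(sub)),
    start = GenomicRanges::start(sub) - 1L,  # BED is 0-based half-open
    end = GenomicRanges::end(sub),
    name = sub$id, score = 0L,
    strand = sub("\\*", ".", as.character(GenomicRanges::strand(sub))))
  fwrite(bed, file.path(out, sprintf("%ss.bed", cls)), sep = "\t",
         col.names = FALSE)
}

for (s in sim$samples) {
  write_allc(sim$allc[[s]], file.path(out, sprintf("allc_%s.tsv", s)))
}
write_result_table(sim$gene_truth, file.path(out, "gene_truth.tsv"), seed = seed)

chip <- simulate_chip_and_expression(sim$reference, cfg)
write_result_table(chip$fpkm, file.path(out, "fpkm.tsv"), seed = seed)
write_result_table(chip$ct, file.path(out, "qpcr_ct.tsv"), seed = seed)
genes <- feats[feats$feature_class == "gene"]
wc <- chip$count_windows(genes)
write_result_table(
  data.table(gene_id = rownames(wc), wc, library_size = chip$library_size),
  file.path(out, "chip_gene_window_counts.tsv"), seed = seed)
peaks_dt <- data.table(
  chrom = as.character(GenomicRanges::seqnames(chip$peaks)),
  start = GenomicRanges::start(chip$peaks), end = GenomicRanges::end(chip$peaks),
  reads = chip$peak_counts)
write_result_table(peaks_dt, file.path(out, "chip_raw_peaks.tsv"), seed = seed)

n_gain <- sum(!is.na(sim$gene_truth$gain_generation))
cat(sprintf(
  "simulated %d sites over %d genes / %d repeats (+%d bp control contig);\n",
  nrow(sim$sites), cfg$n_genes, cfg$n_repeats, cfg$control_len))
cat(sprintf("%d genes planted as CHG-gainers across the series (seed %d)\n",
            n_gain, seed))
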