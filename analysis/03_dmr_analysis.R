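#!/usr/bin/env Rscript
# Stage 3: differential methylation.
#
# Wild type is compared with each generation in each context; significant
# sites are chained into regions (>= 5 differential sites), classified as
# hyper/hypo at the 10-point (CHG/CHH) or 20-point (CG) cutoffs, and
# annotated by overlap (gene > repeat > intergenic). Also writes the
# region-by-sample heatmap matrix ranked by wild-type CHG and the
# interval-overlap Fisher association between the hyper sets of successive
# generations.

suppressPackageStartupMessages({
  library(gbminit)
  library(data.table)
})

seed <- as.integer(Sys.getenv("GBMINIT_SEED", "1"))
simdir <- "results/sim"
out <- "results/dmr"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

samples <- sub("^allc_(.*)\\.tsv$", "\\1",
               basename(Sys.glob(file.path(simdir, "allc_*.tsv"))))
allc <- lapply(setNames(nm = samples), function(s) {
  read_allc(file.path(simdir, sprintf("allc_%s.tsv", s)))
})
feats <- suppressWarnings(c(
  read_features(file.path(simdir, "genes.bed"), feature_class = "gene"),
  read_features(file.path(simdir, "repeats.bed"), feature_class = "repeat")))

gens <- grep("^T", samples, value = TRUE)
all_rows <- list()
hyper_sets <- list()
for (ctx in c("CG", "CHG", "CHH")) {
  for (g in gens) {
    dms <- find_dms(allc$WT, allc[[g]], context = ctx)
    dmrs <- merge_dms_to_dmrs(dms, max_gap = 250L, min_dms = 5L, context = ctx)
    if (!length(dmrs)) next
    ann <- classify_and_annotate_dmrs(dmrs, allc$WT, allc[[g]], feats, ctx)
    row <- data.table(
      context = ctx, sample = g,
      chrom = as.character(GenomicRanges::seqnames(ann)),
      start = GenomicRanges::start(ann), end = GenomicRanges::end(ann),
      n_dms = ann$n_dms, direction = ann$direction,
      overlap_class = ann$overlap_class,
      wt_pct = ann$wt_pct, line_pct = ann$other_pct)
    all_rows[[paste(ctx, g)]] <- row
    if (ctx == "CHG") hyper_sets[[g]] <- ann[!is.na(ann$direction) &
                                               ann$direction == "hyper"]
  }
}
dmr_tab <- rbindlist(all_rows)
write_result_table(dmr_tab, file.path(out, "dmrs.tsv"), seed = seed)

chg <- dmr_tab[context == "CHG"]
cat(sprintf("CHG DMRs: %d total, median %d bp, %.0f%% hyper, %.0f%% genic\n",
            nrow(chg), as.integer(median(chg$end - chg$start + 1)),
            100 * mean(chg$direction == "hyper", na.rm = TRUE),
            100 * mean(chg$overlap_class == "genic")))

# heatmap matrix over the union of hyper CHG regions, ranked by WT level
if (length(hyper_sets)) {
  union_dmrs <- GenomicRanges::reduce(do.call(c, unname(hyper_sets)))
  union_dmrs$id <- sprintf("DMR_%d", seq_along(union_dmrs))
  hm <- dmr_heatmap_matrix(union_dmrs, allc, wt_name = "WT", context = "CHG")
  write_result_table(data.table(region = rownames(hm), hm),
                     file.path(out, "heatmap_chg.tsv"), seed = seed)
  cat(sprintf("heatmap: %d regions pass the 5-site/3-read filter in all samples\n",
              nrow(hm)))
}

# association of hyper-CHG region sets between successive generations
genome_len <- sum(Biostrings::width(
  Biostrings::readDNAStringSet(file.path(simdir, "genome.fa"))))
assoc <- list()
pairs <- utils::combn(names(hyper_sets), 2, simplify = FALSE)
for (pr in pairs) {
  ft <- interval_overlap_fisher(hyper_sets[[pr[1]]], hyper_sets[[pr[2]]],
                                genome_length = genome_len)
  assoc[[paste(pr, collapse = "_")]] <- data.table(
    a = pr[1], b = pr[2],
    overlapping = ft$table[1, 1], a_only = ft$table[1, 2],
    b_only = ft$table[2, 1], p = ft$p)
}
assoc <- rbindlist(assoc)
write_result_table(assoc, file.path(out, "hyper_chg_overlap_fisher.tsv"),
                   seed = seed)
m <- nrow(assoc)
cat(sprintf(
  "hyper-CHG overlap: %d/%d generation pairs significant at Bonferroni %g\n",
  sum(assoc$p < bonferroni_threshold(0.05, m)), m,
  signif(bonferroni_threshold(0.05, m), 2)))
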