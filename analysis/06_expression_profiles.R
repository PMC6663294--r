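#!/usr/bin/env Rscript
# Stage 6: expression coupling and spatial profiles.
#
# Log2 fold-change classification of gain genes (zero-FPKM removal, strict
# +/-2 cutoff), Fisher test of gain-gene enrichment among up/down-regulated
# genes, the transgene-expression ~ genic %CHG regression, qPCR
# delta-delta-Ct, gene-body methylation metaplots per generation, and the
# ChIP peak merge / density filter with the 4-bin metaplot.

suppressPackageStartupMessages({
  library(gbminit)
  library(data.table)
})

seed <- as.integer(Sys.getenv("GBMINIT_SEED", "1"))
simdir <- "results/sim"
gaindir <- "results/gain"
out <- "results/expression_profiles"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

samples <- sub("^allc_(.*)\\.tsv$", "\\1",
               basename(Sys.glob(file.path(simdir, "allc_*.tsv"))))
allc <- lapply(setNames(nm = samples), function(s) {
  read_allc(file.path(simdir, sprintf("allc_%s.tsv", s)))
})
genes <- read_features(file.path(simdir, "genes.bed"), feature_class = "gene")
fpkm <- fread(file.path(simdir, "fpkm.tsv"), skip = 1)
gain_tab <- fread(file.path(gaindir, "gain_genes.tsv"), skip = 1)
gens <- grep("^T", samples, value = TRUE)

## expression fold change of gain genes, T4 vs wild type ----------------------
wt_fpkm <- fpkm[sample == "WT"][match(genes$id, gene_id), fpkm]
t4_fpkm <- fpkm[sample == "T4"][match(genes$id, gene_id), fpkm]
fc <- log2fc_classify(t4_fpkm, wt_fpkm, cutoff = 2)
fc_tab <- data.table(gene_id = genes$id, fc,
                     gain = genes$id %in% gain_tab[sample == "T4" & gain == TRUE,
                                                   gene_id])
write_result_table(fc_tab, file.path(out, "log2fc_T4.tsv"), seed = seed)
kept <- fc_tab[class != "excluded_zero"]
changed <- kept$class %in% c("up", "down")
tab <- matrix(c(sum(kept$gain & changed), sum(kept$gain & !changed),
                sum(!kept$gain & changed), sum(!kept$gain & !changed)),
              2, 2, byrow = TRUE)
ft <- fisher_exact_2x2(tab)
cat(sprintf(
  "gain genes with |log2FC| > 2 at T4: %d/%d; enrichment Fisher p = %.3f\n",
  sum(kept$gain & changed), sum(kept$gain), ft$p))

## transgene expression ~ genic %CHG regression -------------------------------
genic_chg <- vapply(c("WT", gens), function(s) {
  wm <- weighted_methylation(allc[[s]], genes, context = "CHG")
  100 * sum(wm$mc_sum) / sum(wm$cov_sum)
}, numeric(1))
tg <- fpkm[gene_id == "AtCMT3_transgene"]
x <- tg[match(c("WT", gens), sample), fpkm]
reg <- linreg_r2(x, genic_chg)
write_result_table(
  data.table(sample = c("WT", gens), transgene_fpkm = x, genic_pct_chg = genic_chg),
  file.path(out, "expression_vs_chg.tsv"), seed = seed)
cat(sprintf("transgene FPKM ~ genic %%CHG: R2 = %.3f, slope p = %.2g (n = %d)\n",
            reg$r_squared, reg$p, reg$n))

## qPCR delta-delta-Ct --------------------------------------------------------
ct <- fread(file.path(simdir, "qpcr_ct.tsv"), skip = 1)
rel <- ct[, .(relative_expression =
                relative_expression_ddct(ct_target, ct_reference)),
          by = sample]
write_result_table(rel, file.path(out, "qpcr_relative_expression.tsv"),
                   seed = seed)

## gene-body CHG metaplots ----------------------------------------------------
plots <- rbindlist(lapply(c("WT", "T4", "T6"), function(s) {
  mp <- methylation_metaplot(genes, allc[[s]], context = "CHG")
  mp[, sample := s]
  mp
}))
write_result_table(plots, file.path(out, "metaplot_chg_genes.tsv"), seed = seed)
body_t4 <- plots[sample == "T4" & zone == "body", mean(value, na.rm = TRUE)]
body_wt <- plots[sample == "WT" & zone == "body", mean(value, na.rm = TRUE)]
cat(sprintf("mean gene-body %%CHG: WT %.2f%%, T4 %.2f%%\n",
            100 * body_wt, 100 * body_t4))

## ChIP peaks and 4-bin metaplot ----------------------------------------------
raw <- fread(file.path(simdir, "chip_raw_peaks.tsv"), skip = 1)
peaks <- GenomicRanges::GRanges(raw$chrom, IRanges::IRanges(raw$start, raw$end))
merged <- merge_and_filter_peaks(peaks, raw$reads, min_density = 0.05)
cat(sprintf("ChIP peaks: %d raw -> %d merged regions with density > 0.05\n",
            length(peaks), length(merged)))
wc <- fread(file.path(simdir, "chip_gene_window_counts.tsv"), skip = 1)
prof <- chip_metaplot(as.matrix(wc[, 2:5]), library_size = wc$library_size[1])
write_result_table(
  data.table(bin = c("upstream", "into_start", "into_end", "downstream"),
             value = prof),
  file.path(out, "chip_metaplot_genes.tsv"), seed = seed)
cat("gene-body H3K9me2 profile is flat (heterochromatin-restricted mark):\n")
print(signif(prof, 3))
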