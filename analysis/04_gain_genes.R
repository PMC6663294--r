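#!/usr/bin/env Rscript
# Stage 4: CHG-gain genes.
#
# Calls CHG-gain genes in every generation against wild type (joint
# informative-site filter over the whole series), compares the called set
# with the planted truth, characterizes gain vs unmethylated genes
# (length, exon count, expression, CHG site frequency; Wilcoxon), and runs
# the gain-set overlap enrichment between generations.

suppressPackageStartupMessages({
  library(gbminit)
  library(data.table)
})

seed <- as.integer(Sys.getenv("GBMINIT_SEED", "1"))
simdir <- "results/sim"
out <- "results/gain"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

samples <- sub("^allc_(.*)\\.tsv$", "\\1",
               basename(Sys.glob(file.path(simdir, "allc_*.tsv"))))
allc <- lapply(setNames(nm = samples), function(s) {
  read_allc(file.path(simdir, sprintf("allc_%s.tsv", s)))
})
genes <- read_features(file.path(simdir, "genes.bed"), feature_class = "gene")
truth <- fread(file.path(simdir, "gene_truth.tsv"), skip = 1)
genome <- Biostrings::readDNAStringSet(file.path(simdir, "genome.fa"))
fpkm <- fread(file.path(simdir, "fpkm.tsv"), skip = 1)

gens <- grep("^T", samples, value = TRUE)
per_gen <- list()
gain_sets <- list()
for (g in gens) {
  res <- call_chg_gain_genes(allc, "WT", g, genes)
  res[, sample := g]
  per_gen[[g]] <- res
  gain_sets[[g]] <- res[gain == TRUE, gene_id]
}
gain_tab <- rbindlist(per_gen)
write_result_table(gain_tab, file.path(out, "gain_genes.tsv"), seed = seed)
counts <- vapply(gens, function(g) length(gain_sets[[g]]), 0L)
cat("CHG-gain genes per generation:",
    paste(sprintf("%s=%d", gens, counts), collapse = " "), "\n")

# agreement with the planted truth at the peak-expression generation
t4 <- per_gen$T4
tr <- truth$gained_T4[match(t4$gene_id, truth$gene_id)]
cat(sprintf("T4 recovery: sensitivity %.3f, FDR %.3f\n",
            sum(t4$gain & tr) / sum(tr),
            ifelse(sum(t4$gain), sum(t4$gain & !tr) / sum(t4$gain), 0)))

# characteristics: union of gain genes vs never-gain unmethylated genes
gain_union <- unique(unlist(gain_sets))
um <- setdiff(truth[is.na(gain_generation), gene_id], gain_union)
gseq <- genome$chr1
chg <- vapply(seq_along(genes), function(i) {
  s <- Biostrings::subseq(gseq, GenomicRanges::start(genes)[i],
                          GenomicRanges::end(genes)[i])
  chg_site_frequency(as.character(s))$frequency
}, numeric(1))
mean_fpkm <- fpkm[gene_id %in% genes$id,
                  .(expression = mean(fpkm)), by = gene_id]
chars <- data.table(
  gene_id = genes$id,
  length = GenomicRanges::width(genes),
  exon_count = truth$exon_count[match(genes$id, truth$gene_id)],
  chg_frequency = chg)
chars <- mean_fpkm[chars, on = "gene_id"]
write_result_table(chars, file.path(out, "gene_characteristics.tsv"), seed = seed)
cmp <- compare_characteristics(gain_union, um, chars)
write_result_table(cmp, file.path(out, "characteristics_wilcoxon.tsv"),
                   seed = seed)
cat("gain vs UM characteristics (Wilcoxon):\n")
print(cmp[, .(characteristic, p = signif(p, 3), median_gain, median_um)])

# overlap enrichment of gain sets between generations
pairs <- utils::combn(gens[counts > 0], 2, simplify = FALSE)
ov <- rbindlist(lapply(pairs, function(pr) {
  t <- gene_set_overlap_test(gain_sets[[pr[1]]], gain_sets[[pr[2]]],
                             universe_size = length(genes))
  data.table(a = pr[1], b = pr[2], overlap = t$overlap,
             log10_p = t$log10_p)
}))
write_result_table(ov, file.path(out, "gain_overlap_hypergeom.tsv"), seed = seed)
thr <- bonferroni_threshold(0.05, nrow(ov))
cat(sprintf("gain-set overlaps: %d/%d pairs below Bonferroni threshold %.2g\n",
            sum(10^ov$log10_p < thr), nrow(ov), thr))

# the published ortholog gbM enrichment table, recomputed
h <- hypergeom_upper_tail(20211, 4532, 4104, 1526)
cat(sprintf("ortholog gbM enrichment (published counts): log10 p = %.2f\n",
            h$log10_p))
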