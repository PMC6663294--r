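#!/usr/bin/env Rscript
# Stage 5: transgenerational retention and the background CG floor.
#
# Selects cytosines within T4 gain-gene bodies that are covered in every
# sample and unmethylated in wild type, counts binomially-called methylated
# cytosines per context partition in each generation relative to T4, and
# estimates the background CG level over random never-gain unmethylated
# genes (five replicates).

suppressPackageStartupMessages({
  library(gbminit)
  library(data.table)
})

seed <- as.integer(Sys.getenv("GBMINIT_SEED", "1"))
simdir <- "results/sim"
calldir <- "results/calls"
gaindir <- "results/gain"
out <- "results/retention"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

samples <- sub("^calls_(.*)\\.tsv$", "\\1",
               basename(Sys.glob(file.path(calldir, "calls_*.tsv"))))
called <- lapply(setNames(nm = samples), function(s) {
  fread(file.path(calldir, sprintf("calls_%s.tsv", s)))
})
genes <- read_features(file.path(simdir, "genes.bed"), feature_class = "gene")
gain_tab <- fread(file.path(gaindir, "gain_genes.tsv"), skip = 1)

t4_gain <- gain_tab[sample == "T4" & gain == TRUE, gene_id]
regions <- genes[genes$id %in% t4_gain]
elig <- select_eligible_cytosines(regions, called, "WT")
cat(sprintf("%d eligible cytosines over %d T4 gain genes\n",
            nrow(elig), length(regions)))

rr <- retention_ratios(elig, called, reference = "T4")
write_result_table(rr, file.path(out, "retention_ratios.tsv"), seed = seed)
wide <- dcast(rr[grepl("^T", sample)], partition ~ sample, value.var = "ratio")
cat("retention relative to T4 (ratio of methylated cytosines):\n")
print(wide[, lapply(.SD, function(x) if (is.numeric(x)) round(x, 3) else x)])

# background CG over never-gain unmethylated genes, five random sets
truth <- fread(file.path(simdir, "gene_truth.tsv"), skip = 1)
pool <- genes[genes$id %in% setdiff(truth[is.na(gain_generation), gene_id],
                                    unique(gain_tab[gain == TRUE, gene_id]))]
bg <- background_cg_estimate(
  pool, n_genes = min(length(pool), length(regions)),
  total_bp = sum(GenomicRanges::width(regions)),
  called_samples = called, wt_name = "WT",
  n_replicates = 5L, seed = seed + 7L)
write_result_table(bg, file.path(out, "background_cg.tsv"), seed = seed)
cat("mean background %CG by sample (5 random gene sets):\n")
print(bg[, .(mean_pct_cg = round(mean(pct_cg, na.rm = TRUE), 4)), by = sample])

# the retained genic CG level sits above this background
cg_t6 <- 100 * rr[sample == "T6" & partition == "CG", ratio]
cat(sprintf(
  "genic CG retained at T6: %.1f%% of T4 counts; background CG %.4f%%\n",
  cg_t6, mean(bg[sample == "T6", pct_cg], na.rm = TRUE)))
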