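#!/usr/bin/env Rscript
# Stage 2: non-conversion estimation and per-cytosine binomial calls.
#
# Reads the allc tables from stage 1, estimates the bisulfite non-conversion
# rate from the control contig of the wild-type library, then calls every
# covered cytosine in every sample. Writes per-sample call tables and a
# non-conversion report.

suppressPackageStartupMessages({
  library(gbminit)
  library(data.table)
})

seed <- as.integer(Sys.getenv("GBMINIT_SEED", "1"))
simdir <- "results/sim"
out <- "results/calls"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

samples <- sub("^allc_(.*)\\.tsv$", "\\1",
               basename(Sys.glob(file.path(simdir, "allc_*.tsv"))))
allc <- lapply(setNames(nm = samples), function(s) {
  read_allc(file.path(simdir, sprintf("allc_%s.tsv", s)))
})

nc <- lapply(samples, function(s) {
  est <- estimate_nonconversion(allc[[s]], "chrC")
  data.table(sample = s, rate = est$rate, mc_sum = est$mc_sum,
             cov_sum = est$cov_sum)
})
nc <- rbindlist(nc)
write_result_table(nc, file.path(out, "nonconversion.tsv"), seed = seed)

r_wt <- nc[sample == "WT", rate]
for (s in samples) {
  called <- call_methylation(allc[[s]], r = r_wt, min_cov = 3L,
                             q_threshold = 0.01)
  fwrite(called, file.path(out, sprintf("calls_%s.tsv", s)), sep = "\t")
}

cat(sprintf("non-conversion (WT control contig): %.4f%%\n", 100 * r_wt))
cat(sprintf("called %d samples at min_cov 3, q < 0.01 (BH)\n", length(samples)))
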