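# Shared fixtures, built in code.

library(data.table)
suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
})

# a small site table built directly from counts
make_sites <- function(chrom, pos, strand, context3, mc, cov) {
  lab <- classify_context_string(context3)
  dt <- data.table::data.table(
    chrom = chrom, pos = as.integer(pos), strand = strand,
    context3 = context3, mc = as.integer(mc), cov = as.integer(cov),
    major_class = lab$major_class, subclass = lab$subclass)
  data.table::setkeyv(dt, c("chrom", "pos", "strand"))
  dt
}

# site tables pre-marked with calls, bypassing the binomial caller, for
# tests that exercise eligibility/counting logic in isolation
with_calls <- function(sites, calls) {
  out <- data.table::copy(sites)
  out[, call := calls]
  out
}

# one cached small simulated study reused across test files
.sim_cache <- new.env(parent = emptyenv())

small_study <- function() {
  if (is.null(.sim_cache$small)) {
    cfg <- sim_config(seed = 11L, n_genes = 40L, n_repeats = 20L,
                      control_len = 10000L)
    .sim_cache$small <- simulate_study(cfg)
  }
  .sim_cache$small
}

# the full-scale study under the default (study) conditions, with binomial
# calls; used by the parameter-recovery acceptance checks
study_conditions <- function(seed = 20260930L) {
  key <- paste0("full_", seed)
  if (is.null(.sim_cache[[key]])) {
    cfg <- sim_config(seed = seed)
    sim <- simulate_study(cfg)
    r <- estimate_nonconversion(sim$allc$WT, cfg$control_chrom)$rate
    sim$called <- lapply(sim$allc, call_methylation, r = r)
    sim$nonconversion_estimate <- r
    .sim_cache[[key]] <- sim
  }
  .sim_cache[[key]]
}
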