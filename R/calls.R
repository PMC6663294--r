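# Per-cytosine binomial methylation calling against a non-conversion control.
#
# Bisulfite conversion is imperfect: a fraction r of truly unmethylated
# cytosines read out as methylated. r is estimated from a fully unmethylated
# control contig (chloroplast in the real study), and each covered cytosine
# is tested against Binomial(cov, r): the upper-tail probability of observing
# at least the seen number of methylated reads under pure non-conversion.
# P-values are Benjamini-Hochberg adjusted across all tested cytosines of a
# sample; a cytosine is called methylated when its q-value falls below the
# threshold. Cytosines below the minimum coverage are never tested.

#' Estimate the bisulfite non-conversion rate from a control contig
#'
#' Pools methylated and total read counts over every cytosine of the
#' designated unmethylated control contig, across all contexts:
#' `r = sum(mc) / sum(cov)`.
#'
#' @param sites Site table ([read_allc()] layout).
#' @param control_chrom Name of the unmethylated control contig.
#' @return A list with `rate`, `mc_sum`, `cov_sum`.
#' @export
estimate_nonconversion <- function(sites, control_chrom) {
  ctrl <- data.table::as.data.table(sites)[chrom == control_chrom]
  cov_sum <- sum(as.numeric(ctrl$cov))
  if (cov_sum <= 0) {
    stop("no covered cytosines on control contig '", control_chrom,
         "'; supply a non-conversion rate explicitly")
  }
  mc_sum <- sum(as.numeric(ctrl$mc))
  list(rate = mc_sum / cov_sum, mc_sum = mc_sum, cov_sum = cov_sum)
}

#' Upper-tail binomial probability
#'
#' `P(X >= mc)` for `X ~ Binomial(cov, r)`: the probability of seeing at
#' least `mc` methylated reads from pure non-conversion noise. Vectorised.
#'
#' @param mc,cov Methylated and total read counts.
#' @param r Non-conversion rate in `[0, 1)`.
#' @return P-values.
#' @export
binom_upper_tail <- function(mc, cov, r) {
  if (any(r < 0) || any(r >= 1)) stop("non-conversion rate must be in [0, 1)")
  pbinom(mc - 1, cov, r, lower.tail = FALSE)
}

#' Call per-cytosine methylation status
#'
#' Adds `p`, `q` and `call` columns to a site table. Sites with
#' `cov < min_cov` get `call = "no_call"` and are excluded from testing and
#' from the BH correction; the rest are `"methylated"` when `q < q_threshold`
#' and `"unmethylated"` otherwise.
#'
#' @param sites Site table.
#' @param r Non-conversion rate.
#' @param min_cov Minimum read coverage to test a cytosine (default 3).
#' @param q_threshold BH-adjusted significance threshold (default 0.01).
#' @return The site table with `p`, `q`, `call` columns added.
#' @export
call_methylation <- function(sites, r, min_cov = 3L, q_threshold = 0.01) {
  stopifnot(min_cov >= 1L)
  out <- data.table::as.data.table(sites)
  out[, `:=`(p = NA_real_, q = NA_real_, call = "no_call")]
  tested <- out$cov >= min_cov
  if (any(tested)) {
    pv <- binom_upper_tail(out$mc[tested], out$cov[tested], r)
    qv <- p.adjust(pv, method = "BH")
    out[tested, `:=`(p = pv, q = qv,
                     call = ifelse(qv < q_threshold, "methylated", "unmethylated"))]
  }
  out[]
}

#' Weighted methylation level over regions
#'
#' The weighted methylation level of a region is the sum of methylated read
#' counts divided by the sum of total read counts over its cytosines (both
#' strands pooled), optionally restricted to a context class. Raw counts are
#' used, not binomial calls. A region with zero pooled coverage is flagged
#' undefined (`value = NA`), never reported as 0.
#'
#' @param sites Site table.
#' @param regions A `GRanges` with an `id` metadata column, or a single
#'   region given as `GRanges` of length >= 1.
#' @param context Optional filter: a major class (`"CG"`, `"CHG"`, `"CHH"`)
#'   or a subclass (`"CWG"`, `"CCG"`, `"CWA"`, `"CHH_other"`). `NULL` pools
#'   all contexts.
#' @return A `data.table` with one row per region: `region_id`, `mc_sum`,
#'   `cov_sum`, `n_sites`, `value`, `defined`.
#' @export
weighted_methylation <- function(sites, regions, context = NULL) {
  stopifnot(methods::is(regions, "GRanges"))
  ids <- regions$id
  if (is.null(ids)) ids <- paste0("region_", seq_along(regions))
  dt <- filter_context(data.table::as.data.table(sites), context)
  hits <- site_overlaps(dt, regions)
  agg <- hits[, .(mc_sum = sum(as.numeric(mc)), cov_sum = sum(as.numeric(cov)),
                  n_sites = .N), by = region_id]
  out <- data.table::data.table(region_id = ids)
  out <- agg[out, on = "region_id"]
  out[is.na(mc_sum), `:=`(mc_sum = 0, cov_sum = 0, n_sites = 0L)]
  out[, value := ifelse(cov_sum > 0, mc_sum / cov_sum, NA_real_)]
  out[, defined := cov_sum > 0]
  out[]
}

filter_context <- function(dt, context) {
  if (is.null(context)) return(dt)
  if (all(context %in% c("CG", "CHG", "CHH"))) {
    dt[major_class %in% context]
  } else if (all(context %in% c("CWG", "CCG", "CWA", "CHH_other"))) {
    dt[subclass %in% context]
  } else {
    stop("unknown context filter: ", paste(context, collapse = ","))
  }
}

# map sites onto regions; returns the site rows with a region_id column
# (a site overlapping k regions appears k times)
site_overlaps <- function(dt, regions) {
  ids <- regions$id
  if (is.null(ids)) ids <- paste0("region_", seq_along(regions))
  sgr <- GenomicRanges::GRanges(dt$chrom, IRanges::IRanges(dt$pos, dt$pos))
  ov <- GenomicRanges::findOverlaps(sgr, regions, ignore.strand = TRUE)
  out <- dt[S4Vectors::queryHits(ov)]
  out[, region_id := ids[S4Vectors::subjectHits(ov)]]
  out
}
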