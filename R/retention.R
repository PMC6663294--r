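# Transgenerational retention of newly methylated cytosines, and the
# random-gene background CG estimator.
#
# The retention analysis follows cytosines inside a fixed region set (the
# differentially methylated regions over gain genes) that are covered in
# every sample of a generational series and carry no methylation call in
# wild type. Per context partition (CG / CHG / CHH and the CWG/CCG,
# CWA/other-CHH splits) the number of binomially-called methylated cytosines
# in each sample is reported as a ratio to a reference generation.

PARTITIONS <- list(
  CG = list(col = "major_class", val = "CG"),
  CHG = list(col = "major_class", val = "CHG"),
  CHH = list(col = "major_class", val = "CHH"),
  CWG = list(col = "subclass", val = "CWG"),
  CCG = list(col = "subclass", val = "CCG"),
  CWA = list(col = "subclass", val = "CWA"),
  CHH_other = list(col = "subclass", val = "CHH_other")
)

#' Select cytosines eligible for retention analysis
#'
#' Keeps cytosines that lie within the region set, have coverage of at least
#' `min_cov` in every series sample (wild type included), and are called
#' unmethylated in wild type. Sample tables must carry `call` columns from
#' [call_methylation()].
#'
#' @param regions `GRanges` region set (non-empty).
#' @param called_samples Named list of called site tables (the series).
#' @param wt_name Name of the wild-type sample in `called_samples`.
#' @param min_cov Minimum coverage in every sample (default 3).
#' @return A `data.table` keyed by (chrom, pos, strand) with context columns,
#'   one row per eligible cytosine.
#' @export
select_eligible_cytosines <- function(regions, called_samples, wt_name,
                                      min_cov = 3L) {
  if (!length(regions)) stop("empty region set")
  stopifnot(wt_name %in% names(called_samples))
  wt <- data.table::as.data.table(called_samples[[wt_name]])
  stopifnot("call" %in% names(wt))
  elig <- wt[call == "unmethylated" & cov >= min_cov,
             .(chrom, pos, strand, context3, major_class, subclass)]
  # restrict to the region set
  gr <- GenomicRanges::GRanges(elig$chrom, IRanges::IRanges(elig$pos, elig$pos))
  elig <- elig[IRanges::overlapsAny(gr, regions, ignore.strand = TRUE)]
  # covered in every other series sample
  for (s in setdiff(names(called_samples), wt_name)) {
    dt <- data.table::as.data.table(called_samples[[s]])
    covered <- dt[cov >= min_cov, .(chrom, pos, strand)]
    elig <- elig[covered, on = c("chrom", "pos", "strand"), nomatch = NULL]
  }
  data.table::setkeyv(elig, c("chrom", "pos", "strand"))
  elig[]
}

#' Retention ratios of methylated cytosines across a series
#'
#' For each sample and context partition, counts the eligible cytosines
#' called methylated and reports the ratio to the reference sample's count.
#' A partition with a zero reference count has an undefined ratio (`NA`).
#'
#' @param eligible Output of [select_eligible_cytosines()].
#' @param called_samples Named list of called site tables.
#' @param reference Name of the reference sample (ratio 1 by definition).
#' @return A long `data.table`: sample, partition, count, ratio.
#' @export
retention_ratios <- function(eligible, called_samples, reference) {
  stopifnot(reference %in% names(called_samples))
  counts <- lapply(names(called_samples), function(s) {
    dt <- data.table::as.data.table(called_samples[[s]])
    m <- dt[call == "methylated", .(chrom, pos, strand)]
    em <- eligible[m, on = c("chrom", "pos", "strand"), nomatch = NULL]
    data.table::data.table(
      sample = s,
      partition = names(PARTITIONS),
      count = vapply(PARTITIONS, function(p) sum(em[[p$col]] == p$val), 0L))
  })
  out <- data.table::rbindlist(counts)
  ref <- out[sample == reference, .(partition, ref_count = count)]
  out <- ref[out, on = "partition"]
  out[, ratio := ifelse(ref_count > 0, count / ref_count, NA_real_)]
  out[, .(sample, partition, count, ref_count, ratio)]
}

#' Background CG methylation over random unmethylated genes
#'
#' Draws `n_replicates` random sets of `n_genes` genes from a pool of
#' wild-type-unmethylated genes that never gained CHG methylation, takes an
#' equal amount of sequence from each gene (a window of
#' `ceiling(total_bp / n_genes)` bases, centered on the gene midpoint or
#' anchored at its 5' end, truncated to the gene), keeps CG cytosines with
#' coverage >= `min_cov` in every sample and no methylation call in wild
#' type, and reports the percent of those CG cytosines called methylated in
#' each sample. This estimates the false-call floor set by bisulfite
#' non-conversion.
#'
#' @param um_pool `GRanges` of eligible unmethylated genes (with `id`).
#' @param n_genes Genes per replicate (must not exceed the pool).
#' @param total_bp Total sequence per replicate, spread evenly across genes.
#' @param called_samples Named list of called site tables.
#' @param wt_name Wild-type sample name.
#' @param n_replicates Number of random gene sets (default 5).
#' @param seed Integer seed for the gene sampling.
#' @param min_cov Minimum coverage in every sample (default 3).
#' @param anchor `"centered"` (default) or `"five_prime"` window placement.
#' @return A `data.table`: replicate, sample, n_cg_sites, n_methylated,
#'   pct_cg.
#' @export
background_cg_estimate <- function(um_pool, n_genes, total_bp, called_samples,
                                   wt_name, n_replicates = 5L, seed = 1L,
                                   min_cov = 3L,
                                   anchor = c("centered", "five_prime")) {
  anchor <- match.arg(anchor)
  if (length(um_pool) < n_genes) {
    stop(sprintf("unmethylated gene pool (%d) smaller than n_genes (%d)",
                 length(um_pool), n_genes))
  }
  win <- ceiling(total_bp / n_genes)
  res <- list()
  set.seed(seed)
  for (rep_i in seq_len(n_replicates)) {
    sel <- um_pool[sample(length(um_pool), n_genes)]
    if (anchor == "centered") {
      mid <- floor((GenomicRanges::start(sel) + GenomicRanges::end(sel)) / 2)
      st <- pmax(GenomicRanges::start(sel), mid - floor(win / 2))
      en <- pmin(GenomicRanges::end(sel), st + win - 1L)
    } else {
      st <- GenomicRanges::start(sel)
      en <- pmin(GenomicRanges::end(sel), st + win - 1L)
    }
    windows <- GenomicRanges::GRanges(GenomicRanges::seqnames(sel),
                                      IRanges::IRanges(st, en))
    windows$id <- sel$id
    elig <- select_eligible_cytosines(windows, called_samples, wt_name,
                                      min_cov = min_cov)
    elig <- elig[major_class == "CG"]
    for (s in names(called_samples)) {
      dt <- data.table::as.data.table(called_samples[[s]])
      m <- dt[call == "methylated", .(chrom, pos, strand)]
      n_m <- nrow(elig[m, on = c("chrom", "pos", "strand"), nomatch = NULL])
      res[[length(res) + 1L]] <- data.table::data.table(
        replicate = rep_i, sample = s, n_cg_sites = nrow(elig),
        n_methylated = n_m,
        pct_cg = if (nrow(elig)) 100 * n_m / nrow(elig) else NA_real_)
    }
  }
  data.table::rbindlist(res)
}
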