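# CHG-gain gene calling and characterization.
#
# A gene is a CHG-gain gene in a given line when (i) it is essentially
# unmethylated in wild type (< 1 weighted percent in each of CG, CHG and CHH
# separately), (ii) it carries at least 10 informative CHG cytosines
# (coverage >= 5) in every sample of the coverage-harmonization group, and
# (iii) its weighted CHG methylation in the line exceeds wild type by at
# least 5 percentage points. The gene body is the full annotated span,
# introns included.

#' Call CHG-gain genes
#'
#' @param sample_sites Named list of site tables for every member of one
#'   coverage-harmonization group (wild type included); the informative-site
#'   filter is applied jointly across all members.
#' @param wt_name Name of the wild-type sample in `sample_sites`.
#' @param line_name Name of the line sample being called.
#' @param genes `GRanges` of gene features with an `id` column.
#' @param wt_max_pct Wild-type weighted percent methylation ceiling applied
#'   per context (default 1).
#' @param min_informative Minimum CHG cytosines passing the coverage filter
#'   in every group member (default 10).
#' @param informative_cov Coverage defining an informative CHG cytosine
#'   (default 5).
#' @param min_gain_pct Minimum CHG gain over wild type in percentage points
#'   (default 5).
#' @return A `data.table` with one row per gene: the wild-type percent
#'   methylation per context, line and wild-type CHG percents, the gain
#'   `delta`, the minimum informative-site count across the group, filter
#'   flags and the final `gain` call.
#' @export
call_chg_gain_genes <- function(sample_sites, wt_name, line_name, genes,
                                wt_max_pct = 1, min_informative = 10L,
                                informative_cov = 5L, min_gain_pct = 5) {
  stopifnot(wt_name %in% names(sample_sites), line_name %in% names(sample_sites))
  ids <- genes$id
  wt <- sample_sites[[wt_name]]
  out <- data.table::data.table(gene_id = ids)
  for (ctx in c("CG", "CHG", "CHH")) {
    wm <- weighted_methylation(wt, genes, context = ctx)
    out[, paste0("wt_pct_", ctx) := 100 * wm$value]
  }
  # joint informative-site filter over every sample of the coverage group
  inf_min <- rep(Inf, length(genes))
  for (s in names(sample_sites)) {
    dt <- data.table::as.data.table(sample_sites[[s]])
    dt <- dt[major_class == "CHG" & cov >= informative_cov]
    cnt <- weighted_methylation(dt, genes, context = "CHG")$n_sites
    inf_min <- pmin(inf_min, cnt)
  }
  out[, informative := as.integer(ifelse(is.finite(inf_min), inf_min, 0))]
  line_wm <- weighted_methylation(sample_sites[[line_name]], genes, context = "CHG")
  out[, line_pct := 100 * line_wm$value]
  out[, wt_pct := get("wt_pct_CHG")]
  out[, delta := line_pct - wt_pct]
  # a context with no covered sites in wild type carries no evidence of
  # methylation and passes that context's filter
  pass_ctx <- function(v) is.na(v) | v < wt_max_pct
  out[, wt_unmethylated := pass_ctx(wt_pct_CG) & pass_ctx(wt_pct_CHG) &
        pass_ctx(wt_pct_CHH)]
  out[, pass_informative := informative >= min_informative]
  out[, gain := wt_unmethylated & pass_informative &
        !is.na(delta) & delta >= min_gain_pct]
  out[]
}

#' CHG site count and frequency of a sequence
#'
#' Scans the sequence with a 3-base window at step 1 on both the given
#' strand and its reverse complement, counting windows matching C-H-G
#' (H = A, C or T). Windows containing any non-ACGT base never match.
#' Frequency is the count divided by the sequence length.
#'
#' @param seq A character scalar or [Biostrings::DNAString].
#' @return A list with `count` and `frequency`.
#' @export
chg_site_frequency <- function(seq) {
  s <- toupper(as.character(seq))
  if (nchar(s) < 3) stop("sequence must be at least 3 bases")
  list(count = count_chg_windows(s) + count_chg_windows(revcomp(s)),
       frequency = (count_chg_windows(s) + count_chg_windows(revcomp(s))) / nchar(s))
}

count_chg_windows <- function(s) {
  n <- nchar(s)
  b <- strsplit(s, "")[[1]]
  b1 <- b[1:(n - 2)]; b2 <- b[2:(n - 1)]; b3 <- b[3:n]
  sum(b1 == "C" & b2 %in% c("A", "C", "T") & b3 == "G")
}

revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  b <- strsplit(s, "")[[1]]
  m <- comp[b]
  m[is.na(m)] <- "N"
  paste(rev(unname(m)), collapse = "")
}

#' Compare characteristics of two gene sets
#'
#' For each characteristic column, a two-sided Wilcoxon rank-sum comparison
#' of the gain set against the unmethylated set (exact for small combined n,
#' normal approximation with tie correction otherwise), with group medians.
#'
#' @param gain_ids,um_ids Gene id vectors (both non-empty).
#' @param characteristics A table with a `gene_id` column plus numeric
#'   characteristic columns (e.g. length, exon_count, expression,
#'   chg_frequency).
#' @param columns Characteristic columns to compare (default: all numeric).
#' @return A `data.table`: characteristic, W statistic, p, exact flag,
#'   group medians and sizes.
#' @export
compare_characteristics <- function(gain_ids, um_ids, characteristics,
                                    columns = NULL) {
  if (!length(gain_ids) || !length(um_ids)) stop("both gene sets must be non-empty")
  ch <- data.table::as.data.table(characteristics)
  stopifnot("gene_id" %in% names(ch))
  if (is.null(columns)) {
    columns <- setdiff(names(ch)[vapply(ch, is.numeric, TRUE)], "gene_id")
  }
  g <- ch[gene_id %in% gain_ids]
  u <- ch[gene_id %in% um_ids]
  res <- lapply(columns, function(col) {
    w <- wilcoxon_rank_sum(g[[col]], u[[col]])
    data.table::data.table(
      characteristic = col, W = w$statistic, p = w$p, exact = w$exact,
      median_gain = w$median_x, median_um = w$median_y,
      n_gain = sum(!is.na(g[[col]])), n_um = sum(!is.na(u[[col]])))
  })
  data.table::rbindlist(res)
}

#' Gene-set overlap enrichment
#'
#' Upper-tail hypergeometric p of the observed intersection of two gene sets
#' drawn from a common universe.
#'
#' @param set_a,set_b Character vectors of gene ids.
#' @param universe_size Size of the gene universe.
#' @return A list with `overlap`, `p`, `log10_p`.
#' @export
gene_set_overlap_test <- function(set_a, set_b, universe_size) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (length(set_a) > universe_size || length(set_b) > universe_size) {
    stop("set larger than the universe")
  }
  k <- length(intersect(set_a, set_b))
  h <- hypergeom_upper_tail(universe_size, length(set_a), length(set_b), k)
  list(overlap = k, p = h$p, log10_p = h$log10_p)
}
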