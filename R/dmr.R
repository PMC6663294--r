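# Differential methylation: site tests, region merging, classification,
# heatmap matrix, and the interval-overlap Fisher test.
#
# The site/region stage is a deliberately simple, self-contained stand-in
# for external root-mean-square permutation DMR callers: per-site 2x2 Fisher
# exact tests on the (mc, cov - mc) counts of the two samples, BH-corrected,
# then gap-chaining of significant sites into regions. Region-level filters
# follow the study design: at least 5 differential sites per region, and
# direction calls at a minimum percent-methylation change relative to wild
# type (10 points for CHG/CHH, 20 for CG, inclusive).

#' Find differentially methylated sites between two samples
#'
#' Joins two site tables on (chrom, pos, strand), keeps sites of the
#' requested context covered at `>= min_cov` in both samples, and tests each
#' with a two-sided Fisher exact test on the 2x2 table of methylated /
#' unmethylated read counts, BH-corrected across tested sites.
#'
#' @param sites_a,sites_b Site tables ([read_allc()] layout). `sites_a` is
#'   conventionally the wild-type reference.
#' @param context Major class to test: `"CG"`, `"CHG"` or `"CHH"`.
#' @param min_cov Minimum coverage in both samples (default 3).
#' @param q_threshold BH significance threshold (default 0.01).
#' @return A `data.table` of differential sites: chrom, pos, strand,
#'   context3, subclass, mc_a, cov_a, mc_b, cov_b, p, q.
#' @export
find_dms <- function(sites_a, sites_b, context = c("CG", "CHG", "CHH"),
                     min_cov = 3L, q_threshold = 0.01) {
  context <- match.arg(context)
  a <- data.table::as.data.table(sites_a)[major_class == context & cov >= min_cov]
  b <- data.table::as.data.table(sites_b)[major_class == context & cov >= min_cov]
  if (!nrow(a) || !nrow(b)) {
    warning("context filter matched no testable sites")
    return(empty_dms())
  }
  j <- merge(a[, .(chrom, pos, strand, context3, subclass, mc_a = mc, cov_a = cov)],
             b[, .(chrom, pos, strand, mc_b = mc, cov_b = cov)],
             by = c("chrom", "pos", "strand"))
  if (!nrow(j)) {
    warning("no sites covered in both samples")
    return(empty_dms())
  }
  j[, p := fisher_p_vec(mc_a, cov_a, mc_b, cov_b)]
  j[, q := p.adjust(p, method = "BH")]
  out <- j[q < q_threshold]
  data.table::setorderv(out, c("chrom", "pos", "strand"))
  out[]
}

empty_dms <- function() {
  data.table::data.table(
    chrom = character(), pos = integer(), strand = character(),
    context3 = character(), subclass = character(),
    mc_a = integer(), cov_a = integer(), mc_b = integer(), cov_b = integer(),
    p = numeric(), q = numeric())
}

# vectorised two-sided Fisher p over many (mc1,cov1,mc2,cov2) sites;
# memoised over unique count tuples since read depths repeat heavily
fisher_p_vec <- function(mc1, cov1, mc2, cov2) {
  key <- paste(mc1, cov1, mc2, cov2, sep = "_")
  uk <- !duplicated(key)
  pu <- vapply(which(uk), function(i) {
    fisher_exact_2x2(matrix(c(mc1[i], cov1[i] - mc1[i],
                              mc2[i], cov2[i] - mc2[i]), 2, 2, byrow = TRUE))$p
  }, numeric(1))
  unname(pu[match(key, key[uk])])
}

#' Merge differential sites into regions
#'
#' Chains consecutive differential sites of one context on the same contig
#' whose inter-site distance is at most `max_gap` into a single region
#' spanning the first to the last site; regions with fewer than `min_dms`
#' sites are dropped. Output regions are disjoint and ordered, and every
#' retained site lies in exactly one region.
#'
#' @param dms Differential-site table from [find_dms()].
#' @param max_gap Maximum distance between consecutive sites (bp, default 250).
#' @param min_dms Minimum sites per region (default 5).
#' @param context Context label recorded on the regions.
#' @return A `GRanges` (feature_class `"DMR"`) with `id`, `n_dms`, `context`.
#' @export
merge_dms_to_dmrs <- function(dms, max_gap = 250L, min_dms = 5L,
                              context = NA_character_) {
  dms <- data.table::as.data.table(dms)
  if (!nrow(dms)) {
    return(GenomicRanges::GRanges(id = character(), feature_class = character(),
                                  n_dms = integer(), context = character()))
  }
  data.table::setorderv(dms, c("chrom", "pos"))
  dms[, gap := c(Inf, diff(pos)), by = chrom]
  dms[, grp := cumsum(gap > max_gap), by = chrom]
  reg <- dms[, .(start = min(pos), end = max(pos), n_dms = .N),
             by = .(chrom, grp)]
  reg <- reg[n_dms >= min_dms]
  gr <- GenomicRanges::GRanges(reg$chrom, IRanges::IRanges(reg$start, reg$end))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    id = sprintf("DMR_%s_%d_%d", reg$chrom, reg$start, reg$end),
    feature_class = rep("DMR", nrow(reg)),
    n_dms = reg$n_dms,
    context = rep(context, nrow(reg)))
  sort(gr)
}

#' Classify region direction and genomic overlap
#'
#' Direction is relative to wild type on weighted percent methylation:
#' `hyper` when (other - wt) is at least the cutoff in percentage points,
#' `hypo` at or below its negative, else `unclassified`; regions with
#' undefined weighted methylation in either sample are flagged `NA` and
#' excluded from direction classification. Overlap class uses the precedence
#' gene > repeat > intergenic at >= 1 bp overlap.
#'
#' @param dmrs `GRanges` from [merge_dms_to_dmrs()].
#' @param sites_wt,sites_other Site tables of the two samples.
#' @param features Annotation `GRanges` with a `feature_class` column
#'   (classes `gene` and `repeat` are used).
#' @param context Context whose weighted methylation is compared.
#' @param cutoffs Named percent-point cutoffs per context
#'   (default CG 20, CHG 10, CHH 10).
#' @return The input `GRanges` with `wt_pct`, `other_pct`, `delta_pct`,
#'   `direction`, `overlap_class` metadata columns added.
#' @export
classify_and_annotate_dmrs <- function(dmrs, sites_wt, sites_other, features,
                                       context,
                                       cutoffs = c(CG = 20, CHG = 10, CHH = 10)) {
  stopifnot(context %in% names(cutoffs))
  cut <- cutoffs[[context]]
  wt <- weighted_methylation(sites_wt, dmrs, context = context)
  ot <- weighted_methylation(sites_other, dmrs, context = context)
  wt_pct <- 100 * wt$value
  other_pct <- 100 * ot$value
  delta <- other_pct - wt_pct
  direction <- ifelse(is.na(delta), NA_character_,
                      ifelse(delta >= cut, "hyper",
                             ifelse(delta <= -cut, "hypo", "unclassified")))
  genes <- features[features$feature_class == "gene"]
  reps <- features[features$feature_class == "repeat"]
  ov_gene <- IRanges::overlapsAny(dmrs, genes, ignore.strand = TRUE)
  ov_rep <- IRanges::overlapsAny(dmrs, reps, ignore.strand = TRUE)
  overlap_class <- ifelse(ov_gene, "genic", ifelse(ov_rep, "repeat", "intergenic"))
  out <- dmrs
  S4Vectors::mcols(out) <- cbind(S4Vectors::mcols(dmrs), S4Vectors::DataFrame(
    wt_pct = wt_pct, other_pct = other_pct, delta_pct = delta,
    direction = direction, overlap_class = overlap_class))
  out
}

#' Region-by-sample weighted methylation matrix for heatmaps
#'
#' Rows are regions carrying, in every sample, at least `min_sites` cytosines
#' of the context covered at `>= min_cov`; rows are ordered by ascending
#' wild-type weighted percent methylation. Values are weighted percent
#' methylation in `[0, 100]`.
#'
#' @param dmrs `GRanges` of regions with an `id` column.
#' @param sample_sites Named list of site tables; `wt_name` must be a member.
#' @param wt_name Name of the wild-type reference sample.
#' @param context Context class (default `"CHG"`).
#' @param min_sites,min_cov Row-inclusion coverage filter (defaults 5 and 3).
#' @return A numeric matrix (regions x samples), possibly with 0 rows.
#' @export
dmr_heatmap_matrix <- function(dmrs, sample_sites, wt_name, context = "CHG",
                               min_sites = 5L, min_cov = 3L) {
  stopifnot(wt_name %in% names(sample_sites))
  ids <- dmrs$id
  keep <- rep(TRUE, length(dmrs))
  vals <- matrix(NA_real_, nrow = length(dmrs), ncol = length(sample_sites),
                 dimnames = list(ids, names(sample_sites)))
  for (s in names(sample_sites)) {
    dt <- filter_context(data.table::as.data.table(sample_sites[[s]]), context)
    dt <- dt[cov >= min_cov]
    wm <- weighted_methylation(dt, dmrs, context = context)
    keep <- keep & wm$n_sites >= min_sites & wm$defined
    vals[, s] <- 100 * wm$value
  }
  if (!any(keep)) {
    warning("no region passes the coverage filter in all samples")
    return(vals[integer(0), , drop = FALSE])
  }
  vals <- vals[keep, , drop = FALSE]
  vals[order(vals[, wt_name]), , drop = FALSE]
}

#' Interval-overlap Fisher test
#'
#' Association between two interval sets on a shared genome. Both sets are
#' merged to non-overlapping intervals; the 2x2 table is built from interval
#' counts: `a` = merged A intervals overlapping at least one B interval,
#' `b` = A intervals not overlapping, `c` = B intervals not overlapped by A,
#' `d` = max(0, genome_length / mean_interval_length - a - b - c), where the
#' mean interval length is taken over all merged A and B intervals. The p is
#' the two-sided Fisher exact p of that table. This interval-count table is
#' a documented approximation of base-resolution contingency constructions.
#'
#' @param set_a,set_b `GRanges` interval sets.
#' @param genome_length Total genome length (bp).
#' @return A list with `table` (2x2), `p`, `odds_ratio`.
#' @export
interval_overlap_fisher <- function(set_a, set_b, genome_length) {
  a_m <- GenomicRanges::reduce(set_a, ignore.strand = TRUE)
  b_m <- GenomicRanges::reduce(set_b, ignore.strand = TRUE)
  span <- sum(GenomicRanges::width(GenomicRanges::reduce(c(a_m, b_m))))
  if (genome_length < span) {
    stop("genome_length smaller than the total interval span")
  }
  a_hit <- IRanges::overlapsAny(a_m, b_m, ignore.strand = TRUE)
  b_hit <- IRanges::overlapsAny(b_m, a_m, ignore.strand = TRUE)
  a <- sum(a_hit)
  b <- sum(!a_hit)
  cc <- sum(!b_hit)
  mean_len <- mean(c(GenomicRanges::width(a_m), GenomicRanges::width(b_m)))
  d <- max(0, round(genome_length / mean_len) - a - b - cc)
  tab <- matrix(c(a, b, cc, d), 2, 2, byrow = TRUE,
                dimnames = list(c("A", "not A"), c("B", "not B")))
  ft <- fisher_exact_2x2(tab)
  list(table = tab, p = ft$p, odds_ratio = ft$odds_ratio)
}
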