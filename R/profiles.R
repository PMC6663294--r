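# Binned metaplots over features, ChIP metaplots, and peak merging.
#
# Methylation metaplots use the study's binning: 1 kb flanks split into 20
# bins each and the feature body split into 20 near-equal bins (the
# remainder of length mod 20 is spread one base at a time over the first
# body bins). Minus-strand features are mirrored so bin 1 is always the
# distal 5' flank. Per-bin values are weighted methylation levels pooled
# over all features (sum mc / sum cov), so deep and shallow features
# contribute by reads, not equally.

#' Binned methylation metaplot over features
#'
#' @param features `GRanges` of features; `*` strands are treated as `+`.
#' @param sites Site table.
#' @param context Optional context filter (major class or subclass).
#' @param flank Flank size in bp (default 1000).
#' @param bins Bins per zone (flank/body/flank, default 20).
#' @return A `data.table` with `bin` (1..3*bins), `zone`
#'   (upstream/body/downstream in 5'->3' feature orientation), `mc_sum`,
#'   `cov_sum`, `n_sites`, `value` (NA where no coverage), plus an
#'   `n_features`/`n_skipped` attribute pair (features shorter than `bins`
#'   cannot be partitioned and are skipped).
#' @export
methylation_metaplot <- function(features, sites, context = NULL,
                                 flank = 1000L, bins = 20L) {
  stopifnot(methods::is(features, "GRanges"))
  w <- GenomicRanges::width(features)
  skip <- w < bins
  feats <- features[!skip]
  if (!length(feats)) stop("no feature long enough to partition into body bins")
  bin_gr <- metaplot_bins(feats, flank = flank, bins = bins)
  dt <- filter_context(data.table::as.data.table(sites), context)
  sgr <- GenomicRanges::GRanges(dt$chrom, IRanges::IRanges(dt$pos, dt$pos))
  ov <- GenomicRanges::findOverlaps(sgr, bin_gr, ignore.strand = TRUE)
  hit <- data.table::data.table(
    bin = bin_gr$bin[S4Vectors::subjectHits(ov)],
    mc = dt$mc[S4Vectors::queryHits(ov)],
    cov = dt$cov[S4Vectors::queryHits(ov)])
  agg <- hit[, .(mc_sum = sum(as.numeric(mc)), cov_sum = sum(as.numeric(cov)),
                 n_sites = .N), by = bin]
  out <- data.table::data.table(bin = seq_len(3L * bins))
  out <- agg[out, on = "bin"]
  out[is.na(mc_sum), `:=`(mc_sum = 0, cov_sum = 0, n_sites = 0L)]
  out[, zone := rep(c("upstream", "body", "downstream"), each = bins)]
  out[, value := ifelse(cov_sum > 0, mc_sum / cov_sum, NA_real_)]
  data.table::setorderv(out, "bin")
  data.table::setattr(out, "n_features", length(feats))
  data.table::setattr(out, "n_skipped", sum(skip))
  out[]
}

# one GRanges of 3*bins bins per feature, bin numbered in 5'->3' feature
# orientation (mirrored for minus-strand features)
metaplot_bins <- function(feats, flank, bins) {
  n <- length(feats)
  st <- GenomicRanges::start(feats)
  en <- GenomicRanges::end(feats)
  w <- en - st + 1L
  minus <- as.character(GenomicRanges::strand(feats)) == "-"
  chroms <- as.character(GenomicRanges::seqnames(feats))
  res <- vector("list", n)
  for (i in seq_len(n)) {
    body <- bin_breaks(st[i], en[i], bins)
    fl <- flank %/% bins
    up <- data.table::data.table(
      start = st[i] - flank + (seq_len(bins) - 1L) * fl,
      end = st[i] - flank + seq_len(bins) * fl - 1L)
    down <- data.table::data.table(
      start = en[i] + 1L + (seq_len(bins) - 1L) * fl,
      end = en[i] + seq_len(bins) * fl)
    all <- rbind(up, body, down)
    bin_id <- seq_len(3L * bins)
    if (minus[i]) bin_id <- rev(bin_id)
    res[[i]] <- data.table::data.table(chrom = chroms[i], all, bin = bin_id)
  }
  d <- data.table::rbindlist(res)
  d <- d[start <= end & end >= 1L]
  gr <- GenomicRanges::GRanges(d$chrom, IRanges::IRanges(pmax(1L, d$start), d$end))
  gr$bin <- d$bin
  gr
}

# partition [st, en] into `bins` half-open slices; the first (len %% bins)
# bins carry one extra base
bin_breaks <- function(st, en, bins) {
  len <- en - st + 1L
  base <- len %/% bins
  extra <- len %% bins
  sizes <- rep(base, bins) + c(rep(1L, extra), rep(0L, bins - extra))
  ends <- st - 1L + cumsum(sizes)
  data.table::data.table(start = c(st, head(ends, -1L) + 1L), end = ends)
}

#' Four-bin ChIP metaplot
#'
#' Averages per-locus window read counts over the four canonical windows
#' (2 kb upstream, 2 kb inward from the start, 2 kb inward from the end,
#' 2 kb downstream): per-bin value = sum of reads in the bin over all loci,
#' divided by (library size x locus count).
#'
#' @param window_counts A numeric matrix or data.frame, loci x 4 windows.
#' @param library_size Total mapped reads of the library (> 0).
#' @return A numeric vector of 4 normalized bin values.
#' @export
chip_metaplot <- function(window_counts, library_size) {
  m <- as.matrix(window_counts)
  if (ncol(m) != 4L) stop("window_counts must have exactly 4 columns")
  if (!nrow(m)) stop("zero loci")
  if (library_size <= 0) stop("library_size must be positive")
  colSums(m) / (library_size * nrow(m))
}

#' The four ChIP metaplot windows of each locus
#'
#' 2 kb upstream, 2 kb inward from the 5' end, 2 kb inward from the 3' end
#' and 2 kb downstream, in 5'->3' orientation. For loci shorter than 4 kb
#' the two inward windows are truncated at the locus midpoint so they never
#' overlap.
#'
#' @param loci `GRanges`.
#' @param window Window size in bp (default 2000).
#' @return A list of 4 `GRanges`, one per window, parallel to `loci`.
#' @export
chip_windows <- function(loci, window = 2000L) {
  st <- GenomicRanges::start(loci)
  en <- GenomicRanges::end(loci)
  minus <- as.character(GenomicRanges::strand(loci)) == "-"
  mid <- (st + en) %/% 2L
  chrom <- as.character(GenomicRanges::seqnames(loci))
  mk <- function(s, e) GenomicRanges::GRanges(
    chrom, IRanges::IRanges(pmax(1L, pmin(s, e)), pmax(1L, pmax(s, e))))
  up <- mk(ifelse(minus, en + 1L, st - window), ifelse(minus, en + window, st - 1L))
  into5 <- mk(ifelse(minus, pmax(mid + 1L, en - window + 1L), st),
              ifelse(minus, en, pmin(mid, st + window - 1L)))
  into3 <- mk(ifelse(minus, st, pmax(mid + 1L, en - window + 1L)),
              ifelse(minus, pmin(mid, st + window - 1L), en))
  down <- mk(ifelse(minus, st - window, en + 1L), ifelse(minus, st - 1L, en + window))
  list(upstream = up, into_start = into5, into_end = into3, downstream = down)
}

#' Merge book-ended peaks and filter by read density
#'
#' Overlapping or directly adjacent peaks are merged into single regions,
#' their read counts summed; regions are kept when reads / length strictly
#' exceeds `min_density`.
#'
#' @param peaks `GRanges` of peaks.
#' @param counts Non-negative read counts parallel to `peaks`.
#' @param min_density Density threshold (default 0.05, strict).
#' @return A `GRanges` of merged, filtered regions with `reads` and
#'   `density` columns.
#' @export
merge_and_filter_peaks <- function(peaks, counts, min_density = 0.05) {
  if (any(counts < 0)) stop("negative read counts")
  stopifnot(length(peaks) == length(counts))
  merged <- GenomicRanges::reduce(peaks, ignore.strand = TRUE)
  ov <- GenomicRanges::findOverlaps(peaks, merged, ignore.strand = TRUE)
  reads <- as.numeric(tapply(counts[S4Vectors::queryHits(ov)],
                             S4Vectors::subjectHits(ov), sum))
  merged$reads <- reads
  merged$density <- reads / GenomicRanges::width(merged)
  merged[merged$density > min_density]
}
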