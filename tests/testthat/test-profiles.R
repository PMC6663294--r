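test_that("body bins partition the feature with the remainder on leading bins", {
  br <- gbminit:::bin_breaks(1L, 47L, 20L)
  expect_equal(nrow(br), 20L)
  expect_equal(br$start[1], 1L)
  expect_equal(br$end[20], 47L)
  w <- br$end - br$start + 1L
  expect_equal(sum(w), 47L)
  expect_equal(w, c(rep(3L, 7), rep(2L, 13)))  # 47 = 7*3 + 13*2
  expect_true(all(br$start[-1] == br$end[-20] + 1L))
})

test_that("uniform methylation produces a flat metaplot", {
  pos <- seq(1, 12000, by = 7)
  sites <- make_sites("chr1", pos, "+", "CAG", 5L, 10L)
  feats <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(3000, 7000), width = 2000),
                                  strand = c("+", "-"), id = c("a", "b"))
  mp <- methylation_metaplot(feats, sites, context = "CHG")
  expect_equal(nrow(mp), 60L)
  expect_true(all(abs(mp$value - 0.5) < 1e-12))
  expect_equal(unique(mp$zone), c("upstream", "body", "downstream"))
})

test_that("5'-biased methylation lands in leading body bins and mirrors with strand", {
  len <- 2000L
  st <- 5000L
  pos <- seq(st, st + len - 1L, by = 5)
  in_5prime_half <- pos < st + len / 2
  mk <- function(strand_of_feature) {
    # methylation confined to the reference-left half of the feature
    sites <- make_sites("chr1", pos, "+", "CAG",
                        ifelse(in_5prime_half, 8L, 0L), 10L)
    feat <- GenomicRanges::GRanges("chr1", IRanges::IRanges(st, st + len - 1L),
                                   strand = strand_of_feature, id = "g")
    methylation_metaplot(feat, sites, context = "CHG")
  }
  plus <- mk("+")
  body_plus <- plus[plus$zone == "body", ]
  expect_true(all(body_plus$value[1:10] > 0.7))
  expect_true(all(body_plus$value[11:20] < 0.1))
  # the same physical signal on a minus-strand feature appears 3'-biased
  minus <- mk("-")
  body_minus <- minus[minus$zone == "body", ]
  expect_equal(body_minus$value, rev(body_plus$value))
  # and the full 60-bin profile is the reverse of the plus profile
  expect_equal(minus$value, rev(plus$value))
})

test_that("bins without covered sites are undefined, not zero", {
  sites <- make_sites("chr1", 5000L, "+", "CAG", 5L, 10L)
  feat <- GenomicRanges::GRanges("chr1", IRanges::IRanges(4900, 5100), id = "g")
  mp <- methylation_metaplot(feat, sites, context = "CHG")
  expect_true(any(is.na(mp$value)))
  expect_false(any(mp$value == 0, na.rm = TRUE))
})

test_that("features shorter than the bin count are skipped with a counter", {
  sites <- make_sites("chr1", 100L, "+", "CAG", 1L, 2L)
  feats <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(50, 500), c(600, 510)),
                                  id = c("long", "short"))
  mp <- methylation_metaplot(feats, sites)
  expect_equal(attr(mp, "n_features"), 1L)
  expect_equal(attr(mp, "n_skipped"), 1L)
  expect_error(methylation_metaplot(feats[2], sites), "long enough")
})

test_that("ChIP metaplot normalizes by library size and locus count", {
  counts <- matrix(c(10, 20, 30, 40,
                     10, 20, 30, 40,
                     10, 20, 30, 40), nrow = 3, byrow = TRUE)
  got <- chip_metaplot(counts, library_size = 1000)
  expect_equal(got, c(30, 60, 90, 120) / (1000 * 3), ignore_attr = TRUE)
  # uniform coverage: equal bins
  expect_equal(length(unique(chip_metaplot(matrix(7, 5, 4), 100))), 1L)
  # joint rescaling of counts and library size is invariant
  expect_equal(chip_metaplot(counts * 2, 2000), got, ignore_attr = TRUE)
  expect_error(chip_metaplot(counts[, 1:3], 100), "4 columns")
  expect_error(chip_metaplot(counts[0, ], 100), "zero loci")
  expect_error(chip_metaplot(counts, 0), "positive")
})

test_that("inward ChIP windows truncate at the midpoint for short loci", {
  locus <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10001, 11000),
                                  strand = "+", id = "g")
  w <- chip_windows(locus)
  expect_equal(GenomicRanges::start(w$upstream), 8001L)
  expect_equal(GenomicRanges::end(w$upstream), 10000L)
  # 1 kb locus: the two inward windows share no base
  ov <- GenomicRanges::intersect(w$into_start, w$into_end)
  expect_equal(sum(GenomicRanges::width(ov)), 0L)
  expect_equal(GenomicRanges::end(w$into_start), 10500L)
  expect_equal(GenomicRanges::start(w$into_end), 10501L)
})

test_that("peak merging is book-ended, idempotent and strict on density", {
  peaks <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(100, 200, 1000),
                                                           c(199, 299, 1999)))
  merged <- merge_and_filter_peaks(peaks, counts = c(30, 31, 40), min_density = 0.05)
  # [100,199] and [200,299] are book-ended: one region [100,299] with 61 reads
  expect_equal(GenomicRanges::start(merged), 100L)
  expect_equal(GenomicRanges::end(merged), 299L)
  expect_equal(merged$reads, 61)
  # the 1 kb region with 40 reads (density 0.04) is dropped; 0.06 is kept
  kept <- merge_and_filter_peaks(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(1000, 1999)), 60)
  expect_length(kept, 1L)
  dropped <- merge_and_filter_peaks(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(1000, 1999)), 40)
  expect_length(dropped, 0L)
  # exactly at the threshold is dropped (strictly greater than)
  at <- merge_and_filter_peaks(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(1000, 1999)), 50)
  expect_length(at, 0L)
  # idempotence: merging the merged set changes nothing
  again <- merge_and_filter_peaks(merged, merged$reads, min_density = 0.05)
  expect_equal(GenomicRanges::ranges(again), GenomicRanges::ranges(merged))
  expect_error(merge_and_filter_peaks(peaks, c(-1, 2, 3)), "negative")
})
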