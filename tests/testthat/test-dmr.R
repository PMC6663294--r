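test_that("differential sites require divergent counts at sufficient coverage", {
  a <- make_sites("chr1", c(10, 20, 30), "+", "CAG",
                  c(0, 0, 1), c(20, 20, 2))
  b <- make_sites("chr1", c(10, 20, 30), "+", "CAG",
                  c(0, 20, 2), c(20, 20, 2))
  dms <- find_dms(a, b, context = "CHG", q_threshold = 0.05)
  # identical counts at pos 10 -> p = 1; cov 2 at pos 30 -> not tested
  expect_equal(dms$pos, 20L)
  expect_equal(dms$p, 2 / choose(40, 20), tolerance = 1e-12)
})

test_that("differential sites chain into regions with the minimum-site filter", {
  mk_dms <- function(pos) data.table::data.table(
    chrom = "chr1", pos = as.integer(pos), strand = "+",
    context3 = "CAG", subclass = "CWG",
    mc_a = 0L, cov_a = 20L, mc_b = 20L, cov_b = 20L, p = 1e-10, q = 1e-9)
  one <- merge_dms_to_dmrs(mk_dms(seq(100, by = 50, length.out = 5)),
                           max_gap = 250, context = "CHG")
  expect_length(one, 1L)
  expect_equal(one$n_dms, 5L)
  expect_equal(GenomicRanges::start(one), 100L)
  expect_equal(GenomicRanges::end(one), 300L)
  none <- merge_dms_to_dmrs(mk_dms(seq(100, by = 50, length.out = 4)))
  expect_length(none, 0L)
  two <- merge_dms_to_dmrs(mk_dms(c(seq(100, by = 50, length.out = 5),
                                    seq(600, by = 50, length.out = 5))),
                           max_gap = 250)
  expect_length(two, 2L)
  # disjoint, ordered, and each retained site in exactly one region
  pos <- c(seq(100, by = 50, length.out = 5), seq(600, by = 50, length.out = 5))
  hits <- GenomicRanges::countOverlaps(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(pos, pos)), two)
  expect_true(all(hits == 1L))
  expect_true(all(GenomicRanges::width(GenomicRanges::reduce(two)) ==
                    GenomicRanges::width(two)))
})

test_that("direction cutoffs are inclusive and antisymmetric", {
  # one region; wt 2% vs line 12% CHG = exactly +10 points
  n <- 20
  wt <- make_sites("chr1", seq(10, by = 10, length.out = n), "+", "CAG",
                   rep(c(0, 1), c(n / 2, n / 2)), rep(50, n))   # 10/1000 = 1%... build exact:
  wt[, mc := 1L]  # 20/1000 = 2%
  line <- data.table::copy(wt)[, mc := 6L]  # 120/1000 = 12%
  region <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 500), id = "r",
                                   n_dms = 5L)
  feats <- GenomicRanges::GRanges("chr1", IRanges::IRanges(600, 700),
                                  id = "g1", feature_class = "gene")
  ann <- classify_and_annotate_dmrs(region, wt, line, feats, "CHG")
  expect_equal(ann$delta_pct, 10)
  expect_equal(ann$direction, "hyper")  # 10 points is inclusive for CHG
  expect_equal(ann$overlap_class, "intergenic")
  # swapping samples flips hyper <-> hypo
  rev <- classify_and_annotate_dmrs(region, line, wt, feats, "CHG")
  expect_equal(rev$direction, "hypo")
  # a 15-point change is below the 20-point CG cutoff
  line15 <- data.table::copy(wt)[, `:=`(context3 = "CGA", mc = 8L)]  # 17%... set wt too
  wt_cg <- data.table::copy(wt)[, context3 := "CGA"]
  lab <- classify_context_string(wt_cg$context3)
  wt_cg[, `:=`(major_class = lab$major_class, subclass = lab$subclass, mc = 1L)]
  line_cg <- data.table::copy(wt_cg)[, mc := 8L]  # 2% -> 16%: delta 14 < 20
  ann_cg <- classify_and_annotate_dmrs(region, wt_cg, line_cg, feats, "CG")
  expect_equal(ann_cg$direction, "unclassified")
})

test_that("overlap class precedence is gene over repeat over intergenic", {
  dmr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100, 200), id = "d")
  feats <- c(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(150, 300),
                           id = "g", feature_class = "gene"),
    GenomicRanges::GRanges("chr1", IRanges::IRanges(90, 160),
                           id = "r", feature_class = "repeat"))
  sites <- make_sites("chr1", c(120, 180), "+", "CAG", c(0, 5), c(10, 10))
  ann <- classify_and_annotate_dmrs(dmr, sites, sites, feats, "CHG")
  expect_equal(ann$overlap_class, "genic")
})

test_that("heatmap matrix applies the per-sample coverage filter and wild-type order", {
  pos <- seq(10, by = 10, length.out = 6)
  wt <- make_sites("chr1", c(pos, pos + 1000), "+", "CAG",
                   c(rep(0L, 5), 1L, rep(1L, 6)), rep(20L, 12))
  s2 <- data.table::copy(wt)[, mc := rep(c(3L, 10L), each = 6)]
  # third sample misses coverage in region B (cov 2 < 3)
  s3 <- data.table::copy(wt)
  s3[pos >= 1000, cov := 2L]
  regions <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 1001), c(999, 1999)),
                                    id = c("A", "B"))
  m <- dmr_heatmap_matrix(regions, list(WT = wt, L1 = s2, L2 = s3), "WT")
  expect_equal(rownames(m), "A")  # B fails the filter in sample L2
  expect_true(all(m >= 0 & m <= 100))
  # ordering: with both regions covered, rows sort ascending by WT value
  m2 <- dmr_heatmap_matrix(regions, list(WT = wt, L1 = s2), "WT")
  expect_equal(rownames(m2), c("A", "B"))  # WT: A ~0.8%, B 5%
  expect_true(m2["A", "WT"] < m2["B", "WT"])
})

test_that("interval-overlap Fisher reproduces the enumerated toy instance", {
  A <- GenomicRanges::GRanges("c", IRanges::IRanges(c(100, 2000, 5000), width = 100))
  B <- GenomicRanges::GRanges("c", IRanges::IRanges(c(150, 7000, 9000), width = 100))
  got <- interval_overlap_fisher(A, B, genome_length = 10000)
  expect_equal(as.vector(got$table), c(1, 2, 2, 95))
  # oracle: enumerate the hypergeometric support of the 2x2 table
  expect_equal(got$p, oracle_fisher_two_sided(got$table), tolerance = 1e-12)
  expect_equal(got$p, 0.088188, tolerance = 1e-5)
  # identical sets: perfect association, minimal p for the margins
  same <- interval_overlap_fisher(A, A, genome_length = 10000)
  expect_equal(as.vector(same$table)[1:3], c(3, 0, 0))
  # disjoint small sets on a large genome: no association
  far <- interval_overlap_fisher(A, GenomicRanges::shift(B, 40000),
                                 genome_length = 1e6)
  expect_gt(far$p, 0.5)
  expect_error(interval_overlap_fisher(A, B, genome_length = 500), "span")
})

test_that("a planted hypermethylated block is recovered as one hyper region", {
  # CHG sites every 20 bp; block 2000-3000 methylated only in the line
  pos <- seq(100, 5000, by = 20)
  in_block <- pos >= 2000 & pos <= 3000
  set.seed(10)
  cov_a <- rpois(length(pos), 20) + 3L
  cov_b <- rpois(length(pos), 20) + 3L
  wt <- make_sites("chr1", pos, "+", "CTG", rbinom(length(pos), cov_a, 0.005), cov_a)
  line <- make_sites("chr1", pos, "+", "CTG",
                     rbinom(length(pos), cov_b, ifelse(in_block, 0.7, 0.005)), cov_b)
  dms <- find_dms(wt, line, context = "CHG")
  dmrs <- merge_dms_to_dmrs(dms, max_gap = 250, context = "CHG")
  expect_length(dmrs, 1L)
  planted_dms_covered <- mean(
    pos[in_block] >= GenomicRanges::start(dmrs) &
      pos[in_block] <= GenomicRanges::end(dmrs))
  expect_gte(planted_dms_covered, 0.9)
  feats <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10),
                                  id = "x", feature_class = "gene")
  ann <- classify_and_annotate_dmrs(dmrs, wt, line, feats, "CHG")
  expect_equal(ann$direction, "hyper")
})
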