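# Fixture: three genes on one contig with hand-built count tables.
#  geneA [1, 1000]   : unmethylated in WT, strong CHG gain in the line
#  geneB [2001, 3000]: WT CG methylation 1.2% -> fails the <1% filter
#  geneC [4001, 5000]: only 9 informative CHG sites -> fails site filter
gain_fixture <- function() {
  mk <- function(start, n, ctx, mc_wt, mc_line, cov = 10L) {
    pos <- seq(start, by = 10L, length.out = n)
    list(wt = make_sites("chr1", pos, "+", ctx, mc_wt, cov),
         line = make_sites("chr1", pos, "+", ctx, mc_line, cov))
  }
  a_chg <- mk(10, 12, "CAG", 0L, 2L)        # line 20%, wt 0%
  a_cg <- mk(11, 12, "CGA", 0L, 0L)
  b_chg <- mk(2010, 12, "CAG", 0L, 2L)      # line gains...
  b_cg <- mk(2011, 25, "CGA", c(rep(0L, 22), 1L, 1L, 1L), 0L)  # wt CG 3/250 = 1.2%
  c_chg <- mk(4010, 9, "CAG", 0L, 3L)       # 9 informative sites only
  wt <- data.table::rbindlist(list(a_chg$wt, a_cg$wt, b_chg$wt, b_cg$wt, c_chg$wt))
  line <- data.table::rbindlist(list(a_chg$line, a_cg$line, b_chg$line,
                                     b_cg$line, c_chg$line))
  data.table::setkeyv(wt, c("chrom", "pos", "strand"))
  data.table::setkeyv(line, c("chrom", "pos", "strand"))
  genes <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1, 2001, 4001), c(1000, 3000, 5000)),
    id = c("geneA", "geneB", "geneC"))
  list(samples = list(WT = wt, L = line), genes = genes)
}

test_that("gain calling applies the wild-type, informative-site and gain filters", {
  fx <- gain_fixture()
  res <- call_chg_gain_genes(fx$samples, "WT", "L", fx$genes,
                             min_informative = 10L, informative_cov = 5L)
  expect_equal(res$gene_id, c("geneA", "geneB", "geneC"))
  expect_equal(res$gain, c(TRUE, FALSE, FALSE))
  # geneA passes every filter by construction
  expect_equal(res$delta[1], 20)
  # geneB is excluded by wild-type CG at 1.2% despite a 20-point CHG gain
  expect_equal(res$wt_pct_CG[2], 1.2)
  expect_false(res$wt_unmethylated[2])
  expect_equal(res$delta[2], 20)
  # geneC is excluded by the informative-site count
  expect_equal(res$informative[3], 9L)
  expect_false(res$pass_informative[3])
})

test_that("the informative-site filter is joint over the coverage group", {
  fx <- gain_fixture()
  # add a third sample with low coverage on geneA's CHG sites
  third <- data.table::copy(fx$samples$WT)
  third[pos <= 1000 & major_class == "CHG", cov := 4L]
  res <- call_chg_gain_genes(c(fx$samples, list(X = third)), "WT", "L", fx$genes)
  expect_false(res$gain[1])  # geneA now fails the joint filter
})

test_that("the gain set shrinks monotonically as thresholds tighten", {
  sim <- small_study()
  genes <- sim$reference$features[sim$reference$features$feature_class == "gene"]
  base <- call_chg_gain_genes(sim$allc, "WT", "T4", genes)
  stricter <- list(
    call_chg_gain_genes(sim$allc, "WT", "T4", genes, min_gain_pct = 15),
    call_chg_gain_genes(sim$allc, "WT", "T4", genes, min_informative = 40L),
    call_chg_gain_genes(sim$allc, "WT", "T4", genes, informative_cov = 12L),
    call_chg_gain_genes(sim$allc, "WT", "T4", genes, wt_max_pct = 0.5))
  for (s in stricter) {
    expect_true(all(s$gene_id[s$gain] %in% base$gene_id[base$gain]))
  }
})

test_that("CHG window counting covers both strands and skips N windows", {
  expect_equal(chg_site_frequency("CAGCTG")$count, 4L)  # palindromic
  expect_equal(chg_site_frequency("CAGCTG")$frequency, 4 / 6)
  expect_equal(chg_site_frequency("AAAAAA")$count, 0L)
  expect_equal(chg_site_frequency("CCG")$count, 1L)  # revcomp CGG no match
  expect_equal(chg_site_frequency("CNGCAG")$count,
               chg_site_frequency("TTTCAG")$count)
  expect_error(chg_site_frequency("CA"), "at least 3")
})

test_that("window counts agree with a pattern-matching oracle on random sequence", {
  set.seed(12)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
    got <- chg_site_frequency(s)$count
    d <- Biostrings::DNAString(s)
    oracle <- Biostrings::countPattern("CHG", d, fixed = FALSE) +
      Biostrings::countPattern("CHG", Biostrings::reverseComplement(d), fixed = FALSE)
    expect_equal(got, oracle)
  }
})

test_that("characteristics comparison reports exact Wilcoxon results per column", {
  ch <- data.table::data.table(
    gene_id = paste0("g", 1:6),
    length = c(1, 2, 3, 10, 11, 12),
    expression = c(5, 5, 5, 5, 5, 5))
  res <- compare_characteristics(paste0("g", 1:3), paste0("g", 4:6), ch)
  expect_equal(res[res$characteristic == "length", ]$p, 0.1)
  expect_equal(res[res$characteristic == "expression", ]$p, 1)
  expect_equal(res[res$characteristic == "length", ]$median_gain, 2)
  expect_error(compare_characteristics(character(), paste0("g", 4:6), ch),
               "non-empty")
})

test_that("gene-set overlap enrichment follows the hypergeometric tail", {
  ids <- paste0("g", 1:5)
  same <- gene_set_overlap_test(ids, ids, universe_size = 100)
  expect_equal(same$p, 1 / choose(100, 5), tolerance = 1e-12)
  none <- gene_set_overlap_test(ids, paste0("h", 1:5), universe_size = 100)
  expect_equal(none$p, 1)
  expect_error(gene_set_overlap_test(paste0("g", 1:50), ids, 10), "universe")
})
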