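test_that("hypergeometric upper tail matches closed forms", {
  expect_equal(hypergeom_upper_tail(100, 5, 5, 5)$p, 1 / choose(100, 5),
               tolerance = 1e-12)
  expect_equal(hypergeom_upper_tail(10, 5, 5, 5)$p, 1 / 252, tolerance = 1e-12)
  expect_equal(hypergeom_upper_tail(50, 10, 8, 0)$p, 1)
  expect_error(hypergeom_upper_tail(10, 12, 5, 1), "universe")
  expect_error(hypergeom_upper_tail(10, 5, 5, 6), "exceeds")
})

test_that("hypergeometric tail equals brute force across a grid", {
  set.seed(5)
  cases <- 0L
  for (N in c(8, 15, 30, 60)) {
    for (rep in 1:40) {
      K <- sample(1:N, 1); n <- sample(1:N, 1)
      k <- sample(0:min(K, n), 1)
      p1 <- hypergeom_upper_tail(N, K, n, k)$p
      p2 <- oracle_hyper_upper(N, K, n, k)
      expect_equal(p1, p2, tolerance = 1e-12)
      cases <- cases + 1L
    }
  }
  expect_gte(cases, 160L)
})

test_that("log-space tail stays exact far below double underflow", {
  # against R's log-scale hypergeometric survival function
  h <- hypergeom_upper_tail(20211, 4532, 4104, 1526)
  ref <- phyper(1525, 4532, 20211 - 4532, 4104, lower.tail = FALSE, log.p = TRUE)
  expect_equal(h$log10_p, ref / log(10), tolerance = 1e-10)
  big <- hypergeom_upper_tail(5e4, 2e4, 2e4, 16000)
  ref2 <- phyper(15999, 2e4, 3e4, 2e4, lower.tail = FALSE, log.p = TRUE)
  expect_equal(big$log10_p, ref2 / log(10), tolerance = 1e-10)
  expect_true(is.finite(big$log10_p))
})

test_that("two-sided Fisher matches enumeration and the stats reference", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))$p, 1)
  expect_equal(fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2))$p, 1 / 3,
               tolerance = 1e-12)
  expect_error(fisher_exact_2x2(matrix(0, 2, 2)), "all-zero")
  set.seed(6)
  for (i in 1:150) {
    tab <- matrix(sample(0:25, 4, replace = TRUE), 2, 2)
    if (sum(tab) == 0) next
    p <- fisher_exact_2x2(tab)$p
    expect_equal(p, oracle_fisher_two_sided(tab), tolerance = 1e-12)
    expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("Wilcoxon rank-sum: exact small-sample p and tie-corrected approximation", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(10, 11, 12))$p, 0.1)
  expect_equal(wilcoxon_rank_sum(1:4, 1:4 + 0.5)$p,
               suppressWarnings(stats::wilcox.test(1:4, 1:4 + 0.5))$p.value)
  set.seed(7)
  for (i in 1:25) {
    x <- rnorm(sample(3:6, 1)); y <- rnorm(sample(3:6, 1))
    expect_equal(wilcoxon_rank_sum(x, y)$p, oracle_wilcox_two_sided(x, y),
                 tolerance = 1e-12)
  }
  # ties / large samples: normal approximation with tie correction
  x <- rep(1:5, 4); y <- rep(2:6, 5)
  got <- wilcoxon_rank_sum(x, y)
  expect_false(got$exact)
  expect_equal(got$p,
               stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-9)
})

test_that("rank-based p is invariant under strictly monotone transforms", {
  set.seed(8)
  x <- rexp(8); y <- rexp(6) * 2
  p0 <- wilcoxon_rank_sum(x, y)$p
  expect_equal(wilcoxon_rank_sum(log(x), log(y))$p, p0)
  expect_equal(wilcoxon_rank_sum(x^3, y^3)$p, p0)
})

test_that("regression reports R-squared, slope p and rejects degenerate x", {
  fit <- linreg_r2(c(1, 2, 3), c(2, 4, 6))
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$slope, 2)
  set.seed(9)
  x <- rnorm(6); y <- 2 * x + rnorm(6)
  fit2 <- linreg_r2(x, y)
  expect_equal(fit2$r_squared, cor(x, y)^2, tolerance = 1e-12)
  # affine rescale of x leaves R2 and p unchanged
  fit3 <- linreg_r2(10 + 3 * x, y)
  expect_equal(fit3$r_squared, fit2$r_squared, tolerance = 1e-12)
  expect_equal(fit3$p, fit2$p, tolerance = 1e-12)
  expect_error(linreg_r2(rep(1, 5), rnorm(5)), "constant")
  flat <- linreg_r2(1:5, rep(2, 5))
  expect_equal(flat$r_squared, 0)
  expect_true(is.na(flat$p))
})

test_that("log2 fold-change classification: zero removal and strict cutoffs", {
  got <- log2fc_classify(c(8, 0, 20, 1), c(2, 5, 2.5, 16))
  expect_equal(got$log2fc, c(2, NA, 3, -4))
  expect_equal(got$class, c("unchanged", "excluded_zero", "up", "down"))
  # antisymmetry under swapping samples
  a <- log2fc_classify(c(20, 1), c(2.5, 16))
  b <- log2fc_classify(c(2.5, 16), c(20, 1))
  expect_equal(a$log2fc, -b$log2fc)
  expect_equal(a$class, c("up", "down"))
  expect_equal(b$class, c("down", "up"))
  expect_error(log2fc_classify(-1, 2), "non-negative")
})

test_that("delta-delta-Ct relative expression", {
  expect_equal(relative_expression_ddct(c(20, 20, 20), c(20, 20, 20)), 1)
  expect_equal(relative_expression_ddct(c(20, 20, 20), c(22, 22, 22)), 4)
  expect_equal(relative_expression_ddct(c(20, 20, 20), c(21, 22, 23)), 4)
  expect_warning(relative_expression_ddct(c(20, 20), c(21, 22, 23)), "replicates")
  expect_error(relative_expression_ddct(numeric(), c(20)), "empty")
})

test_that("Bonferroni threshold", {
  expect_equal(bonferroni_threshold(0.05, 125), 4e-4)
})
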