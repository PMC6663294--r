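# Exact enrichment and comparison statistics.
#
# The hypergeometric upper tail is evaluated by log-gamma summation so that
# tails far below double-precision underflow (p ~ 1e-222 in the ortholog
# enrichment analysis) are still reported exactly on the log10 scale. The
# two-sided Fisher p uses the point-probability convention: sum over all
# tables with the observed margins whose probability does not exceed that of
# the observed table.

#' Upper-tail hypergeometric test
#'
#' `P(X >= k)` where `X` is the overlap of a sample of `n` draws from a
#' universe of `N` containing `K` successes. Evaluated as a log-space sum of
#' `choose(K,i) choose(N-K,n-i) / choose(N,n)` over `i = k..min(K,n)`,
#' so extreme tails are exact on the log scale.
#'
#' @param N Universe size.
#' @param K Successes in the universe.
#' @param n Sample size.
#' @param k Observed successes in the sample.
#' @return A list with `p` (may underflow to 0 for extreme tails) and
#'   `log10_p` (always finite for k <= min(K, n)).
#' @export
hypergeom_upper_tail <- function(N, K, n, k) {
  if (K > N || n > N) stop("K and n must not exceed the universe N")
  if (k < 0 || k > min(K, n)) {
    if (k > min(K, n)) stop("k exceeds min(K, n)")
    k <- 0
  }
  i <- seq.int(k, min(K, n))
  lt <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  lp <- logsumexp(lt)
  lp <- min(lp, 0)  # guard rounding just above 1
  list(p = exp(lp), log10_p = lp / log(10))
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact two-sided p by the point-probability method: with margins fixed,
#' sum the hypergeometric probabilities of all tables at least as extreme
#' (probability <= observed, with a small relative tolerance for ties).
#' The odds ratio is the conditional maximum-likelihood estimate under the
#' noncentral hypergeometric model.
#'
#' @param tab A 2x2 matrix of non-negative integer counts.
#' @return A list with `p`, `odds_ratio` and the observed `table`.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)))
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  if (sum(tab) == 0) stop("all-zero table")
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  support <- lo:hi
  lp <- dhyper(support, r1, r2, c1, log = TRUE)
  obs <- lp[support == a]
  keep <- lp <= obs + 1e-7
  p <- min(1, exp(logsumexp(lp[keep])))
  list(p = p, odds_ratio = cond_mle_or(a, r1, r2, c1, support, lp),
       table = tab)
}

# conditional MLE of the odds ratio: solve E_psi[A] = a under the noncentral
# hypergeometric distribution on the support
cond_mle_or <- function(a, r1, r2, c1, support, lp) {
  if (a == min(support)) return(0)
  if (a == max(support)) return(Inf)
  mean_a <- function(log_psi) {
    lw <- lp + support * log_psi
    w <- exp(lw - max(lw))
    sum(support * w) / sum(w)
  }
  root <- uniroot(function(lpsi) mean_a(lpsi) - a, c(-50, 50))$root
  exp(root)
}

#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum comparison of two groups: exact null distribution
#' (via the Wilcoxon distribution of the rank-sum statistic) when the
#' combined sample size is at most `exact_max` and there are no ties, and
#' the normal approximation with tie correction and continuity correction
#' otherwise.
#'
#' @param x,y Numeric vectors.
#' @param exact_max Largest combined sample size for the exact path
#'   (default 25).
#' @return A list with `statistic` (W, the Mann-Whitney U of `x`), `p`,
#'   `exact`, and the group medians.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 25L) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  m <- length(x); n <- length(y)
  if (m == 0 || n == 0) stop("both groups must be non-empty")
  r <- rank(c(x, y))
  w <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  ties <- any(duplicated(c(x, y)))
  exact <- (m + n) <= exact_max && !ties
  if (exact) {
    if (w > m * n / 2) {
      p <- min(1, 2 * pwilcox(w - 1, m, n, lower.tail = FALSE))
    } else {
      p <- min(1, 2 * pwilcox(w, m, n))
    }
  } else {
    tie_tab <- table(r)
    mu <- m * n / 2
    sigma2 <- (m * n / 12) *
      ((m + n + 1) - sum(tie_tab^3 - tie_tab) / ((m + n) * (m + n - 1)))
    if (sigma2 <= 0) {
      p <- 1  # all observations tied: no evidence either way
    } else {
      z <- w - mu
      z <- z - sign(z) * 0.5  # continuity correction
      z <- z / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
  }
  list(statistic = w, p = p, exact = exact,
       median_x = median(x), median_y = median(y))
}

#' Ordinary least-squares fit with R-squared and slope p-value
#'
#' Simple linear regression `y ~ x` reporting the slope, intercept,
#' coefficient of determination and the two-sided t-test p-value of the
#' slope (`n - 2` degrees of freedom).
#'
#' @param x,y Numeric vectors, `n >= 3`, `x` not constant.
#' @return A list with `slope`, `intercept`, `r_squared`, `p`, `n`.
#' @export
linreg_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete observations")
  if (stats::var(x) == 0) stop("x is constant")
  if (stats::var(y) == 0) {
    return(list(slope = 0, intercept = mean(y), r_squared = 0, p = NA_real_, n = n))
  }
  fit <- lm(y ~ x)
  # a perfect fit is a legitimate input; silence summary.lm's reliability note
  sm <- suppressWarnings(summary(fit))
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = sm$r.squared, p = unname(sm$coefficients[2, 4]), n = n)
}

#' Classify expression fold change
#'
#' `log2(FPKM_line / FPKM_wt)` with zero-FPKM exclusion: any gene with zero
#' FPKM in either sample is `excluded_zero`. Genes are `up` when the fold
#' change strictly exceeds the cutoff, `down` when strictly below its
#' negative, otherwise `unchanged`.
#'
#' @param fpkm_line,fpkm_wt Non-negative FPKM values (vectorised).
#' @param cutoff Log2 fold-change cutoff (default 2).
#' @return A `data.table` with `log2fc` and `class`.
#' @export
log2fc_classify <- function(fpkm_line, fpkm_wt, cutoff = 2) {
  if (any(fpkm_line < 0, na.rm = TRUE) || any(fpkm_wt < 0, na.rm = TRUE)) {
    stop("FPKM values must be non-negative")
  }
  zero <- fpkm_line == 0 | fpkm_wt == 0
  lfc <- ifelse(zero, NA_real_, log2(fpkm_line / fpkm_wt))
  cls <- ifelse(zero, "excluded_zero",
                ifelse(lfc > cutoff, "up",
                       ifelse(lfc < -cutoff, "down", "unchanged")))
  data.table::data.table(log2fc = lfc, class = cls)
}

#' Relative expression by the double delta-Ct method
#'
#' `2 ^ -(mean(Ct_target) - mean(Ct_reference))` from technical replicate
#' threshold cycles; warns when fewer than three replicates per channel.
#'
#' @param ct_target,ct_reference Numeric Ct replicates.
#' @return Relative expression (positive scalar).
#' @export
relative_expression_ddct <- function(ct_target, ct_reference) {
  ct_target <- ct_target[!is.na(ct_target)]
  ct_reference <- ct_reference[!is.na(ct_reference)]
  if (!length(ct_target) || !length(ct_reference)) stop("empty Ct replicate list")
  if (length(ct_target) < 3 || length(ct_reference) < 3) {
    warning("fewer than 3 technical replicates per channel")
  }
  2^(-(mean(ct_target) - mean(ct_reference)))
}

#' Bonferroni significance threshold
#'
#' @param alpha Family-wise error rate (default 0.05).
#' @param m Number of tests.
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  stopifnot(m >= 1)
  alpha / m
}
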