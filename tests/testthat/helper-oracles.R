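# Brute-force oracles: direct summation/enumeration over the support,
# independent of the log-space implementations they check.

oracle_hyper_upper <- function(N, K, n, k) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

oracle_fisher_two_sided <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  support <- max(0, c1 - r2):min(r1, c1)
  pr <- choose(r1, support) * choose(r2, c1 - support) / choose(r1 + r2, c1)
  obs <- pr[support == tab[1, 1]]
  sum(pr[pr <= obs * (1 + 1e-7)])
}

oracle_wilcox_two_sided <- function(x, y) {
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combos <- utils::combn(m + n, m)
  ws <- apply(combos, 2, function(idx) sum(seq_len(m + n)[idx]) - m * (m + 1) / 2)
  p_low <- mean(ws <= w_obs); p_high <- mean(ws >= w_obs)
  min(1, 2 * min(p_low, p_high))
}

oracle_binom_upper <- function(mc, cov, r) {
  i <- mc:cov
  sum(choose(cov, i) * r^i * (1 - r)^(cov - i))
}
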