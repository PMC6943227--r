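## Independent brute-force oracles, implemented directly from the defining
## formulas. They deliberately share no code with the package.

oracle_shannon <- function(x) {
  p <- x[x > 0] / sum(x)
  -sum(p * log(p))
}

oracle_bray <- function(a, b) sum(abs(a - b)) / sum(a + b)

oracle_cosine <- function(a, b) {
  sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
}

oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  n <- length(x)
  rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  p <- if (abs(rho) == 1) 0 else 2 * stats::pt(-abs(tstat), df = n - 2)
  list(rho = rho, p = p)
}

oracle_kruskal <- function(groups) {
  all_v <- unlist(groups)
  n <- length(all_v)
  r <- rank(all_v)
  idx <- rep(seq_along(groups), lengths(groups))
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, idx, sum)^2 / lengths(groups)) - 3 * (n + 1)
  ties <- table(all_v)
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h <- h / correction
  list(statistic = h,
       p.value = stats::pchisq(h, df = length(groups) - 1, lower.tail = FALSE))
}

oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  q
}
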