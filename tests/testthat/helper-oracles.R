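# Brute-force rank/enumeration oracles, independent of the implementation
# paths they check (no calls to rank(), kruskal.test(), wilcox.test(), cor()).

# average ranks by pairwise counting
avg_rank_oracle <- function(x) {
  vapply(seq_along(x),
         function(i) sum(x < x[i]) + (1 + sum(x == x[i])) / 2,
         numeric(1))
}

# tie-corrected Kruskal-Wallis H from first principles
kw_H_oracle <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  N <- length(x)
  r <- avg_rank_oracle(x)
  g <- rep(seq_along(groups), lengths(groups))
  Rbar <- tapply(r, g, mean)
  n <- lengths(groups)
  H <- 12 / (N * (N + 1)) * sum(n * (Rbar - (N + 1) / 2)^2)
  tie <- table(x)
  H / (1 - sum(tie^3 - tie) / (N^3 - N))
}

# Mann-Whitney U of x by pairwise counting (ties count 1/2)
u_stat_oracle <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# exact two-sided U-test p by enumerating every group-1 assignment of the
# pooled values (feasible for pooled n <= 8)
u_exact_p_oracle <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  n2 <- length(y)
  centre <- n1 * n2 / 2
  obs <- abs(u_stat_oracle(x, y) - centre)
  idx <- utils::combn(length(pooled), n1)
  us <- apply(idx, 2, function(ii) u_stat_oracle(pooled[ii], pooled[-ii]))
  mean(abs(us - centre) >= obs - 1e-9)
}

# Spearman r as Pearson on average ranks, computed from the definition
spearman_oracle <- function(x, y) {
  rx <- avg_rank_oracle(x)
  ry <- avg_rank_oracle(y)
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}
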