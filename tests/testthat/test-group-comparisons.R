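test_that("Kruskal-Wallis H matches the brute-force rank oracle on small fixtures", {
  fixtures <- list(
    list(c(1, 2), c(3, 4), c(5, 6)),
    list(c(1, 1, 2), c(2, 3), c(4, 4, 5)),       # ties across groups
    list(c(0.5, 2.5), c(2.5, 2.5), c(1, 7, 7)),  # heavy ties
    list(c(3, 1, 4), c(1, 5), c(9, 2, 6)),
    list(c(10, 20, 30, 40), c(15, 25, 35, 45))   # two groups
  )
  for (g in fixtures) {
    expect_equal(kruskal_wallis(g)$H, kw_H_oracle(g), tolerance = 1e-12)
  }
  # frozen hand value for the canonical separated fixture
  expect_equal(kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))$H, 32 / 7)
})

test_that("Kruskal-Wallis degenerate and error cases", {
  res <- kruskal_wallis(list(c(2, 2), c(2, 2), c(2, 2)))
  expect_equal(res$H, 0)
  expect_equal(res$p, 1)
  expect_error(kruskal_wallis(list(c(1, 2), numeric(0))), "empty group")
  expect_error(kruskal_wallis(list(c(1, 2))), "2 groups")
})

test_that("two-group Kruskal-Wallis agrees with the rank-sum z-squared identity", {
  x <- c(1.2, 3.4, 2.2, 5.1, 0.7)
  y <- c(2.8, 4.4, 6.0, 3.9)
  H <- kruskal_wallis(list(x, y))$H
  pw <- pairwise_mwu_bonferroni(list(a = x, b = y))
  z2 <- qnorm(pw$p_raw / 2)^2  # two-sided normal p back to z^2
  expect_equal(H, z2, tolerance = 1e-10)
  expect_equal(kruskal_wallis(list(x, y))$p, pw$p_raw, tolerance = 1e-10)
})

test_that("Kruskal-Wallis is invariant under strictly monotone transforms", {
  set.seed(3)
  g <- list(runif(10), runif(8) + 0.2, runif(12) - 0.1)
  h0 <- kruskal_wallis(g)$H
  expect_equal(kruskal_wallis(lapply(g, exp))$H, h0)
  expect_equal(kruskal_wallis(lapply(g, function(v) 5 * v - 2))$H, h0)
})

test_that("Mann-Whitney U matches the counting oracle; p near exact enumeration", {
  fixtures <- list(
    list(x = c(1, 2, 3), y = c(4, 5, 6)),
    list(x = c(1, 3, 5, 7), y = c(2, 4, 6, 8)),
    list(x = c(1, 1, 2, 3), y = c(2, 2, 3, 4)),  # ties
    list(x = c(10, 40), y = c(20, 30, 50, 60))
  )
  for (f in fixtures) {
    pw <- pairwise_mwu_bonferroni(list(a = f$x, b = f$y))
    expect_equal(pw$U, u_stat_oracle(f$x, f$y))
    # the uncorrected normal approximation sits within 0.2 of the exact
    # discrete two-sided p at pooled n = 8 or below; that gap closes at the
    # thousands-of-DAs sizes the approximation is used for
    expect_lt(abs(pw$p_raw - u_exact_p_oracle(f$x, f$y)), 0.2)
  }
  # complete separation gives U = 0 for the lower group
  expect_equal(pairwise_mwu_bonferroni(list(a = 1:3, b = 4:6))$U, 0)
})

test_that("pairwise tests cover all pairs, Bonferroni-multiply, and relabel cleanly", {
  set.seed(11)
  g <- list(metro = rnorm(30), mid = rnorm(25, 0.5), rural = rnorm(20, 1))
  pw <- pairwise_mwu_bonferroni(g)
  expect_equal(nrow(pw), 3L)
  expect_equal(pw$p_adj, pmin(1, 3 * pw$p_raw))

  # relabelling groups permutes rows without changing values
  pw2 <- pairwise_mwu_bonferroni(g[c("rural", "metro", "mid")])
  key <- function(d) paste(pmin(d$group1, d$group2), pmax(d$group1, d$group2))
  expect_setequal(round(pw$p_raw, 12), round(pw2$p_raw, 12))
  expect_setequal(key(pw), key(pw2))

  # identical groups carry no rank information
  same <- pairwise_mwu_bonferroni(list(a = rep(1, 5), b = rep(1, 5)))
  expect_equal(same$p_adj, 1)
})

test_that("Spearman correlation matches the rank-then-Pearson oracle", {
  expect_equal(spearman_r(1:10, (1:10)^3), 1)
  expect_equal(spearman_r(1:10, -(1:10)), -1)
  expect_error(spearman_r(rep(1, 5), 1:5), "constant")
  expect_error(spearman_r(1:3, 1:4), "equal length")

  set.seed(99)
  for (i in 1:100) {
    n <- sample(5:30, 1)
    x <- sample(1:8, n, replace = TRUE)   # heavy ties
    y <- x + sample(-2:2, n, replace = TRUE)
    if (length(unique(x)) == 1L || length(unique(y)) == 1L) next
    expect_equal(spearman_r(x, y), spearman_oracle(x, y), tolerance = 1e-12)
  }
  # invariance under strictly monotone transforms
  set.seed(5)
  x <- runif(20); y <- runif(20)
  expect_equal(spearman_r(exp(x), y), spearman_r(x, y))
  expect_equal(spearman_r(x, 3 * y + 1), spearman_r(x, y))
})

test_that("the correlation gate selects on magnitude with an inclusive boundary", {
  r <- c(income = -0.40, labour_force = 0.40, housework = -0.40,
         divorce = 0.09, university = -0.15, elderly_care = 0.01)
  expect_setequal(select_correlated_indicators(r),
                  c("income", "labour_force", "housework"))
  expect_length(select_correlated_indicators(r * 0.5), 0L)
  expect_equal(select_correlated_indicators(c(a = 0.4)), "a")
  expect_length(select_correlated_indicators(c(a = NA_real_, b = 0.1)), 0L)
})

test_that("population-weighted tertiles cut at first-reach of 1/3 and 2/3 of population", {
  mk <- function(levels, pops) {
    n <- length(levels)
    tibble::tibble(
      da_id = sprintf("DA%03d", seq_len(n)),
      area_type = "rural",
      pop_f = as.integer(pops / 2), pop_m = as.integer(pops - pops / 2),
      divorce_num_f = as.integer(round(levels * 100)),
      divorce_num_m = as.integer(round(levels * 100)),
      divorce_den_f = 100L, divorce_den_m = 100L,
      labour_force_num_f = 1L, labour_force_num_m = 1L,
      labour_force_den_f = 10L, labour_force_den_m = 10L
    )
  }
  # 3 equal-population DAs with distinct levels: one per tertile
  t3 <- population_weighted_tertiles(mk(c(0.1, 0.2, 0.3), rep(500, 3)),
                                     "divorce")
  expect_equal(as.character(t3$tertile), c("low", "intermediate", "high"))

  # 6 equal-population DAs: two per tertile
  t6 <- population_weighted_tertiles(mk(seq(0.1, 0.6, by = 0.1), rep(400, 6)),
                                     "divorce")
  expect_equal(as.vector(table(t6$tertile)), c(2L, 2L, 2L))

  # one DA holding half the population: its tertile holds >= 50% of people
  tsk <- population_weighted_tertiles(
    mk(c(0.1, 0.2, 0.3, 0.4, 0.5), c(100, 100, 400, 100, 100)), "divorce")
  pops <- c(100, 100, 400, 100, 100)
  big_tertile <- tsk$tertile[tsk$da_id == "DA003"]
  expect_gte(sum(pops[tsk$tertile == big_tertile]), 400)

  # every eligible DA gets exactly one tertile; boundaries are non-decreasing
  b <- attr(t6, "boundaries")
  expect_length(b, 2L)
  expect_lte(b[1], b[2])
  expect_equal(nrow(t6), 6L)

  # ties in level break by da_id deterministically
  tt1 <- population_weighted_tertiles(mk(rep(0.2, 6), rep(400, 6)), "divorce")
  tt2 <- population_weighted_tertiles(mk(rep(0.2, 6), rep(400, 6)), "divorce")
  expect_identical(tt1, tt2)
  expect_equal(as.character(tt1$tertile[order(tt1$da_id)]),
               rep(c("low", "intermediate", "high"), each = 2))
})

test_that("tertile-by-area summaries and their tests behave at the extremes", {
  cen <- filtered_census(n = 90, seed = 77)
  assign <- population_weighted_tertiles(cen, "housework")
  scores <- score_table(cen)

  # constant scores: all cell means equal, all p = 1
  const <- scores
  const$score <- 0.5
  s <- tertile_score_summary(const, assign, cen)
  expect_true(all(s$grid$mean_score == 0.5))
  expect_true(all(s$tests$p == 1))

  # planted monotone effect: score decreasing in overall level gives
  # monotone decreasing cell means across tertiles in every area
  lv <- tibble::tibble(da_id = assign$da_id, level = assign$overall_level)
  planted <- scores[scores$indicator == "housework", ]
  planted <- dplyr::inner_join(planted, lv, by = "da_id")
  planted$score <- 1 - planted$level
  s2 <- tertile_score_summary(planted[, names(scores)], assign, cen)
  for (a in unique(s2$grid$area_type)) {
    m <- s2$grid$mean_score[s2$grid$area_type == a]
    if (length(m) == 3L) expect_true(all(diff(m) < 0))
  }

  # single area type: one row of the grid per tertile, others absent
  cen1 <- cen
  cen1$area_type <- "metropolitan"
  s3 <- tertile_score_summary(scores, assign, cen1)
  expect_equal(unique(s3$grid$area_type), "metropolitan")
  expect_equal(nrow(s3$tests), 1L)
})

test_that("between-area comparison gates pairwise tests on the omnibus result", {
  cen <- filtered_census(n = 150, seed = 55)
  scores <- score_table(cen)
  res <- between_area_comparison(scores, cen, alpha = 0.05)
  expect_equal(sort(unique(res$summary$indicator)),
               sort(indicator_definitions()$indicator))
  expect_true(all(res$omnibus$H >= 0))
  if (nrow(res$pairwise)) {
    gated <- unique(res$pairwise$indicator)
    expect_true(all(res$omnibus$p[res$omnibus$indicator %in% gated] < 0.05))
    expect_equal(res$pairwise$p_adj, pmin(1, 3 * res$pairwise$p_raw))
  }
  ungated <- between_area_comparison(scores, cen, gate_pairwise = FALSE)
  expect_equal(nrow(ungated$pairwise), 3L * 12L)
})
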