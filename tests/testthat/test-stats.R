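test_that("rank-sum W follows the pooled-rank convention and its bounds", {
  r <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(r$W, 3)
  expect_true(r$exact)
  # complete separation at n = m = 20 attains the maximum rank sum 610
  x <- 101:120; y <- 1:20
  r2 <- wilcoxon_rank_sum(x, y)
  expect_equal(r2$W, 610)
  expect_equal(r2$W, sum(21:40))
  expect_lt(r2$p, 0.001)
  # reversed separation attains the minimum 210
  expect_equal(wilcoxon_rank_sum(y, x)$W, 210)
  # identical tied samples show no separation
  r3 <- wilcoxon_rank_sum(rep(5, 20), rep(5, 20))
  expect_gt(r3$p, 0.99)
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "nonempty")
})

test_that("rank-sum W stays within n(n+1)/2 and n(n+2m+1)/2 on random data", {
  set.seed(77)
  for (i in 1:50) {
    n <- sample(2:25, 1); m <- sample(2:25, 1)
    r <- wilcoxon_rank_sum(stats::rnorm(n), stats::rnorm(m))
    expect_gte(r$W, n * (n + 1) / 2)
    expect_lte(r$W, n * (n + 2 * m + 1) / 2)
  }
})

test_that("Welch t handles identical, shifted and equal-variance samples", {
  r <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$T, 0)
  expect_equal(r$p, 1)
  # hand calculation: x = {0,1}, y = {10,11}; se = sqrt(0.5/2 + 0.5/2)
  r2 <- welch_t(c(0, 1), c(10, 11))
  expect_equal(abs(r2$T), 10 / sqrt(0.5), tolerance = 1e-12)
  set.seed(13)
  x <- stats::rnorm(20); y <- stats::rnorm(20)
  r3 <- welch_t(x, y)
  expect_lte(r3$df, 38)
  expect_equal(r3$df_display, floor(r3$df))
  expect_error(welch_t(rep(1, 5), rep(2, 5)), "zero variance")
})

test_that("Kruskal-Wallis matches a rank-based oracle and its df", {
  groups <- list(c(1, 2), c(3, 4), c(5, 6))
  r <- kruskal_wallis(groups)
  expect_equal(r$H, kw_oracle(groups), tolerance = 1e-12)
  expect_equal(r$df, 2)
  set.seed(19)
  g4 <- replicate(4, stats::rnorm(20), simplify = FALSE)
  expect_equal(kruskal_wallis(g4)$df, 3)
  expect_equal(kruskal_wallis(g4)$H, kw_oracle(g4), tolerance = 1e-10)
  tied <- list(c(1, 1, 2), c(2, 3, 3), c(1, 3, 2))
  expect_equal(kruskal_wallis(tied)$H, kw_oracle(tied), tolerance = 1e-12)
  const <- list(rep(2, 5), rep(2, 5))
  expect_equal(kruskal_wallis(const)$H, 0)
  expect_equal(kruskal_wallis(const)$p, 1)
  expect_error(kruskal_wallis(list(1:3)), ">= 2")
})

test_that("sequential Bonferroni reproduces the step-down thresholds", {
  res <- sequential_bonferroni(c(0.04, 0.01, 0.002, 0.3), alpha = 0.05)
  expect_equal(sort(res$critical_display),
               c(0.012, 0.016, 0.025, 0.050))
  # all p = 1: nothing significant
  expect_false(any(sequential_bonferroni(rep(1, 4))$significant))
  # hand-evaluated step-down: 0.001 <= 0.0125 passes, 0.02 > 0.0167 stops
  res2 <- sequential_bonferroni(c(0.001, 0.02, 0.03, 0.9), alpha = 0.05)
  expect_equal(res2$significant, c(TRUE, FALSE, FALSE, FALSE))
  # agreement with the Holm adjustment as an independent cross-check
  set.seed(3)
  p <- stats::runif(6)
  res3 <- sequential_bonferroni(p, alpha = 0.05)
  expect_equal(res3$significant, unname(stats::p.adjust(p, "holm") <= 0.05))
  expect_error(sequential_bonferroni(c(0.5, 1.2)), "0, 1")
})

test_that("sequential Bonferroni is monotone in the p-values", {
  set.seed(23)
  for (i in 1:25) {
    p <- stats::runif(4)
    base <- sequential_bonferroni(p)$significant
    j <- sample(4, 1)
    p2 <- p; p2[j] <- p[j] * stats::runif(1)
    shrunk <- sequential_bonferroni(p2)$significant
    # making one p smaller never turns any significant result non-significant
    expect_true(all(shrunk[base]))
  }
})

test_that("planned comparisons pick the right test and correct jointly", {
  set.seed(5)
  rec <- simulate_null_records(seed = 5)
  pc_hue <- planned_comparisons(rec, "hue")
  expect_true(all(pc_hue$test == "welch_t"))
  pc_lum <- planned_comparisons(rec, "luminance")
  expect_true(all(pc_lum$test == "wilcoxon"))
  expect_equal(nrow(pc_lum), 4)
  expect_equal(sort(pc_lum$critical_threshold),
               c(0.012, 0.016, 0.025, 0.050))
  single <- rec[rec$background == "A", ]
  expect_error(planned_comparisons(single, "hue"), "two backgrounds")
  missing_tp <- rec[!(rec$background == "B" & rec$time_min == 10), ]
  expect_error(planned_comparisons(missing_tp, "luminance"), "missing")
})

test_that("null simulations keep the familywise error at or below alpha", {
  n_rep <- 400
  any_sig <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    rec <- simulate_null_records(seed = 1000 + i)
    any_sig[i] <- any(planned_comparisons(rec, "luminance")$significant)
  }
  rate <- mean(any_sig)
  # binomial 99% upper bound around alpha = 0.05 at 400 reps
  expect_lte(rate, 0.05 + 2.576 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("camouflage trend is null-calibrated and detects convergence", {
  nonsig <- vapply(1:100, function(i) {
    rec <- simulate_null_records(seed = 2000 + i)
    !camouflage_trend(rec, "A", "achromatic")$significant
  }, logical(1))
  expect_gte(mean(nonsig), 0.89)
  # constant JNDs give H = 0
  rec <- simulate_null_records(seed = 1)
  rec$chromatic_jnd <- 2
  expect_equal(camouflage_trend(rec, "A", "chromatic")$H, 0)
  # programmed perfect convergence: large H, tiny p
  rec2 <- simulate_null_records(seed = 2)
  rec2$achromatic_jnd <- rec2$achromatic_jnd *
    c(`0` = 1, `1` = 0.4, `10` = 0.2, `60` = 0.1)[as.character(rec2$time_min)]
  tr <- camouflage_trend(rec2, "B", "achromatic")
  expect_gt(tr$H, 30)
  expect_lt(tr$p, 0.001)
})
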