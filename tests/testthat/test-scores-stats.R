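# NSS totals, group summaries, t tests, percent differences,
# per-timepoint series comparison.

rec <- function(motor, sensory, beam, reflex)
  data.frame(motor = motor, sensory = sensory, beam = beam,
             reflex = reflex)

test_that("NSS totals average examiner records and respect the scale", {
  expect_identical(nss_total(rec(0, 0, 0, 0)), 0)
  expect_identical(nss_total(rec(6, 2, 6, 4)), 18)
  # three examiners with totals 4 / 5 / 6 average to 5
  expect_equal(nss_total(rec(c(2, 2, 3), c(1, 1, 1), c(1, 1, 1),
                             c(0, 1, 1))), 5)
  expect_error(nss_total(rec(7, 0, 0, 0)), "out of range")
  expect_error(nss_total(rec(1, 3, 0, 0)), "out of range")
  # bounded on valid cohorts
  co <- make_nss_cohort(9, 6, 20, seed = 4)
  totals <- vapply(1:20, function(r) nss_total(co[co$rat_id == r, ]),
                   numeric(1))
  expect_true(all(totals >= 0 & totals <= 18))
})

test_that("group summaries report mean and SEM with n-1 variance", {
  s <- group_summary(c(1, 1, 1))
  expect_identical(c(s$mean, s$sem), c(1, 0))
  s2 <- group_summary(c(2, 4))        # sd = sqrt(2), sem = 1
  expect_equal(c(s2$mean, s2$sem), c(3, 1))
  expect_error(group_summary(5), "n >= 2")
})

test_that("t tests reproduce hand-computed and degenerate cases", {
  # pooled two-sample case {1,2,3} vs {2,3,4}: t = -sqrt(3/2)
  tt <- ttest_groups(c(1, 2, 3), c(2, 3, 4), var_equal = TRUE)
  expect_equal(tt$t_stat, -1.224745, tolerance = 1e-6)
  expect_equal(tt$t_stat, unname(stats::t.test(c(1, 2, 3), c(2, 3, 4),
                                               var.equal = TRUE)$statistic))
  # identical constant groups: t = 0, p = 1 by convention
  same <- ttest_groups(c(2, 2), c(2, 2))
  expect_identical(c(same$t_stat, same$p_value), c(0, 1))
  # constant groups with different means: certain difference
  diffg <- ttest_groups(c(3, 3), c(1, 1))
  expect_identical(c(diffg$t_stat, diffg$p_value), c(Inf, 0))
  expect_error(ttest_groups(1, c(1, 2)), "n >= 2")
})

test_that("well-separated groups at the reported SEMs are detected", {
  # planted group difference (19.5 vs 12.4 mm^2 at SEM 1.4 / 1.5, n = 11)
  # reaches significance in nearly all replicates
  hits <- vapply(1:40, function(s) {
    set.seed(s)
    a <- stats::rnorm(11, 19.5, 1.4 * sqrt(11))
    b <- stats::rnorm(11, 12.4, 1.5 * sqrt(11))
    ttest_groups(a, b)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("Welch p agrees with the exact permutation p on small samples", {
  a <- c(2.1, 3.4, 1.9, 4.0, 2.8)
  b <- c(4.5, 5.1, 3.9, 6.0, 4.8)
  expect_lt(abs(ttest_groups(a, b)$p_value - perm_p_welch(a, b)), 0.02)
  a2 <- c(4.33, 6.11, 4, 5.06, 6.37, 4.52, 4.62, 4.49)
  b2 <- c(5.77, 6.11, 6.98, 5.36, 5.14, 5.87, 5.14, 5.89)
  expect_lt(abs(ttest_groups(a2, b2)$p_value - perm_p_welch(a2, b2)), 0.02)
})

test_that("percent differences reproduce the published conventions", {
  expect_identical(percent_difference(63.7, 40.1), 58.9)
  expect_identical(percent_difference(5.9, 4.6), 28.3)
  expect_identical(percent_difference(47, 32), 46.9)
  expect_identical(percent_difference(7, 7), 0)
  # scale invariance
  expect_identical(percent_difference(63.7 * 3, 40.1 * 3),
                   percent_difference(63.7, 40.1))
  expect_error(percent_difference(1, 0), "positive")
})

test_that("timepoint comparison tests each bin and flags divergence", {
  times <- 1:15
  mk_series <- function(mu) series_of(times, mu)
  ga <- lapply(1:5, function(i) mk_series(rep(10, 15) + i * 0.01))
  expect_error(timepoint_comparison(ga, list(series_of(2:16, rep(10, 15)))),
               "misaligned")
  # identical groups: p = 1 everywhere
  same <- timepoint_comparison(ga, ga)
  expect_true(all(same$p == 1))
  expect_identical(nrow(same), 15L)
  # groups planted to diverge from 8 min onward: first significant bin
  # at or after 8 min in the clear majority of replicates
  firsts <- vapply(1:20, function(s) {
    set.seed(100 + s)
    mk_rat <- function(extra) {
      mu <- ifelse(times >= 8, 10 + extra * (times - 7), 10)
      series_of(times, mu + stats::rnorm(15, 0, 0.8))
    }
    ga <- lapply(1:6, function(i) mk_rat(1.2))
    gb <- lapply(1:6, function(i) mk_rat(0))
    tp <- timepoint_comparison(ga, gb)
    sig <- which(tp$significant)
    if (length(sig)) tp$time_min[sig[1]] else Inf
  }, numeric(1))
  expect_gte(mean(firsts >= 8), 0.6)
  # Bonferroni toggle is at least as conservative
  set.seed(7)
  ga <- lapply(1:5, function(i) series_of(times, stats::rnorm(15, 10)))
  gb <- lapply(1:5, function(i) series_of(times, stats::rnorm(15, 10.8)))
  raw <- timepoint_comparison(ga, gb)
  adj <- timepoint_comparison(ga, gb, adjust = "bonferroni")
  expect_true(all(adj$p_adj >= raw$p))
  expect_lte(sum(adj$significant), sum(raw$significant))
})
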