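# Window counts, Poisson reliability, signed-rank heuristic, tuning
# correlation, peri-event traces, predicted-vs-observed.

test_that("window counts respect the trial windows and the US artifact gap", {
  trials <- manual_trials(c(10, 20, 30))
  expect_identical(window_counts(numeric(0), trials), c(0L, 0L, 0L))
  expect_identical(window_counts(10.25, trials, "post_cs"), c(1L, 0L, 0L))
  expect_identical(window_counts(10.25, trials, "pre_cs"), c(0L, 0L, 0L))
  expect_identical(window_counts(c(9.9, 10.1), trials, "pre_cs"),
                   c(1L, 0L, 0L))
  # post-US window starts at US offset
  expect_identical(window_counts(10.52, trials, "post_us"), c(1L, 0L, 0L))
  # a spike during the 10 ms US artifact window never contributes
  expect_identical(window_counts(10.505, trials, c(0, 1)), c(0L, 0L, 0L))
  expect_identical(window_counts(10.505, trials, "post_us"), c(0L, 0L, 0L))
})

test_that("window counts of homogeneous Poisson spikes average lambda", {
  set.seed(41)
  r <- 4
  dur <- 2000
  spikes <- sort(runif(rpois(1, r * dur), 0, dur))
  trials <- manual_trials(seq(5, dur - 5, by = 4))
  cnt <- window_counts(spikes, trials, "post_cs")
  expect_equal(mean(cnt), 2, tolerance = 3 * sqrt(2 / length(cnt)) / 2)
})

test_that("expected reliability matches closed forms to 1e-10", {
  # empty pre-window: P(k2 > 0) = 1 - exp(-lambda2)
  expect_equal(expected_reliability(0, log(2)), 0.5, tolerance = 1e-10)
  for (l2 in c(0.3, 1, 4))
    expect_equal(expected_reliability(0, l2), 1 - exp(-l2), tolerance = 1e-10)
  # equal rates: the tie probability is exp(-2l) I0(2l); the rest is split
  for (l in c(0.5, 1, 2)) {
    tie <- exp(-2 * l) * besselI(2 * l, 0)
    expect_equal(expected_reliability(l, l), (1 - tie) / 2, tolerance = 1e-10)
    expect_equal(expected_reliability(l, l, "increase"),
                 expected_reliability(l, l, "decrease"), tolerance = 1e-12)
  }
  expect_equal(expected_reliability(1, 1), 0.3458, tolerance = 5e-4)
  expect_error(expected_reliability(-1, 2), "non-negative")
})

test_that("expected reliability agrees with a Monte Carlo oracle", {
  set.seed(42)
  n <- 2e5
  for (l1 in c(0.5, 2)) for (l2 in c(0.5, 2)) {
    mc <- mean(rpois(n, l2) > rpois(n, l1))
    se <- sqrt(mc * (1 - mc) / n)
    expect_lt(abs(expected_reliability(l1, l2) - mc), 3 * se)
  }
})

test_that("expected reliability is monotone in both rates", {
  l2s <- c(0.1, 0.5, 1, 2, 5)
  v <- vapply(l2s, function(l2) expected_reliability(1, l2), numeric(1))
  expect_true(all(diff(v) > 0))
  v1 <- vapply(l2s, function(l1) expected_reliability(l1, 1), numeric(1))
  expect_true(all(diff(v1) < 0))
})

test_that("observed reliability counts strict inequalities only", {
  expect_equal(observed_reliability(c(0, 1, 2), c(1, 2, 3)), 1)
  expect_equal(observed_reliability(c(1, 1), c(1, 1)), 0)
  expect_equal(observed_reliability(c(2, 0), c(1, 0), "decrease"), 0.5)
  expect_error(observed_reliability(1:3, 1:2), "equal-length")
  # self-consistency: simulated Poisson counts match the expectation
  set.seed(43)
  n <- 1000
  pre <- rpois(n, 1); post <- rpois(n, 2)
  obs <- observed_reliability(pre, post)
  exp_r <- expected_reliability(1, 2)
  expect_lt(abs(obs - exp_r), 3 * sqrt(exp_r * (1 - exp_r) / n))
})

test_that("signed-rank change handles ties and attains the exact minimal p", {
  pre <- rep(3L, 10)
  res <- signed_rank_change(pre, pre)
  expect_equal(res$p, 1)
  expect_true(res$all_tied)
  expect_true(res$heuristic)
  # post = pre + 1 on 20 trials: the most extreme two-sided exact p
  pre <- rpois(20, 5)
  res <- signed_rank_change(pre, pre + 1L)
  expect_equal(res$p, 2 / 2^20, tolerance = 1e-12)
  expect_equal(res$direction, "increase")
})

test_that("signed-rank type-I error is near nominal under a Poisson null", {
  set.seed(44)
  n_cells <- 400
  p <- vapply(seq_len(n_cells), function(i) {
    pre <- rpois(80, 2); post <- rpois(80, 2)
    signed_rank_change(pre, post)$p
  }, numeric(1))
  rate <- mean(p < 0.01)
  expect_gte(rate, 0)
  expect_lte(rate, 0.01 + 3 * sqrt(0.01 * 0.99 / n_cells))
})

test_that("tuning correlation follows the zero-spike convention", {
  expect_equal(tuning_correlation(1:10, (1:10) / 2), 1)
  expect_equal(tuning_correlation(rep(0L, 10), (1:10) / 2), 0)
  expect_true(is.na(tuning_correlation(1:5, rep(NA_real_, 5))))
  # Poisson counts with rate = intensity: rho beats a permutation null
  set.seed(45)
  inten <- rexp(60, 1 / 2)
  cnt <- rpois(60, inten * 0.5)
  rho <- tuning_correlation(cnt, inten)
  null <- replicate(999, tuning_correlation(sample(cnt), inten))
  expect_gt(rho, quantile(null, 0.975))
})

test_that("per-cell summary wires the statistics together", {
  set.seed(46)
  trials <- manual_trials(seq(10, 400, by = 4))
  spikes <- sort(runif(1500, 0, 410))
  s <- cs_response_summary(spikes, trials)
  expect_s3_class(s, "eb_cs_summary")
  expect_equal(s$lambda1, mean(s$pre_counts))
  expect_equal(s$pre_rate, s$lambda1 * 2)
  expect_true(s$observed_reliability >= 0 && s$observed_reliability <= 1)
  expect_true(s$expected_reliability >= 0 && s$expected_reliability <= 1)
})

test_that("peri-event traces integrate to the spike counts", {
  trials <- manual_trials(50)
  pe <- peri_event_rates(50.25, trials, t_range = c(-0.5, 0.5),
                         binwidth = 0.02)
  tr <- pe$traces$all
  expect_equal(sum(tr$rate > 0), 1)
  expect_equal(max(tr$rate), 1 / 0.02)
  # grouping splits trials and omits empty groups
  trials <- manual_trials(c(50, 60, 70))
  pe2 <- peri_event_rates(c(50.1, 60.1), trials,
                          group = c("a", "a", "b"))
  expect_equal(pe2$traces$a$n_trials, 2)
  expect_equal(pe2$traces$b$n_trials, 1)
  # time invariance
  pe3 <- peri_event_rates(c(51.1, 61.1), manual_trials(c(51, 61, 71)),
                          group = c("a", "a", "b"))
  expect_equal(pe2$traces$a$rate, pe3$traces$a$rate)
})

test_that("predicted-vs-observed lies on the diagonal for matched counts", {
  set.seed(47)
  inten <- c(rep(0, 40), rexp(160, 1 / 3))
  cnt <- rpois(200, inten * 0.5)
  pv <- predicted_vs_observed(cnt, inten, seed = 5)
  on_diag <- pv$ci_lo <= pv$predicted & pv$predicted <= pv$ci_hi
  expect_gte(mean(on_diag[pv$n >= 10]), 0.8)
  expect_lt(attr(pv, "discrepancy"), 0.5)
  # mismatched counts (state-gated zeros) push points off the diagonal
  cnt2 <- cnt
  cnt2[inten > 1] <- 0L
  pv2 <- predicted_vs_observed(cnt2, inten, seed = 5)
  expect_gt(attr(pv2, "discrepancy"), attr(pv, "discrepancy"))
})
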