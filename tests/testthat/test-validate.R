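test_that("the truncated concordance index handles worked examples", {
  # perfectly ordered risks, no censoring
  time <- c(1, 2, 3, 4)
  event <- c(1, 1, 1, 1)
  risk <- c(0.9, 0.6, 0.4, 0.2)
  expect_equal(concordance_index(time, event, risk, 10)$c_index, 1)
  # 4-subject set with censoring: usable pairs enumerated by hand.
  # case A (t=2): comparators C (t=5, censored) and D (t=8, event): both
  # concordant (risk A highest). case D (t=8): no comparator at risk at 8
  # within horizon 10 except none -> pairs = {A-B? B censored at 1 (before
  # A) not usable}, so 2 usable pairs via A, 1 discordant pair via D? D has
  # none. Total: A-C concordant, A-D concordant => C = 1.
  time <- c(2, 1, 5, 8)
  event <- c(1, 0, 0, 1)
  risk <- c(0.8, 0.1, 0.3, 0.5)
  expect_equal(concordance_index(time, event, risk, 10)$c_index, 1)
  # flip A's risk below C's: A's two pairs discordant, D has no pairs
  risk2 <- c(0.2, 0.1, 0.3, 0.5)
  expect_equal(concordance_index(time, event, risk2, 10)$c_index, 0)
  # ties in risk count one half: A-C tied (1/2), A-D discordant (0),
  # D has no comparator still at risk => 0.5 / 2 = 0.25
  risk3 <- c(0.3, 0.1, 0.3, 0.5)
  expect_equal(concordance_index(time, event, risk3, 10)$c_index, 0.25)
  # events beyond the horizon are not cases
  expect_error(concordance_index(c(6, 7), c(1, 1), c(0.1, 0.2), 5), "usable")
})

test_that("random risks give chance-level concordance", {
  set.seed(31)
  n <- 400
  time <- stats::rexp(n, 0.05)
  event <- stats::rbinom(n, 1, 0.7)
  cs <- vapply(1:30, function(i) {
    risk <- stats::runif(n)
    concordance_index(time, event, risk, 10)$c_index
  }, numeric(1))
  expect_lt(abs(mean(cs) - 0.5), 0.02)
})

test_that("bootstrap confidence intervals bracket the point estimate", {
  set.seed(8)
  n <- 300
  x <- stats::runif(n)
  time <- stats::rexp(n, 0.02 * exp(2 * x))
  event <- rep(1, n)
  ci <- concordance_index(time, event, x, 20, n_boot = 50, seed = 2)
  expect_true(ci$ci[1] <= ci$c_index && ci$c_index <= ci$ci[2])
})

test_that("calibration reproduces a hand-computed Kaplan-Meier estimate", {
  # 5 subjects, horizon 10: events at 2 and 7, censored at 4, survivors
  # KM: S = (1 - 1/5) at t=2, then at t=7 risk set 3 -> S = 0.8 * (1 - 1/3)
  time <- c(2, 4, 7, 10, 12)
  event <- c(1, 0, 1, 0, 0)
  risk <- rep(0.4, 5)
  tab <- calibration_table(time, event, risk, 10, n_groups = 2)
  km_expected <- 1 - 0.8 * (2 / 3)
  expect_equal(attr(tab, "overall_oe"), km_expected / 0.4, tolerance = 1e-12)
  # no events anywhere: observed zero in every group
  tab0 <- calibration_table(c(3, 4, 5, 6), c(0, 0, 0, 0),
                            c(0.1, 0.2, 0.3, 0.4), 10, n_groups = 2)
  expect_equal(tab0$km_observed, c(0, 0))
  expect_error(calibration_table(1, 1, 0.1, 5, n_groups = 2), "empty")
})

test_that("recalibration fixes the overall O/E at one and preserves ranking", {
  set.seed(12)
  n <- 2000
  risk <- stats::plogis(stats::rnorm(n, -3, 1))
  # simulate events at twice the predicted hazard
  haz <- -log(1 - risk) * 2
  t_event <- stats::rexp(n, haz / 10)
  time <- pmin(t_event, 10)
  event <- as.numeric(t_event <= 10)
  rc <- recalibrate(time, event, risk, 10)
  expect_gt(rc$oe, 1.5)
  # first-order: small risks roughly double
  small <- risk < 0.02
  expect_equal(rc$risk[small] / risk[small], rep(rc$multiplier, sum(small)),
               tolerance = 0.05)
  # post-recalibration overall O/E is 1 by construction
  tab <- calibration_table(time, event, rc$risk, 10, n_groups = 5)
  expect_equal(attr(tab, "overall_oe"), 1, tolerance = 1e-9)
  # ranking (and hence concordance) unchanged
  expect_equal(rank(rc$risk), rank(risk))
  c0 <- concordance_index(time, event, risk, 10)$c_index
  c1 <- concordance_index(time, event, rc$risk, 10)$c_index
  expect_equal(c0, c1, tolerance = 1e-12)
  # O/E of exactly one leaves risks unchanged
  rc2 <- recalibrate(time, event, rc$risk, 10)
  expect_equal(rc2$risk, rc$risk, tolerance = 1e-6)
})

test_that("risk classification captures cases as the quantile widens", {
  n <- 1000
  set.seed(5)
  risk <- stats::runif(n)
  # perfect ranking: the 50 highest risks are the cases
  case <- rank(-risk) <= 50
  time <- ifelse(case, 3, 10)
  event <- as.numeric(case)
  tab <- risk_classification(time, event, risk, 5,
                             quantiles = c(0.01, 0.05, 0.5, 1))
  expect_equal(tab$capture[2], 1)            # top 5% holds all 50 cases
  expect_equal(tab$capture[3], 1)
  expect_equal(tab$capture[4], 1)            # quantile 1.0 is always 100%
  expect_equal(tab$capture[1], 10 / 50)      # top 1% = 10 subjects
  expect_true(all(diff(tab$capture) >= 0))
  # risks independent of outcome: capture roughly equals the quantile
  caps <- replicate(40, {
    risk2 <- stats::runif(n)
    risk_classification(time, event, risk2, 5, quantiles = 0.2)$capture
  })
  expect_lt(abs(mean(caps) - 0.2), 0.03)
})

test_that("imputation fills only affected relatives' missing ages", {
  coh <- cohort_records(data.frame(
    id = c("a", "b", "c"), baseline_age = c(50, 60, 55),
    birth_year = c(1958, 1948, 1953),
    father_affected = c(1, 1, 0),
    father_dx_age = c(NA, 72, NA),
    brothers_affected_dx = c("NA", "", ""),
    brothers_unaffected_censor = c("", "48", ""),
    event = 0, time = 5, stringsAsFactors = FALSE))
  out <- impute_relative_dx_ages(coh)
  # father's age now = 50 + 28 = 78; typical dx 70 fits inside [40, 78]
  expect_equal(out$father_dx_age[1], 70)
  # a stated age is untouched
  expect_equal(out$father_dx_age[2], 72)
  # unaffected relatives are never invented
  expect_true(is.na(out$father_dx_age[3]))
  expect_equal(out$brothers_unaffected_censor, coh$brothers_unaffected_censor)
  # clamping: young consultand pulls the imputed age down to his own age + 0
  expect_equal(out$brothers_affected_dx[1], "50")
  # stochastic mode is seeded and respects the clamp
  p <- toy_params()
  st <- hazard_store(make_incidence_fixture(), p)
  s1 <- impute_relative_dx_ages(coh, stochastic = TRUE, store = st, seed = 4)
  s2 <- impute_relative_dx_ages(coh, stochastic = TRUE, store = st, seed = 4)
  expect_identical(s1, s2)
  expect_true(s1$father_dx_age[1] >= 40 && s1$father_dx_age[1] <= 78)
})

test_that("cohort files round-trip through CSV", {
  p <- toy_params(grid = c(obs = 3L, res = 3L), alpha = 0.5)
  cfg <- simulation_config(p, make_incidence_fixture(), seed = 6,
                           prob_pgs = 1)
  coh <- simulate_cohort(cfg, 25)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_equal(nrow(back), 25L)
  expect_equal(back$baseline_age, coh$baseline_age)
  expect_equal(back$time, coh$time, tolerance = 1e-12)
  expect_equal(back$brothers_affected_dx, coh$brothers_affected_dx)
  expect_equal(back$pgs, coh$pgs, tolerance = 1e-12)
})
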