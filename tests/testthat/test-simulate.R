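test_that("simulation is reproducible and subsets are stream-stable", {
  p <- toy_params(grid = c(obs = 3L, res = 3L), alpha = 0.5)
  inc <- make_incidence_fixture()
  cfg <- simulation_config(p, inc, seed = 21, prob_pgs = 1)
  a <- simulate_families(cfg, 12)
  b <- simulate_families(cfg, 12)
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  write_pedigrees(a, f1)
  write_pedigrees(b, f2)
  expect_identical(readLines(f1), readLines(f2))
  # the first families do not depend on how many are drawn in total
  c5 <- simulate_families(cfg, 5)
  for (i in 1:5) expect_equal(c5[[i]]$members, a[[i]]$members)
})

test_that("ascertainment arms enforce their selection criteria", {
  p <- toy_params(grid = c(obs = 1L, res = 3L))
  inc <- make_incidence_fixture()
  pop <- simulate_families(simulation_config(p, inc, seed = 2,
                                             arm = "population"), 40)
  for (ped in pop) {
    pr <- ped$members[ped$members$proband, ]
    expect_false(is.na(pr$prostate_dx_age))
  }
  yo <- simulate_families(simulation_config(p, inc, seed = 3,
                                            arm = "young_onset",
                                            young_onset_age = 65), 15)
  for (ped in yo) {
    pr <- ped$members[ped$members$proband, ]
    expect_lt(pr$prostate_dx_age, 65)
  }
  fh <- simulate_families(simulation_config(p, inc, seed = 4,
                                            arm = "fh_enriched",
                                            n_brothers_lambda = 2), 15)
  for (ped in fh) {
    m <- ped$members
    fdr <- m[m$sex == "M" & !m$proband, ]
    expect_gt(sum(!is.na(fdr$prostate_dx_age)), 0)
  }
  # unascertained samples have unaffected probands too
  none <- simulate_families(simulation_config(p, inc, seed = 5,
                                              arm = "none"), 60)
  aff <- vapply(none, function(ped)
    !is.na(ped$members$prostate_dx_age[ped$members$id == "proband"]),
    logical(1))
  expect_lt(mean(aff), 1)
})

test_that("simulated founders match the generative distributions", {
  p <- toy_params(frequencies = c(BRCA2 = 0, BRCA1 = 0, HOXB13 = 0,
                                  REC = 0.3),
                  grid = c(obs = 3L, res = 3L), alpha = 0.5)
  inc <- make_incidence_fixture()
  cfg <- simulation_config(p, inc, seed = 17, arm = "none")
  peds <- simulate_families(cfg, 400)
  sp <- build_state_space(p)
  founder_states <- unlist(lapply(peds, function(ped)
    attr(ped, "true_states")[1:2]))
  n <- length(founder_states)
  # REC allele frequency among founders
  counts <- sp$feat$count_REC[founder_states]
  qhat <- mean(counts) / 2
  se <- sqrt(0.3 * 0.7 / (2 * n))
  expect_lt(abs(qhat - 0.3), 3 * se)
  # polygene moments (combined loading has mean 0, variance 1)
  u <- canpros:::polygene_loading(sp, p)[founder_states]
  expect_lt(abs(mean(u)), 3 / sqrt(n))
  expect_lt(abs(stats::var(u) - 1), 3 * sqrt(2 / n))
})

test_that("ascertained families inflate naive familial risk", {
  p <- canpros_params(frequencies = c(BRCA2 = 0, BRCA1 = 0, HOXB13 = 0,
                                      REC = 0.2),
                      rr_rec = 8, sigma70 = 1.5, sigma_rate = 1,
                      grid = c(obs = 1L, res = 3L))
  inc <- make_incidence_fixture()
  asc <- simulate_families(simulation_config(p, inc, seed = 31,
                                             arm = "population",
                                             n_brothers_lambda = 2), 250)
  fathers_aff <- vapply(asc, function(ped)
    !is.na(ped$members$prostate_dx_age[1]), logical(1))
  # fathers of affected probands are affected far above the population rate
  pop_rate <- cumulative_risk(canpros:::store_hazards(
    hazard_store(inc, p), 1895), NULL, 0, 85)
  expect_gt(mean(fathers_aff), pop_rate)
})

test_that("null model gives independent sibling phenotypes", {
  p <- canpros_params(frequencies = c(BRCA2 = 0, BRCA1 = 0, HOXB13 = 0,
                                      REC = 0),
                      sigma70 = 0, grid = c(obs = 1L, res = 1L))
  inc <- make_incidence_fixture()
  peds <- simulate_families(simulation_config(p, inc, seed = 23,
                                              arm = "population",
                                              n_brothers_lambda = 2), 300)
  # brothers of (always affected) probands: their affection rate must match
  # the unascertained population rate for their age profile
  bro_aff <- c()
  bro_exp <- c()
  st <- hazard_store(inc, p)
  for (ped in peds) {
    m <- ped$members
    b <- m[startsWith(m$id, "brother"), ]
    if (!nrow(b)) next
    bro_aff <- c(bro_aff, !is.na(b$prostate_dx_age))
    hzb <- canpros:::store_hazards(st, b$birth_year[1])
    bro_exp <- c(bro_exp, vapply(b$censor_age, function(a)
      if (a < 1) 0 else cumulative_risk(hzb, NULL, 0, a), numeric(1)))
  }
  obs <- mean(bro_aff)
  expected <- mean(bro_exp)
  se <- sqrt(expected * (1 - expected) / length(bro_aff))
  expect_lt(abs(obs - expected), 3 * se)
})

test_that("cohort simulation respects its design", {
  p <- toy_params(grid = c(obs = 3L, res = 3L), alpha = 0.5)
  inc <- make_incidence_fixture()
  # near-zero follow-up gives no events
  cfg0 <- simulation_config(p, inc, seed = 7, followup_range = c(1e-6, 1e-6))
  coh0 <- simulate_cohort(cfg0, 150)
  expect_equal(sum(coh0$event), 0)
  # masking: tests available for roughly the configured fraction
  cfg <- simulation_config(p, inc, seed = 8, prob_pgs = 1,
                           prob_tested = c(BRCA2 = 0.4, BRCA1 = 0.4,
                                           HOXB13 = 0.4))
  coh <- simulate_cohort(cfg, 400)
  frac <- mean(coh$brca2_test != "untested")
  expect_lt(abs(frac - 0.4), 3 * sqrt(0.4 * 0.6 / 400))
  expect_true(all(coh$time > 0))
  expect_true(all(coh$baseline_age >= 45 & coh$baseline_age <= 69))
  # event counts match the model-expected counts
  cfg2 <- simulation_config(p, inc, seed = 9, prob_pgs = 1, arm = "none")
  coh2 <- simulate_cohort(cfg2, 1500)
  st <- hazard_store(inc, p)
  pred <- predict_cohort_risks(coh2, st, 5, info = "all")
  at_risk5 <- coh2$time >= 5 | coh2$event == 1
  obs <- sum(coh2$event == 1 & coh2$time <= 5)
  exp_ev <- sum(pred * mean(at_risk5))
  expect_lt(abs(obs - exp_ev), 3 * sqrt(exp_ev))
})

test_that("the incidence fixture is integrable and scalable", {
  inc <- make_incidence_fixture()
  rates <- incidence_rate(inc, 0:84, 1960)
  lifetime <- 1 - exp(-sum(rates))
  expect_gt(lifetime, 0.05)
  expect_lt(lifetime, 0.35)
  z <- make_incidence_fixture(scale = 0)
  expect_equal(incidence_rate(z, 0:89, 1950), rep(0, 90))
})
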