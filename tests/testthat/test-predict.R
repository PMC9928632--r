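test_that("with no information the posterior is the survivor-weighted prior", {
  p <- toy_params(grid = c(obs = 3L, res = 3L), alpha = 0.5)
  st <- hazard_store(make_incidence_fixture(), p)
  ped <- pedigree(data.frame(id = "c", sex = "M", birth_year = 1960,
                             censor_age = 45))
  post <- posterior_states(ped, "c", st)
  sp <- attr(post, "space")
  hz <- canpros:::store_hazards(st, 1960)
  manual <- sp$prior * hz$S[46, ]
  expect_equal(as.numeric(post), manual / sum(manual), tolerance = 1e-12)
  # and the predicted risk equals the population mixture risk
  r <- predict_risk(ped, "c", st, target_ages = 85)
  expect_equal(r$risk, cumulative_risk(hz, NULL, 45, 85), tolerance = 1e-12)
})

test_that("a positive test implies carrier status (perfect specificity)", {
  p <- canpros_params(grid = c(obs = 3L, res = 3L))
  st <- hazard_store(make_incidence_fixture(), p)
  ped <- pedigree(data.frame(id = "c", sex = "M", birth_year = 1965,
                             censor_age = 45, brca2_test = "carrier",
                             stringsAsFactors = FALSE))
  post <- posterior_states(ped, "c", st)
  sp <- attr(post, "space")
  expect_equal(sum(post[sp$feat$count_BRCA2 >= 1]), 1, tolerance = 1e-12)
})

test_that("an affected consultand is refused", {
  p <- toy_params()
  st <- hazard_store(make_incidence_fixture(), p)
  ped <- pedigree(data.frame(id = "c", sex = "M", censor_age = 60,
                             prostate_dx_age = 55))
  expect_error(posterior_states(ped, "c", st), "affected")
  ped2 <- pedigree(data.frame(id = "c", sex = "M", censor_age = 45))
  expect_error(predict_risk(ped2, "c", st, target_ages = 40), "exceed")
})

test_that("an affected brother updates the posterior by Bayes' rule", {
  p <- toy_params(grid = c(obs = 1L, res = 3L), rr_rec = 4)
  st <- hazard_store(make_incidence_fixture(), p)
  m <- data.frame(
    id = c("f", "m", "c", "b"),
    father_id = c(NA, NA, "f", "f"), mother_id = c(NA, NA, "m", "m"),
    sex = c("M", "F", "M", "M"), birth_year = c(1930, 1932, 1960, 1958),
    censor_age = c(NA, NA, 45, 50),
    prostate_dx_age = c(NA, NA, NA, 50), stringsAsFactors = FALSE)
  post <- posterior_states(pedigree(m), "c", st)
  sp <- attr(post, "space")
  N <- sp$N
  # hand enumeration over (father, mother, consultand, brother)
  hz_p <- canpros:::store_hazards(st, 1930)
  hz_c <- canpros:::store_hazards(st, 1960)
  hz_b <- canpros:::store_hazards(st, 1958)
  Tf <- array(sp$tfull, c(N, N, N))
  manual <- rep(0, N)
  for (f in 1:N) for (mm in 1:N) {
    w <- sp$prior[f] * sp$prior[mm]
    bro <- sum(Tf[f, mm, ] * hz_b$f_year[51, ])
    manual <- manual + w * bro * Tf[f, mm, ]
  }
  manual <- manual * hz_c$S[46, ]
  expect_equal(as.numeric(post), manual / sum(manual), tolerance = 1e-10)
})

test_that("risks are monotone in PGS, family history, and diagnosis age", {
  p <- canpros_params(grid = c(obs = 3L, res = 3L))
  st <- hazard_store(make_incidence_fixture(), p)
  # increasing in the PGS percentile
  pct <- c(0.05, 0.25, 0.5, 0.75, 0.95)
  r_pgs <- vapply(pct, function(q)
    scenario_risk(st, pgs_percentile = q, target_ages = 85)$risk, numeric(1))
  expect_true(all(diff(r_pgs) > 0))
  # increasing in the number of affected first-degree relatives
  r0 <- scenario_risk(st, target_ages = 85)$risk
  r1 <- scenario_risk(st, father_dx_age = 60, target_ages = 85)$risk
  r2 <- scenario_risk(st, father_dx_age = 60, brother_dx_age = 60,
                      target_ages = 85)$risk
  expect_true(r0 < r1 && r1 < r2)
  # decreasing in the relative's age at diagnosis
  r_young <- scenario_risk(st, father_dx_age = 50, target_ages = 85)$risk
  r_old <- scenario_risk(st, father_dx_age = 80, target_ages = 85)$risk
  expect_gt(r_young, r_old)
  # risk curves are nondecreasing and zero-length from the current age
  rc <- scenario_risk(st, father_dx_age = 50, target_ages = seq(50, 85, 5))
  expect_true(all(diff(rc$risk) >= 0))
  expect_true(all(rc$risk >= 0 & rc$risk <= 1))
})

test_that("a negative test lies strictly between untested and noncarrier", {
  p <- canpros_params(frequencies = c(BRCA2 = 0.02, BRCA1 = 0, HOXB13 = 0,
                                      REC = 0),
                      grid = c(obs = 1L, res = 3L))
  st <- hazard_store(make_incidence_fixture(), p)
  r_untested <- scenario_risk(st, target_ages = 85)$risk
  r_negative <- scenario_risk(st, pv = "noncarrier", target_ages = 85)$risk
  # a perfectly sensitive test identifies true noncarriers
  p_perfect <- p
  p_perfect$sensitivity[] <- 1
  st_p <- hazard_store(make_incidence_fixture(), p_perfect)
  r_noncarrier <- scenario_risk(st_p, pv = "noncarrier",
                                target_ages = 85)$risk
  expect_gt(r_untested, r_negative)
  expect_gt(r_negative, r_noncarrier)
})

test_that("familial relative risks collapse to 1 without heterogeneity", {
  p <- canpros_params(frequencies = c(BRCA2 = 0, BRCA1 = 0, HOXB13 = 0,
                                      REC = 0),
                      sigma70 = 0, grid = c(obs = 1L, res = 1L))
  st <- hazard_store(make_incidence_fixture(), p)
  for (rel in c("father", "brother", "son")) {
    frr <- familial_relative_risk(st, rel, 60, c(50, 60, 70))
    expect_equal(frr$frr, rep(1, 3), tolerance = 1e-10)
  }
})

test_that("kin FRRs match brute-force enumeration for a dominant locus", {
  p <- canpros_params(frequencies = c(BRCA2 = 0, BRCA1 = 0, HOXB13 = 0,
                                      REC = 0.1),
                      rec_model = "dominant", rr_rec = 3, sigma70 = 0,
                      grid = c(obs = 1L, res = 1L))
  st <- hazard_store(make_incidence_fixture(), p)
  sp <- st$space
  N <- sp$N
  dx <- 60
  hz <- canpros:::store_hazards(st, p$default_birth_year)
  hz_f <- canpros:::store_hazards(st, p$default_birth_year - 30)
  Tf <- array(sp$tfull, c(N, N, N))
  # father affected at dx: joint sum over (father, mother, son)
  num <- den <- rep(0, N)
  for (f in 1:N) for (m in 1:N) {
    w <- sp$prior[f] * hz_f$f_year[dx + 1, f] * sp$prior[m]
    den <- den + w * Tf[f, m, ]
  }
  t_eval <- 55
  w_son <- den
  h_rel <- sum(w_son * hz$S[t_eval + 1, ] * hz$lam[t_eval + 1, ]) /
    sum(w_son * hz$S[t_eval + 1, ])
  h_pop <- sum(sp$prior * hz$S[t_eval + 1, ] * hz$lam[t_eval + 1, ]) /
    sum(sp$prior * hz$S[t_eval + 1, ])
  frr <- familial_relative_risk(st, "father", dx, t_eval)
  expect_equal(frr$frr, h_rel / h_pop, tolerance = 1e-10)
  expect_gt(frr$frr, 1)
})

test_that("a recessive component makes brother FRRs exceed father FRRs", {
  p <- canpros_params(frequencies = c(BRCA2 = 0, BRCA1 = 0, HOXB13 = 0,
                                      REC = 0.2),
                      rr_rec = 8, sigma70 = 0, grid = c(obs = 1L, res = 1L))
  st <- hazard_store(make_incidence_fixture(), p)
  ages <- c(50, 60, 70)
  frr_f <- familial_relative_risk(st, "father", 60, ages)$frr
  frr_b <- familial_relative_risk(st, "brother", 60, ages)$frr
  expect_true(all(frr_b > frr_f))
  # and father equals son by symmetry of the one-locus kinship
  frr_s <- familial_relative_risk(st, "son", 60, ages,
                                  birth_year = p$default_birth_year,
                                  index_birth_year = p$default_birth_year)$frr
  frr_f2 <- familial_relative_risk(st, "father", 60, ages,
                                   birth_year = p$default_birth_year,
                                   index_birth_year =
                                     p$default_birth_year)$frr
  expect_equal(frr_s, frr_f2, tolerance = 1e-8)
})
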