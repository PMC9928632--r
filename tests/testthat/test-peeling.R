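test_that("a singleton pedigree gives the closed-form survival likelihood", {
  p <- toy_params(grid = c(obs = 1L, res = 1L),
                  frequencies = c(BRCA2 = 0, BRCA1 = 0, HOXB13 = 0, REC = 0),
                  sigma70 = 0)
  lam <- 0.015
  st <- hazard_store(flat_incidence(lam), p)
  ped <- pedigree(data.frame(id = "a", sex = "M", censor_age = 60))
  expect_equal(peel(ped, st), -lam * 60, tolerance = 1e-12)
})

test_that("peeling equals exhaustive enumeration on small pedigrees", {
  p <- toy_params(grid = c(obs = 1L, res = 3L), alpha = 0)  # N = 9
  st <- hazard_store(make_incidence_fixture(), p)
  ped <- nuclear_test_pedigree()
  expect_equal(peel(ped, st), brute_force_loglik(ped, st),
               tolerance = 1e-12)
  # with a daughter carrying a breast cancer diagnosis
  p2 <- toy_params(frequencies = c(BRCA2 = 0.05, BRCA1 = 0, HOXB13 = 0,
                                   REC = 0),
                   grid = c(obs = 1L, res = 3L))
  st2 <- hazard_store(make_incidence_fixture(), p2)
  m <- data.frame(
    id = c("f", "m", "s", "d"),
    father_id = c(NA, NA, "f", "f"), mother_id = c(NA, NA, "m", "m"),
    sex = c("M", "F", "M", "F"),
    birth_year = c(1930, 1932, 1960, 1963),
    censor_age = c(70, 68, 55, 52),
    prostate_dx_age = c(65, NA, NA, NA),
    breast_dx_age = c(NA, NA, NA, 45), stringsAsFactors = FALSE)
  ped2 <- pedigree(m)
  expect_equal(peel(ped2, st2), brute_force_loglik(ped2, st2),
               tolerance = 1e-12)
  # three generations
  m3 <- data.frame(
    id = c("gf", "gm", "f", "m", "s"),
    father_id = c(NA, NA, "gf", NA, "f"),
    mother_id = c(NA, NA, "gm", NA, "m"),
    sex = c("M", "F", "M", "F", "M"),
    birth_year = c(1900, 1902, 1930, 1932, 1960),
    censor_age = c(80, 75, 70, 70, 55),
    prostate_dx_age = c(70, NA, NA, NA, 50), stringsAsFactors = FALSE)
  ped3 <- pedigree(m3)
  expect_equal(peel(ped3, st), brute_force_loglik(ped3, st),
               tolerance = 1e-12)
})

test_that("peeling handles test results and PGS like the enumeration oracle", {
  p <- toy_params(frequencies = c(BRCA2 = 0.08, BRCA1 = 0, HOXB13 = 0,
                                  REC = 0),
                  grid = c(obs = 3L, res = 1L), alpha = 0.6)
  st <- hazard_store(make_incidence_fixture(), p)
  m <- nuclear_test_pedigree()$members
  m$brca2_test <- c("untested", "untested", "carrier", "noncarrier")
  m$pgs <- c(NA, NA, 0.8, NA)
  ped <- pedigree(m)
  expect_equal(peel(ped, st), brute_force_loglik(ped, st), tolerance = 1e-12)
})

test_that("member ordering does not change the log-likelihood", {
  p <- toy_params(grid = c(obs = 1L, res = 3L))
  st <- hazard_store(make_incidence_fixture(), p)
  m3 <- data.frame(
    id = c("gf", "gm", "f", "m", "s"),
    father_id = c(NA, NA, "gf", NA, "f"),
    mother_id = c(NA, NA, "gm", NA, "m"),
    sex = c("M", "F", "M", "F", "M"),
    birth_year = c(1900, 1902, 1930, 1932, 1960),
    censor_age = c(80, 75, 70, 70, 55),
    prostate_dx_age = c(70, NA, NA, NA, 50), stringsAsFactors = FALSE)
  ll <- peel(pedigree(m3), st)
  for (perm in list(c(5, 4, 3, 2, 1), c(3, 1, 5, 2, 4))) {
    expect_equal(peel(pedigree(m3[perm, ]), st), ll, tolerance = 1e-12)
  }
})

test_that("phenotype probabilities sum to one over the outcome partition", {
  # for each member the phenotype space {dx at 0..a-1, unaffected at a}
  # partitions the sample space; the product space must sum to 1
  p <- toy_params(grid = c(obs = 1L, res = 3L), max_age = 6L)
  inc <- flat_incidence(0.08, max_age = 6)
  st <- hazard_store(inc, p)
  base <- data.frame(
    id = c("f", "m", "s"), father_id = c(NA, NA, "f"),
    mother_id = c(NA, NA, "m"), sex = c("M", "F", "M"),
    birth_year = 1960, stringsAsFactors = FALSE)
  a <- c(3L, 0L, 4L)  # mother carries no phenotype information here
  outcomes <- function(cens) c(seq_len(cens) - 1L, NA_integer_)
  total <- 0
  for (dx_f in outcomes(a[1])) for (dx_s in outcomes(a[3])) {
    m <- base
    m$censor_age <- a
    m$prostate_dx_age <- c(dx_f, NA, dx_s)
    m$censor_age[1] <- if (is.na(dx_f)) a[1] else max(dx_f, 1)
    m$censor_age[3] <- if (is.na(dx_s)) a[3] else max(dx_s, 1)
    total <- total + exp(peel(pedigree(m), st))
  }
  expect_equal(total, 1, tolerance = 1e-10)
})

test_that("individual likelihood factors follow their closed forms", {
  p <- canpros_params(frequencies = c(BRCA2 = 0.05, BRCA1 = 0, HOXB13 = 0,
                                      REC = 0),
                      sigma70 = 0, grid = c(obs = 1L, res = 1L))
  lam <- 0.012
  st <- hazard_store(flat_incidence(lam), p)
  sp <- st$space
  carrier <- sp$feat$count_BRCA2 >= 1
  # unaffected, untested male: survival under the baseline (noncarrier)
  # or 7-fold (carrier, RR below age 55) cumulative hazard
  f <- individual_likelihood(list(id = "a", sex = "M", birth_year = 1960,
                                  censor_age = 40), st)
  l0 <- canpros:::store_hazards(st, 1960)$lambda0
  expect_equal(f[!carrier][1], exp(-sum(l0[1:40])), tolerance = 1e-12)
  expect_equal(f[carrier][1], exp(-7 * sum(l0[1:40])), tolerance = 1e-12)
  # a true carrier testing negative contributes 1 - sensitivity
  g <- individual_likelihood(list(id = "a", sex = "M",
                                  brca2_test = "noncarrier"), st)
  expect_equal(unique(g[carrier]), 1 - 0.83, tolerance = 1e-12)
  expect_equal(unique(g[!carrier]), 1)
  # and a positive test zeroes noncarrier states
  h <- individual_likelihood(list(id = "a", sex = "M",
                                  brca2_test = "carrier"), st)
  expect_equal(unique(h[!carrier]), 0)
  expect_equal(unique(h[carrier]), 0.83)
  # affected at age a: survival to a times the probability of an event in
  # [a, a+1); the within-year factor is cross-checked against a finely
  # discretized density integral under the year's constant hazard
  dx <- 35
  fa <- individual_likelihood(list(id = "a", sex = "M", birth_year = 1960,
                                   censor_age = dx, prostate_dx_age = dx),
                              st)
  lam_dx <- l0[dx + 1]
  u <- seq(0, 1 - 1e-4, by = 1e-4)
  year_prob <- sum(lam_dx * exp(-lam_dx * (u + 5e-5)) * 1e-4)
  expect_equal(fa[!carrier][1], exp(-sum(l0[1:dx])) * year_prob,
               tolerance = 1e-6)
})

test_that("a negative test downweights carriers by one minus sensitivity", {
  p <- canpros_params(frequencies = c(BRCA2 = 0.05, BRCA1 = 0, HOXB13 = 0,
                                      REC = 0),
                      sigma70 = 0, grid = c(obs = 1L, res = 1L))
  st <- hazard_store(make_incidence_fixture(), p)
  m <- data.frame(id = "a", sex = "M", censor_age = 1,
                  brca2_test = "noncarrier", stringsAsFactors = FALSE)
  post <- posterior_states(pedigree(m), "a", st)
  sp <- attr(post, "space")
  carrier <- sp$feat$count_BRCA2 >= 1
  prior_odds <- sum(sp$prior[carrier]) / sum(sp$prior[!carrier])
  post_odds <- sum(post[carrier]) / sum(post[!carrier])
  # posterior odds = prior odds x (1 - 0.83), survival cancels at age 1
  expect_equal(post_odds / prior_odds, 1 - 0.83, tolerance = 1e-6)
})

test_that("ascertainment conditioning matches its definition", {
  p <- toy_params(grid = c(obs = 1L, res = 3L))
  st <- hazard_store(make_incidence_fixture(), p)
  m <- nuclear_test_pedigree()$members
  m$proband <- c(FALSE, FALSE, TRUE, FALSE)
  m$detection <- c("not_applicable", "not_applicable", "symptomatic",
                   "not_applicable")
  ped <- pedigree(m, arm = "population")
  # none reproduces the unadjusted likelihood
  expect_equal(condition(ped, st, scheme = "none"), peel(ped, st))
  # proband-phenotype conditioning: subtract the proband's marginal
  sp <- st$space
  pro <- as.list(ped$members[3, ])
  pen <- canpros:::penetrance_vector(pro, st)
  expect_equal(condition(ped, st, scheme = "proband_phenotype"),
               peel(ped, st) - log(sum(sp$prior * pen)),
               tolerance = 1e-10)
  # detection mode drives the automatic scheme
  expect_equal(condition(ped, st, scheme = "auto"),
               condition(ped, st, scheme = "proband_phenotype"))
  m$detection[3] <- "screen"
  ped2 <- pedigree(m, arm = "population")
  expect_equal(condition(ped2, st, scheme = "auto"),
               condition(ped2, st, scheme = "family_phenotypes"))
  # when the family data are exactly the conditioning data the
  # adjusted log-likelihood is zero
  expect_equal(condition(ped2, st, scheme = "family_phenotypes"), 0,
               tolerance = 1e-10)
  # family-phenotype conditioning keeps only the test/PGS information
  m$brca2_test <- c("untested", "untested", "noncarrier", "untested")
  p2 <- toy_params(frequencies = c(BRCA2 = 0.05, BRCA1 = 0, HOXB13 = 0,
                                   REC = 0.3),
                   grid = c(obs = 1L, res = 3L))
  st2 <- hazard_store(make_incidence_fixture(), p2)
  ped3 <- pedigree(m, arm = "population")
  masked <- m
  masked$brca2_test <- "untested"
  expect_equal(condition(ped3, st2, scheme = "family_phenotypes"),
               peel(ped3, st2) - peel(pedigree(masked, arm = "population"),
                                      st2),
               tolerance = 1e-10)
})
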