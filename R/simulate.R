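#' Simulation configuration
#'
#' Bundles the generative model (parameters and incidence constraint) with
#' the family-structure and study-design laws used by [simulate_families()]
#' and [simulate_cohort()]. One pseudo-random stream is derived per family
#' from `(seed, family index)`, so any subset of families is reproducible
#' independently of the total number simulated.
#'
#' @param params a `canpros_params` object (the generative truth).
#' @param incidence a `canpros_incidence` table (the constraint target).
#' @param n_brothers_lambda Poisson mean number of brothers.
#' @param n_sisters_lambda Poisson mean number of sisters.
#' @param proband_birth_range inclusive range of proband birth years.
#' @param parent_age_mean,parent_age_sd parents' age at the proband's birth
#'   (normal, clamped to 18-45).
#' @param sibling_spread siblings' birth years are the proband's plus an
#'   integer uniform on `[-spread, spread]`.
#' @param study_year everyone is censored at this calendar year.
#' @param arm ascertainment arm: probands are affected men
#'   (`"population"`), additionally diagnosed before `young_onset_age`
#'   (`"young_onset"`), or with at least one affected first-degree relative
#'   (`"fh_enriched"`); `"none"` disables ascertainment.
#' @param young_onset_age age cutoff of the young-onset arm.
#' @param detection_mix probabilities of the proband's detection mode.
#' @param prob_tested named per-gene probability that the proband is tested.
#' @param prob_pgs probability that the proband has an observed PGS.
#' @param baseline_age_range cohort mode: baseline ages sampled uniformly.
#' @param entry_year cohort mode: calendar year of baseline.
#' @param followup_range cohort mode: administrative censoring times,
#'   uniform.
#' @param max_rejects bound on ascertainment rejections per family.
#' @param seed master seed.
#' @return A list of class `canpros_simconfig`.
#' @export
simulation_config <- function(params, incidence,
                              n_brothers_lambda = 1.5,
                              n_sisters_lambda = 0,
                              proband_birth_range = c(1920, 1950),
                              parent_age_mean = 28, parent_age_sd = 5,
                              sibling_spread = 5,
                              study_year = 2005,
                              arm = "population",
                              young_onset_age = 60,
                              detection_mix = c(symptomatic = 0.50,
                                                screen = 0.24,
                                                unknown = 0.26),
                              prob_tested = c(BRCA2 = 0, BRCA1 = 0,
                                              HOXB13 = 0),
                              prob_pgs = 0,
                              baseline_age_range = c(45, 69),
                              entry_year = 2008,
                              followup_range = c(9, 13),
                              max_rejects = 5000L,
                              seed = 1L) {
  structure(list(params = params, incidence = incidence,
                 n_brothers_lambda = n_brothers_lambda,
                 n_sisters_lambda = n_sisters_lambda,
                 proband_birth_range = proband_birth_range,
                 parent_age_mean = parent_age_mean,
                 parent_age_sd = parent_age_sd,
                 sibling_spread = sibling_spread,
                 study_year = study_year, arm = arm,
                 young_onset_age = young_onset_age,
                 detection_mix = detection_mix,
                 prob_tested = prob_tested, prob_pgs = prob_pgs,
                 baseline_age_range = baseline_age_range,
                 entry_year = entry_year, followup_range = followup_range,
                 max_rejects = as.integer(max_rejects),
                 seed = as.integer(seed)),
            class = "canpros_simconfig")
}

family_seed <- function(seed, i) {
  (as.double(seed) * 48271 + as.double(i) * 16807) %% 2147483647
}

# inverse-transform sampling of a diagnosis age from per-state annual event
# probabilities; returns NA if no event by censor_age.
sample_dx <- function(f_year_state, censor_age, u) {
  if (censor_age < 1) return(NA_real_)
  cf <- cumsum(f_year_state[seq_len(min(censor_age, length(f_year_state)))])
  idx <- findInterval(u, c(0, cf), left.open = TRUE)
  if (idx > length(cf)) NA_real_ else idx - 1
}

sample_female_dx <- function(params, b1, b2, censor_age) {
  out <- c(breast = NA_real_, ovarian = NA_real_)
  if (censor_age < 1) return(out)
  for (site in c("breast", "ovarian")) {
    fp <- params$female_penetrance[[site]]
    lam <- step_lookup(fp$rates, 0:(censor_age - 1), value_col = "rate") *
      (if (b1) fp$rr_brca1 else 1) * (if (b2 && !b1) fp$rr_brca2 else 1)
    S <- exp(-cumsum(c(0, lam[-length(lam)])))
    f <- S * (1 - exp(-lam))
    out[site] <- sample_dx(f, censor_age, stats::runif(1))
  }
  out
}

# draw one family (states, phenotypes) without ascertainment
draw_family <- function(cfg, store) {
  params <- cfg$params
  space <- store$space
  N <- space$N
  cb <- sample(cfg$proband_birth_range[1]:cfg$proband_birth_range[2], 1L)
  off_f <- round(min(max(stats::rnorm(1, cfg$parent_age_mean,
                                      cfg$parent_age_sd), 18), 45))
  off_m <- round(min(max(stats::rnorm(1, cfg$parent_age_mean,
                                      cfg$parent_age_sd), 18), 45))
  nb <- stats::rpois(1, cfg$n_brothers_lambda)
  ns <- stats::rpois(1, cfg$n_sisters_lambda)
  sib_b <- if (nb + ns > 0)
    cb + sample(-cfg$sibling_spread:cfg$sibling_spread, nb + ns,
                replace = TRUE) else integer(0)
  ids <- c("father", "mother", "proband",
           if (nb > 0) paste0("brother", seq_len(nb)),
           if (ns > 0) paste0("sister", seq_len(ns)))
  sex <- c("M", "F", "M", rep("M", nb), rep("F", ns))
  birth <- c(cb - off_f, cb - off_m, cb, sib_b)
  n <- length(ids)
  # states sampled per component (transmission factorizes)
  K <- length(space$dims)
  strides <- cumprod(c(1L, space$dims[-K]))
  founder_comp <- function() vapply(space$comps, function(cm)
    if (cm$n == 1L) 1L else sample.int(cm$n, 1L, prob = cm$prior),
    integer(1))
  fc <- founder_comp()
  mc <- founder_comp()
  comp_to_state <- function(ci) as.integer(sum((ci - 1L) * strides) + 1L)
  state <- integer(n)
  state[1] <- comp_to_state(fc)
  state[2] <- comp_to_state(mc)
  for (j in 3:n) {
    cc <- vapply(seq_len(K), function(i) {
      cm <- space$comps[[i]]
      if (cm$n == 1L) 1L
      else sample.int(cm$n, 1L, prob = cm$trans[fc[i], mc[i], ])
    }, integer(1))
    state[j] <- comp_to_state(cc)
  }
  censor <- pmin(pmax(cfg$study_year - birth, 0), params$max_age)
  pro_dx <- rep(NA_real_, n)
  br_dx <- rep(NA_real_, n)
  ov_dx <- rep(NA_real_, n)
  for (j in seq_len(n)) {
    if (censor[j] < 1) next
    if (sex[j] == "M") {
      hz <- store_hazards(store, birth[j])
      pro_dx[j] <- sample_dx(hz$f_year[, state[j]], censor[j],
                             stats::runif(1))
    } else {
      b1 <- space$feat$count_BRCA1[state[j]] >= 1L
      b2 <- space$feat$count_BRCA2[state[j]] >= 1L
      fdx <- sample_female_dx(params, b1, b2, censor[j])
      br_dx[j] <- fdx[["breast"]]
      ov_dx[j] <- fdx[["ovarian"]]
    }
  }
  censor_out <- censor
  censor_out[1:2] <- ifelse(censor[1:2] > 0, censor[1:2], NA_real_)
  list(ids = ids, sex = sex, birth = birth, censor = censor_out,
       state = state, prostate_dx = pro_dx, breast_dx = br_dx,
       ovarian_dx = ov_dx, n_brothers = nb)
}

fam_to_pedigree <- function(fam, cfg, store, famid) {
  params <- cfg$params
  space <- store$space
  n <- length(fam$ids)
  m <- data.frame(
    id = fam$ids,
    father_id = c(NA, NA, rep("father", n - 2L)),
    mother_id = c(NA, NA, rep("mother", n - 2L)),
    sex = fam$sex, birth_year = fam$birth,
    censor_age = fam$censor,
    prostate_dx_age = fam$prostate_dx,
    breast_dx_age = fam$breast_dx,
    ovarian_dx_age = fam$ovarian_dx,
    detection = "not_applicable",
    proband = c(FALSE, FALSE, TRUE, rep(FALSE, n - 3L)),
    brca2_test = "untested", brca1_test = "untested",
    hoxb13_test = "untested", pgs = NA_real_,
    stringsAsFactors = FALSE)
  pi <- 3L
  if (!is.na(m$prostate_dx_age[pi]))
    m$detection[pi] <- sample(names(cfg$detection_mix), 1L,
                              prob = cfg$detection_mix)
  for (g in c("BRCA2", "BRCA1", "HOXB13")) {
    if (stats::runif(1) < cfg$prob_tested[[g]]) {
      carrier <- space$feat[[paste0("count_", g)]][fam$state[pi]] >= 1L
      pos <- carrier && stats::runif(1) < params$sensitivity[[g]]
      m[[paste0(tolower(g), "_test")]][pi] <-
        if (pos) "carrier" else "noncarrier"
    }
  }
  if (stats::runif(1) < cfg$prob_pgs)
    m$pgs[pi] <- space$feat$v_obs[fam$state[pi]] +
      stats::rnorm(1, 0, params$pgs_nugget_sd)
  ped <- pedigree(m, famid = famid, arm = cfg$arm, validate = FALSE)
  attr(ped, "true_states") <- fam$state
  ped
}

ascertained <- function(fam, cfg) {
  if (cfg$arm == "none") return(TRUE)
  dx <- fam$prostate_dx[3L]
  if (is.na(dx)) return(FALSE)
  if (cfg$arm == "young_onset" && dx >= cfg$young_onset_age) return(FALSE)
  if (cfg$arm == "fh_enriched") {
    fdr <- c(1L, seq_len(length(fam$ids))[-c(1:3)])
    fdr_male <- fdr[fam$sex[fdr] == "M"]
    if (!any(!is.na(fam$prostate_dx[fdr_male]))) return(FALSE)
  }
  TRUE
}

#' Simulate ascertained prostate cancer families
#'
#' Draws founders from the genotype/polygene prior, transmits states
#' Mendelianly (hypergeometric model for the polygene parts), samples
#' phenotypes from the constrained genotype-specific hazards by inverse
#' transform on the annual hazard grid, and applies the configured
#' ascertainment by rejection (the proband must be an affected man, plus
#' arm-specific criteria). Detection modes, genetic tests (with the
#' configured sensitivities) and PGS observations are attached to the
#' proband per the configuration.
#'
#' @param config a [simulation_config()].
#' @param n number of families.
#' @return List of `canpros_pedigree` objects; each carries its members'
#'   true joint states in the attribute `true_states`.
#' @export
simulate_families <- function(config, n) {
  store <- hazard_store(config$incidence, config$params)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(family_seed(config$seed, i))
    ok <- FALSE
    for (tries in seq_len(config$max_rejects)) {
      fam <- draw_family(config, store)
      if (ascertained(fam, config)) {
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("ascertainment acceptance probability too low: family ", i,
           " rejected ", config$max_rejects, " times (arm ", config$arm, ")")
    out[[i]] <- fam_to_pedigree(fam, config, store,
                                famid = sprintf("fam%05d", i))
  }
  out
}

#' Simulate a prospective validation cohort
#'
#' Generates hidden families as in [simulate_families()], selects the index
#' man if he is unaffected at his sampled baseline age, and derives the
#' baseline family-history summary (affected father/brothers with diagnosis
#' ages known by baseline; unaffected relatives' current ages), sampled
#' genetic tests and PGS, and the prospective outcome (event time within the
#' administrative follow-up, continuous within the diagnosis year).
#'
#' @param config a [simulation_config()]; `prob_tested` masks PV data for a
#'   subset of records, as in validation designs where panel data cover only
#'   part of the cohort.
#' @param n number of cohort records.
#' @return A `canpros_cohort` data frame; the attribute `truth` holds the
#'   index men's true states.
#' @export
simulate_cohort <- function(config, n) {
  store <- hazard_store(config$incidence, config$params)
  params <- config$params
  space <- store$space
  A <- params$max_age
  rows <- vector("list", n)
  truth <- integer(n)
  for (i in seq_len(n)) {
    set.seed(family_seed(config$seed, i) + 1)
    rec <- NULL
    for (tries in seq_len(config$max_rejects)) {
      baseline_age <- sample(
        config$baseline_age_range[1]:config$baseline_age_range[2], 1L)
      cfg_i <- config
      cfg_i$proband_birth_range <- rep(config$entry_year - baseline_age, 2L)
      cfg_i$study_year <- config$entry_year + ceiling(A)
      fam <- draw_family(cfg_i, store)
      dx <- fam$prostate_dx[3L]
      if (!is.na(dx) && dx < baseline_age) next
      # family history as known at baseline
      f_age_now <- min(config$entry_year - fam$birth[1L], A)
      f_dx <- fam$prostate_dx[1L]
      f_aff <- as.numeric(!is.na(f_dx) && f_dx < f_age_now)
      bro <- which(startsWith(fam$ids, "brother"))
      bro_age_now <- pmin(config$entry_year - fam$birth[bro], A)
      bro_dx <- fam$prostate_dx[bro]
      aff_b <- !is.na(bro_dx) & bro_dx < bro_age_now
      tests <- c(brca2_test = "untested", brca1_test = "untested",
                 hoxb13_test = "untested")
      for (g in c("BRCA2", "BRCA1", "HOXB13")) {
        if (stats::runif(1) < config$prob_tested[[g]]) {
          carrier <- space$feat[[paste0("count_", g)]][fam$state[3L]] >= 1L
          pos <- carrier && stats::runif(1) < params$sensitivity[[g]]
          tests[[paste0(tolower(g), "_test")]] <-
            if (pos) "carrier" else "noncarrier"
        }
      }
      pgs <- if (stats::runif(1) < config$prob_pgs)
        space$feat$v_obs[fam$state[3L]] +
          stats::rnorm(1, 0, params$pgs_nugget_sd)
      else NA_real_
      fup <- stats::runif(1, config$followup_range[1],
                          config$followup_range[2])
      fup <- min(fup, A - baseline_age - 0.01)
      t_event <- if (is.na(dx)) Inf else dx + stats::runif(1) - baseline_age
      event <- as.numeric(t_event <= fup)
      rec <- data.frame(
        id = sprintf("sub%06d", i), baseline_age = baseline_age,
        birth_year = fam$birth[3L],
        father_affected = f_aff,
        father_dx_age = if (f_aff == 1) f_dx else NA_real_,
        father_birth_year = fam$birth[1L],
        father_censor_age = if (f_aff == 0) f_age_now else NA_real_,
        brothers_affected_dx = paste(bro_dx[aff_b], collapse = ";"),
        brothers_unaffected_censor = paste(bro_age_now[!aff_b],
                                           collapse = ";"),
        brca2_test = tests[["brca2_test"]],
        brca1_test = tests[["brca1_test"]],
        hoxb13_test = tests[["hoxb13_test"]],
        pgs = pgs,
        event = event,
        time = if (event == 1) t_event else fup,
        stringsAsFactors = FALSE)
      truth[i] <- fam$state[3L]
      break
    }
    if (is.null(rec))
      stop("could not sample an unaffected-at-baseline man for record ", i)
    rows[[i]] <- rec
  }
  out <- cohort_records(do.call(rbind, rows))
  attr(out, "truth") <- truth
  out
}

#' Synthetic national male prostate cancer incidence fixture
#'
#' A smooth, increasing-then-plateauing age-specific incidence table of
#' realistic magnitude for a modern UK-like population, in 5-year bands,
#' constant over calendar periods. Deterministic. This is a synthetic
#' stand-in for national registry tables, not registry data.
#'
#' @param scale multiplies all rates (0 gives an all-zero table).
#' @param max_age upper age bound.
#' @return A `canpros_incidence` object.
#' @export
make_incidence_fixture <- function(scale = 1, max_age = 90) {
  age_lo <- c(0, seq(40, 85, by = 5))
  age_hi <- c(40, seq(45, 85, by = 5), max_age)[seq_along(age_lo)]
  age_hi[length(age_hi)] <- max_age
  rate <- c(0, 5, 20, 55, 150, 350, 600, 750, 800, 750, 700) / 1e5
  incidence_table(data.frame(
    age_lo = age_lo, age_hi = age_hi,
    period_lo = -Inf, period_hi = Inf,
    sex = "M", site = "prostate", rate = rate * scale))
}
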