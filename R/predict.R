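#' Posterior genotype and polygene distribution for a consultand
#'
#' Distribution over the joint major-genotype x polygene states of an
#' unaffected consultand given the whole pedigree's phenotypes, genetic test
#' results and PGS values, conditioned on the consultand being
#' prostate-cancer-free at their current age (`censor_age`). Computed by
#' peeling with the consultand's state retained.
#'
#' @param ped a `canpros_pedigree`.
#' @param consultand_id member id of the consultand.
#' @param store a hazard store from [hazard_store()] (or `canpros_hazards`).
#' @return Numeric vector over `space$N` states summing to 1, with the state
#'   space as attribute `space`.
#' @export
posterior_states <- function(ped, consultand_id, store) {
  store <- as_store(store)
  m <- ped$members
  i <- match(consultand_id, m$id)
  if (is.na(i)) stop("consultand '", consultand_id, "' not in pedigree")
  if (!is.na(m$prostate_dx_age[i]))
    stop("consultand is already affected; the model predicts future first cancers")
  res <- peel_engine(ped, store, mask = "all", keep_id = consultand_id)
  post <- res$states / sum(res$states)
  attr(post, "space") <- store$space
  post
}

#' Predict absolute prostate cancer risks for a consultand
#'
#' Cumulative risk of a first prostate cancer from the consultand's current
#' age to each target age, averaging the genotype-specific cumulative risks
#' under the constrained hazards over the posterior genotype distribution
#' given family history, test results and PGS. Risks are cause-specific
#' (no competing mortality) and conditional on being cancer-free now.
#'
#' @param ped a `canpros_pedigree`.
#' @param consultand_id consultand member id (must be male and unaffected,
#'   with `censor_age` equal to the current age).
#' @param store a hazard store from [hazard_store()].
#' @param target_ages integer ages, all greater than the current age.
#' @return A data frame of class `canpros_risk` with columns `age`, `risk`,
#'   and attributes `consultand`, `current_age`, and `carrier_risks`
#'   (decomposition of the risk to the final target age by carrier status of
#'   each locus).
#' @export
predict_risk <- function(ped, consultand_id, store, target_ages) {
  store <- as_store(store)
  m <- ped$members
  i <- match(consultand_id, m$id)
  current_age <- m$censor_age[i]
  if (is.na(current_age))
    stop("consultand must have a current age (censor_age)")
  if (any(target_ages <= current_age))
    stop("target ages must exceed the consultand's current age")
  post <- posterior_states(ped, consultand_id, store)
  hz <- store_hazards(store, m$birth_year[i])
  risks <- vapply(target_ages, function(to)
    cumulative_risk(hz, post, current_age, to), numeric(1))
  out <- data.frame(age = target_ages, risk = risks)
  class(out) <- c("canpros_risk", "data.frame")
  attr(out, "consultand") <- consultand_id
  attr(out, "current_age") <- current_age
  to <- max(target_ages)
  feat <- store$space$feat
  dec <- lapply(c("BRCA2", "BRCA1", "HOXB13", "REC"), function(g) {
    carrier <- feat[[paste0("count_", g)]] >= 1L
    p_carrier <- sum(post[carrier])
    r <- if (p_carrier > 0)
      cumulative_risk(hz, post * carrier / p_carrier, current_age, to)
    else NA_real_
    c(p_carrier = p_carrier, risk = r)
  })
  names(dec) <- c("BRCA2", "BRCA1", "HOXB13", "REC")
  attr(out, "carrier_risks") <- dec
  out
}

#' @export
print.canpros_risk <- function(x, ...) {
  cat(sprintf("predicted cumulative prostate cancer risks for '%s' (age %g)\n",
              attr(x, "consultand"), attr(x, "current_age")))
  print(as.data.frame(x))
  invisible(x)
}

#' Model-implied familial relative risk
#'
#' Ratio of the prostate cancer hazard at each target age of an unaffected
#' relative of an affected index case to the population hazard at the same
#' age, computed by exact summation over the joint state space of the pair
#' (father/son) or trio of parents (brothers).
#'
#' @param store a hazard store from [hazard_store()].
#' @param relation relation of the affected index case to the consultand:
#'   `"father"`, `"brother"`, or `"son"`.
#' @param index_dx_age the index case's age at diagnosis.
#' @param target_ages ages at which the consultand's hazard ratio is
#'   evaluated.
#' @param birth_year consultand's birth year.
#' @param index_birth_year index case's birth year (defaults: father 30
#'   years earlier, brother same year, son 30 years later).
#' @return Data frame with columns `age` and `frr`.
#' @export
familial_relative_risk <- function(store, relation = c("father", "brother",
                                                       "son"),
                                   index_dx_age, target_ages,
                                   birth_year = NULL,
                                   index_birth_year = NULL) {
  relation <- match.arg(relation)
  store <- as_store(store)
  space <- store$space
  params <- store$params
  if (is.null(birth_year)) birth_year <- params$default_birth_year
  if (is.null(index_birth_year))
    index_birth_year <- birth_year + switch(relation, father = -30,
                                            brother = 0, son = 30)
  hz_c <- store_hazards(store, birth_year)
  hz_i <- store_hazards(store, index_birth_year)
  A <- params$max_age
  if (index_dx_age >= A) stop("index diagnosis age beyond model horizon")
  fpen <- hz_i$f_year[index_dx_age + 1L, ]
  ones <- rep(1, space$N)
  msg <- switch(relation,
    father = child_message(space,
      pair_interleave(space, space$prior * fpen, space$prior)),
    brother = child_message(space,
      pair_interleave(space, space$prior, space$prior) *
        down_message(space, fpen)),
    son = {
      G <- pair_to_standard(space, down_message(space, fpen))
      as.vector(G %*% space$prior) * space$prior
    })
  w <- msg / sum(msg)
  frr <- vapply(target_ages, function(t) {
    if (t >= A) stop("target age beyond model horizon")
    lam <- hz_c$lam[t + 1L, ]
    S <- hz_c$S[t + 1L, ]
    h_rel <- sum(w * S * lam) / sum(w * S)
    h_pop <- sum(space$prior * S * lam) / sum(space$prior * S)
    h_rel / h_pop
  }, numeric(1))
  data.frame(age = target_ages, frr = frr)
}

#' Predicted risks for standard counseling scenarios
#'
#' Builds a small pedigree for a consultand with optional affected father
#' and/or brother, an optional known pathogenic-variant test result, and an
#' optional PGS percentile, then returns the predicted cumulative risk
#' curve. Defaults follow the standard scenario conventions: a 45-year-old
#' consultand born after 1960 with the father born in the 1930-1939 cohort.
#'
#' @param store a hazard store from [hazard_store()].
#' @param consultand_age current age of the consultand.
#' @param birth_year consultand (and brother) birth year.
#' @param father_dx_age,brother_dx_age ages at diagnosis of an affected
#'   father/brother, or `NULL` for no such relative reported. Unreported
#'   relatives carry no phenotype assumption.
#' @param father_birth_year father's birth year.
#' @param pv one of `"BRCA2"`, `"BRCA1"`, `"HOXB13"` for a positive carrier
#'   test, `"noncarrier"` for negative tests on all three genes, or `NULL`
#'   for untested.
#' @param pgs_percentile PGS percentile in (0, 1), or `NULL` for no PGS.
#' @param target_ages target ages of the risk curve.
#' @return A `canpros_risk` data frame (see [predict_risk()]).
#' @export
scenario_risk <- function(store, consultand_age = 45, birth_year = 1965,
                          father_dx_age = NULL, brother_dx_age = NULL,
                          father_birth_year = 1935, pv = NULL,
                          pgs_percentile = NULL,
                          target_ages = seq(50, 85, by = 5)) {
  store <- as_store(store)
  members <- data.frame(
    id = c("father", "mother", "consultand"),
    father_id = c(NA, NA, "father"),
    mother_id = c(NA, NA, "mother"),
    sex = c("M", "F", "M"),
    birth_year = c(father_birth_year, father_birth_year, birth_year),
    censor_age = c(if (is.null(father_dx_age)) NA_real_ else father_dx_age,
                   NA_real_, consultand_age),
    prostate_dx_age = c(if (is.null(father_dx_age)) NA_real_
                        else father_dx_age, NA_real_, NA_real_),
    stringsAsFactors = FALSE)
  if (!is.null(brother_dx_age)) {
    members <- rbind(members, data.frame(
      id = "brother", father_id = "father", mother_id = "mother", sex = "M",
      birth_year = birth_year, censor_age = brother_dx_age,
      prostate_dx_age = brother_dx_age, stringsAsFactors = FALSE))
  }
  ped <- pedigree(members, famid = "scenario", arm = "none")
  m <- ped$members
  ci <- match("consultand", m$id)
  if (!is.null(pv)) {
    if (pv == "noncarrier") {
      m$brca2_test[ci] <- m$brca1_test[ci] <- m$hoxb13_test[ci] <- "noncarrier"
    } else {
      m[[paste0(tolower(pv), "_test")]][ci] <- "carrier"
    }
  }
  if (!is.null(pgs_percentile))
    m$pgs[ci] <- stats::qnorm(pgs_percentile)
  ped$members <- m
  predict_risk(ped, "consultand", store, target_ages)
}
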