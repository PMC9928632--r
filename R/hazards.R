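#' Constrain genotype-specific hazards to population incidence
#'
#' Computes the baseline annual hazard `lambda0(t)` for a birth cohort such
#' that the population-average hazard among still-unaffected men equals the
#' population incidence rate at every integer age: iterating age by age,
#' `lambda0(t) = lambda_pop(t) / E[RR(G, P, t) | unaffected at t]`, where the
#' joint genotype/polygene distribution among the unaffected is updated by
#' survival weighting (`exp(-lambda)`) each year. All heterogeneity in risk
#' is multiplicative via [relative_risk()].
#'
#' The returned object caches, for this birth cohort, the per-state survival
#' matrix `S[a + 1, s]` (probability of being prostate-cancer-free at exact
#' age `a` given state `s`), the per-state annual event probabilities, and
#' the per-state cumulative hazards, which the likelihood and prediction
#' layers read directly.
#'
#' @param incidence a `canpros_incidence` table.
#' @param params a `canpros_params` object.
#' @param birth_year birth cohort to constrain for.
#' @param space optionally a prebuilt `canpros_space` (rebuilt otherwise).
#' @return An object of class `canpros_hazards`.
#' @export
constrain <- function(incidence, params, birth_year, space = NULL) {
  if (is.null(space)) space <- build_state_space(params)
  A <- params$max_age
  ages <- 0:(A - 1L)
  lam_pop <- incidence_rate(incidence, ages, birth_year, sex = "M",
                            site = "prostate")
  sig <- polygenic_sd(ages, params)
  logM <- log_rr_major(space, params, ages, birth_year)  # (A x N)
  u <- polygene_loading(space, params)                   # (N)
  N <- space$N
  lambda0 <- numeric(A)
  p <- space$prior
  S <- matrix(0, A + 1L, N)     # S[a+1, ] = P(unaffected at exact age a | s)
  S[1L, ] <- 1
  lam_mat <- matrix(0, A, N)
  for (t in seq_len(A)) {
    rr <- exp(logM[t, ] + sig[t] * u)
    mean_rr <- sum(p * rr)
    if (!is.finite(mean_rr) || mean_rr <= 0)
      stop("degenerate parameters: E[RR] is not positive at age ", t - 1L)
    lambda0[t] <- lam_pop[t] / mean_rr
    lam <- lambda0[t] * rr
    lam_mat[t, ] <- lam
    S[t + 1L, ] <- S[t, ] * exp(-lam)
    surv <- p * exp(-lam)
    p <- surv / sum(surv)
  }
  structure(list(birth_year = birth_year, lambda0 = lambda0,
                 lam_pop = lam_pop, lam = lam_mat, S = S,
                 cumhaz = rbind(0, apply(lam_mat, 2, cumsum)),
                 f_year = S[seq_len(A), , drop = FALSE] * (1 - exp(-lam_mat)),
                 space = space, params = params, incidence = incidence),
            class = "canpros_hazards")
}

#' @export
print.canpros_hazards <- function(x, ...) {
  cat(sprintf(
    "canpros constrained hazards: birth cohort %d, %d ages, %d states\n",
    x$birth_year, length(x$lambda0), x$space$N))
  invisible(x)
}

#' Cache of constrained hazards per birth cohort
#'
#' Pedigrees span several birth cohorts and each cohort needs its own
#' incidence-constrained baseline; the store computes and caches one
#' [constrain()] result per cohort on demand. Most package functions accept
#' either a store or a single `canpros_hazards` object.
#'
#' @param incidence a `canpros_incidence` table.
#' @param params a `canpros_params` object.
#' @param space optionally a prebuilt `canpros_space`.
#' @return An object of class `canpros_hazard_store`.
#' @export
hazard_store <- function(incidence, params, space = NULL) {
  if (is.null(space)) space <- build_state_space(params)
  env <- new.env(parent = emptyenv())
  structure(list(incidence = incidence, params = params, space = space,
                 cache = env),
            class = "canpros_hazard_store")
}

store_hazards <- function(store, birth_year) {
  if (is.na(birth_year)) birth_year <- store$params$default_birth_year
  key <- as.character(birth_year)
  hz <- store$cache[[key]]
  if (is.null(hz)) {
    # cohorts sharing the same incidence rates and the same HOXB13 cohort
    # class have identical constrained hazards; share one object
    params <- store$params
    rates <- incidence_rate(store$incidence, 0:(params$max_age - 1L),
                            birth_year, sex = "M", site = "prostate")
    sig <- paste0(birth_year >= params$hoxb13_cohort_split, "|",
                  paste0(signif(rates, 12), collapse = ","))
    hz <- store$cache[[sig]]
    if (is.null(hz)) {
      hz <- constrain(store$incidence, params, birth_year,
                      space = store$space)
      assign(sig, hz, envir = store$cache)
    }
    assign(key, hz, envir = store$cache)
  }
  hz
}

#' Cumulative prostate cancer risk between two ages
#'
#' Cause-specific cumulative risk `1 - exp(-sum of annual hazards)` between
#' `from_age` and `to_age`, conditional on being unaffected at `from_age`.
#' `state` may be a single joint state index, a probability vector over
#' states (a mixture, e.g. a posterior from [posterior_states()]), or `NULL`
#' for the population mixture among survivors to `from_age`. No competing
#' mortality is applied.
#'
#' @param hazards a `canpros_hazards` object.
#' @param state state index, mixture weights of length `space$N`, or `NULL`.
#' @param from_age,to_age integer ages with `from_age < to_age <= max_age`.
#' @return A probability in `[0, 1]`.
#' @export
cumulative_risk <- function(hazards, state = NULL, from_age, to_age) {
  A <- length(hazards$lambda0)
  if (to_age <= from_age) stop("to_age must exceed from_age")
  if (to_age > A) stop("to_age exceeds the model horizon ", A)
  ch <- hazards$cumhaz[to_age + 1L, ] - hazards$cumhaz[from_age + 1L, ]
  per_state <- 1 - exp(-ch)
  if (is.null(state)) {
    w <- hazards$space$prior * hazards$S[from_age + 1L, ]
    state <- w / sum(w)
  }
  if (length(state) == 1L) return(per_state[state])
  if (length(state) != hazards$space$N)
    stop("state mixture has wrong length")
  sum(state * per_state)
}
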