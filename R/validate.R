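#' Cohort records for prospective validation
#'
#' A validation cohort is a data frame with one row per unaffected man at
#' baseline:
#'
#' * `id`; `baseline_age`; `birth_year`.
#' * Family history at baseline: `father_affected` (0/1/`NA` for unknown),
#'   `father_dx_age`, `father_birth_year`, `father_censor_age` (father's age
#'   at baseline if his unaffected status is known), `brothers_affected_dx`
#'   (semicolon-separated diagnosis ages of affected brothers, `""` for
#'   none), `brothers_unaffected_censor` (semicolon-separated current ages
#'   of brothers known to be unaffected).
#' * `brca2_test`, `brca1_test`, `hoxb13_test`, `pgs` as in [pedigree()].
#' * Outcome: `event` (1 = incident prostate cancer), `time` (years from
#'   baseline to event or censoring, > 0).
#'
#' @param data data frame with the columns above (missing optional columns
#'   are filled with defaults).
#' @return The validated data frame with class `canpros_cohort`.
#' @export
cohort_records <- function(data) {
  d <- as.data.frame(data, stringsAsFactors = FALSE)
  defaults <- list(father_affected = NA_real_, father_dx_age = NA_real_,
                   father_birth_year = NA_real_, father_censor_age = NA_real_,
                   brothers_affected_dx = "", brothers_unaffected_censor = "",
                   brca2_test = "untested", brca1_test = "untested",
                   hoxb13_test = "untested", pgs = NA_real_)
  for (nm in names(defaults)) if (is.null(d[[nm]])) d[[nm]] <- defaults[[nm]]
  need <- c("id", "baseline_age", "birth_year", "event", "time")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("cohort is missing columns: ", paste(miss, collapse = ", "))
  if (any(d$time <= 0)) stop("follow-up times must be positive")
  if (!all(d$event %in% c(0, 1))) stop("event must be 0/1")
  for (col in c("brothers_affected_dx", "brothers_unaffected_censor"))
    d[[col]][is.na(d[[col]])] <- ""
  class(d) <- c("canpros_cohort", "data.frame")
  d
}

#' Read / write a validation cohort CSV
#'
#' @param path CSV path.
#' @return For `read_cohort`, a `canpros_cohort` data frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(brothers_affected_dx = "character",
                                      brothers_unaffected_censor = "character"))
  cohort_records(d)
}

#' @rdname read_cohort
#' @param cohort a `canpros_cohort` data frame.
#' @return For `write_cohort`, `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "NA")
  invisible(path)
}

split_ages <- function(s) {
  if (is.na(s) || !nzchar(s)) return(numeric(0))
  suppressWarnings(as.numeric(strsplit(s, ";", fixed = TRUE)[[1]]))
}

#' Predict fixed-horizon risks for a validation cohort
#'
#' For each record, builds the minimal pedigree implied by the baseline
#' family history (father, mother, and listed brothers; relatives that are
#' not reported carry no phenotype assumptions), computes the consultand's
#' posterior state distribution given the information level requested, and
#' converts it to the cumulative risk of prostate cancer within `horizon`
#' years of baseline. Identical family-history patterns share one peeling
#' message, so large cohorts with few distinct patterns evaluate quickly.
#'
#' @param cohort a `canpros_cohort` data frame.
#' @param store a hazard store from [hazard_store()].
#' @param horizon years from baseline; may be a vector, in which case all
#'   horizons share one posterior computation per record.
#' @param info which information to use beyond age: any subset of
#'   `c("fh", "pv", "pgs")`; `"all"` is shorthand for all three, `"age"`
#'   for none.
#' @return Numeric vector of predicted risks, one per record, or a matrix
#'   with one column per horizon when several are requested.
#' @export
predict_cohort_risks <- function(cohort, store, horizon,
                                 info = "all") {
  store <- as_store(store)
  if (identical(info, "all")) info <- c("fh", "pv", "pgs")
  if (identical(info, "age")) info <- character(0)
  space <- store$space
  params <- store$params
  A <- params$max_age
  N <- space$N
  n <- nrow(cohort)
  feat <- space$feat
  ba <- cohort$baseline_age
  by <- cohort$birth_year
  fa <- cohort$father_affected
  fdx <- cohort$father_dx_age
  fby <- ifelse(is.na(cohort$father_birth_year), by - 30,
                cohort$father_birth_year)
  fca <- cohort$father_censor_age
  badx <- cohort$brothers_affected_dx
  buc <- cohort$brothers_unaffected_censor
  z <- cohort$pgs
  use_fh <- "fh" %in% info
  use_pv <- "pv" %in% info
  use_pgs <- "pgs" %in% info
  # birth cohorts with identical constrained hazards share one message cache
  # key (the representative cohort of the shared hazards object)
  rep_cohort <- local({
    u <- unique(c(by, fby))
    r <- vapply(u, function(b) store_hazards(store, b)$birth_year, numeric(1))
    function(b) r[match(b, u)]
  })
  rby <- rep_cohort(by)
  rfby <- rep_cohort(fby)
  fh_key <- if (use_fh)
    paste(fa, fdx, fca, rfby, badx, buc, rby, sep = "|") else rep("", n)
  test_key <- if (use_pv)
    paste(cohort$brca2_test, cohort$brca1_test, cohort$hoxb13_test)
  else rep("", n)
  grp_key <- paste(rby, ba, fh_key, test_key, sep = "@")
  msg_cache <- new.env(parent = emptyenv())
  down_cache <- new.env(parent = emptyenv())
  pair0_cache <- new.env(parent = emptyenv())
  down_cached <- function(birth_year, type, age) {
    key <- paste(birth_year, type, age)
    got <- down_cache[[key]]
    if (!is.null(got)) return(got)
    hz <- store_hazards(store, birth_year)
    pen <- if (type == "dx") hz$f_year[min(age, A - 1L) + 1L, ]
           else hz$S[min(age, A) + 1L, ]
    v <- down_message(space, pen)
    assign(key, v, envir = down_cache)
    v
  }
  fh_message <- function(i) {
    informative <- (!is.na(fa[i]) && (fa[i] == 1 || !is.na(fca[i]))) ||
      nzchar(badx[i]) || nzchar(buc[i])
    # the returned message always embeds the consultand's marginal prior
    if (!informative) return(space$prior)
    got <- msg_cache[[fh_key[i]]]
    if (!is.null(got)) return(got)
    ftype <- if (!is.na(fa[i]) && fa[i] == 1) "dx"
             else if (!is.na(fa[i]) && fa[i] == 0 && !is.na(fca[i])) "cens"
             else "none"
    fage <- if (ftype == "dx") fdx[i] else if (ftype == "cens") fca[i] else 0
    if (ftype == "dx" && is.na(fage))
      stop("affected father without diagnosis age; run ",
           "impute_relative_dx_ages() first")
    pkey <- paste(rfby[i], ftype, fage)
    P <- pair0_cache[[pkey]]
    if (is.null(P)) {
      hz_f <- store_hazards(store, rfby[i])
      fpen <- switch(ftype,
        dx = hz_f$f_year[min(fage, A - 1L) + 1L, ],
        cens = hz_f$S[min(fage, A) + 1L, ],
        none = rep(1, N))
      P <- pair_interleave(space, space$prior * fpen, space$prior)
      assign(pkey, P, envir = pair0_cache)
    }
    for (dx in split_ages(badx[i]))
      P <- P * down_cached(rby[i], "dx", dx)
    for (ca in split_ages(buc[i]))
      P <- P * down_cached(rby[i], "cens", ca)
    msg <- child_message(space, P)
    assign(fh_key[i], msg, envir = msg_cache)
    msg
  }
  test_factor <- function(i) {
    f <- rep(1, N)
    for (g in c("BRCA2", "BRCA1", "HOXB13")) {
      res <- cohort[[paste0(tolower(g), "_test")]][i]
      if (is.na(res) || res == "untested") next
      carrier <- feat[[paste0("count_", g)]] >= 1L
      s <- params$sensitivity[[g]]
      f <- f * if (res == "carrier") ifelse(carrier, s, 0)
               else ifelse(carrier, 1 - s, 1)
    }
    f
  }
  n_h <- length(horizon)
  risks <- matrix(0, n, n_h)
  for (idx in split(seq_len(n), grp_key)) {
    i <- idx[1]
    hz <- store_hazards(store, rby[i])
    base <- hz$S[ba[i] + 1L, ] *
      (if (use_fh) fh_message(i) else space$prior)
    if (use_pv) base <- base * test_factor(i)
    zg <- if (use_pgs) z[idx] else rep(NA_real_, length(idx))
    nop <- is.na(zg)
    Phi <- NULL
    if (any(!nop)) {
      Phi <- stats::dnorm(outer(zg[!nop], feat$v_obs, "-"),
                          sd = params$pgs_nugget_sd)
      den <- as.vector(Phi %*% base)
      if (any(den <= 0)) stop("zero-probability record in group")
    }
    for (hj in seq_len(n_h)) {
      to <- min(ba[i] + horizon[hj], A)
      cr <- 1 - exp(-(hz$cumhaz[to + 1L, ] - hz$cumhaz[ba[i] + 1L, ]))
      if (any(nop)) {
        s <- sum(base)
        if (s <= 0) stop("zero-probability record ", cohort$id[i])
        risks[idx[nop], hj] <- sum(base * cr) / s
      }
      if (any(!nop))
        risks[idx[!nop], hj] <- as.vector(Phi %*% (base * cr)) / den
    }
  }
  if (n_h == 1L) as.vector(risks) else risks
}

#' Fixed-horizon concordance index
#'
#' Horizon-truncated Harrell-type concordance of predicted risks with
#' observed outcomes: usable pairs consist of a case with an event within
#' the horizon and a comparator still event-free at that time; risk ties
#' count one half. The optional confidence interval is a seeded
#' nonparametric bootstrap over subjects.
#'
#' @param time,event follow-up times and event indicators (1 = case).
#' @param risk predicted risks at baseline.
#' @param horizon years.
#' @param n_boot bootstrap resamples for the CI (0 = no CI).
#' @param level confidence level.
#' @param seed bootstrap seed.
#' @return List with `c_index`, `n_cases`, and `ci` (or `NULL`).
#' @export
concordance_index <- function(time, event, risk, horizon, n_boot = 0,
                              level = 0.95, seed = 1L) {
  stopifnot(length(time) == length(event), length(time) == length(risk),
            horizon > 0)
  t2 <- pmin(time, horizon)
  e2 <- as.integer(event == 1 & time <= horizon)
  if (sum(e2) == 0L) stop("no usable pairs: no events within the horizon")
  cfit <- survival::concordance(survival::Surv(t2, e2) ~ risk, reverse = TRUE)
  out <- list(c_index = unname(cfit$concordance), n_cases = sum(e2),
              ci = NULL)
  if (n_boot > 0) {
    set.seed(seed)
    n <- length(t2)
    bs <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      if (sum(e2[idx]) == 0L) return(NA_real_)
      unname(survival::concordance(survival::Surv(t2[idx], e2[idx]) ~
                                     risk[idx], reverse = TRUE)$concordance)
    }, numeric(1))
    alpha <- 1 - level
    out$ci <- stats::quantile(bs, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE,
                              names = FALSE)
  }
  out
}

#' Calibration of predicted risks against Kaplan-Meier observed risks
#'
#' Groups subjects by quantiles of the predicted risk and compares the mean
#' predicted risk in each group with the Kaplan-Meier failure probability at
#' the horizon (Greenwood standard errors with a log-log transform for the
#' confidence interval), together with observed/expected ratios.
#'
#' @param time,event,risk,horizon as in [concordance_index()].
#' @param n_groups number of risk groups (default deciles).
#' @param level confidence level for the KM interval.
#' @return Data frame with one row per group: `group`, `n`, `mean_predicted`,
#'   `km_observed`, `km_lower`, `km_upper`, `oe` (observed/expected). The
#'   overall O/E ratio is attached as attribute `overall_oe`.
#' @export
calibration_table <- function(time, event, risk, horizon, n_groups = 10,
                              level = 0.95) {
  n <- length(risk)
  if (n_groups < 2) stop("n_groups must be at least 2")
  if (n < n_groups) stop("a risk group would be empty")
  grp <- floor((rank(risk, ties.method = "first") - 1) * n_groups / n) + 1
  km_fail <- function(idx) {
    sf <- survival::survfit(survival::Surv(pmin(time[idx], horizon),
                                           event[idx] == 1 &
                                             time[idx] <= horizon) ~ 1,
                            conf.type = "log-log", conf.int = level)
    sm <- summary(sf, times = horizon, extend = TRUE)
    c(obs = 1 - sm$surv,
      lower = 1 - ifelse(is.na(sm$upper), 1, sm$upper),
      upper = 1 - ifelse(is.na(sm$lower), 1, sm$lower))
  }
  rows <- lapply(seq_len(n_groups), function(g) {
    idx <- which(grp == g)
    if (!length(idx)) stop("risk group ", g, " is empty")
    km <- km_fail(idx)
    data.frame(group = g, n = length(idx),
               mean_predicted = mean(risk[idx]),
               km_observed = km[["obs"]], km_lower = km[["lower"]],
               km_upper = km[["upper"]],
               oe = km[["obs"]] / mean(risk[idx]))
  })
  out <- do.call(rbind, rows)
  overall <- km_fail(seq_len(n))
  attr(out, "overall_oe") <- overall[["obs"]] / mean(risk)
  out
}

#' Recalibrate predicted risks for cohort-level excess incidence
#'
#' Scales every subject's cumulative hazard by a common factor so that the
#' overall observed/expected ratio after recalibration is exactly 1:
#' `risk' = 1 - (1 - risk)^c`, with `c` solved so the mean recalibrated risk
#' equals the Kaplan-Meier observed risk (to first order, `c` equals the raw
#' overall O/E ratio). Subject ranking is unchanged, so discrimination is
#' unaffected.
#'
#' @param time,event,risk,horizon as in [concordance_index()].
#' @return List with `risk` (recalibrated), `oe` (raw overall O/E), and
#'   `multiplier` (the applied hazard scale factor).
#' @export
recalibrate <- function(time, event, risk, horizon) {
  sf <- survival::survfit(survival::Surv(pmin(time, horizon),
                                         event == 1 & time <= horizon) ~ 1)
  sm <- summary(sf, times = horizon, extend = TRUE)
  observed <- 1 - sm$surv
  expected <- mean(risk)
  if (expected <= 0) stop("expected events are zero; cannot recalibrate")
  oe <- observed / expected
  if (abs(oe - 1) < 1e-12) return(list(risk = risk, oe = oe, multiplier = 1))
  f <- function(c) mean(1 - (1 - risk)^c) - observed
  mult <- stats::uniroot(f, lower = min(oe, 1) / 50, upper = max(oe, 1) * 50,
                         tol = 1e-14)$root
  list(risk = 1 - (1 - risk)^mult, oe = oe, multiplier = mult)
}

#' Risk classification / case-capture table
#'
#' For each quantile `q`, takes the `ceiling(q * n)` subjects with the
#' highest predicted risks and reports which fraction of the observed cases
#' within the horizon they capture, plus sensitivity and specificity at that
#' threshold.
#'
#' @param time,event,risk,horizon as in [concordance_index()].
#' @param quantiles top fractions of the risk distribution, in (0, 1].
#' @return Data frame with `quantile`, `n_top`, `capture`, `sensitivity`,
#'   `specificity`.
#' @export
risk_classification <- function(time, event, risk, horizon,
                                quantiles = c(0.01, 0.1, 0.5)) {
  stopifnot(all(quantiles > 0), all(quantiles <= 1))
  n <- length(risk)
  case <- event == 1 & time <= horizon
  n_cases <- sum(case)
  rk <- rank(-risk, ties.method = "first")
  rows <- lapply(quantiles, function(q) {
    n_top <- ceiling(q * n)
    top <- rk <= n_top
    capture <- if (n_cases) sum(case & top) / n_cases else NA_real_
    spec <- if (n_cases < n) sum(!case & !top) / (n - n_cases) else NA_real_
    data.frame(quantile = q, n_top = n_top, capture = capture,
               sensitivity = capture, specificity = spec)
  })
  do.call(rbind, rows)
}

#' Impute missing diagnosis ages of affected relatives
#'
#' Validation cohorts often record that a relative was affected without the
#' age at diagnosis. This fills in a plausible age from an assumed
#' generational age structure: a relative's current age is the consultand's
#' baseline age plus a configurable offset, and the imputed diagnosis age is
#' a typical diagnosis age clamped to `[min_dx_age, relative's age]`.
#' Nothing is invented for unaffected or unreported relatives. A stochastic
#' mode draws the age from the population diagnosis-age distribution
#' truncated to the same interval, under a fixed seed.
#'
#' @param cohort a `canpros_cohort` data frame.
#' @param offsets named vector of generational age offsets in years
#'   (relative's age minus consultand's age).
#' @param typical_dx_age deterministic fill-in value before clamping.
#' @param min_dx_age lower clamp.
#' @param stochastic draw from the population distribution instead.
#' @param store hazard store (required when `stochastic = TRUE`).
#' @param seed seed for the stochastic mode.
#' @return The cohort with `father_dx_age` (and affected brothers' ages)
#'   completed.
#' @export
impute_relative_dx_ages <- function(cohort, offsets = c(father = 28,
                                                        brother = 0),
                                    typical_dx_age = 70, min_dx_age = 40,
                                    stochastic = FALSE, store = NULL,
                                    seed = 1L) {
  draw_age <- NULL
  if (stochastic) {
    if (is.null(store)) stop("stochastic imputation needs a hazard store")
    store <- as_store(store)
    set.seed(seed)
    draw_age <- function(lo, hi, birth_year) {
      hz <- store_hazards(store, birth_year)
      pr <- as.vector(hz$f_year %*% store$space$prior)
      ages <- seq_along(pr) - 1L
      keep <- ages >= lo & ages <= hi
      if (!any(keep)) return(lo)
      sample(ages[keep], 1L, prob = pr[keep])
    }
  }
  fill <- function(lo, hi, birth_year) {
    hi <- max(hi, lo)
    if (stochastic) draw_age(lo, hi, birth_year)
    else min(max(typical_dx_age, lo), hi)
  }
  for (i in seq_len(nrow(cohort))) {
    fa <- cohort$father_affected[i]
    if (!is.na(fa) && fa == 1 && is.na(cohort$father_dx_age[i])) {
      age_now <- cohort$baseline_age[i] + offsets[["father"]]
      fby <- cohort$father_birth_year[i]
      if (is.na(fby)) fby <- cohort$birth_year[i] - offsets[["father"]]
      cohort$father_dx_age[i] <- fill(min_dx_age, age_now, fby)
    }
    dx <- split_ages(cohort$brothers_affected_dx[i])
    if (length(dx) && anyNA(dx)) {
      age_now <- cohort$baseline_age[i] + offsets[["brother"]]
      dx[is.na(dx)] <- vapply(which(is.na(dx)), function(j)
        fill(min_dx_age, age_now, cohort$birth_year[i]), numeric(1))
      cohort$brothers_affected_dx[i] <- paste(dx, collapse = ";")
    }
  }
  cohort
}

#' Full prospective validation report
#'
#' Runs discrimination, calibration, recalibration and risk classification
#' for each horizon and information level, mirroring the standard external
#' validation workflow for fixed-horizon risk models.
#'
#' @param cohort a `canpros_cohort` data frame.
#' @param store a hazard store from [hazard_store()].
#' @param horizons prediction horizons in years.
#' @param info_levels named list of information levels (see
#'   [predict_cohort_risks()]).
#' @param n_groups calibration groups.
#' @param n_boot bootstrap resamples for C-index CIs.
#' @param seed bootstrap seed.
#' @return A list of class `canpros_validation` with elements `c_index`
#'   (data frame), `calibration`, `recalibrated`, `classification`, and
#'   `risks` (the predicted risks, full information level).
#' @export
validate_cohort <- function(cohort, store, horizons = c(5, 10),
                            info_levels = list(age = "age", full = "all"),
                            n_groups = 10, n_boot = 0, seed = 1L) {
  store <- as_store(store)
  cidx <- list()
  calib <- list()
  recal <- list()
  classif <- list()
  risks_full <- list()
  pred_all <- lapply(info_levels, function(lv)
    predict_cohort_risks(cohort, store, horizons, info = lv))
  for (hi in seq_along(horizons)) {
    h <- horizons[hi]
    preds <- lapply(pred_all, function(m)
      if (is.matrix(m)) m[, hi] else m)
    for (lv in names(preds)) {
      ci <- concordance_index(cohort$time, cohort$event, preds[[lv]], h,
                              n_boot = n_boot, seed = seed)
      cidx[[length(cidx) + 1L]] <- data.frame(
        horizon = h, info = lv, c_index = ci$c_index, n_cases = ci$n_cases,
        ci_lower = if (is.null(ci$ci)) NA_real_ else ci$ci[1],
        ci_upper = if (is.null(ci$ci)) NA_real_ else ci$ci[2])
    }
    full_lv <- names(info_levels)[length(info_levels)]
    r <- preds[[full_lv]]
    risks_full[[as.character(h)]] <- r
    calib[[as.character(h)]] <-
      calibration_table(cohort$time, cohort$event, r, h, n_groups = n_groups)
    rc <- recalibrate(cohort$time, cohort$event, r, h)
    recal[[as.character(h)]] <- list(
      oe = rc$oe,
      table = calibration_table(cohort$time, cohort$event, rc$risk, h,
                                n_groups = n_groups))
    classif[[as.character(h)]] <-
      risk_classification(cohort$time, cohort$event, r, h)
  }
  structure(list(c_index = do.call(rbind, cidx), calibration = calib,
                 recalibrated = recal, classification = classif,
                 risks = risks_full),
            class = "canpros_validation")
}

#' @export
print.canpros_validation <- function(x, ...) {
  cat("canpros prospective validation report\n")
  print(x$c_index)
  for (h in names(x$calibration)) {
    cat(sprintf("\n%s-year calibration (overall O/E = %.3f):\n", h,
                attr(x$calibration[[h]], "overall_oe")))
    print(x$calibration[[h]], row.names = FALSE)
  }
  invisible(x)
}
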