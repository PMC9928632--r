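#' Maximum-likelihood estimation of model parameters from pedigrees
#'
#' Maximizes the sum of ascertainment-conditioned pedigree log-likelihoods
#' over the chosen free parameters on a transformed scale: logit for allele
#' frequencies and for the PGS-explained fraction `alpha`, log for relative
#' risks, the polygenic SD at 70 and its per-year rate. Externally assumed
#' components (the BRCA1/2 age-specific relative-risk curves, the female
#' penetrances, test sensitivities) are never free. Baseline hazards are
#' re-constrained to the population incidences at every parameter evaluation.
#'
#' One-dimensional problems use Brent's method; multi-parameter problems use
#' a derivative-free Nelder-Mead search with a quasi-Newton (BFGS) polish and
#' seeded random restarts. Standard errors come from the numerical Hessian on
#' the transformed scale. Non-convergence or a boundary estimate is flagged
#' in the result, not raised as an error.
#'
#' @param pedigrees list of `canpros_pedigree` objects.
#' @param incidence a `canpros_incidence` table (the constraint target).
#' @param init a `canpros_params` object holding starting values and all
#'   fixed parameters.
#' @param free character vector of free parameter names among
#'   `f_BRCA2`, `f_BRCA1`, `f_HOXB13`, `f_REC`, `rr_hoxb13_pre`,
#'   `rr_hoxb13_post`, `rr_rec`, `sigma70`, `sigma_rate`, `alpha`.
#' @param scheme ascertainment-conditioning scheme passed to [condition()];
#'   `"auto"` selects per family from the proband's detection mode.
#' @param control list: `n_restarts` (default 3 for multi-parameter fits),
#'   `seed` (restart jitter seed, default 1), `maxit`, `reltol` (default
#'   1e-6 on the log-likelihood), `use_batch` (default TRUE when all
#'   pedigrees are nuclear and the state space is small).
#' @return An object of class `canpros_fit` with transformed and
#'   natural-scale estimates, standard errors, log-likelihood, AIC,
#'   convergence diagnostics and the free-parameter mask.
#' @export
fit <- function(pedigrees, incidence, init, free = character(0),
                scheme = "auto", control = list()) {
  validate_params(init)
  stopifnot(length(pedigrees) >= 1L)
  bad <- setdiff(free, names(PARAM_TRANSFORMS))
  if (length(bad)) stop("unknown free parameters: ", paste(bad, collapse = ", "))
  ctl <- utils::modifyList(list(n_restarts = 3L, seed = 1L, maxit = 500L,
                                reltol = 1e-6, use_batch = NA,
                                hessian = TRUE), control)
  rebuild_space <- any(grepl("^f_", free))
  space0 <- build_state_space(init)
  use_batch <- isTRUE(ctl$use_batch) ||
    (is.na(ctl$use_batch) && !is.null(space0$tfull) &&
       all(vapply(pedigrees, is_nuclear, logical(1))))
  batch <- if (use_batch) prepare_nuclear_batch(pedigrees) else NULL
  scheme_override <- if (identical(scheme, "auto")) NULL else scheme

  eval_ll <- function(theta) {
    params <- apply_transformed(init, theta)
    # the space holds only structure (dims, priors of loci, transmission);
    # it must be rebuilt when allele frequencies move, while sigma/alpha
    # enter through constrain() and the penetrances at every evaluation
    space <- if (rebuild_space) build_state_space(params) else space0
    store <- hazard_store(incidence, params, space = space)
    if (use_batch) batch_conditioned_loglik(batch, store, scheme_override)
    else sum(vapply(pedigrees, condition, numeric(1), store = store,
                    scheme = scheme))
  }
  negll <- function(th) {
    names(th) <- free
    val <- tryCatch(-eval_ll(th), error = function(e) Inf)
    if (!is.finite(val)) 1e10 else val
  }
  theta0 <- transform_params(init)[free]
  k <- length(free)
  conv <- 0L
  if (k == 0L) {
    opt <- list(par = numeric(0), value = negll(numeric(0)))
  } else if (k == 1L) {
    # search near the initial value first; if the optimum sits at the
    # bracket edge, locate the basin by a coarse scan — on wide transformed
    # intervals the likelihood can be flat (overflow-guarded) far from the
    # optimum, which defeats golden-section search on its own
    o <- stats::optimize(negll, interval = c(theta0 - 1.5, theta0 + 1.5),
                         tol = 1e-6)
    if (min(abs(o$minimum - (theta0 + c(-1.5, 1.5)))) < 0.01) {
      grid <- theta0 + seq(-6, 6, by = 0.5)
      center <- grid[which.min(vapply(grid, negll, numeric(1)))]
      o <- stats::optimize(negll, interval = c(center - 0.75, center + 0.75),
                           tol = 1e-6)
    }
    opt <- list(par = o$minimum, value = o$objective, convergence = 0L)
  } else {
    set.seed(ctl$seed)
    starts <- c(list(theta0), lapply(seq_len(max(0L, ctl$n_restarts - 1L)),
                                     function(i) theta0 + stats::rnorm(k, 0, 0.5)))
    best <- NULL
    for (s in starts) {
      o <- stats::optim(s, negll, method = "Nelder-Mead",
                        control = list(maxit = ctl$maxit,
                                       reltol = ctl$reltol))
      o <- tryCatch(stats::optim(o$par, negll, method = "BFGS",
                                 control = list(maxit = 100L,
                                                reltol = ctl$reltol)),
                    error = function(e) o)
      if (is.null(best) || o$value < best$value) best <- o
    }
    opt <- best
    conv <- opt$convergence
  }
  se <- rep(NA_real_, k)
  if (k > 0L && isTRUE(ctl$hessian)) {
    H <- tryCatch(stats::optimHess(opt$par, negll), error = function(e) NULL)
    if (!is.null(H)) {
      V <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(V)) se <- sqrt(pmax(diag(V), 0))
    }
  }
  names(se) <- free
  theta_hat <- opt$par
  names(theta_hat) <- free
  params_hat <- apply_transformed(init, theta_hat)
  structure(list(
    free = free,
    estimate_transformed = theta_hat,
    se_transformed = se,
    estimate = natural_scale(theta_hat),
    params = params_hat,
    logLik = -opt$value,
    AIC = 2 * k + 2 * opt$value,
    k = k,
    convergence = conv == 0L,
    boundary = k > 0L && any(abs(theta_hat) > 12),
    n_pedigrees = length(pedigrees),
    data_fingerprint = data_fingerprint(pedigrees),
    scheme = scheme
  ), class = "canpros_fit")
}

PARAM_TRANSFORMS <- c(
  f_BRCA2 = "logit", f_BRCA1 = "logit", f_HOXB13 = "logit", f_REC = "logit",
  rr_hoxb13_pre = "log", rr_hoxb13_post = "log", rr_rec = "log",
  sigma70 = "log", sigma_rate = "log", alpha = "logit")

transform_params <- function(p) {
  v <- c(f_BRCA2 = p$frequencies[["BRCA2"]], f_BRCA1 = p$frequencies[["BRCA1"]],
         f_HOXB13 = p$frequencies[["HOXB13"]], f_REC = p$frequencies[["REC"]],
         rr_hoxb13_pre = p$rr_hoxb13[["pre1930"]],
         rr_hoxb13_post = p$rr_hoxb13[["post1930"]],
         rr_rec = p$rr_rec, sigma70 = p$sigma70, sigma_rate = p$sigma_rate,
         alpha = p$alpha)
  out <- v
  for (nm in names(v))
    out[nm] <- if (PARAM_TRANSFORMS[nm] == "logit") stats::qlogis(v[nm])
               else log(v[nm])
  out
}

natural_scale <- function(theta) {
  out <- theta
  for (nm in names(theta))
    out[nm] <- if (PARAM_TRANSFORMS[nm] == "logit") stats::plogis(theta[nm])
               else exp(theta[nm])
  out
}

apply_transformed <- function(params, theta) {
  if (!length(theta)) return(params)
  nat <- natural_scale(theta)
  for (nm in names(nat)) {
    val <- nat[[nm]]
    switch(nm,
      f_BRCA2 = params$frequencies[["BRCA2"]] <- val,
      f_BRCA1 = params$frequencies[["BRCA1"]] <- val,
      f_HOXB13 = params$frequencies[["HOXB13"]] <- val,
      f_REC = params$frequencies[["REC"]] <- val,
      rr_hoxb13_pre = params$rr_hoxb13[["pre1930"]] <- val,
      rr_hoxb13_post = params$rr_hoxb13[["post1930"]] <- val,
      rr_rec = params$rr_rec <- val,
      sigma70 = params$sigma70 <- val,
      sigma_rate = params$sigma_rate <- val,
      alpha = params$alpha <- val)
  }
  params
}

data_fingerprint <- function(pedigrees) {
  c(n = length(pedigrees),
    members = sum(vapply(pedigrees, function(p) nrow(p$members), integer(1))),
    affected = sum(vapply(pedigrees, function(p)
      sum(!is.na(p$members$prostate_dx_age)), integer(1))))
}

#' @export
print.canpros_fit <- function(x, ...) {
  cat(sprintf("canpros fit: %d free parameter(s), logLik = %.4f, AIC = %.4f\n",
              x$k, x$logLik, x$AIC))
  if (x$k) {
    tab <- data.frame(transformed = x$estimate_transformed,
                      se = x$se_transformed, natural = x$estimate)
    print(tab)
  }
  if (!x$convergence) cat("  WARNING: optimizer did not converge\n")
  if (x$boundary) cat("  WARNING: estimate at or near the boundary\n")
  invisible(x)
}

#' Wald confidence intervals for fitted parameters
#'
#' Intervals are computed on the transformed scale and mapped back, so they
#' respect the natural parameter ranges.
#'
#' @param object a `canpros_fit`.
#' @param parm parameters (default: all free).
#' @param level confidence level.
#' @param ... unused.
#' @return Matrix with columns `lower`, `upper` on the natural scale.
#' @export
confint.canpros_fit <- function(object, parm = object$free, level = 0.95,
                                ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  lo <- object$estimate_transformed[parm] - z * object$se_transformed[parm]
  hi <- object$estimate_transformed[parm] + z * object$se_transformed[parm]
  cbind(lower = natural_scale(stats::setNames(lo, parm)),
        upper = natural_scale(stats::setNames(hi, parm)))
}

#' Compare fitted models by AIC
#'
#' @param fits named list of `canpros_fit` objects fitted to the same data.
#' @return Data frame with `k`, `logLik`, `AIC` and `dAIC`, sorted by AIC.
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 1L)
  fps <- lapply(fits, `[[`, "data_fingerprint")
  if (!all(vapply(fps, identical, logical(1), fps[[1]])))
    stop("models were not fitted to identical data")
  tab <- data.frame(
    model = if (is.null(names(fits))) paste0("model", seq_along(fits))
            else names(fits),
    k = vapply(fits, `[[`, numeric(1), "k"),
    logLik = vapply(fits, `[[`, numeric(1), "logLik"),
    AIC = vapply(fits, `[[`, numeric(1), "AIC"))
  tab$dAIC <- tab$AIC - min(tab$AIC)
  tab[order(tab$AIC), ]
}

#' Likelihood-ratio test of nested fits
#'
#' The reduced model's free parameters must be a subset of the full model's
#' (nesting is required, not inferred); the statistic is referred to a
#' chi-squared distribution with degrees of freedom equal to the difference
#' in free parameter counts.
#'
#' @param full,reduced `canpros_fit` objects on identical data.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
lrt <- function(full, reduced) {
  if (!identical(full$data_fingerprint, reduced$data_fingerprint))
    stop("fits are not on identical data")
  if (!all(reduced$free %in% full$free))
    stop("models are not nested: reduced free set is not a subset")
  df <- full$k - reduced$k
  if (df <= 0L) stop("full model must have more free parameters")
  stat <- max(0, 2 * (full$logLik - reduced$logLik))
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}
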