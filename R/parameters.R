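#' Model parameters for the prostate cancer genetic risk model
#'
#' Constructs and validates the parameter set of the mixed major-gene /
#' polygenic model: allele frequencies of the four biallelic loci (BRCA2,
#' BRCA1, HOXB13 G84E, and a hypothetical residual major gene), age-specific
#' relative-risk curves for BRCA2/BRCA1 (externally assumed, never fitted),
#' birth-cohort-specific per-allele relative risks for HOXB13, the relative
#' risk of the fourth gene under its inheritance model, the polygenic standard
#' deviation at age 70 and its multiplicative change per year of age, the
#' fraction of the polygenic SD explained by the measured polygenic score
#' (PGS), genetic-test sensitivities, and pluggable female breast/ovarian
#' penetrance multipliers for BRCA1/2 genotypes.
#'
#' The polygenic SD at age `t` is `sigma70 * sigma_rate^(t - 70)`. The PGS
#' explains a fraction `alpha` of that SD, so the observed (PGS) part has SD
#' `alpha * sigma(t)` and the independent residual part `sqrt(1 - alpha^2) *
#' sigma(t)`; their variances sum to `sigma(t)^2`.
#'
#' @param frequencies named numeric vector of allele frequencies for
#'   `BRCA2`, `BRCA1`, `HOXB13` and `REC` (the hypothetical fourth gene), each
#'   in `[0, 1)`; a frequency of exactly 0 removes the locus from the state
#'   space.
#' @param rr_brca2,rr_brca1 data frames with columns `age_lo` and `rr` giving
#'   piecewise-constant age-specific carrier relative risks (dominant model:
#'   one or two risk alleles confer the same risk).
#' @param rr_hoxb13 named numeric vector `c(pre1930 = , post1930 = )`:
#'   per-allele (multiplicative) relative risks by birth cohort.
#' @param hoxb13_cohort_split first birth year of the later cohort (default
#'   1930; "pre" means born strictly before this year).
#' @param rec_model inheritance model of the fourth gene: `"recessive"`
#'   (risk confined to homozygotes), `"dominant"` (any risk allele), or
#'   `"multiplicative"` (`rr_rec` per allele).
#' @param rr_rec relative risk parameter of the fourth gene (homozygote RR
#'   under the recessive model, carrier RR under dominant, per-allele under
#'   multiplicative).
#' @param sigma70 polygenic SD on the log-hazard scale at age 70.
#' @param sigma_rate multiplicative change of the polygenic SD per year of age.
#' @param alpha fraction of the polygenic SD explained by the PGS, in `[0, 1]`.
#' @param sensitivity named vector of genetic-test sensitivities in `(0, 1]`
#'   for `BRCA2`, `BRCA1`, `HOXB13`; tests are assumed perfectly specific.
#' @param pgs_nugget_sd measurement SD linking the standardized observed PGS
#'   to the discretized observed-part polygene level.
#' @param grid named integer vector `c(obs = , res = )`: odd numbers of levels
#'   of the discretized observed-part and residual-part polygene grids.
#' @param max_age model horizon; hazards are defined on integer ages
#'   `0 .. max_age - 1`.
#' @param default_birth_year birth cohort assumed when an individual's birth
#'   year is missing.
#' @param female_penetrance list with elements `breast` and `ovarian`, each a
#'   list with `rates` (data frame `age_lo`, `rate`: baseline annual hazard)
#'   and constant hazard multipliers `rr_brca1`, `rr_brca2`. Used for female
#'   relatives; not constrained against female incidence tables.
#'
#' @return An object of class `canpros_params`.
#' @export
canpros_params <- function(frequencies = c(BRCA2 = 0.00102, BRCA1 = 0.00064,
                                           HOXB13 = 0.0017, REC = 0.10),
                           rr_brca2 = data.frame(age_lo = c(0, 55, 65, 75),
                                                 rr = c(7.0, 5.5, 4.2, 3.0)),
                           rr_brca1 = data.frame(age_lo = c(0, 65),
                                                 rr = c(2.35, 1.0)),
                           rr_hoxb13 = c(pre1930 = 2.0, post1930 = 3.6),
                           hoxb13_cohort_split = 1930,
                           rec_model = c("recessive", "dominant",
                                         "multiplicative"),
                           rr_rec = 10,
                           sigma70 = 2.13,
                           sigma_rate = 0.989,
                           alpha = 0.523,
                           sensitivity = c(BRCA2 = 0.83, BRCA1 = 0.65,
                                           HOXB13 = 1.0),
                           pgs_nugget_sd = 0.2,
                           grid = c(obs = 7L, res = 7L),
                           max_age = 90L,
                           default_birth_year = 1960L,
                           female_penetrance = default_female_penetrance()) {
  rec_model <- match.arg(rec_model)
  p <- structure(list(
    frequencies = frequencies,
    rr_brca2 = as.data.frame(rr_brca2),
    rr_brca1 = as.data.frame(rr_brca1),
    rr_hoxb13 = rr_hoxb13,
    hoxb13_cohort_split = as.integer(hoxb13_cohort_split),
    rec_model = rec_model,
    rr_rec = rr_rec,
    sigma70 = sigma70,
    sigma_rate = sigma_rate,
    alpha = alpha,
    sensitivity = sensitivity,
    pgs_nugget_sd = pgs_nugget_sd,
    grid = c(obs = as.integer(grid[["obs"]]), res = as.integer(grid[["res"]])),
    max_age = as.integer(max_age),
    default_birth_year = as.integer(default_birth_year),
    female_penetrance = female_penetrance
  ), class = "canpros_params")
  validate_params(p)
  p
}

#' Default female breast/ovarian penetrance inputs
#'
#' Illustrative baseline annual hazards of realistic magnitude with constant
#' hazard multipliers for BRCA1/2 carriers. These are pluggable external
#' inputs; replace them with calibrated penetrance curves for substantive use
#' in families with female phenotype data.
#'
#' @return A list suitable for the `female_penetrance` field of
#'   [canpros_params()].
#' @export
default_female_penetrance <- function() {
  list(
    breast = list(
      rates = data.frame(
        age_lo = c(0, 25, 30, 35, 40, 45, 50, 60, 70),
        rate = c(0, 8e-5, 2.5e-4, 6e-4, 1.2e-3, 1.8e-3, 2.3e-3, 2.8e-3, 3.0e-3)),
      rr_brca1 = 8, rr_brca2 = 5),
    ovarian = list(
      rates = data.frame(
        age_lo = c(0, 35, 45, 55, 65),
        rate = c(0, 1e-4, 2.5e-4, 4e-4, 5e-4)),
      rr_brca1 = 25, rr_brca2 = 8)
  )
}

validate_params <- function(p) {
  stopifnot(inherits(p, "canpros_params"))
  f <- p$frequencies
  need <- c("BRCA2", "BRCA1", "HOXB13", "REC")
  miss <- setdiff(need, names(f))
  if (length(miss))
    stop("missing allele frequency for: ", paste(miss, collapse = ", "))
  if (any(!is.finite(f)) || any(f < 0) || any(f >= 1))
    stop("allele frequencies must lie in [0, 1)")
  for (nm in c("rr_brca2", "rr_brca1")) {
    cur <- p[[nm]]
    if (!all(c("age_lo", "rr") %in% names(cur)))
      stop(nm, " must have columns age_lo and rr")
    if (is.unsorted(cur$age_lo, strictly = TRUE) || cur$age_lo[1] != 0)
      stop(nm, " age_lo must start at 0 and be strictly increasing")
    if (any(cur$rr <= 0)) stop(nm, " relative risks must be positive")
  }
  if (!all(c("pre1930", "post1930") %in% names(p$rr_hoxb13)) ||
      any(p$rr_hoxb13 <= 0))
    stop("rr_hoxb13 needs positive entries pre1930 and post1930")
  if (!is.finite(p$rr_rec) || p$rr_rec <= 0) stop("rr_rec must be positive")
  if (!is.finite(p$sigma70) || p$sigma70 < 0) stop("sigma70 must be >= 0")
  if (!is.finite(p$sigma_rate) || p$sigma_rate <= 0)
    stop("sigma_rate must be positive")
  if (!is.finite(p$alpha) || p$alpha < 0 || p$alpha > 1)
    stop("alpha must lie in [0, 1]")
  s <- p$sensitivity
  if (!all(c("BRCA2", "BRCA1", "HOXB13") %in% names(s)) ||
      any(s <= 0) || any(s > 1))
    stop("sensitivities must be named BRCA2/BRCA1/HOXB13 and lie in (0, 1]")
  g <- p$grid
  if (any(g < 1L) || any(g %% 2L == 0L))
    stop("polygene grid sizes must be odd positive integers")
  if (p$max_age < 2L) stop("max_age too small")
  if (p$pgs_nugget_sd <= 0) stop("pgs_nugget_sd must be positive")
  invisible(p)
}

#' Read model parameters from a YAML file
#'
#' The YAML schema mirrors the arguments of [canpros_params()]; piecewise
#' relative-risk curves are lists of `{age_lo, rr}` records. All validation of
#' [canpros_params()] applies; a missing required field or an out-of-range
#' value is an error naming the field.
#'
#' @param path path to a YAML parameter file.
#' @return A `canpros_params` object.
#' @export
read_parameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$frequencies)) args$frequencies <- unlist(y$frequencies)
  for (nm in c("rr_brca2", "rr_brca1")) {
    if (!is.null(y[[nm]]))
      args[[nm]] <- do.call(rbind, lapply(y[[nm]], as.data.frame))
  }
  if (!is.null(y$rr_hoxb13)) args$rr_hoxb13 <- unlist(y$rr_hoxb13)
  for (nm in c("hoxb13_cohort_split", "rec_model", "rr_rec", "sigma70",
               "sigma_rate", "alpha", "pgs_nugget_sd", "max_age",
               "default_birth_year")) {
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  }
  if (!is.null(y$sensitivity)) args$sensitivity <- unlist(y$sensitivity)
  if (!is.null(y$grid)) args$grid <- unlist(y$grid)
  if (!is.null(y$female_penetrance)) {
    fp <- y$female_penetrance
    args$female_penetrance <- lapply(fp, function(site) {
      list(rates = do.call(rbind, lapply(site$rates, as.data.frame)),
           rr_brca1 = site$rr_brca1, rr_brca2 = site$rr_brca2)
    })
  }
  do.call(canpros_params, args)
}

#' Write model parameters to a YAML file
#'
#' Inverse of [read_parameters()]; a write/read round trip reproduces the
#' parameter object.
#'
#' @param params a `canpros_params` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  validate_params(params)
  df_to_recs <- function(d) lapply(seq_len(nrow(d)), function(i) as.list(d[i, ]))
  y <- list(
    frequencies = as.list(params$frequencies),
    rr_brca2 = df_to_recs(params$rr_brca2),
    rr_brca1 = df_to_recs(params$rr_brca1),
    rr_hoxb13 = as.list(params$rr_hoxb13),
    hoxb13_cohort_split = params$hoxb13_cohort_split,
    rec_model = params$rec_model,
    rr_rec = params$rr_rec,
    sigma70 = params$sigma70,
    sigma_rate = params$sigma_rate,
    alpha = params$alpha,
    sensitivity = as.list(params$sensitivity),
    pgs_nugget_sd = params$pgs_nugget_sd,
    grid = as.list(params$grid),
    max_age = params$max_age,
    default_birth_year = params$default_birth_year,
    female_penetrance = lapply(params$female_penetrance, function(site)
      list(rates = df_to_recs(site$rates),
           rr_brca1 = site$rr_brca1, rr_brca2 = site$rr_brca2))
  )
  yaml::write_yaml(y, path)
  invisible(path)
}

#' @export
print.canpros_params <- function(x, ...) {
  cat("canpros model parameters\n")
  cat("  allele frequencies:",
      paste(names(x$frequencies), signif(x$frequencies, 4),
            sep = "=", collapse = ", "), "\n")
  cat(sprintf("  polygene: sigma70=%.4g, rate=%.4g per year, alpha=%.4g\n",
              x$sigma70, x$sigma_rate, x$alpha))
  cat(sprintf("  fourth gene: %s, RR=%.4g\n", x$rec_model, x$rr_rec))
  cat(sprintf("  grids: obs=%d, res=%d; max age %d\n",
              x$grid[["obs"]], x$grid[["res"]], x$max_age))
  invisible(x)
}

#' Polygenic standard deviation at a given age
#'
#' The SD of the polygenic component on the log-hazard scale changes
#' log-linearly with age: `sigma(t) = sigma70 * sigma_rate^(t - 70)`.
#'
#' @param age age (years); vectorized.
#' @param params a `canpros_params` object.
#' @return Numeric vector of SDs.
#' @export
polygenic_sd <- function(age, params) {
  params$sigma70 * params$sigma_rate^(age - 70)
}

#' Decompose the polygenic SD into PGS-explained and residual parts
#'
#' The measured PGS explains a fraction `alpha` of the polygenic SD; the
#' residual part is independent with SD fraction `sqrt(1 - alpha^2)`, so the
#' two variances add to the full polygenic variance.
#'
#' @param params a `canpros_params` object.
#' @return Named vector `c(sd_pgs_fraction, sd_residual_fraction)`.
#' @export
decompose_pgs <- function(params) {
  a <- params$alpha
  c(sd_pgs_fraction = a, sd_residual_fraction = sqrt(1 - a^2))
}

# Piecewise-constant lookup of an age curve (data.frame age_lo, rr/rate).
step_lookup <- function(curve, ages, value_col = "rr") {
  idx <- findInterval(ages, curve$age_lo)
  idx[idx < 1L] <- 1L
  curve[[value_col]][idx]
}
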