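# Joint genotype x polygene state space.
#
# Components, in order: BRCA2, BRCA1, HOXB13, REC allele counts (3 states
# each, collapsed to 1 when the allele frequency is 0), then the observed-part
# and residual-part polygene grids. The joint state index runs column-major
# with component 1 fastest. Transmission factorizes across components.

LOCI <- c("BRCA2", "BRCA1", "HOXB13", "REC")

# Mendelian transmission for allele counts 0/1/2 at a biallelic locus.
mendel_trans <- function() {
  tr <- array(0, c(3, 3, 3))
  for (f in 0:2) for (m in 0:2) {
    pf <- c(1 - f / 2, f / 2)  # P(transmit risk allele) = count/2
    pm <- c(1 - m / 2, m / 2)
    for (af in 0:1) for (am in 0:1)
      tr[f + 1, m + 1, af + am + 1] <- tr[f + 1, m + 1, af + am + 1] +
        pf[af + 1] * pm[am + 1]
  }
  tr
}

hwe_prior <- function(q) c((1 - q)^2, 2 * q * (1 - q), q^2)

#' Build the joint major-gene and polygene state space
#'
#' Assembles per-component priors (Hardy-Weinberg within each locus, binomial
#' weights for each polygene grid; linkage equilibrium across components) and
#' transmission arrays. Loci with allele frequency 0 are collapsed to a single
#' noncarrier state, which shrinks the peeling state space without changing
#' the model.
#'
#' @param params a `canpros_params` object.
#' @return An object of class `canpros_space`.
#' @export
build_state_space <- function(params) {
  validate_params(params)
  comps <- list()
  for (locus in LOCI) {
    q <- params$frequencies[[locus]]
    if (q > 0) {
      comps[[locus]] <- list(name = locus, kind = "locus", n = 3L,
                             prior = hwe_prior(q), trans = mendel_trans(),
                             counts = 0:2)
    } else {
      comps[[locus]] <- list(name = locus, kind = "locus", n = 1L,
                             prior = 1, trans = array(1, c(1, 1, 1)),
                             counts = 0L)
    }
  }
  for (part in c("obs", "res")) {
    g <- polygene_grid(params$grid[[part]])
    comps[[paste0("poly_", part)]] <- list(
      name = paste0("poly_", part), kind = "polygene", n = g$n,
      prior = g$probs, trans = g$trans, values = g$values)
  }
  dims <- vapply(comps, `[[`, integer(1), "n")
  N <- prod(dims)
  # joint feature vectors over the N states
  grid_idx <- as.matrix(do.call(expand.grid, lapply(dims, seq_len)))
  feat <- list(
    count_BRCA2 = comps$BRCA2$counts[grid_idx[, 1]],
    count_BRCA1 = comps$BRCA1$counts[grid_idx[, 2]],
    count_HOXB13 = comps$HOXB13$counts[grid_idx[, 3]],
    count_REC = comps$REC$counts[grid_idx[, 4]],
    v_obs = comps$poly_obs$values[grid_idx[, 5]],
    v_res = comps$poly_res$values[grid_idx[, 6]]
  )
  prior <- Reduce(function(a, b) as.vector(outer(a, b)),
                  lapply(comps, `[[`, "prior"))
  # pairwise transmission matrices Tpair[(f-1)*n+m, c], f fastest
  tpair <- lapply(comps, function(cm) {
    matrix(aperm(cm$trans, c(1, 2, 3)), nrow = cm$n^2, ncol = cm$n)
  })
  sp <- structure(list(comps = comps, dims = dims, N = N, prior = prior,
                       feat = feat, tpair = tpair, params_grid = params$grid),
                  class = "canpros_space")
  sp$tfull <- if (N <= 200L) full_transmission_matrix(sp) else NULL
  sp
}

# Full transmission as a (N^2 x N) matrix in standard pair layout
# (pair index = F + (M-1) * N), used on small spaces for batch peeling.
full_transmission_matrix <- function(space) {
  K <- length(space$comps)
  # start with component 1 arranged over (f1, m1, c1), then expand
  out <- NULL
  for (i in seq_len(K)) {
    tr <- space$comps[[i]]$trans  # (n, n, n)
    if (is.null(out)) {
      out <- tr
      dim(out) <- c(dim(tr)[1], dim(tr)[2], dim(tr)[3])
      next
    }
    dF <- dim(out)[1]; dM <- dim(out)[2]; dC <- dim(out)[3]
    n <- space$comps[[i]]$n
    # new[(F,fi),(M,mi),(C,ci)] = out[F,M,C] * tr[fi,mi,ci]
    new <- array(0, c(dF * n, dM * n, dC * n))
    for (ci in 1:n) for (mi in 1:n) for (fi in 1:n) {
      if (all(tr[fi, mi, ci] == 0)) next
      new[(fi - 1) * dF + 1:dF, (mi - 1) * dM + 1:dM, (ci - 1) * dC + 1:dC] <-
        out * tr[fi, mi, ci]
    }
    out <- new
  }
  matrix(out, nrow = space$N^2, ncol = space$N)
}

#' Prior distribution over the joint genotype space
#'
#' Product of per-locus Hardy-Weinberg marginals (linkage equilibrium) for a
#' founder. Returned over major genotypes only, marginalized over the
#' polygene grids.
#'
#' @param params a `canpros_params` object.
#' @param birth_year unused placeholder for cohort-specific frequencies;
#'   frequencies are assumed cohort-constant.
#' @return A data frame with per-locus allele counts and `prob`, summing to 1.
#' @export
genotype_prior <- function(params, birth_year = NULL) {
  pri <- lapply(LOCI, function(locus) {
    q <- params$frequencies[[locus]]
    if (q > 0) data.frame(count = 0:2, p = hwe_prior(q))
    else data.frame(count = 0L, p = 1)
  })
  out <- expand.grid(BRCA2 = pri[[1]]$count, BRCA1 = pri[[2]]$count,
                     HOXB13 = pri[[3]]$count, REC = pri[[4]]$count)
  out$prob <- as.vector(outer(outer(outer(pri[[1]]$p, pri[[2]]$p), pri[[3]]$p),
                              pri[[4]]$p))
  out
}

# log relative risk of the major genotypes for every joint state; BRCA RRs
# are age-piecewise, HOXB13 is birth-cohort-specific per allele, and the
# fourth gene follows its configured inheritance model.
log_rr_major <- function(space, params, ages, birth_year) {
  f <- space$feat
  n_age <- length(ages)
  hox_rr <- if (birth_year < params$hoxb13_cohort_split)
    params$rr_hoxb13[["pre1930"]] else params$rr_hoxb13[["post1930"]]
  rec_mult <- switch(params$rec_model,
    recessive = ifelse(f$count_REC == 2L, params$rr_rec, 1),
    dominant = ifelse(f$count_REC >= 1L, params$rr_rec, 1),
    multiplicative = params$rr_rec^f$count_REC)
  static <- f$count_HOXB13 * log(hox_rr) + log(rec_mult)
  b2 <- log(step_lookup(params$rr_brca2, ages))
  b1 <- log(step_lookup(params$rr_brca1, ages))
  # (n_age x N): age-varying BRCA parts plus static part
  outer(b2, as.numeric(f$count_BRCA2 >= 1L)) +
    outer(b1, as.numeric(f$count_BRCA1 >= 1L)) +
    matrix(static, n_age, space$N, byrow = TRUE)
}

# standardized combined polygene direction: alpha * obs + sqrt(1-a^2) * res
polygene_loading <- function(space, params) {
  a <- params$alpha
  a * space$feat$v_obs + sqrt(1 - a^2) * space$feat$v_res
}

#' Multiplicative relative risk of a genotype and polygene configuration
#'
#' Joint effects are multiplicative on the hazard scale: the major-gene
#' relative risks (dominant BRCA2/BRCA1, per-allele HOXB13 with
#' birth-cohort-specific RRs, and the fourth gene under its inheritance
#' model) times `exp(sigma(age) * (alpha * polygene_obs +
#' sqrt(1 - alpha^2) * polygene_res))`.
#'
#' @param params a `canpros_params` object.
#' @param genotype named vector/list of allele counts (`BRCA2`, `BRCA1`,
#'   `HOXB13`, `REC`), 0/1/2; missing entries default to 0.
#' @param age age in years (scalar).
#' @param birth_year birth year (selects the HOXB13 cohort RR).
#' @param polygene_obs,polygene_res standardized levels of the observed-part
#'   and residual-part polygene.
#' @return The hazard ratio relative to a noncarrier with polygene 0.
#' @export
relative_risk <- function(params, genotype = c(), age, birth_year,
                          polygene_obs = 0, polygene_res = 0) {
  cnt <- c(BRCA2 = 0, BRCA1 = 0, HOXB13 = 0, REC = 0)
  cnt[names(genotype)] <- unlist(genotype)
  if (any(!cnt %in% 0:2)) stop("allele counts must be 0, 1 or 2")
  hox_rr <- if (birth_year < params$hoxb13_cohort_split)
    params$rr_hoxb13[["pre1930"]] else params$rr_hoxb13[["post1930"]]
  rec_mult <- switch(params$rec_model,
    recessive = if (cnt[["REC"]] == 2) params$rr_rec else 1,
    dominant = if (cnt[["REC"]] >= 1) params$rr_rec else 1,
    multiplicative = params$rr_rec^cnt[["REC"]])
  sig <- polygenic_sd(age, params)
  a <- params$alpha
  step_lookup(params$rr_brca2, age)^(cnt[["BRCA2"]] >= 1) *
    step_lookup(params$rr_brca1, age)^(cnt[["BRCA1"]] >= 1) *
    hox_rr^cnt[["HOXB13"]] * rec_mult *
    exp(sig * (a * polygene_obs + sqrt(1 - a^2) * polygene_res))
}

#' Offspring distribution given parental joint states
#'
#' Major loci transmit independently and Mendelianly; each polygene part
#' transmits under the hypergeometric model. Mainly a building block exposed
#' for inspection and testing.
#'
#' @param space a `canpros_space`.
#' @param father_state,mother_state joint state indices (1-based).
#' @return Numeric vector of length `space$N`: the offspring distribution.
#' @export
transmission <- function(space, father_state, mother_state) {
  fi <- state_to_comp_idx(space, father_state)
  mi <- state_to_comp_idx(space, mother_state)
  Reduce(function(a, b) as.vector(outer(a, b)),
         lapply(seq_along(space$comps), function(i)
           space$comps[[i]]$trans[fi[i], mi[i], ]))
}

#' Dump the joint state space for inspection
#'
#' @param params a `canpros_params` object.
#' @return Data frame with one row per joint state: allele counts, polygene
#'   levels, and the founder prior probability.
#' @export
dump_genotypes <- function(params) {
  sp <- build_state_space(params)
  data.frame(state = seq_len(sp$N),
             BRCA2 = sp$feat$count_BRCA2, BRCA1 = sp$feat$count_BRCA1,
             HOXB13 = sp$feat$count_HOXB13, REC = sp$feat$count_REC,
             polygene_obs = sp$feat$v_obs, polygene_res = sp$feat$v_res,
             prior = sp$prior)
}

# joint state index -> per-component indices (component 1 fastest)
state_to_comp_idx <- function(space, s) {
  s <- s - 1L
  idx <- integer(length(space$dims))
  for (i in seq_along(space$dims)) {
    idx[i] <- s %% space$dims[i] + 1L
    s <- s %/% space$dims[i]
  }
  idx
}
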