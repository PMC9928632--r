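# Elston-Stewart peeling over the joint major-genotype x polygene space.
#
# Transmission factorizes across the six components (four loci, two polygene
# parts), so sums over parent pairs and children are computed as sequential
# per-component tensor contractions. Pair functions over (father, mother) use
# either the "standard" layout (pair index = F + (M - 1) * N) or the
# "interleaved" layout with per-component (f_i, m_i) dims, produced naturally
# by the contractions; helpers convert between the two.

interleave_perm <- function(K) as.vector(rbind(seq_len(K), K + seq_len(K)))

# pair function in interleaved layout from two state vectors
pair_interleave <- function(space, wF, wM) {
  d <- space$dims
  K <- length(d)
  x <- array(outer(wF, wM), c(d, d))
  as.vector(aperm(x, interleave_perm(K)))
}

pair_to_standard <- function(space, P) {
  d <- space$dims
  K <- length(d)
  x <- array(P, as.vector(rbind(d, d)))
  matrix(aperm(x, order(interleave_perm(K))), space$N, space$N)
}

# Sum a child state vector against transmission for every parent pair:
# returns g with g[(F,M)] = sum_c T(F,M -> c) w[c], interleaved layout.
down_message <- function(space, w) {
  d <- space$dims
  K <- length(d)
  X <- w
  A <- 1L
  B <- prod(d)
  for (i in seq_len(K)) {
    di <- d[i]
    B <- B %/% di
    X3 <- array(X, c(A, di, B))
    Xp <- matrix(aperm(X3, c(2L, 1L, 3L)), nrow = di)
    Y0 <- space$tpair[[i]] %*% Xp            # (di^2, A*B)
    X <- as.vector(aperm(array(Y0, c(di * di, A, B)), c(2L, 1L, 3L)))
    A <- A * di * di
  }
  X
}

# Contract a pair function (interleaved) with transmission to a child vector:
# m[c] = sum_{F,M} P(F,M) T(F,M -> c).
child_message <- function(space, P) {
  d <- space$dims
  K <- length(d)
  X <- P
  A <- 1L
  B <- prod(d)^2
  for (i in seq_len(K)) {
    di <- d[i]
    B <- B %/% (di * di)
    X3 <- array(X, c(A, di * di, B))
    Xp <- matrix(aperm(X3, c(2L, 1L, 3L)), nrow = di * di)
    Y0 <- crossprod(space$tpair[[i]], Xp)    # (di, A*B)
    X <- as.vector(aperm(array(Y0, c(di, A, B)), c(2L, 1L, 3L)))
    A <- A * di
  }
  X
}

#' Individual likelihood factors over the joint state space
#'
#' The contribution of one individual's data to the pedigree likelihood,
#' as a vector over the joint genotype/polygene states: for males the
#' probability of surviving prostate-cancer-free to the censoring age
#' (times the annual event probability in the diagnosis year if affected)
#' under the constrained hazards of their birth cohort; for females the
#' breast/ovarian penetrance factors; times, for everyone, the per-gene
#' probability of the genetic test result (carriers test positive with the
#' configured sensitivity, noncarriers never test positive) and the PGS
#' measurement density given the observed-part polygene level.
#'
#' @param ind a single-row data frame or named list with the member fields
#'   of [pedigree()].
#' @param store a hazard store from [hazard_store()] (or `canpros_hazards`).
#' @return Numeric vector of length `space$N`.
#' @export
individual_likelihood <- function(ind, store) {
  store <- as_store(store)
  ind <- as.list(ind)
  defaults <- list(censor_age = NA_real_, prostate_dx_age = NA_real_,
                   breast_dx_age = NA_real_, ovarian_dx_age = NA_real_,
                   birth_year = NA_real_, pgs = NA_real_,
                   brca2_test = "untested", brca1_test = "untested",
                   hoxb13_test = "untested")
  for (nm in names(defaults))
    if (is.null(ind[[nm]])) ind[[nm]] <- defaults[[nm]]
  penetrance_vector(ind, store, mask = "all")
}

# Penetrance vector of one individual over the N states: phenotype survival/
# event factors, genetic test factors (perfect specificity), PGS density.
# `mask` switches off data classes for ascertainment conditioning.
penetrance_vector <- function(ind, store, mask = c("all")) {
  space <- store$space
  params <- store$params
  N <- space$N
  pen <- rep(1, N)
  use_phen <- any(mask %in% c("all", "phenotypes"))
  use_tests <- "all" %in% mask
  use_pgs <- "all" %in% mask
  censor <- ind$censor_age
  if (use_phen && !is.na(censor) && censor > 0) {
    A <- params$max_age
    censor <- min(censor, A)
    if (ind$sex == "M") {
      hz <- store_hazards(store, ind$birth_year)
      dx <- ind$prostate_dx_age
      pen <- pen * if (!is.na(dx)) hz$f_year[min(dx, A - 1L) + 1L, ]
                   else hz$S[censor + 1L, ]
    } else {
      pen <- pen * female_penetrance_vector(ind, space, params, censor)
    }
  }
  if (use_tests) {
    for (g in c("BRCA2", "BRCA1", "HOXB13")) {
      res <- ind[[paste0(tolower(g), "_test")]]
      if (is.null(res) || is.na(res) || res == "untested") next
      carrier <- space$feat[[paste0("count_", g)]] >= 1L
      sens <- params$sensitivity[[g]]
      pen <- pen * if (res == "carrier") ifelse(carrier, sens, 0)
                   else ifelse(carrier, 1 - sens, 1)
    }
  }
  if (use_pgs && !is.null(ind$pgs) && !is.na(ind$pgs)) {
    pen <- pen * stats::dnorm(ind$pgs, mean = space$feat$v_obs,
                              sd = params$pgs_nugget_sd)
  }
  pen
}

# Female members carry breast/ovarian phenotypes driven by external
# penetrance curves per BRCA1/2 carrier class, without a polygenic effect.
female_penetrance_vector <- function(ind, space, params, censor) {
  pen <- rep(1, space$N)
  b1 <- space$feat$count_BRCA1 >= 1L
  b2 <- space$feat$count_BRCA2 >= 1L
  for (site in c("breast", "ovarian")) {
    fp <- params$female_penetrance[[site]]
    dx <- ind[[paste0(site, "_dx_age")]]
    stop_age <- if (!is.na(dx)) dx else censor
    base <- step_lookup(fp$rates, 0:max(stop_age - 1L, 0L),
                        value_col = "rate")
    mult <- ifelse(b1, fp$rr_brca1, 1) * ifelse(b2 & !b1, fp$rr_brca2, 1)
    cum <- if (stop_age > 0) sum(base) else 0
    surv <- exp(-cum * mult)
    pen <- pen * if (!is.na(dx)) {
      lam_dx <- step_lookup(fp$rates, dx, value_col = "rate") * mult
      surv * (1 - exp(-lam_dx))
    } else surv
  }
  pen
}

# Core peeling. Returns log-likelihood, or (keep_id given) the unnormalized
# posterior over the kept individual's states plus the log normalizer.
peel_engine <- function(ped, store, mask = "all", keep_id = NULL) {
  space <- store$space
  m <- ped$members
  n <- nrow(m)
  keep <- if (is.null(keep_id)) NA_integer_ else match(keep_id, m$id)
  if (!is.null(keep_id) && is.na(keep))
    stop("individual '", keep_id, "' not in pedigree")
  pen <- lapply(seq_len(n), function(i)
    penetrance_vector(as.list(m[i, ]), store, mask = mask))
  founder <- is.na(m$father_id)
  msgs <- vector("list", n)
  logc <- 0
  weight_of <- function(i, with_prior) {
    w <- pen[[i]]
    if (!is.null(msgs[[i]])) for (v in msgs[[i]]) w <- w * v
    if (with_prior && founder[i]) w <- w * space$prior
    w
  }
  add_msg <- function(i, v) {
    s <- max(v)
    if (s <= 0 || !is.finite(s)) stop("zero-probability pedigree data")
    logc <<- logc + log(s)
    msgs[[i]] <<- c(msgs[[i]], list(v / s))
  }
  ord <- peeling_order(ped, keep = keep)
  in_fam <- unique(unlist(lapply(ord$fams, function(f)
    c(f$father, f$mother, f$children))))
  for (st in ord$steps) {
    f <- st$fam
    pv <- st$pivot
    child_sums <- lapply(setdiff(f$children, pv), function(ci)
      down_message(space, weight_of(ci, with_prior = FALSE)))
    if (!is.na(pv) && pv %in% c(f$father, f$mother)) {
      other <- if (pv == f$father) f$mother else f$father
      wO <- weight_of(other, with_prior = TRUE)
      G <- Reduce(`*`, child_sums,
                  pair_interleave(space, rep(1, space$N), rep(1, space$N)))
      Gm <- pair_to_standard(space, G)
      v <- if (pv == f$father) as.vector(Gm %*% wO)
           else as.vector(crossprod(Gm, wO))
      add_msg(pv, v)
    } else {
      wF <- weight_of(f$father, with_prior = TRUE)
      wM <- weight_of(f$mother, with_prior = TRUE)
      P <- Reduce(`*`, child_sums, pair_interleave(space, wF, wM))
      if (!is.na(pv)) {
        add_msg(pv, child_message(space, P))
      } else {
        s <- sum(P)
        if (s <= 0 || !is.finite(s)) stop("zero-probability pedigree data")
        logc <- logc + log(s)
      }
    }
  }
  isolated <- setdiff(seq_len(n), in_fam)
  if (!is.null(keep_id)) {
    v <- weight_of(keep, with_prior = TRUE)
    for (i in setdiff(isolated, keep)) {
      s <- sum(weight_of(i, with_prior = TRUE))
      if (s <= 0) stop("zero-probability pedigree data")
      logc <- logc + log(s)
    }
    return(list(states = v, logc = logc))
  }
  for (i in isolated) {
    s <- sum(weight_of(i, with_prior = TRUE))
    if (s <= 0) stop("zero-probability pedigree data")
    logc <- logc + log(s)
  }
  logc
}

#' Pedigree log-likelihood by Elston-Stewart peeling
#'
#' Exact log of the sum over all members' joint genotype/polygene states of
#' founder priors, Mendelian/polygenic transmission, and individual
#' likelihood factors (phenotypes under the constrained hazards, genetic test
#' results with the configured sensitivities and perfect specificity, and the
#' PGS measurement density). Underflow is guarded by renormalizing messages
#' in log space.
#'
#' @param ped a `canpros_pedigree` (loop-free; validated pedigrees peel).
#' @param store a hazard store from [hazard_store()], or a
#'   `canpros_hazards` object (then used for all birth cohorts).
#' @return The log-likelihood (scalar).
#' @export
peel <- function(ped, store) {
  store <- as_store(store)
  peel_engine(ped, store, mask = "all")
}

as_store <- function(store) {
  if (inherits(store, "canpros_hazard_store")) return(store)
  if (inherits(store, "canpros_hazards")) {
    st <- hazard_store(store$incidence, store$params, space = store$space)
    assign(as.character(store$birth_year), store, envir = st$cache)
    return(st)
  }
  stop("expected a canpros_hazard_store or canpros_hazards object")
}

#' Ascertainment-adjusted pedigree log-likelihood
#'
#' Adjusts for nonrandom ascertainment by conditioning on the data that may
#' have influenced the family's selection: the adjusted log-likelihood is
#' `peel(full data) - peel(conditioning data only)`. The scheme
#' `"proband_phenotype"` conditions on the proband's affection status and
#' ages only; `"family_phenotypes"` conditions on the affection statuses and
#' ages of all family members (genotype tests and PGS marginalized);
#' `"none"` applies no adjustment. The default `"auto"` maps the proband's
#' detection mode to a scheme: symptomatic diagnoses condition on the proband
#' phenotype, screen-detected or unknown diagnoses on the family phenotypes.
#'
#' @param ped a `canpros_pedigree`.
#' @param store a hazard store from [hazard_store()].
#' @param scheme `"auto"`, `"proband_phenotype"`, `"family_phenotypes"`, or
#'   `"none"`.
#' @return The adjusted log-likelihood.
#' @export
condition <- function(ped, store,
                      scheme = c("auto", "proband_phenotype",
                                 "family_phenotypes", "none")) {
  scheme <- match.arg(scheme)
  store <- as_store(store)
  if (scheme == "auto") scheme <- auto_scheme(ped)
  full <- peel_engine(ped, store, mask = "all")
  if (scheme == "none") return(full)
  cond <- if (scheme == "family_phenotypes") {
    peel_engine(ped, store, mask = "phenotypes")
  } else {
    peel_engine(strip_to_proband(ped), store, mask = "phenotypes")
  }
  if (!is.finite(cond)) stop("impossible conditioning event")
  full - cond
}

auto_scheme <- function(ped) {
  if (is.na(ped$proband_id)) return("none")
  det <- ped$members$detection[match(ped$proband_id, ped$members$id)]
  if (identical(det, "symptomatic")) "proband_phenotype"
  else "family_phenotypes"
}

# keep only the proband's phenotype data; all other members lose phenotypes
strip_to_proband <- function(ped) {
  m <- ped$members
  keep <- m$id == ped$proband_id
  m$censor_age[!keep] <- NA_real_
  m$prostate_dx_age[!keep] <- NA_real_
  m$breast_dx_age[!keep] <- NA_real_
  m$ovarian_dx_age[!keep] <- NA_real_
  ped$members <- m
  ped
}
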