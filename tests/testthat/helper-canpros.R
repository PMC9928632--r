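# Shared fixtures: small parameter sets, flat incidence tables, and an
# exhaustive-enumeration likelihood oracle independent of the peeling code.

toy_params <- function(...) {
  args <- utils::modifyList(
    list(frequencies = c(BRCA2 = 0, BRCA1 = 0, HOXB13 = 0, REC = 0.3),
         grid = c(obs = 1L, res = 3L), sigma70 = 1, sigma_rate = 1,
         alpha = 0),
    list(...))
  do.call(canpros_params, args)
}

flat_incidence <- function(rate = 0.01, max_age = 90) {
  incidence_table(data.frame(age_lo = 0, age_hi = max_age,
                             period_lo = -Inf, period_hi = Inf,
                             sex = "M", site = "prostate", rate = rate))
}

# Exhaustive sum over every member's joint state: prior for founders,
# full transmission for nonfounders, penetrance factors for everyone.
# Independent of peel(): the only shared pieces are the model inputs.
brute_force_loglik <- function(ped, store) {
  store <- canpros:::as_store(store)
  sp <- store$space
  N <- sp$N
  m <- ped$members
  n <- nrow(m)
  stopifnot(N^n <= 1e6)
  pen <- lapply(seq_len(n), function(i)
    canpros:::penetrance_vector(as.list(m[i, ]), store))
  Tf <- array(sp$tfull, c(N, N, N))
  fa <- match(m$father_id, m$id)
  mo <- match(m$mother_id, m$id)
  S <- as.matrix(expand.grid(rep(list(seq_len(N)), n)))
  w <- rep(1, nrow(S))
  for (i in seq_len(n)) {
    w <- w * pen[[i]][S[, i]]
    w <- w * if (is.na(fa[i])) sp$prior[S[, i]]
             else Tf[cbind(S[, fa[i]], S[, mo[i]], S[, i])]
  }
  log(sum(w))
}

# a nuclear test family: affected father, unaffected mother, two sons
nuclear_test_pedigree <- function(dx_father = 65, dx_son1 = 50,
                                  censor_son2 = 60) {
  pedigree(data.frame(
    id = c("f", "m", "s1", "s2"),
    father_id = c(NA, NA, "f", "f"), mother_id = c(NA, NA, "m", "m"),
    sex = c("M", "F", "M", "M"),
    birth_year = c(1930, 1932, 1960, 1962),
    censor_age = c(70, 70, max(dx_son1, 1), censor_son2),
    prostate_dx_age = c(dx_father, NA, dx_son1, NA),
    stringsAsFactors = FALSE))
}
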