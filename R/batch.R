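# Vectorized likelihood evaluation for collections of two-generation nuclear
# families (two founder parents plus children). Used by fit(): a parameter
# search re-evaluates thousands of family likelihoods per step, so the
# per-family Elston-Stewart recursion is replaced by matrix operations shared
# across families, with all member data pre-extracted into plain vectors.
# Results agree with peel()/condition() exactly.

is_nuclear <- function(ped) {
  m <- ped$members
  fams <- nuclear_families(ped)
  length(fams) == 1L &&
    length(fams[[1]]$children) == nrow(m) - 2L &&
    is.na(m$father_id[fams[[1]]$father]) &&
    is.na(m$father_id[fams[[1]]$mother])
}

prepare_nuclear_batch <- function(pedigrees) {
  stopifnot(all(vapply(pedigrees, is_nuclear, logical(1))))
  rows <- list()
  meta <- list()
  for (i in seq_along(pedigrees)) {
    ped <- pedigrees[[i]]
    fam <- nuclear_families(ped)[[1]]
    m <- ped$members
    ord <- c(fam$father, fam$mother, fam$children)
    mm <- m[ord, ]
    mm$.ped <- i
    mm$.role <- c("F", "M", rep("C", length(fam$children)))
    rows[[i]] <- mm
    meta[[i]] <- list(n_children = length(fam$children),
                      scheme = auto_scheme(ped),
                      proband = match(ped$proband_id, mm$id))
  }
  long <- do.call(rbind, rows)
  rownames(long) <- NULL
  cols <- list(
    ped = long$.ped, role = long$.role, sex = long$sex,
    birth_year = long$birth_year, censor = long$censor_age,
    dx = long$prostate_dx_age,
    brca2_test = long$brca2_test, brca1_test = long$brca1_test,
    hoxb13_test = long$hoxb13_test, pgs = long$pgs)
  kvec <- vapply(meta, `[[`, integer(1), "n_children")
  groups <- lapply(sort(unique(kvec)), function(k) {
    ids <- which(kvec == k)
    inpeds <- cols$ped %in% ids
    rowsC <- which(cols$role == "C" & inpeds)
    list(k = k, ids = ids,
         rowsF = which(cols$role == "F" & inpeds),
         rowsM = which(cols$role == "M" & inpeds),
         rowsC = rowsC[order(match(cols$ped[rowsC], ids))])
  })
  # proband singleton rows (for the proband-phenotype conditioning)
  pro_row <- vapply(seq_along(meta), function(i)
    which(cols$ped == i)[meta[[i]]$proband], integer(1))
  list(members = long, cols = cols, meta = meta, groups = groups,
       schemes = vapply(meta, `[[`, character(1), "scheme"),
       pro_row = pro_row, n = length(pedigrees))
}

# Penetrance matrix (n_members x N) for member rows `rows` (default all).
# mask: "all" or "phenotypes" (drop tests and PGS, for conditioning).
batch_penetrance <- function(batch, store, mask = "all",
                             rows = seq_along(batch$cols$ped)) {
  cols <- batch$cols
  space <- store$space
  params <- store$params
  N <- space$N
  n <- length(rows)
  P <- matrix(1, n, N)
  A <- params$max_age
  by <- cols$birth_year[rows]
  by[is.na(by)] <- params$default_birth_year
  # birth cohorts sharing one constrained-hazards object are processed as
  # one group (their representative cohort)
  ub <- unique(by)
  rep_by <- vapply(ub, function(b) store_hazards(store, b)$birth_year,
                   numeric(1))[match(by, ub)]
  has_phen <- !is.na(cols$censor[rows]) & cols$censor[rows] > 0
  males <- which(has_phen & cols$sex[rows] == "M")
  for (b in unique(rep_by[males])) {
    hz <- store_hazards(store, b)
    grp <- males[rep_by[males] == b]
    dx <- cols$dx[rows[grp]]
    cens <- pmin(cols$censor[rows[grp]], A)
    aff <- !is.na(dx)
    if (any(aff))
      P[grp[aff], ] <- hz$f_year[pmin(dx[aff], A - 1L) + 1L, , drop = FALSE]
    if (any(!aff))
      P[grp[!aff], ] <- hz$S[cens[!aff] + 1L, , drop = FALSE]
  }
  females <- which(has_phen & cols$sex[rows] == "F")
  for (i in females) {
    P[i, ] <- female_penetrance_vector(
      as.list(batch$members[rows[i], ]), space, params,
      min(cols$censor[rows[i]], A))
  }
  if (identical(mask, "all")) {
    for (g in c("BRCA2", "BRCA1", "HOXB13")) {
      res <- cols[[paste0(tolower(g), "_test")]][rows]
      carrier <- space$feat[[paste0("count_", g)]] >= 1L
      sens <- params$sensitivity[[g]]
      pos <- which(!is.na(res) & res == "carrier")
      neg <- which(!is.na(res) & res == "noncarrier")
      if (length(pos))
        P[pos, ] <- P[pos, , drop = FALSE] *
          matrix(ifelse(carrier, sens, 0), length(pos), N, byrow = TRUE)
      if (length(neg))
        P[neg, ] <- P[neg, , drop = FALSE] *
          matrix(ifelse(carrier, 1 - sens, 1), length(neg), N, byrow = TRUE)
    }
    z <- cols$pgs[rows]
    haspgs <- which(!is.na(z))
    if (length(haspgs))
      P[haspgs, ] <- P[haspgs, , drop = FALSE] *
        stats::dnorm(outer(z[haspgs], space$feat$v_obs, "-"),
                     sd = params$pgs_nugget_sd)
  }
  P
}

# Joint log-likelihoods of all families given a full penetrance matrix
# (rows aligned with batch$cols). `only` restricts to a subset of families.
batch_joint_loglik <- function(batch, store, P, only = NULL,
                               chunk_target = 2e7) {
  space <- store$space
  N <- space$N
  if (is.null(space$tfull))
    stop("state space too large for the batch path (N = ", N, ")")
  tT <- t(space$tfull)                       # (N x N^2)
  Fidx <- rep(seq_len(N), times = N)
  Midx <- rep(seq_len(N), each = N)
  priorF <- space$prior[Fidx]
  priorM <- space$prior[Midx]
  out <- rep(NA_real_, batch$n)
  for (gr in batch$groups) {
    k <- gr$k
    sel <- if (is.null(only)) seq_along(gr$ids)
           else which(gr$ids %in% only)
    if (!length(sel)) next
    chunk <- max(1L, floor(chunk_target / (max(k, 1L) * N * N)))
    for (start in seq(1L, length(sel), by = chunk)) {
      sub <- sel[start:min(start + chunk - 1L, length(sel))]
      nn <- length(sub)
      Aw <- P[gr$rowsF[sub], , drop = FALSE]
      Bw <- P[gr$rowsM[sub], , drop = FALSE]
      pairw <- Aw[, Fidx, drop = FALSE] * Bw[, Midx, drop = FALSE] *
        matrix(priorF * priorM, nn, N * N, byrow = TRUE)
      if (k > 0) {
        crow <- gr$rowsC[rep((sub - 1L) * k, each = k) + seq_len(k)]
        G <- P[crow, , drop = FALSE] %*% tT   # (nn*k x N^2)
        Gp <- G[seq(1L, nrow(G), by = k), , drop = FALSE]
        if (k > 1) for (j in 2:k)
          Gp <- Gp * G[seq(j, nrow(G), by = k), , drop = FALSE]
        pairw <- pairw * Gp
      }
      out[gr$ids[sub]] <- log(rowSums(pairw))
    }
  }
  out
}

# Ascertainment-conditioned log-likelihood summed over nuclear families.
# Mirrors condition(): per-family scheme from the proband's detection mode
# (or an override), with the proband-phenotype conditioning evaluated in
# closed form via the stationary population prior.
batch_conditioned_loglik <- function(batch, store, scheme_override = NULL) {
  P_full <- batch_penetrance(batch, store, mask = "all")
  ll_full <- batch_joint_loglik(batch, store, P_full)
  schemes <- if (is.null(scheme_override))
    batch$schemes else rep(scheme_override, batch$n)
  ll_cond <- numeric(batch$n)
  fam_ids <- which(schemes == "family_phenotypes")
  pro_ids <- which(schemes == "proband_phenotype")
  if (length(fam_ids) || length(pro_ids)) {
    P_ph <- batch_penetrance(batch, store, mask = "phenotypes")
    if (length(fam_ids))
      ll_cond[fam_ids] <- batch_joint_loglik(batch, store, P_ph,
                                             only = fam_ids)[fam_ids]
    if (length(pro_ids)) {
      pr <- batch$pro_row[pro_ids]
      ll_cond[pro_ids] <- log(as.vector(P_ph[pr, , drop = FALSE] %*%
                                          store$space$prior))
    }
  }
  sum(ll_full - ll_cond)
}
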