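#' Pedigree objects
#'
#' A pedigree is a set of individuals with parent links, phenotypes, genetic
#' test results and an optional standardized polygenic score. The member table
#' has one row per individual with columns:
#'
#' * `id`, `father_id`, `mother_id`: character; both parents present or both
#'   absent (`NA`).
#' * `sex`: `"M"` or `"F"`.
#' * `birth_year`: integer, `NA` allowed (defaults to the reference cohort).
#' * `censor_age`: age at last observation (0/`NA` for no phenotype data).
#' * `prostate_dx_age` (males), `breast_dx_age`, `ovarian_dx_age` (females):
#'   integer age at diagnosis or `NA`; a diagnosis at age `a` contributes the
#'   hazard of the year `[a, a + 1)`.
#' * `detection`: how a prostate cancer was detected (`symptomatic`,
#'   `screen`, `unknown`, `not_applicable`); drives the default
#'   ascertainment-conditioning scheme.
#' * `proband`: logical; exactly one proband when the ascertainment arm is
#'   not `"none"`.
#' * `brca2_test`, `brca1_test`, `hoxb13_test`: `"carrier"`, `"noncarrier"`,
#'   or `"untested"`.
#' * `pgs`: standardized polygenic score or `NA`.
#'
#' @param members member data frame as described above.
#' @param famid family identifier.
#' @param arm ascertainment arm: `"population"`, `"young_onset"`,
#'   `"fh_enriched"`, or `"none"`.
#' @param validate run [validate_pedigree()].
#' @return An object of class `canpros_pedigree`.
#' @export
pedigree <- function(members, famid = "fam1", arm = "none", validate = TRUE) {
  members <- as.data.frame(members, stringsAsFactors = FALSE)
  defaults <- list(father_id = NA_character_, mother_id = NA_character_,
                   birth_year = NA_integer_, censor_age = NA_real_,
                   prostate_dx_age = NA_real_, breast_dx_age = NA_real_,
                   ovarian_dx_age = NA_real_, detection = "not_applicable",
                   proband = FALSE, brca2_test = "untested",
                   brca1_test = "untested", hoxb13_test = "untested",
                   pgs = NA_real_)
  for (nm in names(defaults))
    if (is.null(members[[nm]])) members[[nm]] <- defaults[[nm]]
  members$id <- as.character(members$id)
  members$father_id <- as.character(members$father_id)
  members$mother_id <- as.character(members$mother_id)
  for (nm in c("birth_year", "censor_age", "prostate_dx_age",
               "breast_dx_age", "ovarian_dx_age", "pgs"))
    members[[nm]] <- as.numeric(members[[nm]])
  for (nm in c("detection", "brca2_test", "brca1_test", "hoxb13_test"))
    members[[nm]] <- as.character(members[[nm]])
  members$father_id[members$father_id %in% c("", "0")] <- NA_character_
  members$mother_id[members$mother_id %in% c("", "0")] <- NA_character_
  members$proband <- as.logical(members$proband)
  ped <- structure(list(members = members, famid = famid, arm = arm,
                        proband_id = members$id[which(members$proband)[1]]),
                   class = "canpros_pedigree")
  if (validate) validate_pedigree(ped)
  ped
}

#' Validate a pedigree
#'
#' Checks the structural and phenotype invariants: unique ids; referenced
#' parents exist with correct sexes; both parents present or both absent;
#' parent links are acyclic; site-specific diagnoses match sex and do not
#' exceed the censoring age; exactly one proband when the ascertainment arm
#' is not `"none"`; and the pedigree admits an Elston-Stewart peeling order
#' (pedigrees with marriage or inbreeding loops are rejected rather than
#' loop-broken).
#'
#' @param ped a `canpros_pedigree`.
#' @return `ped`, invisibly; stops with an informative error otherwise.
#' @export
validate_pedigree <- function(ped) {
  m <- ped$members
  who <- function(i) paste0("pedigree ", ped$famid, ", individual ", m$id[i])
  if (anyDuplicated(m$id))
    stop("pedigree ", ped$famid, ": duplicate individual ids")
  if (!all(m$sex %in% c("M", "F")))
    stop("pedigree ", ped$famid, ": sex must be 'M' or 'F'")
  for (i in seq_len(nrow(m))) {
    fa <- m$father_id[i]; mo <- m$mother_id[i]
    if (is.na(fa) != is.na(mo))
      stop(who(i), ": both parents must be present or both absent")
    if (!is.na(fa)) {
      if (!fa %in% m$id) stop(who(i), ": father '", fa, "' not in pedigree")
      if (!mo %in% m$id) stop(who(i), ": mother '", mo, "' not in pedigree")
      if (m$sex[match(fa, m$id)] != "M") stop(who(i), ": father is not male")
      if (m$sex[match(mo, m$id)] != "F") stop(who(i), ": mother is not female")
    }
    if (!is.na(m$prostate_dx_age[i]) && m$sex[i] != "M")
      stop(who(i), ": prostate diagnosis on a female")
    if ((!is.na(m$breast_dx_age[i]) || !is.na(m$ovarian_dx_age[i])) &&
        m$sex[i] != "F")
      stop(who(i), ": breast/ovarian diagnosis on a male")
    for (col in c("prostate_dx_age", "breast_dx_age", "ovarian_dx_age")) {
      dx <- m[[col]][i]
      if (!is.na(dx) && (is.na(m$censor_age[i]) || dx > m$censor_age[i]))
        stop(who(i), ": ", col, " exceeds censor_age")
    }
  }
  # acyclicity of parent links
  idx <- seq_len(nrow(m))
  parent_of <- cbind(match(m$father_id, m$id), match(m$mother_id, m$id))
  depth <- rep(NA_integer_, nrow(m))
  resolve <- function(i, seen) {
    if (!is.na(depth[i])) return(depth[i])
    if (i %in% seen) stop("pedigree ", ped$famid,
                          ": parent links contain a cycle")
    ps <- parent_of[i, ]
    d <- if (all(is.na(ps))) 0L
    else 1L + max(vapply(ps[!is.na(ps)], resolve, integer(1),
                         seen = c(seen, i)))
    depth[i] <<- d
    d
  }
  for (i in idx) resolve(i, integer(0))
  if (ped$arm != "none" && sum(m$proband, na.rm = TRUE) != 1L)
    stop("pedigree ", ped$famid, ": exactly one proband required for arm '",
         ped$arm, "'")
  # peelability (loop check): rejected rather than loop-cut
  po <- try(peeling_order(ped), silent = TRUE)
  if (inherits(po, "try-error"))
    stop("pedigree ", ped$famid,
         ": contains a marriage/inbreeding loop and cannot be peeled")
  invisible(ped)
}

# Nuclear families of a pedigree: list of (father index, mother index,
# children indices), plus per-individual family membership.
nuclear_families <- function(ped) {
  m <- ped$members
  has_par <- !is.na(m$father_id)
  if (!any(has_par)) return(list())
  key <- paste(m$father_id[has_par], m$mother_id[has_par], sep = "\r")
  fams <- lapply(split(which(has_par), key), function(kids) {
    list(father = match(m$father_id[kids[1]], m$id),
         mother = match(m$mother_id[kids[1]], m$id),
         children = kids)
  })
  unname(fams)
}

# A valid peeling sequence: repeatedly take a family sharing at most one
# individual with the remaining families (plus optionally a kept individual),
# pivoting on that individual. Errors if no such family exists (loop).
peeling_order <- function(ped, keep = NA_integer_) {
  fams <- nuclear_families(ped)
  n_mem <- nrow(ped$members)
  if (!length(fams)) return(list(steps = list(), fams = fams))
  remaining <- seq_along(fams)
  fam_members <- lapply(fams, function(f) c(f$father, f$mother, f$children))
  steps <- list()
  while (length(remaining)) {
    found <- FALSE
    for (fi in remaining) {
      others <- setdiff(remaining, fi)
      shared <- if (length(others))
        intersect(fam_members[[fi]], unique(unlist(fam_members[others])))
      else integer(0)
      if (!is.na(keep) && keep %in% fam_members[[fi]])
        shared <- union(shared, keep)
      if (length(shared) <= 1L) {
        steps[[length(steps) + 1L]] <-
          list(fam = fams[[fi]],
               pivot = if (length(shared)) shared else NA_integer_)
        remaining <- others
        found <- TRUE
        break
      }
    }
    if (!found)
      stop("no peelable nuclear family: pedigree contains a loop")
  }
  list(steps = steps, fams = fams)
}

#' @export
print.canpros_pedigree <- function(x, ...) {
  m <- x$members
  cat(sprintf("canpros pedigree '%s' (%d members, arm %s, proband %s)\n",
              x$famid, nrow(m), x$arm,
              if (is.na(x$proband_id)) "none" else x$proband_id))
  invisible(x)
}

PED_COLS <- c("famid", "id", "father_id", "mother_id", "sex", "birth_year",
              "censor_age", "prostate_dx_age", "breast_dx_age",
              "ovarian_dx_age", "detection", "proband", "arm",
              "brca2_test", "brca1_test", "hoxb13_test", "pgs")

#' Read pedigrees from a tab-delimited file
#'
#' The dialect is a columnar, tab-delimited text format with an explicit
#' header naming the columns of [pedigree()] plus `famid` and `arm`; `0` or
#' an empty field denotes a missing parent and `NA` a missing value. Unknown
#' ages are kept missing, never coerced to zero. One file may hold several
#' families, keyed by `famid`.
#'
#' @param path input file path.
#' @return A list of `canpros_pedigree` objects.
#' @export
read_pedigrees <- function(path) {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  d <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", "")),
    error = function(e) stop("malformed pedigree file: ", conditionMessage(e)))
  miss <- setdiff(c("famid", "id", "sex"), names(d))
  if (length(miss))
    stop("pedigree file missing required columns: ",
         paste(miss, collapse = ", "))
  nfields <- utils::count.fields(path, sep = "\t", quote = "")
  bad <- which(nfields != nfields[1])
  if (length(bad))
    stop("malformed pedigree row at line ", bad[1] + 0L,
         ": expected ", nfields[1], " fields, found ", nfields[bad[1]])
  lapply(split(d, d$famid)[unique(d$famid)], function(fd) {
    arm <- if (!is.null(fd$arm)) fd$arm[1] else "none"
    fd$arm <- NULL
    famid <- fd$famid[1]
    fd$famid <- NULL
    pedigree(fd, famid = famid, arm = arm)
  })
}

#' Write pedigrees to the tab-delimited dialect
#'
#' @param peds a `canpros_pedigree` or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pedigrees <- function(peds, path) {
  if (inherits(peds, "canpros_pedigree")) peds <- list(peds)
  rows <- lapply(peds, function(p) {
    m <- p$members
    m$famid <- p$famid
    m$arm <- p$arm
    m[PED_COLS]
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
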