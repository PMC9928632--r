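#' Population incidence tables
#'
#' An incidence table stores rates per person-year in strata of age band,
#' calendar period (or birth cohort), sex, and cancer site. Age bands are
#' half-open `[age_lo, age_hi)` and must partition `[0, max_age)` without
#' overlap within every (sex, site, period) stratum. In `"period"` mode the
#' rate for an individual of age `t` born in year `b` is looked up at calendar
#' year `b + t`; in `"cohort"` mode it is looked up at `b` directly.
#'
#' @param data data frame with columns `age_lo`, `age_hi`, `period_lo`,
#'   `period_hi`, `sex`, `site`, `rate`. Periods are half-open
#'   `[period_lo, period_hi)`; use `-Inf`/`Inf` for open-ended periods.
#' @param mode `"period"` or `"cohort"`.
#' @return An object of class `canpros_incidence`.
#' @export
incidence_table <- function(data, mode = c("period", "cohort")) {
  mode <- match.arg(mode)
  need <- c("age_lo", "age_hi", "period_lo", "period_hi", "sex", "site", "rate")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("incidence table missing columns: ", paste(miss, collapse = ", "))
  data <- as.data.frame(data)[need]
  for (nm in c("age_lo", "age_hi", "period_lo", "period_hi", "rate"))
    data[[nm]] <- as.numeric(data[[nm]])
  if (any(!is.finite(data$rate)) || any(data$rate < 0))
    stop("incidence rates must be finite and >= 0")
  if (any(data$age_hi <= data$age_lo))
    stop("age bands must have age_hi > age_lo")
  # overlap check within (sex, site, period) strata
  key <- interaction(data$sex, data$site, data$period_lo, data$period_hi,
                     drop = TRUE)
  for (k in levels(key)) {
    d <- data[key == k, ]
    d <- d[order(d$age_lo), ]
    if (nrow(d) > 1 && any(d$age_lo[-1] < d$age_hi[-nrow(d)]))
      stop("overlapping age bands in incidence stratum ", k)
  }
  structure(list(data = data, mode = mode,
                 cache = new.env(parent = emptyenv())),
            class = "canpros_incidence")
}

#' Read an incidence table from CSV
#'
#' @param path CSV file with the columns documented in [incidence_table()];
#'   an optional first comment line `# mode: cohort` selects cohort mode.
#' @return A `canpros_incidence` object.
#' @export
read_incidence <- function(path) {
  if (!file.exists(path)) stop("incidence file not found: ", path)
  first <- readLines(path, n = 1L)
  mode <- if (grepl("^#\\s*mode:\\s*cohort", first)) "cohort" else "period"
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  incidence_table(d, mode = mode)
}

#' Write an incidence table to CSV
#'
#' Inverse of [read_incidence()]; round trips are exact for numeric rates
#' written with full precision.
#'
#' @param inc a `canpros_incidence` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_incidence <- function(inc, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (inc$mode == "cohort") writeLines("# mode: cohort", con)
  utils::write.csv(format(inc$data, digits = 17, scientific = FALSE,
                          trim = TRUE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Look up incidence rates by age and birth year
#'
#' @param inc a `canpros_incidence` object.
#' @param ages integer ages (vectorized).
#' @param birth_year birth year of the individual.
#' @param sex `"M"` or `"F"`.
#' @param site cancer site, e.g. `"prostate"`.
#' @return Vector of rates per person-year; ages at or above the oldest band
#'   reuse the last band's rate.
#' @export
incidence_rate <- function(inc, ages, birth_year, sex = "M",
                           site = "prostate") {
  key <- paste(birth_year, sex, site, length(ages), ages[1], sep = "|")
  cached <- inc$cache[[key]]
  if (!is.null(cached)) return(cached)
  d <- inc$data[inc$data$sex == sex & inc$data$site == site, ]
  if (!nrow(d)) stop("no incidence rows for sex=", sex, " site=", site)
  yr <- if (inc$mode == "period") birth_year + ages
        else rep(birth_year, length(ages))
  out <- rep(NA_real_, length(ages))
  for (r in seq_len(nrow(d))) {
    hit <- is.na(out) & d$age_lo[r] <= ages & ages < d$age_hi[r] &
      d$period_lo[r] <= yr & yr < d$period_hi[r]
    out[hit] <- d$rate[r]
  }
  if (anyNA(out)) {
    # ages above the oldest band reuse the last band of the matching period
    for (i in which(is.na(out))) {
      inper <- d$period_lo <= yr[i] & yr[i] < d$period_hi
      if (!any(inper)) stop("no incidence stratum for age ", ages[i],
                            ", year ", yr[i])
      dd <- d[inper, ]
      out[i] <- dd$rate[which.max(dd$age_hi)]
    }
  }
  assign(key, out, envir = inc$cache)
  out
}

#' @export
print.canpros_incidence <- function(x, ...) {
  cat(sprintf("canpros incidence table (%s mode): %d strata, sites: %s\n",
              x$mode, nrow(x$data),
              paste(unique(x$data$site), collapse = ", ")))
  invisible(x)
}
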