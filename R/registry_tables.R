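# Age-banded registry count tables and their conversion to observable hazards.
#
# Conventions:
#  * bands are half-open [start, end) in continuous years of age; an event at
#    an exact boundary belongs to the upper band;
#  * the final band may be open-ended (end = Inf, written "" or "+" in CSV);
#  * counts are annual-scale: multi-year period extracts must be pre-averaged
#    to annual scale by the caller;
#  * the mid-year population N_i plays the role of person-years of exposure
#    per calendar year, so count / N is a per-person-year rate.

validate_bands <- function(age_start, age_end) {
  n <- length(age_start)
  if (n == 0L) stop("no age bands supplied")
  if (length(age_end) != n) stop("age_start and age_end differ in length")
  if (any(!is.finite(age_start)) || any(is.na(age_end)))
    stop("age band boundaries must be numeric (end may be Inf for the open band)")
  if (is.unsorted(age_start, strictly = TRUE))
    stop("age bands must be in strictly ascending order of age_start")
  if (age_start[1] != 0)
    stop("age bands must start at age 0 (first age_start is ", age_start[1], ")")
  if (any(age_end <= age_start))
    stop("each band must satisfy end > start")
  if (any(is.infinite(age_end[-n])))
    stop("only the final band may be open-ended")
  gaps <- which(abs(age_end[-n] - age_start[-1]) > 1e-9)
  if (length(gaps))
    stop("age bands are not contiguous: band ending at ", age_end[gaps[1]],
         " is followed by band starting at ", age_start[gaps[1] + 1])
  invisible(TRUE)
}

band_width <- function(age_start, age_end) {
  ifelse(is.infinite(age_end), NA_real_, age_end - age_start)
}

#' Construct an age-banded registry counts table
#'
#' Holds sex-specific annual counts per age band: mid-year population
#' \code{population} (N), all-cause deaths \code{deaths_all} (M), cancer
#' deaths \code{deaths_cancer} (D) and registered cancer cases \code{cases}
#' (R). Counts may be non-negative reals to support period data averaged to
#' annual scale. Bands must be contiguous, start at age 0 and only the final
#' band may be open-ended (\code{age_end = Inf}).
#'
#' Registries conventionally exclude non-melanoma skin cancer from all-cancer
#' incidence but include it in all-cancer mortality; when the site label of
#' the cases differs from the site label of the cancer deaths a warning is
#' emitted (no automatic correction is attempted).
#'
#' @param age_start,age_end band boundaries in years; \code{age_end = Inf}
#'   marks the open final band.
#' @param population mid-year population per band (persons; person-years of
#'   exposure per calendar year).
#' @param deaths_all,deaths_cancer,cases annual counts per band.
#' @param sex,site free-text labels carried through to estimates.
#' @param site_deaths site label of the cancer-death counts when it differs
#'   from \code{site} (triggers a warning).
#' @param registration_mode \code{"all-primaries"} if \code{cases} counts
#'   every primary registration, \code{"first-primaries-only"} if it counts
#'   only each person's first tumour.
#' @return an object of class \code{age_band_counts} (a data frame with one
#'   row per band plus \code{sex}, \code{site} and \code{registration_mode}
#'   attributes).
#' @seealso [read_counts_csv()], [hazards_from_counts()]
#' @export
age_band_counts <- function(age_start, age_end, population, deaths_all,
                            deaths_cancer, cases,
                            sex = NA_character_, site = NA_character_,
                            site_deaths = site,
                            registration_mode = c("all-primaries",
                                                  "first-primaries-only")) {
  registration_mode <- match.arg(registration_mode)
  o <- order(age_start)
  age_start <- age_start[o]; age_end <- age_end[o]
  population <- population[o]; deaths_all <- deaths_all[o]
  deaths_cancer <- deaths_cancer[o]; cases <- cases[o]
  validate_bands(age_start, age_end)

  counts <- cbind(population, deaths_all, deaths_cancer, cases)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("all counts and populations must be finite and non-negative")
  bad <- which(deaths_cancer > deaths_all + 1e-9)
  if (length(bad))
    stop("deaths_cancer exceeds deaths_all in band starting at age ",
         age_start[bad[1]], " (row ", bad[1], ")")
  zero_pop <- population == 0 &
    (deaths_all > 0 | deaths_cancer > 0 | cases > 0)
  if (any(zero_pop))
    stop("zero population with nonzero counts in band starting at age ",
         age_start[which(zero_pop)[1]])

  if (!is.na(site) && !is.na(site_deaths) && !identical(site, site_deaths))
    warning("site label of cases ('", site, "') differs from site label of ",
            "cancer deaths ('", site_deaths, "'); rates mix definitions ",
            "(e.g. NMSC excluded from incidence but not mortality). ",
            "No correction is applied.")

  out <- data.frame(age_start = age_start, age_end = age_end,
                    population = population, deaths_all = deaths_all,
                    deaths_cancer = deaths_cancer, cases = cases)
  structure(out,
            class = c("age_band_counts", "data.frame"),
            sex = sex, site = site, site_deaths = site_deaths,
            registration_mode = registration_mode)
}

#' @export
print.age_band_counts <- function(x, ...) {
  cat("Age-banded registry counts (", attr(x, "registration_mode"), ")\n",
      sep = "")
  if (!is.na(attr(x, "sex")) || !is.na(attr(x, "site")))
    cat("  sex: ", attr(x, "sex"), "   site: ", attr(x, "site"), "\n",
        sep = "")
  cat("  ", nrow(x), " bands, ",
      if (is.infinite(x$age_end[nrow(x)])) "final band open-ended"
      else paste0("capped at age ", x$age_end[nrow(x)]), "\n", sep = "")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Read an age-banded counts table from CSV
#'
#' Expects a UTF-8 CSV with header columns \code{age_start}, \code{age_end},
#' \code{population}, \code{deaths_all}, \code{deaths_cancer}, \code{cases}.
#' Rows may be in any order (they are sorted by \code{age_start}); an empty
#' or \code{"+"} \code{age_end} on the final row marks the open-ended band.
#'
#' @param path CSV file path.
#' @param rate_scale \code{"count"} if the count columns are raw annual
#'   counts, \code{"per100k"} if they are rates per 100 000 (divided by 1e5
#'   on ingest so that downstream code always sees per-person scales;
#'   \code{population} is left untouched).
#' @inheritParams age_band_counts
#' @return an [age_band_counts] table.
#' @export
read_counts_csv <- function(path, rate_scale = c("count", "per100k"),
                            sex = NA_character_, site = NA_character_,
                            site_deaths = site,
                            registration_mode = "all-primaries") {
  rate_scale <- match.arg(rate_scale)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("age_start", "age_end", "population", "deaths_all",
            "deaths_cancer", "cases")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("CSV ", path, " is missing column(s): ", paste(miss, collapse = ", "))
  age_end_chr <- trimws(raw$age_end)
  open <- age_end_chr %in% c("", "+", "Inf", "inf", "NA")
  age_end <- suppressWarnings(as.numeric(age_end_chr))
  age_end[open] <- Inf
  if (any(is.na(age_end)))
    stop("unparseable age_end value(s) in ", path)
  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    if (any(is.na(v))) stop("unparseable ", col, " value(s) in ", path)
    v
  }
  scl <- if (rate_scale == "per100k") 1e5 else 1
  age_band_counts(age_start = num("age_start"), age_end = age_end,
                  population = num("population"),
                  deaths_all = num("deaths_all") / scl,
                  deaths_cancer = num("deaths_cancer") / scl,
                  cases = num("cases") / scl,
                  sex = sex, site = site, site_deaths = site_deaths,
                  registration_mode = registration_mode)
}

#' Write an age-banded counts table to CSV
#'
#' Inverse of [read_counts_csv()]: the open final band is written with an
#' empty \code{age_end} field.
#'
#' @param counts an [age_band_counts] table.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_counts_csv <- function(counts, path) {
  stopifnot(inherits(counts, "age_band_counts"))
  out <- as.data.frame(counts)
  out$age_end <- ifelse(is.infinite(out$age_end), "",
                        format(out$age_end, trim = TRUE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a table of observable per-band hazards
#'
#' @param age_start,age_end band boundaries (final band may be open-ended).
#' @param lambda_C cancer registration hazard per person-year.
#' @param lambda_X non-cancer mortality hazard per person-year.
#' @param lambda_M all-cause mortality hazard per person-year; defaults to
#'   \code{lambda_X} (i.e. a model in which cancer is never the recorded
#'   cause of death). When counts are available use
#'   [hazards_from_counts()], which sets \code{lambda_M = M/N}.
#' @return an object of class \code{hazard_table}.
#' @export
hazard_table <- function(age_start, age_end, lambda_C, lambda_X,
                         lambda_M = lambda_X) {
  validate_bands(age_start, age_end)
  if (any(lambda_C < 0) || any(lambda_X < 0) || any(lambda_M < 0))
    stop("hazards must be non-negative")
  if (any(lambda_M < lambda_X - 1e-9))
    stop("lambda_M (all-cause) cannot be below lambda_X (non-cancer)")
  out <- data.frame(age_start = age_start, age_end = age_end,
                    lambda_C = lambda_C, lambda_X = lambda_X,
                    lambda_M = lambda_M)
  structure(out, class = c("hazard_table", "data.frame"))
}

#' @export
print.hazard_table <- function(x, ...) {
  cat("Per-band observable hazards (per person-year), ", nrow(x),
      " bands\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 5, ...)
  invisible(x)
}

#' Convert registry counts to observable hazards
#'
#' Per band: registration hazard \eqn{\lambda_C = R/N}, non-cancer mortality
#' \eqn{\lambda_X = (M - D)/N} and all-cause mortality \eqn{\lambda_M = M/N},
#' all per person-year. Bands with zero population and zero counts get zero
#' hazards with a warning; zero population with nonzero counts is rejected
#' at construction time.
#'
#' @param counts an [age_band_counts] table.
#' @return a [hazard_table] on the same bands.
#' @export
#' @examples
#' tab <- age_band_counts(0, Inf, population = 50000, deaths_all = 500,
#'                        deaths_cancer = 100, cases = 100)
#' hazards_from_counts(tab)  # lambda_C = 0.002, lambda_X = 0.008
hazards_from_counts <- function(counts) {
  stopifnot(inherits(counts, "age_band_counts"))
  N <- counts$population
  zero <- N == 0
  if (any(zero))
    warning("band(s) with zero population and zero counts: hazards set to 0")
  Nsafe <- ifelse(zero, 1, N)
  hazard_table(age_start = counts$age_start, age_end = counts$age_end,
               lambda_C = counts$cases / Nsafe,
               lambda_X = (counts$deaths_all - counts$deaths_cancer) / Nsafe,
               lambda_M = counts$deaths_all / Nsafe)
}

as_hazard_table <- function(x) {
  if (inherits(x, "hazard_table")) x
  else if (inherits(x, "age_band_counts")) suppressWarnings(hazards_from_counts(x))
  else stop("expected an age_band_counts or hazard_table object")
}

#' Collapse all bands above a cap age into one open-ended band
#'
#' Registry publications vary in where the open final band starts (85+ vs
#' 90+); this re-bands a counts table so the final band is \code{[cap, Inf)},
#' summing counts and populations of the collapsed bands.
#'
#' @param counts an [age_band_counts] table whose bands include a boundary at
#'   \code{cap}.
#' @param cap age in years at which the open band starts.
#' @return an [age_band_counts] table with final band \code{cap}+.
#' @export
collapse_open_band <- function(counts, cap) {
  stopifnot(inherits(counts, "age_band_counts"))
  if (!any(abs(counts$age_start - cap) < 1e-9))
    stop("cap ", cap, " is not a band boundary of the table")
  keep <- counts$age_start < cap - 1e-9
  up <- !keep
  if (!any(up)) stop("no bands at or above the cap age ", cap)
  age_band_counts(
    age_start = c(counts$age_start[keep], cap),
    age_end = c(counts$age_end[keep], Inf),
    population = c(counts$population[keep], sum(counts$population[up])),
    deaths_all = c(counts$deaths_all[keep], sum(counts$deaths_all[up])),
    deaths_cancer = c(counts$deaths_cancer[keep], sum(counts$deaths_cancer[up])),
    cases = c(counts$cases[keep], sum(counts$cases[up])),
    sex = attr(counts, "sex"), site = attr(counts, "site"),
    registration_mode = attr(counts, "registration_mode"))
}
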