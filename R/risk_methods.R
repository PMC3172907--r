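# Lifetime-risk estimators on age-banded registry data.
#
# All five methods consume per-band, per-person-year hazards and integrate
# them exactly under the piecewise-constant hazard assumption (closed-form
# within each band), so halving the bands of a piecewise-constant table
# leaves every estimate unchanged. A trapezoid variant of the within-band
# integral is available for sensitivity checks.
#
# Within the lifetime integral the three life-table style methods multiply
# the observed cancer rate by different survival-type curves:
#   cumulative risk      -- the probability of being cancer-free,
#   current probability  -- the probability of being alive,
#   AMP                  -- the probability of being alive AND cancer-free
# (the proxy survival S*). On routine all-primaries data the current
# probability method therefore estimates the mean number of primary tumours
# per lifetime (which can exceed 1), while AMP estimates the probability of
# ever being registered, always in [0, 1].

new_risk_estimate <- function(method, value, upper_age, sex = NA, site = NA) {
  structure(list(method = method, value = value, upper_age = upper_age,
                 sex = sex, site = site),
            class = "risk_estimate")
}

#' @export
print.risk_estimate <- function(x, ...) {
  up <- if (is.infinite(x$upper_age)) "lifetime" else paste0("to age ", x$upper_age)
  oix <- if (is.finite(x$value) && x$value > 0) one_in_x(x$value)$string else "-"
  cat(sprintf("%s (%s): %.4f  [%s, %s]\n", x$method, up, x$value,
              fmt_percent(x$value), oix))
  invisible(x)
}

# index of bands wholly below upper_age; errors if upper_age is not a
# boundary or an open band intrudes
bands_upto <- function(hz, upper_age) {
  bounds <- c(hz$age_start, hz$age_end[nrow(hz)])
  if (is.infinite(upper_age)) return(seq_len(nrow(hz))[is.finite(hz$age_end)])
  hit <- which(abs(bounds - upper_age) < 1e-9)
  if (!length(hit)) {
    lo <- max(bounds[is.finite(bounds) & bounds < upper_age])
    hi <- min(bounds[bounds > upper_age])
    stop("upper_age ", upper_age, " is not a band boundary; nearest ",
         "boundaries are ", lo, " and ", hi)
  }
  idx <- which(hz$age_end <= upper_age + 1e-9)
  if (any(is.infinite(hz$age_end[idx])))
    stop("open-ended band inside the truncation range")
  idx
}

#' Cumulative rate up to an age
#'
#' The sum over closed age bands of band width times the age-specific
#' registration rate, \eqn{\sum_i w_i \lambda_{C,i}}. A directly
#' standardised quantity, not a probability: it may exceed 1.
#'
#' @param hazards a [hazard_table] (or [age_band_counts], converted
#'   internally).
#' @param upper_age truncation age in years; must coincide with a band
#'   boundary, and all bands below it must be closed.
#' @return a \code{risk_estimate} with method \code{"cumulative_rate"}.
#' @export
cumulative_rate <- function(hazards, upper_age) {
  src <- hazards
  hz <- as_hazard_table(hazards)
  if (is.infinite(upper_age))
    stop("cumulative rate requires a finite upper age")
  idx <- bands_upto(hz, upper_age)
  w <- hz$age_end[idx] - hz$age_start[idx]
  new_risk_estimate("cumulative_rate", sum(w * hz$lambda_C[idx]), upper_age,
                    sex = attr(src, "sex"), site = attr(src, "site"))
}

#' Convert a cumulative rate to a cumulative risk
#'
#' \eqn{1 - \exp(-\mathrm{rate})}: the probability of at least one event
#' under independent single-event exposure with no competing risks. To a
#' very close approximation, a rate of "1 in x" corresponds to a risk of
#' "1 in (x + 1/2)".
#'
#' @param cum_rate non-negative cumulative rate (dimensionless), or a
#'   \code{risk_estimate} from [cumulative_rate()].
#' @return a bare probability for numeric input, or a \code{risk_estimate}
#'   with method \code{"cumulative_risk"} for estimate input.
#' @export
#' @examples
#' cumulative_risk(0.70)  # 0.5034, the 50.3% in published all-cancer tables
cumulative_risk <- function(cum_rate) {
  if (inherits(cum_rate, "risk_estimate")) {
    stopifnot(cum_rate$method == "cumulative_rate")
    return(new_risk_estimate("cumulative_risk", -expm1(-cum_rate$value),
                             cum_rate$upper_age, cum_rate$sex, cum_rate$site))
  }
  if (any(cum_rate < 0)) stop("cumulative rate must be non-negative")
  -expm1(-cum_rate)
}

#' Express a probability or rate as "1 in x"
#'
#' @param value positive probability or rate.
#' @param digits decimals for x in the formatted string (default 1).
#' @return list with \code{x} (the exact reciprocal) and \code{string}.
#' @export
#' @examples
#' one_in_x(0.5)$string  # "1 in 2.0"
one_in_x <- function(value, digits = 1) {
  if (inherits(value, "risk_estimate")) value <- value$value
  if (length(value) != 1 || !is.finite(value) || value <= 0)
    stop("value must be a single positive number")
  x <- 1 / value
  list(x = x,
       string = sprintf(paste0("1 in %.", digits, "f"),
                        round_half_away(x, digits)))
}

# shared engine: integrate lambda_C(u) * S(u) du where S decays at per-band
# rate `decay`; exact within bands (default) or trapezoid; optional open tail
integrate_rate_against_survival <- function(hz, decay, upper_age,
                                            rule = c("exact", "trapezoid"),
                                            tail_ratio = NULL) {
  rule <- match.arg(rule)
  n <- nrow(hz)
  open <- is.infinite(hz$age_end[n])
  lifetime <- is.infinite(upper_age)
  idx <- bands_upto(hz, if (lifetime) Inf else upper_age)
  # survival knots over closed bands
  w <- hz$age_end[idx] - hz$age_start[idx]
  Sk <- cumprod(c(1, exp(-decay[idx] * w)))
  lc <- hz$lambda_C[idx]
  d <- decay[idx]
  contrib <- ifelse(d > 0,
                    (lc / ifelse(d > 0, d, 1)) * (Sk[-length(Sk)] - Sk[-1]),
                    lc * w * Sk[-length(Sk)])
  if (rule == "trapezoid")
    contrib <- lc * w * (Sk[-length(Sk)] + Sk[-1]) / 2
  value <- sum(contrib)
  if (lifetime && open) {
    K <- n
    Stail <- Sk[length(Sk)]
    value <- value + tail_ratio(K) * Stail
  }
  value
}

#' 'Current probability' estimate of lifetime risk
#'
#' The classical life-table method: applies age-specific registration rates
#' to all-cause survival, \eqn{\int \lambda_C(u)\,S_{all}(u)\,du} with
#' \eqn{S_{all}} built from the all-cause hazard \eqn{\lambda_M = M/N}. On
#' routine all-primaries data this is the expected number of primary tumours
#' per lifetime, which can exceed 1 (a warning, not an error). The open
#' final band contributes the closed-form constant-hazard tail
#' \eqn{(\lambda_{C,K}/\lambda_{M,K})\,S_{all}(a_K)}.
#'
#' @param counts an [age_band_counts] table (or a [hazard_table] carrying
#'   \code{lambda_M}).
#' @param upper_age truncation age (a band boundary) or \code{Inf} for the
#'   full lifetime estimate; truncated estimates carry no tail term.
#' @param rule within-band integration rule; \code{"exact"} is exact under
#'   piecewise-constant hazards and invariant to band refinement,
#'   \code{"trapezoid"} is provided for sensitivity checks.
#' @return a \code{risk_estimate} with method \code{"current_probability"}.
#' @export
current_probability <- function(counts, upper_age = Inf,
                                rule = c("exact", "trapezoid")) {
  hz <- as_hazard_table(counts)
  n <- nrow(hz)
  if (is.infinite(upper_age) && is.infinite(hz$age_end[n]) &&
      hz$lambda_M[n] == 0 && hz$lambda_C[n] > 0)
    stop("non-integrable tail: open final band has zero all-cause mortality ",
         "but positive registration hazard")
  value <- integrate_rate_against_survival(
    hz, decay = hz$lambda_M, upper_age = upper_age, rule = rule,
    tail_ratio = function(K) {
      if (hz$lambda_M[K] == 0) 0 else hz$lambda_C[K] / hz$lambda_M[K]
    })
  if (value > 1)
    warning("current probability estimate exceeds 1: on all-primaries data ",
            "it is a mean count of primaries, not a probability")
  new_risk_estimate("current_probability", value, upper_age,
                    sex = attr(counts, "sex"), site = attr(counts, "site"))
}

#' AMP (adjusted for multiple primaries) estimate of lifetime risk
#'
#' Applies the observed registration rate to a proxy survival \eqn{S^*}
#' that discounts both non-cancer death and prior registration:
#' \eqn{S^*(a_{i+1}) = S^*(a_i)\exp\{-(\lambda_{C,i}+\lambda_{X,i})w_i\}},
#' with band contribution
#' \eqn{[\lambda_C/(\lambda_C+\lambda_X)]\,[S^*(a_i)-S^*(a_{i+1})]} and the
#' constant-hazard tail \eqn{[\lambda_C/(\lambda_C+\lambda_X)]\,S^*(a_K)} on
#' an open final band. The result is always in [0, 1] and corrects the
#' upward bias that multiple primaries induce in the current probability
#' method; a band in which both hazards are zero contributes 0.
#'
#' @inheritParams current_probability
#' @return a \code{risk_estimate} with method \code{"amp"}.
#' @export
amp_estimate <- function(counts, upper_age = Inf,
                         rule = c("exact", "trapezoid")) {
  hz <- as_hazard_table(counts)
  n <- nrow(hz)
  tot <- hz$lambda_C + hz$lambda_X
  if (is.infinite(upper_age) && is.infinite(hz$age_end[n]) &&
      tot[n] == 0 && hz$lambda_C[n] > 0)
    stop("non-integrable tail on the open final band")
  value <- integrate_rate_against_survival(
    hz, decay = tot, upper_age = upper_age, rule = rule,
    tail_ratio = function(K) if (tot[K] == 0) 0 else hz$lambda_C[K] / tot[K])
  new_risk_estimate("amp", value, upper_age,
                    sex = attr(counts, "sex"), site = attr(counts, "site"))
}

#' Proxy survival curve used by the AMP estimator
#'
#' \eqn{S^*(t)}: the probability-scale proxy for being simultaneously alive
#' and free of any prior cancer registration, evaluated at the band
#' boundaries.
#'
#' @param hazards a [hazard_table] or [age_band_counts].
#' @return a data frame of class \code{proxy_survival} with columns
#'   \code{age} (band boundaries) and \code{survival} (\eqn{S^*}), starting
#'   at \eqn{S^*(0) = 1}, non-increasing.
#' @export
amp_proxy_survival <- function(hazards) {
  hz <- as_hazard_table(hazards)
  closed <- is.finite(hz$age_end)
  w <- hz$age_end[closed] - hz$age_start[closed]
  tot <- (hz$lambda_C + hz$lambda_X)[closed]
  knots <- c(hz$age_start[closed][1], hz$age_end[closed])
  structure(data.frame(age = knots, survival = cumprod(c(1, exp(-tot * w)))),
            class = c("proxy_survival", "data.frame"))
}

#' Gold-standard lifetime risk from first-primaries data
#'
#' The current probability algorithm run on incidence restricted to each
#' person's first primary tumour: the benchmark against which AMP and the
#' routine current probability estimate are judged. Refuses all-primaries
#' tables to prevent silent misuse.
#'
#' @param first_primaries_counts an [age_band_counts] table with
#'   \code{registration_mode = "first-primaries-only"}.
#' @inheritParams current_probability
#' @return a \code{risk_estimate} with method \code{"gold_standard"}.
#' @export
gold_standard <- function(first_primaries_counts, upper_age = Inf,
                          rule = c("exact", "trapezoid")) {
  if (!inherits(first_primaries_counts, "age_band_counts") ||
      !identical(attr(first_primaries_counts, "registration_mode"),
                 "first-primaries-only"))
    stop("gold_standard requires an age_band_counts table with ",
         "registration_mode = 'first-primaries-only'")
  est <- current_probability(first_primaries_counts, upper_age, rule)
  if (est$value > 1)
    warning("gold standard estimate exceeds 1; check the input table")
  est$method <- "gold_standard"
  est
}

#' Compare all estimators over a grid of upper ages
#'
#' Reproduces the standard published layout: one row per method and
#' truncation age, on all-primaries counts (cumulative rate/risk, current
#' probability, AMP) plus, when available, the first-primaries gold
#' standard.
#'
#' @param counts_all all-primaries [age_band_counts] table.
#' @param counts_first optional first-primaries table on identical bands.
#' @param ages upper ages (band boundaries); use \code{Inf} for lifetime.
#'   Cumulative rate/risk are reported only at finite ages.
#' @param percent_digits decimals for the percent strings.
#' @return data frame with columns \code{method}, \code{sex}, \code{site},
#'   \code{upper_age}, \code{value}, \code{percent}, \code{one_in_x}.
#' @export
method_comparison <- function(counts_all, counts_first = NULL,
                              ages = c(65, 75, 85, Inf),
                              percent_digits = 1) {
  stopifnot(inherits(counts_all, "age_band_counts"))
  if (!is.null(counts_first)) {
    if (!isTRUE(all.equal(counts_first$age_start, counts_all$age_start)) ||
        !isTRUE(all.equal(counts_first$age_end, counts_all$age_end)))
      stop("counts_first and counts_all must share identical age bands")
  }
  rows <- list()
  add <- function(est) rows[[length(rows) + 1L]] <<- est
  for (a in ages) {
    if (is.finite(a)) {
      cr <- cumulative_rate(counts_all, a)
      add(cr)
      add(cumulative_risk(cr))
    }
    add(suppressWarnings(current_probability(counts_all, a)))
    add(amp_estimate(counts_all, a))
    if (!is.null(counts_first))
      add(suppressWarnings(gold_standard(counts_first, a)))
  }
  out <- do.call(rbind, lapply(rows, function(e) {
    data.frame(method = e$method,
               sex = attr(counts_all, "sex") %||% NA_character_,
               site = attr(counts_all, "site") %||% NA_character_,
               upper_age = e$upper_age, value = e$value,
               percent = fmt_percent(e$value, percent_digits),
               one_in_x = if (e$value > 0) one_in_x(e$value)$string
                          else NA_character_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
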