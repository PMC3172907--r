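#' @keywords internal
"_PACKAGE"

# ---- small numerical helpers shared across modules ----

# integral of exp(-r*s) over [0, w]; stable for r -> 0 and exact at r == 0
intexp <- function(r, w) {
  ifelse(r == 0, w, -expm1(-r * w) / r)
}

# phi(a, b, w) = (exp(-a*w) - exp(-b*w)) / (b - a), the two-exponential
# kernel of the illness-death occupancy; continuous limit w*exp(-a*w) at a == b.
# Switches to the limit form when |a - b| is small relative to max(a, b) to
# avoid catastrophic cancellation.
phi2exp <- function(a, b, w) {
  eps <- 1e-9 * pmax(a, b, 1)
  near <- abs(a - b) <= eps
  out <- numeric(length(w) * 0 + max(length(a), length(b), length(w)))
  a <- rep_len(a, length(out)); b <- rep_len(b, length(out))
  w <- rep_len(w, length(out)); near <- rep_len(near, length(out))
  m <- (a + b) / 2
  out[near] <- w[near] * exp(-m[near] * w[near])
  i <- !near
  out[i] <- (exp(-a[i] * w[i]) - exp(-b[i] * w[i])) / (b[i] - a[i])
  out
}

# J(a, b, w) = integral over [0, w] of phi2exp(a, b, s) ds
jint2exp <- function(a, b, w) {
  n <- max(length(a), length(b), length(w))
  a <- rep_len(a, n); b <- rep_len(b, n); w <- rep_len(w, n)
  eps <- 1e-9 * pmax(a, b, 1)
  near <- abs(a - b) <= eps
  out <- numeric(n)
  m <- (a + b) / 2
  # equal-rate limit: integral of s*exp(-m*s)
  lim <- ifelse(m == 0, w^2 / 2,
                (1 - (1 + m * w) * exp(-m * w)) / m^2)
  out[near] <- lim[near]
  i <- !near
  out[i] <- (intexp(a[i], w[i]) - intexp(b[i], w[i])) / (b[i] - a[i])
  out
}

# round half away from zero (reported percentages; R's round() is banker's)
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Format a probability as a percent string
#'
#' Multiplies by 100 and rounds half away from zero to the requested number
#' of decimals, matching the granularity of published registry tables.
#'
#' @param p probability (or rate) on the 0-1 scale.
#' @param digits decimal places in the percent string (default 1).
#' @return character vector like \code{"39.2\%"}.
#' @export
#' @examples
#' fmt_percent(0.3923)
fmt_percent <- function(p, digits = 1) {
  sprintf(paste0("%.", digits, "f%%"), round_half_away(100 * p, digits))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
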