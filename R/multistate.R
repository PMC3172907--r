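# Ground-truth mathematics of the four-state illness-death model:
#
#   [0] alive, never had cancer   --l0C-->  [C] alive with/after cancer
#   [0] --l0X--> [X] dead, other cause     [C] --lCX--> [X]
#                                          [C] --lCD--> [D] dead of cancer
#   [C] --lCC--> [C]  (a further primary: a counted event, not a state change)
#
# One cannot die of cancer without having had cancer (the 0 -> D hazard is
# zero by construction). All hazards are piecewise constant on an age-band
# grid whose final band is open-ended. Occupancies are propagated by the
# closed-form solution of the forward equations within each band (the
# generator is triangular), so results carry no ODE-solver tolerance.

#' Construct a piecewise-constant four-state hazard model
#'
#' @param age_start,age_end band boundaries in years; the final band must be
#'   open-ended (\code{age_end = Inf}).
#' @param h_0C cancer incidence among the never-cancer (per person-year).
#' @param h_0X non-cancer death among the never-cancer.
#' @param h_CC new-primary incidence among those with prior cancer.
#' @param h_CD cancer death among those with prior cancer.
#' @param h_CX non-cancer death among those with prior cancer.
#' @return an object of class \code{multistate_hazards}.
#' @export
multistate_hazards <- function(age_start, age_end, h_0C, h_0X,
                               h_CC = h_0C, h_CD = 0, h_CX = h_0X) {
  validate_bands(age_start, age_end)
  n <- length(age_start)
  if (!is.infinite(age_end[n]))
    stop("the final band of a multistate model must be open-ended")
  df <- data.frame(age_start = age_start, age_end = age_end,
                   h_0C = rep_len(h_0C, n), h_0X = rep_len(h_0X, n),
                   h_CC = rep_len(h_CC, n), h_CD = rep_len(h_CD, n),
                   h_CX = rep_len(h_CX, n))
  if (any(as.matrix(df[, 3:7]) < 0)) stop("hazards must be non-negative")
  structure(df, class = c("multistate_hazards", "data.frame"))
}

#' @export
print.multistate_hazards <- function(x, ...) {
  cat("Four-state illness-death model, piecewise-constant hazards, ",
      nrow(x), " bands\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 4, ...)
  invisible(x)
}

#' Read a multistate hazard model from CSV
#'
#' Columns: \code{age_start}, \code{age_end} (empty or \code{"+"} for the
#' open final band), \code{h_0C}, \code{h_0X}, \code{h_CC}, \code{h_CD},
#' \code{h_CX}.
#'
#' @param path CSV file path.
#' @return a [multistate_hazards] model.
#' @export
read_model_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("age_start", "age_end", "h_0C", "h_0X", "h_CC", "h_CD", "h_CX")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("model CSV missing column(s): ", paste(miss, collapse = ", "))
  ae <- trimws(raw$age_end)
  age_end <- suppressWarnings(as.numeric(ae))
  age_end[ae %in% c("", "+", "Inf", "inf")] <- Inf
  num <- function(col) as.numeric(raw[[col]])
  multistate_hazards(num("age_start"), age_end, num("h_0C"), num("h_0X"),
                     num("h_CC"), num("h_CD"), num("h_CX"))
}

# ---- closed-form per-band propagation -------------------------------------
# Within one band (constants; alpha = l0C + l0X leaves state 0,
# beta = lCD + lCX leaves state C):
#   S0(s)  = S0 * exp(-alpha s)
#   P(s)   = P * exp(-beta s) + l0C * S0 * phi2exp(alpha, beta, s)
# Integrals over [0, w]:
#   IS0 = S0 * intexp(alpha, w)
#   IP  = P * intexp(beta, w) + l0C * S0 * jint2exp(alpha, beta, w)
# Dead-state increments: dpD = lCD * IP; dpX = l0X * IS0 + lCX * IP.
propagate_band <- function(occ, h, w) {
  alpha <- h$h_0C + h$h_0X
  beta  <- h$h_CD + h$h_CX
  IS0 <- occ["S0"] * intexp(alpha, w)
  IP  <- occ["P"] * intexp(beta, w) +
    h$h_0C * occ["S0"] * jint2exp(alpha, beta, w)
  c(S0 = unname(occ["S0"] * exp(-alpha * w)),
    P  = unname(occ["P"] * exp(-beta * w) +
                  h$h_0C * occ["S0"] * phi2exp(alpha, beta, w)),
    pD = unname(occ["pD"] + h$h_CD * IP),
    pX = unname(occ["pX"] + h$h_0X * IS0 + h$h_CX * IP),
    IS0 = unname(IS0), IP = unname(IP))
}

# occupancy vector at each model band start (and integrals over each band
# when through = TRUE up to band index k)
occupancy_knots <- function(model) {
  n <- nrow(model)
  knots <- matrix(NA_real_, n, 4,
                  dimnames = list(NULL, c("S0", "P", "pD", "pX")))
  occ <- c(S0 = 1, P = 0, pD = 0, pX = 0)
  for (i in seq_len(n)) {
    knots[i, ] <- occ
    if (is.finite(model$age_end[i])) {
      st <- propagate_band(occ, model[i, ], model$age_end[i] - model$age_start[i])
      occ <- st[c("S0", "P", "pD", "pX")]
    }
  }
  knots
}

#' State-occupancy probabilities of the four-state model
#'
#' Forward solution of the model's Kolmogorov equations at the requested
#' ages, by exact closed-form propagation across the piecewise-constant
#' bands (and within the band containing each requested age). Occupancies
#' sum to 1 at every age.
#'
#' @param model a [multistate_hazards] model.
#' @param ages ages (years) at which to evaluate; defaults to an equally
#'   spaced grid from 0 to the start of the open band.
#' @param step grid spacing used for the default \code{ages}; the
#'   propagation itself is exact, so \code{step} only controls output
#'   resolution.
#' @return data frame of class \code{state_occupancy}: \code{age},
#'   \code{S0} (alive, never cancer), \code{P} (alive with/after cancer),
#'   \code{pD} (dead of cancer), \code{pX} (dead of other causes).
#' @export
occupancy <- function(model, ages = NULL, step = 1 / 256) {
  stopifnot(inherits(model, "multistate_hazards"))
  if (step <= 0) stop("step must be positive")
  cap <- model$age_start[nrow(model)]
  if (is.null(ages)) ages <- seq(0, cap, by = step)
  if (any(ages < 0)) stop("ages must be non-negative")
  knots <- occupancy_knots(model)
  band <- findInterval(ages, model$age_start)
  out <- matrix(NA_real_, length(ages), 4,
                dimnames = list(NULL, c("S0", "P", "pD", "pX")))
  for (j in seq_along(ages)) {
    i <- band[j]
    st <- propagate_band(knots[i, ], model[i, ], ages[j] - model$age_start[i])
    out[j, ] <- st[c("S0", "P", "pD", "pX")]
  }
  structure(data.frame(age = ages, out),
            class = c("state_occupancy", "data.frame"))
}

#' True lifetime risk of a first cancer
#'
#' \eqn{\int_0^\infty \lambda_{0C}(u) S_0(u)\,du}: the probability of ever
#' entering the cancer state, computed exactly band-by-band on
#' \eqn{S_0 = \exp\{-\int(\lambda_{0C}+\lambda_{0X})\}} with the
#' constant-hazard tail on the open band.
#'
#' @param model a [multistate_hazards] model.
#' @return probability in [0, 1].
#' @export
true_lifetime_risk <- function(model) {
  stopifnot(inherits(model, "multistate_hazards"))
  knots <- occupancy_knots(model)
  n <- nrow(model)
  alpha <- model$h_0C + model$h_0X
  value <- 0
  for (i in seq_len(n - 1)) {
    if (alpha[i] > 0)
      value <- value + (model$h_0C[i] / alpha[i]) * (knots[i, "S0"] - knots[i + 1, "S0"])
  }
  if (knots[n, "S0"] > 0) {
    if (alpha[n] == 0)
      stop("non-integrable tail: open band has zero total hazard out of ",
           "state 0 while survivors remain")
    value <- value + (model$h_0C[n] / alpha[n]) * knots[n, "S0"]
  }
  unname(value)
}

#' Expected number of primary registrations per lifetime
#'
#' \eqn{\int_0^\infty [\lambda_{0C} S_0(u) + \lambda_{CC} P(u)]\,du}: the
#' mean lifetime count of registered primaries, which exceeds the lifetime
#' risk whenever repeat primaries occur (\eqn{\lambda_{CC} > 0}) and can
#' exceed 1.
#'
#' @param model a [multistate_hazards] model.
#' @return mean count (dimensionless).
#' @export
expected_primaries <- function(model) {
  stopifnot(inherits(model, "multistate_hazards"))
  n <- nrow(model)
  occ <- c(S0 = 1, P = 0, pD = 0, pX = 0)
  value <- 0
  for (i in seq_len(n - 1)) {
    w <- model$age_end[i] - model$age_start[i]
    st <- propagate_band(occ, model[i, ], w)
    value <- value + model$h_0C[i] * st["IS0"] + model$h_CC[i] * st["IP"]
    occ <- st[c("S0", "P", "pD", "pX")]
  }
  alpha <- model$h_0C[n] + model$h_0X[n]
  beta <- model$h_CD[n] + model$h_CX[n]
  # tail integrals: IS0 = S0/alpha; IP = P/beta + l0C*S0/(alpha*beta)
  if (occ["S0"] > 0 || occ["P"] > 0) {
    if (occ["S0"] > 0 && alpha == 0)
      stop("non-integrable tail out of state 0 on the open band")
    tail_IS0 <- if (alpha > 0) occ["S0"] / alpha else 0
    inflow <- model$h_0C[n] * tail_IS0
    if (beta > 0) {
      tail_IP <- occ["P"] / beta + inflow / beta
    } else if (model$h_CC[n] > 0 && (occ["P"] > 0 || inflow > 0)) {
      stop("non-integrable tail: repeat-primary hazard with immortal ",
           "post-cancer population on the open band")
    } else tail_IP <- 0
    value <- value + model$h_0C[n] * tail_IS0 + model$h_CC[n] * tail_IP
  }
  unname(value)
}

#' Population-observable rates implied by a multistate model
#'
#' The registration and mortality rates a registry would observe in the
#' living population: occupancy-weighted mixtures of the state-specific
#' hazards,
#' \eqn{\lambda_C = (\lambda_{0C}S_0 + \lambda_{CC}P)/(S_0+P)} and
#' \eqn{\lambda_X = (\lambda_{0X}S_0 + \lambda_{CX}P)/(S_0+P)},
#' band-averaged by occupancy-weighted integration over each requested band
#' (registry rates are event counts over person-years, not midpoint
#' evaluations). \eqn{\lambda_M} adds the cancer-death component
#' \eqn{\lambda_{CD}P/(S_0+P)}.
#'
#' @param model a [multistate_hazards] model.
#' @param bands data frame with \code{age_start}, \code{age_end} giving the
#'   output bands (boundaries need not coincide with the model grid; the
#'   final output band may be open-ended). Defaults to the model's own grid.
#' @return a [hazard_table] on the requested bands. Bands in which everyone
#'   is dead get zero hazards with a warning.
#' @export
observable_rates <- function(model, bands = NULL) {
  stopifnot(inherits(model, "multistate_hazards"))
  if (is.null(bands))
    bands <- data.frame(age_start = model$age_start, age_end = model$age_end)
  validate_bands(bands$age_start, bands$age_end)
  nb <- nrow(bands)
  knots <- occupancy_knots(model)
  cap <- model$age_start[nrow(model)]

  # occupancy-weighted integrals of S0, P and the event numerators over an
  # arbitrary interval [a, b) (b may be Inf), split at model boundaries
  integrate_piece <- function(a, b) {
    acc <- c(IS0 = 0, IP = 0, nC = 0, nX = 0, nD = 0)
    lo <- a
    while (lo < b - 1e-12 || (is.infinite(b) && lo <= cap)) {
      i <- findInterval(lo, model$age_start)
      hi <- min(b, model$age_end[i])
      h <- model[i, ]
      occ0 <- propagate_band(knots[i, ], h, lo - model$age_start[i])
      if (is.infinite(hi)) {
        alpha <- h$h_0C + h$h_0X; beta <- h$h_CD + h$h_CX
        S0 <- occ0["S0"]; P <- occ0["P"]
        if (S0 > 0 && alpha == 0)
          stop("non-integrable open tail: immortal never-cancer population")
        IS0 <- if (alpha > 0) S0 / alpha else 0
        inflow <- h$h_0C * IS0
        if ((P > 0 || inflow > 0) && beta == 0)
          stop("non-integrable open tail: immortal post-cancer population")
        IP <- if (beta > 0) P / beta + inflow / beta else 0
      } else {
        st <- propagate_band(occ0[c("S0", "P", "pD", "pX")], h, hi - lo)
        IS0 <- st["IS0"]; IP <- st["IP"]
      }
      acc <- acc + c(IS0, IP,
                     h$h_0C * IS0 + h$h_CC * IP,
                     h$h_0X * IS0 + h$h_CX * IP,
                     h$h_CD * IP)
      if (is.infinite(hi)) break
      lo <- hi
    }
    acc
  }

  lc <- lx <- lm <- numeric(nb)
  dead <- logical(nb)
  for (k in seq_len(nb)) {
    acc <- integrate_piece(bands$age_start[k], bands$age_end[k])
    denom <- acc["IS0"] + acc["IP"]
    if (denom <= 0) {
      dead[k] <- TRUE
      lc[k] <- lx[k] <- lm[k] <- 0
    } else {
      lc[k] <- acc["nC"] / denom
      lx[k] <- acc["nX"] / denom
      lm[k] <- (acc["nX"] + acc["nD"]) / denom
    }
  }
  if (any(dead))
    warning("band(s) with zero surviving population: hazards reported as 0")
  hazard_table(bands$age_start, bands$age_end, lc, lx, lm)
}

#' Fine-grid numerical oracle for the lifetime-risk integral
#'
#' Independently evaluates
#' \eqn{\int \lambda_C(u)\exp\{-\int_0^u(\lambda_C+\lambda_X)\}\,du} by
#' marching a fine grid (each band subdivided into cells of at most
#' \code{step} years, cells aligned to band boundaries) and accumulating the
#' exact constant-hazard contribution of each cell. Used as the independent
#' check of [amp_estimate()]'s band-telescoping formula.
#'
#' @param hazards a [hazard_table] or [age_band_counts].
#' @param step maximum cell width in years (default 1/1024).
#' @param upper_age truncation age or \code{Inf}; with \code{Inf} an open
#'   final band contributes its constant-hazard tail.
#' @return probability.
#' @export
fine_grid_oracle <- function(hazards, step = 1 / 1024, upper_age = Inf) {
  if (step <= 0) stop("step must be positive")
  hz <- as_hazard_table(hazards)
  n <- nrow(hz)
  idx <- bands_upto(hz, upper_age)
  S <- 1
  acc <- 0
  for (i in idx) {
    w <- hz$age_end[i] - hz$age_start[i]
    m <- max(1L, ceiling(w / step))
    h <- w / m
    lc <- hz$lambda_C[i]
    lam <- lc + hz$lambda_X[i]
    cell <- intexp(lam, h)
    decay <- exp(-lam * h)
    for (k in seq_len(m)) {
      acc <- acc + lc * S * cell
      S <- S * decay
    }
  }
  if (is.infinite(upper_age) && is.infinite(hz$age_end[n])) {
    lam <- hz$lambda_C[n] + hz$lambda_X[n]
    if (lam > 0) acc <- acc + (hz$lambda_C[n] / lam) * S
    else if (hz$lambda_C[n] > 0)
      stop("non-integrable tail on the open final band")
  }
  acc
}
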