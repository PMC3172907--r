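# Shared generators for test fixtures: everything is built in code.

# a constants-everywhere multistate model on a single open band
const_model <- function(c0 = 0.02, x0 = 0.01, cc = c0, cd = 0, cx = x0) {
  multistate_hazards(0, Inf, h_0C = c0, h_0X = x0, h_CC = cc, h_CD = cd,
                     h_CX = cx)
}

# a plausible 18-band registry table (0-4, 5-9, ..., 85+) from smooth rates
demo_counts <- function(seed = 1, registration_mode = "all-primaries") {
  set.seed(seed)
  starts <- seq(0, 85, by = 5)
  ends <- c(seq(5, 85, by = 5), Inf)
  mid <- ifelse(is.finite(ends), (starts + ends) / 2, 90)
  N <- round(3e5 * exp(-0.02 * mid)) + 1000
  lc <- 1e-4 * exp(0.06 * mid) * exp(stats::rnorm(18, 0, 0.05))
  lx <- 4e-4 * exp(0.075 * mid) * exp(stats::rnorm(18, 0, 0.05))
  ld <- 0.45 * lc
  age_band_counts(starts, ends, population = N,
                  deaths_all = (lx + ld) * N, deaths_cancer = ld * N,
                  cases = lc * N, sex = "persons", site = "all",
                  registration_mode = registration_mode)
}

# random banded hazard table with registry-like structure:
# cancer-death hazard a sub-unit fraction of the registration hazard
random_hazard_table <- function(seed) {
  set.seed(seed)
  wband <- sample(c(1, 5), 1)
  starts <- seq(0, 85, by = wband)
  ends <- c(starts[-1], Inf)
  n <- length(starts)
  lc <- stats::rlnorm(n, log(2e-3), 0.8)
  lx <- stats::rlnorm(n, log(4e-3), 0.8)
  ld <- stats::runif(n, 0, 1) * lc
  hazard_table(starts, ends, lambda_C = lc, lambda_X = lx,
               lambda_M = lx + ld)
}

# hand-written three-person cohort used for pencil-and-paper aggregation
tiny_histories <- function() {
  ev <- data.frame(
    id = c(1L, 1L, 1L, 2L, 3L, 3L),
    age = c(5, 12, 15, 25, 22, 30),
    kind = c("diagnosis", "diagnosis", "death_cancer", "death_other",
             "diagnosis", "death_other"),
    stringsAsFactors = FALSE)
  structure(ev[order(ev$id, ev$age), ],
            class = c("cohort_histories", "data.frame"),
            n = 3L, seed = 0L, max_age = 120)
}
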