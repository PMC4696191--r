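#' Autoaggregation percentage from settling optical densities
#'
#' In the settling assay a culture is left to settle for 24 h, the upper
#' phase's OD600 is read (A2), the culture is vigorously mixed and read again
#' (A1). Aggregating cells settle out of the upper phase, so the percentage
#' is 100 * (1 - A2/A1). Values can be slightly negative when A2 > A1
#' (measurement noise); they are returned as computed.
#'
#' @param a1 OD600 after mixing (> 0).
#' @param a2 OD600 of the settled upper phase (>= 0).
#' @return autoaggregation percentage.
#' @examples
#' autoaggregation_pct(1.0, 0.6331)  # 36.69
#' @export
autoaggregation_pct <- function(a1, a2) {
  if (!is.numeric(a1) || a1 <= 0) abort("A1 must be positive")
  if (!is.numeric(a2) || a2 < 0) abort("A2 must be nonnegative")
  100 * (1 - a2 / a1)
}

#' Generation (doubling) time from a CFU growth curve
#'
#' Least-squares fit of log2(CFU/ml) against time; the doubling time is the
#' reciprocal of the slope. CFU densities come from plate counts (colonies x
#' dilution factor x 10 for a 100-ul aliquot).
#'
#' @param times_h sampling times in hours, strictly increasing.
#' @param cfu_per_ml positive CFU densities.
#' @param window optional numeric length-2 range of times to fit (inclusive);
#'   default all points.
#' @param auto_window if \code{TRUE}, instead fit the contiguous run of >= 4
#'   points maximizing r-squared (exponential-phase selection).
#' @return list with \code{doubling_time_h}, \code{r2}, \code{slope} (in
#'   doublings per hour) and \code{n_points}.
#' @export
generation_time_h <- function(times_h, cfu_per_ml, window = NULL,
                              auto_window = FALSE) {
  if (length(times_h) != length(cfu_per_ml))
    abort("times and CFU vectors differ in length")
  if (any(diff(times_h) <= 0)) abort("times must be strictly increasing")
  if (any(cfu_per_ml <= 0)) abort("all CFU densities must be positive")
  if (!is.null(window)) {
    keep <- times_h >= window[1] & times_h <= window[2]
    times_h <- times_h[keep]; cfu_per_ml <- cfu_per_ml[keep]
  }
  if (length(times_h) < 3) abort("need >= 3 points for the fit")

  fit_range <- function(i, j) {
    t <- times_h[i:j]; y <- log2(cfu_per_ml[i:j])
    f <- stats::lm(y ~ t)
    # summary.lm warns on noiseless data ("essentially perfect fit"); an
    # exact exponential is a legitimate input here
    r2 <- suppressWarnings(summary(f)$r.squared)
    if (!is.finite(r2)) r2 <- 0   # constant response (e.g. saturated phase)
    list(slope = unname(stats::coef(f)[2]), r2 = r2, i = i, j = j)
  }

  if (auto_window && length(times_h) >= 4) {
    best <- NULL
    n <- length(times_h)
    for (i in 1:(n - 3)) for (j in (i + 3):n) {
      f <- fit_range(i, j)
      if (is.null(best) || f$r2 > best$r2) best <- f
    }
  } else {
    best <- fit_range(1L, length(times_h))
  }
  if (!is.finite(best$slope) || best$slope <= 0)
    abort("no exponential growth detected (nonpositive slope)")
  list(doubling_time_h = 1 / best$slope, r2 = best$r2,
       slope = best$slope, n_points = best$j - best$i + 1L)
}

#' Simulate an exponential CFU growth curve
#'
#' CFU(t) = n0 * 2^(t / doubling_time_h) with multiplicative lognormal noise
#' of the given coefficient of variation, sampled every \code{step_h} hours
#' over \code{duration_h} (defaults mirror a 9-h course sampled every 30 min).
#'
#' @param n0 initial CFU/ml.
#' @param doubling_time_h true doubling time.
#' @param duration_h,step_h sampling schedule.
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param seed RNG seed.
#' @return list with \code{times_h} and \code{cfu_per_ml}.
#' @export
simulate_growth_curve <- function(n0 = 1e7, doubling_time_h = 4.5,
                                  duration_h = 9, step_h = 0.5,
                                  noise_cv = 0.05, seed = 1) {
  if (n0 <= 0 || doubling_time_h <= 0 || duration_h <= 0 || step_h <= 0 ||
      noise_cv < 0)
    abort("all parameters must be positive (noise_cv nonnegative)")
  times <- seq(0, duration_h, by = step_h)
  mu <- n0 * 2^(times / doubling_time_h)
  if (noise_cv > 0) {
    set.seed(seed)
    sdlog <- sqrt(log(1 + noise_cv^2))
    noise <- stats::rlnorm(length(times), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    mu <- mu * noise
  }
  list(times_h = times, cfu_per_ml = mu)
}

#' Simulate one settling-assay measurement
#'
#' A2 = a1 * (1 - true_fraction) + Gaussian noise, truncated at 0.
#'
#' @param true_fraction aggregating fraction in [0, 1].
#' @param a1 mixed-culture OD600.
#' @param noise_sd SD of the additive noise on A2.
#' @param seed RNG seed.
#' @return list with \code{A1} and \code{A2}.
#' @export
simulate_aggregation <- function(true_fraction, a1 = 1.0, noise_sd = 0,
                                 seed = 1) {
  if (true_fraction < 0 || true_fraction > 1)
    abort("true_fraction must be in [0, 1]")
  if (a1 <= 0) abort("a1 must be positive")
  a2 <- a1 * (1 - true_fraction)
  if (noise_sd > 0) {
    set.seed(seed)
    a2 <- max(0, a2 + stats::rnorm(1, 0, noise_sd))
  }
  list(A1 = a1, A2 = a2)
}
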