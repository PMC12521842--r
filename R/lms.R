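# Adaptive least-mean-squares (LMS) noise cancellation. The filter learns,
# sample by sample, the FIR mapping from a noise-correlated reference to the
# noise component of the primary input; the running prediction error is the
# cleaned signal.

#' LMS filter configuration
#'
#' @param n_taps Filter order (number of FIR coefficients).
#' @param mu Step size; must sit below the stability bound
#'   [lms_mu_bound()] for convergence. `NULL` picks `0.5 * mu_max` at run
#'   time from the reference power.
#' @param max_iter Cap on adaptation steps (defaults to the signal length).
#' @return A list of class `lms_config`.
#' @export
lms_config <- function(n_taps = 8L, mu = NULL, max_iter = NULL) {
  stopifnot(is_count(n_taps), is.null(mu) || mu >= 0)
  structure(list(n_taps = as.integer(n_taps), mu = mu, max_iter = max_iter),
            class = "lms_config")
}

#' LMS step-size stability bound
#'
#' The largest stable step size for an `n_taps`-coefficient LMS filter driven
#' by a reference of mean power `input_power`:
#' `mu_max = 2 / (3 * n_taps * input_power)`, the classical
#' misadjustment-based bound (keeping roughly one third of the gradient-noise
#' budget).
#'
#' @param n_taps Filter order.
#' @param input_power Mean squared value of the reference signal (> 0).
#' @return The bound `mu_max`.
#' @export
#' @examples
#' lms_mu_bound(4, 1)  # 1/6
lms_mu_bound <- function(n_taps, input_power) {
  stopifnot(is_count(n_taps))
  if (!is.numeric(input_power) || input_power <= 0)
    stop_pcg("`input_power` must be positive", "bad_power")
  2 / (3 * n_taps * input_power)
}

#' Adaptive LMS noise cancellation
#'
#' Runs the per-sample LMS update `w <- w + mu * e[n] * u[n]` where `u[n]` is
#' the recent reference window and `e[n] = primary[n] - w . u[n]` is the
#' prediction error. The error sequence is the cleaned estimate (primary
#' minus the filtered reference).
#'
#' @param primary Noisy observation (signal + noise).
#' @param reference Noise-correlated reference, same length.
#' @param cfg An [lms_config()].
#' @return A list of class `lms_fit`: `clean` (error signal, same length),
#'   `error` (identical to `clean`; one entry per sample), `coefficients`
#'   (final taps), `mu`, `mu_max`.
#' @export
lms_filter <- function(primary, reference, cfg = lms_config()) {
  if (length(primary) != length(reference))
    stop_pcg("primary and reference must have equal length", "length_mismatch")
  n <- length(primary)
  L <- cfg$n_taps
  p_ref <- mean(reference^2)
  mu_max <- if (p_ref > 0) lms_mu_bound(L, p_ref) else Inf
  mu <- cfg$mu %||% (0.5 * mu_max)
  if (is.finite(mu_max) && mu > mu_max)
    rlang::warn(sprintf("mu = %.4g exceeds the stability bound mu_max = %.4g",
                        mu, mu_max))
  n_it <- min(n, cfg$max_iter %||% n)
  w <- numeric(L)
  e <- numeric(n)
  u <- numeric(L)                      # most-recent-first reference window
  for (d in seq_len(n)) {
    u <- c(reference[d], u[-L])
    y <- sum(w * u)
    e[d] <- primary[d] - y
    if (d <= n_it) w <- w + mu * e[d] * u
  }
  structure(list(clean = e, error = e, coefficients = w,
                 mu = mu, mu_max = mu_max),
            class = "lms_fit")
}

#' @export
print.lms_fit <- function(x, ...) {
  cat(sprintf("<lms_fit> %d taps, mu = %.4g (bound %.4g), final error power %.4g\n",
              length(x$coefficients), x$mu, x$mu_max,
              mean(tail(x$error, max(1, length(x$error) %/% 10))^2)))
  invisible(x)
}

#' LMS convergence-time estimate
#'
#' `tau ~ 1 / (4 * alpha * H)` iterations, with `H = (eig_max / eig_min) *
#' cond` the eigenvalue-spread factor of the reference autocorrelation
#' matrix scaled by its condition multiplier.
#'
#' @param eig_max,eig_min Largest / smallest autocorrelation eigenvalues
#'   (`eig_min > 0`).
#' @param cond Condition-number multiplier.
#' @param alpha Normalized step size (> 0).
#' @return Estimated iterations to convergence.
#' @export
#' @examples
#' lms_convergence_time(4, 2, 1, 0.125)  # 1
lms_convergence_time <- function(eig_max, eig_min, cond = 1, alpha = 0.25) {
  if (eig_min <= 0 || eig_max <= 0)
    stop_pcg("eigenvalues must be positive", "bad_eigenvalue")
  stopifnot(alpha > 0)
  H <- (eig_max / eig_min) * cond
  1 / (4 * alpha * H)
}
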