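# Empirical mode decomposition (EMD / EEMD) for 1-D signals.
#
# An intrinsic mode function (IMF) is an oscillatory component whose number
# of extrema and zero crossings differ by at most one and whose upper/lower
# envelope mean is (near) zero. EMD extracts IMFs by iterated sifting on the
# running residual; EEMD averages the decomposition over noise-perturbed
# copies of the input to reduce mode mixing.

#' EEMD configuration
#'
#' @param n_trials Ensemble size (1 = plain EMD when `noise_sd = 0`).
#' @param noise_sd Std of the added white noise, relative to the signal sd.
#' @param max_imfs Maximum number of IMFs to extract.
#' @param sift_tol Cauchy-type sifting stop tolerance
#'   `SD = sum((h_prev - h)^2) / sum(h_prev^2) < sift_tol`.
#' @param max_sift Cap on sifting iterations per IMF.
#' @param seed Integer seed for the ensemble noise.
#' @return A list of class `eemd_config`.
#' @export
eemd_config <- function(n_trials = 1L, noise_sd = 0, max_imfs = 10L,
                        sift_tol = 0.2, max_sift = 50L, seed = 1L) {
  stopifnot(is_count(n_trials), noise_sd >= 0, is_count(max_imfs),
            sift_tol > 0, is_count(max_sift))
  structure(list(n_trials = as.integer(n_trials), noise_sd = noise_sd,
                 max_imfs = as.integer(max_imfs), sift_tol = sift_tol,
                 max_sift = as.integer(max_sift), seed = as.integer(seed)),
            class = "eemd_config")
}

# indices of strict local maxima / minima, with flat-run midpoints
local_extrema <- function(x) {
  n <- length(x)
  if (n < 3) return(list(max = integer(0), min = integer(0)))
  d <- diff(x)
  d[d == 0] <- .Machine$double.eps  # break flats deterministically
  s <- sign(d)
  turn <- diff(s)
  list(max = which(turn < 0) + 1L, min = which(turn > 0) + 1L)
}

n_zero_crossings <- function(x) {
  x <- x[x != 0]
  if (length(x) < 2) return(0L)
  sum(diff(sign(x)) != 0)
}

# cubic-spline envelope through the given extrema, mirror-extending two
# extrema past each boundary to suppress spline end swings
spline_envelope <- function(x, idx) {
  n <- length(x)
  k <- length(idx)
  xi <- idx; yi <- x[idx]
  if (k >= 2) {
    ml <- 2 * idx[1] - idx[c(2, min(3, k))]
    mr <- 2 * idx[k] - idx[c(k - 1, max(k - 2, 1))]
    xi <- c(rev(ml), xi, mr)
    yi <- c(rev(x[idx[c(2, min(3, k))]]), yi, x[idx[c(k - 1, max(k - 2, 1))]])
    keep <- !duplicated(xi)
    xi <- xi[keep]; yi <- yi[keep]
  }
  spline(xi, yi, xout = seq_len(n))$y
}

#' Sift one proto-IMF out of a signal
#'
#' Repeatedly subtracts the mean of the cubic-spline upper and lower
#' envelopes until the IMF criterion holds (extrema and zero-crossing counts
#' differ by at most one, and the Cauchy stopping measure falls below
#' `sift_tol`) or `max_sift` iterations are reached.
#'
#' @param x Numeric signal with at least two maxima and two minima.
#' @param sift_tol,max_sift See [eemd_config()].
#' @return The extracted proto-IMF (same length as `x`).
#' @export
sift_imf <- function(x, sift_tol = 0.2, max_sift = 50L) {
  ext <- local_extrema(x)
  if (length(ext$max) < 2 || length(ext$min) < 2)
    stop_pcg("residual reached: too few extrema to sift", "residual_reached")
  h <- x
  for (i in seq_len(max_sift)) {
    ext <- local_extrema(h)
    if (length(ext$max) < 2 || length(ext$min) < 2) break
    m <- 0.5 * (spline_envelope(h, ext$max) + spline_envelope(h, ext$min))
    h_new <- h - m
    sd_c <- sum((h - h_new)^2) / max(sum(h^2), .Machine$double.xmin)
    h <- h_new
    ext_new <- local_extrema(h)
    n_ext <- length(ext_new$max) + length(ext_new$min)
    if (sd_c < sift_tol && abs(n_ext - n_zero_crossings(h)) <= 1L) break
  }
  h
}

#' Empirical mode decomposition
#'
#' Extracts IMFs by repeated sifting on the running residual until the
#' residual is monotone (fewer than three extrema) or `max_imfs` is reached.
#' The decomposition is exact by construction:
#' `rowSums(imfs) + residual == x`.
#'
#' @param x Numeric signal (or a [pcg_recording()], whose samples are used).
#' @param cfg An [eemd_config()]; only the sifting fields are used.
#' @return An `imf_set`: list with `imfs` (list of numeric vectors, may be
#'   empty), `residual`, and `source_len`.
#' @export
#' @examples
#' s <- sin(2 * pi * 5 * seq(0, 1, length.out = 400)) +
#'   0.5 * sin(2 * pi * 40 * seq(0, 1, length.out = 400))
#' d <- emd(s)
#' length(d$imfs)
emd <- function(x, cfg = eemd_config()) {
  if (inherits(x, "pcg_recording")) x <- x$samples
  if (length(x) == 0) stop_pcg("empty signal", "empty_signal")
  stopifnot(all(is.finite(x)))
  imfs <- list()
  resid <- x
  for (k in seq_len(cfg$max_imfs)) {
    ext <- local_extrema(resid)
    if (length(ext$max) + length(ext$min) < 3) break
    imf <- tryCatch(sift_imf(resid, cfg$sift_tol, cfg$max_sift),
                    pcgfusion_residual_reached = function(e) NULL)
    if (is.null(imf)) break
    imfs[[k]] <- imf
    resid <- resid - imf
  }
  new_imf_set(imfs, resid, length(x))
}

new_imf_set <- function(imfs, residual, source_len) {
  structure(list(imfs = imfs, residual = residual, source_len = source_len),
            class = "imf_set")
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("<imf_set> %d IMFs + residual, n = %d\n",
              length(x$imfs), x$source_len))
  invisible(x)
}

#' Tidy an IMF decomposition
#'
#' @param x An `imf_set` from [emd()] or [eemd()].
#' @param ... Unused.
#' @return Long tibble with columns `index`, `component`
#'   (`IMF1`..`IMFk`, `residual`), `value`.
#' @export
tidy.imf_set <- function(x, ...) {
  comp <- c(purrr::set_names(x$imfs, paste0("IMF", seq_along(x$imfs))),
            list(residual = x$residual))
  purrr::imap_dfr(comp, function(v, nm)
    tibble::tibble(index = seq_along(v), component = nm, value = v))
}

#' @rdname tidy.imf_set
#' @param object An `imf_set`.
#' @export
autoplot.imf_set <- function(object, ...) {
  d <- tidy(object)
  d$component <- factor(d$component, unique(d$component))
  ggplot2::ggplot(d, ggplot2::aes(.data$index, .data$value)) +
    ggplot2::geom_line(linewidth = 0.25) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$component), scales = "free_y") +
    ggplot2::labs(x = "sample", y = NULL)
}

#' Reconstruct the signal from an IMF set
#'
#' @param x An `imf_set`.
#' @return Numeric vector `sum(IMFs) + residual`.
#' @export
imf_reconstruct <- function(x) {
  Reduce(`+`, x$imfs, x$residual)
}

#' Ensemble empirical mode decomposition
#'
#' Runs [emd()] on `n_trials` noise-perturbed copies of the input (noise sd =
#' `noise_sd * sd(x)`) and averages IMFs across trials, aligned by index and
#' zero-padded where a trial yields fewer IMFs. With `n_trials = 1` and
#' `noise_sd = 0` the result equals [emd()] exactly. The ensemble residual is
#' defined as `x - sum(mean IMFs)`, so reconstruction of the input is always
#' exact; for a noisy ensemble the individual IMFs are mode-mixing-reduced
#' averages rather than strict IMFs.
#'
#' @inheritParams emd
#' @return An `imf_set`.
#' @export
eemd <- function(x, cfg = eemd_config()) {
  if (inherits(x, "pcg_recording")) x <- x$samples
  if (length(x) == 0) stop_pcg("empty signal", "empty_signal")
  if (cfg$n_trials == 1L && cfg$noise_sd == 0) return(emd(x, cfg))
  sig_sd <- sd(x)
  decomps <- with_seed_or_not(cfg$seed, {
    purrr::map(seq_len(cfg$n_trials), function(i) {
      xi <- x + rnorm(length(x), sd = cfg$noise_sd * sig_sd)
      emd(xi, cfg)
    })
  })
  k_max <- max(purrr::map_int(decomps, ~ length(.x$imfs)))
  imfs <- purrr::map(seq_len(k_max), function(k) {
    acc <- numeric(length(x))
    for (d in decomps) if (k <= length(d$imfs)) acc <- acc + d$imfs[[k]]
    acc / cfg$n_trials
  })
  residual <- x - Reduce(`+`, imfs, numeric(length(x)))
  new_imf_set(imfs, residual, length(x))
}
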