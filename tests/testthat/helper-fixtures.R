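# Shared fixture builders. Everything is generated in code at test time.

# two-tone signal used by decomposition tests
two_tone <- function(n = 2000, fs = 4000, f1 = 25, f2 = 150) {
  t <- (seq_len(n) - 1) / fs
  sin(2 * pi * f1 * t) + 0.6 * sin(2 * pi * f2 * t)
}

# count of zero crossings / extrema, independent re-implementations for
# checking the IMF defining property
count_zc <- function(x) {
  x <- x[x != 0]
  if (length(x) < 2) return(0L)
  sum(diff(sign(x)) != 0)
}
count_extrema <- function(x) {
  d <- diff(x)
  d[d == 0] <- .Machine$double.eps
  sum(diff(sign(d)) != 0)
}

# planted-feature fixture: K classes, class k separated along feature k,
# plus pure-noise features; each informative feature is necessary
planted_features <- function(n_per = 30, n_classes = 5, n_noise = 15,
                             shift = 3, seed = 1) {
  withr::with_seed(seed, {
    d <- n_classes + n_noise
    X <- NULL; y <- NULL
    for (k in seq_len(n_classes)) {
      Xi <- matrix(rnorm(n_per * d), n_per)
      Xi[, k] <- Xi[, k] + shift
      X <- rbind(X, Xi)
      y <- c(y, rep(paste0("c", k), n_per))
    }
    colnames(X) <- paste0("f", seq_len(d))
    list(X = X, y = y, informative = paste0("f", seq_len(n_classes)))
  })
}

# separable 5-class feature fixture for classifier tests
separable_classes <- function(n_per = 50, d = 24, shift = 3, sd = 0.6,
                              seed = 11) {
  withr::with_seed(seed, {
    X <- NULL; y <- NULL
    for (k in 1:5) {
      Xi <- matrix(rnorm(n_per * d, sd = sd), n_per)
      Xi[, k] <- Xi[, k] + shift
      X <- rbind(X, Xi)
      y <- c(y, rep(paste0("c", k), n_per))
    }
    colnames(X) <- paste0("f", seq_len(d))
    list(X = X, y = y)
  })
}

# Welch-periodogram band-power fraction: the independent spectral oracle
# (direct segmented-FFT implementation, no package code)
oracle_band_fraction <- function(x, fs, f_lo, f_hi, nw = 1024) {
  nw <- min(length(x), nw)
  starts <- seq(1, length(x) - nw + 1, by = max(1, nw %/% 2))
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nw) / (nw + 1))
  p <- Reduce(`+`, lapply(starts, function(s)
    Mod(stats::fft(x[s:(s + nw - 1)] * w))^2))
  half <- seq_len(nw %/% 2 + 1)
  f <- (half - 1) * fs / nw
  sum(p[half][f >= f_lo & f <= f_hi]) / sum(p[half])
}
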