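# Feature extraction: Shannon-energy envelope, S1/S2 cycle segmentation,
# murmur-band spectral power, timing (systolic/diastolic) statistics and
# global descriptors, assembled into one tidy feature table per dataset.

#' Welch power spectral density
#'
#' Averaged Hann-windowed periodogram over 50 %-overlapping segments.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param window_s Segment length in seconds (clipped to the signal length).
#' @param overlap Fractional overlap between segments.
#' @return A tibble with columns `freq` (Hz, one-sided) and `psd`.
#' @export
welch_psd <- function(x, fs, window_s = 1, overlap = 0.5) {
  n <- length(x)
  nw <- min(n, max(16L, round(window_s * fs)))
  step <- max(1L, round(nw * (1 - overlap)))
  starts <- seq(1L, n - nw + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nw) / (nw + 1))   # Hann
  acc <- numeric(nw)
  for (s in starts) {
    seg <- x[s:(s + nw - 1L)] * w
    acc <- acc + Mod(fft(seg))^2
  }
  acc <- acc / (length(starts) * sum(w^2) * fs)
  half <- seq_len(nw %/% 2 + 1L)
  tibble::tibble(freq = (half - 1) * fs / nw, psd = acc[half])
}

band_fraction <- function(psd_tbl, f_lo, f_hi) {
  tot <- sum(psd_tbl$psd)
  if (tot == 0) return(0)
  sum(psd_tbl$psd[psd_tbl$freq >= f_lo & psd_tbl$freq <= f_hi]) / tot
}

#' Normalized Shannon-energy envelope
#'
#' `-x^2 * log(x^2)` of the unit-scaled signal, low-pass smoothed. The
#' Shannon energy emphasises medium-intensity content (heart-sound bursts)
#' over both background and isolated spikes.
#'
#' @param rec A [pcg_recording()] or numeric vector (then `fs` is required).
#' @param fs Sampling rate when `rec` is a bare vector.
#' @param smooth_hz Low-pass cut-off of the envelope smoother, Hz.
#' @return Non-negative numeric vector, same length as the input.
#' @export
shannon_envelope <- function(rec, fs = NULL, smooth_hz = 20) {
  x <- if (inherits(rec, "pcg_recording")) rec$samples else as.numeric(rec)
  fs <- if (inherits(rec, "pcg_recording")) rec$fs else fs
  stopifnot(!is.null(fs))
  m <- max(abs(x))
  if (m == 0) stop_pcg("all-zero signal has no envelope", "zero_signal")
  u <- x / m
  se <- -u^2 * log(pmax(u^2, 1e-12))
  bf <- signal::butter(2, min(0.99, smooth_hz / (fs / 2)), type = "low")
  env <- as.numeric(signal::filtfilt(bf, se))
  pmax(env, 0)
}

#' Segment a recording into cardiac cycles
#'
#' Peak-picking on the Shannon envelope with a minimum inter-peak distance of
#' `min_dist_s`; alternating peaks are assigned S1/S2 by the physiological
#' rule that systole (S1 to S2) is shorter than diastole (S2 to the next S1).
#'
#' @param rec A [pcg_recording()].
#' @param min_dist_s Minimum peak separation in seconds.
#' @param min_height_frac Peaks below this fraction of the envelope maximum
#'   are ignored.
#' @return A tibble with one row per complete cycle: `s1_idx`, `s2_idx`,
#'   `start_idx`, `end_idx`, `s1_amp`, `s2_amp`; attribute `fs`.
#' @export
segment_cycles <- function(rec, min_dist_s = 0.2, min_height_frac = 0.3) {
  env <- shannon_envelope(rec)
  fs <- rec$fs
  pk <- pracma::findpeaks(env, minpeakheight = min_height_frac * max(env),
                          minpeakdistance = max(1L, round(min_dist_s * fs)),
                          sortstr = TRUE)
  if (is.null(pk) || nrow(pk) < 3)
    stop_pcg("fewer than 3 envelope peaks detected", "too_few_peaks")
  p <- sort(pk[, 2])
  g <- diff(p)
  odd <- mean(g[seq(1, length(g), by = 2)])
  even <- if (length(g) >= 2) mean(g[seq(2, length(g), by = 2)]) else Inf
  first_s1 <- odd < even      # S1 leads iff odd gaps (S1->S2) are the short ones
  s1_pos <- seq(if (first_s1) 1L else 2L, length(p) - 1L, by = 2L)
  cyc <- purrr::map_dfr(s1_pos, function(i) {
    end_idx <- if (i + 2L <= length(p)) p[i + 2L]
               else min(length(env), p[i + 1L] + round(1.3 * (p[i + 1L] - p[i])))
    tibble::tibble(s1_idx = p[i], s2_idx = p[i + 1L],
                   start_idx = p[i], end_idx = end_idx,
                   s1_amp = env[p[i]], s2_amp = env[p[i + 1L]])
  })
  attr(cyc, "fs") <- fs
  cyc
}

#' Murmur-band and envelope-modulation spectral features
#'
#' Fraction of Welch-PSD power inside each band of `bands`, plus `delta`
#' (0.5--4 Hz) and `theta` (4--8 Hz) envelope-modulation power fractions.
#'
#' @param rec A [pcg_recording()].
#' @param bands Band table as from [default_band_table()].
#' @param window_s Welch window, seconds.
#' @return A named numeric vector; all values in \[0, 1\].
#' @export
band_power_features <- function(rec, bands = default_band_table(), window_s = 1) {
  if (any(bands$f_hi >= rec$fs / 2))
    stop_pcg("band edge at or above Nyquist", "band_above_nyquist")
  psd <- welch_psd(rec$samples, rec$fs, window_s)
  out <- purrr::map_dbl(seq_len(nrow(bands)),
                        ~ band_fraction(psd, bands$f_lo[.x], bands$f_hi[.x]))
  names(out) <- paste0("band_", bands$name)
  env <- shannon_envelope(rec)
  epsd <- welch_psd(env - mean(env), rec$fs, window_s = min(2, rec$duration_s))
  c(out,
    delta_power = band_fraction(epsd, 0.5, 4),
    theta_power = band_fraction(epsd, 4, 8))
}

#' Timing and intensity features from segmented cycles
#'
#' @param cycles Output of [segment_cycles()].
#' @return Named numeric vector: mean/sd of systolic and diastolic durations
#'   (s), systolic-to-cycle ratio, and the S1/S2 envelope amplitude ratio.
#' @export
interval_features <- function(cycles) {
  if (!is.data.frame(cycles) || nrow(cycles) == 0)
    stop_pcg("empty cycle list", "no_cycles")
  fs <- attr(cycles, "fs")
  syst <- (cycles$s2_idx - cycles$s1_idx) / fs
  diast <- (cycles$end_idx - cycles$s2_idx) / fs
  sd0 <- function(v) if (length(v) > 1) sd(v) else 0
  c(syst_mean = mean(syst), syst_sd = sd0(syst),
    diast_mean = mean(diast), diast_sd = sd0(diast),
    syst_ratio = mean(syst / (syst + diast)),
    s1s2_amp_ratio = mean(cycles$s1_amp) / mean(cycles$s2_amp))
}

# murmur-band fractions computed separately on the systolic and diastolic
# interiors (S1/S2 bursts excluded); these separate diseases whose murmur
# bands overlap but whose murmur timing differs (e.g. MVP vs MS)
segment_band_features <- function(rec, cycles, class_bands) {
  fs <- attr(cycles, "fs")
  guard <- round(0.04 * fs)                  # keep clear of the bursts
  pull_seg <- function(a, b) {
    a <- a + guard; b <- b - guard
    if (b > a) rec$samples[a:b] else numeric(0)
  }
  sys_x <- unlist(purrr::map2(cycles$s1_idx, cycles$s2_idx, pull_seg))
  dia_x <- unlist(purrr::map2(cycles$s2_idx, cycles$end_idx, pull_seg))
  frac_tbl <- function(x, prefix) {
    if (length(x) < 64) {
      out <- rep(0, nrow(class_bands))
    } else {
      psd <- welch_psd(x, fs, window_s = min(0.5, length(x) / fs))
      out <- purrr::map_dbl(seq_len(nrow(class_bands)),
                            ~ band_fraction(psd, class_bands$f_lo[.x],
                                            class_bands$f_hi[.x]))
    }
    setNames(out, paste0(prefix, class_bands$name))
  }
  c(frac_tbl(sys_x, "sys_band_"), frac_tbl(dia_x, "dia_band_"))
}

feature_vector <- function(rec, bands) {
  x <- rec$samples
  bp <- band_power_features(rec, bands)
  class_bands <- bands[bands$name %in% pcg_labels(), ]
  seg <- tryCatch({
    cyc <- segment_cycles(rec)
    c(interval_features(cyc), segment_band_features(rec, cyc, class_bands))
  }, error = function(e) {
    c(syst_mean = 0, syst_sd = 0, diast_mean = 0, diast_sd = 0,
      syst_ratio = 0, s1s2_amp_ratio = 1,
      setNames(rep(0, 2 * nrow(class_bands)),
               c(paste0("sys_band_", class_bands$name),
                 paste0("dia_band_", class_bands$name))))
  })
  psd <- welch_psd(x, rec$fs)
  centroid <- sum(psd$freq * psd$psd) / max(sum(psd$psd), 1e-300)
  glob <- c(rms = sqrt(mean(x^2)),
            zcr = n_zero_crossings(x - mean(x)) / length(x),
            spectral_centroid = centroid)
  c(bp, seg, glob)
}

#' Extract the feature table for a set of recordings
#'
#' One row per recording: the eleven murmur-band power fractions,
#' delta/theta envelope-modulation powers, systolic/diastolic timing and
#' amplitude statistics, systole- and diastole-restricted class-band
#' fractions, and global descriptors (RMS, zero-crossing rate, spectral
#' centroid). Extraction is deterministic.
#'
#' @param recs A list of [pcg_recording()] (e.g. from [simulate_dataset()]).
#' @param bands Band table, default [default_band_table()].
#' @return A tibble with `record_id`, `label`, and one numeric column per
#'   feature; no missing values.
#' @export
extract_features <- function(recs, bands = default_band_table()) {
  if (length(recs) == 0) stop_pcg("no recordings", "empty_input")
  if (inherits(recs, "pcg_recording")) recs <- list(recs)
  rows <- purrr::map(recs, feature_vector, bands = bands)
  feat <- tibble::as_tibble(do.call(rbind, rows))
  stopifnot(all(is.finite(as.matrix(feat))))
  dplyr::bind_cols(
    tibble::tibble(record_id = purrr::map_chr(recs, "record_id"),
                   label = purrr::map_chr(recs, "label")),
    feat
  )
}

#' Names of the feature columns of a feature table
#'
#' @param data A feature table (tibble with metadata + numeric features).
#' @return Character vector of feature column names.
#' @export
feature_names <- function(data) {
  setdiff(names(data)[purrr::map_lgl(data, is.numeric)], "synthetic")
}
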