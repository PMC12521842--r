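#' PCG recording object
#'
#' A `pcg_recording` bundles one mono heart-sound signal with its sampling
#' rate and class label. Labels follow the five-class scheme used throughout
#' the package: `NHF` (normal heart frequency), `AS` (aortic stenosis),
#' `MR` (mitral regurgitation), `MS` (mitral stenosis), `MVP` (mitral valve
#' prolapse), plus `UNKNOWN` for unlabeled audio.
#'
#' @param samples Numeric vector of finite amplitudes (arbitrary units).
#' @param fs Sampling rate in Hz (> 0).
#' @param label Class label, one of [pcg_labels()] or `"UNKNOWN"`.
#' @param record_id Identifier string.
#' @return An object of class `pcg_recording` with fields `samples`, `fs`,
#'   `label`, `record_id` and `duration_s` (= `length(samples) / fs`).
#' @export
#' @examples
#' rec <- pcg_recording(sin(2 * pi * 50 * seq(0, 1, by = 1 / 4000)), fs = 4000)
#' rec$duration_s
pcg_recording <- function(samples, fs, label = "UNKNOWN", record_id = "rec") {
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop_pcg("`fs` must be a single positive number", "bad_fs")
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop_pcg("`samples` must be non-empty", "empty_signal")
  if (!all(is.finite(samples))) stop_pcg("`samples` must be finite", "nonfinite_signal")
  label <- match.arg(label, c(pcg_labels(), "UNKNOWN"))
  structure(
    list(samples = samples, fs = fs, label = label,
         record_id = as.character(record_id),
         duration_s = length(samples) / fs),
    class = "pcg_recording"
  )
}

#' @export
print.pcg_recording <- function(x, ...) {
  cat(sprintf("<pcg_recording> %s  label=%s  fs=%g Hz  %.3f s (%d samples)\n",
              x$record_id, x$label, x$fs, x$duration_s, length(x$samples)))
  invisible(x)
}

#' @rdname pcg_recording
#' @export
pcg_labels <- function() c("NHF", "AS", "MR", "MS", "MVP")

#' Tidy a PCG recording into a time/amplitude tibble
#'
#' @param x A [pcg_recording()].
#' @param ... Unused.
#' @return A tibble with columns `time` (s), `amplitude`, `record_id`, `label`.
#' @export
tidy.pcg_recording <- function(x, ...) {
  tibble::tibble(
    time = (seq_along(x$samples) - 1) / x$fs,
    amplitude = x$samples,
    record_id = x$record_id,
    label = x$label
  )
}

#' @rdname tidy.pcg_recording
#' @param object A [pcg_recording()].
#' @export
autoplot.pcg_recording <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$time, .data$amplitude)) +
    ggplot2::geom_line(linewidth = 0.25) +
    ggplot2::labs(x = "time [s]", y = "amplitude",
                  title = sprintf("%s (%s)", object$record_id, object$label))
}

#' Murmur and normal-heart frequency band table
#'
#' The eleven heart-sound modulation bands used for murmur synthesis and
#' band-power features. Each band has a lower and upper edge in Hz and a
#' symmetric edge tolerance (`tol`, Hz) capturing measurement spread of the
#' band limits.
#'
#' @return A tibble with columns `name`, `long_name`, `f_lo`, `f_hi`, `tol`.
#' @export
#' @examples
#' default_band_table()
default_band_table <- function() {
  tibble::tribble(
    ~name,  ~long_name,                  ~f_lo, ~f_hi, ~tol,
    "AR",   "Aortic regurgitation",        65,   395,  10.5,
    "TR",   "Tricuspid regurgitation",     90,   400,  16.5,
    "PR",   "Pulmonary regurgitation",     90,   150,  15.7,
    "PDA",  "Patent ductus arteriosus",    90,   140,  20.9,
    "MVP",  "Mitral valve prolapse",       45,    90,   7.5,
    "MS",   "Mitral stenosis",             40,    95,   6.7,
    "MR",   "Mitral regurgitation",        45,   160,   9.0,
    "ASD",  "Atrial septal defect",        60,   200,  25.5,
    "AS",   "Aortic stenosis",            100,   450,  35.4,
    "PS",   "Pulmonary stenosis",         150,   380,  27.1,
    "NHF",  "Normal heart frequency",     100,   180,  20.5
  )
}

#' Simulation configuration for synthetic PCG datasets
#'
#' @param n_per_class Recordings per class (>= 1). May also be a named vector
#'   over [pcg_labels()] for imbalanced designs.
#' @param fs Sampling rate, Hz. Default 4000 Hz, the standard auscultation
#'   recording rate.
#' @param duration_s Recording length in seconds (1..30).
#' @param heart_rate_bpm Heart rate, beats per minute.
#' @param snr_db Additive white-noise level in dB relative to the clean
#'   composite signal power.
#' @param seed Integer seed; every stochastic step derives from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_per_class = 10, fs = 4000, duration_s = 3,
                       heart_rate_bpm = 72, snr_db = 15, seed = 1L) {
  stopifnot(all(n_per_class >= 1), duration_s >= 1, duration_s <= 30,
            is.finite(snr_db), fs > 0, heart_rate_bpm > 0)
  structure(list(n_per_class = n_per_class, fs = fs, duration_s = duration_s,
                 heart_rate_bpm = heart_rate_bpm, snr_db = snr_db,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# band-limited unit-variance Gaussian noise via FFT masking with a raised-
# cosine transition of `roll` Hz; gives sharp, controllable murmur spectra
band_noise <- function(n, fs, f_lo, f_hi, roll = 3, seed_offset = 0) {
  x <- rnorm(n)
  X <- fft(x)
  f <- seq(0, fs, length.out = n + 1)[1:n]
  f <- pmin(f, fs - f)              # two-sided frequency axis
  w <- rep(0, n)
  w[f >= f_lo & f <= f_hi] <- 1
  lo_t <- f >= f_lo - roll & f < f_lo
  hi_t <- f > f_hi & f <= f_hi + roll
  w[lo_t] <- 0.5 * (1 + cos(pi * (f_lo - f[lo_t]) / roll))
  w[hi_t] <- 0.5 * (1 + cos(pi * (f[hi_t] - f_hi) / roll))
  y <- Re(fft(X * w, inverse = TRUE)) / n
  s <- sd(y)
  if (s == 0) rep(0, n) else y / s
}

# Gaussian-windowed tone burst centred at `t0` seconds
tone_burst <- function(t, t0, freq, sigma_s, amp) {
  amp * exp(-(t - t0)^2 / (2 * sigma_s^2)) * sin(2 * pi * freq * (t - t0))
}

#' Simulate one synthetic PCG recording
#'
#' Generates periodic cardiac cycles at the configured heart rate. Each cycle
#' holds a Gaussian-windowed S1 burst (spectral energy 30--100 Hz) at the
#' cycle start and an S2 burst (>= 100 Hz) at end-systole; systole occupies
#' the first 35 % of the cycle. Disease labels inject a band-limited noise
#' murmur into the interval where the corresponding murmur is auscultated:
#' systole for AS, MR and MVP, diastole for MS. The murmur band is the
#' label's row of [default_band_table()]. `NHF` has no murmur. White Gaussian
#' noise is added at `cfg$snr_db` relative to the clean composite.
#'
#' @param label One of [pcg_labels()].
#' @param cfg A [sim_config()].
#' @param record_id Identifier for the returned recording.
#' @param seed Seed overriding `cfg$seed` (used when drawing many recordings).
#' @param return_parts If `TRUE`, attach the clean signal and murmur support
#'   indices as attributes `clean` and `murmur_window` (ground truth for
#'   oracles and SNR computations).
#' @return A [pcg_recording()].
#' @export
#' @examples
#' rec <- simulate_recording("AS", sim_config(snr_db = 20, seed = 1))
#' rec
simulate_recording <- function(label, cfg = sim_config(), record_id = NULL,
                               seed = cfg$seed, return_parts = FALSE) {
  label <- match.arg(label, pcg_labels())
  if (cfg$fs <= 0) stop_pcg("sampling rate must be positive", "bad_fs")
  n <- round(cfg$duration_s * cfg$fs)
  t <- (seq_len(n) - 1) / cfg$fs
  period <- 60 / cfg$heart_rate_bpm
  sys_frac <- 0.35                       # systole = first 35 % of the cycle
  bands <- default_band_table()

  with_seed_or_not(seed, {
    clean <- numeric(n)
    murmur_win <- logical(n)
    n_cycles <- ceiling(cfg$duration_s / period) + 1L
    s1_f <- 60 * runif(1, 0.95, 1.05)    # S1 fundamental, well inside 30-100 Hz
    s2_f <- 140 * runif(1, 0.95, 1.05)   # S2 fundamental, >= 100 Hz
    for (k in seq_len(n_cycles) - 1L) {
      t0 <- k * period + 0.05 * period
      t2 <- k * period + sys_frac * period
      clean <- clean + tone_burst(t, t0, s1_f, 0.022, 1.0)
      clean <- clean + tone_burst(t, t2, s2_f, 0.014, 0.8)
      if (label != "NHF") {
        b <- bands[bands$name == label, ]
        if (label == "MS") {            # diastolic murmur
          m_start <- t2 + 0.06; m_end <- (k + 1) * period + 0.02
        } else {                        # systolic murmur (AS, MR, MVP)
          m_start <- t0 + 0.05; m_end <- t2 - 0.04
        }
        idx <- which(t >= m_start & t <= m_end)
        if (length(idx) > 8) {
          env <- sin(pi * seq_along(idx) / length(idx))  # crescendo-decrescendo
          mm <- band_noise(length(idx), cfg$fs, b$f_lo, b$f_hi)
          clean[idx] <- clean[idx] + 0.30 * env * mm
          murmur_win[idx] <- TRUE
        }
      }
    }
    p_sig <- mean(clean^2)
    noise <- rnorm(n) * sqrt(p_sig / 10^(cfg$snr_db / 10))
    samples <- clean + noise
    rec <- pcg_recording(samples, cfg$fs, label,
                         record_id %||% sprintf("%s_seed%d", label, seed))
    if (return_parts) {
      attr(rec, "clean") <- clean
      attr(rec, "murmur_window") <- murmur_win
    }
    rec
  })
}

#' Simulate a labeled PCG dataset with manifest
#'
#' Draws `n_per_class` recordings per class (or a named per-class count
#' vector), optionally writing WAV files, and returns the recordings with a
#' manifest tibble (`record_id`, `path`, `label`).
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory for WAV files, or `NULL` to keep recordings in
#'   memory only (manifest `path` is then `NA`).
#' @param return_parts Passed through to [simulate_recording()].
#' @return A list with elements `recordings` (named list of
#'   [pcg_recording()]) and `manifest` (tibble).
#' @export
simulate_dataset <- function(cfg = sim_config(), dir = NULL, return_parts = FALSE) {
  counts <- cfg$n_per_class
  if (is.null(names(counts))) counts <- setNames(rep(counts[[1]], 5), pcg_labels())
  stopifnot(all(names(counts) %in% pcg_labels()), all(counts >= 1))
  plan <- tidyr::expand_grid(label = names(counts)) |>
    dplyr::mutate(n = counts[.data$label]) |>
    tidyr::uncount(.data$n) |>
    dplyr::group_by(.data$label) |>
    dplyr::mutate(rep = dplyr::row_number()) |>
    dplyr::ungroup()
  # one derived sub-seed per recording, stable under the dataset seed
  sub_seeds <- with_seed_or_not(cfg$seed,
                                sample.int(.Machine$integer.max %/% 2, nrow(plan)))
  recs <- purrr::map(seq_len(nrow(plan)), function(i) {
    simulate_recording(plan$label[i], cfg,
                       record_id = sprintf("%s_%03d", plan$label[i], plan$rep[i]),
                       seed = sub_seeds[i], return_parts = return_parts)
  })
  names(recs) <- purrr::map_chr(recs, "record_id")
  paths <- rep(NA_character_, length(recs))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- file.path(dir, paste0(names(recs), ".wav"))
    purrr::walk2(recs, paths, write_wav)
  }
  manifest <- tibble::tibble(
    record_id = names(recs),
    path = paths,
    label = purrr::map_chr(recs, "label")
  )
  if (!is.null(dir))
    readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  list(recordings = recs, manifest = manifest)
}

#' Read and write mono WAV files
#'
#' Minimal RIFF/WAVE support for the two encodings used in practice for PCG
#' audio: PCM-16 and IEEE float-32. Multi-channel files are reduced to the
#' first channel with a warning.
#'
#' @param path File path.
#' @param label,record_id Metadata attached to the returned recording;
#'   `record_id` defaults to the file stem.
#' @return `read_wav()` returns a [pcg_recording()] with float samples in
#'   \[-1, 1\] for PCM input; `write_wav()` invisibly returns `path`.
#' @export
read_wav <- function(path, label = "UNKNOWN", record_id = NULL) {
  if (!file.exists(path)) stop_pcg(paste0("no such file: ", path), "missing_file")
  con <- file(path, "rb"); on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE"))
    stop_pcg("not a RIFF/WAVE file", "bad_wav")
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", sz + sz %% 2)
      fmt <- list(
        audio_format = readBin(fmt_raw[1:2], "integer", 1, 2, endian = "little"),
        n_channels   = readBin(fmt_raw[3:4], "integer", 1, 2, endian = "little"),
        sample_rate  = readBin(fmt_raw[5:8], "integer", 1, 4, endian = "little"),
        bits         = readBin(fmt_raw[15:16], "integer", 1, 2, endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
      if (sz %% 2 == 1) readBin(con, "raw", 1)
    } else {
      readBin(con, "raw", sz + sz %% 2)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop_pcg("missing fmt/data chunk", "bad_wav")
  if (fmt$audio_format == 1L && fmt$bits == 16L) {
    x <- readBin(data_raw, "integer", length(data_raw) / 2, 2,
                 signed = TRUE, endian = "little") / 32768
  } else if (fmt$audio_format == 3L && fmt$bits == 32L) {
    x <- readBin(data_raw, "double", length(data_raw) / 4, 4, endian = "little")
  } else {
    stop_pcg(sprintf("unsupported WAV encoding (format %d, %d bit)",
                     fmt$audio_format, fmt$bits), "bad_encoding")
  }
  if (fmt$n_channels > 1L) {
    rlang::warn(sprintf("%d channels in %s; taking channel 1", fmt$n_channels, path))
    x <- x[seq(1, length(x), by = fmt$n_channels)]
  }
  pcg_recording(x, fmt$sample_rate, label,
                record_id %||% tools::file_path_sans_ext(basename(path)))
}

#' @rdname read_wav
#' @param rec A [pcg_recording()].
#' @param encoding `"float32"` (lossless) or `"pcm16"`.
#' @export
write_wav <- function(rec, path, encoding = c("float32", "pcm16")) {
  encoding <- match.arg(encoding)
  x <- rec$samples
  if (encoding == "pcm16") {
    body <- writeBin(as.integer(pmax(-32768, pmin(32767, round(x * 32768)))),
                     raw(), size = 2, endian = "little")
    fmt_code <- 1L; bits <- 16L
  } else {
    body <- writeBin(as.numeric(x), raw(), size = 4, endian = "little")
    fmt_code <- 3L; bits <- 32L
  }
  block <- bits %/% 8L
  con <- file(path, "wb"); on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + length(body)), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(as.integer(16), con, size = 4, endian = "little")
  writeBin(as.integer(fmt_code), con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                # mono
  writeBin(as.integer(rec$fs), con, size = 4, endian = "little")
  writeBin(as.integer(rec$fs * block), con, size = 4, endian = "little")
  writeBin(as.integer(block), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(length(body)), con, size = 4, endian = "little")
  writeBin(body, con)
  invisible(path)
}

#' Read a dataset back from a manifest
#'
#' @param manifest_path Path to a `manifest.csv` with columns
#'   `record_id,path,label`.
#' @return Named list of [pcg_recording()].
#' @export
read_manifest <- function(manifest_path) {
  man <- readr::read_csv(manifest_path, show_col_types = FALSE)
  base <- dirname(manifest_path)
  recs <- purrr::pmap(man, function(record_id, path, label, ...) {
    p <- if (file.exists(path)) path else file.path(base, basename(path))
    read_wav(p, label = label, record_id = record_id)
  })
  names(recs) <- man$record_id
  recs
}

`%||%` <- function(a, b) if (is.null(a)) b else a
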