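test_that("band table carries the eleven murmur/normal bands", {
  bt <- default_band_table()
  expect_equal(nrow(bt), 11)
  expect_true(all(bt$f_lo > 0 & bt$f_lo < bt$f_hi))
  expect_true(all(bt$tol >= 0))
  as_row <- bt[bt$name == "AS", ]
  expect_equal(c(as_row$f_lo, as_row$f_hi, as_row$tol), c(100, 450, 35.4))
  expect_equal(unlist(bt[bt$name == "MS", c("f_lo", "f_hi")]),
               c(f_lo = 40, f_hi = 95))
  expect_equal(unlist(bt[bt$name == "NHF", c("f_lo", "f_hi")]),
               c(f_lo = 100, f_hi = 180))
})

test_that("simulated recordings have the right length, determinism and murmur placement", {
  cfg <- sim_config(fs = 4000, duration_s = 5, heart_rate_bpm = 60,
                    snr_db = 20, seed = 1)
  rec <- simulate_recording("AS", cfg, return_parts = TRUE)
  expect_s3_class(rec, "pcg_recording")
  expect_length(rec$samples, 20000)
  expect_equal(rec$duration_s, 5)

  rec2 <- simulate_recording("AS", cfg, return_parts = TRUE)
  expect_identical(rec$samples, rec2$samples)

  # murmur segment spectral power concentrates in the AS band (oracle PSD)
  mw <- attr(rec, "murmur_window")
  expect_gt(oracle_band_fraction(rec$samples[mw], 4000, 100, 450), 0.6)

  # NHF systolic interiors carry no murmur-band energy to speak of
  nhf <- simulate_recording("NHF", cfg)
  t <- (seq_along(nhf$samples) - 1) / 4000
  phase <- (t %% 1) / 1                       # 60 bpm -> 1 s cycles
  sys_interior <- phase > 0.08 & phase < 0.30
  expect_lt(oracle_band_fraction(nhf$samples[sys_interior], 4000, 100, 450), 0.2)

  expect_error(simulate_recording("XX", cfg))
})

test_that("each disease label's murmur lands in its own band most of the time", {
  bands <- default_band_table()
  # dominant band = the rectangular band template most correlated with the
  # measured PSD over 20-600 Hz (independent segmented-FFT implementation)
  template_match <- function(x, fs) {
    nw <- min(length(x), 2048)
    starts <- seq(1, length(x) - nw + 1, by = max(1, nw %/% 2))
    w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nw) / (nw + 1))
    p <- Reduce(`+`, lapply(starts, function(s)
      Mod(stats::fft(x[s:(s + nw - 1)] * w))^2))
    half <- seq_len(nw %/% 2 + 1)
    f <- (half - 1) * fs / nw
    keep <- f >= 20 & f <= 600
    sc <- vapply(seq_len(nrow(bands)), function(i)
      suppressWarnings(cor(p[half][keep],
                           as.numeric(f[keep] >= bands$f_lo[i] &
                                        f[keep] <= bands$f_hi[i]))),
      numeric(1))
    bands$name[which.max(sc)]
  }
  cfg <- sim_config(snr_db = 20, duration_s = 4, heart_rate_bpm = 60, seed = 0)
  hits <- 0; total <- 0
  for (lab in c("AS", "MR", "MS", "MVP")) {
    for (s in 1:8) {
      rec <- simulate_recording(lab, cfg, seed = 1000 + 10 * s, return_parts = TRUE)
      seg <- rec$samples[attr(rec, "murmur_window")]
      total <- total + 1
      if (template_match(seg, rec$fs) == lab) hits <- hits + 1
    }
  }
  expect_gte(hits / total, 0.9)
})

test_that("simulate_dataset respects counts, manifests and seeding", {
  ds <- simulate_dataset(sim_config(n_per_class = 3, duration_s = 2, seed = 5))
  expect_length(ds$recordings, 15)
  expect_equal(as.integer(table(ds$manifest$label)), rep(3L, 5))

  ds2 <- simulate_dataset(sim_config(n_per_class = 3, duration_s = 2, seed = 5))
  expect_identical(purrr::map(ds$recordings, "samples"),
                   purrr::map(ds2$recordings, "samples"))

  imb <- simulate_dataset(sim_config(
    n_per_class = c(NHF = 5, AS = 2), duration_s = 2, seed = 1))
  expect_equal(sum(imb$manifest$label == "NHF"), 5)
  expect_equal(sum(imb$manifest$label == "AS"), 2)
})

test_that("WAV round-trips preserve samples and sampling rate", {
  rec <- simulate_recording("MR", sim_config(duration_s = 2, seed = 2))
  f32 <- withr::local_tempfile(fileext = ".wav")
  write_wav(rec, f32, encoding = "float32")
  back <- read_wav(f32)
  expect_equal(back$samples, as.numeric(as.single <- rec$samples),
               tolerance = 1e-7)  # float-32 storage precision
  expect_equal(back$fs, rec$fs)

  # PCM-16: quantization error bounded by one LSB of full scale
  rec_n <- pcg_recording(rec$samples / max(abs(rec$samples)), rec$fs)
  p16 <- withr::local_tempfile(fileext = ".wav")
  write_wav(rec_n, p16, encoding = "pcm16")
  back16 <- read_wav(p16)
  expect_lt(max(abs(back16$samples - rec_n$samples)), 2^-15 + 1e-9)

  expect_error(read_wav(file.path(tempdir(), "nope.wav")),
               class = "pcgfusion_missing_file")
})

test_that("manifest rows resolve to readable files with matching metadata", {
  dir <- withr::local_tempdir()
  ds <- simulate_dataset(sim_config(n_per_class = 2, duration_s = 1.5, seed = 9),
                         dir = dir)
  recs <- read_manifest(file.path(dir, "manifest.csv"))
  expect_setequal(names(recs), ds$manifest$record_id)
  for (id in names(recs)) {
    expect_equal(recs[[id]]$fs, ds$recordings[[id]]$fs)
    expect_length(recs[[id]]$samples, length(ds$recordings[[id]]$samples))
    expect_equal(recs[[id]]$label, ds$recordings[[id]]$label)
  }
})
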