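test_that("a sinusoid sifts to itself and monotone input signals residual", {
  t <- seq(0, 2, length.out = 1600)
  s <- sin(2 * pi * 4 * t)             # 8 cycles
  imf <- sift_imf(s)
  expect_gt(cor(imf, s), 0.99)
  expect_error(sift_imf(seq(0, 1, length.out = 100)),
               class = "pcgfusion_residual_reached")
})

test_that("EMD reconstructs exactly and IMFs satisfy the defining property", {
  withr::with_seed(42, {
    for (i in 1:10) {
      x <- cumsum(rnorm(600)) + sin(2 * pi * seq_len(600) / 25)
      d <- emd(x)
      expect_lt(max(abs(imf_reconstruct(d) - x)), 1e-8 * max(abs(x)))
      for (imf in d$imfs)
        expect_lte(abs(count_extrema(imf) - count_zc(imf)), 1)
    }
  })
  # constant signal: nothing to extract
  d0 <- emd(rep(2, 50))
  expect_length(d0$imfs, 0)
  expect_equal(d0$residual, rep(2, 50))
  expect_error(emd(numeric(0)), class = "pcgfusion_empty_signal")
})

test_that("two well-separated tones split with the fast tone leading", {
  x <- two_tone(n = 4000, f1 = 25, f2 = 150)
  d <- emd(x, eemd_config(max_imfs = 6))
  expect_gte(length(d$imfs), 2)
  expect_gt(oracle_band_fraction(d$imfs[[1]], 4000, 100, 2000), 0.8)
})

test_that("eemd degenerates to emd and is seed-deterministic", {
  x <- two_tone(n = 1200)
  expect_identical(eemd(x, eemd_config(n_trials = 1, noise_sd = 0)),
                   emd(x, eemd_config()))
  cfg <- eemd_config(n_trials = 5, noise_sd = 0.2, seed = 7)
  expect_identical(eemd(x, cfg), eemd(x, cfg))
})

test_that("ensemble averaging reduces mode mixing of a noisy two-tone signal", {
  withr::with_seed(3, {
    x <- two_tone(n = 3000, f1 = 20, f2 = 200) + rnorm(3000, sd = 0.2)
  })
  mix_index <- function(d) oracle_band_fraction(d$imfs[[1]], 4000, 0, 50)
  plain <- emd(x, eemd_config(max_imfs = 8))
  ens <- eemd(x, eemd_config(n_trials = 30, noise_sd = 0.2, max_imfs = 8, seed = 1))
  expect_lte(mix_index(ens), mix_index(plain))
})

test_that("LMS step-size bound follows the misadjustment formula", {
  expect_equal(lms_mu_bound(4, 1), 1 / 6)
  expect_equal(lms_mu_bound(1, 2 / 3), 1)
  expect_lt(lms_mu_bound(4, 100), lms_mu_bound(4, 1))
  expect_error(lms_mu_bound(4, 0), class = "pcgfusion_bad_power")
})

test_that("LMS identifies a planted FIR below the bound and diverges above it", {
  withr::with_seed(2, {
    n <- 10000
    ref <- rnorm(n)
    h <- c(0.5, -0.3, 0.2, 0.1)
    prim <- as.numeric(stats::filter(ref, h, sides = 1))
    prim[is.na(prim)] <- 0
  })
  mu_max <- lms_mu_bound(4, mean(ref^2))
  fit <- lms_filter(prim, ref, lms_config(4, mu = 0.5 * mu_max))
  expect_lt(sqrt(sum((fit$coefficients - h)^2)), 1e-2)
  expect_length(fit$error, n)

  # mu = 0 never adapts: output is the primary, taps stay zero
  fit0 <- lms_filter(prim, ref, lms_config(4, mu = 0))
  expect_equal(fit0$clean, prim)
  expect_equal(fit0$coefficients, rep(0, 4))

  # far above the bound the error power grows instead of shrinking
  expect_warning(fit3 <- lms_filter(prim, ref, lms_config(4, mu = 3 * mu_max)))
  tail_p <- mean(tail(fit3$error, n %/% 10)^2)
  head_p <- mean(head(fit3$error, n %/% 10)^2)
  expect_gt(tail_p, head_p)

  expect_error(lms_filter(1:5, 1:4, lms_config(2)),
               class = "pcgfusion_length_mismatch")
})

test_that("convergence-time estimate matches its closed form", {
  expect_equal(lms_convergence_time(1, 1, 1, 0.25), 1)
  expect_equal(lms_convergence_time(4, 2, 1, 0.125), 1)
  expect_equal(lms_convergence_time(3, 1, 2, 0.1),
               2 * lms_convergence_time(3, 1, 2, 0.2))
  expect_error(lms_convergence_time(1, 0), class = "pcgfusion_bad_eigenvalue")
})

test_that("snr_db follows its definition including edge cases", {
  expect_equal(snr_db(c(3, 1), c(3, 2)), 10 * log10(10))
  expect_equal(snr_db(c(1, 1), c(2, 0)), 0)
  expect_identical(snr_db(1:4, 1:4), Inf)
  expect_error(snr_db(c(0, 0), c(1, 1)), class = "pcgfusion_zero_power")
})

test_that("denoising preserves clean recordings and length", {
  rec <- simulate_recording("MR", sim_config(snr_db = 60, duration_s = 2, seed = 3),
                            return_parts = TRUE)
  den <- denoise_pcg(rec, eemd_config(n_trials = 1, noise_sd = 0))
  expect_length(den$samples, length(rec$samples))
  expect_gte(snr_db(attr(rec, "clean"), den$samples), -1)
})

test_that("denoising lifts the SNR of a noisy synthetic recording", {
  rec <- simulate_recording("AS", sim_config(snr_db = 0, duration_s = 3, seed = 4),
                            return_parts = TRUE)
  den <- denoise_pcg(rec, eemd_config(n_trials = 4, noise_sd = 0.1,
                                      max_imfs = 8, seed = 4))
  expect_gt(snr_db(attr(rec, "clean"), den$samples),
            snr_db(attr(rec, "clean"), rec$samples) + 3)
})
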