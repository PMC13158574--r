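cfg <- frame_config()

test_that("frame counts follow the closed form", {
  a <- audio_signal(numeric(SR), SR)       # 1.000 s
  fr <- frame_signal(a, cfg)
  expect_identical(fr$n, 98L)              # 1 + (16000-400)/160
  expect_true(all(fr$frames == 0))
  expect_error(frame_signal(audio_signal(numeric(100), SR), cfg),
               "shorter")
  expect_error(frame_config(frame_length = 0.01, hop = 0.01), "framing")
})

test_that("F0 is recovered within 2 Hz across the speech band", {
  for (f in c(80, 120, 220, 300, 400)) {
    c0 <- f0_contour(tone(f), cfg)$f0
    expect_lt(abs(mean(c0$values[c0$voiced_mask]) - f), 2, label = paste(f))
    expect_gt(mean(c0$voiced_mask), 0.8)
  }
})

test_that("unvoiced frames carry F0 = 0 and white noise is unvoiced", {
  set.seed(2)
  a <- audio_signal(0.3 * rnorm(2 * SR), SR)
  f0 <- f0_contour(a, cfg)$f0
  expect_lt(mean(f0$voiced_mask), 0.2)
  expect_true(all(f0$values[!f0$voiced_mask] == 0))
})

test_that("RMS and ZCR behave as definitions require", {
  sq <- audio_signal(rep(c(rep(1, 80), rep(-1, 80)), 100), SR)  # 100 Hz
  rz <- rms_zcr(sq, cfg)
  expect_lt(abs(mean(rz$zcr$values) - 200), 10)

  sil <- rms_zcr(audio_signal(numeric(SR), SR), cfg)
  expect_true(all(sil$rms$values == 0))

  a <- tone(220)
  half <- audio_signal(a$samples * 0.5, SR)
  expect_equal(rms_zcr(half, cfg)$rms$values,
               0.5 * rms_zcr(a, cfg)$rms$values, tolerance = 1e-12)
  expect_equal(rms_zcr(half, cfg)$zcr$values, rms_zcr(a, cfg)$zcr$values)
})

test_that("RASTA filter matches its stated transfer function", {
  # impulse response by direct recursion oracle
  b <- c(0.2, 0.1, 0, -0.1, -0.2)
  h <- numeric(30)
  for (n in 1:30)
    h[n] <- (if (n <= 5) b[n] else 0) + (if (n > 1) 0.94 * h[n - 1] else 0)
  imp <- contour("audSpec[0]", c(1, numeric(29)), 100)
  expect_equal(rasta_filter(imp)$values, h, tolerance = 1e-12)

  # DC is killed: constant trajectory decays to ~0 after settling
  const <- contour("audSpec[1]", rep(3, 400), 100)
  out <- rasta_filter(const)$values
  expect_lt(max(abs(out[300:400])), 1e-3)
  expect_match(rasta_filter(imp)$name, "audSpec_Rfilt")
})

test_that("mel spectrum and MFCC have the right shapes and DCT", {
  a <- tone(400, dur = 1)   # period divides the hop: identical frames
  bands <- mel_auditory_spectrum(a, cfg, 26L)
  expect_length(bands, 26L)
  expect_error(mel_auditory_spectrum(a, cfg, 1L), "bands")

  cs <- mfcc(a, cfg, n_coef = 12L)
  expect_length(cs, 12L)
  expect_error(mfcc(a, cfg, n_coef = 26L, n_bands = 26L), "smaller")

  # identical frames -> constant coefficients
  for (k in c(1, 6, 12))
    expect_lt(stats::sd(cs[[k]]$values[5:90]), 1e-6)

  # brute-force DCT oracle on one frame of log mel energies
  fr <- adspeech:::frame_signal(a, cfg)
  sp <- adspeech:::frame_spectra(fr)
  fb <- adspeech:::mel_filterbank(26L, sp$freqs)
  logE <- log(as.numeric(fb %*% sp$mag[, 10]^2) + 1e-10)
  n <- 26
  oracle <- vapply(1:12, function(k)
    sqrt(2 / n) * sum(logE * cos(pi * k * (2 * (0:(n - 1)) + 1) / (2 * n))),
    numeric(1))
  got <- vapply(cs, function(ct) ct$values[10], numeric(1))
  expect_equal(got, oracle, tolerance = 1e-9)
})

test_that("spectral descriptors match point-spectrum expectations", {
  s1 <- spectral_descriptors(tone(1000), cfg)
  expect_lt(abs(mean(s1$centroid$values) - 1000), 40)   # one bin width
  expect_lt(mean(s1$variance$values), 50^2 * 10)
  expect_lt(max(s1$flux$values[-1]), 1e-6 * max(s1$flux$values[1] + 1))

  two <- audio_signal(0.4 * (sin(2 * pi * 500 * seq(0, 2, by = 1 / SR)) +
                               sin(2 * pi * 1500 * seq(0, 2, by = 1 / SR))),
                      SR)
  s2 <- spectral_descriptors(two, cfg)
  expect_lt(abs(mean(s2$centroid$values) - 1000), 40)
})

test_that("log HNR maps autocorrelation ratios per the closed form", {
  an <- list(ratio = c(0.5, 0.99, 1e-12), voiced = c(TRUE, TRUE, FALSE),
             frames = list(frame_rate = 100))
  h <- adspeech:::hnr_from_analysis(an)
  expect_equal(h$values[1], 0, tolerance = 1e-9)
  expect_equal(h$values[2], 19.956, tolerance = 1e-3)
  expect_true(is.na(h$values[3]))
  expect_true(all(h$values <= 100, na.rm = TRUE))
})

test_that("HNR decreases strictly with injected noise", {
  hnrs <- vapply(c(0.01, 0.05, 0.2, 0.5), function(nl) {
    set.seed(5)
    x <- sin(2 * pi * 150 * seq(0, 2, by = 1 / SR)) +
      rnorm(2 * SR + 1, 0, nl)
    mean(log_hnr(audio_signal(x / max(abs(x)), SR), cfg)$values,
         na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(hnrs) < 0))
})

test_that("acoustic measures are amplitude-scale invariant", {
  fx <- voiced_fixture(2, noise = 0.02, seed = 21)
  a <- fx$audio
  half <- audio_signal(a$samples * 0.5, SR)
  f0a <- f0_contour(a, cfg)$f0; f0b <- f0_contour(half, cfg)$f0
  expect_equal(f0a$values, f0b$values, tolerance = 1e-6)
  expect_equal(jitter_local(period_track(a, f0a, cfg)),
               jitter_local(period_track(half, f0b, cfg)),
               tolerance = 1e-6)
  expect_equal(shimmer_local(period_track(a, f0a, cfg)),
               shimmer_local(period_track(half, f0b, cfg)),
               tolerance = 1e-6)
  expect_equal(log_hnr(a, cfg)$values, log_hnr(half, cfg)$values,
               tolerance = 1e-6)
})
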