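test_that("worked functional examples hold", {
  f <- apply_functionals(contour("x", c(1, 2, 3, 4), 100))
  expect_equal(f[["mean"]], 2.5)
  expect_equal(f[["range"]], 3)
  expect_equal(f[["linreg_slope"]], 1)
  expect_equal(f[["skewness"]], 0)

  fc <- apply_functionals(contour("x", rep(5, 10), 100))
  expect_equal(fc[["std"]], 0)
  expect_true(is.na(fc[["kurtosis_fisher"]]))
  expect_equal(fc[["numPeaks"]], 0)
  expect_equal(fc[["mode"]], 5)

  # distribution-symmetric contour: mode ~ mean, Pearson mode skewness ~ 0
  v <- c(-2, -1, -1, 0, 0, 0, 0, 1, 1, 2)
  fs <- apply_functionals(contour("x", rep(v, 10), 100))
  expect_lt(abs(fs[["pearson_mode_skewness"]]), 0.15)

  short <- apply_functionals(contour("x", c(1, 2, 3), 100))
  expect_true(all(is.na(short)))
})

test_that("functionals agree with a brute-force reference", {
  # independent straightforward implementations
  ref <- function(v, frame_rate) {
    n <- length(v); mu <- mean(v); m2 <- mean((v - mu)^2)
    q <- unname(quantile(v, c(0.01, 0.25, 0.5, 0.75, 0.99), type = 7))
    tt <- 0:(n - 1)
    lf <- lm(v ~ tt)
    qf <- lm(v ~ tt + I(tt^2))
    thr <- min(v) + 0.25 * (max(v) - min(v))
    r <- rle(v > thr)
    segs <- r$lengths[r$values]
    pk <- sum(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] > v[3:n] &
                v[2:(n - 1)] > q[4])
    c(mean = mu, std = sd(v), variance = var(v) * 1, min = min(v),
      max = max(v), range = max(v) - min(v),
      quartile1 = q[2], quartile2 = q[3], quartile3 = q[4],
      `iqr1-3` = q[4] - q[2], percentile99 = q[5],
      skewness = mean((v - mu)^3) / m2^1.5,
      kurtosis_pearson = mean((v - mu)^4) / m2^2,
      linreg_slope = unname(coef(lf)[2]),
      linreg_offset = unname(coef(lf)[1]),
      qreg1 = unname(coef(qf)[2]),
      qregerrQ = sqrt(mean(residuals(qf)^2)),
      meanSegLen = if (length(segs)) mean(segs) / frame_rate else 0,
      riseTime = mean(diff(v) > 0),
      numPeaks = pk)
  }
  set.seed(31)
  for (i in 1:200) {
    n <- sample(5:200, 1)
    v <- rnorm(n) * 10^runif(1, -2, 2) + rnorm(1, 0, 5)
    got <- apply_functionals(contour("x", v, 100))
    want <- ref(v, 100)
    for (nm in names(want))
      expect_equal(got[[nm]], want[[nm]], tolerance = 1e-9, label = nm)
  }
})

test_that("bounded functionals stay in range", {
  set.seed(8)
  for (i in 1:50) {
    v <- cumsum(rnorm(sample(10:300, 1)))
    f <- apply_functionals(contour("x", v, 100))
    expect_gte(f[["riseTime"]], 0); expect_lte(f[["riseTime"]], 1)
    expect_gte(f[["ratioPeaks"]], 0); expect_lte(f[["ratioPeaks"]], 1)
    for (q in c("quartile1", "quartile2", "quartile3", "percentile1",
                "percentile99", "mode"))
      expect_true(f[[q]] >= f[["min"]] - 1e-12 &&
                    f[[q]] <= f[["max"]] + 1e-12, info = q)
  }
})

test_that("SMA smoothing and deltas match hand computations", {
  expect_equal(smooth_sma(contour("x", c(0, 3, 0), 100), 3)$values,
               c(1.5, 1, 1.5))
  expect_equal(smooth_sma(contour("x", c(2, 2, 2), 100), 3)$values,
               c(2, 2, 2))
  expect_equal(smooth_sma(contour("x", 1:5, 100), 1)$values, 1:5)
  expect_error(smooth_sma(contour("x", 1:5, 100), 2), "odd")

  expect_equal(delta_contour(contour("x", c(0, 1, 4), 100))$values,
               c(1, 2, 3))
  ramp <- delta_contour(contour("x", 2 * (0:9), 100))
  expect_true(all(abs(ramp$values - 2) < 1e-12))
  expect_true(all(delta_contour(contour("x", rep(7, 5), 100))$values == 0))
  expect_error(delta_contour(contour("x", c(1, 2), 100)), "short")
})

test_that("feature names render and parse as an identity", {
  cases <- expand.grid(lld = c("F0final", "audSpec_Rfilt[21]", "mfcc[3]",
                               "pcm_RMSenergy", "logHNR"),
                       fun = c("mean", "iqr1-2", "kurtosis_fisher",
                               "pctlrange1-99", "lpc3", "meanSegLen"),
                       de = c(TRUE, FALSE), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    nm <- render_feature_name(cases$lld[i], cases$fun[i], cases$de[i])
    p <- parse_feature_name(nm)
    expect_identical(p$lld, cases$lld[i])
    expect_identical(p$functional, cases$fun[i])
    expect_identical(p$delta, cases$de[i])
  }
  expect_error(parse_feature_name("nonsense"), "unparseable")
})

test_that("recording featurization is deterministic with a full grid", {
  fx <- voiced_fixture(1.5, noise = 0.05, seed = 55, dur = 2)
  grid <- default_lld_grid(n_bands = 4L, n_mfcc = 3L)
  f1 <- featurize_recording(fx$audio, grid = grid)
  f2 <- featurize_recording(fx$audio, grid = grid)
  expect_identical(f1, f2)
  # grid cardinality: 19 LLDs (4 rasta + 3 mfcc + rms + zcr + 3 spectral +
  # hnr + voicing + trailing voicing + F0 + ampEnv + jitter + shimmer)
  # x 33 functionals x {base, delta}
  expect_length(f1, 19 * 33 * 2)
  expect_true(all(grepl("^(acoustic|prosodic)\\.", names(f1))))
  parsed <- lapply(sub("^(acoustic|prosodic)\\.", "", names(f1)),
                   parse_feature_name)
  expect_length(parsed, length(f1))
  expect_error(featurize_recording(audio_signal(numeric(100), SR)),
               "shorter")
})

test_that("silent audio yields valid energy but missing voiced features", {
  sil <- audio_signal(numeric(2 * SR), SR)
  f <- featurize_recording(sil, grid = default_lld_grid(n_bands = 2L,
                                                        n_mfcc = 0L,
                                                        spectral = FALSE,
                                                        deltas = FALSE))
  expect_equal(f[["acoustic.pcm_RMSenergy_sma_mean"]], 0)
  expect_true(is.na(f[["acoustic.logHNR_sma_mean"]]))
  expect_true(is.na(f[["prosodic.F0final_sma_mean"]]))
})
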