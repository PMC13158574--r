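#' Frame analysis configuration
#'
#' @param frame_length Frame length in seconds (default 25 ms).
#' @param hop Hop between frame starts in seconds (default 10 ms).
#' @param window Analysis window, `"hann"` or `"hamming"`.
#' @param f0_floor,f0_ceil Pitch search band in Hz.
#' @param voicing_threshold Normalized-autocorrelation peak ratio above which
#'   a frame is voiced.
#' @return A `frame_config` list.
#' @export
frame_config <- function(frame_length = 0.025, hop = 0.010,
                         window = c("hann", "hamming"),
                         f0_floor = 75, f0_ceil = 500,
                         voicing_threshold = 0.45) {
  window <- match.arg(window)
  if (!(frame_length > hop && hop > 0))
    stop("invalid framing: need frame_length > hop > 0")
  if (!(f0_ceil > f0_floor && f0_floor > 0))
    stop("invalid pitch band: need f0_ceil > f0_floor > 0")
  structure(list(frame_length = frame_length, hop = hop, window = window,
                 f0_floor = f0_floor, f0_ceil = f0_ceil,
                 voicing_threshold = voicing_threshold),
            class = "frame_config")
}

#' A named per-frame descriptor track
#'
#' @param name LLD name.
#' @param values Numeric vector, one value per frame.
#' @param frame_rate Frames per second.
#' @param voiced_mask Optional logical vector of the same length.
#' @return A `contour` object.
#' @export
contour <- function(name, values, frame_rate, voiced_mask = NULL) {
  if (!is.null(voiced_mask) && length(voiced_mask) != length(values))
    stop("voiced mask length mismatch")
  stopifnot(frame_rate > 0)
  structure(list(name = name, values = as.numeric(values),
                 frame_rate = frame_rate, voiced_mask = voiced_mask),
            class = "contour")
}

#' Slice a signal into analysis frames
#'
#' `n_frames = 1 + floor((n - frame_len) / hop)` in samples; both the
#' windowed and raw frame matrices are returned (columns = frames).
#'
#' @param a An `adspeech_audio`.
#' @param cfg A [frame_config()].
#' @return List with `frames` (windowed), `raw`, `flen`, `hop`, `n`,
#'   `frame_rate`, `times` (frame-center seconds).
#' @export
frame_signal <- function(a, cfg = frame_config()) {
  sr <- a$sample_rate
  flen <- as.integer(round(cfg$frame_length * sr))
  hop <- as.integer(round(cfg$hop * sr))
  n_samp <- length(a$samples)
  if (n_samp < flen) stop("signal shorter than one frame")
  n <- 1L + (n_samp - flen) %/% hop
  idx <- outer(seq_len(flen), (seq_len(n) - 1L) * hop, `+`)
  raw <- matrix(a$samples[idx], nrow = flen)
  win <- if (cfg$window == "hann")
    0.5 - 0.5 * cos(2 * pi * (seq_len(flen) - 1) / (flen - 1))
  else 0.54 - 0.46 * cos(2 * pi * (seq_len(flen) - 1) / (flen - 1))
  list(frames = raw * win, raw = raw, flen = flen, hop = hop, n = n,
       frame_rate = sr / hop, sample_rate = sr,
       times = ((seq_len(n) - 1L) * hop + flen / 2) / sr)
}

# Shared normalized-autocorrelation analysis: per frame the lag-domain ACF,
# the best peak in the pitch band (parabolic-interpolated), its ratio to
# r(0), and the voicing decision.
acf_analysis <- function(a, cfg = frame_config()) {
  fr <- frame_signal(a, cfg)
  sr <- fr$sample_rate
  x <- fr$raw
  x <- sweep(x, 2, colMeans(x))
  nfft <- 2^ceiling(log2(2L * fr$flen))
  pad <- rbind(x, matrix(0, nfft - fr$flen, fr$n))
  P <- Mod(stats::mvfft(pad))^2
  acf <- Re(stats::mvfft(P, inverse = TRUE)) / nfft
  # unbiased lag correction so a stationary periodic frame has r(T) ~ r(0)
  lags <- 0:(fr$flen - 1L)
  acf <- acf[lags + 1L, , drop = FALSE] * (fr$flen / (fr$flen - lags))
  r0 <- acf[1, ]

  lmin <- max(2L, floor(sr / cfg$f0_ceil))
  lmax <- min(fr$flen - 2L, ceiling(sr / cfg$f0_floor))
  if (lmax <= lmin) stop("pitch band incompatible with frame length")
  band <- acf[(lmin:lmax) + 1L, , drop = FALSE]
  ratio_band <- sweep(band, 2, pmax(r0, 1e-20), `/`)
  # candidate lags = local maxima of the ACF in the pitch band; an octave
  # cost of 0.1 per octave discourages subharmonic (period-doubled) picks
  nb <- nrow(band)
  cand <- rbind(TRUE,
                band[2:(nb - 1), , drop = FALSE] >=
                  band[1:(nb - 2), , drop = FALSE] &
                band[2:(nb - 1), , drop = FALSE] >=
                  band[3:nb, , drop = FALSE],
                TRUE)
  score <- ratio_band - 0.1 * log2((lmin:lmax) / lmin)
  score[!cand] <- -Inf
  pk_rel <- max.col(t(score), ties.method = "first")
  pk_lag <- pk_rel + lmin - 1L

  # parabolic interpolation around the integer-lag peak (acf row k+1 = lag k)
  i <- seq_len(fr$n)
  ym <- acf[cbind(pk_lag + 1L, i)]
  yl <- acf[cbind(pk_lag, i)]
  yr <- acf[cbind(pk_lag + 2L, i)]
  denom <- yl - 2 * ym + yr
  delta <- ifelse(abs(denom) > 1e-30, 0.5 * (yl - yr) / denom, 0)
  delta <- pmax(pmin(delta, 0.5), -0.5)
  lag_i <- pk_lag + delta
  peak_val <- ym - 0.25 * (yl - yr) * delta

  ratio <- ifelse(r0 > 1e-20, peak_val / r0, 0)
  ratio <- pmax(pmin(ratio, 1), 0)
  voiced <- ratio >= cfg$voicing_threshold & r0 > 1e-20
  f0 <- ifelse(voiced, sr / lag_i, 0)
  list(frames = fr, f0 = f0, ratio = ratio, voiced = voiced, r0 = r0)
}

#' F0 and voicing contours
#'
#' Normalized autocorrelation pitch tracker: per frame the ACF peak in the
#' `[f0_floor, f0_ceil]` band is located with parabolic interpolation;
#' frames whose peak ratio reaches `voicing_threshold` are voiced with
#' `F0 = sample_rate / lag`, others carry `F0 = 0`.
#'
#' @inheritParams frame_signal
#' @return List of contours `f0` (Hz, masked) and `voicing_prob`.
#' @export
f0_contour <- function(a, cfg = frame_config()) {
  f0_from_analysis(acf_analysis(a, cfg))
}

f0_from_analysis <- function(an) {
  fr <- an$frames
  list(f0 = contour("F0final", an$f0, fr$frame_rate, an$voiced),
       voicing_prob = contour("voicingProb", an$ratio, fr$frame_rate))
}

#' Frame energy and zero-crossing rate
#'
#' @inheritParams frame_signal
#' @return List of contours `rms` (of windowed samples) and `zcr`
#'   (sign changes per second).
#' @export
rms_zcr <- function(a, cfg = frame_config()) {
  fr <- frame_signal(a, cfg)
  rms <- sqrt(colMeans(fr$frames^2))
  # crossings over the full frame span (borrowing the next frame's first
  # sample where available), so frame-aligned periodic signals are not
  # undercounted at the frame boundary
  starts <- (seq_len(fr$n) - 1L) * fr$hop
  nxt <- a$samples[pmin(starts + fr$flen + 1L, length(a$samples))]
  ext <- rbind(fr$raw, nxt)
  sgn <- sign(ext)
  changes <- colSums(abs(diff(sgn)) > 1e-12 & sgn[-1, , drop = FALSE] != 0 &
                       sgn[-nrow(sgn), , drop = FALSE] != 0)
  zcr <- changes / cfg$frame_length
  list(rms = contour("pcm_RMSenergy", rms, fr$frame_rate),
       zcr = contour("pcm_zcr", zcr, fr$frame_rate))
}

# mel scale helpers
hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# magnitude spectra of windowed frames: (nfft/2 + 1) x n matrix + bin freqs
frame_spectra <- function(fr) {
  nfft <- 2^ceiling(log2(fr$flen))
  pad <- rbind(fr$frames, matrix(0, nfft - fr$flen, fr$n))
  S <- stats::mvfft(pad)
  keep <- seq_len(nfft %/% 2 + 1L)
  list(mag = Mod(S[keep, , drop = FALSE]),
       freqs = (keep - 1L) * fr$sample_rate / nfft, nfft = nfft)
}

#' Log mel-band auditory spectrum
#'
#' Triangular mel filterbank over the power spectrum, log-compressed.
#'
#' @inheritParams frame_signal
#' @param n_bands Number of mel bands (default 26).
#' @return List of `n_bands` contours named `audSpec[k]`.
#' @export
mel_auditory_spectrum <- function(a, cfg = frame_config(), n_bands = 26L) {
  fr <- frame_signal(a, cfg)
  mel_from_spectra(frame_spectra(fr), n_bands, fr$frame_rate)
}

mel_from_spectra <- function(sp, n_bands, frame_rate) {
  if (n_bands < 2L) stop("need at least 2 mel bands")
  fb <- mel_filterbank(n_bands, sp$freqs)
  E <- fb %*% (sp$mag^2)
  logE <- log(E + 1e-10)
  lapply(seq_len(n_bands), function(b)
    contour(sprintf("audSpec[%d]", b - 1L), logE[b, ], frame_rate))
}

mel_filterbank <- function(n_bands, freqs) {
  fmax <- max(freqs)
  edges <- mel_to_hz(seq(hz_to_mel(0), hz_to_mel(fmax),
                         length.out = n_bands + 2L))
  fb <- matrix(0, n_bands, length(freqs))
  for (b in seq_len(n_bands)) {
    lo <- edges[b]; mid <- edges[b + 1L]; hi <- edges[b + 2L]
    up <- (freqs - lo) / (mid - lo)
    dn <- (hi - freqs) / (hi - mid)
    fb[b, ] <- pmax(0, pmin(up, dn))
  }
  fb
}

#' RASTA band-pass filtering of a log-band trajectory
#'
#' The standard RASTA transfer function: FIR numerator
#' `(0.2, 0.1, 0, -0.1, -0.2)` over a single pole at 0.94, applied along the
#' frame axis of a log mel-band contour. Suppresses the DC component
#' (stationary spectral coloration) and very fast frame-to-frame noise.
#'
#' @param band A [contour()] (a log mel-band trajectory).
#' @return The filtered contour, renamed `audSpec_Rfilt[...]`.
#' @export
rasta_filter <- function(band) {
  b <- c(0.2, 0.1, 0, -0.1, -0.2)
  y <- as.numeric(signal::filter(signal::Arma(b = b, a = c(1, -0.94)),
                                 band$values))
  nm <- sub("^audSpec", "audSpec_Rfilt", band$name)
  contour(nm, y, band$frame_rate, band$voiced_mask)
}

#' Mel-frequency cepstral coefficients
#'
#' Orthonormal DCT-II of the log mel-band energies; coefficients `1..n_coef`
#' (the energy coefficient c0 is excluded).
#'
#' @inheritParams mel_auditory_spectrum
#' @param n_coef Number of cepstral coefficients (default 12).
#' @return List of `n_coef` contours named `mfcc[k]`.
#' @export
mfcc <- function(a, cfg = frame_config(), n_coef = 12L, n_bands = 26L) {
  if (n_coef >= n_bands) stop("n_coef must be smaller than n_bands")
  mfcc_from_bands(mel_auditory_spectrum(a, cfg, n_bands), n_coef)
}

mfcc_from_bands <- function(bands, n_coef) {
  n_bands <- length(bands)
  if (n_coef >= n_bands) stop("n_coef must be smaller than n_bands")
  L <- do.call(rbind, lapply(bands, `[[`, "values"))
  D <- dct_matrix(n_bands)[seq_len(n_coef) + 1L, , drop = FALSE]
  C <- D %*% L
  fr_rate <- bands[[1]]$frame_rate
  lapply(seq_len(n_coef), function(k)
    contour(sprintf("mfcc[%d]", k), C[k, ], fr_rate))
}

# orthonormal DCT-II matrix (rows = coefficients, row 1 = c0)
dct_matrix <- function(n) {
  k <- 0:(n - 1)
  M <- sqrt(2 / n) * cos(pi * outer(k, (2 * k + 1) / (2 * n)))
  M[1, ] <- M[1, ] / sqrt(2)
  M
}

#' Spectral centroid, variance and flux
#'
#' Per frame, centroid and variance are the magnitude-weighted mean and
#' variance of frequency; flux is the L2 norm of the magnitude difference
#' between consecutive frames (0 for the first frame).
#'
#' @inheritParams frame_signal
#' @return List of contours `centroid`, `variance`, `flux`.
#' @export
spectral_descriptors <- function(a, cfg = frame_config()) {
  fr <- frame_signal(a, cfg)
  spectral_from_spectra(frame_spectra(fr), fr$n, fr$frame_rate)
}

spectral_from_spectra <- function(sp, n, frame_rate) {
  fr <- list(n = n, frame_rate = frame_rate)
  wsum <- colSums(sp$mag)
  wsum[wsum < 1e-20] <- 1e-20
  centroid <- colSums(sp$freqs * sp$mag) / wsum
  variance <- colSums(outer(sp$freqs, rep(1, fr$n))^2 * sp$mag) / wsum -
    centroid^2
  variance <- pmax(variance, 0)
  flux <- c(0, sqrt(colSums(
    (sp$mag[, -1, drop = FALSE] - sp$mag[, -fr$n, drop = FALSE])^2)))
  list(centroid = contour("pcm_fftMag_spectralCentroid", centroid,
                          fr$frame_rate),
       variance = contour("pcm_fftMag_spectralVariance", variance,
                          fr$frame_rate),
       flux = contour("pcm_fftMag_spectralFlux", flux, fr$frame_rate))
}

#' Log harmonics-to-noise ratio contour
#'
#' Per voiced frame, with `r` the normalized autocorrelation at the F0 lag,
#' `HNR_dB = 10 log10(r / (1 - r))`, clipped to `[-100, 100]`. Unvoiced
#' frames are masked out.
#'
#' @inheritParams frame_signal
#' @return A masked [contour()] named `logHNR`.
#' @export
log_hnr <- function(a, cfg = frame_config()) {
  hnr_from_analysis(acf_analysis(a, cfg))
}

hnr_from_analysis <- function(an) {
  r <- pmin(pmax(an$ratio, 1e-10), 1 - 1e-10)
  hnr <- 10 * log10(r / (1 - r))
  hnr <- pmin(pmax(hnr, -100), 100)
  hnr[!an$voiced] <- NA_real_
  contour("logHNR", hnr, an$frames$frame_rate, an$voiced)
}
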