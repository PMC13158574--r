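#' The functional catalog
#'
#' Ordered list of the statistical functionals that map a per-frame contour
#' to scalar features. Every functional is defined for any finite contour of
#' at least 4 usable frames; shorter (or fully masked) contours yield `NA`
#' for every functional.
#'
#' Definitions beyond the standard moments/quantiles:
#' \itemize{
#'   \item `mode`: midpoint of the most populated of 20 equal-width bins
#'     (tie broken toward the bin whose center is nearest the mean);
#'   \item `pearson_mode_skewness`: `(mean - mode) / std`;
#'   \item `linreg_slope` / `linreg_offset`: least-squares line over frame
#'     index (slope per frame);
#'   \item `qreg1`: the linear coefficient of a quadratic least-squares fit;
#'     `qregerrQ`: RMS residual of that fit;
#'   \item `lpc1..lpc3`: order-3 autocorrelation-method linear-prediction
#'     coefficients of the mean-removed contour;
#'   \item `meanSegLen` / `maxSegLen`: mean/max length (seconds) of maximal
#'     runs exceeding `min + 0.25 (max - min)`;
#'   \item `riseTime`: fraction of frame-to-frame differences that are
#'     positive;
#'   \item `numPeaks` / `ratioPeaks`: count of strict local maxima above the
#'     75th percentile, and that count divided by the number of frames;
#'   \item `upleveltime75`: fraction of frames above `min + 0.75 (max - min)`.
#' }
#'
#' @return Character vector of functional names.
#' @export
functional_catalog <- function() {
  c("mean", "std", "variance", "min", "max", "range",
    "quartile1", "quartile2", "quartile3",
    "iqr1-2", "iqr2-3", "iqr1-3",
    "percentile1", "percentile99", "pctlrange1-99",
    "skewness", "kurtosis_fisher", "kurtosis_pearson",
    "mode", "pearson_mode_skewness",
    "linreg_slope", "linreg_offset", "qreg1", "qregerrQ",
    "lpc1", "lpc2", "lpc3",
    "meanSegLen", "maxSegLen", "riseTime", "ratioPeaks",
    "upleveltime75", "numPeaks")
}

#' Render / parse feature names
#'
#' Features are named `<lld>_sma[_de]_<functional>`; `parse_feature_name()`
#' inverts `render_feature_name()` exactly (functionals are matched against
#' the catalog, so underscores inside LLD or functional names are safe).
#'
#' @param lld LLD name.
#' @param functional Functional name (must be in the catalog).
#' @param de Whether the feature is computed on the delta contour.
#' @return `render_feature_name()`: a string. `parse_feature_name()`: list
#'   with `lld`, `smoothed`, `delta`, `functional`, or error if unparseable.
#' @export
render_feature_name <- function(lld, functional, de = FALSE) {
  paste0(lld, "_sma", if (de) "_de" else "", "_", functional)
}

#' @rdname render_feature_name
#' @param name Feature name to parse.
#' @export
parse_feature_name <- function(name) {
  cat_names <- functional_catalog()
  alts <- paste(gsub("([][(){}^$.|*+?\\\\-])", "\\\\\\1", cat_names),
                collapse = "|")
  pat <- paste0("^(.*)_sma(_de)?_(", alts, ")$")
  if (!grepl(pat, name)) stop("unparseable feature name: ", name)
  list(lld = sub(pat, "\\1", name),
       smoothed = TRUE,
       delta = sub(pat, "\\2", name) == "_de",
       functional = sub(pat, "\\3", name))
}

#' Simple-moving-average smoothing of a contour
#'
#' Centered moving average with an odd window; edges average the available
#' samples. The voiced mask is carried through unchanged.
#'
#' @param c A [contour()].
#' @param window Odd window length in frames (1 = identity).
#' @return The smoothed contour (name suffixed implicitly by the caller).
#' @export
smooth_sma <- function(c, window = 3L) {
  if (window %% 2L != 1L || window < 1L) stop("SMA window must be odd >= 1")
  v <- c$values
  n <- length(v)
  half <- (window - 1L) %/% 2L
  if (half == 0L || n == 0L) return(c)
  ok <- is.finite(v)
  cs <- cumsum(c(0, ifelse(ok, v, 0)))
  cn <- cumsum(c(0, ok))
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  m <- cn[hi + 1L] - cn[lo]
  out <- ifelse(m > 0, (cs[hi + 1L] - cs[lo]) / m, NA_real_)
  contour(c$name, out, c$frame_rate, c$voiced_mask)
}

#' Symmetric first difference of a contour
#'
#' `d_t = (x_(t+1) - x_(t-1)) / 2`, with one-sided differences at the two
#' endpoints.
#'
#' @param c A [contour()] of length >= 3.
#' @return The delta contour.
#' @export
delta_contour <- function(c) {
  v <- c$values
  n <- length(v)
  if (n < 3L) stop("contour too short for delta")
  d <- c(v[2] - v[1],
         (v[3:n] - v[1:(n - 2)]) / 2,
         v[n] - v[n - 1])
  contour(c$name, d, c$frame_rate, c$voiced_mask)
}

#' Apply the functional catalog to one contour
#'
#' @param c A [contour()].
#' @param catalog Functional names (default the full catalog).
#' @param voiced_only Restrict to frames where the voiced mask is `TRUE`
#'   (used for the F0/HNR/jitter/shimmer families).
#' @return Named numeric vector, one value per functional; all `NA` when
#'   fewer than 4 usable frames remain.
#' @export
apply_functionals <- function(c, catalog = functional_catalog(),
                              voiced_only = FALSE) {
  v <- c$values
  if (voiced_only && !is.null(c$voiced_mask)) v <- v[c$voiced_mask]
  v <- v[is.finite(v)]
  n <- length(v)
  out <- stats::setNames(rep(NA_real_, length(catalog)), catalog)
  if (n < 4L) return(out)

  mu <- mean(v); sdev <- stats::sd(v)
  m2 <- mean((v - mu)^2)
  q <- stats::quantile(v, c(0.01, 0.25, 0.5, 0.75, 0.99), names = FALSE,
                       type = 7)
  rng <- max(v) - min(v)
  md <- mode_binned(v, mu)

  tt <- seq_len(n) - 1
  lin <- unname(stats::lm.fit(cbind(1, tt), v)$coefficients)
  qfit <- stats::lm.fit(cbind(1, tt, tt^2), v)
  qcoef <- unname(qfit$coefficients)
  lpc <- lpc_coefs(v - mu, 3L)
  segs <- threshold_segments(v, 0.25)
  pk <- n_peaks(v, q[4])

  vals <- c(
    mean = mu, std = sdev, variance = sdev^2, min = min(v), max = max(v),
    range = rng,
    quartile1 = q[2], quartile2 = q[3], quartile3 = q[4],
    `iqr1-2` = q[3] - q[2], `iqr2-3` = q[4] - q[3], `iqr1-3` = q[4] - q[2],
    percentile1 = q[1], percentile99 = q[5], `pctlrange1-99` = q[5] - q[1],
    skewness = if (m2 > 1e-30) mean((v - mu)^3) / m2^1.5 else NA_real_,
    kurtosis_fisher = if (m2 > 1e-30) mean((v - mu)^4) / m2^2 - 3
                      else NA_real_,
    kurtosis_pearson = if (m2 > 1e-30) mean((v - mu)^4) / m2^2 else NA_real_,
    mode = md,
    pearson_mode_skewness = if (sdev > 1e-30) (mu - md) / sdev else NA_real_,
    linreg_slope = lin[2], linreg_offset = lin[1],
    qreg1 = qcoef[2],
    qregerrQ = sqrt(mean(qfit$residuals^2)),
    lpc1 = lpc[1], lpc2 = lpc[2], lpc3 = lpc[3],
    meanSegLen = if (length(segs)) mean(segs) / c$frame_rate else 0,
    maxSegLen = if (length(segs)) max(segs) / c$frame_rate else 0,
    riseTime = mean(diff(v) > 0),
    ratioPeaks = pk / n,
    upleveltime75 = if (rng > 0) mean(v > min(v) + 0.75 * rng) else 0,
    numPeaks = pk
  )
  out[catalog] <- vals[catalog]
  out
}

# midpoint of the most populated of 20 equal-width bins; ties broken toward
# the bin center nearest the mean
mode_binned <- function(v, mu, bins = 20L) {
  lo <- min(v); hi <- max(v)
  if (hi - lo < 1e-30) return(lo)
  edges <- seq(lo, hi, length.out = bins + 1L)
  idx <- pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L), bins)
  cnt <- tabulate(idx, bins)
  centers <- (edges[-1] + edges[-(bins + 1L)]) / 2
  best <- which(cnt == max(cnt))
  centers[best[which.min(abs(centers[best] - mu))]]
}

# order-p LPC by Levinson-Durbin on the biased autocorrelation
lpc_coefs <- function(v, p = 3L) {
  n <- length(v)
  r <- vapply(0:p, function(k) sum(v[1:(n - k)] * v[(1 + k):n]) / n,
              numeric(1))
  if (r[1] < 1e-30) return(rep(NA_real_, p))
  a <- numeric(0); e <- r[1]
  for (i in 1:p) {
    acc <- r[i + 1]
    if (i > 1) acc <- acc - sum(a * r[i:2])
    k <- acc / e
    a <- c(a - k * rev(a), k)
    e <- e * (1 - k^2)
    if (e < 1e-30) e <- 1e-30
  }
  a
}

# lengths of maximal runs where v exceeds min + frac * range
threshold_segments <- function(v, frac) {
  rng <- max(v) - min(v)
  if (rng < 1e-30) return(integer(0))
  above <- v > min(v) + frac * rng
  r <- rle(above)
  r$lengths[r$values]
}

# strict local maxima above a threshold
n_peaks <- function(v, thr) {
  n <- length(v)
  if (n < 3L) return(0L)
  mid <- v[2:(n - 1)]
  sum(mid > v[1:(n - 2)] & mid > v[3:n] & mid > thr)
}

#' Extract the full LLD-by-functional feature map of one recording
#'
#' Computes the configured low-level descriptors, smooths each with a
#' 3-frame simple moving average, applies the functional catalog to the
#' smoothed contour and (optionally) to its symmetric first difference, and
#' returns one named scalar per grid cell. Acoustic LLDs: RASTA-filtered log
#' mel bands, MFCC, RMS energy, zero-crossing rate, spectral
#' centroid/variance/flux, log HNR, voicing probability and trailing
#' (pre-pause) voicing probability. Prosodic LLDs: F0, amplitude envelope,
#' per-cycle jitter and shimmer. F0, HNR, jitter and shimmer functionals use
#' voiced frames only.
#'
#' @param a An `adspeech_audio` of at least 1 s.
#' @param cfg A [frame_config()].
#' @param grid A grid from [default_lld_grid()].
#' @return Named numeric vector; names are `acoustic.*` / `prosodic.*` with
#'   the `<lld>_sma[_de]_<functional>` scheme.
#' @export
featurize_recording <- function(a, cfg = frame_config(),
                                grid = default_lld_grid()) {
  if (a$duration < 1) stop("audio shorter than 1 s")
  fr_rate <- 1 / cfg$hop

  an <- acf_analysis(a, cfg)              # shared by F0, voicing, HNR
  f0c <- f0_from_analysis(an)
  n_frames <- length(f0c$f0$values)
  sp <- frame_spectra(an$frames)          # shared by mel/MFCC/spectral
  llds <- list()   # each: list(contour, group, voiced_only)
  add <- function(cont, group, voiced_only = FALSE) {
    llds[[length(llds) + 1L]] <<- list(c = cont, group = group,
                                       voiced = voiced_only)
  }

  bands <- NULL
  if (grid$n_bands > 0 || grid$n_mfcc > 0) {
    bands <- mel_from_spectra(sp, max(grid$n_bands, grid$n_mfcc + 1L),
                              fr_rate)
  }
  if (grid$n_bands > 0)
    for (b in bands[seq_len(grid$n_bands)]) add(rasta_filter(b), "acoustic")
  if (grid$n_mfcc > 0)
    for (m in mfcc_from_bands(bands, grid$n_mfcc)) add(m, "acoustic")
  en <- rms_zcr(a, cfg)
  add(en$rms, "acoustic")
  add(en$zcr, "acoustic")
  if (grid$spectral) {
    sdesc <- spectral_from_spectra(sp, n_frames, fr_rate)
    add(sdesc$centroid, "acoustic")
    add(sdesc$variance, "acoustic")
    add(sdesc$flux, "acoustic")
  }
  add(hnr_from_analysis(an), "acoustic", voiced_only = TRUE)
  add(f0c$voicing_prob, "acoustic")
  add(trailing_voicing(a, f0c$voicing_prob, cfg), "acoustic")

  add(f0c$f0, "prosodic", voiced_only = TRUE)
  amp <- contour("ampEnvelope", colMeans(abs(frame_signal(a, cfg)$raw)),
                 fr_rate)
  add(amp, "prosodic")
  pc <- perturbation_contours(a, f0c$f0, cfg, n_frames, fr_rate)
  add(pc$jitter, "prosodic", voiced_only = TRUE)
  add(pc$shimmer, "prosodic", voiced_only = TRUE)

  out <- numeric(0)
  for (entry in llds) {
    sm <- smooth_sma(entry$c, grid$sma_window)
    base <- apply_functionals(sm, grid$functionals, entry$voiced)
    names(base) <- paste0(entry$group, ".",
                          render_feature_name(entry$c$name,
                                              names(base), de = FALSE))
    out <- c(out, base)
    if (grid$deltas && length(sm$values) >= 3L) {
      d <- apply_functionals(delta_contour(sm), grid$functionals,
                             entry$voiced)
      names(d) <- paste0(entry$group, ".",
                         render_feature_name(entry$c$name,
                                             names(d), de = TRUE))
      out <- c(out, d)
    }
  }
  out
}

#' @rdname featurize_recording
#' @param n_bands Number of RASTA-filtered mel bands (0 disables).
#' @param n_mfcc Number of MFCCs (0 disables).
#' @param spectral Include spectral centroid/variance/flux.
#' @param deltas Also featurize the delta of each smoothed contour.
#' @param sma_window SMA smoothing window (odd frames).
#' @param functionals Functional subset to apply.
#' @export
default_lld_grid <- function(n_bands = 26L, n_mfcc = 12L, spectral = TRUE,
                             deltas = TRUE, sma_window = 3L,
                             functionals = functional_catalog()) {
  list(n_bands = n_bands, n_mfcc = n_mfcc, spectral = spectral,
       deltas = deltas, sma_window = sma_window, functionals = functionals)
}

#' @rdname featurize_recording
#' @export
reduced_lld_grid <- function() {
  default_lld_grid(n_bands = 6L, n_mfcc = 4L, spectral = FALSE,
                   deltas = FALSE,
                   functionals = c("mean", "std", "quartile1", "quartile3",
                                   "iqr1-3", "linreg_slope"))
}

# voicing probability over the trailing 500 ms of each detected speech
# region (the stretch just before every pause)
trailing_voicing <- function(a, vprob, cfg) {
  sil <- detect_silences(a, cfg = cfg)
  regions <- speech_regions(sil)
  n <- length(vprob$values)
  fr_rate <- vprob$frame_rate
  keep <- rep(FALSE, n)
  tt <- (seq_len(n) - 0.5) / fr_rate
  for (k in seq_len(nrow(regions))) {
    keep <- keep | (tt >= max(regions[k, 1], regions[k, 2] - 0.5) &
                      tt < regions[k, 2])
  }
  vals <- rep(NA_real_, n)
  vals[keep] <- vprob$values[keep]
  contour("voicingFinalUnclipped", vals, fr_rate, keep)
}
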