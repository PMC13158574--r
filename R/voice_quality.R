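#' Glottal cycle tracking
#'
#' Locates glottal cycle peaks in the voiced regions of a signal by
#' peak-picking within F0-predicted windows: starting from the first voiced
#' frame, each successive waveform peak is searched for in
#' `[0.8 T, 1.25 T]` after the previous one, where `T` is the local
#' F0-predicted period. Peak positions are refined by parabolic
#' interpolation for sub-sample accuracy. Cycles are grouped into
#' consecutive voiced runs; period differences are only taken within a run.
#'
#' @param a An `adspeech_audio`.
#' @param f0 The `f0` contour from [f0_contour()] (masked).
#' @param cfg The [frame_config()] used to compute `f0`.
#' @return A `period_track`: list with per-cycle `periods` (s),
#'   `amplitudes`, and `run` ids.
#' @export
period_track <- function(a, f0, cfg = frame_config()) {
  sr <- a$sample_rate
  x <- a$samples
  hop <- round(cfg$hop * sr)
  flen <- round(cfg$frame_length * sr)
  voiced <- if (is.null(f0$voiced_mask)) f0$values > 0 else f0$voiced_mask
  runs <- rle(voiced)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L

  periods <- numeric(0); amps <- numeric(0); run_id <- integer(0)
  rid <- 0L
  for (k in seq_along(runs$values)) {
    if (!runs$values[k] || runs$lengths[k] < 2L) next
    rid <- rid + 1L
    fidx <- starts[k]:ends[k]
    seg_start <- (fidx[1] - 1L) * hop + 1L
    seg_end <- min(length(x), (fidx[length(fidx)] - 1L) * hop + flen)
    period_at <- function(pos) {
      fi <- pmin(pmax(1L + (pos - 1L) %/% hop, fidx[1]), fidx[length(fidx)])
      f <- f0$values[fi]
      if (is.na(f) || f <= 0) f <- stats::median(f0$values[fidx], na.rm = TRUE)
      sr / f
    }
    # first peak: global max within ~1.5 predicted periods of the run start
    T0 <- period_at(seg_start)
    w_end <- min(seg_end, seg_start + round(1.5 * T0))
    if (w_end - seg_start < 4) next
    p <- seg_start + which.max(x[seg_start:w_end]) - 1L
    prev <- refine_peak(x, p)
    peaks <- prev["pos"]; pamps <- prev["amp"]
    repeat {
      T_loc <- period_at(round(prev["pos"]))
      lo <- round(prev["pos"] + 0.8 * T_loc)
      hi <- round(prev["pos"] + 1.25 * T_loc)
      if (hi > seg_end || hi - lo < 2) break
      p <- lo + which.max(x[lo:hi]) - 1L
      cur <- refine_peak(x, p)
      peaks <- c(peaks, cur["pos"]); pamps <- c(pamps, cur["amp"])
      prev <- cur
    }
    if (length(peaks) >= 2L) {
      Ts <- diff(peaks) / sr
      ok <- Ts >= 1 / cfg$f0_ceil & Ts <= 1 / cfg$f0_floor
      # amplitude of cycle i taken at its terminating peak
      periods <- c(periods, Ts[ok])
      amps <- c(amps, pamps[-1][ok])
      run_id <- c(run_id, rep(rid, sum(ok)))
    }
  }
  structure(list(periods = periods, amplitudes = amps, run = run_id),
            class = "period_track")
}

# parabolic refinement of an integer-sample peak -> sub-sample pos/amp
refine_peak <- function(x, p) {
  p <- round(unname(p))
  if (p <= 1L || p >= length(x)) return(c(pos = as.numeric(p), amp = x[p]))
  yl <- x[p - 1L]; ym <- x[p]; yr <- x[p + 1L]
  denom <- yl - 2 * ym + yr
  d <- if (abs(denom) > 1e-30) 0.5 * (yl - yr) / denom else 0
  d <- max(min(d, 0.5), -0.5)
  c(pos = p + d, amp = ym - 0.25 * (yl - yr) * d)
}

#' Local jitter and shimmer
#'
#' `jitter_local = mean |T_i - T_(i-1)| / mean T` over consecutive cycles of
#' the same voiced run; `shimmer_local` is the analogous statistic on peak
#' amplitudes. Both are dimensionless ratios (multiply by 100 for percent).
#' Fewer than 3 detected cycles yields `NA`.
#'
#' @param t A `period_track`.
#' @return A single ratio, or `NA_real_`.
#' @export
jitter_local <- function(t) perturbation_ratio(t$periods, t$run)

#' @rdname jitter_local
#' @export
shimmer_local <- function(t) perturbation_ratio(t$amplitudes, t$run)

perturbation_ratio <- function(v, run) {
  if (length(v) < 3L) return(NA_real_)
  d <- abs(diff(v))[diff(run) == 0]
  if (length(d) == 0L) return(NA_real_)
  mean(d) / mean(v)
}

#' Per-frame jitter and shimmer contours
#'
#' Cycle-to-cycle perturbations mapped back to analysis frames (each cycle's
#' local relative perturbation is assigned to the frame containing its
#' peak); frames without a cycle are masked.
#'
#' @inheritParams period_track
#' @param n_frames Number of frames of the parent analysis.
#' @param frame_rate Frames per second of the parent analysis.
#' @return List of masked contours `jitter` and `shimmer`.
#' @export
perturbation_contours <- function(a, f0, cfg = frame_config(),
                                  n_frames, frame_rate) {
  pt <- period_track(a, f0, cfg)
  jit <- rep(NA_real_, n_frames)
  shi <- rep(NA_real_, n_frames)
  if (length(pt$periods) >= 3L) {
    # cumulative position of each cycle end within the signal
    within <- which(diff(pt$run) == 0)
    meanT <- mean(pt$periods)
    meanA <- mean(pt$amplitudes)
    pos <- cumsum(pt$periods)
    for (i in within) {
      fi <- 1L + floor(pos[i] * frame_rate)
      if (fi >= 1L && fi <= n_frames) {
        jit[fi] <- abs(pt$periods[i + 1L] - pt$periods[i]) / meanT
        shi[fi] <- abs(pt$amplitudes[i + 1L] - pt$amplitudes[i]) / meanA
      }
    }
  }
  list(jitter = contour("jitterLocal", jit, frame_rate, !is.na(jit)),
       shimmer = contour("shimmerLocal", shi, frame_rate, !is.na(shi)))
}
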