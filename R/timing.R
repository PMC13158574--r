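#' Detect silent segments
#'
#' Frames whose RMS falls below `threshold_db` relative to the recording's
#' 95th-percentile frame RMS are marked silent; adjacent silent runs closer
#' than `min_gap` are merged. An all-silent recording yields one segment
#' spanning it.
#'
#' @param a An `adspeech_audio`.
#' @param threshold_db Threshold in dB below the 95th-percentile frame RMS.
#' @param min_gap Minimum speech gap (s) between silences before merging.
#' @param cfg A [frame_config()].
#' @return List with `segments` (list of `c(start, end)` in seconds,
#'   disjoint and ordered), `total_duration`, `energy_threshold_db`.
#' @export
detect_silences <- function(a, threshold_db = -35, min_gap = 0.005,
                            cfg = frame_config()) {
  fr <- frame_signal(a, cfg)
  rms <- sqrt(colMeans(fr$raw^2))
  ref <- stats::quantile(rms, 0.95, names = FALSE, type = 7)
  silent <- if (ref <= 0) rep(TRUE, fr$n)
            else 20 * log10(pmax(rms, 1e-12) / ref) < threshold_db

  # frame k covers [(k-1) hop, (k-1) hop + flen) seconds
  hop_s <- fr$hop / fr$sample_rate
  flen_s <- fr$flen / fr$sample_rate
  r <- rle(silent)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- list()
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    s0 <- (starts[k] - 1L) * hop_s
    s1 <- min((ends[k] - 1L) * hop_s + flen_s, a$duration)
    segs[[length(segs) + 1L]] <- c(s0, s1)
  }
  # merge silences separated by less than min_gap of speech
  if (length(segs) > 1L) {
    merged <- list(segs[[1]])
    for (k in 2:length(segs)) {
      last <- merged[[length(merged)]]
      if (segs[[k]][1] - last[2] < min_gap)
        merged[[length(merged)]] <- c(last[1], segs[[k]][2])
      else merged[[length(merged) + 1L]] <- segs[[k]]
    }
    segs <- merged
  }
  list(segments = segs, total_duration = a$duration,
       energy_threshold_db = threshold_db)
}

# speech regions = complement of the silence segments within [0, duration]
speech_regions <- function(sil) {
  dur <- sil$total_duration
  if (length(sil$segments) == 0L)
    return(matrix(c(0, dur), ncol = 2))
  m <- do.call(rbind, sil$segments)
  starts <- c(0, m[, 2])
  ends <- c(m[, 1], dur)
  keep <- ends - starts > 1e-9
  cbind(starts[keep], ends[keep])
}

#' Silence ratios at the five duration thresholds
#'
#' For each threshold in {10, 25, 50, 100, 200} ms, the summed duration of
#' silent segments at least that long, divided by the total recording
#' duration. Non-increasing in the threshold by construction.
#'
#' @param sil Result of [detect_silences()].
#' @return Named numeric vector `silenceRatio_10ms`, ..., `silenceRatio_200ms`.
#' @export
silence_ratios <- function(sil) {
  taus <- c(10, 25, 50, 100, 200) / 1000
  durs <- vapply(sil$segments, function(s) s[2] - s[1], numeric(1))
  vapply(stats::setNames(taus, paste0("silenceRatio_", taus * 1000, "ms")),
         function(tau) sum(durs[durs >= tau]) / sil$total_duration,
         numeric(1))
}

#' Articulation-rate features
#'
#' Words, alphabetic characters and syllables per second of total recording
#' duration (syllable counts via the lexicon and the maximal-onset
#' syllabifier; out-of-vocabulary words use the letter-to-sound fallback).
#'
#' @param t An `adspeech_transcript` or character vector of tokens.
#' @param a An `adspeech_audio` (its duration is the denominator).
#' @param lexicon From [read_lexicon()].
#' @param subtract_silence Use speaking time (duration minus detected
#'   silence) as the denominator instead of total duration.
#' @return Named numeric vector `ratioWords`, `ratioChars`, `ratioSylls`.
#' @export
articulation_rates <- function(t, a, lexicon = read_lexicon(),
                               subtract_silence = FALSE) {
  words <- if (is.character(t)) t else transcript_words(t)
  words <- words[nzchar(vapply(words, normalize_word, character(1)))]
  if (length(words) == 0L) stop("empty transcript")
  dur <- a$duration
  if (subtract_silence) {
    sil <- detect_silences(a)
    dur <- dur - sum(vapply(sil$segments, function(s) s[2] - s[1],
                            numeric(1)))
  }
  if (dur <= 0) stop("non-positive duration")
  chars <- sum(nchar(gsub("[^a-z]", "", tolower(words))))
  sylls <- sum(vapply(words, count_syllables, numeric(1), lexicon = lexicon))
  c(ratioWords = length(words) / dur,
    ratioChars = chars / dur,
    ratioSylls = sylls / dur)
}

#' All timing features of one recording
#'
#' @inheritParams articulation_rates
#' @inheritParams detect_silences
#' @return Named numeric vector with `timing.` prefixes.
#' @export
extract_timing <- function(t, a, lexicon = read_lexicon(),
                           threshold_db = -35, cfg = frame_config()) {
  sil <- detect_silences(a, threshold_db = threshold_db, cfg = cfg)
  out <- c(silence_ratios(sil), articulation_rates(t, a, lexicon))
  stats::setNames(out, paste0("timing.", names(out)))
}
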