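#' Group effect configuration for the synthetic corpus
#'
#' Per-group generative parameters emulating the effect directions reported
#' for impaired speech: reduced F0 variability, raised jitter/shimmer, more
#' additive noise (lower HNR), longer pauses, slower speaking rate and a
#' lexical shift toward high-frequency function words (raising the dental
#' consonant rate through "the/this/that/there").
#'
#' The committed presets are the package's study conditions:
#' \tabular{lcc}{
#'   \tab control \tab impaired (strong) \cr
#'   f0_mean (Hz) \tab 120 \tab 110 \cr
#'   f0_sd (Hz) \tab 25 \tab 12 \cr
#'   jitter_pct \tab 1.0 \tab 2.5 \cr
#'   shimmer_pct \tab 4 \tab 8 \cr
#'   hnr_noise_level \tab 0.03 \tab 0.10 \cr
#'   pause_scale \tab 1.0 \tab 2.0 \cr
#'   words_per_second \tab 2.5 \tab 1.6 \cr
#'   function_word_boost \tab 1 \tab 3 \cr
#' }
#' `weak` places the impaired group halfway between; `null` makes the two
#' groups identical (all control values).
#'
#' @param preset `"strong"`, `"weak"` or `"null"`.
#' @return A `group_config` list with elements `control` and `impaired`
#'   (each a parameter list) plus shared fields `pause_mu`, `pause_sigma`,
#'   `duration_range`, `sample_rate`.
#' @export
preset_config <- function(preset = c("strong", "weak", "null")) {
  preset <- match.arg(preset)
  control <- list(f0_mean = 120, f0_sd = 25, jitter_pct = 1.0,
                  shimmer_pct = 4, hnr_noise_level = 0.03,
                  pause_scale = 1.0, words_per_second = 2.5,
                  function_word_boost = 1)
  impaired <- switch(preset,
    strong = list(f0_mean = 110, f0_sd = 12, jitter_pct = 2.5,
                  shimmer_pct = 8, hnr_noise_level = 0.10,
                  pause_scale = 2.0, words_per_second = 1.6,
                  function_word_boost = 3),
    weak = list(f0_mean = 115, f0_sd = 18, jitter_pct = 1.7,
                shimmer_pct = 6, hnr_noise_level = 0.06,
                pause_scale = 1.5, words_per_second = 2.0,
                function_word_boost = 2),
    null = control)
  structure(list(control = control, impaired = impaired,
                 pause_mu = log(0.15), pause_sigma = 0.6,
                 duration_range = c(20, 60), sample_rate = 16000L,
                 preset = preset),
            class = "group_config")
}

# function words whose sampling probability the boost multiplies
synth_function_words <- function() c("the", "this", "that", "there")

#' Sample a synthetic transcript
#'
#' Words are drawn from the bundled lexicon with the group's function-word
#' boost; sentence lengths are `Poisson(8) + 1`; sentences are added until
#' the word count reaches `duration * words_per_second`.
#'
#' @param group Parameter list (one group of a [preset_config()]).
#' @param duration Target speech duration in seconds.
#' @param lexicon From [read_lexicon()].
#' @return An `adspeech_transcript` (speaker `PAR`, one utterance per
#'   sentence). Uses the current RNG stream.
#' @export
synth_transcript <- function(group, duration, lexicon = read_lexicon()) {
  vocab <- names(lexicon)
  w <- rep(1, length(vocab))
  w[vocab %in% synth_function_words()] <-
    4 * group$function_word_boost
  w <- w / sum(w)
  target <- max(1, round(duration * group$words_per_second))
  utts <- list()
  total <- 0L
  while (total < target) {
    len <- stats::rpois(1, 8) + 1L
    words <- sample(vocab, len, replace = TRUE, prob = w)
    utts[[length(utts) + 1L]] <- list(speaker = "PAR", words = words,
                                      start_time = NA_real_,
                                      end_time = NA_real_)
    total <- total + len
  }
  make_transcript(utts, source_path = "<synthetic>")
}

#' Synthesize the audio of one recording
#'
#' Each sentence becomes a voiced segment (duration = words / rate) built
#' as a glottal-style pulse train: a fixed five-harmonic (1/h rolloff)
#' pulse kernel is placed at cycle onsets whose spacing carries the
#' injected period perturbation, and each pulse is scaled by its cycle
#' amplitude. Perturbations are Gaussian, centered, and rescaled so that
#' the local jitter/shimmer statistic of the realized cycles equals the
#' requested percentage exactly. White noise at `hnr_noise_level` times the
#' segment RMS is added, segments get a 50 ms attack/decay envelope, and
#' sentences are separated by lognormal pauses scaled by `pause_scale`.
#'
#' @param group Parameter list (one group of a [preset_config()]).
#' @param transcript An `adspeech_transcript` from [synth_transcript()].
#' @param cfg A [preset_config()] (for pause distribution and sample rate).
#' @return List `audio` (an `adspeech_audio`) and `truth` (realized cycle
#'   periods/amplitudes per segment, pause durations, segment F0s, and the
#'   ledger jitter/shimmer implied by the realized cycles).
#' @export
synth_audio <- function(group, transcript, cfg = preset_config()) {
  sr <- cfg$sample_rate
  segs <- list()
  pauses <- numeric(0)
  all_periods <- list(); all_amps <- list(); seg_f0 <- numeric(0)

  lead <- stats::rlnorm(1, cfg$pause_mu, cfg$pause_sigma) *
    group$pause_scale
  pieces <- list(numeric(round(lead * sr)))
  for (u in transcript$utterances) {
    dur <- max(0.4, length(u$words) / group$words_per_second)
    f0 <- min(max(stats::rnorm(1, group$f0_mean, group$f0_sd), 70), 320)
    seg <- synth_voiced_segment(dur, f0, group$jitter_pct / 100,
                                group$shimmer_pct / 100,
                                group$hnr_noise_level, sr)
    pieces[[length(pieces) + 1L]] <- seg$x
    all_periods[[length(all_periods) + 1L]] <- seg$periods
    all_amps[[length(all_amps) + 1L]] <- seg$amps
    seg_f0 <- c(seg_f0, f0)
    p <- stats::rlnorm(1, cfg$pause_mu, cfg$pause_sigma) * group$pause_scale
    pauses <- c(pauses, p)
    pieces[[length(pieces) + 1L]] <- numeric(round(p * sr))
  }
  x <- unlist(pieces, use.names = FALSE)
  peak <- max(abs(x))
  if (peak > 0) x <- 0.8 * x / peak

  run <- rep(seq_along(all_periods), vapply(all_periods, length, 1L))
  truth <- list(
    periods = all_periods, amplitudes = all_amps, pauses = pauses,
    segment_f0 = seg_f0,
    jitter = perturbation_ratio(unlist(all_periods), run),
    shimmer = perturbation_ratio(unlist(all_amps), run))
  list(audio = audio_signal(x, sr), truth = truth)
}

# one voiced segment: pulse train with calibrated jitter/shimmer + noise
synth_voiced_segment <- function(dur, f0, jitter, shimmer, noise, sr) {
  T0 <- 1 / f0
  n_cyc <- max(3L, floor(dur / T0))
  eps <- center_scale_perturbation(stats::rnorm(n_cyc), jitter)
  periods <- T0 * (1 + eps)
  eta <- center_scale_perturbation(stats::rnorm(n_cyc), shimmer)
  amps <- pmax(1 + eta, 0.05)

  onsets <- cumsum(c(0, periods[-n_cyc]))
  n <- ceiling((sum(periods) + 2 * T0) * sr)
  train <- numeric(n)
  pos <- onsets * sr + 1
  lo <- floor(pos); frac <- pos - lo
  for (i in seq_len(n_cyc)) {      # fractional impulse placement
    train[lo[i]] <- train[lo[i]] + amps[i] * (1 - frac[i])
    train[lo[i] + 1L] <- train[lo[i] + 1L] + amps[i] * frac[i]
  }
  # fixed five-harmonic pulse kernel (one nominal period long)
  tk <- seq(0, T0, by = 1 / sr)
  kern <- rowSums(vapply(1:5, function(h)
    sin(2 * pi * h * tk / T0) / h, numeric(length(tk))))
  kern <- kern * exp(-3 * tk / T0)
  x <- fft_convolve(train, kern)[seq_len(n)]
  rms <- sqrt(mean(x^2))
  if (noise > 0 && rms > 0)
    x <- x + stats::rnorm(n, 0, noise * rms)
  x <- x * segment_envelope(n, round(0.05 * sr))
  list(x = x, periods = periods, amps = amps)
}

# center, then rescale so mean|diff| / mean equals `target` exactly
center_scale_perturbation <- function(eps, target) {
  if (target <= 0 || length(eps) < 3L) return(rep(0, length(eps)))
  eps <- eps - mean(eps)
  md <- mean(abs(diff(eps)))
  if (md < 1e-12) return(rep(0, length(eps)))
  eps * target / md
}

# linear convolution via power-of-2 padded FFTs
fft_convolve <- function(x, k) {
  n_out <- length(x) + length(k) - 1L
  nfft <- 2^ceiling(log2(n_out))
  X <- stats::fft(c(x, numeric(nfft - length(x))))
  K <- stats::fft(c(k, numeric(nfft - length(k))))
  Re(stats::fft(X * K, inverse = TRUE))[seq_len(n_out)] / nfft
}

segment_envelope <- function(n, ramp) {
  ramp <- min(ramp, n %/% 2)
  env <- rep(1, n)
  if (ramp > 0) {
    up <- seq(0, 1, length.out = ramp)
    env[seq_len(ramp)] <- up
    env[(n - ramp + 1L):n] <- rev(up)
  }
  env
}

#' Generate a balanced labeled synthetic corpus
#'
#' Produces paired audio + transcript recordings for the two groups with a
#' train/test split (defaults mirror a 54-subject train, 24-subject test
#' design, balanced between groups) and a ground-truth ledger sufficient to
#' validate the extraction pipeline independently.
#'
#' @param cfg A [preset_config()].
#' @param n_train,n_test Total subjects per split (half per group).
#' @param seed Integer seed; the corpus is fully determined by it.
#' @param lexicon From [read_lexicon()].
#' @return List with `records` (each: `subject_id`, `label`, `split`,
#'   `audio`, `transcript`) and `ledger` (one row per recording: realized
#'   jitter, shimmer, pause totals, word/syllable counts, mean F0).
#' @export
generate_corpus <- function(cfg = preset_config("strong"), n_train = 54L,
                            n_test = 24L, seed = 1L,
                            lexicon = read_lexicon()) {
  stopifnot(n_train >= 2L, n_test >= 0L)
  set.seed(seed)
  plan <- rbind(
    data.frame(split = "train",
               label = rep(c("control", "positive"),
                           length.out = n_train)),
    if (n_test > 0)
      data.frame(split = "test",
                 label = rep(c("control", "positive"), length.out = n_test)))
  records <- vector("list", nrow(plan))
  ledger <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    group <- if (plan$label[i] == "positive") cfg$impaired else cfg$control
    dur <- stats::runif(1, cfg$duration_range[1], cfg$duration_range[2])
    tr <- synth_transcript(group, dur, lexicon)
    au <- synth_audio(group, tr, cfg)
    words <- transcript_words(tr)
    sid <- sprintf("S%03d", i)
    records[[i]] <- list(subject_id = sid, label = plan$label[i],
                         split = plan$split[i], audio = au$audio,
                         transcript = tr, truth = au$truth)
    ledger[[i]] <- data.frame(
      subject_id = sid, label = plan$label[i], split = plan$split[i],
      jitter = au$truth$jitter, shimmer = au$truth$shimmer,
      pause_total = sum(au$truth$pauses),
      duration = au$audio$duration,
      n_words = length(words),
      n_sylls = sum(vapply(words, count_syllables, numeric(1),
                           lexicon = lexicon)),
      mean_f0 = mean(au$truth$segment_f0),
      stringsAsFactors = FALSE)
  }
  list(records = records, ledger = do.call(rbind, ledger))
}

#' Write a synthetic corpus to disk
#'
#' Lays out `<dir>/wav/<id>.wav`, `<dir>/cha/<id>.cha`, `<dir>/labels.csv`
#' and `<dir>/ledger.csv` — the directory layout [run_extract()] consumes.
#'
#' @param corpus Result of [generate_corpus()].
#' @param dir Output directory (created).
#' @return `dir`, invisibly.
#' @export
simulate_corpus <- function(corpus, dir) {
  dir.create(file.path(dir, "wav"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "cha"), recursive = TRUE, showWarnings = FALSE)
  for (rec in corpus$records) {
    write_wav(rec$audio, file.path(dir, "wav",
                                   paste0(rec$subject_id, ".wav")))
    write_chat_file(rec$transcript,
                    file.path(dir, "cha", paste0(rec$subject_id, ".cha")))
  }
  labs <- do.call(rbind, lapply(corpus$records, function(r)
    data.frame(subject_id = r$subject_id, label = r$label, split = r$split,
               stringsAsFactors = FALSE)))
  utils::write.csv(labs, file.path(dir, "labels.csv"), row.names = FALSE)
  utils::write.csv(corpus$ledger, file.path(dir, "ledger.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Which features measure a generative group axis?
#'
#' The presets vary seven generative axes between groups: F0 level and
#' variability, jitter, shimmer, additive noise (harmonicity), pause
#' durations, speaking rate, and the function-word lexical shift. This
#' predicate marks the features that measure one of those axes. Because the
#' additive-noise axis enters the raw waveform, every spectral family
#' (RASTA bands, MFCC, spectral descriptors, ZCR, HNR, voicing) measures
#' it; the only families generated identically for both groups are overall
#' amplitude (peak-normalized) and its envelope shape.
#'
#' @param names Character vector of feature names from [run_extract()].
#' @return Logical vector: `TRUE` where the feature measures a varied axis.
#' @export
generative_effect_features <- function(names) {
  non_effect <- c("^acoustic\\.pcm_RMSenergy", "^prosodic\\.ampEnvelope")
  !Reduce(`|`, lapply(non_effect, grepl, x = names))
}

# minimal CHAT writer for synthetic transcripts
write_chat_file <- function(t, path) {
  lines <- c("@Begin", "@Languages:\teng",
             "@Participants:\tPAR Participant",
             vapply(t$utterances, function(u)
               paste0("*PAR:\t", paste(u$words, collapse = " "), " ."),
               character(1)),
             "@End")
  writeLines(lines, path)
}
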