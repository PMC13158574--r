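# shared fixtures, all generated in code

SR <- 16000L

tone <- function(freq, dur = 2, sr = SR, amp = 0.8) {
  audio_signal(amp * sin(2 * pi * freq * seq(0, dur, by = 1 / sr)), sr)
}

# labeled two-Gaussian feature matrix with one informative block
gauss_fm <- function(n = 100, d = 10, shift = 6, n_informative = 1,
                     seed = 7, ids = "r") {
  set.seed(seed)
  X <- matrix(rnorm(n * d), n, d)
  y <- rep(c("control", "positive"), each = n / 2)
  X[y == "positive", seq_len(n_informative)] <-
    X[y == "positive", seq_len(n_informative)] + shift
  colnames(X) <- paste0("f", seq_len(d))
  feature_matrix(X, paste0(ids, seq_len(n)), colnames(X), y)
}

split_fm <- function(fm, n_train, seed = 1) {
  set.seed(seed)
  idx <- sample(nrow(fm$values), n_train)
  list(train = feature_matrix(fm$values[idx, , drop = FALSE],
                              fm$row_ids[idx], fm$feature_names,
                              fm$labels[idx]),
       test = feature_matrix(fm$values[-idx, , drop = FALSE],
                             fm$row_ids[-idx], fm$feature_names,
                             fm$labels[-idx]))
}

# one synthetic voiced signal with calibrated perturbations
voiced_fixture <- function(jitter_pct, shimmer_pct = 4, noise = 0,
                           f0 = 120, dur = 3, seed = 11) {
  set.seed(seed)
  seg <- adspeech:::synth_voiced_segment(dur, f0, jitter_pct / 100,
                                         shimmer_pct / 100, noise, SR)
  list(audio = audio_signal(seg$x / max(abs(seg$x)), SR),
       periods = seg$periods, amps = seg$amps)
}

# speech-shaped fixture with known silence gaps
gapped_fixture <- function(gaps = c(0.30, 0.15, 0.05), sr = SR) {
  seg <- function(d) 0.8 * sin(2 * pi * 150 * seq(0, d, by = 1 / sr))
  x <- seg(1.2)
  for (g in gaps) x <- c(x, numeric(round(g * sr)), seg(1.2))
  remaining <- 10 * sr - length(x)
  if (remaining > 0) x <- c(x, seg(remaining / sr))
  audio_signal(x[seq_len(10 * sr)], sr)
}

write_cha_fixture <- function(lines, path = tempfile(fileext = ".cha")) {
  writeLines(c("@Begin", "@Participants:\tPAR Participant, INV Investigator",
               lines, "@End"), path)
  path
}
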