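#' Feature extraction over a corpus
#'
#' Extracts the configured feature groups for every recording — `acoustic`
#' and `prosodic` from the LLD-by-functional grid, `phonological` from the
#' transcript, `timing` from both — and assembles the corpus feature matrix
#' (one row per recording, columns namespaced `acoustic.*`, `prosodic.*`,
#' `phon.*`, `timing.*`).
#'
#' @param corpus Either the result of [generate_corpus()] or a corpus
#'   directory written by [simulate_corpus()] (`wav/`, `cha/`,
#'   `labels.csv`).
#' @param groups Feature groups to extract.
#' @param cfg A [frame_config()].
#' @param grid A grid from [default_lld_grid()].
#' @param lexicon From [read_lexicon()].
#' @param split Restrict to `"train"` or `"test"` recordings (`NULL` = all).
#' @return A labeled `adspeech_fm`.
#' @export
run_extract <- function(corpus, groups = c("acoustic", "prosodic",
                                           "phonological", "timing"),
                        cfg = frame_config(), grid = default_lld_grid(),
                        lexicon = read_lexicon(), split = NULL) {
  groups <- match.arg(groups, several.ok = TRUE)
  records <- if (is.character(corpus)) load_corpus_dir(corpus)
             else corpus$records
  if (!is.null(split))
    records <- Filter(function(r) identical(r$split, split), records)

  onsets <- read_onsets()
  inv <- arpabet_inventory()
  rows <- list(); ids <- character(0); labels <- character(0)
  for (rec in records) {
    if (is.null(rec$audio) && is.null(rec$transcript)) {
      warning("recording ", rec$subject_id,
              " has neither audio nor transcript; skipped")
      next
    }
    feats <- extract_recording_features(rec$audio, rec$transcript, groups,
                                        cfg, grid, lexicon, inv, onsets)
    rows[[length(rows) + 1L]] <- feats
    ids <- c(ids, rec$subject_id)
    labels <- c(labels, rec$label)
  }
  if (length(rows) == 0L) stop("no usable recordings")
  feature_matrix(do.call(rbind, rows), ids, names(rows[[1]]), labels)
}

#' @rdname run_extract
#' @param audio An `adspeech_audio` or `NULL`.
#' @param transcript An `adspeech_transcript` or `NULL`.
#' @param inv,onsets Phonology tables (defaults loaded per call).
#' @export
extract_recording_features <- function(audio, transcript,
                                       groups = c("acoustic", "prosodic",
                                                  "phonological", "timing"),
                                       cfg = frame_config(),
                                       grid = default_lld_grid(),
                                       lexicon = read_lexicon(),
                                       inv = arpabet_inventory(),
                                       onsets = read_onsets()) {
  out <- numeric(0)
  want_grid <- any(c("acoustic", "prosodic") %in% groups)
  if (want_grid && !is.null(audio)) {
    g <- featurize_recording(audio, cfg, grid)
    keep <- rep(FALSE, length(g))
    if ("acoustic" %in% groups) keep <- keep | startsWith(names(g),
                                                          "acoustic.")
    if ("prosodic" %in% groups) keep <- keep | startsWith(names(g),
                                                          "prosodic.")
    out <- c(out, g[keep])
  }
  if ("phonological" %in% groups && !is.null(transcript))
    out <- c(out, extract_phonology(transcript, lexicon, inv, onsets))
  if ("timing" %in% groups && !is.null(audio) && !is.null(transcript))
    out <- c(out, extract_timing(transcript, audio, lexicon, cfg = cfg))
  out
}

# read a corpus directory written by simulate_corpus()
load_corpus_dir <- function(dir) {
  labs <- utils::read.csv(file.path(dir, "labels.csv"),
                          stringsAsFactors = FALSE)
  lapply(seq_len(nrow(labs)), function(i) {
    id <- labs$subject_id[i]
    wav <- file.path(dir, "wav", paste0(id, ".wav"))
    cha <- file.path(dir, "cha", paste0(id, ".cha"))
    list(subject_id = id, label = labs$label[i],
         split = if ("split" %in% names(labs)) labs$split[i] else NA,
         audio = if (file.exists(wav)) read_audio(wav) else NULL,
         transcript = if (file.exists(cha)) read_chat(cha) else NULL)
  })
}

#' Run the full selection + modeling experiment
#'
#' Two-stage feature selection on the train matrix, incremental top-k
#' sweeps of every model under each stage-2 ranking, and the three
#' ensembles on the best-performing ranked subset. The report mirrors the
#' method-by-model-by-k experiment shape.
#'
#' @param train,test Labeled `adspeech_fm`s.
#' @param stage1 Stage-1 screening mode (see [two_stage_select()]).
#' @param global_n,family_fraction Stage-1 quotas.
#' @param models Named list of [model_spec()]s.
#' @param k_grid Feature counts for the sweep (default: [default_k_grid()]).
#' @param ensemble_members Members of the voting/stacking ensembles.
#' @param seed Seed recorded in the report and used for stacking folds.
#' @return List with `selection`, `sweeps` (per ranking method), `best`
#'   (k/model/method with top F1), `ensembles` (hard/soft/stacking
#'   `eval_result`s on the best subset), and a `manifest`.
#' @export
run_full <- function(train, test, stage1 = c("global", "family", "none"),
                     global_n = 300L, family_fraction = 0.10,
                     models = model_zoo(c("SVM", "LR", "RF", "XG")),
                     k_grid = NULL,
                     ensemble_members = model_zoo(c("SVM", "RF", "AB",
                                                    "LR", "XG")),
                     seed = 1L) {
  stage1 <- match.arg(stage1)
  sel <- two_stage_select(train, stage1 = stage1, global_n = global_n,
                          family_fraction = family_fraction)
  sweeps <- list()
  best <- NULL
  for (m in names(sel$rankings)) {
    sw <- incremental_sweep(sel$rankings[[m]], models,
                            fm_subset(train, sel$kept),
                            fm_subset(test, sel$kept), k_grid)
    sweeps[[m]] <- sw
    b <- attr(sw, "best")
    if (is.null(best) || b$f1 > best$f1) {
      best <- b
      best$method <- m
    }
  }
  top_feats <- sel$rankings[[best$method]]$feature[seq_len(best$k)]
  ens <- lapply(c(hard = "hard", soft = "soft", stacking = "stacking"),
                function(mode)
                  ensemble_predict(ensemble_members, mode,
                                   fm_subset(train, top_feats),
                                   fm_subset(test, top_feats), seed = seed))
  list(selection = sel, sweeps = sweeps, best = best, ensembles = ens,
       manifest = list(seed = seed, stage1 = stage1, global_n = global_n,
                       n_train = nrow(train$values),
                       n_test = nrow(test$values),
                       n_features = ncol(train$values),
                       models = names(models),
                       timestamp = format(Sys.time(), tz = "UTC")))
}
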