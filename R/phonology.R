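#' Phonological feature schema
#'
#' The fixed feature schema served by [feature_groups()] and emitted by
#' [extract_phonology()]. Five families:
#' \describe{
#'   \item{CPA}{consonant place of articulation — 9 place classes
#'     (bilabial, labiodental, dental, alveolar, postalveolar, palatal,
#'     velar, glottal, labiovelar), each as a ratio to all phonemes
#'     (`_toPhon`) and to all consonants (`_toCons`): 18 features. The nine
#'     places partition the consonant inventory, so the `_toPhon` ratios sum
#'     exactly to the consonant share.}
#'   \item{CMA}{consonant manner of articulation — 6 manner classes (stop,
#'     fricative, affricate, nasal, liquid, glide) plus 3 composites
#'     (`friAffLiq` = fricative+affricate+liquid, `stopNas` = stop+nasal,
#'     `obstruent` = stop+fricative+affricate), each as `_toPhon`, `_toCons`
#'     and voiced share (`_voiced`): 27 features.}
#'   \item{vowels}{8 vowel types (high, mid, low, front, central, back,
#'     tense, round), each as a ratio to all phonemes (`_toPhon`) and to all
#'     vowels (`_toVow`): 16 features.}
#'   \item{misc}{syllabic consonants (schwa + sonorant) and diphthongs,
#'     each relative to consonants and to all phonemes: 4 features.}
#'   \item{supra}{supra-phonemic structure — consCluster, endConson,
#'     lenOnset, lenCoda, backSyll, frontSyll, diphSyll, avgSyll,
#'     primStress, secondStress, nbLett, nbPhon: 12 features.}
#' }
#'
#' @return Named list mapping group name to the character vector of fully
#'   qualified feature names (`phon.<group>.<name>`).
#' @export
feature_groups <- function() {
  places <- c("bilabial", "labiodental", "dental", "alveolar",
              "postalveolar", "palatal", "velar", "glottal", "labiovelar")
  manners <- c("stop", "fricative", "affricate", "nasal", "liquid", "glide",
               "friAffLiq", "stopNas", "obstruent")
  vtypes <- c("high", "mid", "low", "front", "central", "back",
              "tense", "round")
  list(
    CPA = paste0("phon.CPA.", c(outer(places, c("_toPhon", "_toCons"),
                                      paste0))),
    CMA = paste0("phon.CMA.", c(outer(manners,
                                      c("_toPhon", "_toCons", "_voiced"),
                                      paste0))),
    vowels = paste0("phon.vowels.", c(outer(vtypes, c("_toPhon", "_toVow"),
                                            paste0))),
    misc = paste0("phon.misc.", c("syllCons_toCons", "syllCons_toPhon",
                                  "diphthong_toCons", "diphthong_toPhon")),
    supra = paste0("phon.supra.", c("consCluster", "endConson", "lenOnset",
                                    "lenCoda", "backSyll", "frontSyll",
                                    "diphSyll", "avgSyll", "primStress",
                                    "secondStress", "nbLett", "nbPhon"))
  )
}

#' Extract phonological features from a transcript
#'
#' Converts every word token to ARPABET via the lexicon (letter-to-sound
#' fallback for out-of-vocabulary words), pools phoneme counts over the
#' recording, syllabifies each word with the maximal-onset rule, and emits
#' the full phonological schema of [feature_groups()].
#'
#' Phoneme-level ratios are pooled over all tokens of the recording (not
#' averaged per word); set `per_word = TRUE` to average word-level ratios
#' instead. Words without a vowel nucleus are counted and skipped for the
#' syllable-level features.
#'
#' @param transcript An `adspeech_transcript` (see [read_chat()]) or a
#'   character vector of word tokens.
#' @param lexicon Named list from [read_lexicon()].
#' @param inv Inventory from [arpabet_inventory()].
#' @param onsets Legal-onset table from [read_onsets()].
#' @param per_word Average per-word ratios instead of pooling counts.
#' @return Named numeric vector over the full schema; attributes `n_words`
#'   and `oov_rate` record corpus coverage.
#' @export
extract_phonology <- function(transcript, lexicon = read_lexicon(),
                              inv = arpabet_inventory(),
                              onsets = read_onsets(), per_word = FALSE) {
  words <- if (is.character(transcript)) transcript
           else transcript_words(transcript)
  words <- words[nzchar(vapply(words, normalize_word, character(1)))]
  if (length(words) == 0L) stop("empty transcript: no usable word tokens")

  prons <- lapply(words, to_phonemes, lexicon = lexicon)
  oov <- mean(vapply(prons, function(p) attr(p, "source") == "fallback",
                     logical(1)))

  word_stats <- lapply(seq_along(words), function(i)
    word_phonology(words[[i]], prons[[i]], inv, onsets))

  counts <- Reduce(`+`, lapply(word_stats, `[[`, "counts"))
  per_word_ratio <- function(field) {
    mean(vapply(word_stats, `[[`, numeric(1), field))
  }

  if (per_word) {
    # average word-level pooled ratios: recompute ratios per word, then mean
    ratio_mats <- vapply(word_stats, function(ws) counts_to_ratios(ws$counts),
                         counts_to_ratios(counts))
    ratios <- rowMeans(ratio_mats, na.rm = TRUE)
  } else {
    ratios <- counts_to_ratios(counts)
  }

  # syllable-level aggregates
  sylls <- unlist(lapply(word_stats, `[[`, "n_syll"))
  onset_lens <- unlist(lapply(word_stats, `[[`, "onset_lens"))
  coda_lens <- unlist(lapply(word_stats, `[[`, "coda_lens"))
  nuclei <- unlist(lapply(word_stats, `[[`, "nuclei"))
  nuc_rec <- lapply(nuclei, classify_phoneme, inv = inv)
  backness <- vapply(nuc_rec, function(r) r$backness, character(1))
  diph <- vapply(nuc_rec, function(r) isTRUE(r$diphthong), logical(1))

  supra <- c(
    consCluster = per_word_ratio("n_clusters"),
    endConson = per_word_ratio("ends_cons"),
    lenOnset = mean(onset_lens),
    lenCoda = mean(coda_lens),
    backSyll = mean(backness == "back"),
    frontSyll = mean(backness == "front"),
    diphSyll = mean(diph),
    avgSyll = mean(sylls),
    primStress = per_word_ratio("n_prim"),
    secondStress = per_word_ratio("n_second"),
    nbLett = per_word_ratio("n_lett"),
    nbPhon = per_word_ratio("n_phon")
  )

  grp <- feature_groups()
  out <- c(ratios, supra)
  names(out) <- c(grp$CPA, grp$CMA, grp$vowels, grp$misc, grp$supra)
  structure(out, n_words = length(words), oov_rate = oov)
}

# Per-word phoneme bookkeeping used by extract_phonology.
word_phonology <- function(word, phs, inv, onsets) {
  base <- strip_stress(phs)
  rec <- inv[match(base, inv$phoneme), ]
  isv <- rec$is_vowel

  # syllabic consonants: schwa (AH0) followed by a sonorant in the same word
  n_syllc <- sum(phs[-length(phs)] == "AH0" &
                 rec$syllabic_capable[-1] & !isv[-1])

  parse <- tryCatch(syllabify(phs, onsets), error = function(e) NULL)
  if (is.null(parse)) {
    onset_lens <- coda_lens <- numeric(0)
    nuclei <- character(0)
    n_syll <- integer(0)
    stress <- integer(0)
  } else {
    onset_lens <- vapply(parse$syllables, function(s) length(s$onset),
                         numeric(1))
    coda_lens <- vapply(parse$syllables, function(s) length(s$coda),
                        numeric(1))
    nuclei <- vapply(parse$syllables, `[[`, character(1), "nucleus")
    n_syll <- length(parse$syllables)
    stress <- parse$stress
  }

  # consonant clusters: maximal runs of >= 2 consonants
  runs <- rle(!isv)
  n_clusters <- sum(runs$values & runs$lengths >= 2)

  places <- c("bilabial", "labiodental", "dental", "alveolar",
              "postalveolar", "palatal", "velar", "glottal", "labiovelar")
  manners <- c("stop", "fricative", "affricate", "nasal", "liquid", "glide")
  vtypes <- c("high", "mid", "low", "front", "central", "back",
              "tense", "round")

  cnt <- c(
    n_phon = length(phs), n_cons = sum(!isv), n_vow = sum(isv),
    stats::setNames(vapply(places, function(p)
      sum(rec$place == p, na.rm = TRUE), numeric(1)),
      paste0("place_", places)),
    stats::setNames(vapply(manners, function(m)
      sum(rec$manner == m, na.rm = TRUE), numeric(1)),
      paste0("manner_", manners)),
    stats::setNames(vapply(manners, function(m)
      sum(rec$manner == m & rec$voiced, na.rm = TRUE), numeric(1)),
      paste0("voiced_", manners)),
    stats::setNames(vapply(vtypes, function(v) {
      sum(switch(v,
                 high = rec$height == "high", mid = rec$height == "mid",
                 low = rec$height == "low", front = rec$backness == "front",
                 central = rec$backness == "central",
                 back = rec$backness == "back",
                 tense = rec$tense, round = rec$round), na.rm = TRUE)
    }, numeric(1)), paste0("vtype_", v = vtypes)),
    n_syllc = n_syllc,
    n_diph = sum(rec$diphthong, na.rm = TRUE)
  )

  list(counts = cnt,
       n_clusters = n_clusters,
       ends_cons = as.numeric(!isv[length(isv)]),
       n_prim = sum(stress == 1, na.rm = TRUE),
       n_second = sum(stress == 2, na.rm = TRUE),
       n_lett = nchar(gsub("[^a-z]", "", tolower(word))),
       n_phon = length(phs),
       n_syll = n_syll, onset_lens = onset_lens, coda_lens = coda_lens,
       nuclei = nuclei)
}

# Map pooled counts to the CPA/CMA/vowels/misc ratio block (57 values).
counts_to_ratios <- function(cnt) {
  np <- cnt[["n_phon"]]; nc <- cnt[["n_cons"]]; nv <- cnt[["n_vow"]]
  rat <- function(x, d) if (d > 0) x / d else 0
  places <- c("bilabial", "labiodental", "dental", "alveolar",
              "postalveolar", "palatal", "velar", "glottal", "labiovelar")
  manners <- c("stop", "fricative", "affricate", "nasal", "liquid", "glide")
  vtypes <- c("high", "mid", "low", "front", "central", "back",
              "tense", "round")

  cpa <- c(vapply(places, function(p) rat(cnt[[paste0("place_", p)]], np),
                  numeric(1)),
           vapply(places, function(p) rat(cnt[[paste0("place_", p)]], nc),
                  numeric(1)))

  mcount <- vapply(manners, function(m) cnt[[paste0("manner_", m)]],
                   numeric(1))
  mvoiced <- vapply(manners, function(m) cnt[[paste0("voiced_", m)]],
                    numeric(1))
  comp <- c(friAffLiq = sum(mcount[c("fricative", "affricate", "liquid")]),
            stopNas = sum(mcount[c("stop", "nasal")]),
            obstruent = sum(mcount[c("stop", "fricative", "affricate")]))
  comp_v <- c(friAffLiq = sum(mvoiced[c("fricative", "affricate", "liquid")]),
              stopNas = sum(mvoiced[c("stop", "nasal")]),
              obstruent = sum(mvoiced[c("stop", "fricative", "affricate")]))
  mall <- c(mcount, comp)
  vall <- c(mvoiced, comp_v)
  cma <- c(vapply(mall, rat, numeric(1), d = np),
           vapply(mall, rat, numeric(1), d = nc),
           mapply(function(v, m) rat(v, m), vall, mall))

  vcount <- vapply(vtypes, function(v) cnt[[paste0("vtype_", v)]], numeric(1))
  vow <- c(vapply(vcount, rat, numeric(1), d = np),
           vapply(vcount, rat, numeric(1), d = nv))

  misc <- c(rat(cnt[["n_syllc"]], nc), rat(cnt[["n_syllc"]], np),
            rat(cnt[["n_diph"]], nc), rat(cnt[["n_diph"]], np))

  out <- c(cpa, cma, vow, misc)
  names(out) <- NULL
  out
}
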