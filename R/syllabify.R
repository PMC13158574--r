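#' Legal syllable-onset table
#'
#' Reads the committed inventory of phonotactically legal English onsets
#' (single consonants plus attested clusters such as `S T R`).
#'
#' @param path CSV with a single `onset` column of space-separated ARPABET
#'   consonants. Defaults to the bundled table.
#' @return Character vector of onsets, each a space-separated cluster string.
#' @export
read_onsets <- function(path = system.file("extdata", "onsets.csv",
                                           package = "adspeech",
                                           mustWork = TRUE)) {
  key <- paste0("onsets:", path)
  cached <- .adspeech_cache[[key]]
  if (!is.null(cached)) return(cached)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  .adspeech_cache[[key]] <- tab$onset
  tab$onset
}

#' Maximal-onset syllabification of an ARPABET phoneme sequence
#'
#' Splits the sequence into syllables around vowel nuclei. Each intervocalic
#' consonant cluster is divided so that the following syllable's onset is the
#' longest suffix of the cluster present in the legal-onset table; the
#' remaining consonants close the preceding syllable's coda. The word-initial
#' cluster is taken as the first onset wholesale and the word-final cluster
#' as the last coda. Concatenating onset + nucleus + coda across syllables
#' reproduces the input exactly.
#'
#' @param phonemes Character vector of ARPABET symbols (stress digits on
#'   vowels allowed and preserved).
#' @param onsets Legal-onset table from [read_onsets()].
#' @return List with `syllables` (list of `list(onset, nucleus, coda)`) and
#'   `stress` (integer vector, one stress digit per syllable; `NA` when the
#'   nucleus carries no digit).
#' @export
#' @examples
#' syllabify(c("AE1", "S", "T", "R", "AH0", "N", "AO2", "T"))
syllabify <- function(phonemes, onsets = read_onsets()) {
  inv <- arpabet_inventory()
  vow <- vapply(phonemes, function(p) is_vowel_symbol(p, inv), logical(1),
                USE.NAMES = FALSE)
  nuclei <- which(vow)
  if (length(nuclei) == 0L)
    stop("no syllable nucleus candidate in: ", paste(phonemes, collapse = " "))

  n_syll <- length(nuclei)
  onset_l <- vector("list", n_syll)
  coda_l <- vector("list", n_syll)
  onset_l[[1]] <- if (nuclei[1] > 1) phonemes[seq_len(nuclei[1] - 1L)] else character(0)
  coda_l[[n_syll]] <- if (nuclei[n_syll] < length(phonemes))
    phonemes[(nuclei[n_syll] + 1L):length(phonemes)] else character(0)

  if (n_syll > 1) {
    for (i in seq_len(n_syll - 1L)) {
      lo <- nuclei[i] + 1L
      hi <- nuclei[i + 1L] - 1L
      cluster <- if (hi >= lo) phonemes[lo:hi] else character(0)
      split <- max_onset_split(cluster, onsets)
      coda_l[[i]] <- split$coda
      onset_l[[i + 1L]] <- split$onset
    }
  }

  sylls <- lapply(seq_len(n_syll), function(i) {
    list(onset = onset_l[[i]], nucleus = phonemes[nuclei[i]],
         coda = coda_l[[i]])
  })
  stress <- vapply(nuclei, function(i) stress_digit(phonemes[i]), integer(1))
  list(syllables = sylls, stress = stress)
}

# Longest legal suffix of `cluster` becomes the next onset; the rest is coda.
max_onset_split <- function(cluster, onsets) {
  n <- length(cluster)
  if (n == 0L) return(list(coda = character(0), onset = character(0)))
  for (k in n:1) {
    cand <- cluster[(n - k + 1L):n]
    if (paste(strip_stress(cand), collapse = " ") %in% onsets)
      return(list(coda = cluster[seq_len(n - k)], onset = cand))
  }
  list(coda = cluster, onset = character(0))
}

#' Flatten a syllable parse back to its phoneme sequence
#' @param parse Result of [syllabify()].
#' @return Character vector of ARPABET symbols.
#' @export
flatten_syllables <- function(parse) {
  unlist(lapply(parse$syllables, function(s) c(s$onset, s$nucleus, s$coda)),
         use.names = FALSE)
}

#' Count syllables of a word
#' @inheritParams to_phonemes
#' @return Integer syllable count (number of vowel nuclei).
#' @export
count_syllables <- function(word, lexicon) {
  phs <- to_phonemes(word, lexicon)
  sum(vapply(phs, is_vowel_symbol, logical(1)))
}
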