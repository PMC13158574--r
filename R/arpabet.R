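#' ARPABET articulatory inventory
#'
#' Returns the full articulatory feature table for the 39-phoneme ARPABET
#' inventory used by the CMU Pronouncing Dictionary. Consonants carry a place
#' of articulation (one of bilabial, labiodental, dental, alveolar,
#' postalveolar, palatal, velar, glottal, labiovelar), a manner (stop,
#' fricative, affricate, nasal, liquid, glide) and a voicing flag; both place
#' and manner classes partition the consonants, which is what makes the
#' ratio-conservation identities of [extract_phonology()] exact. Vowels carry
#' height (high/mid/low), backness (front/central/back), tenseness, rounding
#' and a diphthong flag. `L`, `M`, `N`, `R` are marked as capable of serving
#' as syllabic nuclei (detected downstream as schwa + sonorant).
#'
#' @return A data.frame with one row per ARPABET symbol and columns
#'   `phoneme`, `is_vowel`, `place`, `manner`, `voiced`, `height`,
#'   `backness`, `tense`, `round`, `diphthong`, `syllabic_capable`.
#' @export
#' @examples
#' inv <- arpabet_inventory()
#' inv[inv$phoneme == "TH", c("place", "manner", "voiced")]
arpabet_inventory <- function() {
  if (is.null(.adspeech_cache$inventory))
    .adspeech_cache$inventory <- build_arpabet_inventory()
  .adspeech_cache$inventory
}

.adspeech_cache <- new.env(parent = emptyenv())

build_arpabet_inventory <- function() {
  cons <- function(ph, place, manner, voiced, syl = FALSE) {
    data.frame(phoneme = ph, is_vowel = FALSE, place = place, manner = manner,
               voiced = voiced, height = NA_character_,
               backness = NA_character_, tense = NA, round = NA,
               diphthong = NA, syllabic_capable = syl,
               stringsAsFactors = FALSE)
  }
  vow <- function(ph, height, backness, tense, round, diph = FALSE) {
    data.frame(phoneme = ph, is_vowel = TRUE, place = NA_character_,
               manner = NA_character_, voiced = TRUE, height = height,
               backness = backness, tense = tense, round = round,
               diphthong = diph, syllabic_capable = FALSE,
               stringsAsFactors = FALSE)
  }
  rbind(
    # stops
    cons("P", "bilabial", "stop", FALSE), cons("B", "bilabial", "stop", TRUE),
    cons("T", "alveolar", "stop", FALSE), cons("D", "alveolar", "stop", TRUE),
    cons("K", "velar", "stop", FALSE),    cons("G", "velar", "stop", TRUE),
    # fricatives
    cons("F", "labiodental", "fricative", FALSE),
    cons("V", "labiodental", "fricative", TRUE),
    cons("TH", "dental", "fricative", FALSE),
    cons("DH", "dental", "fricative", TRUE),
    cons("S", "alveolar", "fricative", FALSE),
    cons("Z", "alveolar", "fricative", TRUE),
    cons("SH", "postalveolar", "fricative", FALSE),
    cons("ZH", "postalveolar", "fricative", TRUE),
    cons("HH", "glottal", "fricative", FALSE),
    # affricates
    cons("CH", "postalveolar", "affricate", FALSE),
    cons("JH", "postalveolar", "affricate", TRUE),
    # nasals
    cons("M", "bilabial", "nasal", TRUE, syl = TRUE),
    cons("N", "alveolar", "nasal", TRUE, syl = TRUE),
    cons("NG", "velar", "nasal", TRUE),
    # liquids
    cons("L", "alveolar", "liquid", TRUE, syl = TRUE),
    cons("R", "alveolar", "liquid", TRUE, syl = TRUE),
    # glides
    cons("W", "labiovelar", "glide", TRUE),
    cons("Y", "palatal", "glide", TRUE),
    # monophthongs
    vow("IY", "high", "front", TRUE, FALSE),
    vow("IH", "high", "front", FALSE, FALSE),
    vow("EH", "mid", "front", FALSE, FALSE),
    vow("AE", "low", "front", FALSE, FALSE),
    vow("AH", "mid", "central", FALSE, FALSE),
    vow("ER", "mid", "central", FALSE, FALSE),
    vow("AA", "low", "back", TRUE, FALSE),
    vow("AO", "low", "back", TRUE, TRUE),
    vow("UH", "high", "back", FALSE, TRUE),
    vow("UW", "high", "back", TRUE, TRUE),
    # diphthongs
    vow("EY", "mid", "front", TRUE, FALSE, diph = TRUE),
    vow("AY", "low", "central", TRUE, FALSE, diph = TRUE),
    vow("AW", "low", "central", TRUE, FALSE, diph = TRUE),
    vow("OY", "mid", "back", TRUE, TRUE, diph = TRUE),
    vow("OW", "mid", "back", TRUE, TRUE, diph = TRUE)
  )
}

#' Classify one ARPABET phoneme
#'
#' @param ph ARPABET symbol, with or without a trailing stress digit.
#' @param inv Inventory table from [arpabet_inventory()].
#' @return A one-row data.frame (the phoneme's inventory record).
#' @export
classify_phoneme <- function(ph, inv = arpabet_inventory()) {
  base <- strip_stress(ph)
  row <- inv[inv$phoneme == base, , drop = FALSE]
  if (nrow(row) != 1L)
    stop("unknown ARPABET symbol: ", ph)
  row
}

# "AE1" -> "AE"; consonants pass through
strip_stress <- function(ph) sub("[0-2]$", "", ph)

# stress digit of a vowel token, NA for consonants / unstressed notation
stress_digit <- function(ph) {
  m <- regmatches(ph, regexpr("[0-2]$", ph))
  if (length(m) == 0L) NA_integer_ else as.integer(m)
}

is_vowel_symbol <- function(ph, inv = arpabet_inventory()) {
  strip_stress(ph) %in% inv$phoneme[inv$is_vowel]
}
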