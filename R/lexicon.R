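#' Read a pronunciation lexicon in CMU Pronouncing Dictionary format
#'
#' Parses the flat-file format `WORD  PH1 PH2 ...`, where alternate
#' pronunciations are written `WORD(2)`, `WORD(3)`, ... and comment lines
#' start with `;;;`. Only the first pronunciation variant of each word is
#' retained (alternates are ignored throughout the package).
#'
#' @param path Path to a lexicon file. Defaults to the bundled lexicon.
#' @return A named list mapping lowercase words to ARPABET phoneme vectors.
#' @export
read_lexicon <- function(path = adspeech_lexicon_path()) {
  key <- paste0("lex:", path)
  cached <- .adspeech_cache[[key]]
  if (!is.null(cached)) return(cached)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[!startsWith(lines, ";;;") & nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "[ \t]+")[[1]]
    word <- parts[1]
    if (grepl("\\(\\d+\\)$", word)) next  # alternate variant, skip
    out[[tolower(word)]] <- parts[-1]
  }
  .adspeech_cache[[key]] <- out
  out
}

#' @rdname read_lexicon
#' @export
adspeech_lexicon_path <- function() {
  system.file("extdata", "lexicon_cmu.txt", package = "adspeech",
              mustWork = TRUE)
}

#' Word to ARPABET phonemes
#'
#' Looks the word up in the lexicon (first pronunciation variant); when
#' absent, a deterministic letter-to-sound fallback is applied: a digraph map
#' (`th`, `sh`, `ch`, `ng`, `oo`, `ee`, ...) followed by a single-letter map,
#' with word-final silent `e` dropped and a schwa appended if no vowel was
#' produced. Fallback output is always valid ARPABET; the `source` attribute
#' records whether the lexicon or the fallback produced the sequence.
#'
#' @param word A word token; normalized to lowercase alphabetic + apostrophe.
#' @param lexicon Named list from [read_lexicon()].
#' @return Character vector of ARPABET symbols with stress digits on vowels;
#'   attribute `source` is `"lexicon"` or `"fallback"`.
#' @export
#' @examples
#' lex <- read_lexicon()
#' to_phonemes("cat", lex)   # K AE1 T
to_phonemes <- function(word, lexicon) {
  w <- normalize_word(word)
  if (!nzchar(w)) stop("word normalizes to empty: ", sQuote(word))
  hit <- lexicon[[w]]
  if (!is.null(hit)) {
    return(structure(hit, source = "lexicon"))
  }
  structure(g2p_fallback(w), source = "fallback")
}

normalize_word <- function(word) {
  w <- tolower(trimws(word))
  gsub("[^a-z']", "", w)
}

# Deterministic rule-cascade grapheme-to-phoneme fallback.
g2p_fallback <- function(w) {
  w <- gsub("'", "", w)
  # final silent e (length > 2, not the only vowel letter)
  if (nchar(w) > 2 && endsWith(w, "e") &&
      grepl("[aeiouy]", substr(w, 1, nchar(w) - 1)))
    w <- substr(w, 1, nchar(w) - 1)
  digraphs <- list(
    ch = "CH", sh = "SH", th = "TH", ph = "F", wh = "W", ck = "K",
    ng = "NG", qu = c("K", "W"),
    oo = "UW", ee = "IY", ea = "IY", ai = "EY", ay = "EY",
    ou = "AW", ow = "AW", oi = "OY", oy = "OY", au = "AO", aw = "AO")
  letters_map <- list(
    a = "AE", b = "B", c = "K", d = "D", e = "EH", f = "F", g = "G",
    h = "HH", i = "IH", j = "JH", k = "K", l = "L", m = "M", n = "N",
    o = "AA", p = "P", q = "K", r = "R", s = "S", t = "T", u = "AH",
    v = "V", w = "W", x = c("K", "S"), y = "IY", z = "Z")
  vowel_set <- c("AA", "AE", "AH", "AO", "AW", "AY", "EH", "ER", "EY",
                 "IH", "IY", "OW", "OY", "UH", "UW")
  phs <- character(0)
  i <- 1L
  first <- TRUE
  while (i <= nchar(w)) {
    pair <- substr(w, i, i + 1L)
    ch1 <- substr(w, i, i)
    if (nchar(pair) == 2L && !is.null(digraphs[[pair]])) {
      phs <- c(phs, digraphs[[pair]])
      i <- i + 2L
    } else {
      if (ch1 == "y" && first) phs <- c(phs, "Y")
      else phs <- c(phs, letters_map[[ch1]])
      i <- i + 1L
    }
    first <- FALSE
  }
  if (!any(phs %in% vowel_set)) phs <- c(phs, "AH")
  # stress: first vowel primary, the rest unstressed
  seen_vowel <- FALSE
  for (k in seq_along(phs)) {
    if (phs[k] %in% vowel_set) {
      phs[k] <- paste0(phs[k], if (!seen_vowel) "1" else "0")
      seen_vowel <- TRUE
    }
  }
  phs
}
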