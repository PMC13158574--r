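#' Transcript and utterance containers
#'
#' An `adspeech_transcript` is an ordered list of utterances, each with a
#' speaker tier code, normalized lowercase word tokens, and optional start
#' and end times in seconds.
#'
#' @param utterances List of utterances (`list(speaker, words, start_time,
#'   end_time)`).
#' @param source_path Where the transcript came from.
#' @param speaker_filter_applied Whether non-participant tiers were dropped.
#' @return An object of class `adspeech_transcript`.
#' @export
make_transcript <- function(utterances, source_path = NA_character_,
                            speaker_filter_applied = FALSE) {
  structure(list(utterances = utterances, source_path = source_path,
                 speaker_filter_applied = speaker_filter_applied),
            class = "adspeech_transcript")
}

#' @rdname make_transcript
#' @param t An `adspeech_transcript`.
#' @return `transcript_words()`: character vector of all word tokens in order.
#' @export
transcript_words <- function(t) {
  unlist(lapply(t$utterances, `[[`, "words"), use.names = FALSE)
}

#' @export
print.adspeech_transcript <- function(x, ...) {
  cat("<adspeech_transcript>", length(x$utterances), "utterances,",
      length(transcript_words(x)), "word tokens\n")
  invisible(x)
}

#' Read a CHAT (.cha) transcript
#'
#' Parses the TalkBank/DementiaBank CHAT dialect: `@`-header lines are
#' skipped, `%`-dependent tiers are skipped, `*XXX:` main-tier lines (plus
#' tab-indented continuations) become utterances. Inline annotation is
#' normalized according to a fixed table:
#' \itemize{
#'   \item timing bullets (`0x15`-delimited `start_end` in ms) are removed
#'     and recorded as utterance times;
#'   \item retracing and repetition — `<...> [//]`, `<...> [/]` drop the
#'     retraced group; an unbracketed `[//]`/`[/]` drops all tokens back to
#'     the start of the utterance (or the previous retracing point), keeping
#'     the repaired form;
#'   \item `[: word]` replacement codes substitute the target word;
#'   \item all other bracketed codes (`[*]`, `[+ ...]`, `[% ...]`, ...) are
#'     dropped;
#'   \item `&=event` codes and `&+fragments` are dropped; fillers
#'     (`&-uh`, `&uh`) are kept as words;
#'   \item pause codes `(.)`, `(..)`, `(...)` are dropped; parenthesized
#'     completions inside words (`(be)cause`) keep their letters;
#'   \item unintelligible markers `xxx`/`yyy`/`www`, omissions (`0word`),
#'     `+`-codes and terminators are dropped; `word@x` markers lose the
#'     `@x`; compounds split at `_`; everything is lowercased and stripped
#'     to alphabetic characters plus apostrophe.
#' }
#'
#' @param path Path to a `.cha` file.
#' @param participant_only Drop all tiers except the participant tiers.
#' @param participant_tiers Tier codes regarded as the participant.
#' @return An `adspeech_transcript`.
#' @export
read_chat <- function(path, participant_only = TRUE,
                      participant_tiers = c("PAR", "CHI")) {
  if (!file.exists(path)) stop("cannot read CHAT file: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (length(lines) == 0L) stop("empty CHAT file: ", path)

  # merge continuation lines (leading tab) into the preceding line
  merged <- character(0)
  for (ln in lines) {
    if (grepl("^[\t ]+", ln) && length(merged) > 0L)
      merged[length(merged)] <- paste(merged[length(merged)], trimws(ln))
    else merged <- c(merged, ln)
  }

  main <- grep("^\\*[A-Za-z0-9]+:", merged, value = TRUE)
  if (length(main) == 0L) stop("no main tiers found in CHAT file: ", path)

  utts <- lapply(main, function(ln) {
    speaker <- sub("^\\*([A-Za-z0-9]+):.*$", "\\1", ln)
    body <- sub("^\\*[A-Za-z0-9]+:[\t ]*", "", ln)
    tm <- chat_times(body)
    list(speaker = speaker, words = normalize_chat_utterance(body),
         start_time = tm[1], end_time = tm[2])
  })
  if (participant_only)
    utts <- Filter(function(u) u$speaker %in% participant_tiers, utts)
  make_transcript(utts, source_path = path,
                  speaker_filter_applied = participant_only)
}

# timing bullet "\x15start_end\x15" in ms -> c(start_s, end_s)
chat_times <- function(body) {
  m <- regmatches(body, regexpr("[\x15•](\\d+)_(\\d+)[\x15•]", body))
  if (length(m) == 0L) return(c(NA_real_, NA_real_))
  parts <- as.numeric(strsplit(gsub("[\x15•]", "", m), "_")[[1]])
  parts / 1000
}

#' Normalize one CHAT utterance line to word tokens
#'
#' The normalization table of [read_chat()], exposed for testing; idempotent
#' on its own output.
#'
#' @param body Main-tier text after the speaker code.
#' @return Character vector of lowercase word tokens.
#' @export
normalize_chat_utterance <- function(body) {
  s <- gsub("[\x15•]\\d+_\\d+[\x15•]", " ", body)   # timing bullets
  # bracketed retracing/repetition of an angle group: drop the group
  s <- gsub("<[^<>]*>\\s*\\[/{1,2}\\]", " ", s)
  # replacement [: word] after a group or single word
  s <- gsub("<([^<>]*)>\\s*\\[:\\s*([^]]+)\\]", " \\2 ", s)
  s <- gsub("(\\S+)\\s*\\[:\\s*([^]]+)\\]", " \\2 ", s)
  # pause codes
  s <- gsub("\\(\\.{1,3}\\)", " ", s)

  toks <- strsplit(trimws(s), "[ \t]+")[[1]]
  out <- character(0)
  i <- 1L
  n <- length(toks)
  while (i <= n) {
    tk <- toks[i]
    if (grepl("^\\[/{1,2}\\]$", tk)) {        # unbracketed retracing:
      out <- character(0)                     # drop back to utterance start
      i <- i + 1L; next
    }
    if (grepl("^\\[", tk)) {                  # other bracketed code
      while (i <= n && !grepl("\\]$", toks[i])) i <- i + 1L
      i <- i + 1L; next
    }
    if (grepl("^&=", tk) || grepl("^&\\+", tk) || grepl("^\\+", tk) ||
        grepl("^0", tk) || tk %in% c("xxx", "yyy", "www")) {
      i <- i + 1L; next
    }
    tk <- sub("^&-?", "", tk)                 # fillers kept as words
    tk <- sub("@.*$", "", tk)                 # special-form marker
    tk <- gsub("[<>]", "", tk)
    tk <- gsub("\\(([a-zA-Z']*)\\)", "\\1", tk)  # (be)cause -> because
    for (piece in strsplit(tk, "_")[[1]]) {   # compounds split
      w <- normalize_word(piece)
      if (nzchar(w)) out <- c(out, w)
    }
    i <- i + 1L
  }
  out
}
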