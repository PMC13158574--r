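lex <- read_lexicon()

test_that("lexicon lookup returns the first CMU variant", {
  expect_identical(as.character(to_phonemes("cat", lex)),
                   c("K", "AE1", "T"))
  expect_identical(as.character(to_phonemes("the", lex)),
                   c("DH", "AH0"))
  expect_identical(attr(to_phonemes("the", lex), "source"), "lexicon")
})

test_that("out-of-vocabulary words fall back to valid ARPABET", {
  inv <- arpabet_inventory()
  p <- to_phonemes("zzqv", lex)
  expect_identical(attr(p, "source"), "fallback")
  expect_true(all(adspeech:::strip_stress(p) %in% inv$phoneme))
  expect_true(any(vapply(p, adspeech:::is_vowel_symbol, logical(1))))
  expect_error(to_phonemes("123", lex), "empty")
})

test_that("articulatory classification matches the reference records", {
  th <- classify_phoneme("TH")
  expect_false(th$is_vowel)
  expect_identical(th$place, "dental")
  expect_identical(th$manner, "fricative")
  expect_false(th$voiced)

  iy <- classify_phoneme("IY")
  expect_true(iy$is_vowel)
  expect_identical(iy$height, "high")
  expect_identical(iy$backness, "front")
  expect_true(iy$tense); expect_false(iy$round)

  ay <- classify_phoneme("AY1")
  expect_true(ay$diphthong)
  expect_error(classify_phoneme("QQ"), "unknown")
})

test_that("inventory place and manner classes partition the consonants", {
  inv <- arpabet_inventory()
  cons <- inv[!inv$is_vowel, ]
  expect_false(any(is.na(cons$place)))
  expect_false(any(is.na(cons$manner)))
  vows <- inv[inv$is_vowel, ]
  expect_true(all(is.na(vows$place)))
  expect_false(any(duplicated(inv$phoneme)))
})

test_that("maximal-onset syllabification matches hand parses", {
  p <- syllabify(c("AE1", "S", "T", "R", "AH0", "N", "AO2", "T"))
  expect_length(p$syllables, 3L)
  expect_identical(p$syllables[[2]]$onset, c("S", "T", "R"))
  expect_identical(p$syllables[[3]]$onset, "N")
  expect_identical(p$syllables[[3]]$coda, "T")
  expect_identical(p$stress, c(1L, 0L, 2L))

  k <- syllabify(c("K", "AE1", "T"))
  expect_length(k$syllables, 1L)
  expect_identical(k$syllables[[1]]$onset, "K")
  expect_identical(k$syllables[[1]]$coda, "T")

  expect_error(syllabify(c("K", "T")), "nucleus")
})

test_that("golden 30-word syllable parses are exact", {
  golden <- list(
    water = list(c("W", "AO1"), c("T", "ER0")),
    window = list(c("W", "IH1", "N"), c("D", "OW0")),
    cookie = list(c("K", "UH1"), c("K", "IY0")),
    mother = list(c("M", "AH1"), c("DH", "ER0")),
    little = list(c("L", "IH1"), c("T", "AH0", "L")),
    table = list(c("T", "EY1"), c("B", "AH0", "L")),
    standing = list(c("S", "T", "AE1", "N"), c("D", "IH0", "NG")),
    children = list(c("CH", "IH1", "L"), c("D", "R", "AH0", "N")),
    kitchen = list(c("K", "IH1"), c("CH", "AH0", "N")),
    sister = list(c("S", "IH1"), c("S", "T", "ER0")),
    garden = list(c("G", "AA1", "R"), c("D", "AH0", "N")),
    counter = list(c("K", "AW1", "N"), c("T", "ER0")),
    faucet = list(c("F", "AO1"), c("S", "AH0", "T")),
    curtain = list(c("K", "ER1"), c("T", "AH0", "N")),
    summer = list(c("S", "AH1"), c("M", "ER0")),
    ladder = list(c("L", "AE1"), c("D", "ER0")),
    lady = list(c("L", "EY1"), c("D", "IY0")),
    bottle = list(c("B", "AA1"), c("T", "AH0", "L")),
    another = list(c("AH0"), c("N", "AH1"), c("DH", "ER0")),
    overflow = list(c("OW1"), c("V", "ER0"), c("F", "L", "OW2")),
    washing = list(c("W", "AA1"), c("SH", "IH0", "NG")),
    running = list(c("R", "AH1"), c("N", "IH0", "NG")),
    behind = list(c("B", "IH0"), c("HH", "AY1", "N", "D")),
    because = list(c("B", "IH0"), c("K", "AO1", "Z")),
    outside = list(c("AW1", "T"), c("S", "AY1", "D")),
    astronaut = list(c("AE1"), c("S", "T", "R", "AH0"),
                     c("N", "AO2", "T")),
    street = list(c("S", "T", "R", "IY1", "T")),
    splash = list(c("S", "P", "L", "AE1", "SH")),
    square = list(c("S", "K", "W", "EH1", "R")),
    spring = list(c("S", "P", "R", "IH1", "NG")))
  for (w in names(golden)) {
    parse <- syllabify(to_phonemes(w, lex))
    got <- lapply(parse$syllables, function(s) c(s$onset, s$nucleus, s$coda))
    expect_identical(got, golden[[w]], info = w)
  }
})

test_that("syllabification round-trips 5000+ pronunciations legally", {
  onsets <- read_onsets()
  words <- names(lex)
  # extend the lexicon with generated forms through the G2P fallback
  syll <- c("ba", "tri", "sto", "len", "mar", "pli", "gra", "ne", "du",
            "ski", "vo", "cha", "ru", "spel", "dro", "ki", "ta", "mon")
  gen <- do.call(paste0, expand.grid(syll, syll, syll,
                                     stringsAsFactors = FALSE))  # 5832
  all_words <- c(words, gen)
  expect_gte(length(all_words), 5000L)
  n_checked <- 0L
  for (w in all_words) {
    phs <- as.character(to_phonemes(w, lex))
    parse <- tryCatch(syllabify(phs, onsets), error = function(e) NULL)
    if (is.null(parse)) next
    expect_identical(flatten_syllables(parse), phs, info = w)
    # onset legality (the word-initial cluster is exempt by construction)
    if (length(parse$syllables) > 1) {
      for (s in parse$syllables[-1]) {
        if (length(s$onset))
          expect_true(paste(adspeech:::strip_stress(s$onset),
                            collapse = " ") %in% onsets, info = w)
      }
    }
    n_checked <- n_checked + 1L
  }
  expect_gte(n_checked, 5000L)
})

test_that("phonological schema has the documented family sizes", {
  fg <- feature_groups()
  expect_identical(lengths(fg),
                   c(CPA = 18L, CMA = 27L, vowels = 16L, misc = 4L,
                     supra = 12L))
  all_names <- unlist(fg, use.names = FALSE)
  expect_false(any(duplicated(all_names)))   # partition
})

test_that("single-word extractions match hand counts", {
  f <- extract_phonology("cat", lex)
  expect_equal(f[["phon.supra.nbPhon"]], 3)
  expect_equal(f[["phon.CMA.stop_toPhon"]], 2 / 3)
  expect_equal(f[["phon.supra.consCluster"]], 0)
  expect_equal(f[["phon.supra.endConson"]], 1)
  expect_equal(f[["phon.supra.avgSyll"]], 1)
  expect_equal(f[["phon.supra.primStress"]], 1)

  f2 <- extract_phonology("the", lex)
  expect_equal(f2[["phon.CPA.dental_toPhon"]], 0.5)
  expect_equal(f2[["phon.CMA.fricative_toPhon"]], 0.5)
  expect_equal(f2[["phon.supra.endConson"]], 0)

  f3 <- extract_phonology("street", lex)
  expect_equal(f3[["phon.supra.consCluster"]], 1)
  expect_equal(f3[["phon.supra.lenOnset"]], 3)
  expect_equal(f3[["phon.supra.lenCoda"]], 1)

  expect_error(extract_phonology(character(0), lex), "empty")
})

test_that("ratio conservation holds on random transcripts", {
  fg <- feature_groups()
  place_tophon <- fg$CPA[grepl("_toPhon$", fg$CPA)]
  manner_tophon <- paste0("phon.CMA.",
                          c("stop", "fricative", "affricate", "nasal",
                            "liquid", "glide"), "_toPhon")
  set.seed(5)
  for (i in 1:20) {
    words <- sample(names(lex), sample(3:40, 1), replace = TRUE)
    f <- extract_phonology(words, lex)
    p_sum <- sum(f[place_tophon])
    m_sum <- sum(f[manner_tophon])
    expect_lt(abs(p_sum - m_sum), 1e-12)
    # independent vowel share from raw pronunciations
    phs <- unlist(lapply(words, function(w) as.character(to_phonemes(w,
                                                                     lex))))
    v_share <- mean(vapply(phs, adspeech:::is_vowel_symbol, logical(1)))
    expect_lt(abs((1 - v_share) - p_sum), 1e-12)
    expect_true(all(f[c(fg$CPA, fg$CMA, fg$vowels, fg$misc)] >= 0 &
                      f[c(fg$CPA, fg$CMA, fg$vowels, fg$misc)] <= 1))
  }
})

test_that("injecting dental-heavy function words raises the dental rate", {
  base <- c("boy", "cookie", "water", "window", "falls", "garden")
  prev <- -1
  for (n_the in c(0, 3, 8, 20)) {
    f <- extract_phonology(c(base, rep(c("the", "this", "that"),
                                       length.out = n_the)), lex)
    expect_gt(f[["phon.CPA.dental_toPhon"]], prev)
    prev <- f[["phon.CPA.dental_toPhon"]]
  }
})
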