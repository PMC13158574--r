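---
title: "Speech biomarkers for Alzheimer's detection: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Speech biomarkers for Alzheimer's detection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis

`adspeech` implements a complete speech-based screening pipeline for
Alzheimer's disease (AD): three feature families are extracted from a
recording and its transcript, screened and ranked by five feature-selection
methods, and fed to a zoo of classifiers and ensembles. Because the clinical
corpora this kind of analysis is usually run on (DementiaBank / ADReSS-style
picture-description recordings) are membership-gated, the package ships a
synthetic paired audio-plus-transcript generator that reproduces the
*statistical structure* the analysis assumes, with a ground-truth ledger, so
that every stage is testable end to end.

The pipeline is:

1. **Ingest** — CHAT (`.cha`) transcripts with a documented normalization
   table, and mono WAV audio resampled to a 16 kHz working rate.
2. **Phonological features** (transcript): ARPABET pronunciations from a
   CMU-format lexicon, articulatory classification, maximal-onset
   syllabification, and 77 ratio/count features in five families.
3. **Acoustic/prosodic features** (audio): frame-level low-level
   descriptors (F0, voicing, RMS, ZCR, RASTA-filtered log mel bands, MFCC,
   spectral shape, log HNR, per-cycle jitter and shimmer) mapped to scalars
   by a catalog of 33 statistical functionals, with the
   `<lld>_sma[_de]_<functional>` naming scheme.
4. **Timing features**: pause ratios at 10/25/50/100/200 ms thresholds and
   three articulation rates (words, characters, syllables per second).
5. **Selection**: stage-1 mRMR screening (top 300 globally, or the top 10%
   within each feature family), then stage-2 ranking by ANOVA F,
   chi-square, information gain and ReliefF, with letter grades A–D by rank
   percentile.
6. **Modeling**: SVM, logistic regression, linear discriminant, AdaBoost,
   bagging, random forest, gradient boosting and an MLP; incremental top-k
   sweeps; hard/soft voting and a stacked ensemble with an AdaBoost
   meta-learner on out-of-fold probabilities; permutation importance.

# Key parameters

| parameter | default | meaning |
|---|---|---|
| working sample rate | 16 000 Hz | all audio resampled on ingest |
| frame length / hop | 25 ms / 10 ms | analysis framing (Hann window) |
| F0 search band | 75–500 Hz | autocorrelation pitch tracker |
| voicing threshold | 0.45 | normalized ACF peak ratio for voicing |
| SMA window | 3 frames | contour smoothing before functionals |
| mel bands / MFCCs | 26 / 12 | auditory spectrum and cepstrum size |
| silence threshold | −35 dB | relative to the 95th-percentile frame RMS |
| stage-1 quota | 300 global / 10% per family | mRMR screening |
| ReliefF neighbors | 10 | hits/misses per instance |

The classifier defaults are fixed, documented values: AdaBoost with 100
estimators; random forest with depth
limited to 2 (implemented as `maxnodes = 4`, the leaf count of a depth-2
binary tree, since `randomForest` has no depth parameter); XGBoost with
`eta = 0.001`, 5 600 rounds, `max_depth = 5`, `min_child_weight = 1`,
`gamma = 0`, `subsample = 0.8`, `colsample_bytree = 0.9`, binary-logistic
objective; MLP with one hidden layer of 50 units, 200 iterations and weight
decay `1e-8`. The MLP is `nnet::nnet`, the standard single-hidden-layer
network in R; it uses logistic hidden units and quasi-Newton optimization
rather than tanh/Adam, which we accept as the R-native equivalent.

# The pitch, HNR and jitter/shimmer chain

F0 is tracked by the normalized autocorrelation method: per frame the ACF is
computed by FFT, corrected for the triangular lag bias (so a perfectly
periodic frame scores `r ~ 1` at its period), and the best peak in the
pitch band is chosen among local maxima with an octave cost of 0.1 per
octave to suppress period-doubling; parabolic interpolation gives sub-sample
lag resolution. A frame is voiced when the peak ratio reaches the threshold.
The same peak ratio `r` feeds the harmonicity measure
`HNR = 10 log10(r / (1 - r))` dB, clipped to ±100 dB to keep functionals
finite.

Jitter and shimmer are computed from explicit glottal-cycle tracking:
waveform peaks are picked inside F0-predicted windows (`0.8–1.25` periods
after the previous peak) with parabolic sub-sample refinement, and

```
jitter_local  = mean |T_i - T_(i-1)| / mean T
shimmer_local = mean |A_i - A_(i-1)| / mean A
```

with differences taken only within continuous voiced runs and cycles
outside the pitch band discarded. This is a peak-picking rather than
waveform-matching implementation; the test suite requires injected
perturbations of 0–4% to be recovered within 0.5 percentage points, and the
acceptance script reports the realized maximum error.

# Phonological schema decisions

The schema serves 18 consonant-place (CPA), 27 consonant-manner (CMA), 16
vowel, 4 miscellaneous and 12 supra-phonemic features:

* **CPA 18** = nine place classes (bilabial, labiodental, dental, alveolar,
  postalveolar, palatal, velar, glottal, labiovelar) × {ratio to all
  phonemes, ratio to consonants}. The nine places *partition* the consonant
  inventory, which makes the conservation identities exact: the place
  ratios sum to the consonant share, as do the base manner ratios.
* **CMA 27** = six manner classes (stop, fricative, affricate, nasal,
  liquid, glide) plus three composites (`friAffLiq`, `stopNas`,
  `obstruent`) × {to-phon, to-cons, voiced share}.
* **Vowels 16** = eight types (high, mid, low, front, central, back, tense,
  round) × {to-phon, to-vow}. The source literature names only some of its
  eight vowel types; this set is the package's documented choice, not a
  claim about the original.
* Ratios are pooled over the recording's phoneme counts by default (a
  `per_word` flag averages word-level ratios instead); pooling makes the
  conservation identities hold to machine precision on every transcript.

Syllabification is pure maximal onset: each intervocalic cluster is split
so the following onset is the longest suffix attested in the legal-onset
table; word-initial clusters become the first onset wholesale and
word-final clusters the last coda, so flattening a parse always reproduces
the input. The onset table is a committed, hand-curated inventory of
standard English onsets (singles plus clusters such as `S T R`); a
data-driven table induced from the bundled lexicon was rejected because a
~230-word lexicon under-attests legitimate clusters. Syllabic consonants
are detected as schwa + sonorant (`AH0` + L/M/N/R) for the miscellaneous
ratios only, leaving the syllable parse untouched.

The bundled lexicon is a hand-curated ~230-entry subset of conversational
and picture-description vocabulary in CMU flat-file format; only the first
pronunciation variant is used. Out-of-vocabulary words go through a
deterministic two-level letter-to-sound cascade (digraph map, then letter
map, final silent-e removal, schwa insertion when no vowel was produced)
and are flagged, with the corpus OOV rate recorded on the feature vector.

In CHAT normalization, fillers (`uh`, `um`) are kept as words, paren-coded
events and pause codes are dropped, and retracing marks resolve to the
repaired form. An unbracketed retracing mark (`[//]` with no `<...>` group)
drops all tokens back to the utterance start or the previous retracing
point; this is more aggressive than the single-word convention but matches
how repairs are actually written in the picture-description transcripts
this dialect targets ("the boy [//] a boy falls" keeps "a boy falls").

# Functional catalog conventions

Where the openSMILE-style functional names are underspecified we fixed and
documented interpretations: `qreg1` is the linear coefficient of the
quadratic least-squares fit and `qregerrQ` its RMS residual; `lpc1..3` are
order-3 autocorrelation-method linear-prediction coefficients of the
mean-removed contour; segments for `meanSegLen`/`maxSegLen` are maximal
runs above 25% of the contour's range; `riseTime` is the fraction of
positive frame-to-frame differences; peaks are strict local maxima above
the 75th percentile; `upleveltime75` is the fraction of frames above 75% of
the range; the mode is the midpoint of the fullest of 20 equal-width bins
(ties resolved toward the bin nearest the mean); quantiles use the type-7
convention; `kurtosis_pearson` is `m4/m2^2` and `kurtosis_fisher` subtracts
3. Contours with fewer than four usable frames yield missing values for
every functional, and voiced-only families (F0, HNR, jitter, shimmer)
restrict to masked frames. Missing feature values are median-imputed at
modeling time, with statistics estimated on the training split only.

# What the synthetic generator does and does not emulate

Each synthetic recording pairs a transcript (words sampled from the bundled
lexicon, sentence lengths Poisson(8)+1, word count matched to duration ×
speaking rate) with source-only audio: sentences become voiced segments
built from a fixed five-harmonic (1/h rolloff) pulse kernel placed at cycle
onsets, separated by lognormal pauses (`meanlog = log 0.15 s`,
`sdlog = 0.6`). Cycle-period and cycle-amplitude perturbations are drawn
from centered Gaussians and *rescaled so the local jitter/shimmer formula
applied to the realized cycles equals the requested percentage exactly*;
the ledger stores those realized cycles, so the measurement chain can be
validated against ground truth without trusting the extractor.

The committed presets are the package's study conditions (control vs
impaired): F0 mean 120 → 110 Hz, F0 SD 25 → 12 Hz, jitter 1.0 → 2.5%,
shimmer 4 → 8%, relative noise 0.03 → 0.10, pause scale 1.0 → 2.0, rate
2.5 → 1.6 words/s, function-word boost 1 → 3 (raising dental-consonant
rates through "the/this/that/there"). `weak` halves the gaps and `null`
makes the groups identical. These magnitudes are in the range clinical
phonetics reports for healthy older speakers versus dementia cohorts and
were fixed once, before any downstream evaluation.

What the generator does **not** emulate: formant structure (the source is
not filtered by a vocal tract), disfluencies aligned between audio and
transcript, interviewer overlap, channel noise, or ASR errors. MFCC and
spectral features are therefore exercised and noise-sensitive but not
"AD-like" in the clinical sense; passing the end-to-end tests shows the
pipeline recovers the injected statistical structure, not that it would
reach the same operating point on clinical audio.

One consequence matters for interpreting the effect-recovery check: the
additive-noise axis enters the raw waveform, so *every* spectral family
(RASTA bands, MFCC, spectral descriptors, ZCR, HNR, voicing) legitimately
measures a generative group difference. The only families generated
identically for both groups are overall amplitude (peak-normalized away)
and the envelope shape, which is what `generative_effect_features()`
encodes.

# Evaluation protocol and its caveats

The train/test split is balanced by design in the generator (54 + 24
subjects by default, mirroring the challenge-style corpus scale). The
incremental sweep selects the argmax of the *test* curve, exactly as the
challenge-style protocol does; this is optimistic, the documentation flags
it, and `run_full()` reports the sweep curves so a reader can inspect
stability. Hard-vote ties go to the positive class (screening favors
sensitivity). Stacking trains an AdaBoost meta-learner on 5-fold
out-of-fold base probabilities. Cross-corpus evaluation restricts to the
intersection of feature names and carries imputation/scaling statistics
from the training corpus only.

Problem sizes used by the test suite and the acceptance script, chosen to
exercise the full design at desk scale: the strong-preset experiment runs
once at 54 + 24 subjects with the full LLD grid (~3 400 features); the
zero-effect calibration runs 20 seeds at 20 + 12 subjects on the
transcript-and-timing feature groups (the null property — F1 at chance —
does not depend on the feature count, and these groups avoid recomputing
the full spectral grid 20 times); parameter-recovery checks use 20
recordings per level. Within those conditions the strong preset reaches
ensemble F1 = 1.0 and the null preset stays at mean F1 ≈ 0.50.

# Known limitations

* The acoustic front end is a curated, versioned LLD×functional grid, not a
  bit-exact reimplementation of any existing toolkit's 6 000-feature set;
  comparisons across toolkits should be made at the level of feature
  *families*.
* Jitter/shimmer by peak-picking degrade gracefully but are not validated
  on pathological phonation types (diplophonia, creak).
* The G2P fallback is a rule cascade adequate for feature ratios, not a
  pronunciation model; OOV-heavy corpora should supply a full CMU
  dictionary file via `read_lexicon(path)`.
* English-only phonology; CHAT support covers the DementiaBank dialect's
  main-tier conventions, not the full CHAT specification.
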