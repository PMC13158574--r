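#' Discretization scheme for information-theoretic scores
#'
#' Continuous features are discretized before the chi-square, information
#' gain and mutual-information computations. `three_level_sigma` cuts at
#' `mean - k sigma` and `mean + k sigma` (the common mRMR convention);
#' `equal_frequency` uses quantile bins.
#'
#' @param method `"three_level_sigma"` or `"equal_frequency"`.
#' @param bins Number of bins (>= 2; fixed at 3 for `three_level_sigma`).
#' @param sigma_factor The `k` in the sigma cuts (default 0.5).
#' @return A `discretization` list.
#' @export
discretization <- function(method = c("three_level_sigma",
                                      "equal_frequency"),
                           bins = 3L, sigma_factor = 0.5) {
  method <- match.arg(method)
  if (bins < 2L) stop("need at least 2 bins")
  list(method = method, bins = as.integer(bins),
       sigma_factor = sigma_factor)
}

# integer bin codes; constant features land in a single bin
discretize_feature <- function(x, d = discretization()) {
  x <- as.numeric(x)
  ok <- is.finite(x)
  out <- rep(1L, length(x))
  if (!any(ok)) return(out)
  if (d$method == "three_level_sigma") {
    mu <- mean(x[ok]); s <- stats::sd(x[ok])
    if (!is.finite(s) || s < 1e-30) return(out)
    out[ok] <- 1L + (x[ok] >= mu - d$sigma_factor * s) +
      (x[ok] > mu + d$sigma_factor * s)
  } else {
    qs <- unique(stats::quantile(x[ok], probs = seq(0, 1,
                                                    length.out = d$bins + 1L),
                                 names = FALSE, type = 7))
    if (length(qs) < 2L) return(out)
    out[ok] <- findInterval(x[ok], qs, rightmost.closed = TRUE,
                            all.inside = TRUE)
  }
  out
}

#' One-way ANOVA F score
#'
#' Between-group mean square over within-group mean square for a binary
#' grouping. Zero within-group variance with distinct means is guarded to a
#' large sentinel (1e12).
#'
#' @param x Numeric feature column.
#' @param y Binary labels (two classes present).
#' @return The F statistic.
#' @export
anova_f <- function(x, y) {
  y <- as.factor(y)
  if (nlevels(y) < 2L) stop("both classes must be present")
  ok <- is.finite(x)
  x <- x[ok]; y <- droplevels(y[ok])
  if (nlevels(y) < 2L || length(x) < 4L) stop("need n >= 4 with both classes")
  mu <- mean(x)
  ssb <- sum(tapply(x, y, function(g) length(g) * (mean(g) - mu)^2))
  ssw <- sum(tapply(x, y, function(g) sum((g - mean(g))^2)))
  dfb <- nlevels(y) - 1L
  dfw <- length(x) - nlevels(y)
  if (ssw < 1e-30) {
    if (ssb < 1e-30) return(0)
    return(1e12)
  }
  (ssb / dfb) / (ssw / dfw)
}

#' Chi-square, information gain and mutual information
#'
#' `chi2_score()` min-max scales the feature to non-negative, discretizes
#' it, and computes the chi-square statistic of the bin-by-class
#' contingency table. `info_gain()` is `H(Y) - H(Y | bin(X))` in bits;
#' `mutual_info()` is the symmetric mutual information of two discretized
#' features in bits. Constant features score 0.
#'
#' @param x,x1,x2 Numeric feature columns.
#' @param y Binary labels.
#' @param d A [discretization()].
#' @return A non-negative score (chi-square) or bits (IG / MI).
#' @export
chi2_score <- function(x, y, d = discretization()) {
  x <- as.numeric(x)
  ok <- is.finite(x)
  rng <- range(x[ok])
  if (diff(rng) < 1e-30) return(0)
  xs <- (x - rng[1]) / diff(rng)
  tab <- table(discretize_feature(xs, d)[ok], as.factor(y)[ok])
  chisq_stat(tab)
}

chisq_stat <- function(tab) {
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (length(tab) == 0L || nrow(tab) < 2L || ncol(tab) < 2L) return(0)
  expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - expd)^2 / expd)
}

#' @rdname chi2_score
#' @export
info_gain <- function(x, y, d = discretization()) {
  ok <- is.finite(as.numeric(x))
  b <- discretize_feature(x, d)[ok]
  yy <- as.factor(y)[ok]
  entropy_bits(table(yy)) - cond_entropy_bits(b, yy)
}

#' @rdname chi2_score
#' @export
mutual_info <- function(x1, x2, d = discretization()) {
  ok <- is.finite(as.numeric(x1)) & is.finite(as.numeric(x2))
  b1 <- discretize_feature(x1, d)[ok]
  b2 <- discretize_feature(x2, d)[ok]
  entropy_bits(table(b1)) - cond_entropy_bits(b2, b1)
}

entropy_bits <- function(tab) {
  p <- tab[tab > 0] / sum(tab)
  -sum(p * log2(p))
}

cond_entropy_bits <- function(given, target) {
  n <- length(given)
  h <- 0
  for (g in unique(given)) {
    sel <- given == g
    h <- h + sum(sel) / n * entropy_bits(table(target[sel]))
  }
  h
}

# MI between a discretized feature and the class labels
mi_with_label <- function(x, y, d = discretization()) {
  ok <- is.finite(as.numeric(x))
  b <- discretize_feature(x, d)[ok]
  yy <- as.integer(as.factor(y))[ok]
  entropy_bits(table(yy)) - cond_entropy_bits(b, yy)
}

#' ReliefF feature weights
#'
#' Standard ReliefF for binary classes: every instance is visited, its `k`
#' nearest hits (same class) and `k` nearest misses (other class) under
#' range-normalized Manhattan distance are found, and each feature's weight
#' is updated by `sum(diff to misses)/(n k) - sum(diff to hits)/(n k)`,
#' where `diff` is the range-normalized absolute difference. A class with
#' fewer than `k + 1` members reduces `k` with a warning.
#'
#' @param X Numeric matrix (rows = instances) or `adspeech_fm`.
#' @param y Binary labels.
#' @param k_neighbors Number of neighbors per class (default 10).
#' @return Named numeric vector of feature weights.
#' @export
relieff <- function(X, y, k_neighbors = 10L) {
  if (inherits(X, "adspeech_fm")) { y <- X$labels; X <- X$values }
  y <- binary_labels(y)
  X <- as.matrix(X)
  n <- nrow(X)
  cls_n <- min(table(y))
  k <- k_neighbors
  if (cls_n < k + 1L) {
    k <- max(1L, cls_n - 1L)
    warning("class too small for k = ", k_neighbors, "; using k = ", k)
  }
  rng <- apply(X, 2, function(col) diff(range(col, na.rm = TRUE)))
  rng[!is.finite(rng) | rng < 1e-30] <- 1
  Xn <- sweep(X, 2, rng, `/`)
  Xn[!is.finite(Xn)] <- 0
  D <- as.matrix(stats::dist(Xn, method = "manhattan"))
  W <- numeric(ncol(X))
  for (i in seq_len(n)) {
    d <- D[i, ]; d[i] <- Inf
    hits <- order(d + ifelse(y == y[i], 0, Inf))[seq_len(k)]
    miss <- order(d + ifelse(y != y[i], 0, Inf))[seq_len(k)]
    W <- W + colSums(abs(Xn[miss, , drop = FALSE] -
                           matrix(Xn[i, ], k, ncol(X), byrow = TRUE))) -
      colSums(abs(Xn[hits, , drop = FALSE] -
                    matrix(Xn[i, ], k, ncol(X), byrow = TRUE)))
  }
  stats::setNames(W / (n * k), colnames(X))
}

#' Greedy mRMR selection (MID scheme)
#'
#' First pick maximizes mutual information with the label; each subsequent
#' pick maximizes `MI(f; y) - mean MI(f; s)` over already-selected `s`.
#' Ties are broken by feature name.
#'
#' @param X Numeric matrix with column names, or `adspeech_fm`.
#' @param y Binary labels.
#' @param k Number of features to select.
#' @param d A [discretization()].
#' @return Character vector of `k` selected feature names, in pick order.
#' @export
mrmr_select <- function(X, y, k, d = discretization()) {
  if (inherits(X, "adspeech_fm")) { y <- X$labels; X <- X$values }
  if (k <= 0) stop("k must be positive")
  X <- as.matrix(X)
  k <- min(k, ncol(X))
  feats <- colnames(X)
  B <- apply(X, 2, discretize_feature, d = d)   # n x p integer codes
  nb <- max(B)
  yy <- as.integer(as.factor(binary_labels(y)))
  ny <- max(yy)
  ent <- function(cnt) { p <- cnt[cnt > 0] / sum(cnt); -sum(p * log2(p)) }
  hy <- ent(tabulate(yy, ny))
  hb <- vapply(seq_len(ncol(B)), function(j)
    ent(tabulate(B[, j], nb)), numeric(1))
  rel <- vapply(seq_len(ncol(B)), function(j)
    hy + hb[j] - ent(tabulate((B[, j] - 1L) * ny + yy, nb * ny)),
    numeric(1))

  selected <- integer(0)
  red_sum <- numeric(ncol(B))
  remaining <- seq_len(ncol(B))
  for (step in seq_len(k)) {
    score <- if (length(selected) == 0L) rel[remaining]
             else rel[remaining] - red_sum[remaining] / length(selected)
    ord <- order(-score, feats[remaining])
    pick <- remaining[ord[1]]
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
    if (length(remaining) > 0L && step < k) {
      bp <- (B[, pick] - 1L) * nb
      red_sum[remaining] <- red_sum[remaining] + hb[pick] +
        hb[remaining] -
        vapply(remaining, function(j)
          ent(tabulate(bp + B[, j], nb * nb)), numeric(1))
    }
  }
  feats[selected]
}

#' Letter grades from rank percentile
#'
#' Grade by percentile `p = (rank - 1) / n`: `A` if `p < 0.10`, `B` if
#' `p < 0.25`, `C` if `p < 0.50`, `D` if `p < 0.75`, else `-`. The
#' `(rank - 1)` convention makes the top feature of any list an `A`.
#'
#' @param n Number of ranked features.
#' @return Character vector of grades in rank order.
#' @export
letter_grades <- function(n) {
  p <- (seq_len(n) - 1) / n
  ifelse(p < 0.10, "A",
         ifelse(p < 0.25, "B",
                ifelse(p < 0.50, "C",
                       ifelse(p < 0.75, "D", "-"))))
}

#' Rank features with one method
#'
#' @param X Numeric matrix with column names, or `adspeech_fm`.
#' @param y Binary labels.
#' @param method One of `anova`, `chi2`, `infogain`, `relieff`, `mrmr`.
#' @param d A [discretization()].
#' @param k_neighbors ReliefF neighbors.
#' @return A `ranking` data.frame with columns `feature`, `score`, `rank`,
#'   `grade`, ordered best first (score descending, ties by name).
#' @export
rank_features <- function(X, y, method = c("anova", "chi2", "infogain",
                                           "relieff", "mrmr"),
                          d = discretization(), k_neighbors = 10L) {
  method <- match.arg(method)
  if (inherits(X, "adspeech_fm")) { y <- X$labels; X <- X$values }
  y <- binary_labels(y)
  X <- as.matrix(X)
  feats <- colnames(X)
  scores <- switch(method,
    anova = vapply(feats, function(f) anova_f(X[, f], y), numeric(1)),
    chi2 = vapply(feats, function(f) chi2_score(X[, f], y, d), numeric(1)),
    infogain = vapply(feats, function(f) info_gain(X[, f], y, d),
                      numeric(1)),
    relieff = relieff(X, y, k_neighbors),
    mrmr = {
      ord <- mrmr_select(X, y, ncol(X), d)
      stats::setNames(rev(seq_along(ord)), ord)[feats]
    })
  ord <- order(-scores, feats)
  out <- data.frame(feature = feats[ord], score = as.numeric(scores[ord]),
                    rank = seq_along(feats),
                    grade = letter_grades(length(feats)),
                    stringsAsFactors = FALSE)
  attr(out, "method") <- method
  out
}

#' The two-stage selection protocol
#'
#' Stage 1 screens with mRMR, either globally (`global_n`, keeping the top
#' `n` features over the whole table) or within feature families
#' (`family_fraction`, keeping the top fraction per family, at least one
#' per family). Stage 2 ranks the surviving set with each of the four
#' ranking methods (ANOVA, chi-square, information gain, ReliefF).
#'
#' @param X Numeric matrix with column names, or labeled `adspeech_fm`.
#' @param y Binary labels (ignored when `X` is a labeled `adspeech_fm`).
#' @param stage1 `"global"` or `"family"` (or `"none"` to skip screening).
#' @param global_n Features kept by global screening (default 300).
#' @param family_fraction Fraction kept per family (default 0.10).
#' @param families Named character vector mapping feature name to family;
#'   defaults to [feature_family()] of the column names.
#' @param d A [discretization()].
#' @return List with `kept` (stage-1 survivors) and `rankings` (named list
#'   of `ranking` data.frames for the four stage-2 methods).
#' @export
two_stage_select <- function(X, y = NULL, stage1 = c("global", "family",
                                                     "none"),
                             global_n = 300L, family_fraction = 0.10,
                             families = NULL, d = discretization()) {
  stage1 <- match.arg(stage1)
  if (inherits(X, "adspeech_fm")) { y <- X$labels; X <- X$values }
  y <- binary_labels(y)
  X <- as.matrix(X)

  kept <- colnames(X)
  if (stage1 == "global") {
    if (global_n < ncol(X)) kept <- mrmr_select(X, y, global_n, d)
  } else if (stage1 == "family") {
    if (is.null(families)) families <- feature_family(colnames(X))
    kept <- unlist(lapply(split(colnames(X), families), function(fam) {
      quota <- max(1L, floor(family_fraction * length(fam)))
      if (quota >= length(fam)) {
        warning("family quota >= family size; keeping whole family")
        return(fam)
      }
      mrmr_select(X[, fam, drop = FALSE], y, quota, d)
    }), use.names = FALSE)
  }

  Xk <- X[, kept, drop = FALSE]
  rankings <- lapply(c(anova = "anova", chi2 = "chi2",
                       infogain = "infogain", relieff = "relieff"),
                     function(m) rank_features(Xk, y, m, d))
  list(kept = kept, rankings = rankings)
}

#' Feature family of a feature name
#'
#' Used by family-scoped stage-1 screening: phonological and timing
#' features group by their schema prefix (`phon.CPA`, `timing`, ...);
#' acoustic/prosodic grid features group by LLD class (`acoustic.audSpec`,
#' `acoustic.mfcc`, `acoustic.pcm`, `prosodic.F0`, ...).
#'
#' @param names Character vector of feature names.
#' @return Character vector of family labels.
#' @export
feature_family <- function(names) {
  vapply(names, function(nm) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (parts[1] %in% c("phon")) paste(parts[1:2], collapse = ".")
    else if (parts[1] == "timing") "timing"
    else if (parts[1] %in% c("acoustic", "prosodic")) {
      lld <- sub("^([A-Za-z]+).*$", "\\1",
                 sub("_sma.*$", "", parts[2]))
      paste(parts[1], lld, sep = ".")
    } else parts[1]
  }, character(1))
}
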