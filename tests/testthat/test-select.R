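test_that("ANOVA F matches hand computations and guards degeneracy", {
  expect_equal(anova_f(c(1, 2, 3, 4, 5, 6), c(0, 0, 0, 1, 1, 1)), 13.5)
  expect_equal(anova_f(c(1, 3, 1, 3), c(0, 0, 1, 1)), 0)
  expect_equal(anova_f(c(1, 1, 2, 2), c(0, 0, 1, 1)), 1e12)
  expect_error(anova_f(c(1, 2, 3), c(0, 0, 0)), "class")
})

test_that("chi-square, IG and MI match their contingency oracles", {
  x <- c(rep(0, 10), rep(1, 10))
  y <- c(rep(0, 10), rep(1, 10))
  expect_equal(chi2_score(x, y), 20)      # 2x2 [[10,0],[0,10]]
  expect_equal(info_gain(x, y), 1)        # perfect balanced separator
  # independence
  xi <- rep(c(0, 1), 10)
  yi <- rep(c(0, 0, 1, 1), 5)
  expect_equal(chi2_score(xi, yi), 0)
  expect_equal(info_gain(xi, yi), 0, tolerance = 1e-12)
  expect_equal(chi2_score(rep(3, 20), y), 0)   # constant feature
  # non-negativity and MI symmetry on random data
  set.seed(4)
  for (i in 1:25) {
    a <- rnorm(30); b <- rnorm(30); yy <- rep(c(0, 1), 15)
    expect_gte(chi2_score(a, yy), 0)
    expect_gte(info_gain(a, yy), -1e-12)
    expect_lt(abs(mutual_info(a, b) - mutual_info(b, a)), 1e-12)
  }
})

test_that("ReliefF equals a brute-force oracle on small matrices", {
  brute_relieff <- function(X, y, k) {
    n <- nrow(X); p <- ncol(X)
    rng <- apply(X, 2, function(c) max(c) - min(c))
    rng[rng < 1e-30] <- 1
    Xn <- sweep(X, 2, rng, `/`)
    W <- numeric(p)
    for (i in 1:n) {
      d <- apply(Xn, 1, function(r) sum(abs(r - Xn[i, ])))
      d[i] <- Inf
      hits <- order(ifelse(y == y[i], d, Inf))[1:k]
      miss <- order(ifelse(y != y[i], d, Inf))[1:k]
      for (f in 1:p)
        W[f] <- W[f] + sum(abs(Xn[miss, f] - Xn[i, f])) / (n * k) -
          sum(abs(Xn[hits, f] - Xn[i, f])) / (n * k)
    }
    W
  }
  set.seed(9)
  for (i in 1:8) {
    n <- sample(c(12, 16, 20), 1); p <- sample(2:5, 1)
    X <- matrix(rnorm(n * p), n, p)
    colnames(X) <- paste0("f", 1:p)
    y <- rep(c(0, 1), length.out = n)
    k <- sample(2:4, 1)
    expect_equal(unname(relieff(X, y, k)), brute_relieff(X, y, k),
                 tolerance = 1e-12)
  }
})

test_that("ReliefF separates relevant from constant features", {
  set.seed(1)
  y <- rep(c(0, 1), each = 20)
  X <- cbind(lab = y + rnorm(40, 0, 0.01), const = rep(1, 40))
  w <- relieff(X, y, 5)
  expect_gt(w["lab"], 0)
  expect_equal(unname(w["const"]), 0)
  # duplicating the row set preserves the weight ordering
  w2 <- relieff(rbind(X, X), c(y, y), 5)
  expect_identical(order(-w), order(-w2))
})

test_that("mRMR starts at max relevance and avoids redundant picks", {
  set.seed(2)
  n <- 60
  y <- rep(c(0, 1), each = n / 2)
  f1 <- y + rnorm(n, 0, 0.3)
  X <- cbind(a = f1, a_dup = f1, b = y + rnorm(n, 0, 0.8),
             noise1 = rnorm(n), noise2 = rnorm(n), noise3 = rnorm(n))
  # first pick = argmax MI with the label
  mis <- apply(X, 2, function(col) adspeech:::mi_with_label(col, y))
  sel <- mrmr_select(X, y, ncol(X))
  expect_identical(sel[1], names(which.max(mis)))
  # the exact duplicate is maximally redundant: deferred past the
  # independent informative feature (and never adjacent to its original)
  expect_false("a_dup" %in% sel[1:2])
  expect_gt(which(sel == "a_dup"), which(sel == "b"))
  # k = p returns a permutation
  expect_setequal(mrmr_select(X, y, ncol(X)), colnames(X))
  expect_error(mrmr_select(X, y, 0), "positive")
})

test_that("letter grades follow the rank-percentile brackets", {
  g <- letter_grades(100)
  expect_identical(g[5], "A")
  expect_identical(g[10], "A")
  expect_identical(g[11], "B")
  expect_identical(g[20], "B")
  expect_identical(g[26], "C")
  expect_identical(g[75], "D")
  expect_identical(g[80], "-")
  expect_identical(letter_grades(1), "A")
})

test_that("two-stage selection enforces its quotas", {
  set.seed(3)
  n <- 40
  y <- rep(c(0, 1), each = n / 2)
  X <- matrix(rnorm(n * 50), n, 50)
  X[, 1:5] <- X[, 1:5] + y
  colnames(X) <- c(paste0("phon.CPA.f", 1:20), paste0("timing.f", 1:10),
                   paste0("acoustic.mfcc[1]_sma_f", 1:20))
  out <- two_stage_select(X, y, stage1 = "family", family_fraction = 0.10)
  fams <- feature_family(out$kept)
  expect_identical(unname(table(fams)["phon.CPA"]), 2L)   # floor(0.1*20)
  expect_identical(unname(table(fams)["timing"]), 1L)

  out2 <- two_stage_select(X, y, stage1 = "global", global_n = 12L)
  expect_length(out2$kept, 12L)
  expect_named(out2$rankings, c("anova", "chi2", "infogain", "relieff"))
  for (r in out2$rankings) {
    expect_setequal(r$feature, out2$kept)
    expect_identical(r$rank, seq_len(12L))
  }
})

test_that("rankings are invariant to row order", {
  set.seed(6)
  n <- 30
  y <- rep(c(0, 1), each = 15)
  X <- matrix(rnorm(n * 8), n, 8)
  X[, 1] <- X[, 1] + 2 * y
  colnames(X) <- paste0("f", 1:8)
  perm <- sample(n)
  for (m in c("anova", "chi2", "infogain", "relieff")) {
    r1 <- rank_features(X, y, m)
    r2 <- rank_features(X[perm, ], y[perm], m)
    expect_identical(r1$feature, r2$feature, info = m)
  }
})

test_that("a perfectly separating feature ranks first for all methods", {
  set.seed(12)
  n <- 40
  y <- rep(c(0, 1), each = 20)
  X <- cbind(sep = y + rnorm(n, 0, 0.05),
             matrix(rnorm(n * 6), n, 6))
  colnames(X) <- c("sep", paste0("noise", 1:6))
  for (m in c("anova", "chi2", "infogain", "relieff"))
    expect_identical(rank_features(X, y, m)$feature[1], "sep", info = m)
})
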