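test_that("WBMS columns carry round(M*w) ones and rows are never empty", {
  B <- wbmsSample(c(1, 0, 0.5, 0.25), M = 100, seed = 3)
  expect_equal(dim(B), c(100L, 4L))
  expect_setequal(unique(as.integer(B)), c(0L, 1L))
  expect_equal(colSums(B), c(100, 0, 50, 25))
  expect_true(all(rowSums(B) >= 1))
  # reproducible under seed
  expect_identical(B, wbmsSample(c(1, 0, 0.5, 0.25), 100, seed = 3))
  expect_false(identical(B, wbmsSample(c(1, 0, 0.5, 0.25), 100, seed = 4)))
  expect_error(wbmsSample(c(0.5, 1.2), 10), "\\[0, 1\\]")
  # all-zero weights can never produce a usable row
  expect_error(wbmsSample(rep(0, 5), 20, seed = 1), "sampling error")
})

test_that("wavelength importance flags a uniquely informative channel", {
  set.seed(31)
  n <- 40; p <- 30; j <- 17
  X <- matrix(rnorm(n * p), n, p)
  y <- X[, j] + rnorm(n, sd = 0.1)
  T <- wavelengthImportance(X, y, nLV = 4)
  expect_true(all(T >= 0))
  expect_equal(which.max(T), j)

  # argmax identifies the planted channel in nearly all seeded trials
  hits <- sum(vapply(1:20, function(s) {
    set.seed(1000 + s)
    X <- matrix(rnorm(35 * 25), 35)
    y <- X[, 7] + rnorm(35, sd = 0.1)
    which.max(wavelengthImportance(X, y, nLV = 4)) == 7
  }, logical(1)))
  expect_gte(hits, 18)

  # duplicated channel: removal is fully compensated, importance stays ~1
  set.seed(32)
  Xd <- matrix(rnorm(40 * 10), 40)
  Xd[, 10] <- Xd[, 3] + rnorm(40, sd = 1e-6)
  yd <- Xd[, 3] + rnorm(40, sd = 0.1)
  Td <- wavelengthImportance(Xd, yd, nLV = 4)
  expect_equal(Td[3], 1, tolerance = 0.05)

  # numerically perfect full fit has undefined importance
  set.seed(33)
  z <- rnorm(20)
  Xe <- cbind(z, z, z)
  expect_error(wavelengthImportance(Xe, z, nLV = 2), "importance-undefined")
})

test_that("importance normalization and transforms behave", {
  expect_equal(normalizeImportance(c(2, 4)), c(0.5, 1))
  expect_equal(normalizeImportance(c(1, 1, 1)), c(1, 1, 1))
  set.seed(34)
  v <- runif(50, 0, 3)
  expect_equal(normalizeImportance(v), v / max(v))
  expect_error(normalizeImportance(c(0, 0)), "all importances are zero")
  expect_error(normalizeImportance(c(-1, 2)), "non-negative")

  # deviation transform: symmetric around WI = 1, bounded in [0, 1]
  d <- specFusion:::transformImportance(c(0.5, 1, 2), "deviation")
  expect_equal(d[1], d[3])
  expect_equal(d[2], 0)
  expect_equal(max(d), 1)
  expect_equal(specFusion:::transformImportance(c(2, 4), "ratio"), c(0.5, 1))
})

test_that("top-model frequencies implement the sigma-pool count", {
  B <- rbind(c(1, 1, 0), c(1, 0, 1), c(0, 1, 1), c(1, 0, 0))
  # keep top 2 of 4 models (sigma = 0.5); scores rank rows 2, 4 first
  Q <- topModelFrequencies(B, c(0.5, 0.1, 0.9, 0.2), sigma = 0.5)
  expect_equal(Q, c(1, 0, 0.5))
  # all-top variable -> 1; absent variable -> 0
  expect_equal(topModelFrequencies(rbind(c(1, 0), c(1, 0)), c(1, 2), 1), c(1, 0))
  # ties at the cutoff go to the lower row index
  Qt <- topModelFrequencies(rbind(c(1, 0), c(0, 1), c(1, 1)), c(0.3, 0.3, 0.9), 1 / 3)
  expect_equal(Qt, c(1, 0))
  expect_error(topModelFrequencies(B, c(1, 2), 0.5), "one RMSECV per model")
  expect_error(topModelFrequencies(B, c(1, 2, 3, 4), 0.01), "sigma")
})

test_that("weight update is the equal blend", {
  expect_equal(updateWeights(c(1, 0), c(0, 0)), c(0.5, 0))
  expect_equal(updateWeights(0.8, 0.4), 0.6)
  v <- runif(10)
  expect_equal(updateWeights(v, v), v)
  expect_error(updateWeights(1:3 / 3, 1:4 / 4), "length")
})

test_that("runHsicVsio selects K channels reproducibly with a sane trace", {
  set.seed(35)
  n <- 30; p <- 40
  X <- matrix(rnorm(n * p), n, p)
  y <- drop(X[, c(5, 15)] %*% c(1, 0.8)) + rnorm(n, sd = 0.3)
  cfg <- vsioConfig(M = 40, sigma = 0.1, K = 10, nLV = 5, importanceLV = 3,
                    maxOuterIter = 10, seed = 42)
  r <- runHsicVsio(X, y, cfg)
  expect_s4_class(r, "VSIOResult")
  expect_length(r@selected, 10L)
  expect_identical(r@selected, sort(r@selected))
  expect_true(all(r@weights >= 0 & r@weights <= 1))
  expect_true(all(r@frequencies >= 0 & r@frequencies <= 1))
  # running best of the trace is non-increasing and the tail stalls
  expect_true(all(diff(cummin(r@rmsecvTrace)) <= 0))
  nIt <- length(r@rmsecvTrace)
  if (nIt < cfg$maxOuterIter) {
    best <- min(r@rmsecvTrace)
    expect_true(all(utils::tail(r@rmsecvTrace, cfg$patience) >= best))
  }
  # identical config -> identical result in every field
  r2 <- runHsicVsio(X, y, cfg)
  expect_equal(r@weights, r2@weights)
  expect_identical(r@selected, r2@selected)
  expect_equal(r@rmsecvTrace, r2@rmsecvTrace)

  # p = K returns every channel regardless of weights
  rAll <- runHsicVsio(X[, 1:10], y, vsioConfig(M = 20, sigma = 0.2, K = 10,
                                               nLV = 3, importanceLV = 2,
                                               maxOuterIter = 3, seed = 1))
  expect_identical(rAll@selected, 1:10)
  expect_error(runHsicVsio(X[, 1:5], y, cfg), "p < K")
})

test_that("planted channels end with larger weights than noise channels", {
  # enrichment: sign test over seeds on mean final weights
  wins <- 0
  for (s in 1:8) {
    set.seed(400 + s)
    n <- 30; p <- 30
    X <- matrix(rnorm(n * p), n, p)
    inf <- c(4, 12, 21)
    y <- drop(X[, inf] %*% c(1, 0.9, 0.8)) + rnorm(n, sd = 0.4)
    r <- runHsicVsio(X, y, vsioConfig(M = 40, sigma = 0.1, K = 5, nLV = 4,
                                      importanceLV = 3, maxOuterIter = 8,
                                      seed = s))
    if (mean(r@weights[inf]) > mean(r@weights[-inf])) wins <- wins + 1
  }
  # one-sided binomial: 8/8 or 7/8 wins rejects fairness at p < 0.05
  expect_gte(wins, 7)
})

test_that("selection under a null response is indistinguishable from uniform", {
  # y independent of X: any fixed subset should be hit at the chance rate
  target <- 1:5
  hits <- integer(0)
  for (s in 1:12) {
    set.seed(600 + s)
    X <- matrix(rnorm(24 * 30), 24)
    y <- rnorm(24)
    r <- runHsicVsio(X, y, vsioConfig(M = 30, sigma = 0.2, K = 6, nLV = 3,
                                      importanceLV = 2, maxOuterIter = 4,
                                      seed = s))
    hits <- c(hits, sum(target %in% r@selected))
  }
  # expected hits per run: K * |target| / p = 1; chi-squared goodness vs
  # the hypergeometric-mean baseline
  expected <- 6 * 5 / 30
  test <- suppressWarnings(chisq.test(c(sum(hits), 12 * 5 - sum(hits)),
                                      p = c(expected / 5, 1 - expected / 5)))
  expect_gt(test$p.value, 0.01)
})

test_that("config validation catches bad settings", {
  expect_error(vsioConfig(M = 5), "M must be")
  expect_error(vsioConfig(sigma = 0), "sigma")
  expect_error(vsioConfig(sigma = 1.2), "sigma")
  expect_error(vsioConfig(M = 10, sigma = 0.01), "round")
  expect_error(vsioConfig(K = 0), "K must be")
  expect_error(vsioConfig(patience = 0), "patience")
})
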