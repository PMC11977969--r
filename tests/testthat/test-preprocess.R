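test_that("airpls removes smooth baselines and preserves peaks", {
  # fixed point: zero in, zero out
  z <- airplsBaseline(rep(0, 50), lambda = 1e4)
  expect_equal(z$baseline, rep(0, 50), tolerance = 1e-10)
  expect_equal(z$corrected, rep(0, 50), tolerance = 1e-10)

  # pure linear ramp: corrected residual under 1% of the ramp range
  ramp <- seq(0, 10, length.out = 200)
  r <- airplsBaseline(ramp, lambda = 1e5)
  expect_lt(max(abs(r$corrected)), 0.1)

  # ramp + Gaussian peak of height 1: peak survives within 5%
  ax <- seq_len(300)
  peak <- exp(-(ax - 150)^2 / (2 * 8^2))
  spec <- 0.02 * ax + peak
  out <- airplsBaseline(spec, lambda = 1e5)
  expect_equal(max(out$corrected), 1, tolerance = 0.05)
  # baseline stays at or below the signal almost everywhere
  expect_gt(mean(out$corrected > -0.02), 0.95)

  expect_error(airplsBaseline(c(1, NA, 3, 4, 5)), "non-finite")
  expect_error(airplsBaseline(1:10, lambda = -1), "lambda")
  expect_error(airplsBaseline(1:3), "length >= 5")
})

test_that("msc inverts affine distortions exactly", {
  set.seed(3)
  ref <- colMeans(matrix(rnorm(100), 4, 25)) + sin(seq(0, 6, length.out = 25))
  # spectrum equal to the reference is unchanged
  expect_equal(as.numeric(mscCorrect(rbind(ref), ref)), ref, ignore_attr = TRUE)
  # exact affine distortion: 2*ref + 5 comes back as ref
  expect_equal(as.numeric(mscCorrect(rbind(2 * ref + 5), ref)), ref,
               ignore_attr = TRUE, tolerance = 1e-12)
  # 20 random affine distortions collapse to (numerically) one spectrum
  ab <- cbind(runif(20, 0.5, 2), runif(20, -1, 1))
  X <- t(apply(ab, 1, function(p) p[1] * ref + p[2]))
  Xc <- mscCorrect(X, ref)
  expect_lt(max(dist(Xc)), 1e-8)
  # oracle equivalence with lm() per spectrum
  set.seed(4)
  Xn <- X + matrix(rnorm(20 * 25, sd = 0.05), 20)
  Xc2 <- mscCorrect(Xn, ref)
  for (i in c(1, 9, 20)) {
    fit <- lm(Xn[i, ] ~ ref)
    expect_equal(as.numeric(Xc2[i, ]),
                 (Xn[i, ] - coef(fit)[1]) / coef(fit)[2],
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
  # flat spectrum has slope ~0 against any informative reference
  expect_error(mscCorrect(rbind(rep(1, 25)), ref), "degenerate-fit")
})

test_that("snv standardises every spectrum and is affine invariant", {
  set.seed(5)
  x <- rnorm(40)
  z <- snvScale(x)
  expect_lt(abs(mean(z)), 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(snvScale(3 * x + 7), z, tolerance = 1e-12)
  expect_equal(snvScale(z), z, tolerance = 1e-12)     # idempotent
  expect_error(snvScale(rep(2, 10)), "zero-variance")
})

test_that("savgol reproduces polynomials and shrinks white noise", {
  x <- seq(-1, 1, length.out = 101)
  quad <- 2 + 3 * x - 4 * x^2
  expect_equal(savgolFilter(quad, 11, 2, 0), quad, tolerance = 1e-10)
  expect_equal(savgolFilter(rep(5, 50), 11, 2, 0), rep(5, 50), tolerance = 1e-12)
  # variance shrink factor equals the kernel l2 norm squared
  set.seed(6)
  noise <- rnorm(5000)
  sm <- savgolFilter(noise, 11, 2, 0)
  g <- signal::sgolay(p = 2, n = 11)
  shrink <- sqrt(sum(g[6, ]^2))
  expect_equal(sd(sm[100:4900]), shrink, tolerance = 0.05)
  expect_lt(sd(sm), 0.6)

  expect_error(savgolFilter(quad, 10, 2), "odd")
  expect_error(savgolFilter(quad, 5, 5), "exceed")
  expect_error(savgolFilter(1:5, 7, 2), "shorter")
})

test_that("minmax maps ranges onto [0, 1] in both modes", {
  expect_equal(as.numeric(minmaxScale(rbind(c(1, 3, 5)))), c(0, 0.5, 1))
  set.seed(7)
  X <- matrix(rnorm(60), 5)
  Xs <- minmaxScale(X)
  expect_true(all(Xs >= 0 & Xs <= 1))
  expect_equal(minmaxScale(Xs), Xs)   # idempotent
  expect_equal(as.numeric(apply(Xs, 1, range)), rep(c(0, 1), 5))
  Xset <- minmaxScale(X, "set")
  expect_equal(range(Xset), c(0, 1))
  expect_error(minmaxScale(rbind(rep(1, 4))), "constant")
})

test_that("pipelines fit state on calibration only and compose in order", {
  cal <- makeTinySet(n = 5, p = 30, seed = 8)
  pred <- makeTinySet(n = 4, p = 30, seed = 9, conc = 10^-(3:6))

  # identity pipeline
  out <- applyPipeline(preprocessPipeline(), cal, pred)
  expect_equal(intensities(out$cal), intensities(cal))
  expect_equal(intensities(out$pred), intensities(pred))

  # chain equals manual sequential application
  pl <- preprocessPipeline(list(preprocessStep("SAVGOL", window = 7, order = 2),
                                preprocessStep("SNV")))
  auto <- applyPipeline(pl, cal, pred)
  manual <- snvScale(savgolFilter(intensities(cal), 7, 2, 0))
  expect_equal(intensities(auto$cal), manual, tolerance = 1e-12,
               ignore_attr = TRUE)

  # MSC reference comes from the calibration set, not from pred:
  # inject a sentinel reference and check pred correction uses it
  ref <- colMeans(intensities(cal))
  plMSC <- preprocessPipeline(list(preprocessStep("MSC")))
  both <- applyPipeline(plMSC, cal, pred)
  expect_equal(intensities(both$pred),
               mscCorrect(intensities(pred), ref),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_false(isTRUE(all.equal(
    intensities(both$pred),
    mscCorrect(intensities(pred), colMeans(intensities(pred))),
    check.attributes = FALSE)))

  # set-mode minmax bounds fitted on cal are reused for pred
  plMM <- preprocessPipeline(list(preprocessStep("MINMAX", mode = "set")))
  mm <- applyPipeline(plMM, cal, pred)
  b <- list(lo = min(intensities(cal)), hi = max(intensities(cal)))
  expect_equal(intensities(mm$pred),
               (intensities(pred) - b$lo) / (b$hi - b$lo), tolerance = 1e-12)

  # history is recorded
  expect_match(paste(S4Vectors::metadata(mm$cal)$history, collapse = ";"), "minmax")

  predBad <- makeTinySet(n = 2, p = 30, seed = 1,
                         axis = seq(500, 790, by = 10), conc = c(1e-4, 1e-5))
  expect_error(applyPipeline(plMM, cal, predBad), "compatibility")
})

test_that("pipeline presets contain the documented step order", {
  p1 <- pipelinePreset("sg-snv-msc")
  expect_equal(vapply(p1$steps, `[[`, "", "kind"),
               c("SAVGOL", "SNV", "MSC", "MINMAX"))
  p2 <- pipelinePreset("airpls-msc-sg")
  expect_equal(vapply(p2$steps, `[[`, "", "kind"),
               c("AIRPLS", "MSC", "SAVGOL", "MINMAX"))
  expect_error(preprocessStep("SAVGOL", window = 4), "odd")
})
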