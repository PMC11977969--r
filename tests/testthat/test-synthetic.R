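test_that("default designs encode the documented study conditions", {
  d <- defaultDesign("sers")
  expect_s4_class(d, "SyntheticDesign")
  chl <- subset(d@analytePeaks, analyte == "chlorpyrifos")
  expect_true(all(c(609, 990) %in% chl$center))
  pym <- subset(d@analytePeaks, analyte == "pymetrozine")
  expect_true(558 %in% pym$center)
  expect_equal(sort(d@backgroundPeaks$center), c(740, 910, 1040, 1370))
  expect_equal(d@axisStart, 400); expect_equal(d@axisEnd, 1800)
  expect_equal(length(d@concentrationLevels), 6L)
  expect_equal(range(d@concentrationLevels), c(1e-6, 1e-3))
  expect_equal(d@replicatesPerLevel, 10L)
  expect_equal(d@responseModel, "langmuir")

  nir <- defaultDesign("nir")
  expect_true(all(nir@analytePeaks$width >= 50))
  expect_true(1450 %in% nir@backgroundPeaks$center)
  expect_equal(nir@responseModel, "loglinear")

  # pure function: repeated calls agree
  expect_equal(defaultDesign("sers"), defaultDesign("sers"))
})

test_that("noise-free simulation is exactly background + baseline at zero conc", {
  d <- defaultDesign("sers", nChannels = 150L)
  d@scatterSD <- c(0, 0); d@noiseSD <- 0
  d@depositionSD <- 0; d@peakJitterSD <- 0; d@backgroundJitterSD <- 0
  d@concentrationLevels <- c(0, 1e-3)
  d@replicatesPerLevel <- 1L
  sim <- simulateSpectra(d, seed = 1)
  X <- intensities(sim$set)
  axis <- spectralAxis(sim$set)
  u <- seq(0, 1, length.out = 150)
  baseline <- 0.10 + 0.05 * u + 0.05 * u^2
  bg <- rep(0, 150)
  for (i in seq_len(nrow(d@backgroundPeaks)))
    bg <- bg + d@backgroundPeaks$fixedHeight[i] *
      exp(-(axis - d@backgroundPeaks$center[i])^2 / (2 * d@backgroundPeaks$width[i]^2))
  expect_equal(as.numeric(X[1, ]), baseline + bg, tolerance = 1e-12)
  # the analyte-bearing sample exceeds the blank at the peak channels only
  diff <- X[2, ] - X[1, ]
  expect_true(all(diff[sim$truth$informative] > 0.1))
  expect_lt(max(abs(diff[-sim$truth$informative])), 0.35)  # narrow tails only
})

test_that("apex height above background tracks the response model exactly", {
  d <- defaultDesign("sers", nChannels = 200L, responseModel = "linear")
  d@scatterSD <- c(0, 0); d@noiseSD <- 0
  d@depositionSD <- 0; d@peakJitterSD <- 0; d@backgroundJitterSD <- 0
  sim <- simulateSpectra(d, seed = 1)
  X <- intensities(sim$set)
  axis <- spectralAxis(sim$set)
  apex <- which.min(abs(axis - sim$truth$centers[1]))
  conc <- concentrations(sim$set)
  # linear response: apex intensity is affine in concentration with r ~ 1
  expect_gt(cor(X[, apex], conc), 0.999999)

  # langmuir response follows c/(c+Kd)
  dl <- defaultDesign("sers", nChannels = 200L)
  dl@scatterSD <- c(0, 0); dl@noiseSD <- 0
  dl@depositionSD <- 0; dl@peakJitterSD <- 0; dl@backgroundJitterSD <- 0
  simL <- simulateSpectra(dl, seed = 1)
  XL <- intensities(simL$set)
  row <- dl@analytePeaks[1, ]
  theo <- row$response * conc / (conc + row$kd)
  apexL <- which.min(abs(spectralAxis(simL$set) - simL$truth$centers[1]))
  obs <- XL[, apexL] - min(XL[, apexL]) + theo[which.min(conc)]
  expect_gt(cor(obs, theo), 0.999999)
})

test_that("ground-truth informative channels come from construction", {
  d <- defaultDesign("sers", nChannels = 200L)
  sim <- simulateSpectra(d, seed = 5)
  axis <- spectralAxis(sim$set)
  manual <- which(vapply(axis, function(a)
    any(abs(a - sim$truth$centers) <= 2 * d@analytePeaks$width), logical(1)))
  expect_identical(sim$truth$informative, manual)
  # the benchmark geometry plants exactly eight informative channels
  expect_length(sim$truth$informative, 8L)
})

test_that("MSC recovers scatter-distorted noiseless replicates", {
  d <- defaultDesign("sers", nChannels = 120L)
  d@noiseSD <- 0; d@peakJitterSD <- 0; d@depositionSD <- 0
  d@backgroundJitterSD <- 0
  d@scatterSD <- c(0.2, 0.3)
  d@concentrationLevels <- 1e-4; d@replicatesPerLevel <- 12L
  sim <- simulateSpectra(d, seed = 9)
  X <- intensities(sim$set)
  expect_gt(max(dist(X)), 0.1)           # distorted before correction
  Xc <- mscCorrect(X, reference = sim$truth$clean[1, ])
  expect_lt(max(dist(Xc)), 1e-6)         # affine distortion inverted
})

test_that("benchmark dataset pairs modalities and splits consistently", {
  b <- benchmarkDataset(seed = 4)
  expect_equal(concentrations(b$nir), concentrations(b$sers))
  expect_identical(sampleIDs(b$nir), sampleIDs(b$sers))
  expect_equal(ncol(calibrationSet(b$nirSplit)), 36L)
  expect_equal(ncol(predictionSet(b$nirSplit)), 24L)
  expect_equal(ncol(calibrationSet(b$sersSplit)), 36L)
  expect_identical(sampleIDs(calibrationSet(b$nirSplit)),
                   sampleIDs(calibrationSet(b$sersSplit)))
  expect_length(b$truth$sers$informative, 8L)

  # determinism: same seed gives byte-identical CSV exports
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  writeSpectraCSV(b$sers, f1)
  writeSpectraCSV(benchmarkDataset(seed = 4)$sers, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_false(identical(intensities(benchmarkDataset(seed = 5)$sers),
                         intensities(b$sers)))
})
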