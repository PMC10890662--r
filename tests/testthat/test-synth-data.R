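channelsFixture <- buildChannels(gaRegistryTable())

test_that("simulation is reproducible from its seed", {
  a <- simulateRun(simConfig(seed = 5), channelsFixture)
  b <- simulateRun(simConfig(seed = 5), channelsFixture)
  expect_identical(a$run@ms1Peaks, b$run@ms1Peaks)
  expect_identical(a$truth, b$truth)
  # and the serialized mzML is byte-identical too
  f1 <- tempfile(fileext = ".mzML"); f2 <- tempfile(fileext = ".mzML")
  writeRun(a$run, f1); writeRun(b$run, f2)
  expect_identical(readLines(f1, warn = FALSE), readLines(f2, warn = FALSE))
  c2 <- simulateRun(simConfig(seed = 6), channelsFixture)
  expect_false(identical(a$run@ms1Peaks, c2$run@ms1Peaks))
})

test_that("noiseless spikes are recovered at configured RT, ratio and offset", {
  cfg <- simConfig(noisePeaks = 0L, poissonNoise = FALSE, seed = 1)
  sim <- simulateRun(cfg, channelsFixture)
  for (i in seq_len(nrow(sim$truth$spikes))) {
    sp <- sim$truth$spikes[i, ]
    lp <- detectPeaks(extractXic(sim$run, sp$lightMz, 10))
    hp <- detectPeaks(extractXic(sim$run, sp$heavyMz, 10))
    expect_gte(nrow(lp), 1)   # decoys may share the channel at other RTs
    expect_true(any(abs(lp$rt - sp$rt) < 1e-3))
    pairs <- matchPairs(lp, hp)
    pair <- pairs[which.min(abs(pairs$rtLight - sp$rt)), ]
    expect_equal(nrow(pair), 1)
    expect_lt(abs(pair$ratio - sp$ratio), 0.01)
    expect_lt(abs(pair$rtDelta - sp$rtOffset), 2e-3)
  }
})

test_that("spike MS2 spectra carry the candidate's loss ladder within 10 ppm", {
  sim <- simulateRun(simConfig(seed = 2), channelsFixture)
  # the GA2 spike (mono-hydroxylated, lactone) mirrors the Glc-GA3 pattern:
  # precursor, -glucose, -glucose-(CH3)2NH ladder
  prec <- vapply(sim$run@ms2, function(s) s@precursorMz, numeric(1))
  ga2 <- sim$truth$spikes[sim$truth$spikes$name == "GA2", ]
  s <- sim$run@ms2[[which.min(abs(prec - ga2$lightMz))]]
  expected <- c(ga2$lightMz,
                ga2$lightMz - 162.0528,
                ga2$lightMz - 162.0528 - 45.0578)
  for (mz in expected)
    expect_true(any(abs(s@mz - mz) / mz * 1e6 <= 10), label = sprintf("%.4f", mz))
  # ground-truth labels annotate each simulated fragment's rule class
  lad <- sim$truth$ms2[["GA2"]]
  expect_setequal(intersect(lad$class, 1:5), c(1, 2, 3, 4, 5))
})

test_that("the simulated intensity-ratio estimator is unbiased", {
  ratios <- vapply(1:40, function(seed) {
    sim <- simulateRun(simConfig(seed = seed), channelsFixture)
    sp <- sim$truth$spikes[1, ]
    lp <- detectPeaks(extractXic(sim$run, sp$lightMz, 10))
    hp <- detectPeaks(extractXic(sim$run, sp$heavyMz, 10))
    matchPairs(lp, hp)$ratio[1]
  }, numeric(1))
  # configured ratio is 1.0; Poisson noise at height 20000 gives ~1% spread
  expect_lt(abs(mean(ratios) - 1.0), 3 * sd(ratios) / sqrt(length(ratios)) + 0.01)
})

test_that("the fixture bundle reproduces the reference tables", {
  dir <- tempfile("fixtures")
  paths <- makeFixtures(dir)
  expect_true(all(file.exists(paths)))

  pred <- loadPredictedRi(paths[["predicted"]])
  expect_equal(pred$ri_pred[pred$ga_name == "GA104"], 716.94)
  expect_equal(pred$ri_pred[pred$ga_name == "GA105"], 535.52)

  cal <- loadCalibration(paths[["calibration"]])
  expect_equal(rtToRi(7.47, cal), 655.56)

  reg <- loadRegistry(paths[["registry"]])
  ch <- buildChannels(reg)
  tab <- channelTable(ch)
  i <- which.min(abs(tab$lightMz - 563.2963))
  expect_lt(abs(tab$lightMz[i] - 563.2963), 5e-4)
  expect_lt(abs(tab$heavyMz[i] - 567.3214), 5e-4)

  spectra <- readSpectraCsv(paths[["spectra"]])
  expect_setequal(names(spectra), c("compound1", "compound2", "compound10",
                                    "compound11", "compound12"))
  expect_equal(spectra$compound1@precursorMz, 563.2963, tolerance = 5e-4)
  stds <- readSpectraCsv(paths[["standards"]])
  expect_setequal(names(stds), c("GA7", "GA34"))
})

test_that("shipped extdata fixtures match the generating code", {
  shipped <- system.file("extdata", "ga_registry.csv", package = "glcga")
  expect_true(nzchar(shipped))
  expect_equal(loadRegistry(shipped), gaRegistryTable(),
               ignore_attr = TRUE)
})
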