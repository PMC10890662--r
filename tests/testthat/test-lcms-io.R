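# build a minimal two-analyte run directly (independent of the simulator)
makeToyRun <- function(noise = 0) {
  rts <- seq(10, 11, by = 1 / 120)   # 2 Hz
  mkScan <- function(rt) {
    int1 <- gaussianTrace(rt, 10.32, 0.03, 10000)
    int2 <- gaussianTrace(rt, 10.60, 0.03, 8000)
    mz <- c(563.2963, 567.3214)
    int <- c(int1, int2)
    keep <- int > 1
    p <- cbind(mz = mz[keep], intensity = int[keep])
    if (noise > 0) {
      p <- rbind(p, cbind(mz = runif(noise, 300, 700),
                          intensity = rexp(noise, 1 / 50)))
    }
    p[order(p[, 1]), , drop = FALSE]
  }
  ms2 <- list(
    spectrum2(c(401.2435, 356.1857), c(100, 80), 563.2963, rt = 10.33),
    spectrum2(c(401.2435, 300.0000), c(50, 40), 563.2963, rt = 10.42))
  new("MsRun", ms1Rt = rts, ms1Peaks = lapply(rts, mkScan), ms2 = ms2,
      scanRange = c(300, 700))
}

test_that("mzML write/read round-trips spectra, RTs and precursors", {
  run <- makeToyRun()
  f <- tempfile(fileext = ".mzML")
  writeRun(run, f)
  run2 <- readRun(f)
  expect_equal(length(run2@ms1Rt), length(run@ms1Rt))
  expect_equal(run2@ms1Rt, run@ms1Rt, tolerance = 1e-9)
  expect_equal(length(run2@ms2), 2L)
  i <- which.max(vapply(run@ms1Peaks, nrow, integer(1)))
  expect_equal(run2@ms1Peaks[[i]][, 1], run@ms1Peaks[[i]][, 1])
  expect_equal(run2@ms2[[1]]@precursorMz, 563.2963, tolerance = 1e-6)
  expect_error(readRun(tempfile(fileext = ".mzML")), "not found")
})

test_that("XIC extraction recovers a spiked Gaussian apex and ignores blanks", {
  run <- makeToyRun()
  x <- extractXic(run, 563.2963, tolPpm = 10)
  expect_s4_class(x, "XicTrace")
  expect_equal(x@rt[which.max(x@intensity)], 10.32, tolerance = 1 / 120)
  blank <- extractXic(run, 620.0, tolPpm = 10)
  expect_true(all(blank@intensity == 0))
})

test_that("co-eluting isobars within the window sum into one trace", {
  rts <- seq(5, 6, by = 1 / 120)
  mkScan <- function(rt) {
    h <- gaussianTrace(rt, 5.5, 0.05, 1000)
    cbind(mz = c(500.0000, 500.0020), intensity = c(h, h))
  }
  run <- new("MsRun", ms1Rt = rts, ms1Peaks = lapply(rts, mkScan),
             ms2 = list(), scanRange = c(300, 700))
  x <- extractXic(run, 500.001, tolPpm = 10)   # window covers both isobars
  expect_equal(max(x@intensity), 2 * 1000, tolerance = 1e-6)
})

test_that("disjoint m/z windows partition the total ion current", {
  set.seed(3)
  run <- makeToyRun(noise = 20)
  edges <- seq(300, 700, by = 50)
  parts <- sapply(seq_len(length(edges) - 1), function(i)
    extractXicRange(run, edges[i], edges[i + 1]))
  # every centroid lies in (300, 700], so the window sums tile the TIC
  expect_equal(rowSums(parts), ticTrace(run), tolerance = 1e-9)
})

test_that("peak detection finds clean Gaussians and nothing in flat noise", {
  rts <- seq(0, 2, by = 1 / 120)
  mk <- function(ints) new("XicTrace", targetMz = 500, tolPpm = 10,
                           rt = rts, intensity = ints)
  one <- mk(gaussianTrace(rts, 1.0, 0.03, 5000))
  pk <- detectPeaks(one)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$rt, 1.0, tolerance = 1 / 120)

  two <- mk(gaussianTrace(rts, 0.6, 0.03, 5000) +
            gaussianTrace(rts, 1.4, 0.03, 3000))
  pk2 <- detectPeaks(two)
  expect_equal(nrow(pk2), 2)
  expect_equal(pk2$rt, c(0.6, 1.4), tolerance = 1 / 120)
  expect_true(all(diff(pk2$rt) > 0))

  set.seed(5)
  flat <- mk(abs(rnorm(length(rts), 100, 10)))
  expect_equal(nrow(detectPeaks(flat)), 0)
})

test_that("parabolic apex interpolation resolves sub-scan retention times", {
  rts <- seq(0, 2, by = 1 / 120)
  truth <- 1.0021   # deliberately off-grid
  tr <- new("XicTrace", targetMz = 500, tolPpm = 10, rt = rts,
            intensity = gaussianTrace(rts, truth, 0.03, 5000))
  pk <- detectPeaks(tr)
  expect_lt(abs(pk$rt - truth), 1e-3)
})

test_that("peak detection recovers high-SNR simulated peaks reliably", {
  # property: >= 99% recovery of spiked peaks with SNR >= 10, width >= 5 scans
  ch <- buildChannels(gaRegistryTable())
  found <- 0L; total <- 0L
  for (seed in 1:20) {
    sim <- simulateRun(simConfig(seed = seed), ch)
    for (i in seq_len(nrow(sim$truth$spikes))) {
      sp <- sim$truth$spikes[i, ]
      pk <- detectPeaks(extractXic(sim$run, sp$lightMz, 10))
      total <- total + 1L
      if (any(abs(pk$rt - sp$rt) < 0.02)) found <- found + 1L
    }
  }
  expect_gte(found / total, 0.99)
})

test_that("MS2 lookup picks the nearest matching precursor and ties break by RT", {
  run <- makeToyRun()
  hit <- ms2Near(run, 563.2963, rt = 10.32, tolPpm = 10, rtWindow = 0.2)
  expect_equal(hit@rt, 10.33)            # nearer of the two matching spectra
  expect_null(ms2Near(run, 563.2963, rt = 11.5, tolPpm = 10, rtWindow = 0.2))
  expect_null(ms2Near(run, 450.0, rt = 10.32, tolPpm = 10, rtWindow = 0.2))
})
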