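peakDf <- function(rt, height)
  data.frame(rt = rt, height = height, area = height, rtLeft = rt - 0.05,
             rtRight = rt + 0.05, snr = 100)

test_that("pair matching enforces the RT-delta and ratio bounds", {
  crit <- pairCriteria()
  # interior of both bounds -> matched
  p <- matchPairs(peakDf(10.320, 1000), peakDf(10.315, 1000), crit)
  expect_equal(nrow(p), 1)
  expect_equal(p$rtDelta, 0.005, tolerance = 1e-9)
  # RT delta beyond 0.013 min -> rejected
  expect_equal(nrow(matchPairs(peakDf(10.320, 1000),
                               peakDf(10.300, 1000), crit)), 0)
  # heavy eluting after light (negative delta) -> rejected
  expect_equal(nrow(matchPairs(peakDf(10.300, 1000),
                               peakDf(10.310, 1000), crit)), 0)
  # ratio 0.5 below the 0.76 bound -> rejected
  expect_equal(nrow(matchPairs(peakDf(10.320, 500),
                               peakDf(10.315, 1000), crit)), 0)
  expect_equal(nrow(matchPairs(peakDf(10.320, 3000),
                               peakDf(10.315, 1000), crit)), 0)
})

test_that("pair assignment is greedy 1:1 and input-order invariant", {
  light <- peakDf(c(10.320, 10.500), c(1000, 900))
  heavy <- peakDf(c(10.315, 10.318, 10.495), c(1000, 950, 900))
  p <- matchPairs(light, heavy)
  expect_equal(nrow(p), 2)
  # the closer heavy peak (10.318, delta 0.002) wins for the first light peak
  expect_equal(p$rtHeavy[p$rtLight == 10.320], 10.318)
  # permuting inputs never changes the matched set
  perm <- matchPairs(light[2:1, ], heavy[c(3, 1, 2), ])
  expect_equal(p[order(p$rtLight), ], perm[order(perm$rtLight), ],
               ignore_attr = TRUE)
})

test_that("widening the pair criteria never shrinks the matched set", {
  set.seed(21)
  for (k in 1:20) {
    npk <- sample(2:5, 1)
    light <- peakDf(sort(runif(npk, 10, 12)), runif(npk, 500, 2000))
    heavy <- peakDf(sort(runif(npk, 10, 12)), runif(npk, 500, 2000))
    narrow <- matchPairs(light, heavy, pairCriteria())
    wide <- matchPairs(light, heavy,
                       pairCriteria(c(-0.05, 0.05), c(0.5, 2.0)))
    expect_gte(nrow(wide), nrow(narrow))
  }
})

test_that("glucose-loss annotation finds the printed product-ion transition", {
  # derivatized Glc-GA3 579.2912 -> 417.2384 by glucose loss
  ms2 <- spectrum2(c(579.2912, 417.2384, 91.0542),
                   c(1000, 800, 100), precursorMz = 579.2912)
  ev <- annotateLosses(ms2)
  expect_true(ev@classPass[["5"]])
  glcHit <- ev@hits[ev@hits$class == 5L, ]
  expect_equal(glcHit$obsMz, 417.2384)
  expect_lt(abs(glcHit$ppm), 10)
})

test_that("a chained loss ladder yields hits in the expected classes", {
  ms2 <- spectrum2(c(563.2963, 401.2435, 356.1857, 338.1751, 310.1802),
                   c(1000, 800, 600, 400, 350), precursorMz = 563.2963)
  ev <- annotateLosses(ms2)
  hits <- ev@hits
  expect_true(any(hits$class == 5L))                      # glucose
  expect_true(any(hits$class == 1L & hits$name == "(CH3)2NH"))
  expect_true(any(hits$class == 2L & hits$name == "H2O"))
  expect_true(any(hits$class == 2L & hits$name == "HCOOH"))
  # every reported hit is within tolerance of its theoretical mass
  expect_true(all(abs(hits$obsMz - hits$theoMz) <=
                    hits$theoMz * 10e-6))
  # an empty-loss spectrum gives no hits
  none <- annotateLosses(spectrum2(c(100.1, 200.2), c(5, 5),
                                   precursorMz = 563.2963))
  expect_equal(nrow(none@hits), 0)
})

test_that("skeleton series detection assigns odd-numbered CxHy+ cations", {
  ms2 <- spectrum2(c(85.0000, 91.0542, 105.0699, 300.0),
                   c(10, 100, 80, 50), precursorMz = 563.2963)
  skel <- detectSkeletonSeries(ms2)
  expect_equal(nrow(skel), 2)
  expect_equal(skel$x, c(7L, 8L))
  expect_equal(skel$y, c(7L, 9L))
  expect_true(all(skel$y %% 2 == 1))
  # cross-check against cation arithmetic
  expect_equal(skel$theoMz[1], cationMz("C7H7"), tolerance = 1e-6)
  expect_equal(skel$theoMz[2], cationMz("C8H9"), tolerance = 1e-6)
})

test_that("the screening policy demands glucose, reagent, A-ring, plus ring/skeleton", {
  full <- workedExampleSpectrum("compound1")
  ev <- screenSpectrum(full)
  expect_true(ev@pass)
  expect_true(all(ev@classPass[c("1", "2", "5")]))

  # same spectrum minus the glucose-loss fragment fails
  keep <- abs(full@mz - (full@precursorMz - 162.0528)) > 0.01
  noGlc <- spectrum2(full@mz[keep], full@intensity[keep],
                     precursorMz = full@precursorMz)
  expect_false(screenSpectrum(noGlc)@pass)

  # a decoy with only water losses fails
  decoy <- spectrum2(c(563.2963, 545.2857, 527.2752),
                     c(1000, 300, 100), precursorMz = 563.2963)
  expect_false(screenSpectrum(decoy)@pass)
})

test_that("A-ring inference counts hydroxyls and lactones from the anchor ladder", {
  # one lactone + one hydroxyl (anchor 376.2118 with H2O and HCOOH losses)
  ms11 <- workedExampleSpectrum("compound11")
  inf11 <- inferARing(ms11)
  expect_equal(inf11@lactone, 1L)
  expect_equal(inf11@hydroxyls, 1L)
  expect_equal(inf11@anchorMz, 376.2118, tolerance = 5e-4)

  # one lactone + two hydroxyls via the combined CO2+2H2O loss (anchor 374.1962)
  inf10 <- inferARing(workedExampleSpectrum("compound10"))
  expect_equal(inf10@lactone, 1L)
  expect_equal(inf10@hydroxyls, 2L)
  expect_equal(inf10@anchorMz, 374.1962, tolerance = 5e-4)

  # two sequential waters plus HCOOH (anchor 404.2068)
  inf12 <- inferARing(workedExampleSpectrum("compound12"))
  expect_equal(inf12@lactone, 1L)
  expect_equal(inf12@hydroxyls, 2L)

  expect_error(inferARing(spectrum2(c(100, 200), c(5, 5),
                                    precursorMz = 563.2963)),
               "no anchor")
})
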