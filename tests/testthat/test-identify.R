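mkCands <- function(names, lactone, hydroxyls)
  data.frame(name = names, lactone = lactone, hydroxyls = hydroxyls,
             stringsAsFactors = FALSE)

mkInference <- function(lactone, hydroxyls)
  new("AringInference", lactone = as.integer(lactone),
      hydroxyls = as.integer(hydroxyls), anchorMz = 350, anchorObsMz = 350)

test_that("fragmentation-consistency keeps compatible A-ring annotations", {
  cands <- mkCands(c("GAx", "GAy", "GAz"), c(1, 1, 0), c(1, 0, 2))
  kept <- step2FragmentationConsistent(cands, mkInference(1, 1))
  expect_equal(kept$name, "GAx")
  # two inferred hydroxyls exclude the mono-hydroxylated candidate
  kept2 <- step2FragmentationConsistent(mkCands(c("GAa", "GAb"),
                                                c(1, 1), c(2, 0)),
                                        mkInference(1, 2))
  expect_equal(kept2$name, "GAa")
  # a richer annotation (hydroxyls above the inferred count) stays
  kept3 <- step2FragmentationConsistent(mkCands("GAc", 1, 2),
                                        mkInference(1, 1))
  expect_equal(nrow(kept3), 1)
})

test_that("the RI filter removes mismatched candidates and warns on gaps", {
  pred <- predictedRiTable()
  cands <- mkCands(c("GA105", "GA62", "GA104", "GA106", "GA107", "GA7",
                     "GA88"), 1, 1)
  kept1 <- step3RiFilter(cands, 718.97, pred)
  expect_setequal(kept1$name, c("GA62", "GA104", "GA106", "GA107", "GA7",
                                "GA88"))
  kept2 <- step3RiFilter(cands, 760.66, pred)
  expect_setequal(kept2$name, c("GA104", "GA106", "GA107", "GA7", "GA88"))
  # empty prediction table: everything retained, with a warning
  expect_warning(
    kept3 <- step3RiFilter(cands, 718.97,
                           data.frame(ga_name = character(),
                                      ri_pred = numeric())),
    "retained")
  expect_equal(nrow(kept3), nrow(cands))
})

test_that("spectral similarity is 1 for identical, 0 for disjoint spectra", {
  a <- spectrum2(c(100.05, 200.10, 300.15), c(50, 100, 20),
                 precursorMz = 400)
  expect_equal(spectralSimilarity(a, a), 1.0, tolerance = 1e-12)
  b <- spectrum2(c(150.05, 250.10), c(50, 100), precursorMz = 400)
  expect_equal(spectralSimilarity(a, b), 0.0)
  expect_error(spectralSimilarity(a, spectrum2(numeric(0), numeric(0), 400)),
               "empty")
})

test_that("spectral similarity equals the brute-force cosine oracle", {
  set.seed(41)
  for (k in 1:10) {
    n1 <- sample(5:12, 1); n2 <- sample(5:12, 1)
    shared <- runif(4, 100, 500)
    mzA <- sort(c(shared, runif(n1 - 4, 100, 500)))
    mzB <- sort(c(shared * (1 + rnorm(4, 0, 2e-6)), runif(n2 - 4, 100, 500)))
    intA <- runif(n1, 10, 1000); intB <- runif(n2, 10, 1000)
    a <- spectrum2(mzA, intA, precursorMz = 600)
    b <- spectrum2(mzB, intB, precursorMz = 600)
    expect_equal(spectralSimilarity(a, b, tolPpm = 20),
                 oracleCosine(a@mz, a@intensity, b@mz, b@intensity, 20),
                 tolerance = 1e-9)
  }
})

test_that("standard comparison rejects dissimilar and flags similar spectra", {
  std <- syntheticStandards()
  c1 <- workedExampleSpectrum("compound1")
  cands <- mkCands(c("GA7", "GA62"), 1, 1)
  out <- step4StandardCheck(cands, c1, std)
  expect_setequal(out$candidates$name, "GA62")   # GA7 standard mismatch
  expect_lt(out$scores[["GA7"]], 0.5)

  c10 <- workedExampleSpectrum("compound10")
  out10 <- step4StandardCheck(mkCands(c("GA34", "GA16"), 1, 2), c10, std)
  expect_setequal(out10$candidates$name, c("GA34", "GA16"))
  expect_equal(out10$supported, "GA34")
  expect_gt(out10$scores[["GA34"]], 0.8)

  # no standards: untouched
  same <- step4StandardCheck(cands, c1, list())
  expect_equal(same$candidates, cands)
})

test_that("worked-example replay reproduces the reference candidate sets", {
  recs <- suppressWarnings(replayWorkedExamples())
  expect_setequal(recs$compound1@step4,
                  c("GA62", "GA88", "GA104", "GA106", "GA107"))
  expect_setequal(recs$compound2@step4,
                  c("GA88", "GA104", "GA106", "GA107"))
  expect_setequal(recs$compound11@step4, c("GA2", "GA82"))
  expect_identical(recs$compound12@step4, "GA52")
  expect_equal(recs$compound1@ri, 718.97)
  expect_equal(recs$compound2@ri, 760.66)
})

test_that("candidate sets are nested through the four steps", {
  recs <- suppressWarnings(replayWorkedExamples())
  for (r in recs) {
    expect_true(all(r@step2 %in% r@assigned))
    expect_true(all(r@step3 %in% r@step2))
    expect_true(all(r@step4 %in% r@step3))
    expect_lte(length(r@step4), length(r@step3))
    expect_lte(length(r@step3), length(r@step2))
    expect_lte(length(r@step2), length(r@assigned))
  }
})

test_that("the pipeline recovers simulated spikes and drops decoys", {
  ch <- buildChannels(gaRegistryTable())
  sim <- simulateRun(simConfig(seed = 99), ch)
  recs <- suppressWarnings(
    runPipeline(sim$run, ch, riCalibrationTable(), predictedRiTable(),
                syntheticStandards()))
  expect_equal(length(recs), nrow(sim$truth$spikes))
  tab <- reportTable(recs)
  for (i in seq_len(nrow(sim$truth$spikes))) {
    sp <- sim$truth$spikes[i, ]
    row <- tab[abs(tab$light_mz - sp$lightMz) < 0.01 &
                 abs(tab$rt - sp$rt) < 0.05, ]
    expect_equal(nrow(row), 1)
    expect_true(sp$name %in% strsplit(row$identification, ",")[[1]])
  }
  # no record matches any decoy location
  for (i in seq_len(nrow(sim$truth$decoys))) {
    dc <- sim$truth$decoys[i, ]
    expect_false(any(abs(tab$light_mz - dc$lightMz) < 0.01 &
                       abs(tab$rt - dc$rt) < 0.05))
  }
})

test_that("a run whose MS2 spectra fail screening yields no records", {
  ch <- buildChannels(gaRegistryTable())
  spikes <- defaultSpikes()[1, ]
  decoys <- defaultDecoys()[defaultDecoys()$type == "ladder", ]
  sim <- simulateRun(simConfig(spikes = spikes[0, ], decoys = decoys,
                               seed = 17), ch)
  recs <- suppressWarnings(
    runPipeline(sim$run, ch, riCalibrationTable(), predictedRiTable()))
  expect_length(recs, 0)
})

test_that("pipeline reports are byte-identical across repeated runs", {
  ch <- buildChannels(gaRegistryTable())
  files <- vapply(1:2, function(k) {
    sim <- simulateRun(simConfig(seed = 123), ch)
    recs <- suppressWarnings(
      runPipeline(sim$run, ch, riCalibrationTable(), predictedRiTable(),
                  syntheticStandards()))
    f <- tempfile(fileext = ".tsv")
    writeReport(recs, f)
    f
  }, character(1))
  expect_identical(readLines(files[1]), readLines(files[2]))
})
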