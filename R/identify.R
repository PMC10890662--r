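## Four-step candidate identification and the end-to-end pipeline.

#' Step 2: filter candidates by fragmentation (A-ring) consistency
#'
#' Keeps the candidates whose registry A-ring annotations are compatible
#' with the features inferred from the MS2 loss ladder: the lactone flag
#' must agree and the annotated hydroxyl count must be at least the number
#' of sequential water losses observed.
#'
#' @param candidates `data.frame` of channel members (from
#'   [candidatesForMz()] or [channelMembers()]), with `lactone` and
#'   `hydroxyls` columns.
#' @param inference an [AringInference-class].
#' @return The consistent subset of `candidates`.
#' @export
step2FragmentationConsistent <- function(candidates, inference) {
  stopifnot(is(inference, "AringInference"))
  keep <- candidates$lactone == inference@lactone &
          candidates$hydroxyls >= inference@hydroxyls
  candidates[keep, , drop = FALSE]
}

#' Step 3: QSRR retention-index filter
#'
#' Applies [eq1Filter()] per candidate using the predicted retention index
#' of its parent gibberellin's labeled form.  Candidates without a
#' prediction are retained with a warning (the filter only eliminates when
#' evidence exists).
#'
#' @param candidates `data.frame` with a `name` column of parent-GA names.
#' @param riExp numeric(1); experimental retention index of the compound.
#' @param predictedRi `data.frame` with `ga_name`, `ri_pred`
#'   ([loadPredictedRi()]).
#' @param threshold numeric(1); RI error threshold (default 69.5832).
#' @return The retained subset of `candidates`.
#' @export
step3RiFilter <- function(candidates, riExp, predictedRi,
                          threshold = .QSRR_THRESHOLD) {
  if (!nrow(candidates)) return(candidates)
  pred <- predictedRi$ri_pred[match(candidates$name, predictedRi$ga_name)]
  missing <- is.na(pred)
  if (any(missing))
    warning("no RI prediction for ", paste(candidates$name[missing],
                                           collapse = ", "), "; retained")
  keep <- missing | eq1Filter(riExp, pred, threshold)
  candidates[keep, , drop = FALSE]
}

#' Cosine spectral similarity between two MS2 spectra
#'
#' Fragments are matched greedily across the two spectra within a ppm
#' tolerance; the score is the cosine of the square-root-intensity vectors
#' over the union of matched and unmatched fragments (1 for identical
#' spectra, 0 for disjoint fragment sets).
#'
#' @param a,b [Spectrum2-class] objects.
#' @param tolPpm numeric(1); fragment match tolerance (default 20 ppm).
#' @return numeric(1) in `[0, 1]`.
#' @export
spectralSimilarity <- function(a, b, tolPpm = 20) {
  stopifnot(is(a, "Spectrum2"), is(b, "Spectrum2"))
  if (!length(a@mz) || !length(b@mz)) stop("empty spectrum")
  ## greedy matching by increasing ppm distance
  cand <- expand.grid(i = seq_along(a@mz), j = seq_along(b@mz))
  mid <- (a@mz[cand$i] + b@mz[cand$j]) / 2
  err <- abs(a@mz[cand$i] - b@mz[cand$j]) / mid * 1e6
  cand <- cand[err <= tolPpm, , drop = FALSE]
  err <- err[err <= tolPpm]
  usedA <- logical(length(a@mz)); usedB <- logical(length(b@mz))
  pairs <- list()
  for (k in order(err)) {
    if (usedA[cand$i[k]] || usedB[cand$j[k]]) next
    usedA[cand$i[k]] <- TRUE; usedB[cand$j[k]] <- TRUE
    pairs[[length(pairs) + 1L]] <- c(cand$i[k], cand$j[k])
  }
  wa <- sqrt(a@intensity); wb <- sqrt(b@intensity)
  dot <- sum(vapply(pairs, function(p) wa[p[1]] * wb[p[2]], numeric(1)))
  dot / (sqrt(sum(wa^2)) * sqrt(sum(wb^2)))
}

#' Step 4: comparison against reference standard spectra
#'
#' For every candidate whose parent gibberellin has a reference MS2
#' spectrum, the compound spectrum is scored against the standard: a score
#' below `rejectBelow` removes the candidate; a score above `acceptAbove`
#' flags it as supported; candidates in between (or without a standard) are
#' untouched.
#'
#' @param candidates `data.frame` with a `name` column.
#' @param ms2 the compound's [Spectrum2-class].
#' @param standards named list of [Spectrum2-class] reference spectra, names
#'   being parent-GA names (e.g. `"GA7"`).
#' @param rejectBelow,acceptAbove numeric(1); cosine thresholds (defaults
#'   0.5 and 0.8).
#' @param tolPpm numeric(1); fragment tolerance for the similarity score.
#' @return List: `candidates` (retained subset), `supported` (character
#'   names), `scores` (named numeric of all compared candidates).
#' @export
step4StandardCheck <- function(candidates, ms2, standards = list(),
                               rejectBelow = 0.5, acceptAbove = 0.8,
                               tolPpm = 20) {
  scores <- numeric(0)
  supported <- character(0)
  if (length(standards) && nrow(candidates)) {
    compared <- intersect(candidates$name, names(standards))
    scores <- vapply(compared, function(nm)
      spectralSimilarity(ms2, standards[[nm]], tolPpm), numeric(1))
    drop <- compared[scores < rejectBelow]
    supported <- compared[scores > acceptAbove]
    candidates <- candidates[!candidates$name %in% drop, , drop = FALSE]
  }
  list(candidates = candidates, supported = supported, scores = scores)
}

#' Pipeline configuration
#'
#' Bundles the tunable parameters of the screening/identification pipeline
#' with their defaults.
#'
#' @param criteria [pairCriteria()] peak-pair bounds.
#' @param lossLibrary rule library ([defaultLossLibrary()]).
#' @param policy screening pass policy (see [screenSpectrum()]).
#' @param ms1TolPpm,ms2TolPpm numeric(1); XIC and fragment tolerances (ppm).
#' @param rtWindow numeric(1); MS2 precursor-to-peak RT window (minutes).
#' @param minSnr,minPoints peak-picker settings ([detectPeaks()]).
#' @param riThreshold numeric(1); QSRR filter threshold.
#' @param rejectBelow,acceptAbove numeric(1); step-4 cosine thresholds.
#' @return A list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(criteria = pairCriteria(),
                           lossLibrary = defaultLossLibrary(),
                           policy = list(mandatory = c(5L, 1L, 2L),
                                         anyOf = c(3L, 4L)),
                           ms1TolPpm = 10, ms2TolPpm = 10, rtWindow = 0.2,
                           minSnr = 3, minPoints = 5L,
                           riThreshold = .QSRR_THRESHOLD,
                           rejectBelow = 0.5, acceptAbove = 0.8) {
  structure(list(criteria = criteria, lossLibrary = lossLibrary,
                 policy = policy, ms1TolPpm = ms1TolPpm,
                 ms2TolPpm = ms2TolPpm, rtWindow = rtWindow,
                 minSnr = minSnr, minPoints = minPoints,
                 riThreshold = riThreshold, rejectBelow = rejectBelow,
                 acceptAbove = acceptAbove),
            class = "PipelineConfig")
}

#' Identify one screened compound (steps 1-4)
#'
#' Runs the four-step identification for a single peak-pair/MS2 pair:
#' channel assignment, fragmentation-consistency, QSRR retention filter,
#' and standard comparison.
#'
#' @param id character(1); compound label.
#' @param ms2 the compound's [Spectrum2-class].
#' @param lightMz numeric(1); light-channel m/z (Th).
#' @param rt numeric(1); retention time (minutes).
#' @param channels [CandidateChannelSet-class].
#' @param calibration a `CalibrationSeries` (RT to RI).
#' @param predictedRi predicted-RI table ([loadPredictedRi()]); may have 0
#'   rows.
#' @param standards named list of standard [Spectrum2-class] spectra.
#' @param config a [pipelineConfig()].
#' @return An [IdentificationRecord-class], or `NULL` when the spectrum
#'   fails the five-class screen.
#' @export
identifyCompound <- function(id, ms2, lightMz, rt, channels, calibration,
                             predictedRi = data.frame(ga_name = character(),
                                                      ri_pred = numeric()),
                             standards = list(),
                             config = pipelineConfig()) {
  ev <- screenSpectrum(ms2, precursorMz = lightMz,
                       library = config$lossLibrary,
                       tolPpm = config$ms2TolPpm, policy = config$policy)
  if (!ev@pass) return(NULL)
  assigned <- candidatesForMz(channels, lightMz, config$ms1TolPpm)
  inference <- inferARing(ms2, precursorMz = lightMz,
                          tolPpm = config$ms2TolPpm)
  s2 <- step2FragmentationConsistent(assigned, inference)
  ri <- rtToRi(rt, calibration)
  s3 <- step3RiFilter(s2, ri, predictedRi, config$riThreshold)
  s4 <- step4StandardCheck(s3, ms2, standards, config$rejectBelow,
                           config$acceptAbove, config$ms2TolPpm)
  new("IdentificationRecord", id = id,
      lightMz = lightMz, heavyMz = heavyMz(lightMz, channels@tag),
      rt = rt, ri = ri,
      assigned = assigned$name, step2 = s2$name, step3 = s3$name,
      step4 = s4$candidates$name, supported = s4$supported,
      inference = inference, evidence = ev)
}

#' Run the full screening and identification pipeline on one run
#'
#' For every candidate channel: extract the light and heavy XICs, detect
#' chromatographic peaks, match light/heavy peak pairs, fetch the DDA MS2
#' nearest each pair, screen it against the five fragmentation-rule
#' classes, and push survivors through the four-step identification.
#'
#' @param run an [MsRun-class].
#' @param channels a [CandidateChannelSet-class].
#' @param calibration a `CalibrationSeries`.
#' @param predictedRi predicted-RI table.
#' @param standards named list of standard spectra.
#' @param config a [pipelineConfig()].
#' @return List of [IdentificationRecord-class] objects (possibly empty),
#'   ordered by channel m/z then RT; deterministic given identical inputs.
#' @export
runPipeline <- function(run, channels, calibration,
                        predictedRi = data.frame(ga_name = character(),
                                                 ri_pred = numeric()),
                        standards = list(), config = pipelineConfig()) {
  stopifnot(is(run, "MsRun"), is(channels, "CandidateChannelSet"))
  records <- list()
  tab <- channels@channels
  for (ci in seq_len(nrow(tab))) {
    lightMz <- tab$lightMz[ci]
    lightPk <- detectPeaks(extractXic(run, lightMz, config$ms1TolPpm),
                           config$minSnr, config$minPoints)
    heavyPk <- detectPeaks(extractXic(run, tab$heavyMz[ci], config$ms1TolPpm),
                           config$minSnr, config$minPoints)
    pairs <- matchPairs(lightPk, heavyPk, config$criteria)
    for (pi in seq_len(nrow(pairs))) {
      ms2 <- ms2Near(run, lightMz, pairs$rtLight[pi],
                     config$ms2TolPpm, config$rtWindow)
      if (is.null(ms2)) next
      rec <- tryCatch(
        identifyCompound(sprintf("C%03d.%02d", ci, pi), ms2, lightMz,
                         pairs$rtLight[pi], channels, calibration,
                         predictedRi, standards, config),
        error = function(e) NULL)  # e.g. screen passed but anchor unmatched
      if (!is.null(rec)) records[[length(records) + 1L]] <- rec
    }
  }
  records
}

#' Tabulate identification records
#'
#' Flattens a list of [IdentificationRecord-class] objects into the
#' report table (one row per compound, candidate sets comma-separated).
#'
#' @param records list of [IdentificationRecord-class].
#' @return A `data.frame`.
#' @export
reportTable <- function(records) {
  if (!length(records)) {
    return(data.frame(id = character(), light_mz = numeric(),
                      heavy_mz = numeric(), rt = numeric(), ri = numeric(),
                      lactone = integer(), hydroxyls = integer(),
                      assigned = character(), fragmentation_consistent = character(),
                      ri_retained = character(), identification = character(),
                      supported = character()))
  }
  do.call(rbind, lapply(records, function(r) {
    data.frame(id = r@id,
               light_mz = round(r@lightMz, 4), heavy_mz = round(r@heavyMz, 4),
               rt = round(r@rt, 2), ri = round(r@ri, 2),
               lactone = r@inference@lactone,
               hydroxyls = r@inference@hydroxyls,
               assigned = paste(r@assigned, collapse = ","),
               fragmentation_consistent = paste(r@step2, collapse = ","),
               ri_retained = paste(r@step3, collapse = ","),
               identification = paste(r@step4, collapse = ","),
               supported = paste(r@supported, collapse = ","))
  }))
}

#' Write the identification report as TSV
#'
#' @param records list of [IdentificationRecord-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeReport <- function(records, path) {
  utils::write.table(reportTable(records), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
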