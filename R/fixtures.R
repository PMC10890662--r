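## Fixture tables and worked-example spectra.  Everything here is generated
## from code (formula arithmetic plus curated structural annotations); the
## CSVs under inst/extdata are the output of makeFixtures().

#' Built-in gibberellin registry
#'
#' A registry covering the isobaric channel members relevant to glucosylated
#' gibberellin screening in legume/cereal extracts plus a set of well-known
#' core-pathway GAs.  Molecular formulas are the established free-GA
#' formulas; `lactone` and `hydroxyls` are curated A-ring annotations (the
#' features the anchor-fragment loss ladder reports on), `carboxyls` counts
#' free carboxyl groups available to the amine reagent, and `predicted_ri`
#' carries the QSRR-predicted retention index of the DMED-labeled GA where
#' a prediction is available (`NA` otherwise).
#'
#' @return A registry `data.frame` (see [loadRegistry()] for columns).
#' @export
gaRegistryTable <- function() {
  rows <- rbind(
    ## C19H22O5 parents (light channel 563.2963)
    c("GA7",   "C19H22O5", 1, 1, 1, 840.94),
    c("GA62",  "C19H22O5", 1, 1, 1, 685.27),
    c("GA88",  "C19H22O5", 1, 1, 1, 865.36),
    c("GA104", "C19H22O5", 1, 1, 1, 716.94),
    c("GA105", "C19H22O5", 1, 1, 1, 535.52),
    c("GA106", "C19H22O5", 1, 1, 1, 796.48),
    c("GA107", "C19H22O5", 1, 1, 1, 826.57),
    c("GA5",   "C19H22O5", 0, 0, 1, NA),
    c("GA11",  "C19H22O5", 0, 0, 1, NA),
    c("GA31",  "C19H22O5", 0, 1, 1, NA),
    c("GA95",  "C19H22O5", 0, 1, 1, NA),
    c("GA96",  "C19H22O5", 0, 1, 1, NA),
    c("GA108", "C19H22O5", 0, 0, 1, NA),
    c("GA109", "C19H22O5", 0, 0, 1, NA),
    c("GA117", "C19H22O5", 0, 1, 1, NA),
    c("GA121", "C19H22O5", 0, 0, 1, NA),
    c("GA122", "C19H22O5", 0, 1, 1, NA),
    ## C19H24O5 parents (565.3119)
    c("GA4",   "C19H24O5", 1, 1, 1, NA),
    c("GA40",  "C19H24O5", 1, 1, 1, NA),
    c("GA51",  "C19H24O5", 1, 1, 1, NA),
    c("GA61",  "C19H24O5", 1, 1, 1, NA),
    c("GA119", "C19H24O5", 1, 1, 1, NA),
    c("GA20",  "C19H24O5", 0, 0, 1, NA),
    c("GA45",  "C19H24O5", 0, 1, 1, NA),
    c("GA69",  "C19H24O5", 0, 1, 1, NA),
    c("GA70",  "C19H24O5", 0, 1, 1, NA),
    c("GA84",  "C19H24O5", 0, 0, 1, NA),
    ## C19H22O6 parents (579.2912)
    c("GA3",   "C19H22O6", 1, 1, 1, 653.94),
    c("GA6",   "C19H22O6", 1, 1, 1, NA),
    c("GA30",  "C19H22O6", 1, 1, 1, NA),
    c("GA68",  "C19H22O6", 1, 1, 1, NA),
    c("GA80",  "C19H22O6", 1, 1, 1, NA),
    c("GA92",  "C19H22O6", 1, 1, 1, NA),
    c("GA22",  "C19H22O6", 0, 1, 1, NA),
    c("GA94",  "C19H22O6", 0, 1, 1, NA),
    c("GA126", "C19H22O6", 0, 0, 1, NA),
    ## C19H24O6 parents (581.3068)
    c("GA16",  "C19H24O6", 1, 2, 1, NA),
    c("GA34",  "C19H24O6", 1, 2, 1, NA),
    c("GA47",  "C19H24O6", 1, 2, 1, NA),
    c("GA54",  "C19H24O6", 1, 2, 1, NA),
    c("GA90",  "C19H24O6", 1, 2, 1, NA),
    c("GA1",   "C19H24O6", 1, 1, 1, NA),
    c("GA29",  "C19H24O6", 1, 1, 1, NA),
    c("GA35",  "C19H24O6", 1, 1, 1, NA),
    c("GA58",  "C19H24O6", 0, 1, 1, NA),
    c("GA60",  "C19H24O6", 0, 1, 1, NA),
    c("GA63",  "C19H24O6", 0, 1, 1, NA),
    c("GA67",  "C19H24O6", 0, 1, 1, NA),
    c("GA71",  "C19H24O6", 0, 1, 1, NA),
    c("GA77",  "C19H24O6", 0, 0, 1, NA),
    c("GA81",  "C19H24O6", 0, 1, 1, NA),
    c("GA118", "C19H24O6", 0, 1, 1, NA),
    c("GA130", "C19H24O6", 0, 0, 1, NA),
    c("GA131", "C19H24O6", 0, 1, 1, NA),
    c("GA136", "C19H24O6", 0, 0, 1, NA),
    ## C19H26O6 parents (583.3225)
    c("GA2",   "C19H26O6", 1, 1, 1, NA),
    c("GA82",  "C19H26O6", 1, 1, 1, NA),
    ## C20H26O7 parents (611.3174)
    c("GA52",  "C20H26O7", 1, 2, 2, NA),
    c("GA13",  "C20H26O7", 1, 1, 3, NA),
    c("GA17",  "C20H26O7", 0, 1, 3, NA),
    c("GA23",  "C20H26O7", 1, 1, 2, NA),
    c("GA46",  "C20H26O7", 0, 1, 2, NA),
    c("GA66",  "C20H26O7", 0, 1, 2, NA),
    c("GA99",  "C20H26O7", 0, 0, 2, NA),
    c("GA102", "C20H26O7", 0, 1, 2, NA),
    c("GA125", "C20H26O7", 0, 0, 2, NA),
    c("GA129", "C20H26O7", 0, 1, 2, NA),
    ## additional core-pathway GAs (other channels)
    c("GA8",   "C19H24O7", 1, 2, 1, NA),
    c("GA9",   "C19H24O4", 1, 0, 1, NA),
    c("GA12",  "C20H28O4", 0, 0, 2, NA),
    c("GA15",  "C20H26O5", 0, 0, 1, NA),
    c("GA19",  "C20H26O6", 0, 0, 2, NA),
    c("GA24",  "C20H28O5", 0, 0, 2, NA),
    c("GA44",  "C20H26O6", 0, 0, 1, NA),
    c("GA53",  "C20H28O6", 0, 1, 2, NA))
  data.frame(name = rows[, 1], formula = rows[, 2],
             lactone = as.integer(rows[, 3]),
             hydroxyls = as.integer(rows[, 4]),
             carboxyls = as.integer(rows[, 5]),
             predicted_ri = as.numeric(rows[, 6]),
             stringsAsFactors = FALSE)
}

#' Predicted retention indices of DMED-labeled gibberellins
#'
#' The QSRR-predicted retention indices available for the candidate parents
#' of the isobaric 563.2963 channel, plus GA3.
#'
#' @return `data.frame` with columns `ga_name`, `ri_pred`.
#' @export
predictedRiTable <- function() {
  reg <- gaRegistryTable()
  keep <- !is.na(reg$predicted_ri)
  data.frame(ga_name = reg$name[keep], ri_pred = reg$predicted_ri[keep],
             stringsAsFactors = FALSE)
}

#' Retention-index calibration anchors
#'
#' Piecewise-linear (RT, RI) anchors consistent with the retention behavior
#' of derivatized Glc-GAs on the 40-min reversed-phase gradient.
#'
#' @return A `CalibrationSeries`.
#' @export
riCalibrationTable <- function() {
  calibrationSeries(
    rt = c(7.47, 8.20, 8.70, 8.94, 9.55, 10.32, 10.77, 10.79, 11.12,
           12.10, 13.01),
    ri = c(655.56, 671.46, 682.35, 687.58, 700.94, 718.97, 729.51, 729.98,
           737.70, 760.66, 781.97))
}

## fragment table of one worked example, all m/z from formula arithmetic
.exampleFragments <- function(id) {
  h2o <- .lossMass("H2O"); hcooh <- .lossMass("CH2O2")
  co2 <- .lossMass("CO2"); c2h4 <- .lossMass("C2H4")
  skel <- function()
    data.frame(mz = c(cationMz("C4H10N"), cationMz("C7H7"), cationMz("C8H9"),
                      cationMz("C9H11")),
               intensity = c(300, 250, 200, 150))
  ladder <- switch(id,
    compound1 = , compound2 = {
      p <- mzProtonated("C29H42O9N2")          # 563.2963
      a <- p - .GLC_LOSS - .DMED_LOSS
      data.frame(
        mz = c(p, p - .GLC_LOSS, a, a - h2o, a - hcooh, a - hcooh - c2h4),
        intensity = if (id == "compound1") c(1000, 800, 600, 400, 350, 150)
                    else c(900, 850, 500, 450, 300, 120))
    },
    compound10 = {
      p <- mzProtonated("C29H44O10N2")         # 581.3068
      a <- p - .GLC_LOSS - .DMED_LOSS          # 374.1962
      data.frame(
        mz = c(p, p - .GLC_LOSS, a, a - h2o, a - h2o - hcooh,
               a - (co2 + 2 * h2o)),
        intensity = c(1000, 600, 500, 400, 300, 250))
    },
    compound11 = {
      p <- mzProtonated("C29H46O10N2")         # 583.3225
      a <- p - .GLC_LOSS - .DMED_LOSS          # 376.2118
      data.frame(
        mz = c(p, p - .GLC_LOSS, a, a - h2o, a - hcooh, a - hcooh - c2h4),
        intensity = c(1000, 800, 600, 400, 350, 150))
    },
    compound12 = {
      p <- mzProtonated("C30H46O11N2")         # 611.3174
      a <- p - .GLC_LOSS - .DMED_LOSS          # 404.2068
      data.frame(
        mz = c(p, p - .GLC_LOSS, a, a - h2o, a - 2 * h2o,
               a - 2 * h2o - hcooh, a - 2 * h2o - hcooh - c2h4),
        intensity = c(1000, 800, 600, 400, 300, 250, 100))
    },
    stop("unknown worked example: ", id))
  rbind(ladder, skel())
}

.WORKED_EXAMPLES <- data.frame(
  id = c("compound1", "compound2", "compound10", "compound11", "compound12"),
  formula = c("C29H42O9N2", "C29H42O9N2", "C29H44O10N2", "C29H46O10N2",
              "C30H46O11N2"),
  rt = c(10.32, 12.10, 10.77, 8.70, 9.55),
  stringsAsFactors = FALSE)

#' Worked-example compound spectra
#'
#' MS2 spectra of five screened compounds, rebuilt from their neutral-loss
#' ladders by formula arithmetic: two isobaric mono-hydroxylated compounds
#' on the 563.2963 channel, one di-hydroxylated compound each on the
#' 581.3068 and 611.3174 channels, and a mono-hydroxylated compound on
#' 583.3225.
#'
#' @param id one of `"compound1"`, `"compound2"`, `"compound10"`,
#'   `"compound11"`, `"compound12"`.
#' @return A [Spectrum2-class].
#' @export
workedExampleSpectrum <- function(id) {
  meta <- .WORKED_EXAMPLES[.WORKED_EXAMPLES$id == id, ]
  if (!nrow(meta)) stop("unknown worked example: ", id)
  fr <- .exampleFragments(id)
  spectrum2(fr$mz, fr$intensity, precursorMz = mzProtonated(meta$formula),
            rt = meta$rt)
}

#' Synthetic reference-standard spectra
#'
#' Stand-ins for DMED-labeled gibberellin standard MS2 spectra (no public
#' reference spectra are deposited, so these are synthetic constructions):
#' the GA34 standard shares the post-glucose-loss fragment ladder of its
#' conjugate, while the GA7 standard is built with a deliberately disjoint
#' fragment set.
#'
#' @param ga `"GA7"` or `"GA34"`.
#' @return A [Spectrum2-class].
#' @export
syntheticStandardSpectrum <- function(ga) {
  h2o <- .lossMass("H2O"); hcooh <- .lossMass("CH2O2")
  co2 <- .lossMass("CO2")
  if (ga == "GA7") {
    p <- mzProtonated(derivatizeDmed("C19H22O5"))   # 401.2435
    spectrum2(c(p, p - h2o, p - hcooh, p - h2o - hcooh,
                cationMz("C7H11"), cationMz("C8H13")),
              c(1000, 500, 400, 300, 200, 150),
              precursorMz = p)
  } else if (ga == "GA34") {
    p <- mzProtonated(derivatizeDmed("C19H24O6"))   # 419.2540
    a <- p - .DMED_LOSS                             # 374.1962
    spectrum2(c(p, a, a - h2o, a - h2o - hcooh, a - (co2 + 2 * h2o),
                cationMz("C4H10N"), cationMz("C7H7"), cationMz("C8H9"),
                cationMz("C9H11")),
              c(1000, 500, 400, 300, 250, 200, 150, 120, 100),
              precursorMz = p)
  } else stop("no synthetic standard for ", ga)
}

#' Standard spectra keyed by parent GA
#'
#' @return Named list of [Spectrum2-class] for use as the `standards`
#'   argument of [step4StandardCheck()] / [runPipeline()].
#' @export
syntheticStandards <- function()
  list(GA7 = syntheticStandardSpectrum("GA7"),
       GA34 = syntheticStandardSpectrum("GA34"))

#' Replay the worked examples through the four-step identification
#'
#' Drives [identifyCompound()] with the worked-example spectra, retention
#' times, calibration anchors, predicted retention indices, and synthetic
#' standard spectra.
#'
#' @param ids worked-example ids (default all five).
#' @param config a [pipelineConfig()].
#' @return Named list of [IdentificationRecord-class].
#' @export
replayWorkedExamples <- function(ids = .WORKED_EXAMPLES$id,
                                 config = pipelineConfig()) {
  channels <- buildChannels(gaRegistryTable())
  cal <- riCalibrationTable()
  pred <- predictedRiTable()
  std <- syntheticStandards()
  out <- lapply(ids, function(id) {
    meta <- .WORKED_EXAMPLES[.WORKED_EXAMPLES$id == id, ]
    ms2 <- workedExampleSpectrum(id)
    identifyCompound(id, ms2, lightMz = ms2@precursorMz, rt = meta$rt,
                     channels = channels, calibration = cal,
                     predictedRi = pred, standards = std, config = config)
  })
  stats::setNames(out, ids)
}

#' Write the fixture bundle to a directory
#'
#' Writes the registry, predicted-RI and RT-to-RI calibration CSVs plus the
#' worked-example and synthetic-standard spectra (long CSV format:
#' `id`, `precursor_mz`, `rt`, `mz`, `intensity`).
#'
#' @param dir output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
makeFixtures <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(registry = file.path(dir, "ga_registry.csv"),
             predicted = file.path(dir, "predicted_ri.csv"),
             calibration = file.path(dir, "ri_calibration.csv"),
             spectra = file.path(dir, "worked_example_spectra.csv"),
             standards = file.path(dir, "standards_synthetic.csv"))
  utils::write.csv(gaRegistryTable(), paths["registry"], row.names = FALSE,
                   quote = FALSE, na = "")
  utils::write.csv(predictedRiTable(), paths["predicted"], row.names = FALSE,
                   quote = FALSE)
  cal <- riCalibrationTable()
  utils::write.csv(data.frame(rt = cal$rt, ri = cal$ri),
                   paths["calibration"], row.names = FALSE, quote = FALSE)
  specTab <- do.call(rbind, lapply(.WORKED_EXAMPLES$id, function(id) {
    s <- workedExampleSpectrum(id)
    data.frame(id = id, precursor_mz = round(s@precursorMz, 4), rt = s@rt,
               mz = round(s@mz, 4), intensity = s@intensity)
  }))
  utils::write.csv(specTab, paths["spectra"], row.names = FALSE, quote = FALSE)
  stdTab <- do.call(rbind, lapply(names(syntheticStandards()), function(nm) {
    s <- syntheticStandardSpectrum(nm)
    data.frame(id = nm, precursor_mz = round(s@precursorMz, 4),
               rt = NA_real_, mz = round(s@mz, 4), intensity = s@intensity)
  }))
  utils::write.csv(stdTab, paths["standards"], row.names = FALSE,
                   quote = FALSE)
  invisible(paths)
}

#' Read spectra from a long-format CSV
#'
#' Inverse of the spectra files written by [makeFixtures()].
#'
#' @param path CSV with columns `id`, `precursor_mz`, `rt`, `mz`,
#'   `intensity`.
#' @return Named list of [Spectrum2-class].
#' @export
readSpectraCsv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "precursor_mz", "mz", "intensity")
  if (!all(need %in% names(tab)))
    stop("spectra CSV needs columns ", paste(need, collapse = ", "))
  lapply(split(tab, tab$id), function(d)
    spectrum2(d$mz, d$intensity, precursorMz = d$precursor_mz[1],
              rt = if ("rt" %in% names(d)) as.numeric(d$rt[1]) else NA_real_))
}
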