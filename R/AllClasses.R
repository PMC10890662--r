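#' @import methods
NULL

## Central S4 classes.  Molecular formulas themselves are plain named integer
## vectors (element symbol -> count); everything aggregate gets a class with a
## validity method.

#' Isotope reagent pair (light/heavy chemical tag)
#'
#' Describes a pair of derivatization reagents that differ by a fixed number
#' of heavy-isotope labels, e.g. DMED / d4-DMED.  The heavy extracted-ion
#' channel of any labeled analyte is shifted by
#' `labelCount * perLabelShift` Da above the light channel.
#'
#' @slot lightFormula named integer vector; molecular formula of the light
#'   reagent.
#' @slot heavyFormula named integer vector; formula of the heavy reagent
#'   (deuterium written as element `"D"`).
#' @slot labelCount integer; number of isotope labels.
#' @slot perLabelShift numeric; mass difference per label in Da.
#' @seealso [dmedTagPair()]
#' @export
setClass("IsotopeTagPair",
  representation(lightFormula = "integer", heavyFormula = "integer",
                 labelCount = "integer", perLabelShift = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@labelCount < 1L) msg <- c(msg, "labelCount must be >= 1")
    if (object@perLabelShift <= 0) msg <- c(msg, "perLabelShift must be > 0")
    dm <- monoisotopicMass(object@heavyFormula) -
          monoisotopicMass(object@lightFormula)
    if (abs(dm - object@labelCount * object@perLabelShift) > 1e-4)
      msg <- c(msg, "heavy-light formula mass difference disagrees with labelCount * perLabelShift")
    if (length(msg)) msg else TRUE
  })

#' An MS2 (fragment) spectrum
#'
#' @slot precursorMz numeric(1); selected precursor m/z (Th).
#' @slot rt numeric(1); retention time in minutes.
#' @slot mz numeric; fragment m/z values, strictly increasing.
#' @slot intensity numeric; fragment intensities, same length as `mz`.
#' @export
setClass("Spectrum2",
  representation(precursorMz = "numeric", rt = "numeric",
                 mz = "numeric", intensity = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@mz) != length(object@intensity))
      msg <- c(msg, "mz and intensity lengths differ")
    if (is.unsorted(object@mz, strictly = TRUE))
      msg <- c(msg, "mz must be strictly increasing")
    if (any(object@intensity < 0)) msg <- c(msg, "negative intensities")
    if (length(object@precursorMz) != 1 || object@precursorMz <= 0)
      msg <- c(msg, "precursorMz must be a single positive value")
    if (length(msg)) msg else TRUE
  })

#' An LC-MS run (MS1 scans plus a DDA MS2 index)
#'
#' Container for one centroided LC-MS/MS acquisition: ordered MS1 full scans
#' and the data-dependent MS2 spectra indexed by precursor m/z and retention
#' time.
#'
#' @slot ms1Rt numeric; MS1 scan retention times (minutes), non-decreasing.
#' @slot ms1Peaks list of two-column matrices (`mz`, `intensity`), one per
#'   MS1 scan, m/z sorted.
#' @slot ms2 list of [Spectrum2-class] objects.
#' @slot scanRange numeric(2); acquired m/z range (Th).
#' @export
setClass("MsRun",
  representation(ms1Rt = "numeric", ms1Peaks = "list", ms2 = "list",
                 scanRange = "numeric"),
  prototype(scanRange = c(300, 700)),
  validity = function(object) {
    msg <- character()
    if (length(object@ms1Rt) != length(object@ms1Peaks))
      msg <- c(msg, "ms1Rt and ms1Peaks lengths differ")
    if (is.unsorted(object@ms1Rt)) msg <- c(msg, "ms1Rt must be non-decreasing")
    bad <- vapply(object@ms1Peaks, function(p)
      !is.matrix(p) || ncol(p) != 2 || is.unsorted(p[, 1]), logical(1))
    if (any(bad)) msg <- c(msg, "each MS1 scan must be an m/z-sorted 2-column matrix")
    if (!all(vapply(object@ms2, is, logical(1), "Spectrum2")))
      msg <- c(msg, "ms2 must contain Spectrum2 objects")
    if (length(msg)) msg else TRUE
  })

#' An extracted-ion chromatogram (XIC)
#'
#' @slot targetMz numeric(1); extraction target m/z (Th).
#' @slot tolPpm numeric(1); half-window in ppm.
#' @slot rt numeric; retention times (minutes).
#' @slot intensity numeric; per-scan summed intensity inside the window.
#' @export
setClass("XicTrace",
  representation(targetMz = "numeric", tolPpm = "numeric",
                 rt = "numeric", intensity = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@rt) != length(object@intensity))
      msg <- c(msg, "rt and intensity lengths differ")
    if (any(object@intensity < 0)) msg <- c(msg, "negative intensities")
    if (length(msg)) msg else TRUE
  })

#' Candidate mass-channel table for glucose-conjugated gibberellins
#'
#' One row per isobaric channel: the light (DMED) and heavy (d4-DMED)
#' `[M+H]+` m/z shared by all member candidates, plus the member list.
#'
#' @slot channels `data.frame` with columns `lightMz`, `heavyMz`, `n`.
#' @slot members list (parallel to rows) of `data.frame`s describing the
#'   member candidates (`name`, `parentFormula`, `nativeFormula`,
#'   `derivatizedFormula`, `lightMz`, `heavyMz`, `lactone`, `hydroxyls`).
#' @slot tag [IsotopeTagPair-class] used to build the heavy channel.
#' @slot groupTol numeric(1); m/z grouping tolerance (Th).
#' @export
setClass("CandidateChannelSet",
  representation(channels = "data.frame", members = "list",
                 tag = "IsotopeTagPair", groupTol = "numeric"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@channels) != length(object@members))
      msg <- c(msg, "channels/members length mismatch")
    if (!all(c("lightMz", "heavyMz", "n") %in% names(object@channels)))
      msg <- c(msg, "channels needs columns lightMz, heavyMz, n")
    sh <- tagShift(object@tag)
    if (nrow(object@channels) &&
        any(abs(object@channels$heavyMz - object@channels$lightMz - sh) > 1e-4))
      msg <- c(msg, "heavy - light m/z must equal the tag shift within 1e-4")
    if (length(msg)) msg else TRUE
  })

#' Five-class MS/MS fragmentation-rule evidence
#'
#' Result of screening one MS2 spectrum against the neutral-loss /
#' fragment-ion rule library.
#'
#' @slot hits `data.frame` of matched losses/fragments: `class`, `name`,
#'   `theoMz`, `obsMz`, `ppm`, `intensity`.
#' @slot skeleton `data.frame` of carbon-skeleton `CxHy+` assignments:
#'   `obsMz`, `x`, `y`, `theoMz`, `ppm`.
#' @slot classPass named logical, one flag per rule class `"1"`..`"5"`.
#' @slot pass logical(1); overall verdict under the screening policy.
#' @export
setClass("RuleEvidence",
  representation(hits = "data.frame", skeleton = "data.frame",
                 classPass = "logical", pass = "logical"),
  validity = function(object) {
    msg <- character()
    if (!identical(names(object@classPass), as.character(1:5)))
      msg <- c(msg, "classPass must be named '1'..'5'")
    if (length(object@pass) != 1) msg <- c(msg, "pass must be length 1")
    if (length(msg)) msg else TRUE
  })

#' Inferred A-ring features
#'
#' Lactone and hydroxyl counts of the gibberellin A-ring deduced from the
#' H2O / HCOOH / CO2 loss ladder below the `[M - glucose - (CH3)2NH]+`
#' anchor fragment.
#'
#' @slot lactone integer(1); 0 or 1.
#' @slot hydroxyls integer(1); number of A-ring hydroxyl groups.
#' @slot anchorMz numeric(1); theoretical anchor fragment m/z.
#' @slot anchorObsMz numeric(1); observed anchor m/z.
#' @export
setClass("AringInference",
  representation(lactone = "integer", hydroxyls = "integer",
                 anchorMz = "numeric", anchorObsMz = "numeric"),
  validity = function(object) {
    if (object@lactone < 0L || object@hydroxyls < 0L)
      "counts must be >= 0" else TRUE
  })

#' One identified compound (a Table-style report row)
#'
#' Records the nested candidate sets surviving each step of the four-step
#' identification: channel assignment, fragmentation-consistency, QSRR
#' retention-index filtering, and comparison against reference standards.
#'
#' @slot id character(1); compound label.
#' @slot lightMz,heavyMz numeric(1); channel m/z (Th).
#' @slot rt numeric(1); retention time (minutes).
#' @slot ri numeric(1); experimental retention index.
#' @slot assigned,step2,step3,step4 character; candidate parent-GA names
#'   after each step (each a subset of the previous).
#' @slot supported character; candidates whose reference standard matched.
#' @slot inference [AringInference-class].
#' @slot evidence [RuleEvidence-class].
#' @export
setClass("IdentificationRecord",
  representation(id = "character", lightMz = "numeric", heavyMz = "numeric",
                 rt = "numeric", ri = "numeric",
                 assigned = "character", step2 = "character",
                 step3 = "character", step4 = "character",
                 supported = "character",
                 inference = "AringInference", evidence = "RuleEvidence"),
  validity = function(object) {
    msg <- character()
    if (!all(object@step2 %in% object@assigned)) msg <- c(msg, "step2 not nested in assigned")
    if (!all(object@step3 %in% object@step2)) msg <- c(msg, "step3 not nested in step2")
    if (!all(object@step4 %in% object@step3)) msg <- c(msg, "step4 not nested in step3")
    if (length(msg)) msg else TRUE
  })
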