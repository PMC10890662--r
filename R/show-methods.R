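#' @describeIn MsRun-class compact summary
#' @param object an object of the documented class.
#' @export
setMethod("show", "MsRun", function(object) {
  cat("MsRun:", length(object@ms1Rt), "MS1 scans,",
      length(object@ms2), "MS2 spectra\n")
  if (length(object@ms1Rt))
    cat(sprintf("  RT %.2f-%.2f min; scan range %.0f-%.0f Th\n",
                min(object@ms1Rt), max(object@ms1Rt),
                object@scanRange[1], object@scanRange[2]))
})

#' @describeIn Spectrum2-class compact summary
#' @param object an object of the documented class.
#' @export
setMethod("show", "Spectrum2", function(object) {
  cat(sprintf("Spectrum2: precursor m/z %.4f, RT %.2f min, %d fragments\n",
              object@precursorMz, object@rt, length(object@mz)))
})

#' @describeIn XicTrace-class compact summary
#' @param object an object of the documented class.
#' @export
setMethod("show", "XicTrace", function(object) {
  cat(sprintf("XicTrace: m/z %.4f +/- %g ppm, %d scans, max intensity %.0f\n",
              object@targetMz, object@tolPpm, length(object@rt),
              if (length(object@intensity)) max(object@intensity) else 0))
})

#' @describeIn CandidateChannelSet-class compact summary
#' @param object an object of the documented class.
#' @export
setMethod("show", "CandidateChannelSet", function(object) {
  cat("CandidateChannelSet:", nrow(object@channels), "channels,",
      sum(object@channels$n), "candidates; tag shift",
      sprintf("+%.4f Da\n", tagShift(object@tag)))
})

#' @describeIn RuleEvidence-class per-class summary
#' @param object an object of the documented class.
#' @export
setMethod("show", "RuleEvidence", function(object) {
  cat("RuleEvidence:", nrow(object@hits), "loss/fragment hits,",
      nrow(object@skeleton), "skeleton ions;",
      "classes passed:", paste(names(object@classPass)[object@classPass],
                               collapse = ","),
      "; overall", if (object@pass) "PASS" else "FAIL", "\n")
})

#' @describeIn AringInference-class compact summary
#' @param object an object of the documented class.
#' @export
setMethod("show", "AringInference", function(object) {
  cat(sprintf("AringInference: %d lactone, %d hydroxyl(s); anchor m/z %.4f (obs %.4f)\n",
              object@lactone, object@hydroxyls, object@anchorMz,
              object@anchorObsMz))
})

#' @describeIn IdentificationRecord-class report-row summary
#' @param object an object of the documented class.
#' @export
setMethod("show", "IdentificationRecord", function(object) {
  cat(sprintf("IdentificationRecord %s: channel %.4f/%.4f, RT %.2f min, RI %.2f\n",
              object@id, object@lightMz, object@heavyMz, object@rt, object@ri))
  cat("  assigned:", length(object@assigned),
      "-> consistent:", length(object@step2),
      "-> RI-retained:", length(object@step3),
      "-> final:", paste(object@step4, collapse = ", "), "\n")
})
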