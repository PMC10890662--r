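## mzML I/O and basic run-level operations.  File parsing/writing is
## delegated to Bioconductor's mzR (proteowizard backend); everything else
## operates on the in-memory MsRun container.

#' Construct an MS2 spectrum
#'
#' @param mz,intensity numeric; fragment arrays (will be sorted by m/z).
#' @param precursorMz numeric(1); precursor m/z (Th).
#' @param rt numeric(1); retention time (minutes).
#' @return A [Spectrum2-class].
#' @examples
#' spectrum2(c(163.0601, 85.0284), c(100, 40), precursorMz = 325.1129, rt = 5)
#' @export
spectrum2 <- function(mz, intensity, precursorMz, rt = NA_real_) {
  o <- order(mz)
  mz <- mz[o]; intensity <- intensity[o]
  keep <- !duplicated(mz)
  new("Spectrum2", mz = mz[keep], intensity = intensity[keep],
      precursorMz = precursorMz, rt = rt)
}

#' Read a centroided LC-MS/MS run from mzML
#'
#' Loads MS1 full scans and DDA MS2 spectra into an [MsRun-class].  Profile
#' mode data are not expected; spectra flagged as profile are kept as-is
#' with a warning (treated as naive centroids).
#'
#' @param path character(1); mzML file.
#' @param scanRange numeric(2); acquired m/z range used for bookkeeping
#'   (default `c(300, 700)`).
#' @return An [MsRun-class].
#' @export
readRun <- function(path, scanRange = c(300, 700)) {
  if (!file.exists(path)) stop("file not found: ", path)
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh))
  hd <- mzR::header(fh)
  if (nrow(hd) == 0) stop("no spectra in ", path)
  if (any(!hd$centroided %in% TRUE))
    warning("non-centroided spectra present; using them as naive centroids")
  pk <- mzR::peaks(fh)
  if (is.matrix(pk)) pk <- list(pk)
  ms1 <- which(hd$msLevel == 1)
  ms2 <- which(hd$msLevel == 2)
  ms1Peaks <- lapply(pk[ms1], function(p) {
    p <- p[order(p[, 1]), , drop = FALSE]
    colnames(p) <- c("mz", "intensity")
    p
  })
  ms2Spectra <- lapply(ms2, function(i) {
    p <- pk[[i]]
    spectrum2(p[, 1], p[, 2], precursorMz = hd$precursorMZ[i],
              rt = hd$retentionTime[i] / 60)
  })
  new("MsRun", ms1Rt = hd$retentionTime[ms1] / 60, ms1Peaks = ms1Peaks,
      ms2 = ms2Spectra, scanRange = scanRange)
}

#' Write an MsRun to mzML
#'
#' Inverse of [readRun()], via mzR's proteowizard writer.  Spectra are
#' written centroided, retention times in seconds.
#'
#' @param run an [MsRun-class].
#' @param path output mzML path.
#' @return `path`, invisibly.
#' @export
writeRun <- function(run, path) {
  stopifnot(is(run, "MsRun"))
  n1 <- length(run@ms1Rt); n2 <- length(run@ms2)
  ## interleave: all MS1 then MS2 ordered by RT would break DDA ordering;
  ## order all spectra by retention time with MS1 first on ties.
  rt <- c(run@ms1Rt, vapply(run@ms2, function(s) s@rt, numeric(1)))
  lev <- c(rep(1L, n1), rep(2L, n2))
  ord <- order(rt, lev)
  pk <- c(run@ms1Peaks,
          lapply(run@ms2, function(s)
            cbind(mz = s@mz, intensity = s@intensity)))[ord]
  prec <- c(rep(0, n1),
            vapply(run@ms2, function(s) s@precursorMz, numeric(1)))[ord]
  n <- n1 + n2
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n),
    msLevel = lev[ord], polarity = 1L,
    peaksCount = vapply(pk, nrow, integer(1)),
    totIonCurrent = vapply(pk, function(p) sum(p[, 2]), numeric(1)),
    retentionTime = rt[ord] * 60,
    basePeakMZ = vapply(pk, function(p)
      if (nrow(p)) p[which.max(p[, 2]), 1] else 0, numeric(1)),
    basePeakIntensity = vapply(pk, function(p)
      if (nrow(p)) max(p[, 2]) else 0, numeric(1)),
    collisionEnergy = ifelse(lev[ord] == 2L, 55, 0),
    ionisationEnergy = 0,
    lowMZ = vapply(pk, function(p) if (nrow(p)) min(p[, 1]) else 0, numeric(1)),
    highMZ = vapply(pk, function(p) if (nrow(p)) max(p[, 1]) else 0, numeric(1)),
    precursorScanNum = 0L,
    precursorMZ = prec,
    precursorCharge = ifelse(lev[ord] == 2L, 1L, 0L),
    precursorIntensity = 0,
    mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = sprintf("scan=%d", seq_len(n)),
    centroided = TRUE, ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = ifelse(lev[ord] == 2L, prec, NA_real_),
    isolationWindowLowerOffset = ifelse(lev[ord] == 2L, 0.5, NA_real_),
    isolationWindowUpperOffset = ifelse(lev[ord] == 2L, 0.5, NA_real_),
    scanWindowLowerLimit = run@scanRange[1],
    scanWindowUpperLimit = run@scanRange[2],
    stringsAsFactors = FALSE)
  pk <- lapply(pk, function(p) { dimnames(p) <- NULL; p })
  mzR::writeMSData(pk, path, header = hdr, outformat = "mzml")
  invisible(path)
}

#' Extract an ion chromatogram
#'
#' Per-MS1-scan summed intensity of all centroids within `+/- tolPpm` of the
#' target m/z.
#'
#' @param run an [MsRun-class].
#' @param mz numeric(1); target m/z (Th).
#' @param tolPpm numeric(1); half-window in ppm (default 10).
#' @return An [XicTrace-class] (all-zero if nothing matches).
#' @export
extractXic <- function(run, mz, tolPpm = 10) {
  stopifnot(is(run, "MsRun"), length(mz) == 1, mz > 0)
  tol <- mz * tolPpm * 1e-6
  lo <- mz - tol; hi <- mz + tol
  ints <- vapply(run@ms1Peaks, function(p) {
    i <- findInterval(c(lo, hi), p[, 1])
    if (i[2] > i[1]) sum(p[(i[1] + 1):i[2], 2]) else {
      ## findInterval(lo) gives last index <= lo; include exact lo match
      0
    }
  }, numeric(1))
  new("XicTrace", targetMz = mz, tolPpm = tolPpm,
      rt = run@ms1Rt, intensity = ints)
}

#' Find the MS2 spectrum acquired nearest a chromatographic peak
#'
#' Among DDA MS2 spectra whose precursor matches `mz` within `tolPpm` and
#' whose retention time lies within `rtWindow` of `rt`, returns the one
#' nearest in RT (ties broken by higher total ion current).
#'
#' @param run an [MsRun-class].
#' @param mz numeric(1); precursor m/z (Th).
#' @param rt numeric(1); retention time (minutes).
#' @param tolPpm numeric(1); precursor tolerance (ppm, default 10).
#' @param rtWindow numeric(1); RT half-window in minutes (default 0.2).
#' @return A [Spectrum2-class], or `NULL` when none matches.
#' @export
ms2Near <- function(run, mz, rt, tolPpm = 10, rtWindow = 0.2) {
  stopifnot(is(run, "MsRun"))
  if (!length(run@ms2)) return(NULL)
  prec <- vapply(run@ms2, function(s) s@precursorMz, numeric(1))
  rts  <- vapply(run@ms2, function(s) s@rt, numeric(1))
  ok <- abs(ppmError(prec, mz)) <= tolPpm & abs(rts - rt) <= rtWindow
  if (!any(ok)) return(NULL)
  idx <- which(ok)
  drt <- abs(rts[idx] - rt)
  tic <- vapply(run@ms2[idx], function(s) sum(s@intensity), numeric(1))
  idx[order(drt, -tic)][1L]
  run@ms2[[idx[order(drt, -tic)][1L]]]
}

#' Total ion current per MS1 scan
#'
#' @param run an [MsRun-class].
#' @return numeric; per-scan summed intensity.
#' @export
ticTrace <- function(run) {
  stopifnot(is(run, "MsRun"))
  vapply(run@ms1Peaks, function(p) sum(p[, 2]), numeric(1))
}
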