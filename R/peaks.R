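## Chromatographic peak detection on XIC traces.

#' Per-scan intensity summed over an absolute m/z window
#'
#' Companion to [extractXic()] with half-open `(lo, hi]` semantics, so that
#' disjoint windows tiling the scan range partition the total ion current
#' exactly.
#'
#' @param run an [MsRun-class].
#' @param lo,hi numeric(1); window bounds in Th.
#' @return numeric; per-MS1-scan summed intensity.
#' @export
extractXicRange <- function(run, lo, hi) {
  stopifnot(is(run, "MsRun"), lo < hi)
  vapply(run@ms1Peaks, function(p) {
    i <- findInterval(c(lo, hi), p[, 1])
    if (i[2] > i[1]) sum(p[(i[1] + 1):i[2], 2]) else 0
  }, numeric(1))
}

.movingAverage <- function(x, k = 5L) {
  if (length(x) < k) return(x)
  pad <- (k - 1L) %/% 2L
  xx <- c(rep(x[1], pad), x, rep(x[length(x)], k - 1L - pad))
  as.numeric(stats::filter(xx, rep(1 / k, k), sides = 2))[(pad + 1L):(pad + length(x))]
}

#' Detect chromatographic peaks in an XIC trace
#'
#' Simple, transparent picker: the trace is smoothed with a 5-scan moving
#' average; local maxima rising at least `minSnr` noise units above the
#' baseline become peaks, with bounds walked out to the surrounding valleys.
#' Noise is the median absolute deviation of the raw trace (falling back to
#' its standard deviation when the MAD degenerates on sparse traces) and the
#' baseline is the trace median.  Apex retention time is refined by
#' three-point parabolic interpolation around the raw maximum.
#'
#' @param trace an [XicTrace-class].
#' @param minSnr numeric(1); minimal (apex - baseline)/noise (default 3).
#' @param minPoints integer(1); minimal number of in-peak scans above
#'   baseline + noise (default 5).
#' @return `data.frame` of peaks sorted by RT: `rt` (interpolated apex,
#'   minutes), `height` (raw apex intensity), `area` (trapezoidal), `rtLeft`,
#'   `rtRight`, `snr`.
#' @export
detectPeaks <- function(trace, minSnr = 3, minPoints = 5L) {
  stopifnot(is(trace, "XicTrace"))
  x <- trace@intensity
  rt <- trace@rt
  empty <- data.frame(rt = numeric(), height = numeric(), area = numeric(),
                      rtLeft = numeric(), rtRight = numeric(), snr = numeric())
  if (length(x) < minPoints || all(x <= 0)) return(empty)
  sm <- .movingAverage(x, 5L)
  baseline <- stats::median(x)
  noise <- stats::mad(x)
  if (!is.finite(noise) || noise <= 0) noise <- stats::sd(x)
  if (!is.finite(noise) || noise <= 0) noise <- 1
  n <- length(sm)
  ismax <- which(sm > c(-Inf, sm[-n]) & sm >= c(sm[-1], Inf))
  thr <- baseline + minSnr * noise
  peaks <- list()
  for (i in ismax) {
    if (sm[i] < thr) next
    ## walk down to the surrounding valleys
    l <- i; while (l > 1 && sm[l - 1] <= sm[l]) l <- l - 1
    r <- i; while (r < n && sm[r + 1] <= sm[r]) r <- r + 1
    seg <- l:r
    if (sum(x[seg] > baseline + noise) < minPoints) next
    apexIdx <- seg[which.max(x[seg])]
    apexRt <- rt[apexIdx]
    if (apexIdx > 1 && apexIdx < length(x)) {
      y1 <- x[apexIdx - 1]; y2 <- x[apexIdx]; y3 <- x[apexIdx + 1]
      den <- y1 - 2 * y2 + y3
      if (den < 0) {
        delta <- 0.5 * (y1 - y3) / den
        if (abs(delta) <= 0.5)
          apexRt <- rt[apexIdx] + delta * mean(diff(rt[max(1, apexIdx - 1):min(length(rt), apexIdx + 1)]))
      }
    }
    area <- sum(diff(rt[seg]) * (x[seg][-1] + x[seg][-length(seg)]) / 2)
    peaks[[length(peaks) + 1L]] <- data.frame(
      rt = apexRt, height = x[apexIdx], area = area,
      rtLeft = rt[l], rtRight = rt[r],
      snr = (x[apexIdx] - baseline) / noise)
  }
  if (!length(peaks)) return(empty)
  out <- do.call(rbind, peaks)
  ## merge duplicates (two smoothed maxima can resolve to one raw apex)
  out <- out[!duplicated(out$rt), , drop = FALSE]
  out <- out[out$height > 0, , drop = FALSE]
  out[order(out$rt), , drop = FALSE]
}
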