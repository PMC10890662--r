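## Retention-index calibration, QSRR linear modeling, and the retention
## filter used in candidate identification.

.QSRR_THRESHOLD <- 69.5832

#' Retention-index calibration series
#'
#' A piecewise-linear map from retention time (minutes) to the dimensionless
#' retention index, defined by ordered anchor points.
#'
#' @param rt,ri numeric; anchor retention times (strictly increasing) and
#'   their retention indices (strictly increasing).
#' @return A `data.frame` of class `CalibrationSeries`.
#' @export
calibrationSeries <- function(rt, ri) {
  stopifnot(length(rt) == length(ri), length(rt) >= 2)
  if (is.unsorted(rt, strictly = TRUE)) stop("anchor RTs must be strictly increasing")
  if (is.unsorted(ri, strictly = TRUE)) stop("anchor RIs must be strictly increasing")
  structure(data.frame(rt = rt, ri = ri),
            class = c("CalibrationSeries", "data.frame"))
}

#' Load a calibration series from CSV
#'
#' @param path CSV with columns `rt`, `ri`.
#' @return A `CalibrationSeries`.
#' @rdname calibrationSeries
#' @export
loadCalibration <- function(path) {
  tab <- utils::read.csv(path)
  if (!all(c("rt", "ri") %in% names(tab)))
    stop("calibration CSV needs columns rt, ri")
  calibrationSeries(tab$rt, tab$ri)
}

#' Convert retention time to retention index
#'
#' Piecewise-linear interpolation between the bracketing anchors; retention
#' times outside the anchor range are extrapolated linearly from the first
#' (or last) segment with a warning.
#'
#' @param rt numeric; retention times in minutes.
#' @param cal a `CalibrationSeries`.
#' @return numeric; retention indices.
#' @examples
#' cal <- calibrationSeries(c(5, 10), c(600, 700))
#' rtToRi(7.5, cal)   # 650
#' @export
rtToRi <- function(rt, cal) {
  stopifnot(inherits(cal, "CalibrationSeries"))
  if (any(rt < cal$rt[1] | rt > cal$rt[nrow(cal)]))
    warning("retention time outside the calibrated range; extrapolating")
  ## rule = 2 would clamp; extrapolate from the terminal segments instead
  n <- nrow(cal)
  slope1 <- (cal$ri[2] - cal$ri[1]) / (cal$rt[2] - cal$rt[1])
  slopeN <- (cal$ri[n] - cal$ri[n - 1]) / (cal$rt[n] - cal$rt[n - 1])
  out <- stats::approx(cal$rt, cal$ri, xout = rt, rule = 2)$y
  low <- rt < cal$rt[1]; high <- rt > cal$rt[n]
  out[low] <- cal$ri[1] + (rt[low] - cal$rt[1]) * slope1
  out[high] <- cal$ri[n] + (rt[high] - cal$rt[n]) * slopeN
  out
}

#' Fit a QSRR multivariate linear regression
#'
#' Ordinary least squares of retention index on molecular descriptors, the
#' regression underlying retention-index prediction for derivatized
#' gibberellins.
#'
#' @param X numeric matrix (samples x descriptors); column names are used
#'   as descriptor names.
#' @param y numeric; retention indices (length `nrow(X)`).
#' @return List of class `QsrrModel`: `coefficients` (named, incl.
#'   `(Intercept)`), `fitted`, `residuals`, `rmse` (training RMSE),
#'   `descriptors`.
#' @export
fitQsrr <- function(X, y) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  if (nrow(X) < ncol(X) + 2)
    stop("need at least descriptors + 2 samples (got ", nrow(X), ")")
  if (is.null(colnames(X))) colnames(X) <- paste0("d", seq_len(ncol(X)))
  Xd <- cbind(`(Intercept)` = 1, X)
  if (qr(Xd)$rank < ncol(Xd)) stop("rank-deficient descriptor matrix")
  fit <- stats::lm.fit(Xd, y)
  res <- y - Xd %*% fit$coefficients
  structure(list(coefficients = fit$coefficients,
                 fitted = as.numeric(Xd %*% fit$coefficients),
                 residuals = as.numeric(res),
                 rmse = sqrt(mean(res^2)),
                 descriptors = colnames(X)),
            class = "QsrrModel")
}

#' Predict retention indices from a QSRR model
#'
#' @param object a `QsrrModel`.
#' @param newdata numeric matrix with the model's descriptor columns.
#' @param ... unused.
#' @return numeric; predicted retention indices.
#' @export
predict.QsrrModel <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  as.numeric(cbind(1, newdata[, object$descriptors, drop = FALSE]) %*%
               object$coefficients)
}

#' Leave-one-out cross-validated RMSE
#'
#' Closed-form leave-one-out prediction error of the linear QSRR fit,
#' computed from the hat matrix as `e_i / (1 - h_ii)`.
#'
#' @inheritParams fitQsrr
#' @return numeric(1); LOO root-mean-square prediction error.
#' @export
loocvRmse <- function(X, y) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  if (nrow(X) < ncol(X) + 2) stop("need at least descriptors + 2 samples")
  Xd <- cbind(1, X)
  if (qr(Xd)$rank < ncol(Xd)) stop("rank-deficient descriptor matrix")
  H <- Xd %*% solve(crossprod(Xd), t(Xd))
  e <- y - H %*% y
  loo <- e / (1 - diag(H))
  sqrt(mean(loo^2))
}

#' Retention-index filter for Glc-GA candidates
#'
#' A candidate is retained when its experimental retention index lies below
#' the QSRR-predicted index of the corresponding labeled gibberellin plus
#' the model's cross-validated error threshold (default 69.5832): glucose
#' conjugation weakens reversed-phase retention, so genuine Glc-GAs elute
#' at or before their parent's predicted position (one-sided test; positive
#' deviations of any size are retained).
#'
#' @param riExp numeric; experimental retention index (recycled).
#' @param riPred numeric; predicted retention index of the parent-GA
#'   labeled form.
#' @return logical; `TRUE` when retained.
#' @examples
#' eq1Filter(718.97, 535.52)   # FALSE: elutes far later than predicted
#' eq1Filter(718.97, 685.27)   # TRUE
#' @param threshold numeric(1); RI error threshold.
#' @export
eq1Filter <- function(riExp, riPred, threshold = .QSRR_THRESHOLD) {
  stopifnot(is.finite(threshold))
  riExp < riPred + threshold
}

#' Differences between predicted and experimental retention indices
#'
#' @param riPred numeric; predicted retention indices.
#' @param riExp numeric(1); experimental retention index.
#' @param digits integer; rounding of the reported differences (default 2).
#' @return numeric; `riPred - riExp`, rounded.
#' @examples
#' riDifferences(c(535.52, 685.27, 716.94), 718.97)
#' @export
riDifferences <- function(riPred, riExp, digits = 2) {
  if (!length(riPred)) return(numeric(0))
  round(riPred - riExp, digits)
}

#' Load a predicted-RI table
#'
#' @param path CSV with columns `ga_name`, `ri_pred`.
#' @return `data.frame` with those columns.
#' @export
loadPredictedRi <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("ga_name", "ri_pred") %in% names(tab)))
    stop("predicted-RI CSV needs columns ga_name, ri_pred")
  tab
}
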