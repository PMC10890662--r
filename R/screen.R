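## Light/heavy peak-pair matching and five-class MS/MS rule screening —
## the core of the Glc-GA discovery workflow.

## glucose condensation unit (C6H10O5) and dimethylamine ((CH3)2NH) losses,
## derived from element masses at install time
.GLC_LOSS  <- sum(c(6, 10, 5) * c(12, 1.007825, 15.994915))
.DMED_LOSS <- sum(c(2, 7, 1) * c(12, 1.007825, 14.003074))

#' Default five-class fragmentation-rule library
#'
#' Neutral losses and diagnostic fragment ions organized in the five rule
#' classes used to screen labeled Glc-GA MS2 spectra:
#' \describe{
#'   \item{1}{reagent (DMED)-related: loss of (CH3)2NH 45.0578; fragment
#'     cations C4H10N+ 72.0808 and C3H6ON+ 72.0444.}
#'   \item{2}{A-ring related: losses of H2O 18.0106, HCOOH 46.0055,
#'     CO2 43.9898.}
#'   \item{3}{C/D-ring related: loss of C2H4 28.0313 (retro-Diels-Alder
#'     type ring contraction).}
#'   \item{4}{carbon-skeleton related: odd-numbered CxHy+ hydrocarbon
#'     fragments in the m/z 80-230 window (see
#'     [detectSkeletonSeries()]).}
#'   \item{5}{glucose-related: loss of the glucose unit 162.0528.}
#' }
#' All masses are derived from element masses at load time, never typed in.
#'
#' @return `data.frame` with columns `class`, `name`, `type`
#'   (`"loss"`/`"fragment"`), `mass` (Da for losses, Th for fragments).
#' @export
defaultLossLibrary <- function() {
  rbind(
    data.frame(class = 1L, name = "(CH3)2NH", type = "loss",
               mass = .lossMass("C2H7N")),
    data.frame(class = 1L, name = "C4H10N+", type = "fragment",
               mass = cationMz("C4H10N")),
    data.frame(class = 1L, name = "C3H6ON+", type = "fragment",
               mass = cationMz("C3H6ON")),
    data.frame(class = 2L, name = "H2O", type = "loss",
               mass = .lossMass("H2O")),
    data.frame(class = 2L, name = "HCOOH", type = "loss",
               mass = .lossMass("CH2O2")),
    data.frame(class = 2L, name = "CO2", type = "loss",
               mass = .lossMass("CO2")),
    data.frame(class = 3L, name = "C2H4", type = "loss",
               mass = .lossMass("C2H4")),
    data.frame(class = 5L, name = "glucose", type = "loss",
               mass = .lossMass("C6H10O5")))
}

#' Peak-pair acceptance criteria
#'
#' The light (DMED) and heavy (d4-DMED) labeled forms of one analyte must
#' co-elute and, having been mixed 1:1, show near-equal peak intensity.
#' Defaults: RT difference (light - heavy) in `[0, 0.013]` minutes and
#' light/heavy apex-height ratio in `[0.76, 1.50]`.
#'
#' @param rtDelta numeric(2); allowed `rt(light) - rt(heavy)` range, minutes.
#' @param intensityRatio numeric(2); allowed light/heavy height ratio.
#' @return A list of class `PairCriteria`.
#' @export
pairCriteria <- function(rtDelta = c(0, 0.013),
                         intensityRatio = c(0.76, 1.50)) {
  stopifnot(length(rtDelta) == 2, rtDelta[1] <= rtDelta[2],
            length(intensityRatio) == 2,
            intensityRatio[1] <= intensityRatio[2], intensityRatio[1] > 0)
  structure(list(rtDelta = rtDelta, intensityRatio = intensityRatio),
            class = "PairCriteria")
}

#' Match light/heavy chromatographic peak pairs
#'
#' Considers every (light, heavy) combination satisfying the RT-delta and
#' intensity-ratio criteria, then assigns pairs greedily 1:1 by smallest
#' absolute RT difference (ties broken by ratio closest to 1).
#'
#' @param lightPeaks,heavyPeaks peak `data.frame`s from [detectPeaks()] of
#'   the light and heavy channel XICs of one run.
#' @param criteria a [pairCriteria()] object.
#' @return `data.frame`: `rtLight`, `rtHeavy`, `rtDelta`, `heightLight`,
#'   `heightHeavy`, `ratio`, sorted by `rtLight`.
#' @export
matchPairs <- function(lightPeaks, heavyPeaks, criteria = pairCriteria()) {
  stopifnot(inherits(criteria, "PairCriteria"))
  empty <- data.frame(rtLight = numeric(), rtHeavy = numeric(),
                      rtDelta = numeric(), heightLight = numeric(),
                      heightHeavy = numeric(), ratio = numeric())
  if (!nrow(lightPeaks) || !nrow(heavyPeaks)) return(empty)
  combos <- expand.grid(i = seq_len(nrow(lightPeaks)),
                        j = seq_len(nrow(heavyPeaks)))
  delta <- lightPeaks$rt[combos$i] - heavyPeaks$rt[combos$j]
  ratio <- lightPeaks$height[combos$i] / heavyPeaks$height[combos$j]
  ok <- delta >= criteria$rtDelta[1] & delta <= criteria$rtDelta[2] &
        ratio >= criteria$intensityRatio[1] & ratio <= criteria$intensityRatio[2]
  combos <- combos[ok, , drop = FALSE]
  delta <- delta[ok]; ratio <- ratio[ok]
  if (!nrow(combos)) return(empty)
  ord <- order(abs(delta), abs(ratio - 1))
  usedL <- logical(nrow(lightPeaks)); usedH <- logical(nrow(heavyPeaks))
  keep <- logical(nrow(combos))
  for (k in ord) {
    if (usedL[combos$i[k]] || usedH[combos$j[k]]) next
    usedL[combos$i[k]] <- TRUE; usedH[combos$j[k]] <- TRUE
    keep[k] <- TRUE
  }
  out <- data.frame(
    rtLight = lightPeaks$rt[combos$i[keep]],
    rtHeavy = heavyPeaks$rt[combos$j[keep]],
    rtDelta = delta[keep],
    heightLight = lightPeaks$height[combos$i[keep]],
    heightHeavy = heavyPeaks$height[combos$j[keep]],
    ratio = ratio[keep])
  out[order(out$rtLight), , drop = FALSE]
}

## closest observed fragment within tol ppm, or NA
.matchFragment <- function(ms2, theoMz, tolPpm) {
  err <- abs(ms2@mz - theoMz) / theoMz * 1e6
  i <- which.min(err)
  if (length(i) && err[i] <= tolPpm) i else NA_integer_
}

#' Annotate neutral-loss and fragment-ion evidence in an MS2 spectrum
#'
#' Walks neutral-loss ladders seeded at the precursor and at the
#' `[M - glucose - (CH3)2NH]+` anchor (precursor - 162.0528 - 45.0578),
#' chaining observed losses to `maxDepth` steps; fragment-type library
#' entries are checked for direct presence.  Every match is recorded with
#' its ppm error.
#'
#' @param ms2 a [Spectrum2-class].
#' @param precursorMz numeric(1); defaults to the spectrum's own precursor.
#' @param library loss library `data.frame` ([defaultLossLibrary()]).
#' @param tolPpm numeric(1); fragment match tolerance (default 10 ppm).
#' @param maxDepth integer(1); maximal chained-loss depth (default 4).
#' @return A [RuleEvidence-class] with `classPass`/`pass` left `FALSE`
#'   except for the per-hit classes (use [screenSpectrum()] for the policy
#'   verdict).
#' @export
annotateLosses <- function(ms2, precursorMz = ms2@precursorMz,
                           library = defaultLossLibrary(), tolPpm = 10,
                           maxDepth = 4L) {
  stopifnot(is(ms2, "Spectrum2"), length(ms2@mz) >= 0)
  losses <- library[library$type == "loss", , drop = FALSE]
  frags  <- library[library$type == "fragment", , drop = FALSE]
  hits <- data.frame(class = integer(), name = character(),
                     theoMz = numeric(), obsMz = numeric(),
                     ppm = numeric(), intensity = numeric())
  addHit <- function(cls, name, theo, idx) {
    hits[nrow(hits) + 1L, ] <<- list(cls, name, theo, ms2@mz[idx],
                                     ppmError(ms2@mz[idx], theo),
                                     ms2@intensity[idx])
  }
  ## breadth-first ladder walk; a node expands only if it is a seed or was
  ## itself observed in the spectrum
  anchor <- precursorMz - .GLC_LOSS - .DMED_LOSS
  frontier <- data.frame(mz = c(precursorMz, anchor), depth = 0L)
  visited <- as.character(signif(frontier$mz, 10))   # expansion dedup
  hitKeys <- character()               # one hit per distinct fragment mass
  while (nrow(frontier)) {
    nxt <- frontier[0, ]
    for (k in seq_len(nrow(frontier))) {
      node <- frontier$mz[k]; d <- frontier$depth[k]
      if (d >= maxDepth) next
      for (j in seq_len(nrow(losses))) {
        theo <- node - losses$mass[j]
        if (theo <= 0) next
        key <- as.character(signif(theo, 10))
        idx <- .matchFragment(ms2, theo, tolPpm)
        if (!is.na(idx)) {
          if (!key %in% hitKeys) {
            addHit(losses$class[j], losses$name[j], theo, idx)
            hitKeys <- c(hitKeys, key)
          }
          if (!key %in% visited) {
            nxt <- rbind(nxt, data.frame(mz = theo, depth = d + 1L))
            visited <- c(visited, key)
          }
        }
      }
    }
    frontier <- nxt
  }
  for (j in seq_len(nrow(frags))) {
    idx <- .matchFragment(ms2, frags$mass[j], tolPpm)
    if (!is.na(idx)) addHit(frags$class[j], frags$name[j], frags$mass[j], idx)
  }
  classPass <- stats::setNames(vapply(1:5, function(cl)
    any(hits$class == cl), logical(1)), as.character(1:5))
  new("RuleEvidence", hits = hits,
      skeleton = data.frame(obsMz = numeric(), x = integer(), y = integer(),
                            theoMz = numeric(), ppm = numeric()),
      classPass = classPass, pass = FALSE)
}

#' Detect the odd-numbered CxHy+ carbon-skeleton fragment series
#'
#' Annotates spectrum peaks in the `window` (default m/z 80-230) as
#' even-electron hydrocarbon cations CxHy+ with `5 <= x <= 18` and odd
#' hydrogen count (hence odd nominal mass).
#'
#' @param ms2 a [Spectrum2-class].
#' @param window numeric(2); m/z window (Th).
#' @param tolPpm numeric(1); match tolerance (default 10 ppm).
#' @return `data.frame`: `obsMz`, `x`, `y`, `theoMz`, `ppm`.
#' @export
detectSkeletonSeries <- function(ms2, window = c(80, 230), tolPpm = 10) {
  stopifnot(is(ms2, "Spectrum2"))
  grid <- expand.grid(x = 5:18, y = seq(1L, 37L, by = 2L))
  grid$theoMz <- 12 * grid$x + .ELEMENT_MASSES[["H"]] * grid$y - .ELECTRON_MASS
  grid <- grid[grid$theoMz >= window[1] & grid$theoMz <= window[2] &
               grid$y <= 2 * grid$x + 1, , drop = FALSE]
  inWin <- which(ms2@mz >= window[1] & ms2@mz <= window[2])
  out <- data.frame(obsMz = numeric(), x = integer(), y = integer(),
                    theoMz = numeric(), ppm = numeric())
  for (i in inWin) {
    err <- abs(grid$theoMz - ms2@mz[i]) / ms2@mz[i] * 1e6
    j <- which.min(err)
    if (length(j) && err[j] <= tolPpm)
      out[nrow(out) + 1L, ] <- list(ms2@mz[i], grid$x[j], grid$y[j],
                                    grid$theoMz[j],
                                    ppmError(ms2@mz[i], grid$theoMz[j]))
  }
  out
}

#' Screen an MS2 spectrum against the five-class rule policy
#'
#' Combines [annotateLosses()] and [detectSkeletonSeries()] and applies the
#' pass policy.  Default policy: glucose loss (class 5), a reagent-related
#' hit (class 1) and an A-ring hit (class 2) are mandatory, plus at least
#' one of the C/D-ring (class 3) or carbon-skeleton (class 4) classes.
#'
#' @inheritParams annotateLosses
#' @param policy list with `mandatory` and `anyOf` integer class vectors.
#' @param skeletonWindow numeric(2); class-4 m/z window.
#' @return A [RuleEvidence-class] with the overall `pass` verdict.
#' @export
screenSpectrum <- function(ms2, precursorMz = ms2@precursorMz,
                           library = defaultLossLibrary(), tolPpm = 10,
                           policy = list(mandatory = c(5L, 1L, 2L),
                                         anyOf = c(3L, 4L)),
                           skeletonWindow = c(80, 230)) {
  ev <- annotateLosses(ms2, precursorMz, library, tolPpm)
  skel <- detectSkeletonSeries(ms2, skeletonWindow, tolPpm)
  cp <- ev@classPass
  cp[["4"]] <- nrow(skel) > 0
  pass <- all(cp[as.character(policy$mandatory)]) &&
    (length(policy$anyOf) == 0 || any(cp[as.character(policy$anyOf)]))
  new("RuleEvidence", hits = ev@hits, skeleton = skel,
      classPass = cp, pass = pass)
}

#' Infer A-ring lactone and hydroxyl features from the anchor loss ladder
#'
#' The `[M - glucose - (CH3)2NH]+` anchor fragment (precursor - 162.0528 -
#' 45.0578) strips the glucose and reagent parts, so the subsequent H2O /
#' HCOOH / CO2 losses report on the gibberellin A-ring: each sequential H2O
#' loss marks a hydroxyl group (a combined CO2+2H2O loss marks two) and an
#' HCOOH loss marks the A-ring lactone.
#'
#' @param ms2 a [Spectrum2-class].
#' @param precursorMz numeric(1); defaults to the spectrum's precursor.
#' @param tolPpm numeric(1); fragment tolerance (default 10 ppm).
#' @param maxDepth integer(1); ladder depth (default 4).
#' @return An [AringInference-class].
#' @export
inferARing <- function(ms2, precursorMz = ms2@precursorMz, tolPpm = 10,
                       maxDepth = 4L) {
  stopifnot(is(ms2, "Spectrum2"))
  anchor <- precursorMz - .GLC_LOSS - .DMED_LOSS
  aIdx <- .matchFragment(ms2, anchor, tolPpm)
  if (is.na(aIdx))
    stop("no anchor: [M - glucose - (CH3)2NH]+ fragment (m/z ",
         sprintf("%.4f", anchor), ") absent from spectrum")
  ## steps: mass, H2O units contributed, HCOOH units contributed
  steps <- data.frame(
    name = c("H2O", "HCOOH", "CO2", "CO2+2H2O"),
    mass = c(.lossMass("H2O"), .lossMass("CH2O2"), .lossMass("CO2"),
             .lossMass("CO2") + 2 * .lossMass("H2O")),
    nH2O = c(1L, 0L, 0L, 2L),
    nHCOOH = c(0L, 1L, 0L, 0L))
  best <- c(h2o = 0L, hcooh = 0L)
  frontier <- data.frame(mz = anchor, depth = 0L, h2o = 0L, hcooh = 0L)
  seen <- signif(anchor, 10)
  while (nrow(frontier)) {
    nxt <- frontier[0, ]
    for (k in seq_len(nrow(frontier))) {
      if (frontier$depth[k] >= maxDepth) next
      for (j in seq_len(nrow(steps))) {
        theo <- frontier$mz[k] - steps$mass[j]
        if (theo <= 0) next
        key <- signif(theo, 10)
        if (key %in% seen) next
        idx <- .matchFragment(ms2, theo, tolPpm)
        seen <- c(seen, key)
        if (is.na(idx)) next
        h2o <- frontier$h2o[k] + steps$nH2O[j]
        hcooh <- frontier$hcooh[k] + steps$nHCOOH[j]
        best["h2o"] <- max(best[["h2o"]], h2o)
        best["hcooh"] <- max(best[["hcooh"]], hcooh)
        nxt <- rbind(nxt, data.frame(mz = theo, depth = frontier$depth[k] + 1L,
                                     h2o = h2o, hcooh = hcooh))
      }
    }
    frontier <- nxt
  }
  new("AringInference", lactone = as.integer(best[["hcooh"]] > 0),
      hydroxyls = as.integer(best[["h2o"]]),
      anchorMz = anchor, anchorObsMz = ms2@mz[aIdx])
}
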