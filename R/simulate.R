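## Ground-truthed synthetic LC-MS/MS run generator.  Emulates the
## acquisition used for derivatized plant extracts: MS1 full scans over
## m/z 300-700, Gaussian elution profiles for light/heavy labeled analytes
## (heavy channel +4.0251 Da, slightly earlier elution), Poisson counting
## noise, random noise centroids, and one DDA MS2 per analyte carrying its
## neutral-loss ladder.

#' Simulation configuration
#'
#' Spikes are genuine labeled Glc-GA analytes (correct pair behavior and a
#' complete fragmentation ladder); decoys probe one failure mode each:
#' `"ratio"` (light/heavy intensity ratio outside 0.76-1.50), `"rt"`
#' (light-heavy RT offset outside 0-0.013 min), `"ladder"` (a well-behaved
#' pair whose MS2 lacks the glucose loss).
#'
#' @param spikes `data.frame`: `name` (registry GA name of the spiked
#'   candidate), `rt` (apex, minutes), `height` (light apex intensity),
#'   `width` (Gaussian sigma, minutes), `rtOffset` (light minus heavy
#'   apex RT, minutes), `ratio` (light/heavy height ratio).
#' @param decoys `data.frame`: `type` (`"ratio"`, `"rt"`, `"ladder"`),
#'   `name`, `rt`, plus optional `height`, `width`, `rtOffset`, `ratio`
#'   overrides.
#' @param rtRange numeric(2); simulated RT window (minutes).
#' @param scanHz numeric(1); MS1 scan rate (default 2 Hz).
#' @param scanRange numeric(2); m/z acquisition range.
#' @param noisePeaks integer(1); random noise centroids per MS1 scan.
#' @param noiseMean numeric(1); mean intensity of noise centroids.
#' @param poissonNoise logical(1); apply Poisson counting noise to analyte
#'   points (`FALSE` gives noiseless profiles).
#' @param seed integer(1); mandatory RNG seed.
#' @return A list of class `SimConfig`.
#' @export
simConfig <- function(spikes = defaultSpikes(), decoys = defaultDecoys(),
                      rtRange = c(7.2, 13.2), scanHz = 2,
                      scanRange = c(300, 700), noisePeaks = 10L,
                      noiseMean = 100, poissonNoise = TRUE, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(all(spikes$rt > rtRange[1] & spikes$rt < rtRange[2]),
            all(spikes$width > 0))
  structure(list(spikes = spikes, decoys = decoys, rtRange = rtRange,
                 scanHz = scanHz, scanRange = scanRange,
                 noisePeaks = as.integer(noisePeaks), noiseMean = noiseMean,
                 poissonNoise = poissonNoise, seed = as.integer(seed)),
            class = "SimConfig")
}

#' Default spike and decoy panels
#'
#' Three genuine spikes (one per channel class: a mono-hydroxylated
#' C19H26O6-parent, the di-hydroxylated C20H26O7-parent, and a
#' di-hydroxylated C19H24O6-parent) and five decoys covering every
#' rejection criterion.  Heights give apex signal-to-noise well above 10;
#' the light-heavy RT offset (0.006 min) and 1:1 mixing ratio mirror the
#' co-elution behavior of a deuterated tag.
#'
#' @return A `data.frame` suitable for [simConfig()].
#' @export
defaultSpikes <- function() {
  data.frame(name = c("GA2", "GA52", "GA34"),
             rt = c(8.70, 9.55, 10.77),
             height = 20000, width = 0.035,
             rtOffset = 0.006, ratio = 1.0,
             stringsAsFactors = FALSE)
}

#' @rdname defaultSpikes
#' @export
defaultDecoys <- function() {
  data.frame(type = c("ratio", "rt", "ladder", "ratio", "rt"),
             name = c("GA7", "GA7", "GA4", "GA3", "GA1"),
             rt = c(10.30, 12.10, 8.70, 7.80, 12.50),
             height = 20000, width = 0.035,
             rtOffset = c(0.006, 0.050, 0.006, 0.006, -0.050),
             ratio = c(3.0, 1.0, 1.0, 0.3, 1.0),
             stringsAsFactors = FALSE)
}

## theoretical MS2 fragment ladder for a candidate channel member, with
## ground-truth class labels
.candidateLadder <- function(lightMz, lactone, hydroxyls, glucoseLoss = TRUE) {
  frag <- data.frame(mz = lightMz, intensity = 500, class = 0L,
                     name = "precursor")
  add <- function(mz, int, cls, nm)
    frag <<- rbind(frag, data.frame(mz = mz, intensity = int, class = cls,
                                    name = nm))
  if (glucoseLoss) {
    mGlc <- lightMz - .GLC_LOSS
    add(mGlc, 800, 5L, "-glucose")
    anchor <- mGlc - .DMED_LOSS
    add(anchor, 600, 1L, "-glucose-(CH3)2NH")
    node <- anchor
    int <- 400
    for (k in seq_len(hydroxyls)) {
      node <- node - .lossMass("H2O")
      add(node, int, 2L, sprintf("-%dxH2O", k))
      int <- int * 0.8
    }
    if (lactone) {
      node <- node - .lossMass("CH2O2")
      add(node, int, 2L, "-HCOOH")
      int <- int * 0.8
    }
    add(node - .lossMass("C2H4"), int, 3L, "-C2H4")
  } else {
    add(lightMz - .lossMass("H2O"), 400, 2L, "-H2O")
    add(lightMz - .DMED_LOSS, 300, 1L, "-(CH3)2NH")
  }
  add(cationMz("C4H10N"), 300, 1L, "C4H10N+")
  add(cationMz("C7H7"), 250, 4L, "C7H7+")
  add(cationMz("C8H9"), 200, 4L, "C8H9+")
  add(cationMz("C9H11"), 150, 4L, "C9H11+")
  frag
}

#' Simulate a ground-truthed LC-MS/MS run
#'
#' Generates an in-memory [MsRun-class] plus the ground truth needed to
#' verify every downstream stage.  Spiked analytes are drawn from the
#' candidate channel set (by registry GA name); each spike contributes a
#' Gaussian light/heavy chromatographic pair and one DDA MS2 spectrum near
#' its apex containing the candidate's complete neutral-loss ladder.
#' Reproducible: identical config (including seed) gives identical output.
#'
#' @param config a [simConfig()].
#' @param channels a [CandidateChannelSet-class] from [buildChannels()].
#' @return List with elements `run` ([MsRun-class]) and `truth` (list:
#'   `spikes` and `decoys` `data.frame`s with channel m/z, true apex RTs
#'   and ratios; `ms2` a named list of labeled fragment tables).
#' @export
simulateRun <- function(config, channels) {
  stopifnot(inherits(config, "SimConfig"), is(channels, "CandidateChannelSet"))
  set.seed(config$seed)
  allMembers <- do.call(rbind, channels@members)
  lookup <- function(nm) {
    row <- allMembers[allMembers$name == nm, , drop = FALSE]
    if (!nrow(row)) stop("spike/decoy name not in channels: ", nm)
    row[1, ]
  }
  scanDt <- 1 / (config$scanHz * 60)   # minutes between scans
  rts <- seq(config$rtRange[1], config$rtRange[2], by = scanDt)
  nScan <- length(rts)

  ions <- list()   # each: mz, per-scan expected intensity
  addIon <- function(mz, apexRt, sigma, height) {
    mu <- height * exp(-(rts - apexRt)^2 / (2 * sigma^2))
    mu[mu < 1] <- 0
    ions[[length(ions) + 1L]] <<- list(mz = mz, mu = mu)
  }
  analytes <- rbind(
    if (nrow(config$spikes))
      cbind(config$spikes, role = "spike", type = "spike"),
    if (nrow(config$decoys))
      cbind(config$decoys[, c("name", "rt", "height", "width", "rtOffset",
                              "ratio")],
            role = "decoy", type = config$decoys$type))
  if (is.null(analytes))
    analytes <- data.frame(name = character(), rt = numeric(),
                           height = numeric(), width = numeric(),
                           rtOffset = numeric(), ratio = numeric(),
                           role = character(), type = character())
  truthSpikes <- list(); truthDecoys <- list(); ms2Truth <- list()
  ms2 <- list()
  for (i in seq_len(nrow(analytes))) {
    a <- analytes[i, ]
    m <- lookup(a$name)
    addIon(m$lightMz, a$rt, a$width, a$height)
    addIon(m$heavyMz, a$rt - a$rtOffset, a$width, a$height / a$ratio)
    entry <- data.frame(name = a$name, lightMz = m$lightMz,
                        heavyMz = m$heavyMz, rt = a$rt,
                        rtOffset = a$rtOffset, ratio = a$ratio,
                        height = a$height, stringsAsFactors = FALSE)
    wantsMs2 <- a$role == "spike" || a$type == "ladder"
    if (wantsMs2) {
      lad <- .candidateLadder(m$lightMz, m$lactone, m$hydroxyls,
                              glucoseLoss = a$role == "spike")
      ms2[[length(ms2) + 1L]] <- spectrum2(lad$mz, lad$intensity,
                                           precursorMz = m$lightMz,
                                           rt = a$rt + scanDt / 3)
      ms2Truth[[a$name]] <- lad
    }
    if (a$role == "spike") truthSpikes[[length(truthSpikes) + 1L]] <- entry
    else truthDecoys[[length(truthDecoys) + 1L]] <-
           cbind(entry, type = a$type)
  }

  ## assemble MS1 scans
  ionMz <- vapply(ions, `[[`, numeric(1), "mz")
  muMat <- vapply(ions, `[[`, numeric(nScan), "mu")   # nScan x nIon
  if (is.null(dim(muMat))) muMat <- matrix(muMat, nrow = nScan)
  ms1Peaks <- vector("list", nScan)
  for (s in seq_len(nScan)) {
    mu <- muMat[s, ]
    on <- which(mu > 0)
    int <- if (config$poissonNoise) stats::rpois(length(on), mu[on]) else mu[on]
    mzv <- ionMz[on]
    if (config$noisePeaks > 0) {
      nz <- config$noisePeaks
      mzv <- c(mzv, stats::runif(nz, config$scanRange[1], config$scanRange[2]))
      int <- c(int, stats::rexp(nz, 1 / config$noiseMean))
    }
    keep <- int > 0
    mzv <- mzv[keep]; int <- int[keep]
    o <- order(mzv)
    p <- cbind(mz = mzv[o], intensity = as.numeric(int[o]))
    ms1Peaks[[s]] <- p
  }
  run <- new("MsRun", ms1Rt = rts, ms1Peaks = ms1Peaks, ms2 = ms2,
             scanRange = config$scanRange)
  list(run = run,
       truth = list(spikes = do.call(rbind, truthSpikes),
                    decoys = if (length(truthDecoys))
                      do.call(rbind, truthDecoys),
                    ms2 = ms2Truth))
}
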