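## Gibberellin registry and candidate channel construction.

.REGISTRY_COLS <- c("name", "formula", "lactone", "hydroxyls", "carboxyls")

#' Load a gibberellin registry
#'
#' Reads a CSV registry of free gibberellins: one row per GA with its
#' molecular formula and structural annotations used downstream by the
#' fragmentation-consistency and QSRR filters.
#'
#' Required columns: `name` (unique, e.g. `"GA3"`), `formula` (Hill string),
#' `lactone` (0/1: A-ring lactone present), `hydroxyls` (A-ring hydroxyl
#' count), `carboxyls` (free carboxyl count; 0 means the GA cannot react
#' with the amine reagent and is excluded from derivatized channels).
#' Optional column: `predicted_ri` (QSRR-predicted retention index of the
#' DMED-labeled GA; `NA` when no prediction is available).
#'
#' @param path character(1); CSV file path.
#' @return `data.frame` of validated records with a `predicted_ri` column
#'   (all `NA` if absent from the file).
#' @examples
#' reg <- loadRegistry(system.file("extdata", "ga_registry.csv",
#'                                 package = "glcga"))
#' head(reg)
#' @export
loadRegistry <- function(path) {
  reg <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(reg) == 0) {
    warning("empty registry: ", path)
    reg <- data.frame(name = character(), formula = character(),
                      lactone = integer(), hydroxyls = integer(),
                      carboxyls = integer(), predicted_ri = numeric(),
                      stringsAsFactors = FALSE)
    return(reg)
  }
  missing <- setdiff(.REGISTRY_COLS, names(reg))
  if (length(missing))
    stop("registry missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(reg$name))
    stop("duplicate registry name(s): ",
         paste(unique(reg$name[duplicated(reg$name)]), collapse = ", "))
  if (is.null(reg$predicted_ri)) reg$predicted_ri <- NA_real_
  ## validate every formula and annotation
  for (i in seq_len(nrow(reg))) {
    f <- parseFormula(reg$formula[i])
    if (!length(f)) stop("empty formula for ", reg$name[i])
  }
  if (any(reg$hydroxyls < 0)) stop("hydroxyl count must be >= 0")
  if (any(!reg$lactone %in% c(0, 1))) stop("lactone must be 0 or 1")
  reg[.unique_cols(reg)]
}

.unique_cols <- function(reg)
  c(.REGISTRY_COLS, intersect("predicted_ri", names(reg)))

#' Build light/heavy candidate mass channels from a registry
#'
#' Each registry GA with at least one free carboxyl is glucosylated
#' (+C6H10O5), amide-derivatized (+C4H12N2 - H2O), protonated, and given a
#' heavy twin via the isotope tag; candidates whose light m/z agree within
#' `groupTol` merge into one isobaric channel.
#'
#' @param registry `data.frame` from [loadRegistry()].
#' @param tag [IsotopeTagPair-class]; default [dmedTagPair()].
#' @param groupTol numeric(1); m/z grouping tolerance in Th (default 0.001,
#'   i.e. isobaric means identical formula).
#' @return A [CandidateChannelSet-class], channels sorted by light m/z.
#' @examples
#' reg <- loadRegistry(system.file("extdata", "ga_registry.csv",
#'                                 package = "glcga"))
#' ch <- buildChannels(reg)
#' channelTable(ch)
#' @export
buildChannels <- function(registry, tag = dmedTagPair(), groupTol = 0.001) {
  if (nrow(registry) == 0) stop("registry is empty")
  reactive <- registry[registry$carboxyls > 0, , drop = FALSE]
  cand <- do.call(rbind, lapply(seq_len(nrow(reactive)), function(i) {
    parent <- parseFormula(reactive$formula[i])
    native <- glucosylate(parent)
    deriv  <- derivatizeDmed(native)
    light  <- mzProtonated(deriv)
    data.frame(name = reactive$name[i],
               parentFormula = formatFormula(parent),
               nativeFormula = formatFormula(native),
               derivatizedFormula = formatFormula(deriv),
               lightMz = light, heavyMz = heavyMz(light, tag),
               lactone = as.integer(reactive$lactone[i]),
               hydroxyls = as.integer(reactive$hydroxyls[i]),
               stringsAsFactors = FALSE)
  }))
  cand <- cand[order(cand$lightMz, cand$name), , drop = FALSE]
  ## group candidates whose light m/z agree within groupTol
  grp <- cumsum(c(1, diff(cand$lightMz) > groupTol))
  members <- lapply(split(seq_len(nrow(cand)), grp), function(idx) {
    m <- cand[idx, , drop = FALSE]
    m[order(m$name), , drop = FALSE]
  })
  channels <- data.frame(
    lightMz = vapply(members, function(m) mean(m$lightMz), numeric(1)),
    heavyMz = vapply(members, function(m) mean(m$heavyMz), numeric(1)),
    n = vapply(members, nrow, integer(1)))
  rownames(channels) <- NULL
  new("CandidateChannelSet", channels = channels,
      members = unname(members), tag = tag, groupTol = groupTol)
}

#' Accessors for CandidateChannelSet
#'
#' `channelTable()` returns the per-channel summary; `channelMembers()` the
#' member candidates of one channel.
#'
#' @param x a [CandidateChannelSet-class].
#' @param i channel row index.
#' @return A `data.frame`.
#' @export
channelTable <- function(x) {
  stopifnot(is(x, "CandidateChannelSet"))
  x@channels
}

#' @rdname channelTable
#' @export
channelMembers <- function(x, i) {
  stopifnot(is(x, "CandidateChannelSet"))
  x@members[[i]]
}

#' Look up candidates matching an observed m/z
#'
#' Returns all member candidates of channels whose light m/z matches the
#' observation within a ppm tolerance.
#'
#' @param channels a [CandidateChannelSet-class].
#' @param mz numeric(1); observed light-channel m/z (Th).
#' @param tolPpm numeric(1); match tolerance in ppm (default 10).
#' @return `data.frame` of candidates (possibly zero rows).
#' @export
candidatesForMz <- function(channels, mz, tolPpm = 10) {
  stopifnot(is(channels, "CandidateChannelSet"))
  tab <- channels@channels
  hit <- which(abs(ppmError(mz, tab$lightMz)) <= tolPpm)
  if (!length(hit)) return(channels@members[[1]][0, , drop = FALSE])
  do.call(rbind, channels@members[hit])
}

#' Export channels as a TSV table
#'
#' Writes one row per channel: `light_mz`, `heavy_mz`, `members`
#' (comma-separated candidate names).
#'
#' @param channels a [CandidateChannelSet-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
exportChannels <- function(channels, path) {
  stopifnot(is(channels, "CandidateChannelSet"))
  tab <- channels@channels
  out <- data.frame(
    light_mz = sprintf("%.4f", tab$lightMz),
    heavy_mz = sprintf("%.4f", tab$heavyMz),
    members = vapply(channels@members, function(m)
      paste(m$name, collapse = ","), character(1)))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
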