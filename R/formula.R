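## Molecular formulas are plain named integer vectors: element symbol -> count.
## All counts >= 0; the empty formula (integer(0)) has mass 0.

.checkFormula <- function(f) {
  if (!is.numeric(f)) stop("formula must be a named integer vector")
  if (length(f)) {
    if (is.null(names(f)) || any(!nzchar(names(f))))
      stop("formula must be a named integer vector")
    unknown <- setdiff(names(f), names(.ELEMENT_MASSES))
    if (length(unknown))
      stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
    if (any(f < 0)) stop("negative element count")
    if (any(f != round(f))) stop("non-integer element count")
  }
  invisible(f)
}

.canonFormula <- function(f) {
  f <- f[f > 0]
  if (!length(f)) return(stats::setNames(integer(0), character(0)))
  storage.mode(f) <- "integer"
  ## Hill order: C first, then H, then the rest alphabetically (D after H).
  els <- names(f)
  hill <- c(intersect(c("C", "H", "D"), els),
            sort(setdiff(els, c("C", "H", "D"))))
  f[hill]
}

#' Parse and format molecular formula strings
#'
#' `parseFormula()` reads a Hill-style element-count string such as
#' `"C25H32O10"` (counts default to 1, any element order accepted, deuterium
#' written `"D"`); `formatFormula()` writes a formula back in Hill order.
#'
#' @param text character(1); formula string.
#' @return `parseFormula`: a named integer vector of element counts.
#' @examples
#' parseFormula("C6H10O5")
#' formatFormula(parseFormula("H2O"))
#' @export
parseFormula <- function(text) {
  if (!is.character(text) || length(text) != 1 || is.na(text))
    stop("formula text must be a single string")
  text <- gsub("[[:space:]]", "", text)
  if (!nzchar(text)) return(.canonFormula(integer(0)))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text)[[1]]
  parts <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text))
    stop("malformed formula string: '", text, "'")
  els <- sub("^([A-Z][a-z]?).*$", "\\1", parts)
  cnt <- sub("^[A-Z][a-z]?", "", parts)
  cnt <- ifelse(nzchar(cnt), as.integer(cnt), 1L)
  f <- tapply(cnt, els, sum)
  f <- stats::setNames(as.integer(f), names(f))
  .checkFormula(f)
  .canonFormula(f)
}

#' @param f a formula (named integer vector).
#' @return `formatFormula`: character(1), Hill-ordered formula string.
#' @rdname parseFormula
#' @export
formatFormula <- function(f) {
  f <- .canonFormula(.checkFormula(f))
  if (!length(f)) return("")
  paste0(names(f), ifelse(f > 1L, f, ""), collapse = "")
}

#' Monoisotopic mass of a molecular formula
#'
#' Sum of monoisotopic element masses; e.g. the glucose neutral-loss unit
#' C6H10O5 weighs 162.0528 Da and water 18.0106 Da.
#'
#' @param f a formula (named integer vector) or a formula string.
#' @return numeric(1); mass in Da (0 for the empty formula).
#' @examples
#' monoisotopicMass("C6H10O5")  # 162.0528
#' @export
monoisotopicMass <- function(f) {
  if (is.character(f)) f <- parseFormula(f)
  .checkFormula(f)
  if (!length(f)) return(0)
  sum(.ELEMENT_MASSES[names(f)] * f)
}

#' Formula deltas: chemical transformations as added/removed atoms
#'
#' A delta bundles the atoms gained and lost in a reaction step, e.g. amide
#' derivatization with DMED adds C4H12N2 and removes H2O.  `applyDelta()`
#' applies it; the removal must never drive an element count negative.
#'
#' @param add,remove formulas (or formula strings) of the added and removed
#'   atoms.
#' @return `formulaDelta`: a list with components `added` and `removed`.
#' @examples
#' d <- formulaDelta("C4H12N2", "H2O")   # DMED amide derivatization
#' formatFormula(applyDelta(parseFormula("C25H32O11"), d))
#' @export
formulaDelta <- function(add = character(0), remove = character(0)) {
  if (is.character(add) && length(add) <= 1)
    add <- parseFormula(if (length(add)) add else "")
  if (is.character(remove) && length(remove) <= 1)
    remove <- parseFormula(if (length(remove)) remove else "")
  structure(list(added = .canonFormula(.checkFormula(add)),
                 removed = .canonFormula(.checkFormula(remove))),
            class = "FormulaDelta")
}

#' @param f a formula.
#' @param delta a `FormulaDelta` from [formulaDelta()].
#' @return `applyDelta`: the transformed formula.
#' @rdname formulaDelta
#' @export
applyDelta <- function(f, delta) {
  if (is.character(f)) f <- parseFormula(f)
  .checkFormula(f)
  stopifnot(inherits(delta, "FormulaDelta"))
  els <- union(names(f), union(names(delta$added), names(delta$removed)))
  get0 <- function(x) ifelse(els %in% names(x), x[match(els, names(x))], 0L)
  out <- stats::setNames(as.integer(get0(f) + get0(delta$added) - get0(delta$removed)), els)
  if (any(out < 0))
    stop("delta not applicable: removal exceeds available atoms (",
         paste(els[out < 0], collapse = ", "), ")")
  .canonFormula(out)
}

#' Standard transformations of the Glc-GA workflow
#'
#' `glucosylate()` attaches one glucose unit (+C6H10O5, condensation);
#' `derivatizeDmed()` forms the DMED amide on a free carboxyl
#' (+C4H12N2 - H2O).
#'
#' @param f a formula (or formula string) of the neutral molecule.
#' @return The transformed neutral formula.
#' @examples
#' formatFormula(glucosylate("C19H22O6"))        # GA3 -> Glc-GA3, C25H32O11
#' formatFormula(derivatizeDmed("C25H32O11"))    # C29H42O10N2
#' @export
glucosylate <- function(f) applyDelta(f, formulaDelta("C6H10O5", ""))

#' @rdname glucosylate
#' @export
derivatizeDmed <- function(f) applyDelta(f, formulaDelta("C4H12N2", "H2O"))

#' m/z of protonated molecules and even-electron cations
#'
#' `mzProtonated()` returns the `[M+H]+` m/z of a neutral formula (mass plus
#' the proton mass 1.007276 Da, charge 1).  `cationMz()` returns the m/z of
#' an even-electron cation whose formula itself carries the charge (mass
#' minus one electron), e.g. C4H10N+ at 72.0808.
#'
#' @param f a formula (or formula string).
#' @return numeric(1); m/z in Th.
#' @examples
#' mzProtonated("C29H42O10N2")  # 579.2912, derivatized Glc-GA3
#' cationMz("C4H10N")           # 72.0808
#' @export
mzProtonated <- function(f) {
  if (is.character(f)) f <- parseFormula(f)
  if (!length(.canonFormula(.checkFormula(f)))) stop("empty formula")
  monoisotopicMass(f) + .PROTON_MASS
}

#' @rdname mzProtonated
#' @export
cationMz <- function(f) {
  if (is.character(f)) f <- parseFormula(f)
  if (!length(.canonFormula(.checkFormula(f)))) stop("empty formula")
  monoisotopicMass(f) - .ELECTRON_MASS
}

#' Heavy-channel m/z for an isotope tag pair
#'
#' Adds the tag's total label shift to a light-channel m/z; for d4-DMED the
#' shift is `4 x (m(D) - m(H)) = 4.0251` Da.
#'
#' @param lightMz numeric; light-channel m/z (Th).
#' @param tag an [IsotopeTagPair-class]; default [dmedTagPair()].
#' @return numeric; heavy-channel m/z.
#' @examples
#' heavyMz(563.2963)   # 567.3214
#' @export
heavyMz <- function(lightMz, tag = dmedTagPair()) {
  stopifnot(is.numeric(lightMz), all(lightMz >= 0))
  lightMz + tagShift(tag)
}

#' ppm mass error and tolerance helpers
#'
#' @param observed,expected m/z values (Th).
#' @return `ppmError`: signed error in parts per million.
#' @keywords internal
ppmError <- function(observed, expected) (observed - expected) / expected * 1e6
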