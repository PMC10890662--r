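## Monoisotopic element masses (IUPAC/CODATA), Da.  "D" is deuterium (2H),
## kept as a distinct symbol so isotope-tag formulas can be written directly.
.ELEMENT_MASSES <- c(
  H  = 1.007825,
  D  = 2.014102,
  C  = 12.000000,
  N  = 14.003074,
  O  = 15.994915,
  F  = 18.998403,
  Na = 22.989770,
  P  = 30.973762,
  S  = 31.972071,
  Cl = 34.968853,
  K  = 38.963707,
  Br = 78.918338,
  I  = 126.904473
)

.PROTON_MASS   <- 1.007276
.ELECTRON_MASS <- 0.000549

#' Monoisotopic element mass table
#'
#' Constants underlying every m/z printed by the package: monoisotopic masses
#' of the supported elements plus the proton and electron masses used for
#' `[M+H]+` and even-electron cation arithmetic.  Exported so that a user can
#' audit (or dump to CSV) exactly the constants in force.
#'
#' @return A `data.frame` with columns `symbol` (element or particle symbol)
#'   and `mass` (monoisotopic mass in Da).
#' @examples
#' elementMassTable()
#' @export
elementMassTable <- function() {
  data.frame(
    symbol = c(names(.ELEMENT_MASSES), "proton", "electron"),
    mass   = c(unname(.ELEMENT_MASSES), .PROTON_MASS, .ELECTRON_MASS),
    stringsAsFactors = FALSE
  )
}

#' Proton and electron masses
#'
#' @return Mass in Da.
#' @rdname elementMassTable
#' @export
protonMass <- function() .PROTON_MASS

#' @rdname elementMassTable
#' @export
electronMass <- function() .ELECTRON_MASS

#' The DMED / d4-DMED isotope tag pair
#'
#' N,N-dimethylethylenediamine (DMED, C4H12N2) forms an amide with the free
#' carboxyl group of a (conjugated) gibberellin; the heavy reagent carries
#' four deuteriums (C4H8D4N2).  The heavy channel of a labeled analyte sits
#' `4 x (m(D) - m(H)) = +4.0251` Da above the light channel.
#'
#' @return An [IsotopeTagPair-class] object.
#' @examples
#' tag <- dmedTagPair()
#' tagShift(tag)   # 4.0251
#' @export
dmedTagPair <- function() {
  new("IsotopeTagPair",
      lightFormula  = parseFormula("C4H12N2"),
      heavyFormula  = parseFormula("C4H8D4N2"),
      labelCount    = 4L,
      perLabelShift = .ELEMENT_MASSES[["D"]] - .ELEMENT_MASSES[["H"]])
}

#' @param tag An [IsotopeTagPair-class].
#' @return `tagShift`: the total heavy-minus-light mass shift in Da.
#' @rdname dmedTagPair
#' @export
tagShift <- function(tag) {
  stopifnot(is(tag, "IsotopeTagPair"))
  tag@labelCount * tag@perLabelShift
}

## Field-standard neutral-loss / fragment masses, derived once from formulas.
.lossMass <- function(text) monoisotopicMass(parseFormula(text))
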