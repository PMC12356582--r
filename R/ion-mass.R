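# Monoisotopic element masses (Da), most abundant isotope, 6 d.p.
# Transcribed from the CODATA/IUPAC atomic mass evaluation; the electron mass
# is subtracted per positive charge so that cation m/z is exact.
.element_masses <- c(
  H  = 1.007825,
  C  = 12.000000,
  N  = 14.003074,
  O  = 15.994915,
  F  = 18.998403,
  Na = 22.989769,
  Mg = 23.985042,
  Si = 27.976927,
  P  = 30.973762,
  S  = 31.972071,
  Cl = 34.968853,
  K  = 38.963707,
  Br = 78.918338,
  I  = 126.904473
)

.electron_mass <- 0.000549

# Adduct table: mass delta added to the neutral monoisotopic mass and the
# charge state. [M+H-H2O]+ is the in-source water loss common for necine
# esters; [M-H]- is kept for completeness (negative-mode acquisition).
.adducts <- list(
  "[M+H]+"     = list(delta = 1.007825,                charge = +1L),
  "[M+H-H2O]+" = list(delta = 1.007825 - 18.010565,    charge = +1L),
  "[M+Na]+"    = list(delta = 22.989769,               charge = +1L),
  "[M+K]+"     = list(delta = 38.963707,               charge = +1L),
  "[M+NH4]+"   = list(delta = 14.003074 + 4 * 1.007825, charge = +1L),
  "[M-H]-"     = list(delta = -1.007825,               charge = -1L)
)

#' Supported adducts
#'
#' @return Character vector of adduct labels understood by [compute_ion_mz()].
#' @export
supported_adducts <- function() names(.adducts)

#' Parse an elemental formula
#'
#' Parses a Hill-notation molecular formula (e.g. `"C15H25NO5"`) into named
#' element counts. Only single-letter or capital+lowercase element symbols
#' are recognised; counts default to 1.
#'
#' @param formula Character scalar, e.g. `"C8H15NO2"`.
#' @return Named integer vector of element counts.
#' @examples
#' parse_formula("C8H15NO2")
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  tokens <- regmatches(formula, list(m))[[1]]
  if (paste(tokens, collapse = "") != formula) {
    stop("cannot parse formula: '", formula, "'", call. = FALSE)
  }
  syms <- sub("[0-9]*$", "", tokens)
  cnts <- as.integer(ifelse(grepl("[0-9]+$", tokens),
                            sub("^[A-Za-z]+", "", tokens), "1"))
  unknown <- setdiff(syms, names(.element_masses))
  if (length(unknown)) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  counts <- tapply(cnts, factor(syms, levels = unique(syms)), sum)
  storage.mode(counts) <- "integer"
  counts[counts < 0] <- 0L
  c(counts)
}

#' Neutral monoisotopic mass of a formula
#'
#' @param formula Character formula, e.g. `"C15H25NO5"`.
#' @return Monoisotopic mass in Da.
#' @export
monoisotopic_mass <- function(formula) {
  counts <- parse_formula(formula)
  sum(.element_masses[names(counts)] * counts)
}

#' Exact m/z of a charged adduct species
#'
#' Computes the monoisotopic m/z of `[M+X]z` for a neutral formula, adding the
#' adduct mass and subtracting (adding) one electron mass per positive
#' (negative) charge.
#'
#' @param formula Neutral molecular formula.
#' @param adduct One of [supported_adducts()].
#' @return m/z of the charged species (Da per unit charge).
#' @examples
#' compute_ion_mz("C8H15NO2", "[M+H]+")      # protonated platynecine, 158.1176
#' compute_ion_mz("C8H15NO2", "[M+H-H2O]+")  # water loss, 140.1070
#' @export
compute_ion_mz <- function(formula, adduct = "[M+H]+") {
  ad <- .adducts[[adduct]]
  if (is.null(ad)) {
    stop("unsupported adduct '", adduct, "'; supported: ",
         paste(supported_adducts(), collapse = ", "), call. = FALSE)
  }
  m <- monoisotopic_mass(formula) + ad$delta - ad$charge * .electron_mass
  m / abs(ad$charge)
}

#' m/z of a fragment cation given its ion formula
#'
#' For fragment ions specified as the formula of the cation itself (e.g.
#' `"C8H14NO"` for m/z 140.1070), i.e. the electron is subtracted but no
#' proton added.
#'
#' @param ion_formula Formula of the (singly charged) cation.
#' @return m/z in Da.
#' @export
fragment_mz <- function(ion_formula) {
  monoisotopic_mass(ion_formula) - .electron_mass
}

#' Parts-per-million mass difference
#'
#' @param mz_obs,mz_ref Observed and reference m/z.
#' @return Signed ppm error of `mz_obs` relative to `mz_ref`.
#' @export
ppm_error <- function(mz_obs, mz_ref) (mz_obs - mz_ref) / mz_ref * 1e6

#' Match within a ppm tolerance
#'
#' @inheritParams ppm_error
#' @param tol_ppm Tolerance in ppm.
#' @return Logical.
#' @export
ppm_match <- function(mz_obs, mz_ref, tol_ppm = 5) {
  abs(ppm_error(mz_obs, mz_ref)) <= tol_ppm
}
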