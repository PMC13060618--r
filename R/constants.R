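# Element data and physical constants shared across modules.

# Bohr radius in Angstrom (CODATA 2018).
.A0 <- 0.529177210903

#' Mott-Bethe prefactor
#'
#' The constant \eqn{C = m_e e^2 / (8 \pi \epsilon_0 h^2) = 1/(8 \pi^2 a_0)}
#' in Angstrom, used to convert an X-ray (electron-density) form factor into
#' an electron-scattering (electrostatic-potential) form factor via
#' \eqn{f_e(s) = C (Z - f_x(s)) / s^2} with \eqn{s = \sin\theta/\lambda}.
#' Numerically 0.0239337 A to six significant digits.
#'
#' @return The prefactor in Angstrom.
#' @export
mott_bethe_constant <- function() 1 / (8 * pi^2 * .A0)

# Elements supported by the typing and form-factor machinery.  Covalent radii
# are single-bond radii (Cordero et al. 2008); n_core/n_val split off the
# outermost shell group.  Elements with Z > 36 carry no Slater shells and are
# served by the Gaussian tables only.
.ELEMENTS <- data.frame(
  symbol = c("H", "C", "N", "O", "F", "P", "S", "Cl", "Fe", "Br", "I"),
  z      = c(1L, 6L, 7L, 8L, 9L, 15L, 16L, 17L, 26L, 35L, 53L),
  radius = c(0.31, 0.76, 0.71, 0.66, 0.57, 1.07, 1.05, 1.02, 1.32, 1.20, 1.39),
  n_core = c(0L, 2L, 2L, 2L, 2L, 10L, 10L, 10L, 18L, 28L, 46L),
  n_val  = c(1L, 4L, 5L, 6L, 7L, 5L, 6L, 7L, 8L, 7L, 7L),
  stringsAsFactors = FALSE
)

#' Look up element data
#'
#' @param element Element symbol (e.g. "C") or atomic number.
#' @return One-row data frame with symbol, z, covalent radius (Angstrom),
#'   and core/valence electron counts.
#' @export
element_info <- function(element) {
  if (is.numeric(element)) {
    i <- match(as.integer(element), .ELEMENTS$z)
  } else {
    i <- match(toupper_first(element), .ELEMENTS$symbol)
  }
  if (any(is.na(i))) {
    bad <- element[is.na(i)]
    stop("unknown element: ", paste(bad, collapse = ", "))
  }
  .ELEMENTS[i, , drop = FALSE]
}

#' Element symbol from atomic number
#' @param z Atomic number(s).
#' @return Character vector of symbols.
#' @export
element_symbol <- function(z) element_info(z)$symbol

#' Atomic number from element symbol
#' @param symbol Element symbol(s).
#' @return Integer atomic numbers.
#' @export
element_z <- function(symbol) element_info(symbol)$z

#' Default covalent radii table
#'
#' Single-bond covalent radii in Angstrom used by [build_bond_graph()].
#' @return Named numeric vector (names are element symbols).
#' @export
covalent_radii <- function() {
  stats::setNames(.ELEMENTS$radius, .ELEMENTS$symbol)
}

toupper_first <- function(x) {
  x <- trimws(x)
  paste0(toupper(substr(x, 1, 1)), tolower(substr(x, 2, nchar(x))))
}
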