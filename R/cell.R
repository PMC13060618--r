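# Unit-cell metric utilities.  Fractional coordinates are the internal
# convention; Cartesian conversion uses the standard orthogonalization with
# the a axis along x.

#' Construct a unit cell
#'
#' @param a,b,c Cell edges in Angstrom.
#' @param alpha,beta,gamma Cell angles in degrees.
#' @return An object of class `unit_cell`.
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  stopifnot(a > 0, b > 0, c > 0)
  ang <- c(alpha, beta, gamma)
  if (any(ang <= 0) || any(ang >= 180)) stop("cell angles must lie in (0, 180) degrees")
  structure(list(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma),
            class = "unit_cell")
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("unit cell  a=%.4f b=%.4f c=%.4f  alpha=%.3f beta=%.3f gamma=%.3f\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma))
  invisible(x)
}

#' Fractional-to-Cartesian orthogonalization matrix
#'
#' Columns are the cell vectors in a Cartesian frame with a along x and b in
#' the xy plane; `r_cart = M %*% x_frac`.
#'
#' @param cell A `unit_cell`.
#' @return 3x3 numeric matrix (Angstrom).
#' @export
frac_to_cart_matrix <- function(cell) {
  ca <- cos(cell$alpha * pi / 180); cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180); sg <- sin(cell$gamma * pi / 180)
  v <- sqrt(max(0, 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg))
  matrix(c(cell$a, cell$b * cg, cell$c * cb,
           0,      cell$b * sg, cell$c * (ca - cb * cg) / sg,
           0,      0,           cell$c * v / sg),
         nrow = 3, byrow = TRUE)
}

#' Cell volume
#' @param cell A `unit_cell`.
#' @return Volume in cubic Angstrom.
#' @export
cell_volume <- function(cell) {
  det(frac_to_cart_matrix(cell))
}

#' Reciprocal-space matrix
#'
#' Returns B such that the Cartesian reciprocal vector of Miller index h is
#' `g = B %*% h` (in inverse Angstrom, no 2-pi factor).
#'
#' @param cell A `unit_cell`.
#' @return 3x3 numeric matrix.
#' @export
recip_matrix <- function(cell) {
  t(solve(frac_to_cart_matrix(cell)))
}

#' Scattering-vector data for Miller indices
#'
#' @param hkl Integer matrix with rows (h, k, l).
#' @param cell A `unit_cell`.
#' @return List with `g` (n x 3 Cartesian reciprocal vectors, 1/Angstrom),
#'   `s` (sin(theta)/lambda = |g|/2) and `d` (resolution, Angstrom; Inf for
#'   the origin).
#' @export
scattering_vectors <- function(hkl, cell) {
  hkl <- matrix(as.numeric(hkl), ncol = 3)
  g <- hkl %*% t(recip_matrix(cell))
  glen <- sqrt(rowSums(g^2))
  list(g = g, s = glen / 2, d = ifelse(glen > 0, 1 / glen, Inf))
}
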