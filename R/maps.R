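# Fourier synthesis of real-space maps from structure factors, rmsd-based
# contour helpers, and TAAM-minus-IAM deformation maps.

#' Map synthesis specification
#'
#' @param d_min Resolution limit in Angstrom.
#' @param oversampling Grid oversampling factor (>= 2; default 3, i.e. grid
#'   spacing at most d_min/3).
#' @return A `map_spec`.
#' @export
map_spec <- function(d_min, oversampling = 3) {
  if (oversampling < 2) stop("oversampling must be >= 2")
  structure(list(d_min = d_min, oversampling = oversampling), class = "map_spec")
}

# smallest 2,3,5-smooth integer >= n (FFT-friendly grid dimension)
.smooth235 <- function(n) {
  n <- max(2L, as.integer(ceiling(n)))
  repeat {
    m <- n
    for (p in c(2, 3, 5)) while (m %% p == 0) m <- m / p
    if (m == 1) return(n)
    n <- n + 1L
  }
}

.map_grid_dims <- function(cell, spec) {
  spacing <- spec$d_min / spec$oversampling
  vapply(c(cell$a, cell$b, cell$c), function(len) .smooth235(len / spacing), 0L)
}

#' Fourier synthesis of a real-space map
#'
#' \eqn{\rho(x) = (1/V) \sum_h F(h) \exp(-2\pi i h\cdot x)} on an
#' FFT-friendly grid; Friedel mates are reconstituted from the unique
#' reflection set, so the synthesis is real (the imaginary residue is
#' checked against 1e-10 of the map scale and discarded).  When F(000) is
#' absent the map has zero mean and is flagged in the metadata.
#'
#' @param sf A `structure_factor_set` (unique reflections, one per Friedel
#'   pair).
#' @param spec A [map_spec()].
#' @param cell Unit cell override (defaults to the miller set's cell).
#' @return A `real_space_map`; quantity is electron-density (e/A^3) for
#'   X-rays and electrostatic-potential (1/A^2) for electrons.
#' @export
fourier_map <- function(sf, spec, cell = sf$miller$cell) {
  dims <- .map_grid_dims(cell, spec)
  V <- cell_volume(cell)
  G <- array(0i, dims)
  hkl <- sf$miller$hkl
  f000 <- NA
  idx0 <- function(h, n) (h %% n) + 1L
  for (r in seq_len(nrow(hkl))) {
    h <- hkl[r, ]
    if (all(h == 0)) {
      f000 <- Re(sf$f[r])
      G[1, 1, 1] <- G[1, 1, 1] + sf$f[r]
      next
    }
    G[idx0(h[1], dims[1]), idx0(h[2], dims[2]), idx0(h[3], dims[3])] <-
      G[idx0(h[1], dims[1]), idx0(h[2], dims[2]), idx0(h[3], dims[3])] + sf$f[r]
    G[idx0(-h[1], dims[1]), idx0(-h[2], dims[2]), idx0(-h[3], dims[3])] <-
      G[idx0(-h[1], dims[1]), idx0(-h[2], dims[2]), idx0(-h[3], dims[3])] + Conj(sf$f[r])
  }
  rho <- fft(G) / V        # forward FFT: sum_h G[h] exp(-2 pi i h.x)
  scale <- max(Mod(rho), 1e-300)
  if (max(abs(Im(rho))) > 1e-10 * scale)
    warning("imaginary residue above 1e-10 of map scale; check Friedel completeness")
  quantity <- if (sf$radiation == "electron") "electrostatic-potential" else "electron-density"
  real_space_map(Re(rho), cell, quantity = quantity, f000 = f000)
}

#' rmsd-based contour levels for a map pair
#'
#' Levels are k times the root-mean-square deviation of each map about its
#' mean, on the absolute scale of the map's units, plus their midpoint --
#' the display convention for comparing a spherical-model and an
#' aspherical-model map at matched contours.
#'
#' @param map_a,map_b `real_space_map` objects (or plain numeric arrays).
#' @param k Multiplier (default 1.5).
#' @return List with `level_a`, `level_b`, `midpoint`.
#' @export
rmsd_contour_levels <- function(map_a, map_b, k = 1.5) {
  vals <- function(m) if (inherits(m, "real_space_map")) as.numeric(m$values) else as.numeric(m)
  rmsd <- function(v) sqrt(mean((v - mean(v))^2))
  la <- k * rmsd(vals(map_a))
  lb <- k * rmsd(vals(map_b))
  list(level_a = la, level_b = lb, midpoint = (la + lb) / 2)
}

#' TAAM-minus-IAM deformation map
#'
#' Synthesizes \eqn{\Delta F(h) = F_{taam}(h) - \kappa_{scale} F_{iam}(h)}
#' into a real-space map.  With `scaling = FALSE`, \eqn{\kappa_{scale} = 1};
#' otherwise it is the least-squares scalar minimizing
#' \eqn{\sum_h |F_{taam} - \kappa F_{iam}|^2}.  The IAM leg uses the
#' 6 1/Angstrom-valid Gaussian dialect for the radiation by default.
#' F(000) is excluded by default (the electron origin term diverges for
#' ions); the map is then a zero-mean difference map.
#'
#' @inheritParams direct_summation_sf
#' @param d_min Resolution limit in Angstrom.
#' @param scaling Apply least-squares scaling between the legs?
#' @param oversampling Grid oversampling (see [map_spec()]).
#' @param iam_dialect Gaussian dialect for the IAM leg.
#' @return A `real_space_map` with attributes `kappa_scale`, `sf_taam`,
#'   `sf_iam` attached.
#' @export
deformation_map <- function(structure, assignment, bank, d_min,
                            radiation = c("xray", "electron"),
                            scaling = FALSE, oversampling = 3,
                            iam_dialect = NULL) {
  radiation <- match.arg(radiation)
  if (assignment$coverage < 1)
    warning(sprintf("multipolar coverage is %.1f%%; deformation map mixes representation levels",
                    100 * assignment$coverage))
  miller <- generate_reflections(structure, d_min)
  f_taam <- direct_summation_sf(structure, assignment, miller, bank,
                                radiation = radiation, mode = "taam")
  f_iam <- direct_summation_sf(structure, assignment, miller, bank,
                               radiation = radiation, mode = "iam",
                               dialect = iam_dialect %||% .default_dialect(radiation))
  kappa_scale <- 1
  if (scaling) {
    denom <- sum(Mod(f_iam$f)^2)
    if (denom > 0) kappa_scale <- sum(Re(Conj(f_iam$f) * f_taam$f)) / denom
  }
  dsf <- structure_factor_set(miller, f_taam$f - kappa_scale * f_iam$f,
                              radiation = radiation, mode = "taam")
  map <- fourier_map(dsf, map_spec(d_min, oversampling))
  attr(map, "kappa_scale") <- kappa_scale
  attr(map, "sf_taam") <- f_taam
  attr(map, "sf_iam") <- f_iam
  map
}
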