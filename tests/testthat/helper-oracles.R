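# Shared fixtures and independent oracles for the test suite.

# One fixture bank per session (the Gaussian fits are deterministic but cost
# a couple of seconds).
fixture_bank <- local({
  bank <- NULL
  function() {
    if (is.null(bank)) bank <<- make_fixture_bank(0)
    bank
  }
})

# Spherical Bessel functions j_0..j_4 in closed form.
sph_bessel <- function(l, x) {
  ifelse(x == 0, as.numeric(l == 0), switch(l + 1,
    sin(x) / x,
    sin(x) / x^2 - cos(x) / x,
    (3 / x^3 - 1 / x) * sin(x) - 3 * cos(x) / x^2,
    (15 / x^4 - 6 / x^2) * sin(x) - (15 / x^3 - 1 / x) * cos(x),
    (105 / x^5 - 45 / x^3 + 1 / x) * sin(x) - (105 / x^4 - 10 / x^2) * cos(x)))
}

# Adaptive-quadrature oracle for the Slater Fourier-Bessel transform:
# piecewise integration between oscillation nodes up to a far cutoff.
quad_fourier_bessel <- function(n, zeta, l, H) {
  R <- function(r) zeta^(n + 3) / factorial(n + 2) * r^n * exp(-zeta * r)
  f <- function(r) r^2 * R(r) * sph_bessel(l, H * r)
  rmax <- (n + 90) / zeta
  if (H < 1e-8) return(stats::integrate(f, 0, rmax, rel.tol = 1e-13)$value)
  brk <- seq(0, rmax, by = pi / max(H, 1))
  if (brk[length(brk)] < rmax) brk <- c(brk, rmax)
  sum(vapply(seq_len(length(brk) - 1), function(i)
    stats::integrate(f, brk[i], brk[i + 1], rel.tol = 1e-13,
                     subdivisions = 200L)$value, 0))
}

# Brute-force 3D numerical Fourier transform of the real-space model density
# of one bank entry (radial Gauss-Legendre x angular product grid).
ft3d_oracle <- function(entry, frame, g, nr = 90, nt = 80, np = 160, rmax = 12) {
  glr <- taamsf:::.gauss_legendre(nr, 0, rmax)
  glt <- taamsf:::.gauss_legendre(nt, -1, 1)
  phi <- (seq_len(np) - 1) * 2 * pi / np
  st <- sqrt(pmax(0, 1 - glt$x^2))
  ux <- as.numeric(outer(st, cos(phi)))
  uy <- as.numeric(outer(st, sin(phi)))
  uz <- as.numeric(matrix(glt$x, nt, np))
  wang <- as.numeric(matrix(glt$w, nt, np)) * (2 * pi / np)
  tot <- 0 + 0i
  for (ir in seq_len(nr)) {
    r <- glr$x[ir]
    xyz <- cbind(r * ux, r * uy, r * uz)
    rho <- multipolar_density(entry, frame, xyz)
    tot <- tot + glr$w[ir] * r^2 * sum(wang * rho * exp(2i * pi * (xyz %*% g)))
  }
  tot
}

# Independent FFT-based sampled-Gaussian structure-factor oracle for IAM on
# a P1 structure (periodic real-space sampling of the Gaussian densities,
# then a forward FFT).
fft_sf_oracle <- function(structure, bank, dialect = "five-gauss", n = 64) {
  cell <- structure$cell
  stopifnot(abs(cell$alpha - 90) < 1e-9, length(structure$ops) == 1)
  tab <- bank$gauss[[dialect]]
  V <- cell_volume(cell)
  axx <- (0:(n - 1)) / n * cell$a
  axy <- (0:(n - 1)) / n * cell$b
  axz <- (0:(n - 1)) / n * cell$c
  xyz_at <- site_cart(structure)
  rho <- array(0, c(n, n, n))
  for (j in seq_len(n_sites(structure))) {
    co <- tab$coef[[structure$sites$element[j]]]
    B <- structure$sites$biso[j]
    dx <- abs(axx - xyz_at[j, 1]); dx <- pmin(dx, cell$a - dx)
    dy <- abs(axy - xyz_at[j, 2]); dy <- pmin(dy, cell$b - dy)
    dz <- abs(axz - xyz_at[j, 3]); dz <- pmin(dz, cell$c - dz)
    r2 <- outer(outer(dx^2, dy^2, "+"), dz^2, "+")
    dens <- array(0, c(n, n, n))
    for (i in seq_along(co$a)) {
      bb <- co$b[i] + B
      dens <- dens + co$a[i] * (4 * pi / bb)^1.5 * exp(-4 * pi^2 * r2 / bb)
    }
    rho <- rho + structure$sites$occ[j] * dens
  }
  Fg <- Conj(fft(rho)) * (V / n^3)
  function(hkl) {
    idx <- function(h, nn) (h %% nn) + 1L
    vapply(seq_len(nrow(hkl)), function(r)
      Fg[idx(hkl[r, 1], n), idx(hkl[r, 2], n), idx(hkl[r, 3], n)], 0i)
  }
}

# Exhaustive simple-cycle enumeration (independent of the production MCB
# code path beyond the shared adjacency): all chordless membership checks in
# tests use this.
enumerate_cycles <- function(graph, maxlen = 12) {
  taamsf:::.simple_cycles(graph$adj, graph$n, maxlen)
}

# 5-atom triclinic TAAM fixture (water fragment + extra C, N; one
# anisotropic atom, one partial occupancy).
triclinic_fixture <- function() {
  cell <- unit_cell(7, 8, 9, 80, 95, 105)
  sites <- data.frame(label = c("O1", "H2", "H3", "C4", "N5"),
                      element = c("O", "H", "H", "C", "N"),
                      fx = c(0.30, 0.36, 0.24, 0.70, 0.55),
                      fy = c(0.40, 0.47, 0.46, 0.60, 0.25),
                      fz = c(0.50, 0.55, 0.44, 0.30, 0.75),
                      occ = c(1, 1, 1, 0.8, 1), biso = c(5, 4, 4, 0, 6))
  U <- matrix(c(0.02, 0.004, -0.002, 0.004, 0.03, 0.001, -0.002, 0.001, 0.025), 3, 3)
  crystal_structure(cell, sites, spacegroup = "P1",
                    u_aniso = list(NULL, NULL, NULL, U, NULL))
}

random_rotation <- function(seed) {
  set.seed(seed)
  Q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
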