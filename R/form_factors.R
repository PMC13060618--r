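# Atomic form factors: Gaussian IAM, spherical Slater (core + kappa-scaled
# valence), Hansen-Coppens multipolar deformation terms, and Mott-Bethe
# conversion to electron scattering.
#
# Conventions.  s = sin(theta)/lambda in 1/Angstrom; Gaussian b coefficients
# act on s^2.  Radial functions R(r) = (zeta^(n+3)/(n+2)!) r^n exp(-zeta r)
# are density-normalized, i.e. integral of r^2 R dr = 1, so <j_0>(0) = 1.
# Real spherical harmonics d_lm are density-normalized (the integral of
# |d_lm| over the sphere is 2 for l >= 1, and d_00 = 1/(4 pi)); their
# normalization constants are computed numerically once and cached.

# ---------------------------------------------------------------------------
# Slater-type Fourier-Bessel transforms

# I(m, l; zeta, H) = integral r^m exp(-zeta r) j_l(H r) dr, H vectorized.
.slater_I <- function(m, l, zeta, H) {
  out <- numeric(length(H))
  small <- H <= 0.1 * zeta
  if (any(small)) out[small] <- .slater_I_series(m, l, zeta, H[small])
  if (any(!small)) out[!small] <- .slater_I_closed(m, l, zeta, H[!small])
  out
}

# Power-series branch for small H (j_l(x) = x^l sum_k (-x^2/2)^k / (k! (2l+2k+1)!!)),
# integrated termwise; avoids the cancellation of the closed forms near H = 0.
.slater_I_series <- function(m, l, zeta, H) {
  out <- numeric(length(H))
  dfact <- function(k) if (k <= 0) 1 else prod(seq(k, 1, by = -2))
  for (i in seq_along(H)) {
    h <- H[i]
    if (h == 0) { out[i] <- if (l == 0) factorial(m) / zeta^(m + 1) else 0; next }
    tot <- 0
    for (k in 0:60) {
      term <- (-1)^k * h^(2 * k + l) / (2^k * factorial(k) * dfact(2 * l + 2 * k + 1)) *
        factorial(m + l + 2 * k) / zeta^(m + l + 2 * k + 1)
      tot <- tot + term
      if (abs(term) < 1e-17 * abs(tot) && k > 2) break
    }
    out[i] <- tot
  }
  out
}

# Closed forms from the complex moment integral
# integral r^p exp(-(zeta - iH) r) dr = p! / (zeta - iH)^(p+1),
# with the spherical-Bessel upward recursion in l.
.slater_I_closed <- function(m, l, zeta, H) {
  w <- complex(real = zeta, imaginary = -H)
  if (l == 0) {
    return(Im(factorial(m - 1) / w^m) / H)
  }
  if (l == 1) {
    return(Im(factorial(m - 2) / w^(m - 1)) / H^2 -
             Re(factorial(m - 1) / w^m) / H)
  }
  (2 * l - 1) / H * .slater_I_closed(m - 1, l - 1, zeta, H) -
    .slater_I_closed(m, l - 2, zeta, H)
}

#' Fourier-Bessel transform of a density-normalized Slater function
#'
#' Computes \eqn{\langle j_l \rangle(H) = \int_0^\infty r^2 R(r) j_l(H r) dr}
#' for the density-normalized radial function
#' \eqn{R(r) = (\zeta^{n+3}/(n+2)!)\, r^n e^{-\zeta r}} (so that
#' \eqn{\int r^2 R\,dr = 1} and \eqn{\langle j_0\rangle(0) = 1}), using
#' closed-form recursions; no numerical quadrature is involved.
#'
#' @param n Non-negative integer power of r; must satisfy `n >= l`.
#' @param zeta Positive exponent (1/Angstrom).
#' @param l Spherical-Bessel order, 0..4.
#' @param H Scattering-vector magnitude \eqn{4\pi s} (1/Angstrom); vectorized.
#' @return Numeric vector of transform values.
#' @export
slater_fourier_bessel <- function(n, zeta, l, H) {
  if (zeta <= 0) stop("zeta must be positive")
  if (l < 0 || l > 4) stop("l must be in 0..4")
  if (n < l) stop("n < l is unphysical for an order-l radial function")
  if (any(H < 0)) stop("H must be non-negative")
  zeta^(n + 3) / factorial(n + 2) * .slater_I(n + 2, l, zeta, H)
}

# ---------------------------------------------------------------------------
# Real spherical harmonics (density-normalized)

# Associated Legendre P_l^m(x) without Condon-Shortley phase, l <= 4.
.assoc_legendre <- function(l, m, x) {
  pmm <- rep(1, length(x))
  if (m > 0) {
    somx2 <- sqrt(pmax(0, 1 - x^2))
    pmm <- prod(seq(2 * m - 1, 1, by = -2)) * somx2^m
  }
  if (l == m) return(pmm)
  pmmp1 <- x * (2 * m + 1) * pmm
  if (l == m + 1) return(pmmp1)
  for (ll in (m + 2):l) {
    p <- ((2 * ll - 1) * x * pmmp1 - (ll + m - 1) * pmm) / (ll - m)
    pmm <- pmmp1; pmmp1 <- p
  }
  pmmp1
}

# Orthonormal real spherical harmonic y_lm at unit vectors u (n x 3).
.ylm <- function(l, m, u) {
  ct <- pmin(1, pmax(-1, u[, 3]))
  phi <- atan2(u[, 2], u[, 1])
  am <- abs(m)
  nlm <- sqrt((2 * l + 1) / (4 * pi) * factorial(l - am) / factorial(l + am))
  p <- .assoc_legendre(l, am, ct)
  if (m == 0) return(nlm * p)
  if (m > 0) sqrt(2) * nlm * p * cos(am * phi) else sqrt(2) * nlm * p * sin(am * phi)
}

.harm_cache <- new.env(parent = emptyenv())

# Density-normalization factors f_lm: d_lm = f_lm * y_lm with
# integral |d_lm| dOmega = 2 (l >= 1) and d_00 = 1/(4 pi).
.density_norm_factor <- function(l, m) {
  key <- paste0("f", l, "_", m)
  if (!is.null(.harm_cache[[key]])) return(.harm_cache[[key]])
  if (l == 0) {
    val <- 1 / (4 * pi) / .ylm(0, 0, matrix(c(0, 0, 1), 1))[1]
  } else {
    # |y_lm| integrates separably: theta and phi factors done by 1D adaptive
    # quadrature (the integrand has kinks at the zeros, so the polar factor
    # is integrated in pieces between sign changes)
    am <- abs(m)
    nlm <- sqrt((2 * l + 1) / (4 * pi) * factorial(l - am) / factorial(l + am))
    ftheta <- function(x) abs(.assoc_legendre(l, am, x))
    brk <- seq(-1, 1, length.out = 201)
    itheta <- sum(vapply(seq_len(length(brk) - 1), function(i)
      stats::integrate(ftheta, brk[i], brk[i + 1], rel.tol = 1e-12,
                       subdivisions = 50L)$value, 0))
    iphi <- if (m == 0) 2 * pi else sqrt(2) * 4  # integral |cos/sin(m phi)| over 2 pi
    val <- 2 / (nlm * itheta * iphi)
  }
  .harm_cache[[key]] <- val
  val
}

# Gauss-Legendre nodes/weights on [a, b] via the Golub-Welsch eigenproblem.
.gauss_legendre <- function(n, a = -1, b = 1) {
  i <- seq_len(n - 1)
  beta <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- beta; J[cbind(i + 1, i)] <- beta
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  ord <- order(x)
  list(x = (b - a) / 2 * x[ord] + (a + b) / 2, w = (b - a) / 2 * w[ord])
}

#' Density-normalized real spherical harmonic
#'
#' @param l Degree 0..4.
#' @param m Order, -l..l.
#' @param u Numeric n x 3 matrix of unit vectors (or length-3 vector).
#' @return Numeric vector of values.
#' @export
sph_harm_d <- function(l, m, u) {
  if (is.null(dim(u))) u <- matrix(u, 1)
  if (abs(m) > l || l < 0 || l > 4) stop("invalid (l, m)")
  .density_norm_factor(l, m) * .ylm(l, m, u)
}

# (l, m) -> slot in the 25-long p_lm vector
plm_index <- function(l, m) l^2 + l + m + 1

# ---------------------------------------------------------------------------
# Gaussian IAM

#' Gaussian IAM form factor
#'
#' Evaluates \eqn{f(s) = \sum_i a_i \exp(-b_i s^2) + c} for one element of a
#' Gaussian table.  A warning is recorded when `s` exceeds the dialect's
#' stated fit validity; the value is still returned.
#'
#' @param element Element symbol or atomic number.
#' @param s sin(theta)/lambda values (1/Angstrom).
#' @param table A `gaussian_table` (see [load_bank()] / [gaussian_table_set()]).
#' @return Numeric vector; electrons for X-ray dialects, Angstrom for
#'   electron dialects.
#' @export
gaussian_ff <- function(element, s, table) {
  sym <- element_info(element)$symbol
  row <- table$coef[[sym]]
  if (is.null(row)) stop("element ", sym, " not present in Gaussian table dialect ", table$dialect)
  if (any(s > table$validity_smax)) {
    warning(sprintf("s exceeds the %s dialect fit validity (%.3g 1/A)",
                    table$dialect, table$validity_smax))
  }
  out <- rep(row$c, length(s))
  for (i in seq_along(row$a)) out <- out + row$a[i] * exp(-row$b[i] * s^2)
  out
}

# ---------------------------------------------------------------------------
# Spherical Slater (core + kappa-scaled valence)

# f for a shell group (data.frame coef, n, zeta), exponents optionally scaled.
.shell_ff <- function(shells, s, scale = 1) {
  H <- 4 * pi * s
  out <- numeric(length(s))
  for (i in seq_len(nrow(shells))) {
    out <- out + shells$coef[i] *
      slater_fourier_bessel(shells$n[i], scale * shells$zeta[i], 0, H)
  }
  out
}

#' Spherical Hansen-Coppens form factor (core + spherical valence)
#'
#' \eqn{f(s) = f_{core}(s) + P_{val} f_{val}(s;\kappa)} where the valence
#' transform is evaluated with exponents scaled \eqn{\zeta \to \kappa\zeta}
#' (each shell re-normalized to one electron), so that
#' \eqn{f(0) = p_{core} + P_{val}} exactly.
#'
#' @param shells A `slater_shell_set` (fields `core`, `valence`, each a data
#'   frame with coef, n, zeta; `element`).
#' @param p_val Valence population (electrons).
#' @param kappa Contraction-expansion scalar (> 0).
#' @param s sin(theta)/lambda values (1/Angstrom).
#' @return Numeric vector (electrons).
#' @export
spherical_slater_ff <- function(shells, p_val, kappa, s) {
  if (kappa <= 0) stop("kappa must be positive")
  n_val_ref <- sum(shells$valence$coef)
  f_core <- .shell_ff(shells$core, s)
  f_val1 <- if (n_val_ref > 0) .shell_ff(shells$valence, s, scale = kappa) / n_val_ref
            else numeric(length(s))
  f_core + p_val * f_val1
}

# ---------------------------------------------------------------------------
# Full multipolar form factor

#' Hansen-Coppens multipolar form factor
#'
#' \eqn{f(\mathbf{g}) = f_{core}(s) + P_{val} f_{val}(s;\kappa) +
#' \sum_{l=1}^{4} 4\pi i^l \langle j_l\rangle(H;\kappa'\zeta, n_l)
#' \sum_m P_{lm} d_{lm}(\mathbf{u})} with \eqn{\mathbf{u}} the unit scattering
#' direction expressed in the atom's local frame and \eqn{H = 4\pi s}.
#' Deformation terms vanish at the origin (\eqn{s = 0}) by convention.
#'
#' @param entry A `multipolar_entry` from a bank.
#' @param frame A `local_frame` (3x3 rotation, local -> crystal Cartesian), or
#'   NULL only if all deformation populations are zero.
#' @param g_cart n x 3 matrix of Cartesian scattering vectors (1/Angstrom).
#' @param shells The `slater_shell_set` providing the core/valence model for
#'   the entry's element (defaults to the entry's `core_valence_model`).
#' @return Complex vector of form-factor values (electrons).
#' @export
multipolar_ff <- function(entry, frame, g_cart, shells = entry$core_valence_model) {
  if (is.null(dim(g_cart))) g_cart <- matrix(g_cart, 1)
  glen <- sqrt(rowSums(g_cart^2))
  s <- glen / 2
  H <- 4 * pi * s
  f <- as.complex(spherical_slater_ff(shells, entry$p_val, entry$kappa, s))
  has_def <- any(entry$p_lm[plm_index(1, -1):plm_index(4, 4)] != 0)
  if (!has_def) return(f)
  if (is.null(frame)) stop("a local frame is required when deformation populations are non-zero")
  R <- if (is.matrix(frame)) frame else frame$rotation
  pos <- glen > 0
  if (!any(pos)) return(f)
  u_cart <- g_cart[pos, , drop = FALSE] / glen[pos]
  u_loc <- u_cart %*% R          # rows become t(R) %*% u
  for (l in 1:4) {
    pl <- entry$p_lm[plm_index(l, -l):plm_index(l, l)]
    if (all(pl == 0)) next
    radial <- slater_fourier_bessel(entry$radial$n_l[l + 1],
                                    entry$kappa_prime * entry$radial$zeta,
                                    l, H[pos])
    ang <- numeric(sum(pos))
    for (m in -l:l) {
      p <- pl[m + l + 1]
      if (p != 0) ang <- ang + p * sph_harm_d(l, m, u_loc)
    }
    f[pos] <- f[pos] + 4 * pi * (1i)^l * radial * ang
  }
  f
}

#' Real-space multipolar model density
#'
#' Evaluates the Hansen-Coppens density of one bank entry at Cartesian
#' positions relative to the atom: core + kappa-contracted spherical valence
#' + deformation terms \eqn{P_{lm} R_l(r) d_{lm}}.  Useful for map checks and
#' as the real-space side of Fourier consistency tests.
#'
#' @inheritParams multipolar_ff
#' @param xyz n x 3 Cartesian offsets from the atom (Angstrom).
#' @return Numeric density values (electrons / cubic Angstrom).
#' @export
multipolar_density <- function(entry, frame, xyz, shells = entry$core_valence_model) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, 1)
  r <- sqrt(rowSums(xyz^2))
  dens_norm <- function(n, zeta) zeta^(n + 3) / factorial(n + 2)
  rho <- numeric(length(r))
  for (i in seq_len(nrow(shells$core))) {
    sh <- shells$core[i, ]
    rho <- rho + sh$coef * dens_norm(sh$n, sh$zeta) * r^sh$n * exp(-sh$zeta * r) / (4 * pi)
  }
  n_val_ref <- sum(shells$valence$coef)
  k <- entry$kappa
  for (i in seq_len(nrow(shells$valence))) {
    sh <- shells$valence[i, ]
    rho <- rho + entry$p_val * (sh$coef / n_val_ref) *
      dens_norm(sh$n, k * sh$zeta) * r^sh$n * exp(-k * sh$zeta * r) / (4 * pi)
  }
  has_def <- any(entry$p_lm[plm_index(1, -1):plm_index(4, 4)] != 0)
  if (!has_def) return(rho)
  R <- if (is.matrix(frame)) frame else frame$rotation
  pos <- r > 0
  u_loc <- (xyz[pos, , drop = FALSE] / r[pos]) %*% R
  for (l in 1:4) {
    pl <- entry$p_lm[plm_index(l, -l):plm_index(l, l)]
    if (all(pl == 0)) next
    zl <- entry$kappa_prime * entry$radial$zeta
    nl <- entry$radial$n_l[l + 1]
    radial <- dens_norm(nl, zl) * r[pos]^nl * exp(-zl * r[pos])
    for (m in -l:l) {
      p <- pl[m + l + 1]
      if (p != 0) rho[pos] <- rho[pos] + p * radial * sph_harm_d(l, m, u_loc)
    }
  }
  rho
}

# ---------------------------------------------------------------------------
# Mott-Bethe conversion

#' Mott-Bethe conversion of an X-ray form factor
#'
#' \eqn{f_e(s) = C (Z - f_x(s)) / s^2} with \eqn{C = 1/(8\pi^2 a_0)} Angstrom
#' (see [mott_bethe_constant()]).  At `s = 0` the formula diverges unless an
#' analytic limit is supplied; for a neutral Gaussian parameterization the
#' limit is \eqn{C \sum_i a_i b_i} (see [mott_bethe_gaussian_origin()]).
#'
#' @param f_x X-ray form factor value(s), real or complex (electrons).
#' @param z Atomic number.
#' @param s sin(theta)/lambda values (1/Angstrom), positive.
#' @return Electron form factor value(s) in Angstrom.
#' @export
mott_bethe <- function(f_x, z, s) {
  if (any(s <= 0)) stop("mott_bethe requires s > 0; use an analytic origin limit for s = 0")
  mott_bethe_constant() * (z - f_x) / s^2
}

#' Analytic s = 0 limit of the Mott-Bethe conversion for a Gaussian atom
#'
#' For a neutral Gaussian parameterization (\eqn{\sum a_i + c = Z}) the
#' limit of \eqn{C (Z - f_x)/s^2} as \eqn{s \to 0} is \eqn{C \sum_i a_i b_i}.
#' A net-charged parameterization makes F(000) divergent and raises an error.
#'
#' @param element Element symbol or atomic number.
#' @param table A `gaussian_table`.
#' @param tol Neutrality tolerance on \eqn{\sum a_i + c - Z} (electrons).
#' @return The origin limit in Angstrom.
#' @export
mott_bethe_gaussian_origin <- function(element, table, tol = 1e-3) {
  info <- element_info(element)
  row <- table$coef[[info$symbol]]
  if (is.null(row)) stop("element ", info$symbol, " not in table")
  if (abs(sum(row$a) + row$c - info$z) > tol) {
    stop("divergent F(000): net-charged Gaussian parameterization for ", info$symbol)
  }
  mott_bethe_constant() * sum(row$a * row$b)
}
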