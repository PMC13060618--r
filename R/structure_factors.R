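# Direct-summation structure factors over the unit cell with symmetry,
# Debye-Waller attenuation and occupancies; analytic gradients with respect
# to atomic parameters, accumulated on the fly against caller-supplied
# target derivatives so that outputs scale with the number of parameters,
# never with reflections x parameters.

#' Debye-Waller factor
#'
#' Isotropic: \eqn{\exp(-B s^2)}; anisotropic: \eqn{\exp(-2\pi^2 g^T U g)}
#' with g the Cartesian reciprocal vector of h and U the Cartesian ADP
#' tensor (this equals the reciprocal-frame form
#' \eqn{\exp(-2\pi^2 h^T U^* h)}).  An isotropic tensor U I reproduces
#' \eqn{B = 8\pi^2 U} exactly.
#'
#' @param adp Either a single non-negative B (Angstrom^2) or a 3x3 Cartesian
#'   U tensor (Angstrom^2).
#' @param hkl Integer matrix of Miller indices (rows).
#' @param cell A `unit_cell`.
#' @return Numeric vector of attenuation factors in (0, 1].
#' @export
debye_waller <- function(adp, hkl, cell) {
  hkl <- matrix(as.numeric(hkl), ncol = 3)
  g <- hkl %*% t(recip_matrix(cell))
  if (is.matrix(adp)) {
    expo <- rowSums((g %*% adp) * g)
    exp(-2 * pi^2 * expo)
  } else {
    s2 <- rowSums(g^2) / 4
    exp(-adp * s2)
  }
}

# ---------------------------------------------------------------------------
# Per-atom form-factor provider

.default_dialect <- function(radiation) {
  if (radiation == "electron") "electron-6invA" else "five-gauss"
}

# f_j evaluated at Cartesian scattering vectors g (n x 3) for atom j under
# the given representation level.  Complex for multipolar, real otherwise.
.atom_ff <- function(j, g, structure, assignment, bank, radiation, mode, dialect) {
  el <- structure$sites$element[j]
  z <- element_z(el)
  s <- sqrt(rowSums(g^2)) / 2
  level <- if (mode == "iam") "gaussian-iam" else assignment$atoms$level[j]
  if (level == "gaussian-iam") {
    dia <- dialect %||% .default_dialect(radiation)
    tab <- bank$gauss[[dia]]
    if (is.null(tab)) stop("bank has no Gaussian table for dialect ", dia)
    return(as.complex(gaussian_ff(el, s, tab)))
  }
  if (radiation == "electron" && any(s == 0))
    stop("divergent F(000): electron scattering at s = 0 requires the analytic-limit path")
  if (level == "spherical-slater") {
    shells <- bank$slater[[el]]
    if (is.null(shells)) stop("no Slater shell set for element ", el)
    fx <- spherical_slater_ff(shells, element_info(el)$n_val, 1, s)
    fx <- as.complex(fx)
  } else {
    entry <- bank$entries[[assignment$atoms$type_id[j]]]
    fx <- multipolar_ff(entry, assignment$frames[[j]], g)
  }
  if (radiation == "electron") mott_bethe(fx, z, s) else fx
}

# ---------------------------------------------------------------------------
# Direct summation

#' Direct-summation structure factors
#'
#' \eqn{F(h) = \sum_{sym} \sum_{atoms} occ_j f_j(R_s^T h) DW_j(R_s^T h)
#' \exp[2\pi i\, h \cdot (R_s x_j + t_s)]}.  Cost scales with reflections x
#' atoms x symmetry operators.  In "taam" mode atoms use their assigned
#' representation level; in "iam" mode every atom uses the Gaussian table of
#' the chosen dialect (default: the 6 1/Angstrom-valid dialect for each
#' radiation).
#'
#' @param structure A `crystal_structure`.
#' @param assignment A `type_assignment` (may be NULL for mode "iam").
#' @param miller A `miller_set`.
#' @param bank A `multipolar_bank` (supplies Gaussian tables and Slater
#'   shells in both modes).
#' @param radiation "xray" or "electron".
#' @param mode "taam" or "iam".
#' @param dialect Gaussian dialect override for gaussian-iam atoms.
#' @return A `structure_factor_set`.
#' @export
direct_summation_sf <- function(structure, assignment, miller, bank,
                                radiation = c("xray", "electron"),
                                mode = c("taam", "iam"), dialect = NULL) {
  radiation <- match.arg(radiation)
  mode <- match.arg(mode)
  if (mode == "taam" && is.null(assignment))
    stop("taam mode requires a type assignment")
  hkl <- miller$hkl
  B <- recip_matrix(miller$cell)
  F <- complex(nrow(hkl))
  s <- structure$sites
  fr <- as.matrix(s[, c("fx", "fy", "fz")])
  for (op in structure$ops) {
    hp <- hkl %*% op$rot            # h' = R_s^T h, rows
    g <- hp %*% t(B)
    phase_t <- as.numeric(hkl %*% op$trans)
    for (j in seq_len(nrow(s))) {
      fj <- .atom_ff(j, g, structure, assignment, bank, radiation, mode, dialect)
      adp <- structure$u_aniso[[j]] %||% s$biso[j]
      dw <- debye_waller(adp, hp, miller$cell)
      ph <- 2 * pi * (as.numeric(hp %*% fr[j, ]) + phase_t)
      F <- F + s$occ[j] * fj * dw * exp(1i * ph)
    }
  }
  structure_factor_set(miller, F, radiation = radiation, mode = mode)
}

# ---------------------------------------------------------------------------
# Gradients

# Selection flags for parameter classes.
.grad_params <- function(params) {
  list(xyz = "xyz" %in% params, adp = "adp" %in% params, occ = "occ" %in% params)
}

#' Target gradients with respect to atomic parameters
#'
#' Accumulates \eqn{\partial T/\partial p = \sum_h \mathrm{Re}[\overline{
#' (\partial T/\partial F_h)}\; \partial F_h/\partial p]} on the fly.  The
#' caller supplies \eqn{\partial T/\partial F} per reflection (convention:
#' `dT/dF = dT/dA + i dT/dB` for F = A + iB); see [make_ls_target()] for the
#' least-squares provider.  Positional gradients are per fractional
#' coordinate (use [gradients_to_cart()] for per-Angstrom); ADP gradients
#' are per B (isotropic atoms) or per unique Cartesian U component
#' (anisotropic atoms, off-diagonals carrying the factor 2).
#'
#' @inheritParams direct_summation_sf
#' @param dtarget_df Complex vector, length matching the miller set.
#' @param params Character subset of c("xyz", "adp", "occ").
#' @return A `parameter_gradients`: data frame with per-atom columns x, y, z,
#'   adp (B column for isotropic atoms), u11..u23, occ (NA where not
#'   selected/applicable).
#' @export
sf_gradients <- function(structure, assignment, miller, bank, dtarget_df,
                         radiation = c("xray", "electron"),
                         mode = c("taam", "iam"), dialect = NULL,
                         params = c("xyz", "adp", "occ")) {
  radiation <- match.arg(radiation)
  mode <- match.arg(mode)
  if (length(dtarget_df) != nrow(miller$hkl))
    stop("dtarget_df length must match the reflection set")
  if (any(!is.finite(dtarget_df))) stop("non-finite target derivatives")
  sel <- .grad_params(params)
  hkl <- miller$hkl
  B <- recip_matrix(miller$cell)
  s <- structure$sites
  n <- nrow(s)
  fr <- as.matrix(s[, c("fx", "fy", "fz")])
  gx <- matrix(NA_real_, n, 3)
  gocc <- rep(NA_real_, n)
  gb <- rep(NA_real_, n)
  gu <- matrix(NA_real_, n, 6)
  colnames(gu) <- c("u11", "u22", "u33", "u12", "u13", "u23")
  if (sel$xyz) gx[] <- 0
  if (sel$occ) gocc[] <- 0
  has_u <- !vapply(structure$u_aniso, is.null, TRUE)
  if (sel$adp) { gb[!has_u] <- 0; gu[has_u, ] <- 0 }
  cd <- Conj(dtarget_df)
  for (op in structure$ops) {
    hp <- hkl %*% op$rot
    g <- hp %*% t(B)
    phase_t <- as.numeric(hkl %*% op$trans)
    for (j in seq_len(n)) {
      fj <- .atom_ff(j, g, structure, assignment, bank, radiation, mode, dialect)
      adp <- structure$u_aniso[[j]] %||% s$biso[j]
      dw <- debye_waller(adp, hp, miller$cell)
      ph <- 2 * pi * (as.numeric(hp %*% fr[j, ]) + phase_t)
      base <- fj * dw * exp(1i * ph)          # term without occupancy
      term <- s$occ[j] * base
      if (sel$xyz) {
        for (ax in 1:3) {
          gx[j, ax] <- gx[j, ax] + sum(Re(cd * (2i * pi * hp[, ax] * term)))
        }
      }
      if (sel$occ) gocc[j] <- gocc[j] + sum(Re(cd * base))
      if (sel$adp) {
        if (has_u[j]) {
          pairs <- list(c(1, 1), c(2, 2), c(3, 3), c(1, 2), c(1, 3), c(2, 3))
          for (k in seq_along(pairs)) {
            a <- pairs[[k]][1]; b2 <- pairs[[k]][2]
            mult <- if (a == b2) 1 else 2
            gu[j, k] <- gu[j, k] +
              sum(Re(cd * (-2 * pi^2 * mult * g[, a] * g[, b2] * term)))
          }
        } else {
          s2 <- rowSums(g^2) / 4
          gb[j] <- gb[j] + sum(Re(cd * (-s2 * term)))
        }
      }
    }
  }
  out <- data.frame(label = s$label, x = gx[, 1], y = gx[, 2], z = gx[, 3],
                    b = gb, gu, occ = gocc, stringsAsFactors = FALSE)
  structure(out, class = c("parameter_gradients", "data.frame"))
}

#' Convert fractional positional gradients to per-Angstrom
#'
#' With \eqn{r = M x} (M the orthogonalization matrix), gradients transform
#' as \eqn{\nabla_r T = M^{-T} \nabla_x T}.
#'
#' @param grads A `parameter_gradients`.
#' @param cell The `unit_cell` used in the calculation.
#' @return The gradients with x, y, z replaced by Cartesian derivatives.
#' @export
gradients_to_cart <- function(grads, cell) {
  Minv_t <- t(solve(frac_to_cart_matrix(cell)))
  xyz <- as.matrix(grads[, c("x", "y", "z")]) %*% Minv_t
  grads$x <- xyz[, 1]; grads$y <- xyz[, 2]; grads$z <- xyz[, 3]
  grads
}

#' Explicit per-reflection structure-factor gradients
#'
#' Materializes the complex derivative table \eqn{\partial F(h)/\partial p}
#' for a small reflection subset.  Guarded: reflections x parameters must
#' not exceed 1e7 entries (the full table for a refinement-sized problem
#' would run to hundreds of gigabytes, which is why the accumulated path in
#' [sf_gradients()] exists).  Contracting the table with
#' \eqn{\partial T/\partial F} reproduces [sf_gradients()] to 1e-10.
#'
#' @inheritParams sf_gradients
#' @return List of complex matrices: `dx`, `dy`, `dz` (reflections x atoms,
#'   per fractional coordinate), `db` (isotropic atoms, NA columns for
#'   anisotropic ones), `du` (reflections x (6 atoms) for anisotropic
#'   atoms), `docc`.
#' @export
per_reflection_sf_gradients <- function(structure, assignment, miller, bank,
                                        radiation = c("xray", "electron"),
                                        mode = c("taam", "iam"), dialect = NULL,
                                        params = c("xyz", "adp", "occ")) {
  radiation <- match.arg(radiation)
  mode <- match.arg(mode)
  sel <- .grad_params(params)
  s <- structure$sites
  n <- nrow(s)
  nref <- nrow(miller$hkl)
  npar <- (3 * sel$xyz + 6 * sel$adp + sel$occ) * n
  if (nref * npar > 1e7)
    stop("resource guard: reflections x parameters = ", format(nref * npar, big.mark = ","),
         " exceeds 1e7; use sf_gradients() for the accumulated path")
  hkl <- miller$hkl
  B <- recip_matrix(miller$cell)
  fr <- as.matrix(s[, c("fx", "fy", "fz")])
  zmat <- function() matrix(0i, nref, n)
  out <- list(dx = zmat(), dy = zmat(), dz = zmat(), db = zmat(),
              du = array(0i, c(nref, n, 6)), docc = zmat())
  has_u <- !vapply(structure$u_aniso, is.null, TRUE)
  for (op in structure$ops) {
    hp <- hkl %*% op$rot
    g <- hp %*% t(B)
    phase_t <- as.numeric(hkl %*% op$trans)
    for (j in seq_len(n)) {
      fj <- .atom_ff(j, g, structure, assignment, bank, radiation, mode, dialect)
      adp <- structure$u_aniso[[j]] %||% s$biso[j]
      dw <- debye_waller(adp, hp, miller$cell)
      ph <- 2 * pi * (as.numeric(hp %*% fr[j, ]) + phase_t)
      base <- fj * dw * exp(1i * ph)
      term <- s$occ[j] * base
      if (sel$xyz) {
        out$dx[, j] <- out$dx[, j] + 2i * pi * hp[, 1] * term
        out$dy[, j] <- out$dy[, j] + 2i * pi * hp[, 2] * term
        out$dz[, j] <- out$dz[, j] + 2i * pi * hp[, 3] * term
      }
      if (sel$occ) out$docc[, j] <- out$docc[, j] + base
      if (sel$adp) {
        if (has_u[j]) {
          pairs <- list(c(1, 1), c(2, 2), c(3, 3), c(1, 2), c(1, 3), c(2, 3))
          for (k in seq_along(pairs)) {
            a <- pairs[[k]][1]; b2 <- pairs[[k]][2]
            mult <- if (a == b2) 1 else 2
            out$du[, j, k] <- out$du[, j, k] - 2 * pi^2 * mult * g[, a] * g[, b2] * term
          }
        } else {
          s2 <- rowSums(g^2) / 4
          out$db[, j] <- out$db[, j] - s2 * term
        }
      }
    }
  }
  out
}

#' Contract an explicit gradient table with target derivatives
#'
#' @param table Output of [per_reflection_sf_gradients()].
#' @param dtarget_df Complex per-reflection target derivatives.
#' @return A data frame in the layout of [sf_gradients()].
#' @export
contract_gradient_table <- function(table, dtarget_df) {
  cd <- Conj(dtarget_df)
  n <- ncol(table$dx)
  red <- function(m) colSums(Re(cd * matrix(m, ncol = n)))
  gu <- vapply(1:6, function(k) red(table$du[, , k]), numeric(n))
  if (is.null(dim(gu))) gu <- matrix(gu, nrow = n)
  colnames(gu) <- c("u11", "u22", "u33", "u12", "u13", "u23")
  data.frame(x = red(table$dx), y = red(table$dy), z = red(table$dz),
             b = red(table$db), gu, occ = red(table$docc))
}
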