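# Deterministic toy-crystal generators.  Every recipe regenerates
# byte-identically from (name, seed); float formatting in the emitted files
# is frozen by the writers in model_io.R.

FIXTURE_RECIPES <- c("methane", "water", "water-noH", "benzene", "decalin",
                     "tripeptide-like", "random-P1", "chiral-P21-pair",
                     "altloc-overlap")

#' Describe a fixture recipe
#'
#' @param name One of `FIXTURE_RECIPES`.
#' @param seed Integer seed.
#' @param noise Coordinate noise amplitude in Angstrom (Gaussian, seeded).
#' @return A `fixture_recipe`.
#' @export
fixture_recipe <- function(name, seed = 0, noise = 0) {
  name <- match.arg(name, FIXTURE_RECIPES)
  structure(list(name = name, seed = seed, noise = noise), class = "fixture_recipe")
}

unit3 <- function(v) v / sqrt(sum(v^2))

# Directions completing an approximately tetrahedral site: `existing` is a
# matrix of unit bond vectors already present (>= 1), n_add in 1..3.
.tetrahedral_fill <- function(existing, n_add) {
  if (is.null(dim(existing))) existing <- matrix(existing, 1)
  k <- nrow(existing)
  if (k == 1) {
    e1 <- existing[1, ]
    ref <- if (abs(e1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    w1 <- unit3(ref - sum(ref * e1) * e1)
    w2 <- unit3(pracma_cross(e1, w1))
    th <- 109.47 * pi / 180
    dirs <- t(vapply(seq_len(n_add), function(i) {
      phi <- 2 * pi * (i - 1) / 3
      unit3(cos(th) * e1 + sin(th) * (cos(phi) * w1 + sin(phi) * w2))
    }, numeric(3)))
    return(dirs)
  }
  if (k == 2) {
    u <- unit3(-(existing[1, ] + existing[2, ]))
    w <- unit3(pracma_cross(existing[1, ], existing[2, ]))
    th <- 54.735 * pi / 180
    d1 <- cos(th) * u + sin(th) * w
    d2 <- cos(th) * u - sin(th) * w
    return(matrix(c(d1, d2), ncol = 3, byrow = TRUE)[seq_len(n_add), , drop = FALSE])
  }
  matrix(unit3(-colSums(existing)), 1)[seq_len(n_add), , drop = FALSE]
}

pracma_cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                                 a[3] * b[1] - a[1] * b[3],
                                 a[1] * b[2] - a[2] * b[1])

# Cartesian -> sites data frame centred in a P1 box
.box_structure <- function(xyz, elements, box, labels = NULL, resname = "LIG",
                           biso = 3, occ = 1, altloc = "", resid = 1L,
                           spacegroup = "P1", center = TRUE) {
  cell <- unit_cell(box[1], box[2], box[3])
  if (center) xyz <- sweep(xyz, 2, colMeans(xyz)) + matrix(box / 2, nrow(xyz), 3, byrow = TRUE)
  fr <- xyz %*% t(solve(frac_to_cart_matrix(cell)))
  sites <- data.frame(
    label = if (is.null(labels)) paste0(elements, seq_along(elements)) else labels,
    element = elements, fx = fr[, 1], fy = fr[, 2], fz = fr[, 3],
    occ = rep(occ, length.out = nrow(fr)), biso = rep(biso, length.out = nrow(fr)),
    altloc = rep(altloc, length.out = nrow(fr)),
    resname = rep(resname, length.out = nrow(fr)),
    resid = rep(resid, length.out = nrow(fr)),
    stringsAsFactors = FALSE)
  sites$is_water <- sites$resname %in% c("HOH", "WAT")
  crystal_structure(cell, sites, spacegroup = spacegroup)
}

.geom_methane <- function() {
  d <- 1.09
  h <- d / sqrt(3) * matrix(c(1, 1, 1, 1, -1, -1, -1, 1, -1, -1, -1, 1), 4, 3, byrow = TRUE)
  list(xyz = rbind(c(0, 0, 0), h), el = c("C", rep("H", 4)), box = c(10, 10, 10))
}

.geom_water <- function(with_h = TRUE) {
  ang <- 104.5 * pi / 180
  xyz <- rbind(c(0, 0, 0),
               0.9572 * c(sin(ang / 2), cos(ang / 2), 0),
               0.9572 * c(-sin(ang / 2), cos(ang / 2), 0))
  if (!with_h) xyz <- xyz[1, , drop = FALSE]
  list(xyz = xyz, el = c("O", "H", "H")[seq_len(nrow(xyz))], box = c(8, 8, 8),
       resname = "HOH")
}

.geom_benzene <- function() {
  ang <- (0:5) * pi / 3
  cc <- 1.39; ch <- 1.09
  c_xyz <- cbind(cc * cos(ang), cc * sin(ang), 0)
  h_xyz <- cbind((cc + ch) * cos(ang), (cc + ch) * sin(ang), 0)
  list(xyz = rbind(c_xyz, h_xyz), el = c(rep("C", 6), rep("H", 6)), box = c(14, 14, 14))
}

.geom_decalin <- function() {
  # chair ring: C-C = 1.54 A
  ang <- (0:5) * pi / 3
  ring <- cbind(1.46 * cos(ang), 1.46 * sin(ang), 0.25 * (-1)^(0:5))
  # second chair fused on the 1-2 edge: rotate the other four atoms by pi
  # about the shared edge axis
  a0 <- ring[1, ]; a1 <- ring[2, ]
  axis <- unit3(a1 - a0)
  rot180 <- function(p) {
    v <- p - a0
    2 * sum(v * axis) * axis - v + a0
  }
  ringB <- t(apply(ring[3:6, ], 1, rot180))
  c_xyz <- rbind(ring, ringB)
  # hydrogens: fill sp3 valences from the C-C connectivity
  nb <- lapply(seq_len(10), function(i) {
    which(sqrt(rowSums(sweep(c_xyz, 2, c_xyz[i, ])^2)) < 1.8 &
            seq_len(10) != i)
  })
  h_xyz <- NULL
  for (i in seq_len(10)) {
    ex <- t(apply(c_xyz[nb[[i]], , drop = FALSE], 1, function(p) unit3(p - c_xyz[i, ])))
    n_add <- 4 - nrow(ex)
    if (n_add <= 0) next
    dirs <- .tetrahedral_fill(ex, n_add)
    h_xyz <- rbind(h_xyz, sweep(1.09 * dirs, 2, c_xyz[i, ], `+`))
  }
  list(xyz = rbind(c_xyz, h_xyz), el = c(rep("C", 10), rep("H", nrow(h_xyz))),
       box = c(16, 16, 16))
}

# N-methylacetamide-like fragment: CH3-C(=O)-N(H)-CH3
.geom_peptide <- function() {
  rot2 <- function(v, deg) {
    a <- deg * pi / 180
    c(cos(a) * v[1] - sin(a) * v[2], sin(a) * v[1] + cos(a) * v[2], 0)
  }
  c2 <- c(0, 0, 0)
  c1 <- c(-1.52, 0, 0)                                   # sp2 C: 120 deg spread
  o3 <- c2 + 1.23 * rot2(c(1, 0, 0), 60)
  n4 <- c2 + 1.33 * rot2(c(1, 0, 0), -60)
  u <- unit3(c2 - n4)
  c5 <- n4 + 1.45 * rot2(u, 120)
  hn <- n4 + 1.01 * rot2(u, -120)
  xyz <- rbind(c1, c2, o3, n4, c5, hn)
  el <- c("C", "C", "O", "N", "C", "H")
  for (ci in c(1, 5)) {
    nbr <- if (ci == 1) 2 else 4
    ex <- matrix(unit3(xyz[nbr, ] - xyz[ci, ]), 1)
    dirs <- .tetrahedral_fill(ex, 3)
    xyz <- rbind(xyz, sweep(1.09 * dirs, 2, xyz[ci, ], `+`))
    el <- c(el, rep("H", 3))
  }
  list(xyz = xyz, el = el, box = c(14, 14, 14), resname = "NMA")
}

.geom_random_p1 <- function(rng, n = 20, box = 12) {
  xyz <- matrix(NA_real_, 0, 3)
  while (nrow(xyz) < n) {
    p <- box * rng(3)
    ok <- TRUE
    if (nrow(xyz) > 0) {
      dv <- sweep(xyz, 2, p)
      dv <- dv - box * round(dv / box)   # minimum-image
      if (min(sqrt(rowSums(dv^2))) < 1.0) ok <- FALSE
    }
    if (ok) xyz <- rbind(xyz, p)
  }
  el <- c("C", "N", "O")[floor(rng(n) * 3) + 1]
  biso <- round(10 + 15 * rng(n), 4)
  occ <- rep(1, n); occ[1:2] <- c(0.75, 0.5)
  list(xyz = xyz, el = el, box = c(box, box, box), biso = biso, occ = occ,
       center = FALSE)
}

# chiral C with N, O, C, H substituents in a P21 cell
.geom_chiral <- function() {
  c0 <- c(0, 0, 0)
  xyz <- rbind(c0,
               c0 + 1.47 * unit3(c(1, 1, 1)),
               c0 + 1.43 * unit3(c(1, -1, -1)),
               c0 + 1.53 * unit3(c(-1, 1, -1)),
               c0 + 1.09 * unit3(c(-1, -1, 1)))
  list(xyz = xyz, el = c("C", "N", "O", "C", "H"), box = c(9, 11, 10),
       spacegroup = "P21")
}

.geom_altloc <- function() {
  w <- .geom_water(TRUE)
  xyz <- rbind(w$xyz,
               w$xyz[1, ] + c(0.28, 0, 0),   # altloc B oxygen overlapping A
               c(3.0, 0, 0), c(3.18, 0.1, 0))  # same-altloc clash pair
  el <- c(w$el, "O", "C", "C")
  list(xyz = xyz, el = el, box = c(10, 10, 10), resname = "LIG",
       altloc = c("A", "", "", "B", "", ""))
}

#' Generate a fixture crystal structure
#'
#' Deterministic toy structures: methane, water (with and without
#' hydrogens), benzene, trans-decalin, an N-methylacetamide peptide-like
#' fragment, a 20-atom random P1 cell (minimum pairwise distance 1 Angstrom
#' under periodic boundary conditions), a chiral fragment in P21, and an
#' altloc-overlap case with both a different-altloc overlap (0.28 Angstrom)
#' and a same-altloc clash pair.  Bond lengths follow standard values.
#'
#' @param recipe A [fixture_recipe()], or a recipe name.
#' @param seed,noise Used when `recipe` is a name.
#' @return A `crystal_structure`.
#' @export
make_structure <- function(recipe, seed = 0, noise = 0) {
  if (is.character(recipe)) recipe <- fixture_recipe(recipe, seed, noise)
  rng <- local_rng(recipe$seed)
  g <- switch(recipe$name,
              "methane" = .geom_methane(),
              "water" = .geom_water(TRUE),
              "water-noH" = .geom_water(FALSE),
              "benzene" = .geom_benzene(),
              "decalin" = .geom_decalin(),
              "tripeptide-like" = .geom_peptide(),
              "random-P1" = .geom_random_p1(rng),
              "chiral-P21-pair" = .geom_chiral(),
              "altloc-overlap" = .geom_altloc())
  xyz <- g$xyz
  if (recipe$noise > 0) {
    xyz <- xyz + recipe$noise * matrix(stats::qnorm(rng(3 * nrow(xyz))), nrow(xyz), 3)
  }
  xyz <- round(xyz, 6)
  .box_structure(xyz, g$el, g$box,
                 resname = g$resname %||% "LIG",
                 biso = g$biso %||% 3,
                 occ = g$occ %||% 1,
                 altloc = g$altloc %||% "",
                 spacegroup = g$spacegroup %||% "P1",
                 center = g$center %||% TRUE)
}

#' Materialize a fixture to disk
#'
#' Writes the structure in both PDB and mmCIF form next to each other.
#'
#' @param recipe A recipe or name.
#' @param dir Output directory.
#' @param seed,noise Passed to [make_structure()].
#' @return Named character vector of the two paths.
#' @export
write_fixture <- function(recipe, dir = ".", seed = 0, noise = 0) {
  if (is.character(recipe)) recipe <- fixture_recipe(recipe, seed, noise)
  st <- make_structure(recipe)
  base <- file.path(dir, gsub("[^A-Za-z0-9-]", "_", recipe$name))
  p1 <- paste0(base, ".pdb"); p2 <- paste0(base, ".cif")
  write_structure(st, p1, "pdb")
  write_structure(st, p2, "mmcif")
  c(pdb = p1, mmcif = p2)
}

#' Expand a structure to P1
#'
#' Applies every symmetry operator to every site, producing the full unit
#' cell as an explicit P1 structure.
#'
#' @param structure A `crystal_structure`.
#' @return A `crystal_structure` in P1 with multiplicity-times as many sites.
#' @export
expand_to_p1 <- function(structure) {
  s <- structure$sites
  out <- NULL; u_out <- list()
  for (k in seq_along(structure$ops)) {
    op <- structure$ops[[k]]
    si <- s
    fr <- as.matrix(s[, c("fx", "fy", "fz")]) %*% t(op$rot) +
      matrix(op$trans, nrow(s), 3, byrow = TRUE)
    si$fx <- fr[, 1] %% 1; si$fy <- fr[, 2] %% 1; si$fz <- fr[, 3] %% 1
    si$label <- paste0(s$label, "_", k)
    out <- rbind(out, si)
    M <- frac_to_cart_matrix(structure$cell)
    Rc <- M %*% op$rot %*% solve(M)
    u_out <- c(u_out, lapply(structure$u_aniso, function(U)
      if (is.null(U)) NULL else Rc %*% U %*% t(Rc)))
  }
  crystal_structure(structure$cell, out, spacegroup = "P1", u_aniso = u_out)
}

#' Least-squares demo target from noisy amplitudes
#'
#' Builds observed amplitudes |F_obs| = |F_true| + Gaussian noise and returns
#' the least-squares target \eqn{T = \sum (|F_{calc}| - |F_{obs}|)^2}
#' together with its structure-factor derivative provider
#' \eqn{\partial T/\partial F = 2 (|F_{calc}| - |F_{obs}|) F_{calc}/|F_{calc}|}.
#'
#' @param sf_true A `structure_factor_set` with the true model amplitudes.
#' @param noise_sd Standard deviation of the amplitude noise.
#' @param seed Integer seed.
#' @return List with `f_obs` (amplitudes), `target(f_calc)` and
#'   `dtarget_df(f_calc)` functions.
#' @export
make_ls_target <- function(sf_true, noise_sd = 0, seed = 0) {
  rng <- local_rng(seed)
  f_obs <- Mod(sf_true$f) + noise_sd * stats::qnorm(rng(length(sf_true$f)))
  f_obs <- pmax(f_obs, 0)
  list(
    f_obs = f_obs,
    target = function(f_calc) sum((Mod(f_calc) - f_obs)^2),
    dtarget_df = function(f_calc) {
      amp <- Mod(f_calc)
      scale <- ifelse(amp > 0, 2 * (amp - f_obs) / amp, 0)
      scale * f_calc
    }
  )
}
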