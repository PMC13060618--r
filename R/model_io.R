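# Reading and writing atomic models (PDB, mmCIF, small-molecule CIF),
# reflection-set generation, structure-factor files and CCP4/MRC maps.
#
# Internal convention: fractional coordinates; anisotropic U tensors are
# stored in the Cartesian crystal frame (Angstrom^2) and take precedence
# over isotropic B when both are present.

#' Construct a crystal structure
#'
#' @param cell A [unit_cell()].
#' @param sites Data frame with columns label, element, fx, fy, fz, occ,
#'   biso, altloc, is_water, charge, resname, resid, chain (missing columns
#'   are filled with defaults).
#' @param spacegroup Space-group symbol (see [spacegroup_ops()]) or a list of
#'   operators; defaults to P1.
#' @param u_aniso Optional list (one per site) of 3x3 Cartesian U tensors in
#'   Angstrom^2, NULL where the atom is isotropic.
#' @return A `crystal_structure`.
#' @export
crystal_structure <- function(cell, sites, spacegroup = "P1", u_aniso = NULL) {
  defaults <- list(occ = 1, biso = 0, altloc = "", is_water = FALSE, charge = 0,
                   resname = "LIG", resid = 1L, chain = "A")
  for (nm in names(defaults)) {
    if (is.null(sites[[nm]])) sites[[nm]] <- rep(defaults[[nm]], nrow(sites))
  }
  if (is.null(sites$label)) sites$label <- paste0(sites$element, seq_len(nrow(sites)))
  if (any(sites$occ < 0 | sites$occ > 1)) stop("occupancies must lie in [0, 1]")
  if (any(sites$biso < 0, na.rm = TRUE)) stop("isotropic B must be non-negative")
  element_z(sites$element)  # validates symbols
  if (is.character(spacegroup)) {
    ops <- spacegroup_ops(spacegroup)
    sg <- normalize_sg_symbol(spacegroup)
  } else {
    ops <- spacegroup
    sg <- sprintf("(%d ops)", length(ops))
  }
  check_ops_closure(ops)
  if (is.null(u_aniso)) u_aniso <- vector("list", nrow(sites))
  for (i in seq_along(u_aniso)) {
    U <- u_aniso[[i]]
    if (!is.null(U)) {
      ev <- eigen(U, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < -1e-8) warning("anisotropic U for site ", sites$label[i],
                                   " is not positive semi-definite")
    }
  }
  structure(list(cell = cell, spacegroup = sg, ops = ops, sites = sites,
                 u_aniso = u_aniso),
            class = "crystal_structure")
}

#' @export
print.crystal_structure <- function(x, ...) {
  cat(sprintf("crystal structure: %d sites, space group %s\n",
              nrow(x$sites), x$spacegroup))
  print(x$cell)
  invisible(x)
}

#' Number of atoms in a structure
#' @param structure A `crystal_structure`.
#' @return Integer.
#' @export
n_sites <- function(structure) nrow(structure$sites)

#' Cartesian coordinates of the sites
#' @param structure A `crystal_structure`.
#' @return n x 3 matrix (Angstrom).
#' @export
site_cart <- function(structure) {
  as.matrix(structure$sites[, c("fx", "fy", "fz")]) %*% t(frac_to_cart_matrix(structure$cell))
}

# Split an element field like "O1-" or "FE2+" into (symbol, charge).
.parse_element_charge <- function(txt) {
  txt <- trimws(txt)
  m <- regmatches(txt, regexec("^([A-Za-z]{1,2})([0-9]*)([+-]?)$", txt))[[1]]
  if (length(m) == 0) stop("unknown element symbol: '", txt, "'")
  sym <- toupper_first(m[2])
  chg <- 0
  if (nzchar(m[4])) chg <- (if (nzchar(m[3])) as.numeric(m[3]) else 1) * (if (m[4] == "-") -1 else 1)
  list(symbol = sym, charge = chg)
}

# ---------------------------------------------------------------------------
# PDB

#' Read an atomic model
#'
#' Dispatches on `format` (or the file extension): fixed-column PDB, mmCIF
#' (`_atom_site` loop with Cartesian or fractional coordinates) or
#' small-molecule CIF (`_atom_site_fract_*`).  Elements with formal-charge
#' suffixes (e.g. "O1-") are normalized to the neutral element with the
#' charge recorded in the `charge` column.  Anisotropic U records take
#' precedence over isotropic B.
#'
#' @param path Model file.
#' @param format "pdb", "mmcif" or "cif-small-molecule"; guessed from the
#'   extension when omitted.
#' @return A `crystal_structure`.
#' @export
read_structure <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     pdb = "pdb", cif = "mmcif", mmcif = "mmcif",
                     stop("cannot guess model format from extension of ", path))
  }
  switch(format,
         "pdb" = .read_pdb(path),
         "mmcif" = .read_cif_model(path, small = FALSE),
         "cif-small-molecule" = .read_cif_model(path, small = TRUE),
         stop("unknown model format: ", format))
}

.read_pdb <- function(path) {
  lines <- readLines(path)
  cr <- grep("^CRYST1", lines, value = TRUE)
  if (length(cr) == 0) stop("PDB file has no CRYST1 record (missing cell): ", path)
  cell <- unit_cell(as.numeric(substr(cr[1], 7, 15)), as.numeric(substr(cr[1], 16, 24)),
                    as.numeric(substr(cr[1], 25, 33)), as.numeric(substr(cr[1], 34, 40)),
                    as.numeric(substr(cr[1], 41, 47)), as.numeric(substr(cr[1], 48, 54)))
  sg <- trimws(substr(cr[1], 56, 66))
  at <- grep("^(ATOM  |HETATM)", lines, value = TRUE)
  Minv <- solve(frac_to_cart_matrix(cell))
  n <- length(at)
  sites <- data.frame(label = character(n), element = character(n),
                      fx = numeric(n), fy = numeric(n), fz = numeric(n),
                      occ = numeric(n), biso = numeric(n), altloc = character(n),
                      is_water = logical(n), charge = numeric(n),
                      resname = character(n), resid = integer(n), chain = character(n),
                      stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    l <- at[i]
    elfield <- trimws(substr(l, 77, 78))
    chfield <- trimws(substr(l, 79, 80))
    if (!nzchar(elfield)) elfield <- trimws(substr(l, 13, 14))
    ec <- .parse_element_charge(paste0(elfield, chfield))
    xyz <- c(as.numeric(substr(l, 31, 38)), as.numeric(substr(l, 39, 46)),
             as.numeric(substr(l, 47, 54)))
    fr <- as.numeric(Minv %*% xyz)
    resname <- trimws(substr(l, 18, 20))
    sites[i, c("fx", "fy", "fz")] <- fr
    sites$label[i] <- trimws(substr(l, 13, 16))
    sites$element[i] <- ec$symbol
    sites$charge[i] <- ec$charge
    sites$occ[i] <- as.numeric(substr(l, 55, 60))
    sites$biso[i] <- as.numeric(substr(l, 61, 66))
    sites$altloc[i] <- trimws(substr(l, 17, 17))
    sites$resname[i] <- resname
    sites$is_water[i] <- resname %in% c("HOH", "WAT", "DOD")
    sites$resid[i] <- suppressWarnings(as.integer(substr(l, 23, 26)))
    sites$chain[i] <- substr(l, 22, 22)
  }
  u_aniso <- vector("list", n)
  anis <- grep("^ANISOU", lines, value = TRUE)
  if (length(anis)) {
    serials <- as.integer(substr(at, 7, 11))
    for (l in anis) {
      ser <- as.integer(substr(l, 7, 11))
      i <- match(ser, serials)
      if (is.na(i)) next
      u <- as.numeric(c(substr(l, 29, 35), substr(l, 36, 42), substr(l, 43, 49),
                        substr(l, 50, 56), substr(l, 57, 63), substr(l, 64, 70))) / 1e4
      u_aniso[[i]] <- matrix(c(u[1], u[4], u[5],
                               u[4], u[2], u[6],
                               u[5], u[6], u[3]), 3, 3)
    }
  }
  crystal_structure(cell, sites, spacegroup = sg, u_aniso = u_aniso)
}

#' Write an atomic model
#'
#' @param structure A `crystal_structure`.
#' @param path Output file.
#' @param format "pdb", "mmcif" or "cif-small-molecule".
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path, format = c("pdb", "mmcif", "cif-small-molecule")) {
  format <- match.arg(format)
  switch(format,
         "pdb" = .write_pdb(structure, path),
         "mmcif" = .write_mmcif(structure, path),
         "cif-small-molecule" = .write_small_cif(structure, path))
}

.write_pdb <- function(structure, path) {
  cell <- structure$cell
  out <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s%4d",
                 cell$a, cell$b, cell$c, cell$alpha, cell$beta, cell$gamma,
                 .sg_pdb_symbol(structure$spacegroup), length(structure$ops))
  xyz <- site_cart(structure)
  s <- structure$sites
  for (i in seq_len(nrow(s))) {
    name <- s$label[i]
    if (nchar(name) < 4) name <- paste0(" ", name)
    rec <- if (s$is_water[i]) "HETATM" else "ATOM  "
    out <- c(out, sprintf("%s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                          rec, i, substr(name, 1, 4), s$altloc[i], s$resname[i], s$chain[i],
                          s$resid[i], xyz[i, 1], xyz[i, 2], xyz[i, 3], s$occ[i], s$biso[i],
                          toupper(s$element[i])))
    U <- structure$u_aniso[[i]]
    if (!is.null(U)) {
      u <- round(1e4 * c(U[1, 1], U[2, 2], U[3, 3], U[1, 2], U[1, 3], U[2, 3]))
      out <- c(out, sprintf("ANISOU%5d %-4s%1s%-3s %1s%4d  %7d%7d%7d%7d%7d%7d      %2s",
                            i, substr(name, 1, 4), s$altloc[i], s$resname[i], s$chain[i],
                            s$resid[i], u[1], u[2], u[3], u[4], u[5], u[6],
                            toupper(s$element[i])))
    }
  }
  out <- c(out, "END")
  writeLines(out, path)
  invisible(path)
}

.sg_pdb_symbol <- function(sg) {
  switch(sg, "P21" = "P 1 21 1", "P212121" = "P 21 21 21", "P-1" = "P -1", "P1" = "P 1", sg)
}

# ---------------------------------------------------------------------------
# CIF (shared tokenizer for mmCIF and small-molecule CIF)

.cif_tokens <- function(lines) {
  lines <- lines[!grepl("^[[:space:]]*#", lines)]
  toks <- list()
  for (l in lines) {
    while (nzchar(trimws(l))) {
      l <- sub("^[[:space:]]+", "", l)
      if (!nzchar(l)) break
      ch <- substr(l, 1, 1)
      if (ch == "'" || ch == "\"") {
        end <- regexpr(paste0(ch, "([[:space:]]|$)"), substr(l, 2, nchar(l)))
        if (end < 0) end <- nchar(l)
        toks[[length(toks) + 1]] <- substr(l, 2, end)
        l <- substr(l, end + 2, nchar(l))
      } else {
        sp <- regexpr("[[:space:]]", l)
        if (sp < 0) { toks[[length(toks) + 1]] <- l; l <- "" }
        else { toks[[length(toks) + 1]] <- substr(l, 1, sp - 1); l <- substr(l, sp, nchar(l)) }
      }
    }
  }
  unlist(toks)
}

# Parse key-value items and loops into a list (scalars + data.frames).
.cif_parse <- function(path) {
  toks <- .cif_tokens(readLines(path))
  items <- list(); loops <- list()
  i <- 1; n <- length(toks)
  while (i <= n) {
    t <- toks[i]
    if (tolower(t) == "loop_") {
      tags <- character(0); i <- i + 1
      while (i <= n && startsWith(toks[i], "_")) { tags <- c(tags, tolower(toks[i])); i <- i + 1 }
      vals <- character(0)
      while (i <= n && !startsWith(toks[i], "_") && tolower(toks[i]) != "loop_" &&
             !startsWith(tolower(toks[i]), "data_")) {
        vals <- c(vals, toks[i]); i <- i + 1
      }
      if (length(tags) && length(vals) %% length(tags) == 0) {
        m <- matrix(vals, ncol = length(tags), byrow = TRUE)
        df <- as.data.frame(m, stringsAsFactors = FALSE)
        names(df) <- tags
        loops[[length(loops) + 1]] <- df
      }
    } else if (startsWith(t, "_")) {
      items[[tolower(t)]] <- if (i + 1 <= n) toks[i + 1] else NA
      i <- i + 2
    } else i <- i + 1
  }
  list(items = items, loops = loops)
}

.cif_num <- function(x) as.numeric(sub("\\(.*\\)$", "", x))

.read_cif_model <- function(path, small = FALSE) {
  p <- .cif_parse(path)
  it <- p$items
  need <- function(keys) {
    for (k in keys) if (!is.null(it[[k]])) return(.cif_num(it[[k]]))
    stop("missing cell in CIF file ", path)
  }
  cell <- unit_cell(need(c("_cell.length_a", "_cell_length_a")),
                    need(c("_cell.length_b", "_cell_length_b")),
                    need(c("_cell.length_c", "_cell_length_c")),
                    need(c("_cell.angle_alpha", "_cell_angle_alpha")),
                    need(c("_cell.angle_beta", "_cell_angle_beta")),
                    need(c("_cell.angle_gamma", "_cell_angle_gamma")))
  # symmetry: explicit operator loop wins, else the H-M symbol
  ops <- NULL; sg <- "P1"
  for (lp in p$loops) {
    opcol <- intersect(c("_space_group_symop.operation_xyz", "_space_group_symop_operation_xyz",
                         "_symmetry_equiv.pos_as_xyz", "_symmetry_equiv_pos_as_xyz"), names(lp))
    if (length(opcol)) ops <- lapply(lp[[opcol[1]]], parse_symop_xyz)
  }
  for (k in c("_symmetry.space_group_name_h-m", "_symmetry_space_group_name_h-m",
              "_space_group.name_h-m_alt", "_space_group_name_h-m_alt")) {
    if (!is.null(it[[k]])) sg <- it[[k]]
  }
  atom_loop <- NULL
  for (lp in p$loops) {
    if (any(grepl("^_atom_site[._]", names(lp))) && !any(grepl("anisotrop", names(lp))))
      atom_loop <- lp
  }
  if (is.null(atom_loop)) stop("no _atom_site loop in ", path)
  gc1 <- function(df, keys) { for (k in keys) if (!is.null(df[[k]])) return(df[[k]]); NULL }
  n <- nrow(atom_loop)
  frx <- gc1(atom_loop, c("_atom_site.fract_x", "_atom_site_fract_x"))
  if (!is.null(frx)) {
    fr <- cbind(.cif_num(frx),
                .cif_num(gc1(atom_loop, c("_atom_site.fract_y", "_atom_site_fract_y"))),
                .cif_num(gc1(atom_loop, c("_atom_site.fract_z", "_atom_site_fract_z"))))
  } else {
    xyz <- cbind(.cif_num(gc1(atom_loop, c("_atom_site.cartn_x", "_atom_site_cartn_x"))),
                 .cif_num(gc1(atom_loop, c("_atom_site.cartn_y", "_atom_site_cartn_y"))),
                 .cif_num(gc1(atom_loop, c("_atom_site.cartn_z", "_atom_site_cartn_z"))))
    fr <- xyz %*% t(solve(frac_to_cart_matrix(cell)))
  }
  elraw <- gc1(atom_loop, c("_atom_site.type_symbol", "_atom_site_type_symbol"))
  if (is.null(elraw)) stop("no element (type_symbol) column in ", path)
  ec <- lapply(elraw, .parse_element_charge)
  occ <- gc1(atom_loop, c("_atom_site.occupancy", "_atom_site_occupancy"))
  biso <- gc1(atom_loop, c("_atom_site.b_iso_or_equiv", "_atom_site_b_iso_or_equiv"))
  uiso <- gc1(atom_loop, c("_atom_site_u_iso_or_equiv"))
  lab <- gc1(atom_loop, c("_atom_site.label_atom_id", "_atom_site_label", "_atom_site.id"))
  alt <- gc1(atom_loop, c("_atom_site.label_alt_id", "_atom_site_label_alt_id"))
  resname <- gc1(atom_loop, c("_atom_site.label_comp_id", "_atom_site_label_comp_id"))
  resid <- gc1(atom_loop, c("_atom_site.label_seq_id", "_atom_site_label_seq_id"))
  chain <- gc1(atom_loop, c("_atom_site.label_asym_id", "_atom_site_label_asym_id"))
  clean <- function(x) ifelse(is.null(x) | x %in% c(".", "?"), "", x)
  b <- if (!is.null(biso)) .cif_num(biso) else if (!is.null(uiso)) 8 * pi^2 * .cif_num(uiso)
       else numeric(n)
  sites <- data.frame(
    label = if (!is.null(lab)) lab else paste0(vapply(ec, `[[`, "", "symbol"), seq_len(n)),
    element = vapply(ec, `[[`, "", "symbol"),
    fx = fr[, 1], fy = fr[, 2], fz = fr[, 3],
    occ = if (!is.null(occ)) .cif_num(occ) else rep(1, n),
    biso = ifelse(is.na(b), 0, b),
    altloc = if (!is.null(alt)) clean(alt) else rep("", n),
    charge = vapply(ec, `[[`, 0, "charge"),
    resname = if (!is.null(resname)) resname else rep("LIG", n),
    resid = if (!is.null(resid)) suppressWarnings(as.integer(resid)) else rep(1L, n),
    chain = if (!is.null(chain)) chain else rep("A", n),
    stringsAsFactors = FALSE)
  sites$is_water <- sites$resname %in% c("HOH", "WAT", "DOD")
  sites$resid[is.na(sites$resid)] <- 1L
  # anisotropic loop
  u_aniso <- vector("list", n)
  for (lp in p$loops) {
    if (!any(grepl("anisotrop|aniso_u", names(lp)))) next
    gid <- gc1(lp, c("_atom_site_anisotrop.id", "_atom_site_aniso_label"))
    u11 <- gc1(lp, c("_atom_site_anisotrop.u[1][1]", "_atom_site_aniso_u_11"))
    if (is.null(u11)) next
    g <- function(a, b2) .cif_num(gc1(lp, c(a, b2)))
    u22 <- g("_atom_site_anisotrop.u[2][2]", "_atom_site_aniso_u_22")
    u33 <- g("_atom_site_anisotrop.u[3][3]", "_atom_site_aniso_u_33")
    u12 <- g("_atom_site_anisotrop.u[1][2]", "_atom_site_aniso_u_12")
    u13 <- g("_atom_site_anisotrop.u[1][3]", "_atom_site_aniso_u_13")
    u23 <- g("_atom_site_anisotrop.u[2][3]", "_atom_site_aniso_u_23")
    idx <- match(gid, sites$label)
    if (all(is.na(idx))) idx <- seq_along(gid)
    u11 <- .cif_num(u11)
    for (j in seq_along(idx)) {
      i <- idx[j]
      if (is.na(i)) next
      u_aniso[[i]] <- matrix(c(u11[j], u12[j], u13[j],
                               u12[j], u22[j], u23[j],
                               u13[j], u23[j], u33[j]), 3, 3)
    }
  }
  if (is.null(ops)) {
    crystal_structure(cell, sites, spacegroup = sg, u_aniso = u_aniso)
  } else {
    st <- crystal_structure(cell, sites, spacegroup = ops, u_aniso = u_aniso)
    st$spacegroup <- sg
    st
  }
}

.write_mmcif <- function(structure, path) {
  cell <- structure$cell
  num <- function(x) sprintf("%.6f", x)
  ops_xyz <- vapply(structure$ops, .symop_to_xyz, "")
  xyz <- site_cart(structure)
  s <- structure$sites
  out <- c("data_taamsf",
           paste("_cell.length_a", num(cell$a)), paste("_cell.length_b", num(cell$b)),
           paste("_cell.length_c", num(cell$c)), paste("_cell.angle_alpha", num(cell$alpha)),
           paste("_cell.angle_beta", num(cell$beta)), paste("_cell.angle_gamma", num(cell$gamma)),
           sprintf("_symmetry.space_group_name_H-M '%s'", .sg_pdb_symbol(structure$spacegroup)),
           "loop_", "_space_group_symop.operation_xyz",
           sprintf("'%s'", ops_xyz),
           "loop_",
           "_atom_site.group_PDB", "_atom_site.id", "_atom_site.label_atom_id",
           "_atom_site.label_alt_id", "_atom_site.label_comp_id", "_atom_site.label_asym_id",
           "_atom_site.label_seq_id", "_atom_site.Cartn_x", "_atom_site.Cartn_y",
           "_atom_site.Cartn_z", "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
           "_atom_site.type_symbol")
  alt <- ifelse(nzchar(s$altloc), s$altloc, ".")
  out <- c(out, sprintf("%s %d %s %s %s %s %d %s %s %s %s %s %s",
                        ifelse(s$is_water, "HETATM", "ATOM"), seq_len(nrow(s)), s$label, alt,
                        s$resname, s$chain, s$resid, num(xyz[, 1]), num(xyz[, 2]), num(xyz[, 3]),
                        num(s$occ), num(s$biso), s$element))
  has_u <- !vapply(structure$u_aniso, is.null, TRUE)
  if (any(has_u)) {
    out <- c(out, "loop_", "_atom_site_anisotrop.id",
             "_atom_site_anisotrop.U[1][1]", "_atom_site_anisotrop.U[2][2]",
             "_atom_site_anisotrop.U[3][3]", "_atom_site_anisotrop.U[1][2]",
             "_atom_site_anisotrop.U[1][3]", "_atom_site_anisotrop.U[2][3]")
    for (i in which(has_u)) {
      U <- structure$u_aniso[[i]]
      out <- c(out, paste(s$label[i], num(U[1, 1]), num(U[2, 2]), num(U[3, 3]),
                          num(U[1, 2]), num(U[1, 3]), num(U[2, 3])))
    }
  }
  writeLines(out, path)
  invisible(path)
}

.write_small_cif <- function(structure, path) {
  cell <- structure$cell
  num <- function(x) sprintf("%.6f", x)
  s <- structure$sites
  out <- c("data_taamsf_small",
           paste("_cell_length_a", num(cell$a)), paste("_cell_length_b", num(cell$b)),
           paste("_cell_length_c", num(cell$c)), paste("_cell_angle_alpha", num(cell$alpha)),
           paste("_cell_angle_beta", num(cell$beta)), paste("_cell_angle_gamma", num(cell$gamma)),
           sprintf("_symmetry_space_group_name_H-M '%s'", .sg_pdb_symbol(structure$spacegroup)),
           "loop_", "_symmetry_equiv_pos_as_xyz",
           sprintf("'%s'", vapply(structure$ops, .symop_to_xyz, "")),
           "loop_",
           "_atom_site_label", "_atom_site_type_symbol",
           "_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z",
           "_atom_site_occupancy", "_atom_site_U_iso_or_equiv",
           sprintf("%s %s %s %s %s %s %s", s$label, s$element, num(s$fx), num(s$fy), num(s$fz),
                   num(s$occ), num(s$biso / (8 * pi^2))))
  writeLines(out, path)
  invisible(path)
}

.symop_to_xyz <- function(op) {
  fr <- function(v) {
    if (abs(v) < 1e-9) return("")
    f <- c("1/2" = 0.5, "1/3" = 1/3, "2/3" = 2/3, "1/4" = 0.25, "3/4" = 0.75)
    k <- names(f)[which(abs(f - (v %% 1)) < 1e-9)][1]
    if (is.na(k)) sprintf("%+g", v) else paste0("+", k)
  }
  axes <- c("x", "y", "z")
  comp <- character(3)
  for (i in 1:3) {
    terms <- ""
    for (j in 1:3) {
      c0 <- op$rot[i, j]
      if (c0 == 1) terms <- paste0(terms, if (nzchar(terms)) "+" else "", axes[j])
      else if (c0 == -1) terms <- paste0(terms, "-", axes[j])
    }
    comp[i] <- paste0(terms, fr(op$trans[i]))
  }
  paste(comp, collapse = ",")
}

# ---------------------------------------------------------------------------
# Reflection generation

#' Generate unique reflections to a resolution limit
#'
#' Enumerates all Miller indices with d >= d_min, keeps one representative
#' per Friedel pair (the lexicographically largest of h and -h) and excludes
#' the origin unless `include_000` is set.
#'
#' @param structure A `crystal_structure` (only the cell is used), or a
#'   `unit_cell`.
#' @param d_min Resolution limit in Angstrom (> 0).
#' @param include_000 Include the (0,0,0) reflection?
#' @return A `miller_set`: list with integer matrix `hkl`, vectors `s` and
#'   `d`, and the `cell`.
#' @export
generate_reflections <- function(structure, d_min, include_000 = FALSE) {
  if (d_min <= 0) stop("d_min must be positive")
  cell <- if (inherits(structure, "unit_cell")) structure else structure$cell
  hmax <- ceiling(cell$a / d_min) + 1
  kmax <- ceiling(cell$b / d_min) + 1
  lmax <- ceiling(cell$c / d_min) + 1
  grid <- as.matrix(expand.grid(h = -hmax:hmax, k = -kmax:kmax, l = -lmax:lmax))
  sv <- scattering_vectors(grid, cell)
  keep <- sv$d >= d_min & sv$d < Inf
  hkl <- grid[keep, , drop = FALSE]
  # Friedel representative: lexicographically largest of (h,k,l) vs -(h,k,l)
  flip <- (hkl[, 1] < 0) |
    (hkl[, 1] == 0 & hkl[, 2] < 0) |
    (hkl[, 1] == 0 & hkl[, 2] == 0 & hkl[, 3] < 0)
  hkl[flip, ] <- -hkl[flip, , drop = FALSE]
  hkl <- unique(hkl)
  hkl <- hkl[order(hkl[, 1], hkl[, 2], hkl[, 3]), , drop = FALSE]
  if (include_000) hkl <- rbind(c(0L, 0L, 0L), hkl)
  miller_set(hkl, cell)
}

#' Construct a Miller set
#'
#' @param hkl Integer matrix of Miller indices (rows).
#' @param cell A `unit_cell`.
#' @return A `miller_set` with `s = 1/(2 d)` per reflection.
#' @export
miller_set <- function(hkl, cell) {
  hkl <- matrix(as.integer(round(hkl)), ncol = 3)
  colnames(hkl) <- c("h", "k", "l")
  sv <- scattering_vectors(hkl, cell)
  structure(list(hkl = hkl, s = sv$s, d = sv$d, g = sv$g, cell = cell),
            class = "miller_set")
}

#' @export
print.miller_set <- function(x, ...) {
  cat(sprintf("miller set: %d reflections, d range %.3f - %.3f A\n",
              nrow(x$hkl), min(x$d), suppressWarnings(max(x$d[is.finite(x$d)]))))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Structure-factor files

#' Write structure factors
#'
#' `hkl-text` is a whitespace-delimited table (h k l amplitude phase_deg)
#' with a commented header; `cif-sf` is a small CIF `_refln` loop.  Phases
#' are stored in degrees in [-180, 180).  Round-tripping reproduces
#' amplitudes and phases to at least 6 significant digits.
#'
#' @param sf A `structure_factor_set`.
#' @param path Output file.
#' @param format "hkl-text" or "cif-sf".
#' @return `path`, invisibly.
#' @export
write_structure_factors <- function(sf, path, format = c("hkl-text", "cif-sf")) {
  format <- match.arg(format)
  amp <- Mod(sf$f)
  ph <- Arg(sf$f) * 180 / pi
  ph <- ((ph + 180) %% 360) - 180
  # keep the stored (9-decimal) representation inside [-180, 180)
  ph <- round(ph, 9)
  ph[ph >= 180] <- ph[ph >= 180] - 360
  hkl <- sf$miller$hkl
  if (format == "hkl-text") {
    out <- c(sprintf("# taamsf structure factors; radiation=%s mode=%s n=%d",
                     sf$radiation, sf$mode, length(sf$f)),
             "# h k l amplitude phase_deg")
    if (length(sf$f)) {
      out <- c(out, sprintf("%4d %4d %4d %15.8e %15.9f", hkl[, 1], hkl[, 2], hkl[, 3], amp, ph))
    }
  } else {
    out <- c("data_taamsf_sf",
             sprintf("_taamsf.radiation %s", sf$radiation),
             sprintf("_taamsf.mode %s", sf$mode),
             "loop_", "_refln.index_h", "_refln.index_k", "_refln.index_l",
             "_refln.F_calc", "_refln.phase_calc")
    if (length(sf$f)) {
      out <- c(out, sprintf("%d %d %d %.8e %.9f", hkl[, 1], hkl[, 2], hkl[, 3], amp, ph))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Read structure factors written by [write_structure_factors()]
#'
#' @param path File path.
#' @param cell Optional `unit_cell` for resolution bookkeeping; defaults to a
#'   unit cube (s and d are then placeholders).
#' @return A `structure_factor_set`.
#' @export
read_structure_factors <- function(path, cell = unit_cell(1, 1, 1)) {
  lines <- readLines(path)
  if (any(grepl("^data_", lines))) {
    p <- .cif_parse(path)
    radiation <- p$items[["_taamsf.radiation"]] %||% "xray"
    mode <- p$items[["_taamsf.mode"]] %||% "iam"
    lp <- NULL
    for (l2 in p$loops) if ("_refln.index_h" %in% names(l2)) lp <- l2
    if (is.null(lp)) {
      hkl <- matrix(integer(0), 0, 3); amp <- numeric(0); ph <- numeric(0)
    } else {
      hkl <- cbind(as.integer(lp[["_refln.index_h"]]), as.integer(lp[["_refln.index_k"]]),
                   as.integer(lp[["_refln.index_l"]]))
      amp <- as.numeric(lp[["_refln.f_calc"]]); ph <- as.numeric(lp[["_refln.phase_calc"]])
    }
  } else {
    hdr <- grep("^#", lines, value = TRUE)
    radiation <- if (any(grepl("radiation=electron", hdr))) "electron" else "xray"
    mode <- if (any(grepl("mode=taam", hdr))) "taam" else "iam"
    body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
    if (length(body) == 0) {
      hkl <- matrix(integer(0), 0, 3); amp <- numeric(0); ph <- numeric(0)
    } else {
      m <- do.call(rbind, lapply(strsplit(trimws(body), "[[:space:]]+"), as.numeric))
      hkl <- matrix(as.integer(m[, 1:3]), ncol = 3); amp <- m[, 4]; ph <- m[, 5]
    }
  }
  structure_factor_set(miller_set(hkl, cell), complex(modulus = amp, argument = ph * pi / 180),
                       radiation = radiation, mode = mode)
}

#' Construct a structure-factor set
#'
#' @param miller A `miller_set`.
#' @param f Complex structure factors, one per reflection.
#' @param radiation "xray" or "electron".
#' @param mode "iam" or "taam".
#' @return A `structure_factor_set`.
#' @export
structure_factor_set <- function(miller, f, radiation = "xray", mode = "iam") {
  if (length(f) != nrow(miller$hkl)) stop("length(f) must match the miller set")
  if (any(!is.finite(f))) stop("non-finite structure factors")
  structure(list(miller = miller, f = f, radiation = radiation, mode = mode),
            class = "structure_factor_set")
}

#' @export
print.structure_factor_set <- function(x, ...) {
  cat(sprintf("structure factors: %d reflections, %s %s\n",
              length(x$f), x$mode, x$radiation))
  invisible(x)
}

# ---------------------------------------------------------------------------
# CCP4/MRC maps

#' Construct a real-space map
#'
#' @param values Numeric 3D array on the periodic grid (axis order x, y, z in
#'   fractional coordinates).
#' @param cell A `unit_cell`.
#' @param quantity "electron-density" (e/A^3) or "electrostatic-potential"
#'   (1/A^2).
#' @param f000 The DC term used in synthesis, or NA when excluded (the map
#'   then has zero mean and is flagged).
#' @return A `real_space_map`.
#' @export
real_space_map <- function(values, cell, quantity = "electron-density", f000 = NA) {
  d <- dim(values)
  if (length(d) != 3 || any(d < 2)) stop("map grid must be 3D with at least 2 points per axis")
  structure(list(values = values, dim = d, cell = cell, quantity = quantity, f000 = f000),
            class = "real_space_map")
}

#' @export
print.real_space_map <- function(x, ...) {
  cat(sprintf("real-space map %dx%dx%d (%s), mean %.4g, rms %.4g\n",
              x$dim[1], x$dim[2], x$dim[3], x$quantity, mean(x$values),
              stats::sd(as.numeric(x$values))))
  invisible(x)
}

#' Write a CCP4/MRC map file
#'
#' Mode-2 (32-bit float) CCP4/MRC with cell and axis-order metadata;
#' [read_map()] reproduces the values bitwise (after the float32 rounding
#' applied on write).
#'
#' @param map A `real_space_map`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  d <- map$dim
  vals <- as.numeric(map$values)
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)               # NC, NR, NS
  wi(2)               # mode 2: float32
  wi(c(0, 0, 0))      # start
  wi(d)               # intervals MX, MY, MZ
  wf(c(map$cell$a, map$cell$b, map$cell$c, map$cell$alpha, map$cell$beta, map$cell$gamma))
  wi(c(1, 2, 3))      # axis order
  wf(c(min(vals), max(vals), mean(vals)))
  wi(1)               # ISPG
  wi(0)               # NSYMBT
  wi(rep(0, 25))      # extra
  wi(c(0, 0, 0))      # origin
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(vals))
  wi(1)               # NLABL
  lab <- sprintf("taamsf %s map", map$quantity)
  writeChar(formatC(lab, width = 80, flag = "-"), con, 80, eos = NULL)
  writeChar(paste(rep(" ", 80 * 9), collapse = ""), con, 80 * 9, eos = NULL)
  wf(vals)
  invisible(path)
}

#' Read a CCP4/MRC map file
#'
#' @param path Map file written by [write_map()] (mode 2, axis order 1,2,3).
#' @return A `real_space_map`.
#' @export
read_map <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  d <- ri(3)
  mode <- ri(1)
  if (mode != 2) stop("unsupported MRC mode: ", mode)
  ri(3); mx <- ri(3)
  cellpar <- rf(6)
  axes <- ri(3)
  if (!identical(axes, c(1L, 2L, 3L))) stop("unsupported axis order in map")
  rf(3); ri(1)
  nsymbt <- ri(1)
  ri(25); ri(3)
  magic <- readChar(con, 4, useBytes = TRUE)
  if (magic != "MAP ") stop("not a CCP4/MRC map: ", path)
  readBin(con, "raw", 4)
  rf(1)
  nlabl <- ri(1)
  readChar(con, 800, useBytes = TRUE)
  if (nsymbt > 0) readBin(con, "raw", nsymbt)
  vals <- rf(prod(d))
  cell <- unit_cell(cellpar[1], cellpar[2], cellpar[3], cellpar[4], cellpar[5], cellpar[6])
  real_space_map(array(vals, dim = d), cell)
}
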