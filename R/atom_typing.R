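# Chemistry-aware atom typing: bonding connectivity from covalent radii,
# ring perception (minimum cycle basis), planarity, bank-type matching with
# a most-specific-first rule, local-frame construction and the three-level
# representation fallback (multipolar -> spherical Slater -> Gaussian IAM).

#' Build bonding connectivity from geometry
#'
#' Atoms i and j are bonded iff `0.4 <= d(i,j) <= r(i) + r(j) + tolerance`,
#' where d is the minimum distance over all symmetry images (including
#' lattice translations).  Hydrogens keep only the bond to their nearest
#' heavy atom (ties broken by the lower atom index).  Atom pairs closer than
#' 0.4 Angstrom are mutually invisible to bonding when their altloc labels
#' differ; with the same altloc they are recorded as clashes.
#'
#' @param structure A `crystal_structure`.
#' @param radii Named per-element covalent radii in Angstrom
#'   (default [covalent_radii()]).
#' @param tolerance Bonding tolerance in Angstrom (default 0.40).
#' @return A `bond_graph`: list with `edges` (data frame i, j, d, and the
#'   Cartesian vector vx, vy, vz from i to the bonded image of j), `adj`
#'   (adjacency index list), `clashes` (data frame of same-altloc overlaps)
#'   and `overlap` (logical per atom: involved in a different-altloc overlap).
#' @export
build_bond_graph <- function(structure, radii = covalent_radii(), tolerance = 0.40) {
  if (tolerance < 0) stop("tolerance must be non-negative")
  s <- structure$sites
  n <- nrow(s)
  M <- frac_to_cart_matrix(structure$cell)
  fr <- as.matrix(s[, c("fx", "fy", "fz")])
  r_el <- radii[s$element]
  if (any(is.na(r_el))) stop("no covalent radius for element(s): ",
                             paste(unique(s$element[is.na(r_el)]), collapse = ", "))
  edges <- NULL
  clashes <- NULL
  overlap <- logical(n)
  # minimum-image vector from i to the nearest symmetry image of j
  min_image <- function(i, j) {
    best <- NULL; bestd <- Inf
    for (op in structure$ops) {
      fj <- as.numeric(op$rot %*% fr[j, ] + op$trans)
      dfr <- fj - fr[i, ]
      dfr <- dfr - round(dfr)
      v <- as.numeric(M %*% dfr)
      d <- sqrt(sum(v^2))
      if (d < bestd && !(d < 1e-6 && i == j)) { bestd <- d; best <- v }
      if (i == j && d < 1e-6) next
    }
    list(d = bestd, v = best)
  }
  cutmax <- max(r_el) * 2 + tolerance
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      mi <- min_image(i, j)
      if (mi$d > cutmax) next
      cut <- r_el[i] + r_el[j] + tolerance
      alt_i <- s$altloc[i]; alt_j <- s$altloc[j]
      if (mi$d < 0.4) {
        if (nzchar(alt_i) && nzchar(alt_j) && alt_i != alt_j) {
          overlap[c(i, j)] <- TRUE          # mutually invisible
        } else {
          clashes <- rbind(clashes, data.frame(i = i, j = j, d = mi$d))
        }
        next
      }
      if (nzchar(alt_i) && nzchar(alt_j) && alt_i != alt_j) next
      if (mi$d <= cut) {
        edges <- rbind(edges, data.frame(i = i, j = j, d = mi$d,
                                         vx = mi$v[1], vy = mi$v[2], vz = mi$v[3]))
      }
    }
  }
  if (is.null(edges)) edges <- data.frame(i = integer(0), j = integer(0), d = numeric(0),
                                          vx = numeric(0), vy = numeric(0), vz = numeric(0))
  if (!is.null(clashes) && nrow(clashes)) {
    warning(sprintf("%d same-altloc clash(es) below 0.4 A recorded", nrow(clashes)))
  } else clashes <- data.frame(i = integer(0), j = integer(0), d = numeric(0))
  # hydrogen monovalence: keep only the nearest heavy-atom bond
  is_h <- element_z(s$element) == 1
  keep <- rep(TRUE, nrow(edges))
  for (a in which(is_h)) {
    rows <- which(edges$i == a | edges$j == a)
    if (length(rows) <= 1) next
    partner <- ifelse(edges$i[rows] == a, edges$j[rows], edges$i[rows])
    heavy <- !is_h[partner]
    cand <- rows[heavy]
    if (length(cand) == 0) cand <- rows
    best <- cand[order(edges$d[cand], pmin(edges$i[cand], edges$j[cand]))][1]
    keep[setdiff(rows, best)] <- FALSE
  }
  edges <- edges[keep, , drop = FALSE]
  rownames(edges) <- NULL
  adj <- lapply(seq_len(n), function(a) {
    rows <- which(edges$i == a | edges$j == a)
    partner <- ifelse(edges$i[rows] == a, edges$j[rows], edges$i[rows])
    sgn <- ifelse(edges$i[rows] == a, 1, -1)
    list(idx = partner,
         vec = if (length(rows)) cbind(sgn * edges$vx[rows], sgn * edges$vy[rows],
                                       sgn * edges$vz[rows]) else matrix(0, 0, 3),
         d = edges$d[rows])
  })
  structure(list(edges = edges, adj = adj, n = n, clashes = clashes, overlap = overlap),
            class = "bond_graph")
}

#' Neighbour indices of an atom
#' @param graph A `bond_graph`.
#' @param i Atom index.
#' @return Integer vector of bonded atom indices.
#' @export
neighbours <- function(graph, i) graph$adj[[i]]$idx

# ---------------------------------------------------------------------------
# Ring perception (minimum cycle basis, sizes 3-8)

# All simple cycles up to maxlen, deduplicated, as sorted vertex sets with an
# ordered vertex path attribute.
.simple_cycles <- function(adj, n, maxlen = 8) {
  cycles <- list()
  seen <- character(0)
  for (start in seq_len(n)) {
    stack <- list(list(path = start))
    while (length(stack)) {
      fr <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      last <- fr$path[length(fr$path)]
      for (nx in adj[[last]]$idx) {
        if (nx == start && length(fr$path) >= 3) {
          key <- paste(sort(fr$path), collapse = ",")
          if (!key %in% seen) { seen <- c(seen, key); cycles[[length(cycles) + 1]] <- fr$path }
        } else if (nx > start && !nx %in% fr$path && length(fr$path) < maxlen) {
          stack[[length(stack) + 1]] <- list(path = c(fr$path, nx))
        }
      }
    }
  }
  cycles
}

.edge_key <- function(i, j) paste(pmin(i, j), pmax(i, j))

# GF(2) independence over edge space, greedy by cycle length (Horton).
.min_cycle_basis <- function(cycles, edges, n_vert) {
  if (length(cycles) == 0) return(list())
  m <- nrow(edges)
  if (m == 0) return(list())
  ekeys <- .edge_key(edges$i, edges$j)
  comp_count <- length(unique(.components(edges, n_vert)))
  target <- m - n_vert + comp_count
  if (target <= 0) return(list())
  cycles <- cycles[order(vapply(cycles, length, 0L))]
  basis <- list(); rows <- NULL
  for (cy in cycles) {
    vec <- rep(0L, m)
    k <- length(cy)
    for (t in seq_len(k)) {
      e <- .edge_key(cy[t], cy[t %% k + 1])
      vec[match(e, ekeys)] <- 1L
    }
    # Gaussian elimination over GF(2)
    red <- vec
    if (!is.null(rows)) {
      for (ri in seq_len(nrow(rows))) {
        piv <- which(rows[ri, ] == 1L)[1]
        if (red[piv] == 1L) red <- (red + rows[ri, ]) %% 2L
      }
    }
    if (any(red == 1L)) {
      rows <- rbind(rows, red)
      basis[[length(basis) + 1]] <- cy
      if (length(basis) == target) break
    }
  }
  basis
}

.components <- function(edges, n) {
  comp <- seq_len(n)
  find <- function(x) { while (comp[x] != x) x <- comp[x]; x }
  for (r in seq_len(nrow(edges))) {
    a <- find(edges$i[r]); b <- find(edges$j[r])
    if (a != b) comp[max(a, b)] <- min(a, b)
  }
  vapply(seq_len(n), find, 0L)
}

#' Perceive rings
#'
#' Annotates every atom with the sizes of the rings (from a minimum cycle
#' basis, sizes 3-8) it belongs to.
#'
#' @param graph A `bond_graph`.
#' @return List per atom of integer ring sizes (empty when not in a ring);
#'   the basis cycles are attached as the "cycles" attribute.
#' @export
perceive_rings <- function(graph) {
  cycles <- .simple_cycles(graph$adj, graph$n, maxlen = 8)
  basis <- .min_cycle_basis(cycles, graph$edges, graph$n)
  out <- lapply(seq_len(graph$n), function(i) integer(0))
  for (cy in basis) {
    for (v in cy) out[[v]] <- c(out[[v]], length(cy))
  }
  attr(out, "cycles") <- basis
  out
}

#' Planarity of an atom's bonded environment
#'
#' TRUE iff the RMS out-of-plane deviation of the atom and its bonded
#' neighbours from their best-fit plane is below `threshold`.  Atoms with
#' fewer than three neighbours return NA (treated as non-planar by match
#' rules).
#'
#' @param i Atom index.
#' @param graph A `bond_graph`.
#' @param structure The `crystal_structure` the graph was built on.
#' @param threshold RMS threshold in Angstrom (default 0.10).
#' @return TRUE, FALSE or NA.
#' @export
planarity <- function(i, graph, structure, threshold = 0.10) {
  nb <- graph$adj[[i]]
  if (length(nb$idx) < 3) return(NA)
  pts <- rbind(c(0, 0, 0), nb$vec)     # atom at origin plus bond vectors
  ctr <- sweep(pts, 2, colMeans(pts))
  sv <- svd(ctr)
  rms <- sqrt(mean((ctr %*% sv$v[, 3])^2))
  rms < threshold
}

# ---------------------------------------------------------------------------
# Type matching

.element_counts <- function(els) {
  if (length(els) == 0) return(stats::setNames(integer(0), character(0)))
  t0 <- table(els)
  stats::setNames(as.integer(t0), names(t0))
}

# second shell: atoms at graph distance exactly 2
.second_shell <- function(graph, i) {
  nb1 <- graph$adj[[i]]$idx
  nb2 <- unique(unlist(lapply(nb1, function(j) graph$adj[[j]]$idx)))
  setdiff(nb2, c(i, nb1))
}

.match_entry <- function(entry, i, structure, graph, rings, planar_flags) {
  mr <- entry$match_rule
  if (entry$element != structure$sites$element[i]) return(-1L)
  score <- 0L
  if (!is.null(mr$nbr)) {
    have <- .element_counts(structure$sites$element[graph$adj[[i]]$idx])
    key <- function(x) paste(sprintf("%s:%d", names(x), as.integer(x))[order(names(x))],
                             collapse = ",")
    if (key(mr$nbr) != key(have)) return(-1L)
    score <- score + 1L
  }
  if (!is.null(mr$nbr2)) {
    shell2 <- .second_shell(graph, i)
    have <- .element_counts(structure$sites$element[shell2])
    for (el in names(mr$nbr2)) {
      if (is.na(have[el]) || have[el] < mr$nbr2[el]) return(-1L)
    }
    score <- score + 1L
  }
  if (mr$planar != "any") {
    fl <- planar_flags[i]
    is_planar <- !is.na(fl) && fl
    if ((mr$planar == "yes") != is_planar) return(-1L)
    score <- score + 1L
  }
  if (mr$ring != "any") {
    in_ring <- length(rings[[i]]) > 0
    if ((mr$ring == "yes") != in_ring) return(-1L)
    score <- score + 1L
  }
  score
}

# Resolve a frame-recipe selector to a Cartesian direction from atom i.
# Returns NULL when unresolvable.  `exclude` is an atom index to skip.
.resolve_selector <- function(sel, i, structure, graph, exclude = integer(0)) {
  if (startsWith(sel, "2:")) {
    want <- sub("^2:", "", sel)
    shell2 <- setdiff(.second_shell(graph, i), exclude)
    if (want != "any") {
      shell2 <- shell2[structure$sites$element[shell2] == want]
    }
    if (length(shell2) == 0) return(NULL)
    j <- min(shell2)
    # geometric direction: through-space vector using minimum image
    M <- frac_to_cart_matrix(structure$cell)
    dfr <- as.numeric(structure$sites[j, c("fx", "fy", "fz")]) -
      as.numeric(structure$sites[i, c("fx", "fy", "fz")])
    dfr <- dfr - round(dfr)
    return(list(atom = j, v = as.numeric(M %*% dfr)))
  }
  nb <- graph$adj[[i]]
  cand <- seq_along(nb$idx)
  cand <- cand[!nb$idx[cand] %in% exclude]
  if (sel != "any") cand <- cand[structure$sites$element[nb$idx[cand]] == sel]
  if (length(cand) == 0) return(NULL)
  k <- cand[order(nb$idx[cand])][1]
  list(atom = nb$idx[k], v = nb$vec[k, ])
}

#' Build a local coordinate frame for a typed atom
#'
#' Z axis along the recipe's first direction; X is the Gram-Schmidt
#' complement of the second direction against Z; Y completes the
#' right-handed frame.  Returns NULL when a recipe neighbour is missing or
#' the two directions are collinear (the caller demotes the atom).
#'
#' @param i Atom index.
#' @param recipe Frame recipe (list with `z`, `x` selectors).
#' @param structure A `crystal_structure`.
#' @param graph A `bond_graph`.
#' @return A `local_frame` (list with `origin` and 3x3 `rotation`, columns =
#'   local axes in crystal-Cartesian coordinates), or NULL.
#' @export
build_local_frame <- function(i, recipe, structure, graph) {
  if (is.null(recipe$z) || is.null(recipe$x)) return(NULL)
  selz <- .resolve_selector(recipe$z, i, structure, graph)
  if (is.null(selz)) return(NULL)
  selx <- .resolve_selector(recipe$x, i, structure, graph, exclude = selz$atom)
  if (is.null(selx)) return(NULL)
  z <- selz$v / sqrt(sum(selz$v^2))
  x0 <- selx$v - sum(selx$v * z) * z
  nx <- sqrt(sum(x0^2))
  if (nx < 1e-6) return(NULL)  # collinear -> degenerate
  x <- x0 / nx
  y <- pracma_cross(z, x)
  R <- unname(cbind(x, y, z))
  structure(list(origin = i, rotation = R), class = "local_frame")
}

#' Assign representation levels and bank types to every atom
#'
#' For each atom the most specific matching bank entry (constraint count
#' descending, ties by bank order) gives a multipolar assignment with a
#' local frame; otherwise an element with a Slater shell set (Z <= 36) falls
#' back to the spherical core + valence model, and anything else to the
#' Gaussian IAM.  Atoms in altloc overlaps or same-altloc clashes are forced
#' to Gaussian IAM; a matched atom whose frame recipe cannot be resolved is
#' demoted to spherical Slater ("incomplete-environment").
#'
#' @param structure A `crystal_structure`.
#' @param graph A `bond_graph` built on the same structure.
#' @param bank A `multipolar_bank`.
#' @param planarity_threshold RMS planarity threshold (Angstrom).
#' @return A `type_assignment`: data frame `atoms` (level, type_id, reason),
#'   list `frames`, and `coverage` (fraction multipolar).
#' @export
assign_atom_types <- function(structure, graph, bank, planarity_threshold = 0.10) {
  n <- n_sites(structure)
  s <- structure$sites
  rings <- perceive_rings(graph)
  planar_flags <- vapply(seq_len(n), function(i)
    planarity(i, graph, structure, planarity_threshold), NA)
  z <- element_z(s$element)
  clash_atoms <- unique(c(graph$clashes$i, graph$clashes$j))
  level <- character(n); type_id <- rep(NA_character_, n); reason <- character(n)
  frames <- vector("list", n)
  entry_scores <- function(i) {
    vapply(bank$entries, function(e) .match_entry(e, i, structure, graph,
                                                  rings, planar_flags), 0L)
  }
  for (i in seq_len(n)) {
    el <- s$element[i]
    has_slater <- !is.null(bank$slater[[el]]) && z[i] <= 36
    in_gauss <- any(vapply(bank$gauss, function(tb) !is.null(tb$coef[[el]]), TRUE))
    if (!in_gauss && !has_slater)
      stop("element ", el, " has no Gaussian coefficients in any table (atom ", s$label[i], ")")
    if (graph$overlap[i]) {
      level[i] <- "gaussian-iam"; reason[i] <- "altloc-overlap"; next
    }
    if (i %in% clash_atoms) {
      level[i] <- "gaussian-iam"; reason[i] <- "clash"; next
    }
    sc <- entry_scores(i)
    best <- which(sc == max(sc) & sc >= 0)
    if (length(best) && max(sc) >= 0) {
      # most specific first; ties resolved by bank order (lowest index)
      cand <- best[1]
      fr <- build_local_frame(i, bank$entries[[cand]]$frame_recipe, structure, graph)
      if (is.null(fr)) {
        if (has_slater) {
          level[i] <- "spherical-slater"; reason[i] <- "incomplete-environment"
        } else {
          level[i] <- "gaussian-iam"; reason[i] <- "incomplete-environment"
        }
      } else {
        level[i] <- "multipolar"
        type_id[i] <- names(bank$entries)[cand]
        reason[i] <- "matched"
        frames[[i]] <- fr
      }
      next
    }
    # no matching type: explain the common hydrogen-dependency case
    el_entries <- Filter(function(e) e$element == el, bank$entries)
    nb_els <- s$element[graph$adj[[i]]$idx]
    rules_need_h <- vapply(el_entries, function(e) !is.null(e$match_rule$nbr) &&
                             "H" %in% names(e$match_rule$nbr), TRUE)
    needs_h <- length(el_entries) > 0 &&
      (all(rules_need_h) || (s$is_water[i] && any(rules_need_h)))
    if (has_slater) {
      level[i] <- "spherical-slater"
      reason[i] <- if (needs_h && !"H" %in% nb_els) "no-H-neighbour" else "no-matching-type"
    } else {
      level[i] <- "gaussian-iam"
      reason[i] <- if (z[i] > 36) "Z>36-no-slater" else "no-matching-type"
    }
  }
  structure(list(
    atoms = data.frame(label = s$label, element = s$element, level = level,
                       type_id = type_id, reason = reason, stringsAsFactors = FALSE),
    frames = frames,
    coverage = if (n > 0) sum(level == "multipolar") / n else NA_real_),
    class = "type_assignment")
}

#' @export
print.type_assignment <- function(x, ...) {
  cat(sprintf("type assignment: %d atoms, %.1f%% multipolar\n",
              nrow(x$atoms), 100 * x$coverage))
  invisible(x)
}

#' Typing coverage report
#'
#' Per-level counts and percentages (summing to 100), the multipolar
#' percentage recommended for inspection, and per-atom reasons.
#'
#' @param assignment A `type_assignment`.
#' @param json Return a JSON string instead of a list?
#' @return List (or JSON string) with `counts`, `percent`,
#'   `percent_multipolar` and `atoms`.
#' @export
type_coverage_report <- function(assignment, json = FALSE) {
  lv <- factor(assignment$atoms$level,
               levels = c("multipolar", "spherical-slater", "gaussian-iam"))
  counts <- table(lv)
  n <- nrow(assignment$atoms)
  pct <- if (n > 0) 100 * as.numeric(counts) / n else rep(0, 3)
  rep_list <- list(
    n_atoms = n,
    counts = stats::setNames(as.integer(counts), names(counts)),
    percent = stats::setNames(round(pct, 4), names(counts)),
    percent_multipolar = if (n > 0) round(100 * assignment$coverage, 4) else NA,
    atoms = assignment$atoms[, c("label", "element", "level", "type_id", "reason")]
  )
  if (json) jsonlite::toJSON(rep_list, auto_unbox = TRUE, pretty = TRUE, na = "null")
  else rep_list
}

#' Force an assignment to the Gaussian IAM level
#'
#' Utility for IAM-mode calculations and TAAM/IAM consistency checks: every
#' atom is mapped to level "gaussian-iam".
#'
#' @param assignment A `type_assignment`.
#' @return A `type_assignment`.
#' @export
force_iam <- function(assignment) {
  assignment$atoms$level <- "gaussian-iam"
  assignment$atoms$type_id <- NA_character_
  assignment$atoms$reason <- "forced-iam"
  assignment$frames <- vector("list", nrow(assignment$atoms))
  assignment$coverage <- 0
  assignment
}
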