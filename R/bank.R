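# Multipolar parameter bank: domain types, the line-oriented text schema,
# parser/writer, generated Slater shell sets and Gaussian IAM tables, and the
# fixture bank used throughout the tests.
#
# Schema (version 1), line oriented, '#' comments:
#
#   taamsf-bank 1
#
#   slater <El>                      # one Slater shell set per element
#     core  <coef> <n> <zeta> ...    # triples; zeta in 1/Angstrom
#     valence <coef> <n> <zeta> ...
#
#   gauss <dialect> <El> smax <smax>
#     a <a1> ... ; b <b1> ... ; c <c>
#
#   type <type_id>
#     element <El>
#     nbr H:4            # exact multiset of first neighbours
#     nbr2 C:1           # optional minimum counts two bonds away
#     planar yes|no|any
#     ring yes|no|any
#     frame z=<sel> x=<sel>          # sel: element | any | 2:element
#     pcore <v> ; pval <v> ; kappa <v> ; kprime <v>
#     nl <n0> <n1> <n2> <n3> <n4>    # radial powers for l = 0..4
#     zeta <v>
#     plm <l>,<m> <value>            # sparse; omitted populations are 0
#
# Exponents are on the Angstrom^-1 scale; a `unit bohr` line after
# `taamsf-bank` declares bohr^-1 input (converted on load).

GAUSS_DIALECTS <- c("four-gauss-const", "five-gauss", "electron-2invA", "electron-6invA")

# ---------------------------------------------------------------------------
# Constructors and validation

#' Construct a radial function description
#'
#' @param n_l Integer powers of r for l = 0..4 (length 5); `n_l[l+1] >= l`.
#' @param zeta Positive exponent (1/Angstrom).
#' @return A `radial_function`.
#' @export
radial_function <- function(n_l, zeta) {
  if (length(n_l) != 5 || any(n_l < 0) || any(n_l != round(n_l)))
    stop("n_l must be 5 non-negative integer powers (l = 0..4)")
  if (any(n_l < 0:4)) stop("radial powers must satisfy n_l >= l")
  if (zeta <= 0) stop("zeta must be positive")
  structure(list(n_l = as.integer(n_l), zeta = zeta,
                 normalization = "density-normalized"),
            class = "radial_function")
}

#' Construct a multipolar bank entry
#'
#' One transferable atom type: a matching rule over the local chemical
#' environment, a local-frame recipe, and Hansen-Coppens parameters.
#'
#' @param type_id Unique type identifier.
#' @param element Element symbol.
#' @param match_rule List with `nbr` (named integer vector, exact first-shell
#'   element counts), optional `nbr2` (minimum second-shell counts), `planar`
#'   and `ring` (each "yes", "no" or "any").
#' @param frame_recipe List with `z` and `x` neighbour selectors
#'   (element symbol, "any", or "2:<element>" for the second shell).
#' @param p_core,p_val Core and valence populations (electrons).
#' @param kappa,kappa_prime Contraction-expansion scalars (> 0).
#' @param p_lm Numeric vector of 25 real multipole populations, slots ordered
#'   (l, m) = (0,0), (1,-1)..(1,1), ..., (4,-4)..(4,4).
#' @param radial A [radial_function()].
#' @param core_valence_model A `slater_shell_set` for the element.
#' @return A `multipolar_entry`.
#' @export
multipolar_entry <- function(type_id, element, match_rule, frame_recipe,
                             p_core, p_val, kappa, kappa_prime, p_lm, radial,
                             core_valence_model) {
  if (length(p_lm) != 25)
    stop("p_lm must have exactly 25 slots (l = 0..4); got ", length(p_lm))
  if (kappa <= 0) stop("kappa must be positive in type ", type_id)
  if (kappa_prime <= 0) stop("kappa_prime must be positive in type ", type_id)
  if (p_core + p_val < 0) stop("p_core + p_val must be non-negative in type ", type_id)
  planar <- match_rule$planar %||% "any"
  ring <- match_rule$ring %||% "any"
  if (!planar %in% c("yes", "no", "any") || !ring %in% c("yes", "no", "any"))
    stop("planar/ring flags must be yes, no or any in type ", type_id)
  structure(list(type_id = type_id, element = element, z = element_z(element),
                 match_rule = list(nbr = match_rule$nbr, nbr2 = match_rule$nbr2,
                                   planar = planar, ring = ring),
                 frame_recipe = frame_recipe,
                 p_core = p_core, p_val = p_val,
                 kappa = kappa, kappa_prime = kappa_prime,
                 p_lm = as.numeric(p_lm), radial = radial,
                 core_valence_model = core_valence_model),
            class = "multipolar_entry")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
# Slater shell sets from screening rules

# Shell-group electron configurations (group principal n; "d3"/"d4" are the
# 3d/4d groups) for the supported elements.
.SLATER_CONFIG <- list(
  H  = list(c("1", 1)),
  C  = list(c("1", 2), c("2", 4)),
  N  = list(c("1", 2), c("2", 5)),
  O  = list(c("1", 2), c("2", 6)),
  F  = list(c("1", 2), c("2", 7)),
  P  = list(c("1", 2), c("2", 8), c("3", 5)),
  S  = list(c("1", 2), c("2", 8), c("3", 6)),
  Cl = list(c("1", 2), c("2", 8), c("3", 7)),
  Fe = list(c("1", 2), c("2", 8), c("3", 8), c("d3", 6), c("4", 2)),
  Br = list(c("1", 2), c("2", 8), c("3", 8), c("d3", 10), c("4", 7)),
  I  = list(c("1", 2), c("2", 8), c("3", 8), c("d3", 10), c("4", 8), c("d4", 10), c("5", 7))
)

.NSTAR <- c("1" = 1, "2" = 2, "3" = 3, "4" = 3.7, "5" = 4.0)

#' Generate a Slater shell set for an element
#'
#' Builds simple exponential shells (one per shell group) with exponents from
#' Slater's screening rules; each shell is density-normalized so the set
#' integrates exactly to Z electrons.  These are the package's reference
#' spherical densities for the core + spherical-valence model.
#'
#' @param element Element symbol or atomic number (Z <= 36 is the contract
#'   for typing fallback; sets can be generated for iodine as well, used only
#'   to seed Gaussian fits).
#' @return A `slater_shell_set` with fields `element`, `core`, `valence`
#'   (data frames with coef, n, zeta).
#' @export
slater_shell_set <- function(element) {
  info <- element_info(element)
  cfg <- .SLATER_CONFIG[[info$symbol]]
  if (is.null(cfg)) stop("no shell configuration for element ", info$symbol)
  groups <- data.frame(grp = vapply(cfg, `[`, "", 1),
                       count = as.numeric(vapply(cfg, `[`, "", 2)))
  groups$princ <- as.numeric(sub("^d", "", groups$grp))
  groups$is_d <- grepl("^d", groups$grp)
  shells <- data.frame(coef = numeric(0), n = integer(0), zeta = numeric(0))
  for (i in seq_len(nrow(groups))) {
    g <- groups[i, ]
    if (g$is_d) {
      sigma <- 0.35 * (g$count - 1) + sum(groups$count[seq_len(i - 1)])
    } else {
      same_minus1 <- groups$princ == g$princ - 1
      deeper <- groups$princ < g$princ - 1
      shield_inner <- if (g$princ == 1) 0.30 else 0.35
      sigma <- shield_inner * (g$count - 1) +
        0.85 * sum(groups$count[same_minus1 & seq_len(nrow(groups)) < i]) +
        1.00 * sum(groups$count[deeper])
    }
    zeta_orb <- (info$z - sigma) / .NSTAR[[as.character(g$princ)]]
    shells <- rbind(shells, data.frame(coef = g$count,
                                       n = as.integer(2 * (g$princ - 1)),
                                       zeta = 2 * zeta_orb / .A0))
  }
  nval <- info$n_val
  cum_from_end <- rev(cumsum(rev(shells$coef)))
  first_val <- which(cum_from_end <= nval + 1e-9)[1]
  core <- shells[seq_len(first_val - 1), , drop = FALSE]
  valence <- shells[first_val:nrow(shells), , drop = FALSE]
  rownames(core) <- rownames(valence) <- NULL
  out <- structure(list(element = info$symbol, z = info$z,
                        core = core, valence = valence),
                   class = "slater_shell_set")
  stopifnot(abs(sum(core$coef) + sum(valence$coef) - info$z) < 1e-9)
  out
}

# ---------------------------------------------------------------------------
# Gaussian tables (generated by constrained least-squares fits against the
# package's Slater-shell IAM form factors and their Mott-Bethe conversions)

.fit_gaussians <- function(s, f, n_gauss, constant, total, b_init) {
  # separable fit: Nelder-Mead over log(b), inner linear solve for a (and c),
  # with sum(a) + c == total enforced exactly when `total` is given.
  design <- function(logb) exp(-outer(s^2, exp(logb)))
  safe_ls <- function(M, y) {
    # tiny ridge keeps near-duplicate Gaussian widths from producing huge
    # cancelling amplitude pairs
    lam <- 1e-5 * max(abs(y))
    Ma <- rbind(M, diag(lam, ncol(M)))
    ya <- c(y, numeric(ncol(M)))
    co <- qr.coef(qr(Ma), ya)
    co[is.na(co)] <- 0
    unname(co)
  }
  solve_a <- function(logb) {
    A <- design(logb)
    if (!is.null(total) && constant) {
      # substitute the neutrality constraint: c = total - sum(a)
      a <- safe_ls(A - 1, f - total)
      c0 <- total - sum(a)
    } else if (!is.null(total)) {
      # no constant term: let the last Gaussian absorb the constraint
      M <- A[, -n_gauss, drop = FALSE] - A[, n_gauss]
      a_head <- safe_ls(M, f - total * A[, n_gauss])
      a <- c(a_head, total - sum(a_head))
      c0 <- 0
    } else if (constant) {
      a <- safe_ls(cbind(1, A), f)
      c0 <- a[1]; a <- a[-1]
    } else {
      a <- safe_ls(A, f)
      c0 <- 0
    }
    list(a = a, c = c0)
  }
  obj <- function(logb) {
    fit <- solve_a(logb)
    pred <- design(logb) %*% fit$a + fit$c
    sum((pred - f)^2)
  }
  opt <- stats::optim(log(b_init), obj, method = "Nelder-Mead",
                      control = list(maxit = 800, reltol = 1e-12))
  fit <- solve_a(opt$par)
  list(a = fit$a, b = exp(opt$par), c = fit$c)
}

#' Generate the embedded Gaussian IAM tables
#'
#' Fits the four Gaussian dialects per element against the package's
#' Slater-shell neutral-atom form factors (X-ray dialects, with
#' \eqn{\sum a_i + c = Z} exact) and their Mott-Bethe conversions (electron
#' dialects), over each dialect's validity range (2 or 6 1/Angstrom).
#'
#' @param elements Element symbols to include.
#' @param dialects Subset of `GAUSS_DIALECTS`.
#' @return Named list of `gaussian_table` objects keyed by dialect.
#' @export
gaussian_table_set <- function(elements = c("H", "C", "N", "O", "F", "P", "S", "Cl", "Fe", "Br", "I"),
                               dialects = GAUSS_DIALECTS) {
  key <- paste(c(elements, "|", dialects), collapse = ",")
  cached <- .harm_cache[[paste0("gtab_", key)]]
  if (!is.null(cached)) return(cached)
  spec <- list(
    "four-gauss-const" = list(n = 4, constant = TRUE, smax = 2, electron = FALSE,
                              b_init = c(0.2, 1.5, 7, 30)),
    "five-gauss" = list(n = 5, constant = FALSE, smax = 6, electron = FALSE,
                        b_init = c(0.05, 0.4, 2, 8, 30)),
    "electron-2invA" = list(n = 5, constant = FALSE, smax = 2, electron = TRUE,
                            b_init = c(0.1, 0.6, 2.5, 9, 35)),
    "electron-6invA" = list(n = 5, constant = FALSE, smax = 6, electron = TRUE,
                            b_init = c(0.05, 0.4, 2, 8, 30))
  )
  out <- list()
  for (d in dialects) {
    sp <- spec[[d]]
    coef <- list()
    for (el in elements) {
      info <- element_info(el)
      shells <- slater_shell_set(el)
      s <- seq(1e-3, sp$smax, length.out = 161)
      fx <- spherical_slater_ff(shells, info$n_val, 1, s)
      if (sp$electron) {
        target <- mott_bethe(fx, info$z, s)
        total <- NULL
      } else {
        target <- fx
        total <- info$z
      }
      coef[[el]] <- .fit_gaussians(s, target, sp$n, sp$constant, total, sp$b_init)
    }
    out[[d]] <- gaussian_table(d, coef, sp$smax)
  }
  .harm_cache[[paste0("gtab_", key)]] <- out
  out
}

#' Construct a Gaussian table
#'
#' @param dialect One of `GAUSS_DIALECTS`.
#' @param coef Named list per element: list(a, b, c).
#' @param validity_smax Fit validity bound in 1/Angstrom.
#' @return A `gaussian_table`.
#' @export
gaussian_table <- function(dialect, coef, validity_smax) {
  if (!dialect %in% GAUSS_DIALECTS) stop("unknown Gaussian dialect: ", dialect)
  for (el in names(coef)) {
    if (any(coef[[el]]$b < 0)) stop("negative Gaussian b coefficient for ", el)
  }
  structure(list(dialect = dialect, coef = coef, validity_smax = validity_smax),
            class = "gaussian_table")
}

# ---------------------------------------------------------------------------
# Parameter counting

#' Count refinable parameters per atom
#'
#' Positions (3) + ADPs (1 isotropic or 6 anisotropic) + occupancy for the
#' IAM; the multipolar model adds the valence population, kappa, kappa-prime
#' (only when deformation terms are present, l_max >= 1) and the
#' \eqn{\sum_{l=1}^{l_{max}} (2l+1)} multipole populations.  With anisotropic
#' ADPs this gives 10 (IAM) up to 37 (hexadecapoles, l_max = 4).
#'
#' @param model_kind "iam" or "multipolar".
#' @param adp_kind "iso" or "aniso".
#' @param l_max Highest multipole order 0..4 (ignored for "iam").
#' @return Integer parameter count.
#' @export
count_refinable_parameters <- function(model_kind = c("iam", "multipolar"),
                                       adp_kind = c("aniso", "iso"),
                                       l_max = 4) {
  model_kind <- match.arg(model_kind)
  adp_kind <- match.arg(adp_kind)
  base <- 3L + (if (adp_kind == "aniso") 6L else 1L) + 1L
  if (model_kind == "iam") return(base)
  if (l_max < 0 || l_max > 4) stop("l_max must be in 0..4")
  extra <- 1L + 1L + (if (l_max >= 1) 1L else 0L)
  if (l_max >= 1) extra <- extra + sum(2L * seq_len(l_max) + 1L)
  base + extra
}

# ---------------------------------------------------------------------------
# Bank container, parser and writer

new_bank <- function(entries = list(), slater = list(), gauss = list(), version = 1) {
  ids <- vapply(entries, function(e) e$type_id, "")
  if (anyDuplicated(ids)) stop("duplicate type_ids in bank: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(entries) <- ids
  structure(list(version = version, entries = entries, slater = slater, gauss = gauss),
            class = "multipolar_bank")
}

#' @export
print.multipolar_bank <- function(x, ...) {
  cat(sprintf("multipolar bank (schema v%d): %d atom types, %d Slater shell sets, %d Gaussian tables\n",
              x$version, length(x$entries), length(x$slater), length(x$gauss)))
  invisible(x)
}

.parse_kv_counts <- function(txt) {
  parts <- strsplit(txt, ",", fixed = TRUE)[[1]]
  counts <- integer(0)
  for (p in parts) {
    kv <- strsplit(trimws(p), ":", fixed = TRUE)[[1]]
    counts[kv[1]] <- as.integer(kv[2])
  }
  counts
}

.fmt_counts <- function(x) paste(sprintf("%s:%d", names(x), x), collapse = ",")

#' Load a multipolar parameter bank
#'
#' Parses and validates a bank file under the schema documented in this file's
#' header (and the package vignette).  Malformed entries raise errors naming
#' the offending line; duplicate type identifiers are rejected.
#'
#' @param path Path to a bank file.
#' @return A `multipolar_bank`.
#' @export
load_bank <- function(path) {
  lines <- readLines(path)
  strip <- sub("#.*$", "", lines)
  unit_scale <- 1
  version <- 1
  slater <- list(); gauss <- list(); raw_types <- list()
  i <- 1
  perr <- function(i, msg) stop(sprintf("bank parse error at line %d: %s", i, msg), call. = FALSE)
  nonblank <- function(i) nzchar(trimws(strip[i]))
  tok <- function(i) strsplit(trimws(strip[i]), "[[:space:]]+")[[1]]
  n <- length(strip)
  while (i <= n) {
    if (!nonblank(i)) { i <- i + 1; next }
    t <- tok(i)
    if (t[1] == "taamsf-bank") {
      version <- as.integer(t[2]); i <- i + 1
    } else if (t[1] == "unit") {
      if (t[2] == "bohr") unit_scale <- 1 / .A0
      else if (t[2] != "invang") perr(i, paste("unknown unit", t[2]))
      i <- i + 1
    } else if (t[1] == "slater") {
      el <- t[2]
      sh <- list(core = data.frame(coef = numeric(0), n = integer(0), zeta = numeric(0)),
                 valence = data.frame(coef = numeric(0), n = integer(0), zeta = numeric(0)))
      i <- i + 1
      while (i <= n && (!nonblank(i) || grepl("^[[:space:]]", strip[i]))) {
        if (!nonblank(i)) { i <- i + 1; next }
        t2 <- tok(i)
        if (!t2[1] %in% c("core", "valence")) perr(i, "expected 'core' or 'valence' shell line")
        v <- as.numeric(t2[-1])
        if (length(v) %% 3 != 0) perr(i, "shell line needs (coef, n, zeta) triples")
        m <- matrix(v, ncol = 3, byrow = TRUE)
        if (any(m[, 3] <= 0)) perr(i, "shell exponents must be positive")
        sh[[t2[1]]] <- rbind(sh[[t2[1]]],
                             data.frame(coef = m[, 1], n = as.integer(m[, 2]),
                                        zeta = m[, 3] * unit_scale))
        i <- i + 1
      }
      slater[[el]] <- structure(list(element = el, z = element_z(el),
                                     core = sh$core, valence = sh$valence),
                                class = "slater_shell_set")
    } else if (t[1] == "gauss") {
      dialect <- t[2]; el <- t[3]
      smax <- as.numeric(t[5])
      rec <- list(a = NULL, b = NULL, c = 0)
      i <- i + 1
      while (i <= n && (!nonblank(i) || grepl("^[[:space:]]", strip[i]))) {
        if (!nonblank(i)) { i <- i + 1; next }
        t2 <- tok(i)
        if (!t2[1] %in% c("a", "b", "c")) perr(i, "expected a/b/c coefficient line")
        rec[[t2[1]]] <- as.numeric(t2[-1])
        i <- i + 1
      }
      if (is.null(rec$a) || is.null(rec$b) || length(rec$a) != length(rec$b))
        perr(i - 1, paste("incomplete Gaussian coefficients for", el))
      if (any(rec$b < 0)) perr(i - 1, "field b: Gaussian widths must be >= 0")
      if (is.null(gauss[[dialect]])) gauss[[dialect]] <- gaussian_table(dialect, list(), smax)
      gauss[[dialect]]$coef[[el]] <- list(a = rec$a, b = rec$b, c = rec$c[1])
    } else if (t[1] == "type") {
      id <- t[2]
      rec <- list(line = i, type_id = id, planar = "any", ring = "any", plm = numeric(25))
      i <- i + 1
      while (i <= n && (!nonblank(i) || grepl("^[[:space:]]", strip[i]))) {
        if (!nonblank(i)) { i <- i + 1; next }
        t2 <- tok(i)
        key <- t2[1]
        if (key == "element") rec$element <- t2[2]
        else if (key == "nbr") rec$nbr <- .parse_kv_counts(t2[2])
        else if (key == "nbr2") rec$nbr2 <- .parse_kv_counts(t2[2])
        else if (key == "planar") rec$planar <- t2[2]
        else if (key == "ring") rec$ring <- t2[2]
        else if (key == "frame") {
          kv <- strsplit(t2[-1], "=", fixed = TRUE)
          for (p in kv) rec$frame[[p[1]]] <- p[2]
        }
        else if (key == "pcore") rec$p_core <- as.numeric(t2[2])
        else if (key == "pval") rec$p_val <- as.numeric(t2[2])
        else if (key == "kappa") rec$kappa <- as.numeric(t2[2])
        else if (key == "kprime") rec$kprime <- as.numeric(t2[2])
        else if (key == "nl") rec$nl <- as.integer(t2[-1])
        else if (key == "zeta") rec$zeta <- as.numeric(t2[2]) * unit_scale
        else if (key == "plm") {
          lm <- as.integer(strsplit(t2[2], ",", fixed = TRUE)[[1]])
          if (length(lm) != 2 || abs(lm[2]) > lm[1] || lm[1] > 4)
            perr(i, paste("field plm: invalid (l,m) index", t2[2]))
          rec$plm[plm_index(lm[1], lm[2])] <- as.numeric(t2[3])
        }
        else perr(i, paste("unknown field", key))
        i <- i + 1
      }
      raw_types[[length(raw_types) + 1]] <- rec
    } else perr(i, paste("unknown directive", t[1]))
  }
  entries <- list()
  for (rec in raw_types) {
    for (fld in c("element", "kappa", "kprime", "p_core", "p_val", "nl", "zeta")) {
      if (is.null(rec[[fld]]))
        stop(sprintf("bank validation error near line %d: type %s is missing field %s",
                     rec$line, rec$type_id, fld), call. = FALSE)
    }
    if (rec$kappa <= 0)
      stop(sprintf("bank validation error near line %d: type %s: field kappa must be positive",
                   rec$line, rec$type_id), call. = FALSE)
    shells <- slater[[rec$element]]
    if (is.null(shells)) shells <- slater_shell_set(rec$element)
    entries[[length(entries) + 1]] <- multipolar_entry(
      rec$type_id, rec$element,
      match_rule = list(nbr = rec$nbr, nbr2 = rec$nbr2, planar = rec$planar, ring = rec$ring),
      frame_recipe = rec$frame,
      p_core = rec$p_core, p_val = rec$p_val,
      kappa = rec$kappa, kappa_prime = rec$kprime,
      p_lm = rec$plm, radial = radial_function(rec$nl, rec$zeta),
      core_valence_model = shells)
  }
  new_bank(entries, slater, gauss, version)
}

#' Write a multipolar parameter bank
#'
#' Serializes a bank to the version-1 text schema; `load_bank()` on the
#' result reproduces every field (floats written with 10 significant digits).
#'
#' @param bank A `multipolar_bank`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bank <- function(bank, path) {
  num <- function(x) sprintf("%.10g", x)
  out <- c(sprintf("taamsf-bank %d", bank$version), "unit invang", "")
  for (el in names(bank$slater)) {
    sh <- bank$slater[[el]]
    out <- c(out, paste("slater", el))
    for (grp in c("core", "valence")) {
      df <- sh[[grp]]
      if (nrow(df) == 0) next
      trip <- paste(apply(df, 1, function(r) paste(num(r["coef"]), r["n"], num(r["zeta"]))),
                    collapse = "  ")
      out <- c(out, paste0("  ", grp, " ", trip))
    }
    out <- c(out, "")
  }
  for (d in names(bank$gauss)) {
    tab <- bank$gauss[[d]]
    for (el in names(tab$coef)) {
      rec <- tab$coef[[el]]
      out <- c(out, sprintf("gauss %s %s smax %s", d, el, num(tab$validity_smax)),
               paste("  a", paste(num(rec$a), collapse = " ")),
               paste("  b", paste(num(rec$b), collapse = " ")),
               paste("  c", num(rec$c)), "")
    }
  }
  for (e in bank$entries) {
    out <- c(out, paste("type", e$type_id),
             paste("  element", e$element))
    if (!is.null(e$match_rule$nbr)) out <- c(out, paste("  nbr", .fmt_counts(e$match_rule$nbr)))
    if (!is.null(e$match_rule$nbr2)) out <- c(out, paste("  nbr2", .fmt_counts(e$match_rule$nbr2)))
    out <- c(out, paste("  planar", e$match_rule$planar),
             paste("  ring", e$match_rule$ring),
             sprintf("  frame z=%s x=%s", e$frame_recipe$z, e$frame_recipe$x),
             paste("  pcore", num(e$p_core)), paste("  pval", num(e$p_val)),
             paste("  kappa", num(e$kappa)), paste("  kprime", num(e$kappa_prime)),
             paste("  nl", paste(e$radial$n_l, collapse = " ")),
             paste("  zeta", num(e$radial$zeta)))
    for (l in 1:4) for (m in -l:l) {
      v <- e$p_lm[plm_index(l, m)]
      if (v != 0) out <- c(out, sprintf("  plm %d,%d %s", l, m, num(v)))
    }
    out <- c(out, "")
  }
  writeLines(out, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Fixture bank

#' Generate the fixture bank
#'
#' A deterministic 12-type toy bank over C, N, O, H and S covering
#' methane-like, water-like, peptide-like and aromatic-ring environments,
#' plus Slater shell sets for all supported elements with Z <= 36 and the
#' four Gaussian dialects for every supported element (iodine, Z = 53,
#' carries Gaussian parameters only).  Parameters are invented but physically
#' plausible (|P_lm| <= 0.3, kappa within 10% of 1).
#'
#' @param seed Integer seed; the same seed yields a byte-identical bank file.
#' @return A `multipolar_bank`.
#' @export
make_fixture_bank <- function(seed = 0) {
  rng <- local_rng(seed)
  slater <- list()
  for (el in c("H", "C", "N", "O", "F", "P", "S", "Cl", "Fe", "Br")) {
    slater[[el]] <- slater_shell_set(el)
  }
  gauss <- gaussian_table_set()

  rnd <- function(lo, hi) round(lo + (hi - lo) * rng(), 6)
  mk_plm <- function(lmax, nz = 3) {
    p <- numeric(25)
    idx <- integer(0)
    for (l in 1:lmax) idx <- c(idx, plm_index(l, -l):plm_index(l, l))
    pick <- idx[floor(rng(min(nz, length(idx))) * length(idx)) + 1]
    for (j in unique(pick)) p[j] <- rnd(-0.3, 0.3)
    p
  }
  nl_for <- function(el) {
    if (el == "H") c(0L, 1L, 2L, 3L, 4L) else c(0L, 2L, 2L, 3L, 4L)
  }
  val_zeta <- function(el) {
    sh <- slater[[el]]
    sh$valence$zeta[nrow(sh$valence)]
  }
  mk <- function(id, el, nbr, frame, planar = "any", ring = "any", nbr2 = NULL,
                 lmax = 4, nz = 3) {
    info <- element_info(el)
    multipolar_entry(
      id, el,
      match_rule = list(nbr = nbr, nbr2 = nbr2, planar = planar, ring = ring),
      frame_recipe = frame,
      p_core = info$n_core, p_val = round(info$n_val + rnd(-0.25, 0.25), 6),
      kappa = rnd(0.92, 1.08), kappa_prime = rnd(0.85, 1.15),
      p_lm = mk_plm(lmax, nz),
      radial = radial_function(nl_for(el), round(val_zeta(el), 6)),
      core_valence_model = slater[[el]])
  }
  cnt <- function(...) {
    v <- c(...)
    stats::setNames(as.integer(v), names(v))
  }
  entries <- list(
    mk("C_sp3_H4",   "C", cnt(H = 4), list(z = "H", x = "H"), planar = "no", ring = "no"),
    mk("H_C_sp3",    "H", cnt(C = 1), list(z = "C", x = "2:any"), nbr2 = cnt(H = 1), lmax = 2, nz = 2),
    mk("O_water",    "O", cnt(H = 2), list(z = "H", x = "H"), ring = "no", lmax = 3),
    mk("H_O",        "H", cnt(O = 1), list(z = "O", x = "2:any"), lmax = 2, nz = 2),
    mk("C_aromatic", "C", cnt(C = 2, H = 1), list(z = "C", x = "C"), planar = "yes", ring = "yes"),
    mk("H_C_aro",    "H", cnt(C = 1), list(z = "C", x = "2:C"), nbr2 = cnt(C = 2), lmax = 2, nz = 2),
    mk("N_amide",    "N", cnt(C = 2, H = 1), list(z = "H", x = "C"), planar = "yes"),
    mk("H_N",        "H", cnt(N = 1), list(z = "N", x = "2:any"), lmax = 2, nz = 2),
    mk("C_carbonyl", "C", cnt(C = 1, N = 1, O = 1), list(z = "O", x = "N"), planar = "yes"),
    mk("O_carbonyl", "O", cnt(C = 1), list(z = "C", x = "2:N"), nbr2 = cnt(N = 1), lmax = 3),
    mk("C_sp3_C2H2", "C", cnt(C = 2, H = 2), list(z = "C", x = "C"), planar = "no", ring = "any"),
    mk("S_thiol",    "S", cnt(C = 1, H = 1), list(z = "C", x = "H"), ring = "no", lmax = 3)
  )
  new_bank(entries, slater, gauss)
}

# Deterministic uniform(0,1) stream isolated from the global RNG state.
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv())
  function(n = 1) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    x <- stats::runif(n)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    x
  }
}
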