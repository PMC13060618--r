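# Space-group operators.  A built-in table covers the space groups used by
# the fixtures (P1, P-1, P21, P212121); mmCIF symmetry loops override it.
# Anything else raises an explicit error rather than guessing.

.sg_op <- function(rot, trans) list(rot = matrix(rot, 3, 3, byrow = TRUE), trans = trans)

.SPACEGROUPS <- list(
  "P1" = list(.sg_op(c(1,0,0, 0,1,0, 0,0,1), c(0, 0, 0))),
  "P-1" = list(.sg_op(c(1,0,0, 0,1,0, 0,0,1), c(0, 0, 0)),
               .sg_op(c(-1,0,0, 0,-1,0, 0,0,-1), c(0, 0, 0))),
  # P21, unique axis b
  "P21" = list(.sg_op(c(1,0,0, 0,1,0, 0,0,1), c(0, 0, 0)),
               .sg_op(c(-1,0,0, 0,1,0, 0,0,-1), c(0, 0.5, 0))),
  "P212121" = list(.sg_op(c(1,0,0, 0,1,0, 0,0,1), c(0, 0, 0)),
                   .sg_op(c(-1,0,0, 0,-1,0, 0,0,1), c(0.5, 0, 0.5)),
                   .sg_op(c(-1,0,0, 0,1,0, 0,0,-1), c(0, 0.5, 0.5)),
                   .sg_op(c(1,0,0, 0,-1,0, 0,0,-1), c(0.5, 0.5, 0)))
)

normalize_sg_symbol <- function(symbol) {
  s <- toupper(gsub("[[:space:]_]", "", symbol))
  s <- sub("^P21212 1$", "P212121", s)
  map <- c("P1" = "P1", "P-1" = "P-1", "P21" = "P21", "P1211" = "P21",
           "P121/1" = "P21", "P212121" = "P212121")
  if (!s %in% names(map)) stop("unsupported space group: ", symbol)
  unname(map[s])
}

#' Space-group operators
#'
#' @param symbol Hermann-Mauguin symbol; supported: P1, P-1, P21 (unique axis
#'   b), P212121.
#' @return List of operators, each a list with 3x3 `rot` and length-3 `trans`
#'   acting on fractional coordinates.
#' @export
spacegroup_ops <- function(symbol) {
  .SPACEGROUPS[[normalize_sg_symbol(symbol)]]
}

#' Check closure of an operator set
#'
#' Verifies (for sets of at most 48 operators) that composing any two
#' operators yields another operator of the set, modulo lattice translations.
#'
#' @param ops List of operators as returned by [spacegroup_ops()].
#' @return TRUE invisibly; stops if the set is not closed.
#' @export
check_ops_closure <- function(ops) {
  if (length(ops) > 48) return(invisible(TRUE))
  key <- function(rot, trans) {
    paste(c(round(rot), round(trans %% 1, 6)), collapse = ",")
  }
  have <- vapply(ops, function(o) key(o$rot, o$trans), "")
  for (a in ops) for (b in ops) {
    rot <- a$rot %*% b$rot
    trans <- a$rot %*% b$trans + a$trans
    if (!key(rot, as.numeric(trans)) %in% have) {
      stop("symmetry operator set is not closed under composition")
    }
  }
  invisible(TRUE)
}

# Parse an xyz-style symmetry string such as "-x,y+1/2,-z".
parse_symop_xyz <- function(txt) {
  parts <- strsplit(gsub("[[:space:]]", "", tolower(txt)), ",")[[1]]
  if (length(parts) != 3) stop("malformed symmetry operator: ", txt)
  rot <- matrix(0, 3, 3); trans <- numeric(3)
  for (i in 1:3) {
    p <- parts[i]
    # coefficients of x, y, z
    for (j in 1:3) {
      var <- c("x", "y", "z")[j]
      if (grepl(paste0("-", var), p, fixed = TRUE)) rot[i, j] <- -1
      else if (grepl(var, p, fixed = TRUE)) rot[i, j] <- 1
    }
    q <- gsub("[+-]?[xyz]", "", p)
    if (nzchar(q)) {
      if (grepl("/", q, fixed = TRUE)) {
        num <- strsplit(q, "/", fixed = TRUE)[[1]]
        trans[i] <- as.numeric(num[1]) / as.numeric(num[2])
      } else trans[i] <- as.numeric(q)
    }
  }
  list(rot = rot, trans = trans)
}
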