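# Bond perception, ring/planarity analysis, bank matching and the
# three-level representation fallback.

test_that("bonding follows covalent radii plus tolerance", {
  cell <- unit_cell(20, 20, 20)
  two_c <- function(d) crystal_structure(cell, data.frame(
    label = c("C1", "C2"), element = "C",
    fx = c(0.5, 0.5 + d / 20), fy = 0.5, fz = 0.5))
  g <- build_bond_graph(two_c(1.50))          # 1.50 <= 0.76 + 0.76 + 0.40
  expect_identical(nrow(g$edges), 1L)
  expect_equal(g$edges$d, 1.50, tolerance = 1e-9)
  expect_identical(nrow(build_bond_graph(two_c(3.00))$edges), 0L)
  expect_error(build_bond_graph(two_c(1.5), tolerance = -0.1), "tolerance")
})

test_that("a hydrogen bonds only to its nearest heavy atom, ties to the lower index", {
  cell <- unit_cell(20, 20, 20)
  st <- crystal_structure(cell, data.frame(
    label = c("O1", "O2", "H3"), element = c("O", "O", "H"),
    fx = c(0.40, 0.50, 0.45), fy = 0.5, fz = 0.5))  # H equidistant (1.0 A)
  g <- build_bond_graph(st)
  hrows <- g$adj[[3]]$idx
  expect_identical(hrows, 1L)                 # tie broken to the lower index
  expect_identical(length(g$adj[[3]]$idx), 1L)
})

test_that("symmetry mates participate in bonding", {
  # atom near the cell edge bonds to the translated image of its partner
  cell <- unit_cell(10, 10, 10)
  st <- crystal_structure(cell, data.frame(
    label = c("C1", "C2"), element = "C",
    fx = c(0.02, 0.95), fy = 0.5, fz = 0.5))  # 0.7 A through the boundary
  g <- suppressWarnings(build_bond_graph(st))
  expect_identical(nrow(g$edges) + nrow(g$clashes), 1L)
})

test_that("ring perception matches exhaustive cycle enumeration", {
  bank <- fixture_bank()
  stb <- make_structure("benzene")
  gb <- build_bond_graph(stb)
  rb <- perceive_rings(gb)
  for (i in 1:6) expect_identical(rb[[i]], 6L)       # six atoms, one 6-ring each
  for (i in 7:12) expect_length(rb[[i]], 0)
  # linear chain: no rings
  cell <- unit_cell(20, 20, 20)
  pent <- crystal_structure(cell, data.frame(
    label = paste0("C", 1:5), element = "C",
    fx = 0.3 + 1.53 * (0:4) / 20, fy = 0.5, fz = 0.5))
  expect_true(all(lengths(perceive_rings(build_bond_graph(pent))) == 0))
  # decalin: bridgeheads in two 6-rings, others in one
  std <- make_structure("decalin")
  gd <- build_bond_graph(std)
  rd <- perceive_rings(gd)
  nring <- lengths(rd[1:10])
  expect_identical(sort(nring, decreasing = TRUE)[1:2], c(2L, 2L))
  expect_identical(sum(nring == 1), 8L)
  expect_true(all(unlist(rd[1:10]) == 6L))
  # the basis cycles agree with exhaustive enumeration (every basis cycle is
  # a genuine simple cycle, and the basis has the cyclomatic count)
  cyc_all <- enumerate_cycles(gd)
  basis <- attr(rd, "cycles")
  keyset <- vapply(cyc_all, function(cy) paste(sort(cy), collapse = ","), "")
  for (cy in basis) expect_true(paste(sort(cy), collapse = ",") %in% keyset)
  # cyclomatic number: edges - vertices + components
  expect_length(basis, nrow(gd$edges) - gd$n +
                  length(unique(taamsf:::.components(gd$edges, gd$n))))
})

test_that("planarity thresholds behave on ideal geometries", {
  bank <- fixture_bank()
  stb <- make_structure("benzene")
  gb <- build_bond_graph(stb)
  expect_true(planarity(1, gb, stb))              # aromatic carbon: deviation 0
  stm <- make_structure("methane")
  gm <- build_bond_graph(stm)
  expect_false(planarity(1, gm, stm))             # tetrahedral carbon
  expect_true(is.na(planarity(2, gm, stm)))       # H has one neighbour
  # pyramidalized N: out-of-plane apex 0.3 A fails at 0.1 A threshold
  cell <- unit_cell(20, 20, 20)
  base <- 1.4 * cbind(cos(2 * pi * (0:2) / 3), sin(2 * pi * (0:2) / 3), 0)
  xyz <- rbind(c(0, 0, 0.3), base)
  fr <- sweep(xyz, 2, c(10, 10, 10), `+`) / 20
  stn <- crystal_structure(cell, data.frame(label = c("N1", "C2", "C3", "C4"),
                                            element = c("N", "C", "C", "C"),
                                            fx = fr[, 1], fy = fr[, 2], fz = fr[, 3]))
  gn <- build_bond_graph(stn)
  expect_false(planarity(1, gn, stn, threshold = 0.10))
  expect_true(planarity(1, gn, stn, threshold = 0.50))
})

test_that("designed fixtures reach full multipolar coverage", {
  bank <- fixture_bank()
  for (nm in c("methane", "water", "benzene")) {
    st <- make_structure(nm)
    asn <- assign_atom_types(st, build_bond_graph(st), bank)
    expect_equal(asn$coverage, 1, info = nm)
    expect_true(all(!is.na(asn$atoms$type_id)))
  }
})

test_that("fallback hierarchy: Slater for Z <= 36, Gaussian beyond, with reasons", {
  bank <- fixture_bank()
  lone <- function(el) crystal_structure(unit_cell(8, 8, 8), data.frame(
    label = el, element = el, fx = 0.5, fy = 0.5, fz = 0.5))
  fe <- assign_atom_types(lone("Fe"), build_bond_graph(lone("Fe")), bank)
  expect_identical(fe$atoms$level, "spherical-slater")
  io <- assign_atom_types(lone("I"), build_bond_graph(lone("I")), bank)
  expect_identical(io$atoms$level, "gaussian-iam")
  expect_identical(io$atoms$reason, "Z>36-no-slater")
  # water oxygen without hydrogens
  stw <- make_structure("water-noH")
  aw <- assign_atom_types(stw, build_bond_graph(stw), bank)
  expect_identical(aw$atoms$level, "spherical-slater")
  expect_identical(aw$atoms$reason, "no-H-neighbour")
})

test_that("altloc overlaps and clashes force Gaussian IAM", {
  bank <- fixture_bank()
  st <- make_structure("altloc-overlap")
  expect_warning(g <- build_bond_graph(st), "clash")
  asn <- assign_atom_types(st, g, bank)
  a <- asn$atoms
  expect_identical(a$level[st$sites$altloc == "A"], "gaussian-iam")
  expect_identical(a$reason[st$sites$altloc == "A"], "altloc-overlap")
  expect_identical(a$reason[st$sites$altloc == "B"], "altloc-overlap")
  clash_pair <- a$level[st$sites$element == "C"]
  expect_true(all(clash_pair == "gaussian-iam"))
})

test_that("local frames follow the recipe and degrade gracefully", {
  bank <- fixture_bank()
  # O-H along crystal x: local z maps to (1, 0, 0)
  cell <- unit_cell(10, 10, 10)
  st <- crystal_structure(cell, data.frame(
    label = c("O1", "H2", "H3"), element = c("O", "H", "H"),
    fx = c(0.5, 0.5 + 0.096, 0.47), fy = c(0.5, 0.5, 0.59), fz = 0.5))
  g <- build_bond_graph(st)
  fr <- build_local_frame(1, list(z = "H", x = "H"), st, g)
  expect_equal(fr$rotation %*% c(0, 0, 1), matrix(c(1, 0, 0)), tolerance = 1e-9)
  expect_equal(t(fr$rotation) %*% fr$rotation, diag(3), tolerance = 1e-10)
  expect_equal(det(fr$rotation), 1, tolerance = 1e-10)
  # collinear references: degenerate, frame construction refuses
  stc <- crystal_structure(cell, data.frame(
    label = c("C1", "O2", "O3"), element = c("C", "O", "O"),
    fx = c(0.5, 0.62, 0.38), fy = 0.5, fz = 0.5))
  gc0 <- build_bond_graph(stc)
  expect_null(build_local_frame(1, list(z = "O", x = "O"), stc, gc0))
  # a matched atom with a degenerate frame is demoted with a reason
  asn <- assign_atom_types(stc, gc0, fixture_bank())
  expect_false(any(asn$atoms$level == "multipolar" & is.na(asn$atoms$type_id)))
})

test_that("frames are equivariant under rigid rotation of the model", {
  bank <- fixture_bank()
  st <- make_structure("tripeptide-like")
  g <- build_bond_graph(st)
  a1 <- assign_atom_types(st, g, bank)
  R <- random_rotation(9)
  xyz <- site_cart(st) %*% t(R)
  fr <- xyz %*% t(solve(frac_to_cart_matrix(st$cell)))
  str <- st
  str$sites$fx <- fr[, 1] %% 1; str$sites$fy <- fr[, 2] %% 1; str$sites$fz <- fr[, 3] %% 1
  a2 <- assign_atom_types(str, build_bond_graph(str), bank)
  expect_identical(a1$atoms$level, a2$atoms$level)
  for (i in seq_len(n_sites(st))) {
    if (is.null(a1$frames[[i]])) next
    expect_equal(R %*% a1$frames[[i]]$rotation, a2$frames[[i]]$rotation,
                 tolerance = 1e-8)
  }
})

test_that("typing is a pure function of coordinates, elements and bank", {
  bank <- fixture_bank()
  st <- make_structure("tripeptide-like")
  g <- build_bond_graph(st)
  a1 <- assign_atom_types(st, g, bank)
  a2 <- assign_atom_types(st, build_bond_graph(st), bank)
  expect_identical(a1$atoms, a2$atoms)
})

test_that("removing hydrogens strictly decreases multipolar coverage", {
  bank <- fixture_bank()
  st <- make_structure("tripeptide-like")
  asn <- assign_atom_types(st, build_bond_graph(st), bank)
  keep <- element_z(st$sites$element) != 1
  st_noh <- crystal_structure(st$cell, st$sites[keep, ],
                              spacegroup = "P1", u_aniso = st$u_aniso[keep])
  asn_noh <- assign_atom_types(st_noh, build_bond_graph(st_noh), bank)
  expect_lt(asn_noh$coverage, asn$coverage)
})

test_that("coverage report percentages sum to 100 and handle empty input", {
  bank <- fixture_bank()
  st <- make_structure("tripeptide-like")
  asn <- assign_atom_types(st, build_bond_graph(st), bank)
  rep0 <- type_coverage_report(asn)
  expect_equal(sum(rep0$percent), 100, tolerance = 1e-9)
  expect_equal(rep0$percent_multipolar, 100 * asn$coverage, tolerance = 1e-3)
  js <- type_coverage_report(asn, json = TRUE)
  expect_true(jsonlite::validate(js))
  # 9 typed atoms with 1 iodine -> 90% multipolar is pure arithmetic
  fake <- asn
  fake$atoms <- data.frame(label = paste0("A", 1:10), element = "C",
                           level = c(rep("multipolar", 9), "gaussian-iam"),
                           type_id = NA, reason = "x")
  fake$coverage <- 0.9
  expect_equal(type_coverage_report(fake)$percent_multipolar, 90)
  # empty structure: no division by zero
  empty <- asn
  empty$atoms <- asn$atoms[0, ]; empty$coverage <- NA_real_
  expect_identical(type_coverage_report(empty)$n_atoms, 0L)
})
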