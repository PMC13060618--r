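# Direct-summation structure factors, Debye-Waller factors and analytic
# gradients.

test_that("single-atom structure factors follow the textbook forms", {
  bank <- fixture_bank()
  cell <- unit_cell(10, 10, 10)
  at_origin <- crystal_structure(cell, data.frame(
    label = "C1", element = "C", fx = 0, fy = 0, fz = 0, occ = 1, biso = 0))
  ms <- generate_reflections(at_origin, 2)
  sf <- direct_summation_sf(at_origin, NULL, ms, bank, "xray", "iam")
  expect_equal(Im(sf$f), rep(0, length(sf$f)), tolerance = 1e-12)
  expect_true(all(Re(sf$f) > 0))
  expect_equal(Re(sf$f),
               suppressWarnings(gaussian_ff("C", ms$s, bank$gauss[["five-gauss"]])),
               tolerance = 1e-12)
  # atom at (1/2, 0, 0): F(100) = -f
  at_half <- at_origin; at_half$sites$fx <- 0.5
  ms1 <- miller_set(matrix(c(1, 0, 0), 1), cell)
  sf1 <- direct_summation_sf(at_half, NULL, ms1, bank, "xray", "iam")
  expect_equal(sf1$f, -as.complex(gaussian_ff("C", ms1$s, bank$gauss[["five-gauss"]])),
               tolerance = 1e-12)
})

test_that("F(000) equals the occupancy-weighted electron count (X-ray IAM)", {
  bank <- fixture_bank()
  st <- make_structure("random-P1", seed = 3)
  ms <- generate_reflections(st, 3, include_000 = TRUE)
  sf <- direct_summation_sf(st, NULL, ms, bank, "xray", "iam", dialect = "four-gauss-const")
  i000 <- which(rowSums(abs(ms$hkl)) == 0)
  expect_equal(Re(sf$f[i000]),
               sum(st$sites$occ * element_z(st$sites$element)), tolerance = 1e-6)
})

test_that("Debye-Waller factors: closed forms and the B = 8 pi^2 U identity", {
  cell <- unit_cell(10, 12, 14, 85, 95, 100)
  hkl <- rbind(c(1, 2, 3), c(-2, 0, 1), c(4, -1, 2))
  expect_equal(debye_waller(0, hkl, cell), rep(1, 3))
  # B = 10, s = 0.5: exp(-2.5)
  cub <- unit_cell(10, 10, 10)
  h <- matrix(c(10, 0, 0), 1)   # s = 0.5 for a = 10
  expect_equal(debye_waller(10, h, cub), exp(-2.5), tolerance = 1e-12)
  # isotropic tensor U I reproduces B = 8 pi^2 U
  U <- 0.02
  expect_equal(debye_waller(diag(U, 3), hkl, cell),
               debye_waller(8 * pi^2 * U, hkl, cell), tolerance = 1e-10)
  expect_true(all(debye_waller(15, hkl, cell) > 0 & debye_waller(15, hkl, cell) <= 1))
})

test_that("IAM direct summation matches the FFT sampled-Gaussian oracle", {
  bank <- fixture_bank()
  st <- make_structure("random-P1", seed = 7)
  ms <- generate_reflections(st, 2.0)
  sf <- direct_summation_sf(st, NULL, ms, bank, "xray", "iam", dialect = "five-gauss")
  oracle <- fft_sf_oracle(st, bank)
  Fo <- oracle(ms$hkl)
  expect_lt(max(abs(Mod(sf$f) - Mod(Fo)) / Mod(Fo)), 1e-3)
  expect_lt(max(abs(Arg(sf$f / Fo))) * 180 / pi, 0.1)
})

test_that("Friedel symmetry, translation and occupancy linearity hold", {
  bank <- fixture_bank()
  st <- triclinic_fixture()
  g <- build_bond_graph(st)
  asn <- assign_atom_types(st, g, bank)
  hkl <- rbind(c(1, 2, -1), c(3, 0, 2), c(-2, 1, 4))
  for (mode in c("taam", "iam")) {
    msp <- miller_set(hkl, st$cell)
    msm <- miller_set(-hkl, st$cell)
    fp <- direct_summation_sf(st, asn, msp, bank, "xray", mode)
    fm <- direct_summation_sf(st, asn, msm, bank, "xray", mode)
    expect_equal(fm$f, Conj(fp$f), tolerance = 1e-12)
    # translation by t multiplies F(h) by exp(2 pi i h.t)
    t0 <- c(0.11, -0.23, 0.37)
    st_t <- st
    st_t$sites$fx <- st$sites$fx + t0[1]
    st_t$sites$fy <- st$sites$fy + t0[2]
    st_t$sites$fz <- st$sites$fz + t0[3]
    ft <- direct_summation_sf(st_t, asn, msp, bank, "xray", mode)
    expect_equal(ft$f, fp$f * exp(2i * pi * as.numeric(hkl %*% t0)), tolerance = 1e-10)
    # doubling occupancies doubles F (here: halving, to stay within [0, 1])
    st_h <- st; st_h$sites$occ <- st$sites$occ / 2
    fh <- direct_summation_sf(st_h, asn, msp, bank, "xray", mode)
    expect_equal(fh$f * 2, fp$f, tolerance = 1e-12)
  }
})

test_that("a P21 asymmetric unit and its P1 expansion give identical F", {
  bank <- fixture_bank()
  st <- make_structure("chiral-P21-pair")
  expect_length(st$ops, 2)
  p1 <- expand_to_p1(st)
  expect_identical(n_sites(p1), 2L * n_sites(st))
  ms <- generate_reflections(st, 1.5)
  f_sym <- direct_summation_sf(st, NULL, ms, bank, "xray", "iam")
  f_p1 <- direct_summation_sf(p1, NULL, ms, bank, "xray", "iam")
  expect_equal(f_sym$f, f_p1$f, tolerance = 1e-10)
})

test_that("taam mode on an all-Gaussian assignment equals iam mode bit for bit", {
  bank <- fixture_bank()
  st <- make_structure("methane")
  asn <- force_iam(assign_atom_types(st, build_bond_graph(st), bank))
  ms <- generate_reflections(st, 1.5)
  for (rad in c("xray", "electron")) {
    f_taam <- direct_summation_sf(st, asn, ms, bank, rad, "taam")
    f_iam <- direct_summation_sf(st, asn, ms, bank, rad, "iam")
    expect_identical(f_taam$f, f_iam$f)
  }
})

test_that("analytic target gradients match central finite differences", {
  bank <- fixture_bank()
  st <- triclinic_fixture()
  asn <- assign_atom_types(st, build_bond_graph(st), bank)
  ms <- generate_reflections(st, 1.4)
  for (rad in c("xray", "electron")) for (mode in c("taam", "iam")) {
    sf0 <- direct_summation_sf(st, asn, ms, bank, rad, mode)
    tgt <- make_ls_target(sf0, noise_sd = 0.5, seed = 3)
    dT <- tgt$dtarget_df(sf0$f)
    gr <- sf_gradients(st, asn, ms, bank, dT, rad, mode)
    fd <- function(mod_fn, h) {
      sp <- direct_summation_sf(mod_fn(st, h), asn, ms, bank, rad, mode)
      sm <- direct_summation_sf(mod_fn(st, -h), asn, ms, bank, rad, mode)
      (tgt$target(sp$f) - tgt$target(sm$f)) / (2 * h)
    }
    checks <- list(
      list(gr$x[2], fd(function(s0, h) { s0$sites$fx[2] <- s0$sites$fx[2] + h; s0 }, 1e-5)),
      list(gr$z[5], fd(function(s0, h) { s0$sites$fz[5] <- s0$sites$fz[5] + h; s0 }, 1e-5)),
      list(gr$b[1], fd(function(s0, h) { s0$sites$biso[1] <- s0$sites$biso[1] + h; s0 }, 1e-4)),
      list(gr$occ[4], fd(function(s0, h) { s0$sites$occ[4] <- s0$sites$occ[4] + h; s0 }, 1e-5)),
      list(gr$u11[4], fd(function(s0, h) { s0$u_aniso[[4]][1, 1] <- s0$u_aniso[[4]][1, 1] + h; s0 }, 1e-5)),
      list(gr$u13[4], fd(function(s0, h) {
        s0$u_aniso[[4]][1, 3] <- s0$u_aniso[[4]][1, 3] + h
        s0$u_aniso[[4]][3, 1] <- s0$u_aniso[[4]][3, 1] + h; s0 }, 1e-5))
    )
    for (ck in checks) {
      expect_lt(abs(ck[[1]] - ck[[2]]) / max(abs(ck[[2]]), 1e-8), 1e-5)
    }
  }
})

test_that("gradients vanish at the least-squares minimum", {
  bank <- fixture_bank()
  st <- triclinic_fixture()
  asn <- assign_atom_types(st, build_bond_graph(st), bank)
  ms <- generate_reflections(st, 1.6)
  sf0 <- direct_summation_sf(st, asn, ms, bank, "xray", "taam")
  tgt <- make_ls_target(sf0, noise_sd = 0, seed = 1)   # F_obs = |F_calc|
  gr <- sf_gradients(st, asn, ms, bank, tgt$dtarget_df(sf0$f), "xray", "taam")
  expect_lt(max(abs(as.matrix(gr[, c("x", "y", "z")]))), 1e-10)
  expect_lt(max(abs(gr$occ)), 1e-10)
})

test_that("occupancy gradient closed form for a lone atom under T = |F|^2", {
  bank <- fixture_bank()
  cell <- unit_cell(10, 10, 10)
  st <- crystal_structure(cell, data.frame(
    label = "C1", element = "C", fx = 0.3, fy = 0.2, fz = 0.6, occ = 1, biso = 4))
  ms <- miller_set(matrix(c(2, 1, 0), 1), cell)
  sf <- direct_summation_sf(st, NULL, ms, bank, "xray", "iam")
  # T = |F|^2: dT/dF = 2 F; dT/docc = 2 |F|^2 / occ at occ = 1
  gr <- sf_gradients(st, NULL, ms, bank, 2 * sf$f, "xray", "iam")
  expect_equal(gr$occ, 2 * Mod(sf$f)^2, tolerance = 1e-10)
})

test_that("explicit dF/dp table contracts to the accumulated gradients", {
  bank <- fixture_bank()
  st <- triclinic_fixture()
  asn <- assign_atom_types(st, build_bond_graph(st), bank)
  ms <- generate_reflections(st, 1.8)
  sf0 <- direct_summation_sf(st, asn, ms, bank, "xray", "taam")
  tgt <- make_ls_target(sf0, noise_sd = 0.3, seed = 2)
  dT <- tgt$dtarget_df(sf0$f)
  gr <- sf_gradients(st, asn, ms, bank, dT, "xray", "taam")
  tab <- per_reflection_sf_gradients(st, asn, ms, bank, "xray", "taam")
  ct <- contract_gradient_table(tab, dT)
  expect_equal(ct$x, gr$x, tolerance = 1e-10)
  expect_equal(ct$occ, gr$occ, tolerance = 1e-10)
  expect_equal(ct$u12[4], gr$u12[4], tolerance = 1e-10)
  # single atom in P1: dF/dx at h = (1,0,0) is 2 pi i f DW exp(2 pi i x)
  cell <- unit_cell(10, 10, 10)
  st1 <- crystal_structure(cell, data.frame(
    label = "C1", element = "C", fx = 0.3, fy = 0, fz = 0, occ = 1, biso = 7))
  ms1 <- miller_set(matrix(c(1, 0, 0), 1), cell)
  t1 <- per_reflection_sf_gradients(st1, NULL, ms1, bank, "xray", "iam")
  f <- suppressWarnings(gaussian_ff("C", ms1$s, bank$gauss[["five-gauss"]]))
  dw <- debye_waller(7, ms1$hkl, cell)
  expect_equal(t1$dx[1, 1], 2i * pi * f * dw * exp(2i * pi * 0.3), tolerance = 1e-12)
})

test_that("the explicit-table resource guard triggers above the limit", {
  bank <- fixture_bank()
  st <- make_structure("random-P1", seed = 1)  # 20 atoms -> 200 parameters
  ms <- generate_reflections(st, 0.38)         # > 5e4 reflections
  expect_gt(nrow(ms$hkl) * 10 * n_sites(st), 1e7)
  expect_error(per_reflection_sf_gradients(st, NULL, ms, bank, "xray", "iam"),
               "resource guard")
})

test_that("accumulated gradient output size is independent of the reflection count", {
  bank <- fixture_bank()
  st <- triclinic_fixture()
  asn <- assign_atom_types(st, build_bond_graph(st), bank)
  sizes <- vapply(c(2.2, 1.2), function(dmin) {
    ms <- generate_reflections(st, dmin)
    sf0 <- direct_summation_sf(st, asn, ms, bank, "xray", "taam")
    gr <- sf_gradients(st, asn, ms, bank, 2 * sf0$f, "xray", "taam")
    as.numeric(utils::object.size(gr))
  }, 0)
  expect_identical(sizes[1], sizes[2])
  # and non-finite target derivatives are rejected
  ms <- generate_reflections(st, 2.2)
  expect_error(sf_gradients(st, asn, ms, bank, rep(NaN + 0i, nrow(ms$hkl)),
                            "xray", "taam"), "finite")
})
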