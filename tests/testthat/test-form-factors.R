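# Gaussian, spherical Slater and multipolar form factors; Fourier-Bessel
# closed forms; Mott-Bethe conversion.

test_that("gaussian_ff evaluates the sum of Gaussians and tracks validity", {
  tab <- gaussian_table("four-gauss-const",
                        list(C = list(a = c(2, 0, 0, 0), b = c(0, 1, 1, 1), c = 0),
                             N = list(a = c(1, 0, 0, 0), b = c(1, 1, 1, 1), c = 0)),
                        validity_smax = 2)
  expect_equal(gaussian_ff("C", c(0, 0.5, 1.7), tab), rep(2, 3))
  expect_equal(gaussian_ff("N", 1, tab), exp(-1), tolerance = 1e-12)
  expect_warning(gaussian_ff("C", 2.5, tab), "validity")
  expect_error(gaussian_ff("O", 1, tab), "not present")
  expect_error(gaussian_table("four-gauss-const",
                              list(C = list(a = 1, b = -1, c = 0)), 2), "negative")
})

test_that("embedded X-ray tables recover Z at s = 0 for every element", {
  bank <- fixture_bank()
  for (d in c("four-gauss-const", "five-gauss")) {
    tab <- bank$gauss[[d]]
    for (el in names(tab$coef)) {
      expect_equal(gaussian_ff(el, 0, tab), element_z(el), tolerance = 1e-8,
                   info = paste(d, el))
    }
  }
})

test_that("slater_fourier_bessel reproduces closed-form and limit values", {
  # normalized density: <j_0>(0) = 1, <j_l>(0) = 0 for l >= 1
  for (n in 0:4) expect_equal(slater_fourier_bessel(n, 3.1, 0, 0), 1)
  for (l in 1:4) expect_equal(slater_fourier_bessel(l + 1, 2.5, l, 0), 0)
  # n = 0, l = 0: zeta^4 / (zeta^2 + H^2)^2, checked at H = zeta -> 1/4
  z <- 2.37
  expect_equal(slater_fourier_bessel(0, z, 0, z), 0.25, tolerance = 1e-12)
  H <- c(0.3, 1, 5, 12)
  expect_equal(slater_fourier_bessel(0, z, 0, H), z^4 / (z^2 + H^2)^2,
               tolerance = 1e-12)
  expect_error(slater_fourier_bessel(1, 4, 2, 1), "unphysical")
  expect_error(slater_fourier_bessel(2, -1, 0, 1), "zeta")
})

test_that("closed-form transforms match adaptive quadrature over the parameter box", {
  set.seed(11)
  for (trial in 1:40) {
    l <- sample(0:4, 1)
    n <- l + sample(0:4, 1)
    zeta <- runif(1, 1, 10)
    H <- runif(1, 0, 25)
    a <- slater_fourier_bessel(n, zeta, l, H)
    b <- quad_fourier_bessel(n, zeta, l, H)
    expect_lt(abs(a - b) / max(abs(b), 1e-7), 1e-8)
  }
})

test_that("spherical Slater form factor: origin value and kappa contraction", {
  sh <- slater_shell_set("C")
  expect_equal(spherical_slater_ff(sh, 4, 1, 0), 6)        # f(0) = Z when neutral
  expect_equal(spherical_slater_ff(sh, 4.3, 0.9, 0), 2 + 4.3)  # f(0) = p_core + p_val
  expect_equal(spherical_slater_ff(sh, 0, 1.1, c(0, 0.7)),
               taamsf:::.shell_ff(sh$core, c(0, 0.7)))     # pure core when p_val = 0
  # kappa > 1 contracts the density: higher scattering in the high-s flank
  # of the valence transform (checked below the transform's node; the
  # single-exponential valence shells change sign near s ~ 0.8)
  f_contracted <- spherical_slater_ff(sh, 4, 1.2, 0.5)
  f_neutral <- spherical_slater_ff(sh, 4, 1.0, 0.5)
  expect_gt(f_contracted, f_neutral)
})

test_that("multipolar form factor: spherical limit, Hermitian symmetry, rotation", {
  bank <- fixture_bank()
  entry <- bank$entries[["O_water"]]
  frame <- structure(list(origin = 1, rotation = random_rotation(5)),
                     class = "local_frame")
  # spherical limit equals the spherical Slater path at machine precision
  sph <- entry; sph$p_lm[] <- 0; sph$kappa_prime <- 1
  set.seed(3)
  s <- runif(1000, 0, 2)
  f_multi <- multipolar_ff(sph, frame, cbind(2 * s, 0, 0))
  f_slater <- spherical_slater_ff(entry$core_valence_model, entry$p_val, entry$kappa, s)
  expect_equal(f_multi, as.complex(f_slater), tolerance = 1e-15)
  # Hermitian: f(-h) = conj(f(h))
  g <- matrix(rnorm(30), 10, 3) * 0.4
  expect_equal(multipolar_ff(entry, frame, -g),
               Conj(multipolar_ff(entry, frame, g)), tolerance = 1e-13)
  # rotating frame and scattering vector together leaves f unchanged
  R <- random_rotation(21)
  frame2 <- frame; frame2$rotation <- R %*% frame$rotation
  f1 <- multipolar_ff(entry, frame, g)
  f2 <- multipolar_ff(entry, frame2, g %*% t(R))
  expect_equal(f1, f2, tolerance = 1e-10)
})

test_that("multipolar form factor agrees with a 3D numerical Fourier transform", {
  bank <- fixture_bank()
  frame <- structure(list(origin = 1, rotation = random_rotation(5)),
                     class = "local_frame")
  set.seed(7)
  for (id in c("O_water", "C_sp3_H4")) {
    entry <- bank$entries[[id]]
    for (k in 1:3) {
      gdir <- rnorm(3); gdir <- gdir / sqrt(sum(gdir^2))
      g <- runif(1, 0.2, 1.2) * gdir
      a <- multipolar_ff(entry, frame, matrix(g, 1))
      b <- ft3d_oracle(entry, frame, g)
      expect_lt(Mod(a - b) / Mod(b), 1e-4)
    }
  }
})

test_that("density-normalized harmonics integrate |d_lm| to 2", {
  gl <- taamsf:::.gauss_legendre(200, -1, 1)
  phi <- (seq_len(400) - 1) * 2 * pi / 400
  st <- sqrt(pmax(0, 1 - gl$x^2))
  u <- cbind(as.numeric(outer(st, cos(phi))), as.numeric(outer(st, sin(phi))),
             as.numeric(matrix(gl$x, 200, 400)))
  w <- as.numeric(matrix(gl$w, 200, 400)) * (2 * pi / 400)
  for (l in 1:4) for (m in c(-l, 0, l)) {
    expect_equal(sum(abs(sph_harm_d(l, m, u)) * w), 2, tolerance = 1e-3)
  }
  expect_equal(sph_harm_d(0, 0, c(0, 0, 1)), 1 / (4 * pi))
})

test_that("Mott-Bethe conversion matches its closed forms and origin limit", {
  C <- mott_bethe_constant()
  expect_equal(C, 1 / (8 * pi^2 * 0.529177210903), tolerance = 1e-12)
  # f_x = Z exactly -> zero electron scattering
  expect_equal(mott_bethe(6, 6, c(0.3, 1, 2)), rep(0, 3))
  # single-Gaussian atom: f_e(s) = C Z (1 - exp(-b s^2)) / s^2
  Z <- 7; b1 <- 12
  fx <- function(s) Z * exp(-b1 * s^2)
  s0 <- 0.5
  expect_equal(mott_bethe(fx(s0), Z, s0), C * Z * (1 - exp(-b1 * s0^2)) / s0^2,
               tolerance = 1e-12)
  # s -> 0 limit equals C Z b1 (Taylor), matching a tiny-s evaluation
  tab <- gaussian_table("five-gauss", list(N = list(a = Z, b = b1, c = 0)), 6)
  expect_equal(mott_bethe_gaussian_origin("N", tab), C * Z * b1, tolerance = 1e-12)
  expect_equal(mott_bethe(fx(1e-4), Z, 1e-4), C * Z * b1, tolerance = 1e-4)
  # net-charged parameterization: divergent origin
  tab_ion <- gaussian_table("five-gauss", list(N = list(a = Z - 1, b = b1, c = 0)), 6)
  expect_error(mott_bethe_gaussian_origin("N", tab_ion), "divergent")
  expect_error(mott_bethe(5, 7, 0), "s > 0")
})

test_that("Mott-Bethe of the X-ray tables approximates the electron tables", {
  # dialect-level consistency: the electron fits must track the converted
  # X-ray Slater reference within a few percent over their validity range
  bank <- fixture_bank()
  for (d in c("electron-2invA", "electron-6invA")) {
    tab_e <- bank$gauss[[d]]
    for (el in c("H", "C", "N", "O", "S")) {
      s <- seq(0.05, tab_e$validity_smax, length.out = 40)
      f_x <- suppressWarnings(gaussian_ff(el, s, bank$gauss[["five-gauss"]]))
      f_conv <- mott_bethe(f_x, element_z(el), s)
      f_tab <- gaussian_ff(el, s, tab_e)
      expect_lt(max(abs(f_conv - f_tab)) / max(abs(f_tab)), 0.05,
                label = paste(d, el))
    }
  }
})
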