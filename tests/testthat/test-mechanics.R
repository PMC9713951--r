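test_that("radius_from_volume inverts the sphere-volume formula", {
  expect_equal(radius_from_volume(4 * pi / 3), 1)
  ## frozen from the independent uniroot inversion of (4/3) pi r^3 = V
  expect_equal(radius_from_volume(268.0826e-6), 0.0400000013, tolerance = 1e-7)
  for (V in c(1e-6, 2.5e-4, 3)) {
    r <- radius_from_volume(V)
    expect_equal(4 / 3 * pi * r^3, V, tolerance = 1e-12)
  }
  expect_error(radius_from_volume(0), "V must be")
  expect_error(radius_from_volume(-1), "V must be")
})

test_that("stretches from volumes satisfy the spherical kinematics", {
  d0 <- stretches_from_volumes(2e-4, 2e-4)
  expect_equal(d0$lam1, 1)
  expect_equal(d0$lam2, 1)
  expect_equal(d0$I1, 3)
  d8 <- stretches_from_volumes(8, 1)
  expect_equal(d8$lam1, 2)
  expect_equal(d8$lam2, 0.25)
  expect_equal(d8$lam3, d8$lam1)
  ## incompressibility identity over random volume pairs
  set.seed(42)
  for (i in 1:25) {
    V0 <- runif(1, 1e-5, 1e-3)
    V <- V0 * runif(1, 0.3, 6)
    d <- stretches_from_volumes(V, V0)
    expect_equal(d$lam1^2 * d$lam2, 1, tolerance = 1e-12)
    expect_gte(d$I1, 3)
  }
  expect_error(stretches_from_volumes(0, 1), "must be > 0")
})

test_that("reference volume from thickness inverts the thinning relation", {
  expect_equal(reference_volume_from_thickness(2.75e-3, 2.75e-3, 2e-4), 2e-4)
  expect_equal(reference_volume_from_thickness(1, 4, 8), 8 * (1 / 4)^1.5)
  ## composition round trip: h = lam2 * h0
  V0 <- 1.5e-4; V <- 2.6e-4; h0 <- 2.75e-3
  h <- stretches_from_volumes(V, V0)$lam2 * h0
  expect_equal(reference_volume_from_thickness(h, h0, V), V0,
               tolerance = 1e-12)
  expect_error(reference_volume_from_thickness(0, 1, 1), "must be > 0")
})

test_that("thin-wall law agrees with the thick-wall logarithmic relation", {
  expect_equal(thin_wall_pressure(0, 1e-3, 0.04), 0)
  expect_equal(thin_wall_pressure(10e3, 2.5e-3, 0.04), 2500)
  expect_equal(log_wall_pressure(5, 1, 1), 0)
  expect_error(log_wall_pressure(5, 1, 0.9), "b_out must be")
  ## relative difference < 1% at b/a = 1.01, monotone growth on (1, 2]
  rel_diff <- function(ba) {
    a <- 0.04; h <- (ba - 1) * a / 2
    p_log <- log_wall_pressure(1, a, ba * a)
    abs(p_log - thin_wall_pressure(1, h, a)) / p_log
  }
  expect_lt(rel_diff(1.01), 0.01)
  ratios <- seq(1.001, 2, length.out = 40)
  diffs <- vapply(ratios, rel_diff, numeric(1))
  expect_true(all(diff(diffs) > 0))
  ## 2% consistency band for b/a <= 1.04
  expect_true(all(vapply(seq(1.001, 1.04, length.out = 10), rel_diff,
                         numeric(1)) <= 0.02))
})

test_that("stress difference matches the energy's finite-difference gradient", {
  mat <- material_model(mu0 = 20e3, b_stiff = 0)
  d <- deformation_state(1.2)
  ## neo-Hookean reduction
  expect_equal(demiray_fung_stress_difference(d, mat)$t_diff,
               20e3 * (1.2^2 - 1.2^-4))
  expect_equal(demiray_fung_stress_difference(deformation_state(1),
                                              material_model(5e3, 5))$t_diff, 0)
  for (l1 in c(1.05, 1.2, 1.5)) {
    for (b in c(0, 1, 5)) {
      mat <- material_model(mu0 = 12e3, b_stiff = b)
      t_pkg <- demiray_fung_stress_difference(deformation_state(l1),
                                              mat)$t_diff
      t_fd <- oracle_moduli_fd(l1, l1^-2, 12e3, b)$t_diff
      expect_equal(t_pkg, t_fd, tolerance = 1e-6)
    }
  }
})

test_that("t_diff is monotone in mu0 and b; P monotone in V", {
  d <- stretches_from_volumes(1.5, 1)
  tds <- vapply(c(1e3, 5e3, 2e4), function(mu)
    demiray_fung_stress_difference(d, material_model(mu, 5))$t_diff,
    numeric(1))
  expect_true(all(diff(tds) > 0))
  tds_b <- vapply(c(0, 2, 5, 10), function(b)
    demiray_fung_stress_difference(d, material_model(5e3, b))$t_diff,
    numeric(1))
  expect_true(all(diff(tds_b) > 0))
  ## doubling mu0 doubles t_diff (linearity)
  expect_equal(2 * tds[1],
               demiray_fung_stress_difference(d, material_model(2e3, 5))$t_diff)
  V0 <- 1.5e-4
  mat <- material_model(3e3, 5)
  Ps <- vapply(seq(1.05, 4, length.out = 20), function(q) {
    g <- compartment_geometry(q * V0, V0)
    thin_wall_pressure(demiray_fung_stress_difference(g$defm, mat)$t_diff,
                       g$h, g$r)
  }, numeric(1))
  expect_true(all(diff(Ps) > 0))
})

test_that("closed-form moduli match the finite-difference oracle", {
  for (l1 in c(1.05, 1.2, 1.5)) {
    for (b in c(0, 1, 5)) {
      for (mu0 in c(5e3, 2e4, 8e4)) {
        m <- incremental_moduli(deformation_state(l1), material_model(mu0, b))
        o <- oracle_moduli_fd(l1, l1^-2, mu0, b)
        expect_equal(m$alpha, o$alpha, tolerance = 1e-6)
        expect_equal(m$gamma, o$gamma, tolerance = 1e-6)
        expect_equal(m$beta2, o$beta2, tolerance = 1e-6)
      }
    }
  }
})

test_that("moduli have the classical limit and exact alpha/gamma ratio", {
  mat <- material_model(20e3, 5)
  m <- incremental_moduli(deformation_state(1 + 1e-6), mat)
  expect_equal(m$alpha, 20e3, tolerance = 1e-3)
  expect_equal(m$gamma, 20e3, tolerance = 1e-3)
  expect_equal(m$beta2, 40e3, tolerance = 1e-3)
  for (l1 in c(1.05, 1.3, 1.8)) {
    d <- deformation_state(l1)
    m <- incremental_moduli(d, mat)
    expect_equal(m$alpha / m$gamma, d$lam1^2 / d$lam2^2, tolerance = 1e-14)
  }
})

test_that("published beta variants differ by the documented factors", {
  d <- deformation_state(1 + 1e-8)
  mat <- material_model(10e3, 5)
  expect_equal(incremental_moduli(d, mat, "derived")$beta2, 2e4,
               tolerance = 1e-6)
  expect_equal(incremental_moduli(d, mat, "eq19")$beta2, 2e4,
               tolerance = 1e-6)
  expect_equal(incremental_moduli(d, mat, "eq17")$beta2, 4e4,
               tolerance = 1e-6)
  ## eq17 is exactly twice eq19 for any state
  d2 <- deformation_state(1.4)
  expect_equal(incremental_moduli(d2, mat, "eq17")$beta2,
               2 * incremental_moduli(d2, mat, "eq19")$beta2)
})

test_that("pressure route to the moduli equals the constitutive route", {
  mat <- material_model(mu0 = 20e3, b_stiff = 5)
  geom <- make_geom(1.5)
  t_diff <- demiray_fung_stress_difference(geom$defm, mat)$t_diff
  P <- thin_wall_pressure(t_diff, geom$h, geom$r)
  m1 <- incremental_moduli(geom$defm, mat)
  m2 <- moduli_from_pressure(P, geom, 5)
  expect_equal(m2$alpha, m1$alpha, tolerance = 1e-9)
  expect_equal(m2$gamma, m1$gamma, tolerance = 1e-9)
  expect_equal(m2$beta2, m1$beta2, tolerance = 1e-9)
  ## P = 0 gives vanishing moduli
  m0 <- moduli_from_pressure(0, geom, 5)
  expect_equal(c(m0$alpha, m0$gamma, m0$beta2), c(0, 0, 0))
  expect_error(moduli_from_pressure(-5, geom, 5), "P must be")
})

test_that("beta2 from the pressure route stays finite as V approaches V0", {
  ## B_coef itself diverges at V = V0 (t_diff -> 0), but the product
  ## beta2 = B_coef * t_diff tends to 2 mu0: evaluate at a small excess volume
  mat <- material_model(mu0 = 20e3, b_stiff = 5)
  V0 <- 1.5e-4
  geom <- compartment_geometry((1 + 1e-6) * V0, V0)
  t_diff <- demiray_fung_stress_difference(geom$defm, mat)$t_diff
  P <- thin_wall_pressure(t_diff, geom$h, geom$r)
  m <- moduli_from_pressure(P, geom, 5)
  expect_equal(m$beta2, 2 * 20e3, tolerance = 1e-3)
  expect_error(stretch_coefficients(V0, V0, 5), "undefined at V = V0")
})

test_that("constructors reject invalid states", {
  expect_error(material_model(-1, 5), "mu0")
  expect_error(material_model(1e3, -2), "b_stiff")
  expect_error(fluid_model(0), "rho_fluid")
  expect_error(compartment_geometry(0, 1e-4), "V must be")
  expect_error(deformation_state(-1), "lam1")
})
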