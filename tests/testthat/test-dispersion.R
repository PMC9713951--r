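test_that("the wavenumber quartic factors exactly in the unstressed limit", {
  mu0 <- 20e3; rho <- 1000
  m <- incremental_moduli(deformation_state(1), material_model(mu0, 5))
  for (c in c(1, 3, 4.4)) {
    r <- quadratic_wave_roots(m, rho, c)
    expect_equal(sort(Re(c(r$s1sq, r$s2sq))),
                 sort(c(1, 1 - rho * c^2 / mu0)), tolerance = 1e-12)
    expect_equal(max(abs(Im(c(r$s1sq, r$s2sq)))), 0, tolerance = 1e-12)
  }
})

test_that("returned roots satisfy the quartic with small residual", {
  geom <- make_geom(1.3)
  mods <- moduli_from_pressure(mmhg_to_pa(15), geom, 5)
  coef_scale <- max(abs(c(mods$gamma, mods$beta2, mods$alpha)))
  for (c in c(0.5, 2, 5, 10)) {
    r <- quadratic_wave_roots(mods, 1000, c)
    for (s2 in c(r$s1sq, r$s2sq)) {
      resid <- mods$gamma * s2^2 - (mods$beta2 - 1000 * c^2) * s2 +
        (mods$alpha - 1000 * c^2)
      expect_lt(Mod(resid), 1e-9 * coef_scale)
    }
  }
  ## ordering: s1sq has the larger real part
  r <- quadratic_wave_roots(mods, 1000, 3)
  expect_gte(Re(r$s1sq), Re(r$s2sq))
})

test_that("a negative discriminant yields a conjugate pair without error", {
  ## construct moduli with (2b - rc2)^2 < 4 g (a - rc2)
  m <- structure(list(alpha = 4e4, gamma = 3.9e4, beta2 = 2e4,
                      beta_variant = "derived"), class = "moduli")
  disc <- (2e4 - 1000)^2 - 4 * 3.9e4 * (4e4 - 1000)
  expect_lt(disc, 0)
  r <- quadratic_wave_roots(m, 1000, 1)
  expect_equal(r$s1sq, Conj(r$s2sq), tolerance = 1e-12)
  expect_error(quadratic_wave_roots(
    structure(list(alpha = 0, gamma = 0, beta2 = 0), class = "moduli"),
    1000, 1), "degenerate")
})

test_that("compositional residual equals the monolithic transcription", {
  V0 <- 1.5e-4
  for (variant in c("derived", "eq19")) {
    for (ratio in c(1.2, 1.5)) {
      geom <- compartment_geometry(ratio * V0, V0)
      P <- mmhg_to_pa(20)
      ctx <- characteristic_context(P, geom, b_stiff = 5,
                                    beta_variant = variant)
      grid <- expand.grid(c = c(1.2, 2.5, 4, 6, 9), f = c(150, 325, 500))
      for (i in seq_len(nrow(grid))) {
        th_pkg <- characteristic_residual(grid$c[i], grid$f[i], ctx)
        th_mono <- oracle_theta_monolithic(grid$c[i], grid$f[i], P,
                                           geom$V, V0, geom$h0,
                                           beta_variant = variant)
        expect_lt(Mod(as.complex(th_pkg) - th_mono), 1e-9 * Mod(th_mono))
      }
    }
  }
})

test_that("the residual vanishes at solved roots and not elsewhere", {
  geom <- make_geom(1.3)
  ctx <- characteristic_context(mmhg_to_pa(15), geom)
  f <- 300
  c_star <- forward_phase_velocity(f, ctx)
  expect_lt(Mod(characteristic_residual(c_star, f, ctx)),
            1e-8 * Mod(characteristic_residual(0.5 * c_star, f, ctx)))
  expect_error(characteristic_residual(1600, f, ctx), "cp")
  expect_error(characteristic_residual(3, -1, ctx), "f must be")
})

test_that("the residual is continuous across the discriminant sign change", {
  geom <- make_geom(1.3)
  ctx <- characteristic_context(mmhg_to_pa(15), geom)
  cs <- seq(0.5, 12, by = 0.1)
  th <- vapply(cs, function(cc) {
    v <- characteristic_residual(cc, 300, ctx)
    Re(v) + Im(v)
  }, numeric(1))
  jumps <- abs(diff(th))
  ## no isolated jump: each increment bounded by 5x its neighbours' scale
  local_scale <- pmax(stats::filter(jumps, rep(1 / 5, 5), sides = 2),
                      1e-6 * max(jumps))
  inner <- !is.na(local_scale)
  expect_true(all(jumps[inner] <= 5 * local_scale[inner]))
})

test_that("forward dispersion is rising and increases with pressure", {
  geom <- make_geom(1.3)
  ctx <- characteristic_context(mmhg_to_pa(15), geom)
  expect_gt(forward_phase_velocity(500, ctx), forward_phase_velocity(150, ctx))
  freqs <- seq(150, 500, 50)
  c_lo <- forward_dispersion_curve(freqs, ctx)
  c_hi <- forward_dispersion_curve(
    freqs, characteristic_context(mmhg_to_pa(30), geom))
  expect_true(all(c_hi$phase_velocity_m_s > c_lo$phase_velocity_m_s))
})

test_that("forward curves exist for the standard fitting conditions", {
  ## b = 5, h0 = 2.75 mm, V = 1.3 V0, P = 10 mmHg
  geom <- make_geom(1.3)
  ctx <- characteristic_context(mmhg_to_pa(10), geom, b_stiff = 5)
  cv <- forward_dispersion_curve(seq(150, 500, 25), ctx)
  expect_equal(nrow(cv), 15)
  expect_true(all(is.finite(cv$phase_velocity_m_s)))
  expect_true(all(cv$phase_velocity_m_s > 0))
  ## every emitted sample satisfies the normalized residual bound
  for (i in seq_len(nrow(cv))) {
    th <- characteristic_residual(cv$phase_velocity_m_s[i],
                                  cv$frequency_hz[i], ctx)
    expect_lt(Mod(th) / attr(th, "scale"), 1e-8)
  }
  ## branch continuity: adjacent increments bounded by the local secant trend
  dc <- abs(diff(cv$phase_velocity_m_s))
  expect_true(all(dc[-1] <= 5 * pmax(dc[-length(dc)], 1e-4)))
})

test_that("forward solving is deterministic and order-invariant", {
  geom <- make_geom(1.5)
  ctx <- characteristic_context(mmhg_to_pa(20), geom)
  expect_equal(nrow(forward_dispersion_curve(numeric(0), ctx)), 0)
  freqs <- c(150, 300, 450)
  a <- forward_dispersion_curve(freqs, ctx)
  b <- forward_dispersion_curve(rev(freqs), ctx)
  expect_identical(a, b)
})

test_that("the stressed coefficients reduce to the classical ones as P -> 0", {
  V0 <- 1.5e-4
  geom <- compartment_geometry((1 + 1e-8) * V0, V0)
  m <- moduli_from_pressure(thin_wall_pressure(
    demiray_fung_stress_difference(geom$defm, material_model(20e3, 5))$t_diff,
    geom$h, geom$r), geom, 5)
  expect_equal(m$alpha / m$gamma, 1, tolerance = 1e-6)
  expect_equal(m$beta2 / (2 * m$alpha), 1, tolerance = 1e-6)
})

test_that("the solver reproduces an independent unstressed fluid-loaded curve", {
  mu0 <- 20e3; h <- 2.5e-3
  m_cl <- incremental_moduli(deformation_state(1), material_model(mu0, 5))
  fl <- fluid_model()
  theta_fun <- function(cc, ff) {
    lamb_characteristic(cc, ff, m_cl, h, 1000, fl)
  }
  for (f in c(150, 300, 500)) {
    ## package path: bracketed scan + bisection on the package residual
    grid <- seq(0.2, 15, by = 0.2)
    g <- vapply(grid, function(cc) { v <- theta_fun(cc, f); Re(v) + Im(v) },
                numeric(1))
    i <- which(g[-1] * g[-length(g)] < 0)[1]
    lo <- grid[i]; hi <- grid[i + 1]; glo <- g[i]
    while (hi - lo > 1e-10) {
      mid <- (lo + hi) / 2
      gm <- { v <- theta_fun(mid, f); Re(v) + Im(v) }
      if (glo * gm <= 0) hi <- mid else { lo <- mid; glo <- gm }
    }
    c_pkg <- (lo + hi) / 2
    c_ind <- oracle_classical_a0(f, mu0, h)
    expect_equal(c_pkg, c_ind, tolerance = 1e-6)
  }
})
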