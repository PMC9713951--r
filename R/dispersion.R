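## Pre-stressed, fluid-loaded (leaky) Lamb-wave characteristic equation for the
## antisymmetric transverse branch, and the forward phase-velocity solver.
##
## Theta(c, f) = gamma s1 (1 + s2^2)^2 tanh(s1 k h)
##             - gamma s2 (1 + s1^2)^2 tanh(s2 k h)
##             + rhoF c^2 (s1^2 - s2^2) / xi
## with s1^2, s2^2 the roots of gamma s^4 - (2beta - rho c^2) s^2
## + (alpha - rho c^2) = 0, k = 2 pi f / c, and xi = sqrt(1 - c^2/cp^2)
## (the standard leaky-plate convention; a literal `linear` reading
## xi = 1 - c^2/cp^2 is available for reproduction studies). The fluid loads
## both faces symmetrically (organ in a water bath).

#' Context for the pressurized-compartment characteristic equation
#'
#' Bundles everything the dispersion relation needs: pressure, geometry,
#' strain-stiffening exponent, fluid and solid densities, plus the
#' configuration switches for the published-form ambiguities.
#'
#' @param P inflation pressure, Pa (> 0; the stressed characteristic equation
#'   degenerates at exactly P = 0, where all moduli vanish).
#' @param geom a [compartment_geometry()].
#' @param b_stiff strain-stiffening exponent (default 5, the soft-tissue
#'   value used for fitting).
#' @param fluid a [fluid_model()].
#' @param rho_solid wall density, kg/m^3.
#' @param beta_variant,xi_convention,fluid_term dispersion-form switches; see
#'   [incremental_moduli()] and the module notes. Defaults `"derived"`,
#'   `"sqrt"` and `"ratio"` (fluid term divided by xi).
#' @return object of class `characteristic_context`.
#' @export
characteristic_context <- function(P, geom, b_stiff = 5,
                                   fluid = fluid_model(),
                                   rho_solid = 1000,
                                   beta_variant = c("derived", "eq17", "eq19"),
                                   xi_convention = c("sqrt", "linear"),
                                   fluid_term = c("ratio", "product")) {
  stopifnot(inherits(geom, "compartment_geometry"), inherits(fluid, "fluid_model"))
  if (!is.finite(P) || P < 0) stop_domain("P must be >= 0")
  structure(list(P = P, geom = geom, b_stiff = b_stiff, fluid = fluid,
                 rho_solid = rho_solid,
                 beta_variant = match.arg(beta_variant),
                 xi_convention = match.arg(xi_convention),
                 fluid_term = match.arg(fluid_term)),
            class = "characteristic_context")
}

#' Roots of the acoustoelastic wavenumber-ratio quartic
#'
#' Solves \eqn{\gamma s^4 - (2\beta - \rho c^2) s^2 + (\alpha - \rho c^2) = 0}
#' for \eqn{s^2} with complex arithmetic. `s1sq` is the root with the larger
#' real part (ties broken by the larger imaginary part), which keeps the
#' characteristic function single-valued.
#'
#' @param moduli a `moduli` object.
#' @param rho_solid wall density, kg/m^3.
#' @param c phase velocity, m/s.
#' @return list with complex `s1sq`, `s2sq`.
#' @export
quadratic_wave_roots <- function(moduli, rho_solid, c) {
  g <- moduli$gamma
  if (g == 0) {
    stop_domain("gamma = 0: the stressed characteristic equation is degenerate ",
                "(P = 0 or V = V0); use the unstressed classical branch instead")
  }
  ## polynomial in s^2, coefficients in increasing order
  rt <- polyroot(c(moduli$alpha - rho_solid * c^2,
                   -(moduli$beta2 - rho_solid * c^2),
                   g))
  ord <- order(Re(rt), Im(rt), decreasing = TRUE)
  rt <- rt[ord]
  list(s1sq = rt[1], s2sq = rt[2])
}

#' Characteristic function of the fluid-loaded plate from explicit moduli
#'
#' The compositional building block shared by the stressed and classical
#' paths: given incremental moduli (from [moduli_from_pressure()] for the
#' pressurized wall, or [incremental_moduli()] at \eqn{\lambda_1 = 1} for the
#' unstressed classical limit), evaluates the antisymmetric fluid-loaded
#' plate characteristic function Theta(c, f).
#'
#' @param c phase velocity, m/s (0 < c < cp).
#' @param f frequency, Hz.
#' @param moduli a `moduli` object.
#' @param h plate half-thickness, m.
#' @param rho_solid plate density, kg/m^3.
#' @param fluid a [fluid_model()].
#' @param xi_convention,fluid_term see [characteristic_context()].
#' @return complex residual with attribute `"scale"`.
#' @export
lamb_characteristic <- function(c, f, moduli, h, rho_solid, fluid,
                       xi_convention = "sqrt", fluid_term = "ratio") {
  if (any(c <= 0) || any(c >= fluid$cp)) {
    stop_domain("c must lie in (0, cp) for the real-xi leaky convention")
  }
  k <- 2 * pi * f / c
  roots <- quadratic_wave_roots(moduli, rho_solid, c)
  s1 <- sqrt(roots$s1sq)  # principal branch
  s2 <- sqrt(roots$s2sq)
  xi <- switch(xi_convention,
               sqrt = sqrt(1 - c^2 / fluid$cp^2),
               linear = 1 - c^2 / fluid$cp^2)
  fl <- switch(fluid_term,
               ratio = fluid$rho_fluid * c^2 * (roots$s1sq - roots$s2sq) / xi,
               product = fluid$rho_fluid * c^2 * xi * (roots$s1sq - roots$s2sq))
  t1 <- moduli$gamma * s1 * (1 + roots$s2sq)^2 * tanh(s1 * k * h)
  t2 <- moduli$gamma * s2 * (1 + roots$s1sq)^2 * tanh(s2 * k * h)
  theta <- t1 - t2 + fl
  attr(theta, "scale") <- abs(t1) + abs(t2) + abs(fl)
  theta
}

#' Characteristic residual of the pressurized-compartment dispersion relation
#'
#' Evaluates the characteristic function Theta(c, f) compositionally: moduli
#' from pressure via the thin-wall stress substitution, then the
#' wavenumber-ratio roots, then the fluid-loaded plate equation. A
#' (c, f) pair lies on the dispersion curve when Theta = 0.
#'
#' @param c trial phase velocity, m/s (0 < c < cp).
#' @param f frequency, Hz (> 0).
#' @param ctx a [characteristic_context()].
#' @return complex residual, with attribute `"scale"` (sum of term magnitudes,
#'   for normalization).
#' @export
characteristic_residual <- function(c, f, ctx) {
  stopifnot(inherits(ctx, "characteristic_context"))
  if (any(f <= 0)) stop_domain("f must be > 0")
  moduli <- moduli_from_pressure(ctx$P, ctx$geom, ctx$b_stiff, ctx$beta_variant)
  lamb_characteristic(c, f, moduli, ctx$geom$h, ctx$rho_solid, ctx$fluid,
                      ctx$xi_convention, ctx$fluid_term)
}

## Real-valued root indicator: Re + Im. Theta is purely real where both
## s^2 roots are real and purely imaginary where they form a conjugate pair,
## so this single function changes sign at roots in either regime. Candidates
## are verified against the normalized magnitude afterwards.
theta_indicator <- function(cs, f, theta_fun) {
  vapply(cs, function(cc) {
    th <- theta_fun(cc, f)
    Re(th) + Im(th)
  }, numeric(1))
}

theta_norm <- function(cc, f, theta_fun) {
  th <- theta_fun(cc, f)
  sc <- attr(th, "scale")
  if (!is.finite(sc) || sc == 0) return(Inf)
  Mod(th) / sc
}

solve_phase_velocity <- function(f, theta_fun, c_range, c_seed = NULL,
                                 grid_step = 1, c_tol = 1e-12, resid_tol = 1e-8) {
  lo <- max(c_range[1], 1e-3)
  hi <- c_range[2]
  grid <- seq(lo, hi, by = grid_step)
  if (grid[length(grid)] < hi) grid <- c(grid, hi)
  g <- theta_indicator(grid, f, theta_fun)
  i_sc <- which(g[-1] * g[-length(g)] < 0)
  roots <- numeric(0)
  for (i in i_sc) {
    a <- grid[i]; b <- grid[i + 1]
    ga <- g[i]
    while (b - a > c_tol) {
      m <- (a + b) / 2
      gm <- theta_indicator(m, f, theta_fun)
      if (ga * gm <= 0) b <- m else { a <- m; ga <- gm }
    }
    cand <- (a + b) / 2
    if (theta_norm(cand, f, theta_fun) < resid_tol) roots <- c(roots, cand)
  }
  if (length(roots) == 0) {
    return(structure(NA_real_,
                     diagnostic = data.frame(c = grid, indicator = g)))
  }
  if (!is.null(c_seed)) roots[which.min(abs(roots - c_seed))] else min(roots)
}

#' Forward phase velocity at one frequency
#'
#' Finds the slowest phase velocity in `c_range` at which the characteristic
#' residual vanishes (the antisymmetric fundamental branch in this regime), by
#' a bracketed scan of sign changes refined by bisection. When `c_seed` is
#' supplied (branch-continuity seeding from a neighbouring frequency) the
#' root closest to the seed is returned instead of the slowest.
#'
#' @param f frequency, Hz.
#' @param ctx a [characteristic_context()].
#' @param c_range search interval for c, m/s; default c(0.2, 15).
#' @param c_seed optional previous-frequency root, m/s.
#' @param grid_step initial scan resolution, m/s.
#' @param c_tol bisection tolerance, m/s.
#' @return phase velocity, m/s.
#' @export
forward_phase_velocity <- function(f, ctx, c_range = c(0.2, 15), c_seed = NULL,
                                   grid_step = 1, c_tol = 1e-12) {
  stopifnot(inherits(ctx, "characteristic_context"))
  if (f <= 0) stop_domain("f must be > 0")
  if (c_range[1] <= 0 || c_range[2] >= ctx$fluid$cp) {
    stop_domain("c_range must lie within (0, cp)")
  }
  theta_fun <- function(cc, ff) characteristic_residual(cc, ff, ctx)
  res <- solve_phase_velocity(f, theta_fun, c_range, c_seed, grid_step, c_tol)
  if (is.na(res)) {
    stop_domain(sprintf(
      "no dispersion root found at f = %g Hz in [%g, %g] m/s; inspect the indicator scan",
      f, c_range[1], c_range[2]))
  }
  as.numeric(res)
}

#' Forward dispersion curve over a frequency grid
#'
#' Applies [forward_phase_velocity()] across an ascending frequency grid with
#' branch-continuity seeding (each root seeds the search at the next
#' frequency).
#'
#' @param freqs frequencies, Hz, sorted ascending.
#' @param ctx a [characteristic_context()].
#' @param c_range,grid_step,c_tol passed to [forward_phase_velocity()].
#' @return a [dispersion_curve()] data frame with columns `frequency_hz`,
#'   `phase_velocity_m_s`.
#' @export
#' @examples
#' geom <- compartment_geometry(V = 1.3 * 150e-6, V0 = 150e-6)
#' ctx <- characteristic_context(P = mmhg_to_pa(10), geom = geom)
#' forward_dispersion_curve(seq(150, 500, 50), ctx)
forward_dispersion_curve <- function(freqs, ctx, c_range = c(0.2, 15),
                                     grid_step = 1, c_tol = 1e-12) {
  if (length(freqs) == 0) return(dispersion_curve(numeric(0), numeric(0)))
  freqs <- sort(freqs)
  if (freqs[1] <= 0) stop_domain("frequencies must be > 0")
  cs <- numeric(length(freqs))
  seed <- NULL
  for (i in seq_along(freqs)) {
    cs[i] <- tryCatch(
      forward_phase_velocity(freqs[i], ctx, c_range, seed, grid_step, c_tol),
      error = function(e) {
        stop_domain(sprintf("forward solve failed at f = %g Hz: %s",
                            freqs[i], conditionMessage(e)))
      })
    seed <- cs[i]
  }
  dispersion_curve(freqs, cs)
}

#' Dispersion-curve container
#'
#' A plain data frame with columns `frequency_hz` and `phase_velocity_m_s`
#' (plus optional `fill_volume_ml` and `acquisition` labels), carrying class
#' `dispersion_curve`.
#'
#' @param frequency_hz frequencies, Hz, strictly increasing within a curve.
#' @param phase_velocity_m_s phase velocities, m/s (> 0).
#' @param fill_volume_ml,acquisition optional replicate labels.
#' @return data frame of class `dispersion_curve`.
#' @export
dispersion_curve <- function(frequency_hz, phase_velocity_m_s,
                             fill_volume_ml = NULL, acquisition = NULL) {
  d <- data.frame(frequency_hz = frequency_hz,
                  phase_velocity_m_s = phase_velocity_m_s)
  if (!is.null(fill_volume_ml)) d$fill_volume_ml <- fill_volume_ml
  if (!is.null(acquisition)) d$acquisition <- acquisition
  class(d) <- c("dispersion_curve", "data.frame")
  d
}
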