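## Inverse problem: estimate the inflation pressure P from a measured
## dispersion curve by minimizing the summed squared magnitude of the
## characteristic residual over the fitted frequency band with a simplex
## (Nelder-Mead) search. The optimization variable is P in mmHg (scale
## ~10-100), which keeps the 1-D simplex well conditioned; conversion to Pa
## happens inside the objective.

#' Fit configuration for pressure estimation
#'
#' Defaults follow the fitting protocol for bladder vibrometry: fit band
#' 150-500 Hz, initializer 100 mmHg, strain-stiffening exponent 5 and
#' undeformed half-thickness 2.75 mm (a 5.5 mm undeformed wall).
#'
#' @param f_min,f_max closed fitting band, Hz.
#' @param P_init simplex starting point, Pa. Default 100 mmHg.
#' @param b_stiff assumed strain-stiffening exponent.
#' @param h0 undeformed half-thickness, m.
#' @param beta_variant,xi_convention,fluid_term dispersion-form switches,
#'   see [characteristic_context()].
#' @param simplex_tol simplex diameter convergence tolerance, mmHg.
#' @param objective_tol relative objective-change convergence tolerance.
#' @param max_iter iteration cap for the simplex search.
#' @return object of class `fit_config`.
#' @export
fit_config <- function(f_min = 150, f_max = 500,
                       P_init = mmhg_to_pa(100),
                       b_stiff = 5, h0 = 2.75e-3,
                       beta_variant = c("derived", "eq17", "eq19"),
                       xi_convention = c("sqrt", "linear"),
                       fluid_term = c("ratio", "product"),
                       simplex_tol = 1e-3, objective_tol = 1e-10,
                       max_iter = 500) {
  if (f_min <= 0 || f_max <= f_min) stop_domain("need 0 < f_min < f_max")
  if (P_init <= 0) stop_domain("P_init must be > 0")
  structure(list(f_min = f_min, f_max = f_max, P_init = P_init,
                 b_stiff = b_stiff, h0 = h0,
                 beta_variant = match.arg(beta_variant),
                 xi_convention = match.arg(xi_convention),
                 fluid_term = match.arg(fluid_term),
                 simplex_tol = simplex_tol, objective_tol = objective_tol,
                 max_iter = max_iter),
            class = "fit_config")
}

restrict_band <- function(curve, f_min, f_max) {
  keep <- curve$frequency_hz >= f_min & curve$frequency_hz <= f_max
  curve[keep, , drop = FALSE]
}

#' Pressure-fit objective: summed squared characteristic residual
#'
#' \eqn{\sum_i \Theta_i(P)\,\overline{\Theta_i(P)}} over the retained
#' frequencies of the measured curve, where \eqn{\Theta_i(P)} is the
#' characteristic residual evaluated at the measured \eqn{(f_i, c_i)} with
#' trial pressure P. Real-valued and nonnegative by construction.
#'
#' @param P trial pressure, Pa.
#' @param curve a [dispersion_curve()].
#' @param geom a [compartment_geometry()] (its V0 is the fitted reference
#'   volume; cfg$h0 only enters through geom).
#' @param cfg a [fit_config()].
#' @param fluid a [fluid_model()].
#' @return nonnegative scalar.
#' @export
pressure_objective <- function(P, curve, geom, cfg = fit_config(),
                               fluid = fluid_model()) {
  band <- restrict_band(curve, cfg$f_min, cfg$f_max)
  if (nrow(band) == 0) {
    stop_domain(sprintf("no dispersion samples inside the fit band [%g, %g] Hz",
                        cfg$f_min, cfg$f_max))
  }
  ctx <- characteristic_context(P, geom, cfg$b_stiff, fluid,
                                rho_solid = 1000,
                                beta_variant = cfg$beta_variant,
                                xi_convention = cfg$xi_convention,
                                fluid_term = cfg$fluid_term)
  total <- 0
  for (i in seq_len(nrow(band))) {
    th <- characteristic_residual(band$phase_velocity_m_s[i],
                                  band$frequency_hz[i], ctx)
    if (!is.finite(Re(th)) || !is.finite(Im(th))) {
      stop_domain(sprintf("nonfinite residual at f = %g Hz",
                          band$frequency_hz[i]))
    }
    total <- total + Re(th * Conj(th))
  }
  total
}

## Deterministic 1-D Nelder-Mead (the simplex in 1-D is an interval), with the
## standard reflection/expansion/contraction/shrink coefficients. Kept local
## so the fit is bitwise-reproducible from a fixed start.
nm_minimize_1d <- function(fn, x0, step = NULL, x_tol = 1e-3, f_tol = 1e-10,
                           max_iter = 500) {
  if (is.null(step)) step <- max(0.05 * abs(x0), 0.5)
  xs <- c(x0, x0 + step)
  fs <- vapply(xs, fn, numeric(1))
  n_eval <- 2L
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    ord <- order(fs)
    xs <- xs[ord]; fs <- fs[ord]
    if (abs(xs[2] - xs[1]) < x_tol &&
        abs(fs[2] - fs[1]) <= f_tol * (abs(fs[1]) + f_tol)) {
      converged <- TRUE
      break
    }
    xb <- xs[1]                      # best; centroid of the rest is just xb
    xr <- xb + (xb - xs[2])          # reflection
    fr <- fn(xr); n_eval <- n_eval + 1L
    if (fr < fs[1]) {
      xe <- xb + 2 * (xb - xs[2])    # expansion
      fe <- fn(xe); n_eval <- n_eval + 1L
      if (fe < fr) { xs[2] <- xe; fs[2] <- fe } else { xs[2] <- xr; fs[2] <- fr }
    } else if (fr < fs[2]) {
      xs[2] <- xr; fs[2] <- fr
    } else {
      xc <- xb + 0.5 * (xs[2] - xb)  # contraction
      fc <- fn(xc); n_eval <- n_eval + 1L
      if (fc < fs[2]) { xs[2] <- xc; fs[2] <- fc }
      else { xs[2] <- xb + 0.5 * (xs[2] - xb); fs[2] <- fn(xs[2]); n_eval <- n_eval + 1L }
    }
  }
  ord <- order(fs)
  list(x = xs[ord][1], f = fs[ord][1], iterations = iter,
       n_eval = n_eval, converged = converged,
       simplex_size = abs(diff(xs)))
}

#' Estimate compartment pressure from a dispersion curve
#'
#' Simplex (Nelder-Mead) minimization of [pressure_objective()] over P,
#' starting from `cfg$P_init`. The search variable is P in mmHg;
#' nonnegativity is enforced by a quadratic penalty below a small positive
#' floor rather than a hard bound, so the search remains a plain simplex.
#'
#' @inheritParams pressure_objective
#' @return object of class `pressure_estimate` with fields `P_est_pa`,
#'   `P_est_mmhg`, `objective_value`, `n_freqs_used`, `converged`,
#'   `iterations` and `simplex_size`.
#' @export
#' @examples
#' geom <- compartment_geometry(V = 1.3 * 150e-6, V0 = 150e-6)
#' ctx <- characteristic_context(P = mmhg_to_pa(15), geom = geom)
#' curve <- forward_dispersion_curve(seq(150, 500, 25), ctx)
#' estimate_pressure(curve, geom)
estimate_pressure <- function(curve, geom, cfg = fit_config(),
                              fluid = fluid_model()) {
  band <- restrict_band(curve, cfg$f_min, cfg$f_max)
  if (nrow(band) == 0) {
    stop_domain(sprintf("no dispersion samples inside the fit band [%g, %g] Hz",
                        cfg$f_min, cfg$f_max))
  }
  p_floor <- 1e-3  # mmHg; the stressed equation degenerates at exactly P = 0
  obj_mmhg <- function(p) {
    p_eval <- max(p, p_floor)
    base <- pressure_objective(mmhg_to_pa(p_eval), curve, geom, cfg, fluid)
    if (p < p_floor) base <- base * (1 + (p_floor - p)^2)
    base
  }
  res <- nm_minimize_1d(obj_mmhg, pa_to_mmhg(cfg$P_init),
                        x_tol = cfg$simplex_tol, f_tol = cfg$objective_tol,
                        max_iter = cfg$max_iter)
  p_mmhg <- max(res$x, 0)
  structure(list(P_est_pa = mmhg_to_pa(p_mmhg),
                 P_est_mmhg = p_mmhg,
                 objective_value = res$f,
                 n_freqs_used = nrow(band),
                 converged = res$converged,
                 iterations = res$iterations,
                 simplex_size = res$simplex_size),
            class = "pressure_estimate")
}

#' @export
print.pressure_estimate <- function(x, ...) {
  cat(sprintf(
    "pressure_estimate: %.2f mmHg (%.1f Pa)\n  objective = %.4g over %d frequencies; %s after %d iterations\n",
    x$P_est_mmhg, x$P_est_pa, x$objective_value, x$n_freqs_used,
    if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' Infer the reference volume from per-fill thickness measurements
#'
#' Applies \eqn{V_0 = (h/h_0)^{3/2} V} to each (V, h) pair and averages:
#' the per-experiment reference volume used for fitting.
#'
#' @param fills data frame (or list coercible to one) with columns `V` (m^3)
#'   and `h_measured` (m).
#' @param h0 undeformed half-thickness, m.
#' @return mean inferred reference volume V0, m^3.
#' @export
infer_reference_volume <- function(fills, h0) {
  fills <- as.data.frame(fills)
  if (nrow(fills) == 0) stop_domain("fills must be nonempty")
  if (any(fills$V <= 0) || any(fills$h_measured <= 0)) {
    stop_domain("fill volumes and thicknesses must be > 0")
  }
  mean(vapply(seq_len(nrow(fills)), function(i) {
    reference_volume_from_thickness(fills$h_measured[i], h0, fills$V[i])
  }, numeric(1)))
}

#' Sensitivity of the pressure estimate to the fixed parameters
#'
#' Re-runs [estimate_pressure()] over the Cartesian product of candidate
#' strain-stiffening exponents and undeformed half-thicknesses, holding
#' everything else fixed. Changing `h0` rescales the inferred reference
#' volume via \eqn{V_0 \propto h_0^{-3/2}} (the thickness measurements
#' themselves are unchanged), which is how the fixed-parameter uncertainty
#' propagates in practice.
#'
#' @inheritParams pressure_objective
#' @param b_grid candidate strain-stiffening exponents.
#' @param h0_grid candidate undeformed half-thicknesses, m.
#' @return data frame with one row per (b_stiff, h0) cell: `P_est_mmhg`,
#'   `converged`, `error` (NA unless the cell's fit failed) and
#'   `rel_change_vs_default` relative to the cfg default cell (added when the
#'   default cell is in the grid).
#' @export
sensitivity_analysis <- function(curve, geom, cfg = fit_config(),
                                 fluid = fluid_model(),
                                 b_grid = c(2, 5, 10),
                                 h0_grid = c(2.0e-3, 2.75e-3, 3.5e-3)) {
  if (length(b_grid) == 0 || length(h0_grid) == 0) {
    stop_domain("b_grid and h0_grid must be nonempty")
  }
  cells <- expand.grid(b_stiff = b_grid, h0 = h0_grid,
                       KEEP.OUT.ATTRS = FALSE)
  out <- cells
  out$P_est_mmhg <- NA_real_
  out$converged <- NA
  out$error <- NA_character_
  for (i in seq_len(nrow(cells))) {
    cfg_i <- cfg
    cfg_i$b_stiff <- cells$b_stiff[i]
    cfg_i$h0 <- cells$h0[i]
    ## rescale the inferred V0 for the new h0 assumption
    V0_i <- geom$V0 * (cfg$h0 / cells$h0[i])^(3 / 2)
    geom_i <- compartment_geometry(geom$V, V0_i, cells$h0[i])
    fit <- tryCatch(estimate_pressure(curve, geom_i, cfg_i, fluid),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      out$error[i] <- conditionMessage(fit)
    } else {
      out$P_est_mmhg[i] <- fit$P_est_mmhg
      out$converged[i] <- fit$converged
    }
  }
  i_def <- which(out$b_stiff == cfg$b_stiff & out$h0 == cfg$h0)
  if (length(i_def) == 1 && is.finite(out$P_est_mmhg[i_def])) {
    out$rel_change_vs_default <-
      (out$P_est_mmhg - out$P_est_mmhg[i_def]) / out$P_est_mmhg[i_def]
  }
  out
}
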