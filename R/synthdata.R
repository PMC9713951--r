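## Seeded generators for every input the tool consumes. Each generator is the
## documented exact or statistical inverse of a processing stage:
## simulate_iq <-> kasai_velocity, simulate_wavefield <-> kspace_dispersion,
## simulate_dispersion_measurements <-> estimate_pressure, and
## make_method_comparison_dataset <-> lin_ccc_repeated.

#' Noise specification for synthetic measurements
#'
#' @param sigma_c additive Gaussian noise on phase velocity, m/s.
#' @param outlier_fraction fraction of samples/pixels replaced by outliers
#'   (uniform multiplicative corruption on [0.5, 3] x truth, standing in for
#'   bubble-type artifacts).
#' @param pixel_sigma additive pixel noise for movies, as a fraction of the
#'   wave amplitude.
#' @param seed RNG seed recorded in every generated artifact.
#' @return object of class `noise_spec`.
#' @export
noise_spec <- function(sigma_c = 0, outlier_fraction = 0, pixel_sigma = 0,
                       seed = 1L) {
  if (sigma_c < 0 || outlier_fraction < 0 || pixel_sigma < 0) {
    stop_domain("noise parameters must be >= 0")
  }
  structure(list(sigma_c = sigma_c, outlier_fraction = outlier_fraction,
                 pixel_sigma = pixel_sigma, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Simulate a filling experiment via the forward mechanics
#'
#' For each fill volume above the reference volume, computes the principal
#' stretches, the Demiray-Fung stress difference, the thin-wall pressure and
#' the deformed half-thickness. The defaults emulate an ex vivo bladder
#' filling protocol: fills in 10 ml increments, reference volume 150 ml,
#' 5.5 mm undeformed wall, initial shear modulus 3 kPa and stiffening
#' exponent 5, giving pressures of roughly 1-45 mmHg across the fill range.
#'
#' @param fill_volumes_ml deformed volumes, ml; all must exceed `V0_ml`.
#' @param V0_ml reference volume, ml.
#' @param h0 undeformed half-thickness, m.
#' @param mat a [material_model()].
#' @return object of class `filling_protocol`: data frame with columns
#'   `fill_volume_ml`, `V_m3`, `lam1`, `lam2`, `h_m`, `t_diff_pa`,
#'   `P_true_pa`, `P_true_mmhg`.
#' @export
#' @examples
#' simulate_filling_experiment()
simulate_filling_experiment <- function(fill_volumes_ml = seq(170, 280, 10),
                                        V0_ml = 150, h0 = 2.75e-3,
                                        mat = material_model(mu0 = 3e3,
                                                             b_stiff = 5)) {
  if (any(fill_volumes_ml <= V0_ml)) {
    stop_domain("all fill volumes must exceed V0 (slack wall otherwise)")
  }
  V0 <- ml_to_m3(V0_ml)
  rows <- lapply(fill_volumes_ml, function(v_ml) {
    V <- ml_to_m3(v_ml)
    defm <- stretches_from_volumes(V, V0)
    t_diff <- demiray_fung_stress_difference(defm, mat)$t_diff
    h <- defm$lam2 * h0
    P <- thin_wall_pressure(t_diff, h, radius_from_volume(V))
    data.frame(fill_volume_ml = v_ml, V_m3 = V, lam1 = defm$lam1,
               lam2 = defm$lam2, h_m = h, t_diff_pa = t_diff,
               P_true_pa = P, P_true_mmhg = pa_to_mmhg(P))
  })
  out <- do.call(rbind, rows)
  attr(out, "V0_ml") <- V0_ml
  attr(out, "h0") <- h0
  attr(out, "material") <- mat
  class(out) <- c("filling_protocol", "data.frame")
  out
}

#' Simulate replicate dispersion-curve acquisitions
#'
#' Wraps [forward_dispersion_curve()] at the true pressure, then produces R
#' replicate curves: truth plus iid Gaussian noise per sample, with a
#' fraction of samples replaced by multiplicative outliers (uniform on
#' [0.5, 3] x truth). Seeded and bitwise-reproducible.
#'
#' @param P true pressure, Pa.
#' @param geom a [compartment_geometry()].
#' @param freqs frequency grid, Hz.
#' @param R number of replicate acquisitions.
#' @param noise a [noise_spec()].
#' @param b_stiff,fluid forward-model settings, see
#'   [characteristic_context()].
#' @return data frame in the curve CSV schema (`fill_volume_ml`,
#'   `acquisition`, `frequency_hz`, `phase_velocity_m_s`); attribute `truth`
#'   holds the noiseless forward curve.
#' @export
simulate_dispersion_measurements <- function(P, geom, freqs = seq(150, 500, 25),
                                             R = 5, noise = noise_spec(),
                                             b_stiff = 5,
                                             fluid = fluid_model()) {
  ctx <- characteristic_context(P, geom, b_stiff, fluid)
  truth <- forward_dispersion_curve(freqs, ctx)
  set.seed(noise$seed)
  reps <- lapply(seq_len(R), function(r) {
    c_noisy <- truth$phase_velocity_m_s +
      stats::rnorm(nrow(truth), 0, noise$sigma_c)
    if (noise$outlier_fraction > 0) {
      is_out <- stats::runif(nrow(truth)) < noise$outlier_fraction
      c_noisy[is_out] <- truth$phase_velocity_m_s[is_out] *
        stats::runif(sum(is_out), 0.5, 3)
    }
    data.frame(fill_volume_ml = m3_to_ml(geom$V), acquisition = r,
               frequency_hz = truth$frequency_hz,
               phase_velocity_m_s = c_noisy)
  })
  out <- do.call(rbind, reps)
  attr(out, "truth") <- truth
  attr(out, "seed") <- noise$seed
  out
}

#' Synthesize a propagating-wave particle-velocity movie
#'
#' Builds \eqn{v(x,t) = \sum_f A(f)\cos(2\pi f t - k(f) x + \phi_f)} from a
#' dispersion curve (k(f) = 2 pi f / c(f)), with random phases, an amplitude
#' spectrum that is flat over the excitation band with raised-cosine rolloff
#' (loosely emulating a radiation-force tone-burst excitation), an optional
#' reversed-wavenumber component (waves propagating away from the push in
#' both directions), additive pixel noise and outlier pixels. When
#' `wall_rows` is given, returns a full (axial, lateral, time) movie whose
#' wall rows carry the wave and whose remaining rows hold only noise,
#' together with the implied flat [wall_geometry()].
#'
#' @param curve a [dispersion_curve()] defining c(f) (linearly interpolated).
#' @param extent_m lateral extent, m.
#' @param duration_s record duration, s.
#' @param dx,dt spatial and temporal sampling. Must satisfy
#'   `dt <= 1/(2 f_max)` and `dx` at most the smallest half-wavelength.
#' @param amplitude peak particle velocity scale, m/s.
#' @param bidirectional also add the reversed-direction component.
#' @param phase `"pulse"` (default): all components in phase at the origin,
#'   emulating a coherent radiation-force push; `"random"`: iid uniform
#'   component phases (a diffuse field, much harsher for peak picking).
#' @param noise a [noise_spec()] (`pixel_sigma` is relative to `amplitude`).
#' @param wall_rows number of axial pixels spanned by the wall (odd), or NULL
#'   for profile form.
#' @param n_margin_rows noise-only rows added above and below the wall.
#' @return a [velocity_movie()]; for full movies, attribute `wall` holds the
#'   [wall_geometry()]. Attribute `seed` records the RNG seed.
#' @export
simulate_wavefield <- function(curve, extent_m = 0.04, duration_s = 0.064,
                               dx = 3e-4, dt = 2.5e-4, amplitude = 1e-3,
                               bidirectional = FALSE, phase = c("pulse", "random"),
                               noise = noise_spec(),
                               wall_rows = NULL, n_margin_rows = 12) {
  phase <- match.arg(phase)
  f <- curve$frequency_hz
  cph <- curve$phase_velocity_m_s
  if (length(f) < 1) stop_domain("curve must be nonempty")
  f_max <- max(f)
  if (dt > 1 / (2 * f_max)) stop_domain("dt violates the Nyquist limit for the curve")
  min_half_wavelength <- min(cph / f) / 2
  if (dx > min_half_wavelength) {
    stop_domain("dx exceeds the smallest half-wavelength on the curve")
  }
  x <- seq(0, extent_m, by = dx)
  t <- seq(0, duration_s, by = dt)
  ## dense frequency comb, flat across the curve's band with raised-cosine
  ## rolloff *outside* it (the excitation band is wider than the analysis
  ## band); comb spacing well below the record's 1/T resolution so the
  ## synthesized spectrum is effectively continuous (a comb at exactly 1/T
  ## beats against padded FFT bins -- an analysis artifact, not a wave
  ## property)
  band <- max(f) - min(f)
  edge <- 0.15 * band
  f_lo <- max(min(f) - edge, 1 / duration_s)
  f_hi <- min(max(f) + edge, 0.95 / (2 * dt))
  f_comb <- seq(f_lo, f_hi, by = 1 / (4 * duration_s))
  c_comb <- stats::approx(f, cph, xout = f_comb, rule = 2)$y
  amp_env <- rep(1, length(f_comb))
  lo <- f_comb < min(f)
  hi <- f_comb > max(f)
  amp_env[lo] <- 0.5 * (1 - cos(pi * pmax(f_comb[lo] - f_lo, 0) / edge))
  amp_env[hi] <- 0.5 * (1 - cos(pi * pmax(f_hi - f_comb[hi], 0) / edge))
  set.seed(noise$seed)
  phases <- if (phase == "random") {
    stats::runif(length(f_comb), 0, 2 * pi)
  } else {
    ## coherent push: all components aligned at the space-time origin
    rep(0, length(f_comb))
  }
  k_comb <- 2 * pi * f_comb / c_comb
  ## waves radiate away from the push location: the aperture edge for a
  ## single direction, mid-aperture when both directions are kept (a backward
  ## pulse launched at the edge would leave the field of view immediately)
  x_push <- if (bidirectional) extent_m / 2 else 0
  xr <- x - x_push
  prof <- matrix(0, length(x), length(t))
  for (i in seq_along(f_comb)) {
    wave <- outer(-k_comb[i] * xr, 2 * pi * f_comb[i] * t, `+`) + phases[i]
    prof <- prof + amp_env[i] * cos(wave)
  }
  if (bidirectional) {
    phases_b <- if (phase == "random") {
      stats::runif(length(f_comb), 0, 2 * pi)
    } else rep(pi / 4, length(f_comb))
    for (i in seq_along(f_comb)) {
      wave <- outer(k_comb[i] * xr, 2 * pi * f_comb[i] * t, `+`) + phases_b[i]
      prof <- prof + 0.8 * amp_env[i] * cos(wave)
    }
  }
  prof <- prof * amplitude / max(abs(prof))
  corrupt <- function(m) {
    if (noise$pixel_sigma > 0) {
      m <- m + stats::rnorm(length(m), 0, noise$pixel_sigma * amplitude)
    }
    if (noise$outlier_fraction > 0) {
      n_out <- round(noise$outlier_fraction * length(m))
      if (n_out > 0) {
        idx <- sample.int(length(m), n_out)
        m[idx] <- m[idx] + amplitude *
          stats::runif(n_out, 0.5, 3) * sign(stats::runif(n_out) - 0.5)
      }
    }
    m
  }
  if (is.null(wall_rows)) {
    out <- velocity_movie(corrupt(prof), dx, dt)
  } else {
    n_ax <- wall_rows + 2 * n_margin_rows
    v <- array(0, dim = c(n_ax, length(x), length(t)))
    wall_idx <- n_margin_rows + seq_len(wall_rows)
    for (r in wall_idx) v[r, , ] <- prof
    v <- array(corrupt(v), dim = dim(v))
    out <- velocity_movie(v, dx, dt)
    dz <- 2e-4
    attr(out, "wall") <- wall_geometry(
      centerline_z = rep((n_margin_rows + (wall_rows + 1) / 2 - 1) * dz,
                         length(x)),
      half_thickness_px = (wall_rows - 1) / 2, dz = dz)
  }
  attr(out, "seed") <- noise$seed
  out
}

#' Synthesize an IQ sequence from a particle-velocity movie
#'
#' Exact inverse of [kasai_velocity()]: a static random speckle phase field
#' accumulates inter-frame phase increments
#' \eqn{\Delta\phi = 4\pi f_{demod} v\, dt / c_{us}}. Velocities beyond the
#' aliasing limit wrap, as in the estimator.
#'
#' @param movie a 3-D [velocity_movie()].
#' @param f_demod demodulation frequency, Hz.
#' @param c_us ultrasound speed, m/s.
#' @param phase_noise_sd iid phase noise per frame, radians.
#' @param seed RNG seed for the speckle field and phase noise.
#' @return an [iq_sequence()] with one more frame than the movie has velocity
#'   samples.
#' @export
simulate_iq <- function(movie, f_demod = 5e6, c_us = 1540,
                        phase_noise_sd = 0, seed = 1L) {
  stopifnot(inherits(movie, "velocity_movie"))
  v <- movie$v
  if (length(dim(v)) != 3) stop_domain("simulate_iq needs a 3-D movie")
  d <- dim(v)
  prf <- 1 / movie$dt
  set.seed(seed)
  speckle <- stats::runif(d[1] * d[2], 0, 2 * pi)
  amp <- 0.5 + stats::runif(d[1] * d[2])
  frames <- array(0i, dim = c(d[1], d[2], d[3] + 1))
  phase <- matrix(speckle, d[1], d[2])
  frames[, , 1] <- matrix(amp, d[1], d[2]) * exp(1i * phase)
  for (t in seq_len(d[3])) {
    dphi <- 4 * pi * f_demod * v[, , t] * movie$dt / c_us
    if (phase_noise_sd > 0) {
      dphi <- dphi + stats::rnorm(length(dphi), 0, phase_noise_sd)
    }
    phase <- phase + dphi
    frames[, , t + 1] <- matrix(amp, d[1], d[2]) * exp(1i * phase)
  }
  iq_sequence(frames, prf = prf, f_demod = f_demod, c_us = c_us,
              dx = movie$dx, dz = 2e-4)
}

#' Generate a two-method repeated-measures comparison dataset
#'
#' Draws the crossed random-effects structure behind the repeated-measures
#' concordance model: subject, subject x repeat, subject x method,
#' method x repeat and residual effects, all independent zero-mean Gaussians
#' with the stated variances. Two methods per subject x repeat cell. The
#' plug-in concordance of the generating components,
#' \eqn{(\sigma^2_s + \sigma^2_{sn}) / (\sigma^2_s + \sigma^2_{sn} +
#' \sigma^2_{sm} + \sigma^2_{mn} + \sigma^2_e)}, is returned as the recovery
#' target.
#'
#' @param n_subjects number of subjects (>= 3).
#' @param n_repeats repeated measurements per subject and method.
#' @param sigma2_s,sigma2_sn,sigma2_sm,sigma2_mn,sigma2_e variance
#'   components (>= 0).
#' @param grand_mean mean structure (scalar).
#' @param seed RNG seed.
#' @return data frame with columns `subject`, `method`, `repeat_idx`,
#'   `value`; attributes `ccc_target` and `components`.
#' @export
make_method_comparison_dataset <- function(n_subjects = 50, n_repeats = 5,
                                           sigma2_s = 4, sigma2_sn = 1,
                                           sigma2_sm = 1, sigma2_mn = 0.5,
                                           sigma2_e = 0.5,
                                           grand_mean = 20, seed = 1L) {
  if (n_subjects < 3) stop_domain("need >= 3 subjects")
  comps <- c(s = sigma2_s, sn = sigma2_sn, sm = sigma2_sm,
             mn = sigma2_mn, e = sigma2_e)
  if (any(comps < 0)) stop_domain("variance components must be >= 0")
  set.seed(seed)
  s_eff <- stats::rnorm(n_subjects, 0, sqrt(sigma2_s))
  sn_eff <- matrix(stats::rnorm(n_subjects * n_repeats, 0, sqrt(sigma2_sn)),
                   n_subjects, n_repeats)
  sm_eff <- matrix(stats::rnorm(n_subjects * 2, 0, sqrt(sigma2_sm)),
                   n_subjects, 2)
  mn_eff <- matrix(stats::rnorm(2 * n_repeats, 0, sqrt(sigma2_mn)),
                   2, n_repeats)
  grid <- expand.grid(subject = seq_len(n_subjects), method = 1:2,
                      repeat_idx = seq_len(n_repeats),
                      KEEP.OUT.ATTRS = FALSE)
  grid$value <- grand_mean +
    s_eff[grid$subject] +
    sn_eff[cbind(grid$subject, grid$repeat_idx)] +
    sm_eff[cbind(grid$subject, grid$method)] +
    mn_eff[cbind(grid$method, grid$repeat_idx)] +
    stats::rnorm(nrow(grid), 0, sqrt(sigma2_e))
  attr(grid, "ccc_target") <-
    (sigma2_s + sigma2_sn) / sum(comps)
  attr(grid, "components") <- comps
  attr(grid, "seed") <- seed
  grid
}
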