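make_iq_ramp <- function(dz_per_frame, n_ax = 8, n_lat = 10, n_t = 20,
                         prf = 4000, f_demod = 5e6, c_us = 1540) {
  dphi <- 4 * pi * f_demod * dz_per_frame / c_us
  frames <- array(0i, dim = c(n_ax, n_lat, n_t))
  for (t in seq_len(n_t)) frames[, , t] <- exp(1i * (0.3 + (t - 1) * dphi))
  iq_sequence(frames, prf = prf, f_demod = f_demod, c_us = c_us)
}

test_that("autocorrelation velocity recovers uniform motion and aliases", {
  ## static phantom
  iq0 <- make_iq_ramp(0)
  expect_equal(max(abs(kasai_velocity(iq0)$v)), 0)
  ## uniform inter-frame displacement: v = dz * prf
  dz <- 2e-8
  v <- kasai_velocity(make_iq_ramp(dz))$v
  expect_equal(max(abs(v - dz * 4000)), 0, tolerance = 1e-12)
  ## beyond the limit c_us * prf / (4 f_demod) the estimate wraps
  v_nyq <- 1540 * 4000 / (4 * 5e6)          # aliasing velocity limit
  dz_big <- 1.5 * v_nyq / 4000              # 1.5x the limit per frame
  v_wrap <- kasai_velocity(make_iq_ramp(dz_big))$v
  expect_lt(max(v_wrap), 0)                  # wrapped to the negative branch
  expect_equal(max(abs(v_wrap)), 0.5 * v_nyq, tolerance = 1e-9)
  expect_error(kasai_velocity(make_iq_ramp(0, n_t = 3), ensemble = 5),
               "fewer frames")
})

test_that("the 3x3 median filter removes isolated outliers and is idempotent", {
  const <- velocity_movie(array(2, dim = c(8, 9, 4)), 3e-4, 2.5e-4)
  expect_equal(median_filter_movie(const)$v, const$v)
  ## smooth field with one corrupted pixel
  base <- outer(seq_len(12), seq_len(15), function(i, j) 1 + 1e-3 * i + 2e-3 * j)
  m <- array(rep(base, 3), dim = c(12, 15, 3))
  m[6, 7, 2] <- 100 * max(base)
  filt <- median_filter_movie(velocity_movie(m, 3e-4, 2.5e-4))$v
  expect_lt(abs(filt[6, 7, 2] - base[6, 7]) / abs(base[6, 7]), 0.01)
  ## idempotence away from edges on a piecewise-constant field
  pc <- matrix(1, 16, 16); pc[, 9:16] <- 5
  mv <- velocity_movie(array(pc, dim = c(16, 16, 1)), 3e-4, 2.5e-4)
  once <- median_filter_movie(mv)
  twice <- median_filter_movie(once)
  expect_equal(twice$v[3:14, 3:14, ], once$v[3:14, 3:14, ])
})

test_that("wall profiles collapse thickness by median and measure arc length", {
  ## flat wall: arc length equals lateral distance, profile is column median
  n_lat <- 40; n_t <- 6; dz <- 2e-4; dx <- 3e-4
  v <- array(0, dim = c(15, n_lat, n_t))
  for (t in seq_len(n_t)) v[5:9, , t] <- matrix(rep(seq_len(n_lat), each = 5),
                                                5, n_lat) + t
  wall <- wall_geometry(rep(6 * dz, n_lat), half_thickness_px = 2, dz = dz)
  prof <- wall_profile(velocity_movie(v, dx, 2.5e-4), wall)
  expect_equal(nrow(prof$v), n_lat)
  expect_equal(prof$v[3, 2], v[7, 3, 2])
  ## corrupted row inside the wall does not leak through the median
  v2 <- v; v2[6, , ] <- 1e6
  prof2 <- wall_profile(velocity_movie(v2, dx, 2.5e-4), wall)
  expect_equal(prof2$v[3, 2], v[7, 3, 2])
  ## circular-arc wall: recovered arc length matches R * dtheta within 1%
  R_arc <- 0.03
  xs <- (seq_len(n_lat) - 1) * dx
  theta <- asin(xs / R_arc)
  z_center <- R_arc * (1 - cos(theta)) + 10 * dz
  v3 <- array(1, dim = c(40, n_lat, 2))
  wall3 <- wall_geometry(z_center, half_thickness_px = 1, dz = dz)
  prof3 <- wall_profile(velocity_movie(v3, dx, 2.5e-4), wall3)
  arc_true <- R_arc * (max(theta) - min(theta))
  expect_equal(attr(prof3, "arc_length_m"), arc_true, tolerance = 0.01)
  expect_gt(attr(prof3, "arc_length_m"), max(xs))  # arc exceeds the chord
})

test_that("k-space estimation recovers a nondispersive wave to sub-bin accuracy", {
  c0 <- 3
  curve_flat <- dispersion_curve(seq(100, 600, 25), rep(c0, 21))
  mov <- simulate_wavefield(curve_flat, noise = noise_spec(seed = 2))
  kd <- kspace_dispersion(mov, seq(150, 500, 25))
  expect_gte(nrow(kd), 14)
  k_true <- 2 * pi * kd$frequency_hz / c0
  halfbin <- attr(kd, "dk") / 2 / k_true
  rel <- abs(kd$phase_velocity_m_s - c0) / c0
  expect_true(all(rel <= halfbin))
  ## two opposite-direction waves agree with the single-direction estimate
  ## within the combined peak-location uncertainty (each estimate is good to
  ## about half a padded k bin, plus an interpolation margin under the
  ## cross-interference of the two ridges)
  mov2 <- simulate_wavefield(curve_flat, bidirectional = TRUE,
                             noise = noise_spec(seed = 2))
  kd2 <- kspace_dispersion(mov2, seq(150, 500, 25))
  common <- intersect(round(kd$frequency_hz), round(kd2$frequency_hz))
  i1 <- match(common, round(kd$frequency_hz))
  i2 <- match(common, round(kd2$frequency_hz))
  halfbin_rel <- attr(kd, "dk") / 2 / (2 * pi * kd$frequency_hz[i1] / c0)
  expect_true(all(abs(kd2$phase_velocity_m_s[i2] - kd$phase_velocity_m_s[i1])
                  / c0 <= 2.5 * halfbin_rel))
})

test_that("non-propagating temporal oscillation is rejected (k peak at zero)", {
  t <- seq(0, 0.064, 2.5e-4)
  prof <- matrix(rep(sin(2 * pi * 300 * t), each = 40), 40, length(t))
  mov <- velocity_movie(prof, 3e-4, 2.5e-4)
  kd <- kspace_dispersion(mov, c(300))
  expect_equal(nrow(kd), 0)
  expect_gte(nrow(attr(kd, "dropped")), 1)
})

test_that("replicate medians pass through and resist single corrupt curves", {
  f <- seq(150, 500, 50)
  clean <- dispersion_curve(f, 2 + f / 500)
  expect_identical(median_over_acquisitions(list(clean)), clean)
  same5 <- replicate(5, clean, simplify = FALSE)
  med <- median_over_acquisitions(same5)
  expect_equal(med$phase_velocity_m_s, clean$phase_velocity_m_s)
  expect_equal(med$frequency_hz, clean$frequency_hz)
  ## one corrupted replicate of five leaves the median unchanged
  bad <- clean; bad$phase_velocity_m_s <- bad$phase_velocity_m_s * 3
  med2 <- median_over_acquisitions(c(replicate(4, clean, simplify = FALSE),
                                     list(bad)))
  expect_equal(med2$phase_velocity_m_s, clean$phase_velocity_m_s)
  expect_error(median_over_acquisitions(list()), "no acquisitions")
})

test_that("MPVV is the mean per-cell replicate variance", {
  f <- seq(150, 500, 50)
  clean <- dispersion_curve(f, 2 + f / 500)
  tab <- make_acq_table(clean, R = 5)
  expect_equal(mpvv(tab)$mpvv, 0)
  ## known variance: truth + N(0, 4) over 200 cells
  set.seed(31)
  cells <- expand.grid(fill_volume_ml = 1:10,
                       frequency_hz = seq(150, 500, length.out = 20))
  acq <- do.call(rbind, lapply(1:5, function(r) {
    cells$acquisition <- r
    cells$phase_velocity_m_s <- 3 + rnorm(nrow(cells), 0, 2)
    cells
  }))
  res <- mpvv(acq)
  expect_equal(res$n_cells, 200)
  expect_lt(abs(res$mpvv - 4) / 4, 0.15)
  ## single-replicate cells are excluded
  extra <- data.frame(fill_volume_ml = 99, acquisition = 1,
                      frequency_hz = 150, phase_velocity_m_s = 50)
  res2 <- mpvv(rbind(acq, extra))
  expect_equal(res2$n_cells, 200)
  expect_equal(res2$n_excluded, 1)
  expect_equal(res2$mpvv, res$mpvv)
  expect_error(mpvv(extra), "no .* cell")
})
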