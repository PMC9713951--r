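## Wavefield processing chain: particle velocity from beamformed IQ
## (autocorrelation), 3x3 spatial median filtering, wall-profile extraction
## with arc-length reparameterization, 2D-FFT k-space phase-velocity
## estimation, replicate aggregation, and the mean phase-velocity variance
## (MPVV) noise summary.

#' IQ frame sequence container
#'
#' @param frames complex array, dims (axial sample, lateral position, time).
#' @param prf effective frame rate after compounding, Hz.
#' @param f_demod demodulation frequency, Hz.
#' @param c_us compressional ultrasound speed used for beamforming, m/s.
#' @param dx lateral pitch, m.
#' @param dz axial pitch, m.
#' @return object of class `iq_sequence`.
#' @export
iq_sequence <- function(frames, prf, f_demod, c_us = 1540, dx = 3e-4, dz = 2e-4) {
  if (!is.complex(frames) || length(dim(frames)) != 3) {
    stop_domain("frames must be a complex 3-D array (axial, lateral, time)")
  }
  if (dim(frames)[3] < 2) stop_domain("need at least 2 frames")
  if (prf <= 0 || f_demod <= 0) stop_domain("prf and f_demod must be > 0")
  structure(list(frames = frames, prf = prf, f_demod = f_demod,
                 c_us = c_us, dx = dx, dz = dz),
            class = "iq_sequence")
}

#' Particle-velocity movie container
#'
#' Holds either a full (axial, lateral, time) velocity array or a wall
#' profile in (arc position, time) form.
#'
#' @param v real array of particle velocities, m/s; 3-D (axial, lateral,
#'   time) or 2-D matrix (arc position, time).
#' @param dx spatial sampling (lateral pitch or arc-length step), m.
#' @param dt temporal sampling, s.
#' @return object of class `velocity_movie`.
#' @export
velocity_movie <- function(v, dx, dt) {
  if (!is.numeric(v) || !(length(dim(v)) %in% c(2, 3))) {
    stop_domain("v must be a 2-D or 3-D numeric array")
  }
  if (dx <= 0 || dt <= 0) stop_domain("dx and dt must be > 0")
  structure(list(v = v, dx = dx, dt = dt), class = "velocity_movie")
}

is_profile <- function(movie) length(dim(movie$v)) == 2

#' Autocorrelation (Kasai) particle-velocity estimation from IQ data
#'
#' Phase-based lag-1 autocorrelation:
#' \deqn{v = \frac{c_{us}\,\mathrm{prf}}{4\pi f_{demod}}
#'   \arg\!\Big(\sum_{t} IQ_{t+1}\,\overline{IQ_t}\Big)}
#' summed over `ensemble - 1` lag-1 products per output frame (sliding
#' window). Sign convention: positive v corresponds to a positive inter-frame
#' phase increment, i.e. increasing echo phase; the aliasing limit is
#' \eqn{|v| < c_{us}\,\mathrm{prf}/(4 f_{demod})}.
#'
#' @param iq an [iq_sequence()].
#' @param ensemble ensemble length (frames per velocity estimate), >= 2.
#' @return a [velocity_movie()] with `dim(v)[3] = n_frames - ensemble + 1`.
#' @export
kasai_velocity <- function(iq, ensemble = 2) {
  stopifnot(inherits(iq, "iq_sequence"))
  if (ensemble < 2) stop_domain("ensemble must be >= 2")
  d <- dim(iq$frames)
  n_t <- d[3]
  if (n_t < ensemble) stop_domain("fewer frames than ensemble length")
  ## lag-1 products for every adjacent pair
  prod1 <- iq$frames[, , 2:n_t, drop = FALSE] *
    Conj(iq$frames[, , 1:(n_t - 1), drop = FALSE])
  n_out <- n_t - ensemble + 1
  scale <- iq$c_us * iq$prf / (4 * pi * iq$f_demod)
  v <- array(0, dim = c(d[1], d[2], n_out))
  for (j in seq_len(n_out)) {
    acc <- prod1[, , j]
    if (ensemble > 2) {
      for (l in seq_len(ensemble - 2)) acc <- acc + prod1[, , j + l]
    }
    v[, , j] <- scale * Arg(acc)
  }
  velocity_movie(v, iq$dx, 1 / iq$prf)
}

## Vectorized median of 9 equal-length vectors (Paeth's 19-exchange sorting
## network); used for the 3x3 spatial median filter.
median9 <- function(p) {
  xch <- function(i, j) {
    lo <- pmin(p[[i]], p[[j]]); hi <- pmax(p[[i]], p[[j]])
    p[[i]] <<- lo; p[[j]] <<- hi
  }
  xch(2, 3); xch(5, 6); xch(8, 9)
  xch(1, 2); xch(4, 5); xch(7, 8)
  xch(2, 3); xch(5, 6); xch(8, 9)
  xch(1, 4); xch(6, 9); xch(5, 8)
  xch(4, 7); xch(2, 5); xch(3, 6)
  xch(5, 8); xch(5, 3); xch(7, 5)
  xch(5, 3)
  p[[5]]
}

median_filter_frame <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  ## edge replication
  rp <- c(1, seq_len(nr), nr)
  cp <- c(1, seq_len(nc), nc)
  pad <- m[rp, cp, drop = FALSE]
  shifts <- list()
  idx <- 1
  for (dr in 0:2) for (dc in 0:2) {
    shifts[[idx]] <- pad[dr + seq_len(nr), dc + seq_len(nc), drop = FALSE]
    idx <- idx + 1
  }
  med <- median9(shifts)
  dim(med) <- c(nr, nc)
  med
}

#' Spatial 3x3 median filter applied per frame
#'
#' Removes isolated outlier pixels (e.g. bubble artifacts and velocity
#' estimator failures) from each frame of a particle-velocity movie. Borders
#' are handled by edge replication.
#'
#' @param movie a [velocity_movie()] with spatial dimensions >= 3 x 3.
#' @return a filtered [velocity_movie()].
#' @export
median_filter_movie <- function(movie) {
  stopifnot(inherits(movie, "velocity_movie"))
  v <- movie$v
  if (length(dim(v)) == 2) {
    if (any(dim(v) < 3)) stop_domain("spatial dims must be >= 3x3")
    out <- median_filter_frame(v)
  } else {
    if (any(dim(v)[1:2] < 3)) stop_domain("spatial dims must be >= 3x3")
    out <- v
    for (t in seq_len(dim(v)[3])) out[, , t] <- median_filter_frame(v[, , t])
  }
  velocity_movie(out, movie$dx, movie$dt)
}

#' Wall geometry: centerline polyline plus half-thickness
#'
#' Describes the compartment wall within the imaging plane by a centerline
#' (axial position in m as a function of lateral pixel index, strictly one
#' value per lateral position) and a half-thickness in pixels.
#'
#' @param centerline_z axial centerline positions, m, one per lateral index.
#' @param half_thickness_px wall half-thickness in axial pixels.
#' @param dz axial pitch, m.
#' @return object of class `wall_geometry`.
#' @export
wall_geometry <- function(centerline_z, half_thickness_px, dz) {
  if (length(centerline_z) < 2) stop_domain("centerline needs >= 2 points")
  if (half_thickness_px < 0) stop_domain("half_thickness_px must be >= 0")
  structure(list(centerline_z = centerline_z,
                 half_thickness_px = half_thickness_px, dz = dz),
            class = "wall_geometry")
}

#' Extract the wall velocity profile with arc-length reparameterization
#'
#' For each lateral position the particle velocity is collapsed to the median
#' across the wall-thickness pixels (robust against corrupted rows inside the
#' wall). The lateral coordinate is then re-parameterized as arc length along
#' the wall centerline (linear interpolation onto a uniform grid with step
#' `movie$dx`), so wave propagation distance along a curved wall is measured
#' along the wall rather than across the image. Columns whose wall window
#' falls outside the movie are dropped and recorded in the `gaps` attribute.
#'
#' @param movie a 3-D [velocity_movie()].
#' @param wall a [wall_geometry()].
#' @return a profile-form [velocity_movie()] (arc position x time); attribute
#'   `gaps` lists dropped lateral indices.
#' @export
wall_profile <- function(movie, wall) {
  stopifnot(inherits(movie, "velocity_movie"), inherits(wall, "wall_geometry"))
  v <- movie$v
  if (length(dim(v)) != 3) stop_domain("wall_profile needs a 3-D movie")
  d <- dim(v)
  n_lat <- d[2]
  if (length(wall$centerline_z) != n_lat) {
    stop_domain("centerline length must match the lateral dimension")
  }
  row_idx <- round(wall$centerline_z / wall$dz) + 1
  ht <- wall$half_thickness_px
  prof <- matrix(NA_real_, n_lat, d[3])
  gaps <- integer(0)
  for (j in seq_len(n_lat)) {
    rows <- (row_idx[j] - ht):(row_idx[j] + ht)
    rows <- rows[rows >= 1 & rows <= d[1]]
    if (length(rows) == 0) { gaps <- c(gaps, j); next }
    ## median across the wall thickness, per frame
    block <- v[rows, j, , drop = FALSE]
    prof[j, ] <- apply(block, 3, stats::median)
  }
  keep <- setdiff(seq_len(n_lat), gaps)
  prof <- prof[keep, , drop = FALSE]
  ## arc length along the centerline
  x_lat <- (keep - 1) * movie$dx
  z <- wall$centerline_z[keep]
  seg <- sqrt(diff(x_lat)^2 + diff(z)^2)
  s <- c(0, cumsum(seg))
  s_grid <- seq(0, s[length(s)], by = movie$dx)
  prof_s <- matrix(NA_real_, length(s_grid), d[3])
  for (t in seq_len(d[3])) {
    prof_s[, t] <- stats::approx(s, prof[, t], xout = s_grid)$y
  }
  out <- velocity_movie(prof_s, movie$dx, movie$dt)
  attr(out, "gaps") <- gaps
  attr(out, "arc_length_m") <- s[length(s)]
  out
}

## Tukey (tapered cosine) window, taper fraction alpha.
tukey_window <- function(n, alpha = 0.1) {
  if (n == 1) return(1)
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- t < alpha / 2
  hi <- t > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * t[hi] / alpha - 2 / alpha + 1)))
  w
}

## Quadratic sub-bin interpolation around a magnitude peak. Returns the
## fractional offset in [-0.5, 0.5].
subbin_offset <- function(m_minus, m_peak, m_plus) {
  denom <- m_minus - 2 * m_peak + m_plus
  if (denom >= 0) return(0)  # not a proper local max
  off <- 0.5 * (m_minus - m_plus) / denom
  max(min(off, 0.5), -0.5)
}

#' k-space (2D-FFT) phase-velocity estimation from a wall profile
#'
#' Windows the (arc position x time) profile with a Tukey window in both
#' axes, zero-pads, takes the 2-D FFT, and for each requested frequency
#' locates the magnitude peak along k separately in the positive-going and
#' negative-going half-planes. Peaks are refined by quadratic sub-bin
#' interpolation and converted via \eqn{c = 2\pi f / k}; the two directions
#' are merged by median. Samples whose row SNR (peak magnitude / median
#' magnitude across the row) falls below `snr_min`, or whose peak sits at
#' k = 0 / below the k resolution, are dropped with a reason.
#'
#' @param profile a profile-form [velocity_movie()].
#' @param f_grid requested frequencies, Hz (mapped to nearest FFT bins).
#' @param pad zero-padding factor for both axes (default 4).
#' @param snr_min per-frequency SNR threshold (default 2).
#' @param tukey_alpha taper fraction of the analysis window.
#' @return a [dispersion_curve()] with extra columns `snr` and `direction`
#'   ("merged"); attribute `dropped` is a data frame of dropped frequencies
#'   and reasons.
#' @export
kspace_dispersion <- function(profile, f_grid, pad = 4, snr_min = 2,
                              tukey_alpha = 0.1) {
  stopifnot(inherits(profile, "velocity_movie"))
  if (!is_profile(profile)) stop_domain("kspace_dispersion needs a profile-form movie")
  v <- profile$v
  n_x <- nrow(v); n_t <- ncol(v)
  if (n_x < 16 || n_t < 32) {
    stop_domain("profile too small: need >= 16 positions and >= 32 frames")
  }
  w <- outer(tukey_window(n_x, tukey_alpha), tukey_window(n_t, tukey_alpha))
  vw <- v * w
  n_xp <- pad * n_x; n_tp <- pad * n_t
  buf <- matrix(0, n_xp, n_tp)
  buf[seq_len(n_x), seq_len(n_t)] <- vw
  S <- stats::fft(buf)
  mag <- Mod(S)
  df <- 1 / (n_tp * profile$dt)
  dk <- 2 * pi / (n_xp * profile$dx)
  ## one-sided f: bins 2..(n_tp/2); two-sided k handled via half-planes:
  ## spatial bins 2..(n_xp/2) are +k, bins n_xp..(n_xp/2+2) are -k.
  half_x <- floor(n_xp / 2)
  pos_rows <- 2:half_x                    # k = (row-1)*dk
  neg_rows <- n_xp:(half_x + 2)           # k = (n_xp - row + 1)*dk
  est <- data.frame()
  dropped <- data.frame()
  for (f_req in f_grid) {
    bin <- round(f_req / df) + 1
    if (bin < 2 || bin > floor(n_tp / 2)) {
      dropped <- rbind(dropped, data.frame(frequency_hz = f_req,
                                           reason = "outside f range"))
      next
    }
    f_bin <- (bin - 1) * df
    row_mag <- mag[, bin]
    cs <- numeric(0); snrs <- numeric(0); pks <- numeric(0)
    for (dir in c("pos", "neg")) {
      rows <- if (dir == "pos") pos_rows else neg_rows
      m <- row_mag[rows]
      i_pk <- which.max(m)
      snr <- m[i_pk] / stats::median(m)
      if (i_pk == 1 || i_pk == length(m)) next  # peak at k->0 or edge
      off <- subbin_offset(m[i_pk - 1], m[i_pk], m[i_pk + 1])
      k_pk <- (i_pk + off) * dk            # index i corresponds to |k| = i*dk
      if (k_pk <= dk) next
      cs <- c(cs, 2 * pi * f_bin / k_pk)
      snrs <- c(snrs, snr)
      pks <- c(pks, m[i_pk])
    }
    ## keep only directions with a genuine wave: a leakage peak in the empty
    ## half-plane is far weaker than the true direction's peak
    if (length(cs) == 2 && min(pks) < 0.25 * max(pks)) {
      keep_dir <- which.max(pks)
      cs <- cs[keep_dir]; snrs <- snrs[keep_dir]
    }
    if (length(cs) == 0) {
      dropped <- rbind(dropped, data.frame(frequency_hz = f_bin,
                                           reason = "no k peak"))
      next
    }
    snr_f <- max(snrs)
    if (snr_f < snr_min) {
      dropped <- rbind(dropped, data.frame(frequency_hz = f_bin,
                                           reason = "SNR below threshold"))
      next
    }
    est <- rbind(est, data.frame(frequency_hz = f_bin,
                                 phase_velocity_m_s = stats::median(cs),
                                 snr = snr_f))
  }
  if (nrow(est) == 0) {
    curve <- dispersion_curve(numeric(0), numeric(0))
    curve$snr <- numeric(0)
  } else {
    est <- est[!duplicated(est$frequency_hz), , drop = FALSE]
    curve <- dispersion_curve(est$frequency_hz, est$phase_velocity_m_s)
    curve$snr <- est$snr
  }
  attr(curve, "dropped") <- dropped
  attr(curve, "dk") <- dk
  attr(curve, "df") <- df
  curve
}

#' Median dispersion curve across replicate acquisitions
#'
#' Aligns replicate curves on a common frequency grid (nearest bin within
#' half a bin) and takes the per-frequency median of phase velocity.
#' Frequencies present in no more than half of the acquisitions are dropped.
#'
#' @param curves list of [dispersion_curve()] objects (replicates of one
#'   measurement condition).
#' @param f_bin optional bin width for alignment, Hz; default is the smallest
#'   positive frequency spacing found in the curves.
#' @return a [dispersion_curve()] with column `n_acq` (replicates per
#'   frequency).
#' @export
median_over_acquisitions <- function(curves, f_bin = NULL) {
  if (length(curves) == 0) stop_domain("no acquisitions supplied")
  if (length(curves) == 1) return(curves[[1]])
  all_f <- unlist(lapply(curves, function(d) d$frequency_hz))
  if (length(all_f) == 0) stop_domain("all acquisitions are empty")
  if (is.null(f_bin)) {
    sp <- diff(sort(unique(all_f)))
    f_bin <- if (length(sp)) min(sp) else 1
  }
  key <- function(f) round(f / f_bin)
  tab <- do.call(rbind, lapply(seq_along(curves), function(i) {
    d <- curves[[i]]
    if (nrow(d) == 0) return(NULL)
    data.frame(bin = key(d$frequency_hz), f = d$frequency_hz,
               c = d$phase_velocity_m_s)
  }))
  n_acq_total <- length(curves)
  out <- do.call(rbind, lapply(split(tab, tab$bin), function(g) {
    data.frame(frequency_hz = stats::median(g$f),
               phase_velocity_m_s = stats::median(g$c),
               n_acq = nrow(g))
  }))
  out <- out[out$n_acq > n_acq_total / 2, , drop = FALSE]
  out <- out[order(out$frequency_hz), , drop = FALSE]
  curve <- dispersion_curve(out$frequency_hz, out$phase_velocity_m_s)
  curve$n_acq <- out$n_acq
  rownames(curve) <- NULL
  curve
}

#' Mean phase-velocity variance (MPVV)
#'
#' Sample variance (denominator n-1) of phase velocity across replicate
#' acquisitions for each (fill volume, frequency) cell, averaged (unweighted)
#' over all cells with at least two replicates. A single-number summary of
#' measurement noise for one experiment.
#'
#' @param acq_table data frame with columns `fill_volume_ml`, `acquisition`,
#'   `frequency_hz`, `phase_velocity_m_s` (the curve CSV schema).
#' @return list with `mpvv` (m^2/s^2), `n_cells` used, and `n_excluded`
#'   single-replicate cells.
#' @export
mpvv <- function(acq_table) {
  acq_table <- as.data.frame(acq_table)
  need <- c("fill_volume_ml", "frequency_hz", "phase_velocity_m_s")
  if (!all(need %in% names(acq_table))) {
    stop_domain("acq_table needs columns ", paste(need, collapse = ", "))
  }
  cells <- split(acq_table$phase_velocity_m_s,
                 list(acq_table$fill_volume_ml, acq_table$frequency_hz),
                 drop = TRUE)
  ns <- vapply(cells, length, integer(1))
  ok <- ns >= 2
  if (!any(ok)) stop_domain("no (fill, frequency) cell has >= 2 replicates")
  vars <- vapply(cells[ok], stats::var, numeric(1))
  list(mpvv = mean(vars), n_cells = sum(ok), n_excluded = sum(!ok))
}
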