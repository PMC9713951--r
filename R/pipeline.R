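## File formats and the end-to-end pipeline: CSV for tabular data, JSON for
## results and configuration, CSV matrix + JSON sidecar for profile movies.
## Pressures are mmHg and volumes ml in every file; SI inside.

#' Read and write dispersion-curve tables
#'
#' The curve CSV schema has columns `fill_volume_ml`, `acquisition`,
#' `frequency_hz`, `phase_velocity_m_s`.
#'
#' @param path CSV file path.
#' @param tab data frame in the curve schema.
#' @return `read_curves_csv` returns the data frame; `write_curves_csv`
#'   returns `path` invisibly.
#' @export
read_curves_csv <- function(path) {
  if (!file.exists(path)) stop_domain("curve file not found: ", path)
  tab <- utils::read.csv(path)
  need <- c("fill_volume_ml", "acquisition", "frequency_hz",
            "phase_velocity_m_s")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop_domain("curve CSV is missing columns: ", paste(miss, collapse = ", "))
  }
  tab
}

#' @rdname read_curves_csv
#' @export
write_curves_csv <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Read and write profile-form wavefield movies
#'
#' A profile movie is stored as a plain CSV matrix (rows = arc positions,
#' columns = frames, no header) with a JSON sidecar `<path>.json` holding
#' `dx_m`, `dt_s`, `units` and the generator seed when known.
#'
#' @param path CSV file path (sidecar is `<path>.json`).
#' @param movie a profile-form [velocity_movie()].
#' @param seed optional seed recorded in the sidecar.
#' @return `read_wavefield_csv` returns a [velocity_movie()];
#'   `write_wavefield_csv` returns `path` invisibly.
#' @export
read_wavefield_csv <- function(path) {
  if (!file.exists(path)) stop_domain("wavefield file not found: ", path)
  side_path <- paste0(path, ".json")
  if (!file.exists(side_path)) stop_domain("sidecar not found: ", side_path)
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(m) <- NULL
  velocity_movie(m, dx = side$dx_m, dt = side$dt_s)
}

#' @rdname read_wavefield_csv
#' @export
write_wavefield_csv <- function(movie, path, seed = NULL) {
  stopifnot(inherits(movie, "velocity_movie"))
  if (!is_profile(movie)) stop_domain("only profile-form movies are written to CSV")
  utils::write.table(movie$v, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  side <- list(dx_m = movie$dx, dt_s = movie$dt,
               axes = c("arc_position", "time"), units = "m/s")
  if (!is.null(seed)) side$seed <- seed
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Default pipeline configuration
#'
#' A serializable list describing a full synthetic study:
#' `simulate -> fit -> evaluate`. Every run's output embeds the effective
#' configuration. Defaults reproduce the generator's standard conditions:
#' subjects with initial shear moduli spanning soft to cross-linked tissue,
#' 12 fills of 10 ml, 5 replicate acquisitions per fill, phase-velocity noise
#' 0.1 m/s with 2% outliers, and the standard fit settings.
#'
#' @param seed master RNG seed; all stage seeds derive from it.
#' @param n_subjects number of simulated compartments.
#' @param mu0_range range of initial shear moduli across subjects, Pa.
#' @param b_stiff_true generating strain-stiffening exponent.
#' @param V0_ml,h0 generating reference volume (ml) and half-thickness (m).
#' @param fills_ml fill volumes, ml.
#' @param freqs dispersion frequency grid, Hz.
#' @param replicates acquisitions per fill.
#' @param sigma_c,outlier_fraction phase-velocity noise, m/s, and outlier rate.
#' @param h_noise_rel relative noise on the per-fill thickness measurement
#'   used to infer V0.
#' @param fit named list of [fit_config()] overrides.
#' @param n_boot bootstrap draws for the concordance CI.
#' @return configuration list of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_subjects = 6,
                       mu0_range = c(2e3, 8e3), b_stiff_true = 5,
                       V0_ml = 150, h0 = 2.75e-3,
                       fills_ml = seq(170, 280, 10),
                       freqs = seq(150, 500, 25),
                       replicates = 5, sigma_c = 0.1,
                       outlier_fraction = 0.02, h_noise_rel = 0.02,
                       fit = list(), n_boot = 500) {
  cfg <- list(seed = as.integer(seed), n_subjects = n_subjects,
              mu0_range = mu0_range, b_stiff_true = b_stiff_true,
              V0_ml = V0_ml, h0 = h0, fills_ml = fills_ml, freqs = freqs,
              replicates = replicates, sigma_c = sigma_c,
              outlier_fraction = outlier_fraction,
              h_noise_rel = h_noise_rel, fit = fit, n_boot = n_boot)
  class(cfg) <- c("run_config", "list")
  cfg
}

apply_fit_overrides <- function(overrides) {
  cfg <- fit_config()
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  cfg
}

#' Run the full synthetic study pipeline
#'
#' For each simulated subject: generate the filling protocol from the forward
#' mechanics, simulate replicate dispersion acquisitions at each fill, take
#' the per-frequency median across replicates, infer the reference volume
#' from noisy thickness measurements, fit the pressure at each fill, and
#' evaluate (RMSD/ME/RME per subject and pooled, MPVV per subject, and the
#' repeated-measures concordance between estimated and true pressures across
#' subjects with fill index as the repeat).
#'
#' @param config a [run_config()] list, or a path to a JSON file holding one.
#' @return list of class `run_result`: `estimates` (one row per subject and
#'   fill), `per_subject` (measures and MPVV), `pooled`
#'   ([performance_measures()]), `concordance` ([lin_ccc_repeated()] result,
#'   NULL when fewer than 3 subjects), `config`, and `log` (stage messages,
#'   dropped frequencies, truncated components).
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_domain("config file not found: ", config)
    config <- utils::modifyList(run_config(),
                                jsonlite::read_json(config,
                                                    simplifyVector = TRUE))
  }
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))
  set.seed(config$seed)
  mu0s <- seq(config$mu0_range[1], config$mu0_range[2],
              length.out = config$n_subjects)
  subject_seeds <- sample.int(2^20, config$n_subjects)
  fit_cfg <- apply_fit_overrides(config$fit)
  estimates <- list()
  per_subject <- list()
  for (s in seq_len(config$n_subjects)) {
    mat <- material_model(mu0 = mu0s[s], b_stiff = config$b_stiff_true)
    proto <- simulate_filling_experiment(config$fills_ml, config$V0_ml,
                                         config$h0, mat)
    note("subject %d: mu0 = %.0f Pa, %d fills, P range %.2f-%.2f mmHg",
         s, mu0s[s], nrow(proto), min(proto$P_true_mmhg),
         max(proto$P_true_mmhg))
    ## noisy per-fill thickness measurements -> averaged inferred V0
    set.seed(subject_seeds[s])
    h_meas <- proto$h_m * (1 + stats::rnorm(nrow(proto), 0,
                                            config$h_noise_rel))
    V0_hat <- infer_reference_volume(
      data.frame(V = proto$V_m3, h_measured = h_meas), fit_cfg$h0)
    note("subject %d: inferred V0 = %.1f ml (true %.1f ml)",
         s, m3_to_ml(V0_hat), config$V0_ml)
    acq_all <- list()
    for (i in seq_len(nrow(proto))) {
      geom_true <- compartment_geometry(proto$V_m3[i],
                                        ml_to_m3(config$V0_ml), config$h0)
      acq <- simulate_dispersion_measurements(
        proto$P_true_pa[i], geom_true, config$freqs,
        R = config$replicates,
        noise = noise_spec(sigma_c = config$sigma_c,
                           outlier_fraction = config$outlier_fraction,
                           seed = subject_seeds[s] + i),
        b_stiff = config$b_stiff_true)
      acq_all[[i]] <- acq
      reps <- split(acq, acq$acquisition)
      med <- median_over_acquisitions(lapply(reps, function(d) {
        dispersion_curve(d$frequency_hz, d$phase_velocity_m_s)
      }))
      geom_fit <- compartment_geometry(proto$V_m3[i], V0_hat, fit_cfg$h0)
      fit <- estimate_pressure(med, geom_fit, fit_cfg)
      if (!fit$converged) note("subject %d fill %g ml: fit did not converge",
                               s, proto$fill_volume_ml[i])
      estimates[[length(estimates) + 1]] <- data.frame(
        subject = s, fill_volume_ml = proto$fill_volume_ml[i],
        P_meas_mmhg = proto$P_true_mmhg[i],
        P_est_mmhg = fit$P_est_mmhg,
        converged = fit$converged)
    }
    acq_tab <- do.call(rbind, acq_all)
    sub_rows <- do.call(rbind, estimates[
      vapply(estimates, function(d) d$subject[1], numeric(1)) == s])
    pm <- performance_measures(sub_rows$P_est_mmhg, sub_rows$P_meas_mmhg)
    per_subject[[s]] <- data.frame(
      subject = s, mu0_pa = mu0s[s],
      V0_inferred_ml = m3_to_ml(V0_hat),
      rmsd_mmhg = pm$rmsd, me_mmhg = pm$me, rme_pct = pm$rme,
      mpvv_m2s2 = mpvv(acq_tab)$mpvv)
  }
  estimates <- do.call(rbind, estimates)
  per_subject <- do.call(rbind, per_subject)
  pooled <- performance_measures(estimates$P_est_mmhg, estimates$P_meas_mmhg)
  concordance <- NULL
  if (config$n_subjects >= 3) {
    ccc_tab <- rbind(
      data.frame(subject = estimates$subject, method = "estimated",
                 repeat_idx = match(estimates$fill_volume_ml,
                                    sort(unique(estimates$fill_volume_ml))),
                 value = estimates$P_est_mmhg),
      data.frame(subject = estimates$subject, method = "measured",
                 repeat_idx = match(estimates$fill_volume_ml,
                                    sort(unique(estimates$fill_volume_ml))),
                 value = estimates$P_meas_mmhg))
    concordance <- lin_ccc_repeated(ccc_tab, n_boot = config$n_boot,
                                    seed = config$seed)
    if (any(concordance$components_raw < 0)) {
      note("concordance: negative moment estimates truncated to zero (%s)",
           paste(names(concordance$components_raw)[
             concordance$components_raw < 0], collapse = ", "))
    }
  }
  structure(list(estimates = estimates, per_subject = per_subject,
                 pooled = pooled, concordance = concordance,
                 config = config, log = log),
            class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("run_result: %d subjects x %d fills\n",
              x$config$n_subjects, length(x$config$fills_ml)))
  cat("pooled: "); print(x$pooled)
  if (!is.null(x$concordance)) print(x$concordance)
  invisible(x)
}
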