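# End-to-end pipeline driver: simulate (or import) -> clusters -> rdf ->
# tilt -> msd -> viscosity fit, with tidy CSV artifacts and a JSON summary.

`%||%` <- function(a, b) if (is.null(a)) b else a

pipeline_stage <- function(name, code) {
  tryCatch(code, error = function(e) {
    stop_user("pipeline stage '", name, "' failed: ", conditionMessage(e))
  })
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages and writes all artifacts into the output
#' directory: \code{clusters.csv} (time_ns, cutoff_nm, n_clusters, n_max,
#' mean_size), per-cutoff label files, \code{rdf.csv} (r_nm, g),
#' \code{tilt.csv} (time_ns, mean_cos_theta, when orientations exist),
#' \code{msd.csv}, \code{diffusion_records.csv}, \code{summary.json} and
#' \code{run.log}.  Two runs with the same configuration and seed produce
#' byte-identical summaries.
#'
#' @param config a \code{pipeline_config} (see
#'   \code{\link{read_pipeline_config}}) or a list in the same layout.
#' @param seed optional integer overriding \code{config$seed}.
#' @param out_dir optional output directory overriding
#'   \code{config$output$dir}.
#' @return invisibly, a list with the computed objects and artifact paths.
#' @export
run_pipeline <- function(config, seed = NULL, out_dir = NULL) {
  config <- validate_pipeline_config(unclass(config))
  seed <- as.integer(seed %||% config$seed %||% 1L)
  out_dir <- out_dir %||% config$output$dir %||% stop_user(
    "no output directory configured")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)
  logf("memclust %s pipeline run", as.character(utils::packageVersion("memclust")))
  logf("seed = %d", seed)

  an <- config$analysis %||% list()
  cutoffs <- an$cutoffs %||% c(1.7, 2.25)
  logf("cutoffs_nm = %s", paste(cutoffs, collapse = ", "))

  # --- stage: trajectory (simulate or import) -----------------------------
  simulated <- is.null(config$input)
  params <- NULL
  traj <- pipeline_stage("trajectory", {
    if (!simulated) {
      logf("input trajectory = %s", config$input$trajectory)
      read_trajectory(config$input$trajectory,
                      box_length = config$input$box_length)
    } else {
      sim <- config$simulation
      tilt_cfg <- sim$tilt; sim$tilt <- NULL
      n_side <- sim$n_side; sim$n_side <- NULL
      sim$initial <- NULL
      sim$seed <- seed
      params <- do.call(sim_params, sim)
      n_side <- n_side %||% round(sqrt(params$n_inclusions))
      if (n_side^2 != params$n_inclusions)
        stop_user("n_inclusions must be a perfect square for the grid ",
                  "start, or supply simulation$n_side")
      logf("simulating %d inclusions, %d frames", params$n_inclusions,
           params$n_frames)
      tr <- simulate_aggregation(
        make_grid_configuration(n_side, params$box_length), params)
      if (!is.null(tilt_cfg)) {
        tp <- tilt_params(mean_cos = tilt_cfg$mean_cos %||% 0.95,
                          relaxation_time = tilt_cfg$relaxation_time %||% 5,
                          noise_amplitude = tilt_cfg$noise_amplitude %||% 0.05,
                          seed = tilt_cfg$seed %||% (seed + 1L))
        tr$orientations <- simulate_tilt(n_inclusions(tr), n_frames(tr), tp,
                                         frame_interval = params$frame_interval)
      }
      tr
    }
  })
  if (isTRUE(config$output$write_trajectory))
    write_trajectory(traj, file.path(out_dir, "trajectory.tsv"))

  # --- stage: clusters ----------------------------------------------------
  series <- pipeline_stage("clusters", {
    lapply(cutoffs, function(cc) cluster_series(traj, cc))
  })
  names(series) <- as.character(cutoffs)
  cl_tab <- do.call(rbind, lapply(seq_along(cutoffs), function(i) {
    s <- series[[i]]
    data.frame(time_ns = s$times, cutoff_nm = cutoffs[i],
               n_clusters = s$n_clusters, n_max = s$n_max,
               mean_size = s$mean_size)
  }))
  utils::write.csv(cl_tab, file.path(out_dir, "clusters.csv"),
                   row.names = FALSE)
  for (i in seq_along(cutoffs)) {
    s <- series[[i]]
    lab <- data.frame(frame = rep(seq_along(s$times), each = n_inclusions(traj)),
                      inclusion_id = rep(seq_len(n_inclusions(traj)),
                                         length(s$times)),
                      label = as.vector(s$labels))
    utils::write.csv(lab, file.path(out_dir, sprintf("labels_%gnm.csv",
                                                     cutoffs[i])),
                     row.names = FALSE)
  }

  # --- stage: growth law --------------------------------------------------
  main_cut <- as.character(max(cutoffs))
  growth <- pipeline_stage("power_law", {
    s <- series[[main_cut]]
    rng <- an$power_law_range %||%
      c(s$times[s$times > 0][1], max(s$times))
    ok <- sum(s$times >= rng[1] & s$times <= rng[2] & s$times > 0) >= 5 &&
      all(s$n_max[s$times >= rng[1] & s$times <= rng[2] & s$times > 0] > 0)
    if (ok) fit_power_law(s, rng) else NULL
  })

  # --- stage: rdf ---------------------------------------------------------
  rdf <- pipeline_stage("rdf", {
    rdf_2d(traj, bin_width = an$rdf_bin_width %||% 0.05,
           r_max = an$rdf_r_max, frames = an$rdf_frames)
  })
  utils::write.csv(data.frame(r_nm = rdf$bin_centers, g = rdf$g),
                   file.path(out_dir, "rdf.csv"), row.names = FALSE)
  peak <- first_peak(rdf, r_min_search = an$r_min_search %||% 0,
                     prominence = an$prominence %||% 1.2)

  # --- stage: tilt --------------------------------------------------------
  tilt <- NULL
  if (!is.null(traj$orientations)) {
    tilt <- pipeline_stage("tilt", tilt_series(traj))
    utils::write.csv(data.frame(time_ns = tilt$times,
                                mean_cos_theta = tilt$mean_cos_theta),
                     file.path(out_dir, "tilt.csv"), row.names = FALSE)
  }

  # --- stage: msd + records ----------------------------------------------
  msd_cut <- an$msd_cutoff %||% max(cutoffs)
  window <- an$fit_window %||% c(5, 15)
  r_cnt <- if (!is.null(params)) params$inclusion_radius else 1.05
  curves <- pipeline_stage("msd", {
    msd_by_size(traj, cutoff = msd_cut, max_lag = an$msd_max_lag %||%
                  max(window))
  })
  msd_tab <- do.call(rbind, lapply(curves, function(cu)
    data.frame(cluster_size = cu$cluster_size, lag_ns = cu$lags,
               msd_nm2 = cu$msd, n_samples = cu$n_samples)))
  utils::write.csv(msd_tab, file.path(out_dir, "msd.csv"), row.names = FALSE)

  fit <- NULL
  records <- NULL
  enough <- length(curves) >= 2
  if (enough) {
    fit <- pipeline_stage("fit", {
      records <- diffusion_records(curves, window = window, r_cnt = r_cnt)
      eta_w <- if (!is.null(params)) params$eta_w else 7e-4
      temperature <- if (!is.null(params)) params$temperature else 300
      sh <- an$solvent_height %||%
        (if (!is.null(params)) params$solvent_height else Inf)
      f <- fit_viscosity_corrected(records, box_length = traj$box_length,
                                   solvent_height = sh, eta_w = eta_w,
                                   temperature = temperature,
                                   model = an$fit_model %||% "HPW-PS")
      records <- attr(f, "records")
      f
    })
    utils::write.csv(records, file.path(out_dir, "diffusion_records.csv"),
                     row.names = FALSE)
  } else {
    logf("fewer than 2 persistent cluster sizes; viscosity fit skipped")
  }

  summary <- list(
    schema_version = 1L,
    seed = seed,
    simulated = simulated,
    n_inclusions = n_inclusions(traj),
    n_frames = n_frames(traj),
    box_length_nm = traj$box_length,
    cutoffs_nm = cutoffs,
    n_clusters_final = vapply(series, function(s)
      s$n_clusters[length(s$n_clusters)], integer(1)),
    n_max_series = series[[main_cut]]$n_max,
    power_law_exponent = if (!is.null(growth)) growth$exponent else NULL,
    rdf_peak_nm = if (peak$found) peak$r else NULL,
    mean_cos_theta = if (!is.null(tilt)) mean(tilt$mean_cos_theta) else NULL,
    eta_m_hat_Pa_s_m = if (!is.null(fit)) fit$eta_m_hat else NULL,
    chi2_reduced = if (!is.null(fit)) fit$chi2_reduced else NULL,
    fit_model = if (!is.null(fit)) fit$model_name else NULL)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  logf("done")
  invisible(list(trajectory = traj, series = series, growth = growth,
                 rdf = rdf, peak = peak, tilt = tilt, curves = curves,
                 records = records, fit = fit, summary = summary,
                 out_dir = out_dir))
}
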