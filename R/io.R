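# Trajectory and configuration file IO.
#
# The canonical interchange format is column text (tab-separated) with a
# single comment header line carrying the box size:
#
#   #memclust-trajectory box_length_nm=<L>
#   frame  time_ns  inclusion_id  x_nm  y_nm  x_unwrapped  y_unwrapped [ox oy oz]
#
# Wrapped coordinates lie in [0, L); unwrapped coordinates are continuous
# and agree with the wrapped ones modulo L.  Files may be gzipped (.gz).

#' Write a trajectory to the column-text format
#'
#' @param traj a \code{trajectory}.
#' @param path output file; a \code{.gz} suffix writes a gzipped file.
#' @return \code{path}, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  if (!inherits(traj, "trajectory")) stop_user("traj must be a trajectory")
  Tn <- n_frames(traj); n <- n_inclusions(traj)
  dt <- data.table::data.table(
    frame = rep(seq_len(Tn), each = n),
    time_ns = rep(traj$times, each = n),
    inclusion_id = rep(seq_len(n), Tn),
    x_nm = as.vector(traj$x), y_nm = as.vector(traj$y),
    x_unwrapped = as.vector(traj$ux), y_unwrapped = as.vector(traj$uy))
  if (!is.null(traj$orientations)) {
    dt$ox <- as.vector(traj$orientations[, 1, ])
    dt$oy <- as.vector(traj$orientations[, 2, ])
    dt$oz <- as.vector(traj$orientations[, 3, ])
  }
  header <- sprintf("#memclust-trajectory box_length_nm=%.17g",
                    traj$box_length)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  writeLines(header, con)
  close(con)
  data.table::fwrite(dt, path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Read a trajectory from the column-text format
#'
#' Validates on load: consistent inclusion count and ids in every frame,
#' strictly increasing frame times, wrapped coordinates inside the box and
#' consistent with the unwrapped ones modulo the box length, unit
#' orientation vectors when present.
#'
#' @param path file written by \code{\link{write_trajectory}} (or any file
#'   in the documented format).
#' @param box_length box size (nm); only needed when the file lacks the
#'   header line.
#' @return a \code{trajectory}.
#' @export
read_trajectory <- function(path, box_length = NULL) {
  if (!file.exists(path)) stop_user("file not found: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  first <- readLines(con, n = 1)
  close(con)
  skip <- 0L
  if (length(first) == 1 && startsWith(first, "#")) {
    skip <- 1L
    m <- regmatches(first, regexec("box_length_nm=([0-9.eE+-]+)", first))[[1]]
    if (length(m) == 2) box_length <- as.numeric(m[2])
  }
  if (is.null(box_length) || !is.finite(box_length) || box_length <= 0)
    stop_user("box_length not found in header and not supplied")
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "r")
    lines <- readLines(con)
    close(con)
    dt <- data.table::fread(text = lines[(skip + 1):length(lines)],
                            sep = "\t")
  } else {
    dt <- data.table::fread(path, skip = skip, sep = "\t")
  }
  need <- c("frame", "time_ns", "inclusion_id", "x_nm", "y_nm",
            "x_unwrapped", "y_unwrapped")
  if (!all(need %in% names(dt)))
    stop_user("malformed trajectory file: missing columns ",
              paste(setdiff(need, names(dt)), collapse = ", "))
  dtf <- as.data.frame(dt)
  if (anyNA(dtf[, need]))
    stop_user("malformed trajectory file: non-numeric or missing values ",
              "(first bad row ", which(rowSums(is.na(dtf[, need])) > 0)[1],
              ")")
  frames <- sort(unique(dt$frame))
  counts <- table(dt$frame)
  if (length(unique(as.integer(counts))) != 1) {
    bad <- names(counts)[which(counts != counts[1])[1]]
    stop_user("inconsistent inclusion count across frames (frame ", bad,
              " has ", counts[bad], ", expected ", counts[1], ")")
  }
  n <- as.integer(counts[1])
  Tn <- length(frames)
  data.table::setorderv(dt, c("frame", "inclusion_id"))
  ids <- unique(dt$inclusion_id)
  if (length(ids) != n)
    stop_user("inclusion ids are not consistent across frames")
  times <- dt$time_ns[seq(1, nrow(dt), by = n)]
  if (Tn > 1 && any(diff(times) <= 0))
    stop_user("frame times must be strictly increasing")
  shape <- function(col) matrix(dt[[col]], nrow = n, ncol = Tn)
  x <- shape("x_nm"); y <- shape("y_nm")
  ux <- shape("x_unwrapped"); uy <- shape("y_unwrapped")
  if (any(x < 0) || any(x >= box_length) || any(y < 0) || any(y >= box_length))
    stop_user("wrapped coordinates outside [0, box_length)")
  mism <- pmax(abs(min_image_delta(x - ux, box_length)),
               abs(min_image_delta(y - uy, box_length)))
  if (max(mism) > 1e-6)
    stop_user("wrapped and unwrapped coordinates disagree modulo box_length")
  orientations <- NULL
  if (all(c("ox", "oy", "oz") %in% names(dt))) {
    orientations <- array(0, dim = c(n, 3, Tn))
    orientations[, 1, ] <- shape("ox")
    orientations[, 2, ] <- shape("oy")
    orientations[, 3, ] <- shape("oz")
    nrm <- sqrt(orientations[, 1, ]^2 + orientations[, 2, ]^2 +
                orientations[, 3, ]^2)
    if (any(abs(nrm - 1) > 1e-6))
      stop_user("orientation vectors must have unit norm")
  }
  new_trajectory(times, box_length, ux, uy, params = NULL,
                 orientations = orientations)
}

# ---------------------------------------------------------------------------
# Pipeline configuration (YAML)

config_allowed <- function() list(
  top = c("seed", "simulation", "input", "analysis", "output"),
  simulation = c(names(formals(sim_params)), "tilt", "initial", "n_side"),
  tilt = c("mean_cos", "relaxation_time", "noise_amplitude", "seed"),
  input = c("trajectory", "box_length"),
  analysis = c("cutoffs", "rdf_bin_width", "rdf_r_max", "rdf_frames",
               "msd_cutoff", "msd_max_lag", "fit_window", "fit_model",
               "power_law_range", "r_min_search", "prominence",
               "solvent_height"),
  output = c("dir", "write_trajectory"))

check_keys <- function(x, section) {
  unknown <- setdiff(names(x), config_allowed()[[section]])
  if (length(unknown))
    stop_user("unknown key(s) in config section '", section, "': ",
              paste(unknown, collapse = ", "))
}

#' Read and validate a pipeline configuration file
#'
#' The configuration is a YAML file with sections \code{simulation}
#' (fields of \code{\link{sim_params}}, optional \code{tilt} subsection,
#' optional \code{n_side}), \code{input} (an existing trajectory for
#' analysis-only runs), \code{analysis} (cutoffs, RDF binning, MSD window,
#' fit model) and \code{output}.  Unknown keys are rejected; the file
#' round-trips losslessly through \code{\link{write_pipeline_config}}.
#'
#' @param path YAML file.
#' @return a validated config list of class \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_user("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  validate_pipeline_config(cfg)
}

#' @rdname read_pipeline_config
#' @param config a config list.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

validate_pipeline_config <- function(cfg) {
  if (!is.list(cfg)) stop_user("config must be a key-value mapping")
  check_keys(cfg, "top")
  if (!is.null(cfg$simulation)) {
    check_keys(cfg$simulation, "simulation")
    if (!is.null(cfg$simulation$tilt)) check_keys(cfg$simulation$tilt, "tilt")
  }
  if (!is.null(cfg$input)) check_keys(cfg$input, "input")
  if (!is.null(cfg$analysis)) check_keys(cfg$analysis, "analysis")
  if (!is.null(cfg$output)) check_keys(cfg$output, "output")
  if (is.null(cfg$simulation) && is.null(cfg$input))
    stop_user("config needs a 'simulation' or an 'input' section")
  structure(cfg, class = "pipeline_config")
}
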