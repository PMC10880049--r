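#' Simulation parameters for the synthetic membrane generator
#'
#' Bundles the physical and numerical parameters of the Brownian-dynamics
#' aggregation generator.  The defaults describe the standard study system:
#' 100 inclusions of radius 1.05 nm in a 70 nm square periodic box, membrane
#' surface viscosity 4.5e-11 Pa s m, fusing irreversibly at a center-to-center
#' cutoff of 2.25 nm and repacking into hexagonal clusters with 2.1 nm
#' nearest-neighbor spacing (one shared annular lipid shell).
#'
#' @param n_inclusions number of inclusions.
#' @param box_length side of the square periodic box (nm).
#' @param inclusion_radius hydrodynamic radius of a single inclusion (nm).
#' @param eta_m membrane surface viscosity (Pa s m).
#' @param eta_w bulk solvent viscosity (Pa s).
#' @param temperature temperature (K); 0 is allowed and freezes all motion.
#' @param time_step integration step (ns).
#' @param n_frames number of recorded frames (including the initial one).
#' @param frame_interval time between recorded frames (ns); must be an
#'   integer multiple of \code{time_step}.
#' @param fusion_cutoff center-to-center distance (nm) at which clusters fuse.
#' @param packing_distance nearest-neighbor spacing imposed when a fused
#'   cluster is repacked on a triangular lattice (nm).  May be smaller than
#'   \code{2 * inclusion_radius} is not required; lipid-separated packing
#'   exceeds contact distance.
#' @param solvent_height height of the solvent slab used by the finite-size
#'   correction (nm); \code{Inf} for unbounded solvent.
#' @param pbc_mobility logical; if \code{TRUE} (default) the generating
#'   mobilities emulate a periodic simulation box: the finite-size
#'   suppression \code{finite_size_correction()} describes is subtracted
#'   from the infinite-system model mobility.
#' @param seed integer seed; identical parameters and seed give bit-identical
#'   trajectories.
#' @return an object of class \code{sim_params}.
#' @export
sim_params <- function(n_inclusions = 100,
                       box_length = 70,
                       inclusion_radius = 1.05,
                       eta_m = 4.5e-11,
                       eta_w = 7e-4,
                       temperature = 300,
                       time_step = 0.1,
                       n_frames = 1000,
                       frame_interval = 1,
                       fusion_cutoff = 2.25,
                       packing_distance = 2.1,
                       solvent_height = Inf,
                       pbc_mobility = TRUE,
                       seed = 1L) {
  p <- list(n_inclusions = as.integer(n_inclusions), box_length = box_length,
            inclusion_radius = inclusion_radius, eta_m = eta_m, eta_w = eta_w,
            temperature = temperature, time_step = time_step,
            n_frames = as.integer(n_frames), frame_interval = frame_interval,
            fusion_cutoff = fusion_cutoff, packing_distance = packing_distance,
            solvent_height = solvent_height,
            pbc_mobility = isTRUE(pbc_mobility), seed = as.integer(seed))
  validate_sim_params(p)
  class(p) <- "sim_params"
  p
}

validate_sim_params <- function(p) {
  if (!is.finite(p$box_length) || p$box_length <= 0)
    stop_user("box_length must be positive")
  if (p$eta_m <= 0 || p$eta_w <= 0)
    stop_user("viscosities must be positive")
  if (p$temperature < 0)
    stop_user("temperature must be >= 0")
  if (p$time_step <= 0 || p$frame_interval <= 0)
    stop_user("time_step and frame_interval must be positive")
  k <- p$frame_interval / p$time_step
  if (abs(k - round(k)) > 1e-9)
    stop_user("frame_interval must be an integer multiple of time_step")
  if (p$n_inclusions < 1 || p$n_frames < 1)
    stop_user("n_inclusions and n_frames must be >= 1")
  if (p$fusion_cutoff < 0 || p$fusion_cutoff >= p$box_length / 2)
    stop_user("fusion_cutoff must lie in [0, box_length/2)")
  if (p$packing_distance <= 0)
    stop_user("packing_distance must be positive")
  if (p$inclusion_radius <= 0)
    stop_user("inclusion_radius must be positive")
  if (p$solvent_height <= 0)
    stop_user("solvent_height must be positive (Inf for unbounded solvent)")
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Membrane aggregation simulation parameters\n")
  cat(sprintf("  %d inclusions (R = %g nm) in %g nm periodic box\n",
              x$n_inclusions, x$inclusion_radius, x$box_length))
  cat(sprintf("  eta_m = %g Pa s m, eta_w = %g Pa s, T = %g K\n",
              x$eta_m, x$eta_w, x$temperature))
  cat(sprintf("  dt = %g ns, %d frames every %g ns\n",
              x$time_step, x$n_frames, x$frame_interval))
  cat(sprintf("  fusion cutoff %g nm, packing distance %g nm, seed %d\n",
              x$fusion_cutoff, x$packing_distance, x$seed))
  invisible(x)
}

#' Tilt-dynamics parameters
#'
#' Parameters of the mean-reverting (AR(1)/Ornstein-Uhlenbeck) model used to
#' generate per-inclusion axis-tilt fluctuations around an equilibrium
#' mean cosine.
#'
#' @param mean_cos equilibrium mean of cos(theta), in (0, 1].
#' @param relaxation_time relaxation time of the fluctuations (ns).
#' @param noise_amplitude stationary standard deviation of cos(theta)
#'   (dimensionless, >= 0).
#' @param seed integer seed.
#' @return an object of class \code{tilt_params}.
#' @export
tilt_params <- function(mean_cos = 0.95, relaxation_time = 5,
                        noise_amplitude = 0.05, seed = 1L) {
  if (!(mean_cos > 0 && mean_cos <= 1))
    stop_user("mean_cos must lie in (0, 1]")
  if (relaxation_time <= 0) stop_user("relaxation_time must be positive")
  if (noise_amplitude < 0) stop_user("noise_amplitude must be >= 0")
  structure(list(mean_cos = mean_cos, relaxation_time = relaxation_time,
                 noise_amplitude = noise_amplitude, seed = as.integer(seed)),
            class = "tilt_params")
}

#' Membrane hydrodynamic parameters
#'
#' Collects the symbols of the Saffman-Delbruck (SD) and
#' Hughes-Pailthorpe-White / Petrov-Schwille (HPW-PS) models: membrane
#' surface viscosity, bulk solvent viscosity and temperature, with the
#' derived thermal energy k_B T and SD length l_SD = eta_m / (2 eta_w)
#' (the crossover length between membrane- and bulk-dominated drag for a
#' membrane bounded by solvent on both sides).
#'
#' @param eta_m membrane surface viscosity (Pa s m).
#' @param eta_w bulk solvent viscosity (Pa s).
#' @param temperature temperature (K).
#' @return an object of class \code{hydro_params} with fields
#'   \code{thermal_energy} (J) and \code{sd_length} (m) in addition to the
#'   inputs.
#' @export
hydro_params <- function(eta_m = 4.5e-11, eta_w = 7e-4, temperature = 300) {
  if (eta_m <= 0 || eta_w <= 0 || temperature <= 0)
    stop_user("eta_m, eta_w and temperature must all be positive")
  structure(list(eta_m = eta_m, eta_w = eta_w, temperature = temperature,
                 thermal_energy = .kB * temperature,
                 sd_length = eta_m / (2 * eta_w)),
            class = "hydro_params")
}

#' @export
print.hydro_params <- function(x, ...) {
  cat("Membrane hydrodynamic parameters\n")
  cat(sprintf("  eta_m = %g Pa s m, eta_w = %g Pa s, T = %g K\n",
              x$eta_m, x$eta_w, x$temperature))
  cat(sprintf("  kT = %g J, SD length = %g nm\n",
              x$thermal_energy, x$sd_length / .NM))
  invisible(x)
}

#' Single-frame configuration of inclusion positions
#'
#' A frame of in-plane inclusion center-of-mass positions in a square
#' periodic box.  Positions are wrapped into [0, box_length).
#'
#' @param positions numeric matrix with one row per inclusion and two
#'   columns (x, y), in nm.  Positions are wrapped into the box.
#' @param box_length side of the square periodic box (nm).
#' @param time frame time (ns).
#' @return an object of class \code{configuration}.
#' @export
configuration <- function(positions, box_length, time = 0) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 2 || !is.numeric(positions))
    stop_user("positions must be a numeric n x 2 matrix")
  if (!is.finite(box_length) || box_length <= 0)
    stop_user("box_length must be positive")
  positions <- positions %% box_length
  dimnames(positions) <- list(NULL, c("x", "y"))
  structure(list(positions = positions, box_length = box_length, time = time),
            class = "configuration")
}

#' @export
print.configuration <- function(x, ...) {
  cat(sprintf("Configuration: %d inclusions in %g nm box at t = %g ns\n",
              nrow(x$positions), x$box_length, x$time))
  invisible(x)
}

# Internal trajectory constructor.  x, y are wrapped and ux, uy unwrapped
# coordinate matrices (n_inclusions x n_frames).
new_trajectory <- function(times, box_length, ux, uy, params = NULL,
                           orientations = NULL, labels = NULL) {
  stopifnot(is.matrix(ux), is.matrix(uy), length(times) == ncol(ux))
  if (length(times) > 1 && any(diff(times) <= 0))
    stop_user("frame times must be strictly increasing")
  structure(list(times = times, box_length = box_length,
                 x = ux %% box_length, y = uy %% box_length,
                 ux = ux, uy = uy, params = params,
                 orientations = orientations, labels = labels),
            class = "trajectory")
}

#' Number of frames / inclusions in a trajectory
#' @param traj a \code{trajectory}.
#' @return integer count.
#' @export
n_frames <- function(traj) length(traj$times)

#' @rdname n_frames
#' @export
n_inclusions <- function(traj) nrow(traj$ux)

#' Extract one frame of a trajectory as a configuration
#' @param traj a \code{trajectory}.
#' @param i frame index (1-based).
#' @return a \code{configuration}.
#' @export
get_frame <- function(traj, i) {
  if (i < 1 || i > n_frames(traj)) stop_user("frame index out of range")
  configuration(cbind(traj$x[, i], traj$y[, i]), traj$box_length,
                time = traj$times[i])
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d inclusions, %d frames (t = %g..%g ns), box %g nm\n",
              n_inclusions(x), n_frames(x), x$times[1],
              x$times[n_frames(x)], x$box_length))
  if (!is.null(x$orientations)) cat("  with per-inclusion orientations\n")
  if (!is.null(x$labels)) cat("  with constant cluster memberships\n")
  invisible(x)
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = genv)
    on.exit(assign(".Random.seed", old, envir = genv))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = genv)))
  }
  set.seed(seed)
  code
}
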