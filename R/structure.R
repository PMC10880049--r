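# Structural observables: 2D radial distribution function with periodic
# boundaries, and tilt-order statistics.

#' 2D radial distribution function
#'
#' Histogram of minimum-image pair distances, normalized per frame by the
#' 2D ideal-gas expectation \code{N * rho * pi * ((r + dr)^2 - r^2) / 2}
#' per inclusion (with \code{rho = N / L^2}), averaged over frames.  For a
#' homogeneous system g approaches 1 at large r.
#'
#' @param traj a \code{trajectory} or a single \code{\link{configuration}}.
#' @param bin_width histogram bin width (nm), default 0.05.
#' @param r_max largest distance (nm); default and maximum
#'   \code{box_length / 2}.
#' @param frames optional integer vector of frame indices to average over
#'   (default all frames).
#' @return an object of class \code{rdf_result} with \code{bin_centers},
#'   \code{g}, \code{bin_width}, \code{r_max}, \code{n_frames_averaged},
#'   plus \code{n_inclusions} and \code{box_length} for normalization
#'   checks.
#' @export
rdf_2d <- function(traj, bin_width = 0.05, r_max = NULL, frames = NULL) {
  if (inherits(traj, "configuration")) {
    confs <- list(traj)
    box_length <- traj$box_length
  } else if (inherits(traj, "trajectory")) {
    idx <- if (is.null(frames)) seq_len(n_frames(traj)) else frames
    confs <- lapply(idx, function(i) get_frame(traj, i))
    box_length <- traj$box_length
  } else stop_user("traj must be a trajectory or configuration")
  if (is.null(r_max)) r_max <- box_length / 2
  if (r_max > box_length / 2 + 1e-9)
    stop_user("r_max must not exceed box_length / 2")
  if (bin_width <= 0 || bin_width > r_max)
    stop_user("bin_width must be in (0, r_max]")
  breaks <- seq(0, r_max, by = bin_width)
  if (breaks[length(breaks)] < r_max) breaks <- c(breaks, r_max)
  nb <- length(breaks) - 1L
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  gsum <- numeric(nb)
  for (cf in confs) {
    n <- nrow(cf$positions)
    if (n < 2) stop_user("need at least 2 inclusions for an RDF")
    dmat <- min_image_dist_mat(cf$positions, box_length)
    d <- dmat[upper.tri(dmat)]
    d <- d[d < r_max]
    counts <- tabulate(.bincode(d, breaks, right = FALSE,
                                include.lowest = TRUE), nbins = nb)
    rho <- n / box_length^2
    ideal <- n * rho * pi * (breaks[-1]^2 - breaks[-length(breaks)]^2) / 2
    gsum <- gsum + counts / ideal
  }
  structure(list(bin_centers = centers, g = gsum / length(confs),
                 bin_width = bin_width, r_max = r_max,
                 n_frames_averaged = length(confs),
                 n_inclusions = nrow(confs[[1]]$positions),
                 box_length = box_length),
            class = "rdf_result")
}

#' @export
print.rdf_result <- function(x, ...) {
  cat(sprintf("2D RDF: %d bins of %g nm up to %g nm, averaged over %d frame(s)\n",
              length(x$g), x$bin_width, x$r_max, x$n_frames_averaged))
  pk <- first_peak(x)
  if (pk$found)
    cat(sprintf("  first peak at r = %g nm (g = %.3g)\n", pk$r, pk$g))
  invisible(x)
}

#' First peak of a radial distribution function
#'
#' Bin center of the first local maximum with g at or above a prominence
#' threshold, searched from \code{r_min_search} upward.  Returns an
#' explicit "no peak" result rather than an error when nothing qualifies.
#'
#' @param rdf an \code{rdf_result}.
#' @param r_min_search smallest r (nm) considered, default 0.
#' @param prominence minimum g value for a peak, default 1.2 (suppresses
#'   counting-noise wiggles around g = 1).
#' @return a list with elements \code{found} (logical), \code{r} (nm,
#'   \code{NA} if not found) and \code{g}.
#' @export
first_peak <- function(rdf, r_min_search = 0, prominence = 1.2) {
  if (!inherits(rdf, "rdf_result")) stop_user("rdf must be an rdf_result")
  g <- rdf$g; r <- rdf$bin_centers
  nb <- length(g)
  if (nb == 0) return(list(found = FALSE, r = NA_real_, g = NA_real_))
  left <- c(-Inf, g[-nb])
  right <- c(g[-1], -Inf)
  is_max <- g >= left & g >= right & (g > left | g > right)
  cand <- which(is_max & g >= prominence & r >= r_min_search)
  if (length(cand) == 0) return(list(found = FALSE, r = NA_real_,
                                     g = NA_real_))
  i <- cand[1]
  list(found = TRUE, r = r[i], g = g[i])
}

#' Tilt-order time series
#'
#' Per-frame average of |cos(theta)| between each inclusion axis and the
#' membrane normal.  The absolute value folds theta to [0, 90]: inclusions
#' are treated as symmetric under flipping, so up and down orientations are
#' equivalent.
#'
#' @param orientations array of unit vectors with dimension
#'   \code{c(n_inclusions, 3, n_frames)} (as produced by
#'   \code{\link{simulate_tilt}}), or a \code{trajectory} carrying
#'   orientations.
#' @param membrane_normal unit membrane normal, default \code{c(0, 0, 1)}.
#' @param times optional frame times (ns); taken from the trajectory when
#'   one is supplied, otherwise defaults to 0, 1, 2, ...
#' @param tol tolerance on unit norm of the vectors, default 1e-6.
#' @return an object of class \code{tilt_series} with \code{times} and
#'   \code{mean_cos_theta}.
#' @export
tilt_series <- function(orientations, membrane_normal = c(0, 0, 1),
                        times = NULL, tol = 1e-6) {
  if (inherits(orientations, "trajectory")) {
    if (is.null(orientations$orientations))
      stop_user("trajectory carries no orientations")
    if (is.null(times)) times <- orientations$times
    orientations <- orientations$orientations
  }
  if (length(dim(orientations)) != 3 || dim(orientations)[2] != 3)
    stop_user("orientations must be an n x 3 x n_frames array")
  nrm <- sqrt(orientations[, 1, , drop = FALSE]^2 +
              orientations[, 2, , drop = FALSE]^2 +
              orientations[, 3, , drop = FALSE]^2)
  if (any(abs(nrm - 1) > tol))
    stop_user("orientation vectors must have unit norm (tolerance ", tol, ")")
  membrane_normal <- membrane_normal / sqrt(sum(membrane_normal^2))
  ct <- abs(orientations[, 1, ] * membrane_normal[1] +
            orientations[, 2, ] * membrane_normal[2] +
            orientations[, 3, ] * membrane_normal[3])
  if (is.null(dim(ct))) ct <- matrix(ct, nrow = dim(orientations)[1])
  mean_ct <- colMeans(ct)
  if (is.null(times)) times <- seq_along(mean_ct) - 1
  structure(list(times = times, mean_cos_theta = mean_ct),
            class = "tilt_series")
}

#' @export
print.tilt_series <- function(x, ...) {
  cat(sprintf("Tilt series over %d frames: <cos theta> = %.4g (time average)\n",
              length(x$times), mean(x$mean_cos_theta)))
  invisible(x)
}
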