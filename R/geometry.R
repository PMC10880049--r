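# Periodic geometry kernel: minimum-image distances in a square 2D box.

# Minimum-image separation components.  Works on vectors or matrices.
min_image_delta <- function(d, box_length) d - box_length * round(d / box_length)

# Full n x n minimum-image distance matrix for positions (n x 2) in a square
# periodic box.
min_image_dist_mat <- function(positions, box_length) {
  x <- positions[, 1]; y <- positions[, 2]
  dx <- min_image_delta(outer(x, x, "-"), box_length)
  dy <- min_image_delta(outer(y, y, "-"), box_length)
  sqrt(dx * dx + dy * dy)
}

#' Pairwise minimum-image distances
#'
#' Computes all center-to-center distances between inclusions under the 2D
#' minimum-image convention for a square periodic box: each separation
#' component is mapped to the nearest periodic image before the Euclidean
#' norm is taken.
#'
#' @param config a \code{\link{configuration}}.
#' @return a symmetric numeric matrix of distances (nm) with zero diagonal.
#' @examples
#' cfg <- configuration(rbind(c(1, 0), c(69, 0)), box_length = 70)
#' min_image_distances(cfg)[1, 2]  # 2, across the periodic boundary
#' @export
min_image_distances <- function(config) {
  if (!inherits(config, "configuration"))
    stop_user("config must be a configuration")
  min_image_dist_mat(config$positions, config$box_length)
}
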