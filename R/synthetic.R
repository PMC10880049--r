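# Synthetic membrane generator: deterministic starting configurations and
# overdamped Brownian-dynamics aggregation trajectories whose mobilities
# follow membrane hydrodynamics (HPW-PS), optionally suppressed by the
# periodic-box finite-size term so that the generated data emulate what a
# periodic-box simulation would measure.

#' Square-grid starting configuration
#'
#' Places \code{n_side^2} inclusions on a square lattice with spacing
#' \code{box_length / n_side}, centered in the lattice cells.  This is the
#' canonical fully dispersed starting state of the aggregation study
#' (e.g. a 10 x 10 grid in a 70 nm box gives 100 inclusions 7 nm apart).
#'
#' @param n_side inclusions per box side (>= 1).
#' @param box_length side of the square periodic box (nm).
#' @return a \code{\link{configuration}} at time 0.
#' @export
make_grid_configuration <- function(n_side, box_length) {
  if (length(n_side) != 1 || !is.finite(n_side) || n_side < 1 ||
      n_side != round(n_side))
    stop_user("n_side must be a positive integer")
  if (!is.finite(box_length) || box_length <= 0)
    stop_user("box_length must be positive")
  a <- box_length / n_side
  centers <- (seq_len(n_side) - 0.5) * a
  pos <- as.matrix(expand.grid(x = centers, y = centers))
  configuration(pos, box_length, time = 0)
}

# First n sites of a triangular lattice with spacing a, ordered by distance
# from the origin (ties broken by angle, then index), then recentered so the
# centroid is at the origin.
hex_sites <- function(n, a) {
  m <- ceiling(sqrt(n)) + 2
  ij <- as.matrix(expand.grid(i = -m:m, j = -m:m))
  x <- a * (ij[, 1] + 0.5 * ij[, 2])
  y <- a * (sqrt(3) / 2 * ij[, 2])
  r <- sqrt(x^2 + y^2)
  ang <- atan2(y, x)
  ord <- order(round(r, 9), round(ang, 9))
  sel <- ord[seq_len(n)]
  sites <- cbind(x[sel], y[sel])
  sweep(sites, 2, colMeans(sites))
}

#' Hexagonally packed cluster configuration
#'
#' Builds a compact cluster of \code{n_inclusions} positions on a triangular
#' (hexagonal) lattice with nearest-neighbor distance \code{spacing}, placed
#' at the center of the box.  With spacing equal to the lipid-separated
#' packing distance (2.1 nm) this reproduces the packing of inclusions
#' sharing a single annular lipid shell.
#'
#' @param n_inclusions number of lattice sites (>= 1).
#' @param spacing nearest-neighbor distance (nm).
#' @param box_length side of the square periodic box (nm).
#' @param center optional cluster center, default the box center.
#' @return a \code{\link{configuration}} at time 0.
#' @export
make_hex_cluster <- function(n_inclusions, spacing, box_length,
                             center = c(box_length / 2, box_length / 2)) {
  if (n_inclusions < 1 || n_inclusions != round(n_inclusions))
    stop_user("n_inclusions must be a positive integer")
  if (spacing <= 0) stop_user("spacing must be positive")
  if (!is.finite(box_length) || box_length <= 0)
    stop_user("box_length must be positive")
  sites <- hex_sites(n_inclusions, spacing)
  if (2 * max(sqrt(rowSums(sites^2))) + spacing > box_length)
    stop_user("cluster does not fit inside the box")
  configuration(sweep(sites, 2, center, "+"), box_length, time = 0)
}

# Generating mobility (nm^2/ns) of a cluster of size s.  Uses the HPW-PS
# model at the area-equivalent effective radius; when pbc = TRUE the
# periodic-box suppression (the same term finite_size_correction() adds
# back) is subtracted, emulating a periodic simulation box.
generating_D <- function(sizes, params) {
  if (params$temperature == 0) return(rep(0, length(sizes)))
  hydro <- hydro_params(params$eta_m, params$eta_w, params$temperature)
  r <- effective_radius(sizes, params$inclusion_radius)
  d <- hpw_ps_model(r, hydro)
  if (params$pbc_mobility) {
    delta <- pbc_suppression(params$box_length, params$solvent_height, hydro)
    if (any(d - delta <= 0))
      stop_user("periodic-box suppression exceeds model mobility for some ",
                "cluster size; box too small relative to the SD length")
    d <- d - delta
  }
  d
}

# Union-find over cluster ids (merge-only, guarantees irreversibility).
uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

# Repack members of a fused cluster on a triangular lattice at spacing a,
# preserving the cluster's (unwrapped) center of mass.  anchor is the index
# (into members) whose unwrapped position anchors the local frame.
repack_cluster <- function(ux, uy, members, anchor, a, box_length) {
  refx <- ux[anchor]; refy <- uy[anchor]
  lx <- refx + min_image_delta(ux[members] - refx, box_length)
  ly <- refy + min_image_delta(uy[members] - refy, box_length)
  # members may carry unwrapped offsets that differ by box multiples; fold
  # them into the minimum image of the anchor before averaging
  comx <- mean(lx); comy <- mean(ly)
  sites <- hex_sites(length(members), a)
  ord_m <- order((lx - comx)^2 + (ly - comy)^2, members)
  ord_s <- order(rowSums(sites^2))
  ux[members[ord_m]] <- comx + sites[ord_s, 1]
  uy[members[ord_m]] <- comy + sites[ord_s, 2]
  list(ux = ux, uy = uy)
}

#' Simulate irreversible Brownian aggregation of membrane inclusions
#'
#' Overdamped 2D Brownian dynamics of rigid clusters.  At every step the
#' current clusters (connected components at \code{fusion_cutoff}) each
#' receive an isotropic Gaussian displacement with per-coordinate variance
#' \code{2 D(s) dt}, where \code{D(s)} is the HPW-PS mobility of the
#' area-equivalent disk of a size-\code{s} cluster (see
#' \code{\link{hpw_ps_model}}), by default reduced by the periodic-box
#' finite-size suppression.  When two clusters come within
#' \code{fusion_cutoff} they fuse irreversibly and the merged cluster is
#' repacked on a triangular lattice at \code{packing_distance}, preserving
#' its center of mass.  Displacements are drawn in canonical cluster order
#' (ascending minimum member index), so results are reproducible and
#' independent of internal iteration details.
#'
#' @param initial a \code{\link{configuration}} of starting positions.
#' @param params a \code{\link{sim_params}} object.
#' @return a \code{trajectory} with wrapped and unwrapped coordinates.
#' @export
simulate_aggregation <- function(initial, params) {
  simulate_bd(initial, params, fusion = TRUE)
}

#' Simulate persistent clusters of fixed sizes
#'
#' Same rigid-cluster Brownian dynamics as
#' \code{\link{simulate_aggregation}}, but with fusion disabled: cluster
#' memberships are constant for the whole run.  Clusters of the requested
#' sizes are built as hexagonal packings at \code{packing_distance} and
#' placed on a coarse grid (or at user-supplied centers).  Because the
#' clusters do not interact, per-step Gaussian increments sum exactly to
#' per-frame Gaussian increments; displacements are therefore generated at
#' frame resolution, which represents any finer step size exactly.
#'
#' @param cluster_sizes integer vector of cluster sizes.
#' @param params a \code{\link{sim_params}} object
#'   (\code{params$n_inclusions} is ignored; the total is
#'   \code{sum(cluster_sizes)}).
#' @param centers optional matrix (one row per cluster) of cluster centers
#'   (nm); default places clusters on a square grid of cells large enough
#'   to hold the biggest cluster.
#' @return a \code{trajectory}; constant memberships are stored in
#'   \code{$labels}.
#' @export
simulate_fixed_clusters <- function(cluster_sizes, params, centers = NULL) {
  if (length(cluster_sizes) < 1 || any(cluster_sizes < 1) ||
      any(cluster_sizes != round(cluster_sizes)))
    stop_user("cluster_sizes must be positive integers")
  validate_sim_params(params)
  k <- length(cluster_sizes)
  L <- params$box_length
  a <- params$packing_distance
  radius <- vapply(cluster_sizes, function(s) {
    if (s == 1) 0 else max(sqrt(rowSums(hex_sites(s, a)^2)))
  }, numeric(1))
  if (is.null(centers)) {
    ncell <- ceiling(sqrt(k))
    cell <- L / ncell
    if (max(2 * radius + a) > cell)
      stop_user("clusters do not fit in the box without overlap; ",
                "supply centers or enlarge the box")
    idx <- seq_len(k) - 1L
    centers <- cbind((idx %% ncell + 0.5) * cell,
                     (idx %/% ncell + 0.5) * cell)
  } else {
    centers <- as.matrix(centers)
    if (nrow(centers) != k || ncol(centers) != 2)
      stop_user("centers must be a k x 2 matrix")
  }
  # initial unwrapped positions, cluster by cluster
  ux0 <- numeric(0); uy0 <- numeric(0); labels <- integer(0)
  for (c in seq_len(k)) {
    s <- cluster_sizes[c]
    sites <- hex_sites(s, a)
    ux0 <- c(ux0, centers[c, 1] + sites[, 1])
    uy0 <- c(uy0, centers[c, 2] + sites[, 2])
    labels <- c(labels, rep(c, s))
  }
  n <- length(ux0)
  Tn <- params$n_frames
  dvec <- generating_D(cluster_sizes, params)
  check_step_safety(max(dvec), params)
  times <- (seq_len(Tn) - 1) * params$frame_interval
  ux <- matrix(0, n, Tn); uy <- matrix(0, n, Tn)
  ux[, 1] <- ux0; uy[, 1] <- uy0
  with_seed(params$seed, {
    if (Tn > 1) {
      sd_frame <- sqrt(2 * dvec * params$frame_interval)
      # draw per cluster in canonical order
      for (c in seq_len(k)) {
        inc <- matrix(stats::rnorm(2 * (Tn - 1), sd = sd_frame[c]),
                      nrow = 2)
        px <- cumsum(inc[1, ]); py <- cumsum(inc[2, ])
        mem <- which(labels == c)
        ux[mem, -1] <- ux[mem, 1] + rep(px, each = length(mem))
        uy[mem, -1] <- uy[mem, 1] + rep(py, each = length(mem))
      }
    }
  })
  new_trajectory(times, L, ux, uy, params = params, labels = labels)
}

check_step_safety <- function(dmax, params) {
  if (sqrt(2 * dmax * params$time_step) > params$box_length / 4)
    stop_user("typical step displacement exceeds box_length/4; ",
              "reduce time_step (minimum-image dynamics unsafe)")
}

# Shared BD engine (fusion = TRUE for aggregation).
simulate_bd <- function(initial, params, fusion = TRUE) {
  if (!inherits(initial, "configuration"))
    stop_user("initial must be a configuration")
  validate_sim_params(params)
  L <- params$box_length
  if (abs(initial$box_length - L) > 1e-9)
    stop_user("initial configuration box_length differs from params")
  n <- nrow(initial$positions)
  Tn <- params$n_frames
  substeps <- round(params$frame_interval / params$time_step)
  dt <- params$time_step
  cutoff <- params$fusion_cutoff

  d_cache <- new.env(parent = emptyenv())
  D_of <- function(s) {
    key <- as.character(s)
    if (is.null(d_cache[[key]])) d_cache[[key]] <- generating_D(s, params)
    d_cache[[key]]
  }
  check_step_safety(D_of(1L), params)

  ux <- initial$positions[, 1]
  uy <- initial$positions[, 2]
  # initial clustering at the fusion cutoff
  labels <- cluster_labels_pos(initial$positions, L, cutoff)

  out_ux <- matrix(0, n, Tn); out_uy <- matrix(0, n, Tn)
  out_ux[, 1] <- ux; out_uy[, 1] <- uy

  with_seed(params$seed, {
    for (f in seq_len(Tn - 1L)) {
      for (st in seq_len(substeps)) {
        # labels are canonical (clusters numbered by ascending minimum
        # member index), so drawing in label order is the canonical order
        sizes <- tabulate(labels)
        k <- length(sizes)
        sdv <- sqrt(2 * dt * vapply(sizes, D_of, numeric(1)))
        draws <- stats::rnorm(2L * k)
        stepx <- draws[seq.int(1L, by = 2L, length.out = k)] * sdv
        stepy <- draws[seq.int(2L, by = 2L, length.out = k)] * sdv
        ux <- ux + stepx[labels]
        uy <- uy + stepy[labels]
        if (fusion) {
          # iterate: repacking a fused cluster can create new contacts,
          # which must fuse within the same step (irreversibility)
          repeat {
            pos <- cbind(ux %% L, uy %% L)
            dmat <- min_image_dist_mat(pos, L)
            touch <- which(dmat <= cutoff & upper.tri(dmat), arr.ind = TRUE)
            touch <- touch[labels[touch[, 1]] != labels[touch[, 2]], ,
                           drop = FALSE]
            if (nrow(touch) == 0) break
            parent <- seq_len(n)
            for (r in seq_len(nrow(touch))) {
              ri <- uf_find(parent, labels[touch[r, 1]])
              rj <- uf_find(parent, labels[touch[r, 2]])
              if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
            }
            roots <- vapply(labels, function(l) uf_find(parent, l),
                            integer(1))
            for (root in unique(roots[duplicated(roots) |
                                      duplicated(roots, fromLast = TRUE)])) {
              members <- which(roots == root)
              if (length(unique(labels[members])) < 2) next
              # anchor: member of the largest old sub-cluster (ties: lowest id)
              subsizes <- table(labels[members])
              big <- as.integer(names(subsizes)[which.max(subsizes)])
              anchor <- members[labels[members] == big][1]
              rp <- repack_cluster(ux, uy, members, anchor,
                                   params$packing_distance, L)
              ux <- rp$ux; uy <- rp$uy
            }
            labels <- match(roots, unique(roots))
          }
        }
      }
      out_ux[, f + 1L] <- ux
      out_uy[, f + 1L] <- uy
    }
  })
  times <- (seq_len(Tn) - 1) * params$frame_interval
  new_trajectory(times, L, out_ux, out_uy, params = params,
                 labels = if (fusion) NULL else labels)
}

#' Simulate tilt fluctuations of inclusion axes
#'
#' Generates per-inclusion unit orientation vectors whose cosine with the
#' membrane normal (z) fluctuates around \code{tilt$mean_cos} as a
#' stationary AR(1) (discretized Ornstein-Uhlenbeck) process with the
#' requested relaxation time and stationary standard deviation
#' \code{tilt$noise_amplitude}.  The cosine is reflected into [0, 1];
#' azimuthal angles are independent and uniform.
#'
#' @param n_inclusions number of inclusions.
#' @param n_frames number of frames.
#' @param tilt a \code{\link{tilt_params}} object.
#' @param frame_interval time between frames (ns), used with
#'   \code{tilt$relaxation_time}.
#' @return an array of unit vectors, dimension
#'   \code{c(n_inclusions, 3, n_frames)}.
#' @export
simulate_tilt <- function(n_inclusions, n_frames, tilt, frame_interval = 1) {
  if (!inherits(tilt, "tilt_params")) stop_user("tilt must be tilt_params")
  if (n_inclusions < 1 || n_frames < 1)
    stop_user("n_inclusions and n_frames must be >= 1")
  phi <- exp(-frame_interval / tilt$relaxation_time)
  innov_sd <- tilt$noise_amplitude * sqrt(1 - phi^2)
  reflect01 <- function(c) {
    c <- abs(c)
    c <- ifelse(c > 1, 2 - c, c)
    pmin(pmax(c, 0), 1)   # guard pathological amplitudes
  }
  with_seed(tilt$seed, {
    cmat <- matrix(0, n_inclusions, n_frames)
    cmat[, 1] <- reflect01(tilt$mean_cos +
                           stats::rnorm(n_inclusions,
                                        sd = tilt$noise_amplitude))
    if (n_frames > 1) {
      for (f in 2:n_frames) {
        cmat[, f] <- reflect01(tilt$mean_cos +
                               phi * (cmat[, f - 1] - tilt$mean_cos) +
                               stats::rnorm(n_inclusions, sd = innov_sd))
      }
    }
    az <- matrix(stats::runif(n_inclusions * n_frames, 0, 2 * pi),
                 n_inclusions, n_frames)
    sint <- sqrt(pmax(0, 1 - cmat^2))
    orient <- array(0, dim = c(n_inclusions, 3, n_frames))
    orient[, 1, ] <- sint * cos(az)
    orient[, 2, ] <- sint * sin(az)
    orient[, 3, ] <- cmat
    orient
  })
}
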