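# Cluster identification under periodic boundaries, identity tracking over
# time, growth kinetics.

# Internal: canonical cluster labels for raw positions.  Connected components
# of the graph linking pairs with minimum-image distance <= cutoff, relabeled
# so clusters are numbered by ascending minimum member index.
cluster_labels_pos <- function(positions, box_length, cutoff) {
  n <- nrow(positions)
  dmat <- min_image_dist_mat(positions, box_length)
  pairs <- which(dmat <= cutoff & upper.tri(dmat), arr.ind = TRUE)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(pairs) > 0) g <- igraph::add_edges(g, t(pairs))
  memb <- igraph::components(g)$membership
  match(memb, unique(memb))
}

#' Identify clusters at a distance cutoff
#'
#' Clusters are the connected components of the graph linking inclusion
#' pairs whose minimum-image center-to-center distance is at most
#' \code{cutoff}.  Two canonical cutoffs are used in the CNT-porin system:
#' 1.7 nm (full contact) and 2.25 nm (separation by one layer of lipids).
#' Labels are canonicalized: clusters are numbered by ascending minimum
#' member index.
#'
#' @param config a \code{\link{configuration}}.
#' @param cutoff center-to-center distance cutoff (nm); must be positive and
#'   below \code{box_length / 2} (beyond that the minimum image is
#'   ambiguous).
#' @return an object of class \code{cluster_assignment} with fields
#'   \code{labels}, \code{sizes}, \code{cutoff}, \code{time}.
#' @export
find_clusters <- function(config, cutoff) {
  if (!inherits(config, "configuration"))
    stop_user("config must be a configuration")
  if (!is.finite(cutoff) || cutoff <= 0 || cutoff >= config$box_length / 2)
    stop_user("cutoff must lie in (0, box_length/2)")
  labels <- cluster_labels_pos(config$positions, config$box_length, cutoff)
  structure(list(labels = labels, sizes = tabulate(labels),
                 cutoff = cutoff, time = config$time),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("Cluster assignment at cutoff %g nm (t = %g ns): %d clusters\n",
              x$cutoff, x$time, length(x$sizes)))
  cat("  sizes:", paste(sort(x$sizes, decreasing = TRUE), collapse = " "),
      "\n")
  invisible(x)
}

#' Per-inclusion neighbor counts
#'
#' Number of other inclusions within the minimum-image cutoff of each
#' inclusion (self excluded).
#'
#' @inheritParams find_clusters
#' @return integer vector, one count per inclusion.
#' @export
neighbor_counts <- function(config, cutoff) {
  if (!inherits(config, "configuration"))
    stop_user("config must be a configuration")
  if (!is.finite(cutoff) || cutoff <= 0 || cutoff >= config$box_length / 2)
    stop_user("cutoff must lie in (0, box_length/2)")
  dmat <- min_image_dist_mat(config$positions, config$box_length)
  as.integer(rowSums(dmat <= cutoff) - 1L)
}

#' Cluster statistics and identity tracking over a trajectory
#'
#' Applies \code{\link{find_clusters}} to every frame and follows cluster
#' identities through time: a cluster at frame k+1 inherits the identity of
#' the frame-k cluster with which it shares the most members (ties broken
#' toward the lower identity).  Fusion events (a cluster containing members
#' of two or more previous identities) and fission events (one previous
#' identity split over several clusters) are logged.
#'
#' @param traj a \code{trajectory}.
#' @param cutoff center-to-center distance cutoff (nm).
#' @return an object of class \code{cluster_series} with per-frame
#'   \code{times}, \code{n_clusters}, \code{n_max}, \code{mean_size}, a
#'   \code{labels} matrix (inclusions x frames, canonical per-frame labels),
#'   an \code{identities} matrix (persistent identities), and an
#'   \code{events} data frame.
#' @export
cluster_series <- function(traj, cutoff) {
  if (!inherits(traj, "trajectory")) stop_user("traj must be a trajectory")
  Tn <- n_frames(traj)
  n <- n_inclusions(traj)
  labels <- matrix(0L, n, Tn)
  ident <- matrix(0L, n, Tn)
  n_clusters <- integer(Tn); n_max <- integer(Tn)
  events <- list()
  next_id <- 0L
  prev_ident <- NULL
  for (f in seq_len(Tn)) {
    ca <- find_clusters(get_frame(traj, f), cutoff)
    labels[, f] <- ca$labels
    n_clusters[f] <- length(ca$sizes)
    n_max[f] <- max(ca$sizes)
    if (f == 1) {
      ident[, 1] <- ca$labels
      next_id <- max(ca$labels)
    } else {
      cur <- integer(n)
      claimed <- integer(0)
      # overlap of each current cluster with previous identities
      ids_new <- sort(unique(ca$labels))
      inherit <- integer(length(ids_new))
      overlap_n <- integer(length(ids_new))
      for (c in ids_new) {
        mem <- ca$labels == c
        tab <- sort(table(prev_ident[mem]), decreasing = TRUE)
        best_n <- max(tab)
        cands <- as.integer(names(tab)[tab == best_n])
        inherit[c] <- min(cands)
        overlap_n[c] <- best_n
        if (length(unique(prev_ident[mem])) > 1) {
          events[[length(events) + 1]] <-
            data.frame(time = traj$times[f], type = "fusion",
                       ids = paste(sort(unique(prev_ident[mem])),
                                   collapse = "+"),
                       new_id = min(cands))
        }
      }
      # resolve several clusters inheriting the same previous identity:
      # the one with the largest overlap keeps it, others get fresh ids
      for (id in unique(inherit)) {
        holders <- which(inherit == id)
        if (length(holders) > 1) {
          keep <- holders[order(-overlap_n[holders], holders)][1]
          losers <- setdiff(holders, keep)
          for (l in losers) {
            next_id <- next_id + 1L
            inherit[l] <- next_id
          }
          events[[length(events) + 1]] <-
            data.frame(time = traj$times[f], type = "fission",
                       ids = as.character(id),
                       new_id = max(inherit[losers]))
        }
      }
      for (c in ids_new) cur[ca$labels == c] <- inherit[c]
      ident[, f] <- cur
    }
    prev_ident <- ident[, f]
  }
  structure(list(times = traj$times, n_clusters = n_clusters, n_max = n_max,
                 mean_size = n / n_clusters, cutoff = cutoff,
                 labels = labels, identities = ident,
                 events = if (length(events)) do.call(rbind, events)
                          else data.frame(time = numeric(0),
                                          type = character(0),
                                          ids = character(0),
                                          new_id = integer(0))),
            class = "cluster_series")
}

#' @export
print.cluster_series <- function(x, ...) {
  Tn <- length(x$times)
  cat(sprintf("Cluster series at cutoff %g nm over %d frames\n", x$cutoff, Tn))
  cat(sprintf("  n_clusters: %d -> %d; N_max: %d -> %d\n",
              x$n_clusters[1], x$n_clusters[Tn], x$n_max[1], x$n_max[Tn]))
  cat(sprintf("  %d fusion, %d fission events\n",
              sum(x$events$type == "fusion"), sum(x$events$type == "fission")))
  invisible(x)
}

#' Fit a power law to largest-cluster growth
#'
#' Unweighted least-squares line in (log t, log N_max); the exponent is the
#' slope.  Frames at t <= 0 are excluded; the fit range is a required,
#' logged input because growth-law fits are sensitive to it.
#'
#' @param series a \code{cluster_series}, or a data frame with columns
#'   \code{time} and \code{n_max}.
#' @param fit_range numeric length-2 vector \code{c(t_min, t_max)} (ns).
#' @return an object of class \code{power_law_fit} with fields
#'   \code{exponent}, \code{prefactor}, \code{fit_range}, \code{residual}
#'   (RMS residual in log space) and \code{n_points}.
#' @export
fit_power_law <- function(series, fit_range) {
  if (inherits(series, "cluster_series")) {
    dat <- data.frame(time = series$times, n_max = series$n_max)
  } else {
    dat <- as.data.frame(series)
    if (!all(c("time", "n_max") %in% names(dat)))
      stop_user("series must be a cluster_series or have columns time, n_max")
  }
  if (length(fit_range) != 2 || fit_range[1] >= fit_range[2])
    stop_user("fit_range must be c(t_min, t_max) with t_min < t_max")
  keep <- dat$time >= fit_range[1] & dat$time <= fit_range[2] & dat$time > 0
  dat <- dat[keep, ]
  if (nrow(dat) < 5)
    stop_user("need at least 5 frames with t > 0 inside fit_range")
  if (any(dat$n_max <= 0)) stop_user("n_max must be positive in fit range")
  fit <- stats::lm(log(n_max) ~ log(time), data = dat)
  res <- sqrt(mean(stats::residuals(fit)^2))
  structure(list(exponent = unname(stats::coef(fit)[2]),
                 prefactor = exp(unname(stats::coef(fit)[1])),
                 fit_range = fit_range, residual = res,
                 n_points = nrow(dat)),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf(
    "Power-law fit over t in [%g, %g] ns: N_max ~ %.4g * t^%.4g (RMS log-resid %.3g, n = %d)\n",
    x$fit_range[1], x$fit_range[2], x$prefactor, x$exponent, x$residual,
    x$n_points))
  invisible(x)
}
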