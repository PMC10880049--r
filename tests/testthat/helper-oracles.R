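# Independent brute-force oracles and small fixture builders shared across
# tests.  These deliberately avoid the package's vectorized minimum-image
# code paths.

# Brute-force minimum-image distance: explicit minimum over the 9 periodic
# images of the second point.
bf_min_image_dist <- function(p1, p2, L) {
  best <- Inf
  for (sx in c(-L, 0, L)) for (sy in c(-L, 0, L)) {
    d <- sqrt((p1[1] - p2[1] - sx)^2 + (p1[2] - p2[2] - sy)^2)
    best <- min(best, d)
  }
  best
}

bf_dist_mat <- function(pos, L) {
  n <- nrow(pos)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j) m[i, j] <- bf_min_image_dist(pos[i, ], pos[j, ], L)
  m
}

# Brute-force connected components by BFS over the brute-force adjacency,
# with the same canonical numbering convention (ascending minimum member).
bf_clusters <- function(pos, L, cutoff) {
  n <- nrow(pos)
  adj <- bf_dist_mat(pos, L) <= cutoff
  diag(adj) <- FALSE
  labels <- rep(0L, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (labels[i] > 0) next
    cur <- cur + 1L
    queue <- i
    labels[i] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & labels == 0L)
      labels[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  labels
}

# Naive double-loop 2D RDF for a single frame, following the documented
# normalization (pair counts over N * rho * annulus / 2).
bf_rdf <- function(pos, L, bin_width, r_max) {
  n <- nrow(pos)
  breaks <- seq(0, r_max, by = bin_width)
  if (breaks[length(breaks)] < r_max) breaks <- c(breaks, r_max)
  counts <- numeric(length(breaks) - 1)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- bf_min_image_dist(pos[i, ], pos[j, ], L)
    if (d < r_max) {
      b <- findInterval(d, breaks, rightmost.closed = FALSE)
      counts[b] <- counts[b] + 1
    }
  }
  rho <- n / L^2
  ideal <- n * rho * pi * (breaks[-1]^2 - breaks[-length(breaks)]^2) / 2
  counts / ideal
}

random_configuration <- function(n, L) {
  configuration(matrix(runif(2 * n, 0, L), ncol = 2), L)
}

default_hydro <- function() hydro_params(4.5e-11, 7e-4, 300)
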