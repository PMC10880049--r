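# Diffusion analysis: per-cluster-size MSD, diffusion coefficients,
# membrane-hydrodynamic models (SD and HPW-PS), finite-size correction, and
# membrane-viscosity fitting.

#' Effective hydrodynamic radius of a cluster
#'
#' Maps a cluster of \code{cluster_size} inclusions to the radius of the
#' area-equivalent disk, \code{R = r_cnt * sqrt(cluster_size)}.  A single
#' inclusion maps to its own radius (default 1.05 nm).
#'
#' @param cluster_size integer cluster size(s), >= 1.
#' @param r_cnt radius of a single inclusion (nm), default 1.05.
#' @return effective radius (nm), vectorized over \code{cluster_size}.
#' @export
effective_radius <- function(cluster_size, r_cnt = 1.05) {
  if (any(cluster_size < 1) || any(cluster_size != round(cluster_size)))
    stop_user("cluster_size must be a positive integer")
  if (r_cnt <= 0) stop_user("r_cnt must be positive")
  r_cnt * sqrt(cluster_size)
}

#' Saffman-Delbruck diffusion coefficient
#'
#' Lateral diffusion coefficient of a disk of radius R in a thin membrane
#' of surface viscosity eta_m bounded on both sides by solvent of viscosity
#' eta_w:
#' \deqn{D = \frac{k_B T}{4\pi\eta_m}\left[\ln\frac{2\ell_{SD}}{R} - \gamma\right]}
#' with \eqn{\ell_{SD} = \eta_m / (2\eta_w)} and \eqn{\gamma} the
#' Euler-Mascheroni constant (equivalently, the classical
#' \eqn{\ln(\eta_m/(\eta_w R)) - \gamma} bracket).  Valid for
#' \eqn{R \ll \ell_{SD}}; a warning (not an error) is issued outside that
#' domain, where \code{\link{hpw_ps_model}} should be used.
#'
#' @param radius disk radius (nm); vectorized.
#' @param hydro a \code{\link{hydro_params}} object.
#' @return diffusion coefficient(s) in nm^2/ns.
#' @export
sd_model <- function(radius, hydro) {
  if (!inherits(hydro, "hydro_params")) stop_user("hydro must be hydro_params")
  if (any(radius <= 0)) stop_user("radius must be positive")
  r_m <- radius * .NM
  if (any(r_m >= hydro$sd_length))
    warning("radius at or beyond the SD length; the SD model is outside ",
            "its validity domain here (use hpw_ps_model)")
  eps <- r_m / hydro$sd_length
  d_si <- hydro$thermal_energy / (4 * pi * hydro$eta_m) *
    (log(2 / eps) - .euler_gamma)
  d_from_si(d_si)
}

# Petrov-Schwille interpolation constants for the Hughes-Pailthorpe-White
# mobility (Petrov & Schwille, Biophys. J. 94:L41, 2008).
.ps_c1 <- 0.73761
.ps_b1 <- 2.74819
.ps_c2 <- 0.52119
.ps_b2 <- 0.51465

#' Hughes-Pailthorpe-White diffusion coefficient (Petrov-Schwille form)
#'
#' Closed-form interpolation of the Hughes-Pailthorpe-White solution for
#' the mobility of a disk in a membrane, due to Petrov and Schwille.  With
#' reduced radius \eqn{\epsilon = R/\ell_{SD}}, \eqn{\ell_{SD} =
#' \eta_m/(2\eta_w)}:
#' \deqn{D = \frac{k_B T}{4\pi\eta_m}\,
#'   \frac{\ln(2/\epsilon) - \gamma + 4\epsilon/\pi -
#'         (\epsilon^2/2)\ln(2/\epsilon)}
#'        {1 - (\epsilon^3/\pi)\ln(2/\epsilon) +
#'         c_1\epsilon^{b_1}/(1 + c_2\epsilon^{b_2})}}
#' with \eqn{c_1 = 0.73761}, \eqn{b_1 = 2.74819}, \eqn{c_2 = 0.52119},
#' \eqn{b_2 = 0.51465}.  Reduces to \code{\link{sd_model}} as
#' \eqn{\epsilon \to 0} and crosses over to bulk-dominated (Stokes-Einstein
#' like, ~1/R) behavior at large \eqn{\epsilon}.
#'
#' @inheritParams sd_model
#' @return diffusion coefficient(s) in nm^2/ns.
#' @export
hpw_ps_model <- function(radius, hydro) {
  if (!inherits(hydro, "hydro_params")) stop_user("hydro must be hydro_params")
  if (any(radius <= 0)) stop_user("radius must be positive")
  eps <- radius * .NM / hydro$sd_length
  lg <- log(2 / eps)
  num <- lg - .euler_gamma + 4 * eps / pi - (eps^2 / 2) * lg
  den <- 1 - (eps^3 / pi) * lg + .ps_c1 * eps^.ps_b1 /
    (1 + .ps_c2 * eps^.ps_b2)
  d_si <- hydro$thermal_energy / (4 * pi * hydro$eta_m) * num / den
  d_from_si(d_si)
}

# Magnitude of the periodic-box suppression of the diffusion coefficient
# (nm^2/ns); see finite_size_correction() for documentation.
pbc_suppression <- function(box_length, solvent_height, hydro) {
  if (!is.finite(box_length) || box_length <= 0)
    stop_user("box_length must be positive")
  if (solvent_height <= 0)
    stop_user("solvent_height must be positive (Inf for unbounded solvent)")
  l_sd <- hydro$sd_length
  h <- solvent_height * .NM
  # screened SD length: -> l_sd for deep solvent, -> sqrt(l_sd * h) when the
  # solvent slab is shallower than the SD length
  l_eff <- l_sd / sqrt(1 + l_sd / h)
  alpha <- 2 * exp(1.3106 - .euler_gamma)
  d_si <- hydro$thermal_energy / (4 * pi * hydro$eta_m) *
    log(1 + alpha * l_eff / (box_length * .NM))
  d_from_si(d_si)
}

#' Finite-size correction for periodic-box diffusion coefficients
#'
#' Converts a diffusion coefficient measured in a periodic simulation box
#' to its infinite-system value, \code{D_corrected = D_pbc + Delta}.  In a
#' membrane the periodic images suppress long-range momentum transport, so
#' the measured D underestimates the open-system value, logarithmically so
#' once the box is smaller than the Saffman-Delbruck length.  The additive
#' term used here is the leading-order periodic Saffman-Delbruck result
#' with a smooth crossover to the open-box limit,
#' \deqn{\Delta = \frac{k_B T}{4\pi\eta_m}
#'   \ln\!\left(1 + \alpha\,\ell/L\right), \qquad
#'   \alpha = 2 e^{c_0 - \gamma},\; c_0 = 1.3106,}
#' where \eqn{c_0} is the square-lattice constant of immersed-boundary
#' periodic Saffman-Delbruck calculations (Camley et al., J. Chem. Phys.
#' 143:243113, 2015).  For \eqn{L \ll \ell} this reproduces
#' \eqn{(k_BT/4\pi\eta_m)[\ln(2\ell/L) - \gamma + c_0]}; for
#' \eqn{L \gg \ell} it vanishes as \eqn{\alpha\ell/L}.  A finite solvent
#' slab of height H screens membrane momentum transport; this enters
#' through the screened length \eqn{\ell = \ell_{SD}/\sqrt{1 +
#' \ell_{SD}/H}} (crossing over to the confined-membrane screening length
#' \eqn{\sqrt{\ell_{SD} H}} for shallow solvent).  The correction is
#' independent of inclusion size.
#'
#' @param d_pbc diffusion coefficient(s) measured in the periodic box
#'   (nm^2/ns); vectorized.
#' @param box_length side of the square periodic box (nm).
#' @param solvent_height height of the solvent slab (nm); \code{Inf}
#'   (default) for unbounded solvent.
#' @param hydro a \code{\link{hydro_params}} object (the membrane viscosity
#'   used for the correction; see \code{\link{fit_viscosity_corrected}} for
#'   the self-consistent choice when it is unknown).
#' @return corrected diffusion coefficient(s), nm^2/ns.
#' @export
finite_size_correction <- function(d_pbc, box_length, solvent_height = Inf,
                                   hydro = hydro_params()) {
  d_pbc + pbc_suppression(box_length, solvent_height, hydro)
}

#' Mean-squared displacements grouped by cluster size
#'
#' For every observed cluster size s, averages squared displacements over
#' all inclusions, time origins and cluster instances whose cluster
#' membership is unchanged over the whole lag interval (the persistence
#' rule: an inclusion contributes to the size-s curve at lag tau only if
#' its cluster's member set is identical throughout [t0, t0 + tau]).
#' Per-lag sample counts (number of contributing inclusion/origin pairs)
#' are recorded.
#'
#' Uses unwrapped coordinates.  If the trajectory carries constant
#' memberships (as produced by \code{\link{simulate_fixed_clusters}}) they
#' are used directly; otherwise clusters are identified per frame at
#' \code{cutoff}.
#'
#' @param traj a \code{trajectory} with unwrapped coordinates.
#' @param cutoff cluster cutoff (nm); required unless the trajectory
#'   carries constant memberships.
#' @param max_lag largest lag (ns).
#' @return a named list of \code{msd_curve} objects (names are cluster
#'   sizes), each with \code{lags} (ns, starting at 0), \code{msd} (nm^2),
#'   \code{cluster_size} and \code{n_samples}.  Sizes with no persistent
#'   interval of length \code{max_lag} are omitted with a warning.
#' @export
msd_by_size <- function(traj, cutoff = NULL, max_lag = 15) {
  if (!inherits(traj, "trajectory")) stop_user("traj must be a trajectory")
  Tn <- n_frames(traj); n <- n_inclusions(traj)
  if (Tn < 2) stop_user("need at least 2 frames")
  dts <- diff(traj$times)
  if (max(abs(dts - dts[1])) > 1e-9 * dts[1])
    stop_user("frames must be evenly spaced for MSD analysis")
  dt <- dts[1]
  n_lag <- floor(max_lag / dt + 1e-9)
  if (n_lag < 1) stop_user("max_lag smaller than the frame interval")
  n_lag <- min(n_lag, Tn - 1L)

  if (!is.null(traj$labels)) {
    # constant memberships: no membership changes by construction
    labmat <- matrix(traj$labels, n, Tn)
    sizes <- matrix(tabulate(traj$labels)[traj$labels], n, Tn)
    cumc <- matrix(0L, n, Tn)
  } else {
    if (is.null(cutoff))
      stop_user("cutoff required when the trajectory has no stored memberships")
    labmat <- vapply(seq_len(Tn),
                     function(f) find_clusters(get_frame(traj, f),
                                               cutoff)$labels,
                     integer(n))
    # member-set key per inclusion per frame; a change in an inclusion's key
    # marks a membership change for the persistence rule
    keys <- vapply(seq_len(Tn), function(f) {
      byc <- split(seq_len(n), labmat[, f])
      kc <- vapply(byc, paste, character(1), collapse = ",")
      kc[as.character(labmat[, f])]
    }, character(n))
    keys <- matrix(keys, n, Tn)
    sizes <- matrix(0L, n, Tn)
    for (f in seq_len(Tn)) sizes[, f] <- tabulate(labmat[, f])[labmat[, f]]
    changes <- keys[, -1, drop = FALSE] != keys[, -Tn, drop = FALSE]
    cumc <- cbind(0L, t(apply(changes, 1, cumsum)))
  }

  all_sizes <- sort(unique(as.vector(sizes)))
  acc_sum <- matrix(0, length(all_sizes), n_lag,
                    dimnames = list(all_sizes, NULL))
  acc_n <- matrix(0, length(all_sizes), n_lag,
                  dimnames = list(all_sizes, NULL))
  for (L in seq_len(n_lag)) {
    i0 <- seq_len(Tn - L)
    valid <- cumc[, i0 + L, drop = FALSE] == cumc[, i0, drop = FALSE]
    sq <- (traj$ux[, i0 + L, drop = FALSE] - traj$ux[, i0, drop = FALSE])^2 +
          (traj$uy[, i0 + L, drop = FALSE] - traj$uy[, i0, drop = FALSE])^2
    sv <- sizes[, i0, drop = FALSE][valid]
    vv <- sq[valid]
    if (length(vv)) {
      sums <- rowsum(vv, sv)
      acc_sum[rownames(sums), L] <- acc_sum[rownames(sums), L] + sums[, 1]
      cnts <- table(sv)
      acc_n[names(cnts), L] <- acc_n[names(cnts), L] + as.numeric(cnts)
    }
  }
  out <- list()
  for (i in seq_along(all_sizes)) {
    s <- all_sizes[i]
    if (any(acc_n[i, ] == 0)) {
      warning("cluster size ", s, " has no persistent interval at some ",
              "lags up to ", n_lag * dt, " ns; omitted")
      next
    }
    out[[as.character(s)]] <- structure(
      list(lags = c(0, seq_len(n_lag) * dt),
           msd = c(0, acc_sum[i, ] / acc_n[i, ]),
           cluster_size = s,
           n_samples = c(sum(sizes == s), acc_n[i, ])),
      class = "msd_curve")
  }
  out
}

#' @export
print.msd_curve <- function(x, ...) {
  cat(sprintf("MSD curve for cluster size %d: %d lags up to %g ns\n",
              x$cluster_size, length(x$lags) - 1, max(x$lags)))
  invisible(x)
}

#' Pool MSD curves of the same cluster size
#'
#' Combines curves (e.g. from independent runs) by per-lag weighted
#' averaging with the sample counts as weights.
#'
#' @param curves list of \code{msd_curve} objects with identical lags and
#'   cluster size.
#' @return a single \code{msd_curve}.
#' @export
combine_msd <- function(curves) {
  if (length(curves) == 0) stop_user("no curves to combine")
  if (length(curves) == 1) return(curves[[1]])
  s <- unique(vapply(curves, function(c) c$cluster_size, numeric(1)))
  if (length(s) != 1) stop_user("curves must share one cluster size")
  lags <- curves[[1]]$lags
  for (c in curves)
    if (length(c$lags) != length(lags) || max(abs(c$lags - lags)) > 1e-9)
      stop_user("curves must share identical lags")
  nmat <- vapply(curves, function(c) c$n_samples, numeric(length(lags)))
  mmat <- vapply(curves, function(c) c$msd, numeric(length(lags)))
  ntot <- rowSums(nmat)
  msd <- rowSums(mmat * nmat) / pmax(ntot, 1)
  msd[1] <- 0
  structure(list(lags = lags, msd = msd, cluster_size = s, n_samples = ntot),
            class = "msd_curve")
}

#' Diffusion coefficient from an MSD curve
#'
#' Weighted linear fit of MSD versus lag inside \code{window}
#' (per-lag sample counts as weights); for 2D diffusion
#' \code{D = slope / 4}.  Slope-only: an MSD offset (e.g. from localization
#' noise or ballistic transients) does not bias D.  The standard error is
#' taken from the fit covariance; note that overlapping time origins make
#' neighboring MSD lags correlated, so this error is approximate.
#'
#' @param msd an \code{msd_curve}.
#' @param window numeric \code{c(t_min, t_max)} lag window (ns), default
#'   \code{c(5, 15)} (the standard extraction window for this system).
#' @return list with \code{D} (nm^2/ns), \code{sigma} (nm^2/ns),
#'   \code{window}, \code{n_lags}, \code{cluster_size}.
#' @export
estimate_D <- function(msd, window = c(5, 15)) {
  if (!inherits(msd, "msd_curve")) stop_user("msd must be an msd_curve")
  if (length(window) != 2 || window[1] >= window[2])
    stop_user("window must be c(t_min, t_max) with t_min < t_max")
  keep <- msd$lags >= window[1] - 1e-9 & msd$lags <= window[2] + 1e-9 &
    msd$lags > 0
  if (sum(keep) < 3)
    stop_user("need at least 3 lags inside the fit window")
  dat <- data.frame(tau = msd$lags[keep], m = msd$msd[keep],
                    w = msd$n_samples[keep])
  fit <- stats::lm(m ~ tau, data = dat, weights = w)
  slope <- unname(stats::coef(fit)[2])
  se <- sqrt(stats::vcov(fit)[2, 2])
  list(D = slope / 4, sigma = se / 4, window = window,
       n_lags = nrow(dat), cluster_size = msd$cluster_size)
}

#' Diffusion records from per-size MSD curves
#'
#' Convenience wrapper applying \code{\link{estimate_D}} to every curve and
#' assembling the table that feeds the hydrodynamic fit.
#'
#' @param curves named list of \code{msd_curve} objects (from
#'   \code{\link{msd_by_size}}).
#' @param window lag window (ns) passed to \code{\link{estimate_D}}.
#' @param r_cnt single-inclusion radius (nm) for
#'   \code{\link{effective_radius}}.
#' @return data frame of class \code{diffusion_records} with columns
#'   \code{cluster_size}, \code{effective_radius}, \code{d_pbc},
#'   \code{sigma}.
#' @export
diffusion_records <- function(curves, window = c(5, 15), r_cnt = 1.05) {
  rows <- lapply(curves, function(cu) {
    est <- estimate_D(cu, window)
    data.frame(cluster_size = cu$cluster_size,
               effective_radius = effective_radius(cu$cluster_size, r_cnt),
               d_pbc = est$D, sigma = est$sigma)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[order(out$cluster_size), ]
  class(out) <- c("diffusion_records", "data.frame")
  out
}

#' Fit the membrane viscosity to diffusion records
#'
#' One-parameter weighted least squares over eta_m minimizing
#' \code{sum(((D_i - D_model(R_i; eta_m)) / sigma_i)^2)} with the SD or
#' HPW-PS model.  The minimization is a bounded scalar search on
#' log10(eta_m) to 1e-6 relative tolerance, so the result is deterministic
#' given the inputs.  The reduced chi-square uses \code{n_points - 1}
#' degrees of freedom (one fitted parameter); a value near 1 means the
#' residuals match the quoted uncertainties.
#'
#' @param records a \code{diffusion_records} data frame (or any data frame
#'   with columns \code{effective_radius}, \code{sigma} and the column
#'   named by \code{d_col}).
#' @param eta_w solvent viscosity (Pa s), held fixed.
#' @param temperature temperature (K), held fixed.
#' @param model \code{"HPW-PS"} (default) or \code{"SD"}.
#' @param d_col which column holds the diffusion coefficients to fit,
#'   default \code{"d_corrected"} falling back to \code{"d_pbc"} when
#'   absent.
#' @param interval log10 search interval for eta_m (Pa s m).
#' @return object of class \code{viscosity_fit}: \code{eta_m_hat} (Pa s m),
#'   \code{chi2_reduced}, \code{model_name}, \code{n_points}.
#' @export
fit_viscosity <- function(records, eta_w = 7e-4, temperature = 300,
                          model = c("HPW-PS", "SD"), d_col = NULL,
                          interval = c(-13, -8)) {
  model <- match.arg(model)
  records <- as.data.frame(records)
  if (is.null(d_col))
    d_col <- if ("d_corrected" %in% names(records)) "d_corrected" else "d_pbc"
  need <- c("effective_radius", "sigma", d_col)
  if (!all(need %in% names(records)))
    stop_user("records must have columns ", paste(need, collapse = ", "))
  if (nrow(records) < 2) stop_user("need at least 2 records")
  if (any(records$sigma <= 0)) stop_user("all sigma must be positive")
  if (length(unique(records$effective_radius)) < 2)
    stop_user("degenerate input: all effective radii are equal")
  r <- records$effective_radius
  d <- records[[d_col]]
  s <- records$sigma
  mfun <- if (model == "SD") {
    function(rr, h) suppressWarnings(sd_model(rr, h))
  } else hpw_ps_model
  obj <- function(lg_eta) {
    h <- hydro_params(10^lg_eta, eta_w, temperature)
    sum(((d - mfun(r, h)) / s)^2)
  }
  opt <- stats::optimize(obj, interval = interval, tol = 1e-7)
  eta_hat <- 10^opt$minimum
  structure(list(eta_m_hat = eta_hat,
                 chi2_reduced = opt$objective / (nrow(records) - 1),
                 chi2 = opt$objective,
                 model_name = model, n_points = nrow(records),
                 eta_w = eta_w, temperature = temperature, d_col = d_col),
            class = "viscosity_fit")
}

#' @export
print.viscosity_fit <- function(x, ...) {
  cat(sprintf(
    "%s fit to %d diffusion records (%s): eta_m = %.3g Pa s m, reduced chi^2 = %.3g\n",
    x$model_name, x$n_points, x$d_col, x$eta_m_hat, x$chi2_reduced))
  invisible(x)
}

#' Self-consistent finite-size-corrected viscosity fit
#'
#' The finite-size correction itself depends on the membrane viscosity, so
#' when eta_m is unknown the correction and the fit are iterated to a fixed
#' point: fit eta_m to the uncorrected coefficients, recompute the
#' correction at the fitted value, correct, refit, until the estimate is
#' stable.  If the measured coefficients truly are periodic-box values of a
#' membrane obeying the model, the fixed point is the generating viscosity.
#'
#' @inheritParams fit_viscosity
#' @param box_length side of the periodic box the coefficients were
#'   measured in (nm).
#' @param solvent_height solvent slab height (nm), \code{Inf} for
#'   unbounded.
#' @param max_iter,tol iteration control (relative tolerance on eta_m).
#' @return a \code{viscosity_fit} with extra fields \code{n_iter} and
#'   \code{delta} (the converged correction, nm^2/ns); the corrected
#'   coefficients are attached as attribute \code{"records"}.
#' @export
fit_viscosity_corrected <- function(records, box_length, solvent_height = Inf,
                                    eta_w = 7e-4, temperature = 300,
                                    model = c("HPW-PS", "SD"),
                                    max_iter = 50, tol = 1e-8) {
  model <- match.arg(model)
  records <- as.data.frame(records)
  fit <- fit_viscosity(records, eta_w, temperature, model, d_col = "d_pbc")
  eta <- fit$eta_m_hat
  delta <- NA_real_
  for (it in seq_len(max_iter)) {
    h <- hydro_params(eta, eta_w, temperature)
    delta <- pbc_suppression(box_length, solvent_height, h)
    records$d_corrected <- records$d_pbc + delta
    fit <- fit_viscosity(records, eta_w, temperature, model,
                         d_col = "d_corrected")
    if (abs(fit$eta_m_hat - eta) <= tol * eta) {
      eta <- fit$eta_m_hat
      break
    }
    eta <- fit$eta_m_hat
  }
  fit$n_iter <- it
  fit$delta <- delta
  attr(fit, "records") <- records
  fit
}
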