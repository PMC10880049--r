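# Physical constants and unit conversions (single authority for the package).
# Internal model evaluation is in SI; user-facing lengths are nm, times ns,
# diffusion coefficients nm^2/ns.  1 nm^2/ns = 1e-18 m^2 / 1e-9 s = 1e-9 m^2/s.

.kB <- 1.380649e-23        # Boltzmann constant, J/K (SI 2019 exact)
.euler_gamma <- 0.57721566490153286

.NM <- 1e-9                # m per nm
.D_SI_PER_NM2NS <- 1e-9    # (m^2/s) per (nm^2/ns)

d_to_si <- function(d_nm2_ns) d_nm2_ns * .D_SI_PER_NM2NS
d_from_si <- function(d_m2_s) d_m2_s / .D_SI_PER_NM2NS

#' @keywords internal
stop_user <- function(...) {
  stop(errorCondition(paste0(...), class = c("memclust_user_error", "error")))
}
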