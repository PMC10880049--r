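# memclust

Aggregation kinetics and membrane hydrodynamics of cylindrical membrane
inclusions — carbon-nanotube (CNT) porins, barrel-like transmembrane
proteins — analyzed from 2D center-of-mass trajectories in periodic boxes.

Membrane-embedded CNT porins self-assemble into dense, lipid-separated
clusters: inclusions pack on a near-hexagonal lattice with a shared
annular lipid shell, ~2.1 nm between centers, and the clusters themselves
keep diffusing and fusing. `memclust` provides the complete analysis
chain for such systems, plus a Brownian-dynamics generator of synthetic
trajectories for validation:

* **Cluster identification** under the 2D minimum-image convention, at
  the two physically meaningful cutoffs (1.7 nm full contact, 2.25 nm
  lipid-separated), with identity tracking, fusion/fission logging and
  power-law fits of largest-cluster growth `N_max(t) ~ t^a`.
* **Structure**: 2D radial distribution functions `g(r)` with ideal-gas
  normalization, first-peak location, per-inclusion neighbor counts, and
  tilt-order series `<|cos θ|>` from axis orientations.
* **Diffusion**: per-cluster-size mean-squared displacements with a
  strict membership-persistence rule, diffusion coefficients
  `D = slope/4` from a configurable lag window (default 5–15 ns), and a
  finite-size correction for periodic boxes.
* **Hydrodynamic fitting**: the Saffman–Delbrück model
  `D = kT/(4π η_m) [ln(2 ℓ_SD/R) − γ]` with `ℓ_SD = η_m/(2 η_w)`, and
  the Hughes–Pailthorpe–White solution in the Petrov–Schwille closed
  form, valid at all reduced radii `ε = R/ℓ_SD`. A one-parameter weighted
  fit over cluster sizes (effective radius `R = R_CNT √s`) recovers the
  membrane surface viscosity `η_m` with reduced chi-square diagnostics;
  a self-consistent variant iterates the viscosity-dependent finite-size
  correction to its fixed point.
* **Synthetic generator**: rigid-cluster overdamped Brownian dynamics
  with HPW-PS mobilities, irreversible fusion and hexagonal repacking at
  the packing distance, optional periodic-box mobility suppression, and
  AR(1) tilt fluctuations. Deterministic under a single seed.

## Worked example

```r
library(memclust)

# the standard system: 100 inclusions on a 10x10 grid in a 70 nm box
params <- sim_params(n_frames = 500, time_step = 0.5, seed = 1)
traj   <- simulate_aggregation(make_grid_configuration(10, 70), params)

cluster_series(traj, cutoff = 2.25)
#> Cluster series at cutoff 2.25 nm over 500 frames
#>   n_clusters: 100 -> 44; N_max: 1 -> 6
#>   56 fusion, 0 fission events

first_peak(rdf_2d(traj, bin_width = 0.05, frames = 400:500),
           r_min_search = 1)
#> $found TRUE; $r 2.075; $g 68.9      # lipid-separated packing peak ~2.1 nm

# hydrodynamics on persistent clusters of known sizes
curves <- msd_by_size(simulate_fixed_clusters(c(1, 4, 9, 16, 25, 64),
                                              sim_params(n_frames = 4000,
                                                         seed = 2)),
                      max_lag = 15)
rec <- diffusion_records(curves, window = c(5, 15))
fit_viscosity_corrected(rec, box_length = 70)
#> HPW-PS fit to 6 diffusion records (d_corrected):
#>   eta_m = 4.34e-11 Pa s m, ...
```

The run starts from 100 dispersed inclusions and ends with 44 clusters,
the largest holding 6 members; the late-time `g(r)` peaks within one bin
of the 2.1 nm packing distance; and the viscosity fit recovers the
generating membrane viscosity (4.5e-11 Pa s m) to within a few percent
from 4000 ns of data per size.

A thin command-line wrapper over the same functions ships at
`inst/cli/memclust.R`:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/memclust.R", package="memclust"))') \
    run --config config.yaml --seed 1
```

with subcommands `simulate | clusters | rdf | tilt | msd | fit | run`
(see `--help`). Trajectories interchange through a documented
tab-separated text format; configurations are YAML.

## Vignette

`vignettes/membrane-inclusion-clustering.Rmd` documents the models, the
generator's assumptions and what they do and do not emulate, the
estimator design choices (persistence rule, normalizations, tie-breaks,
tolerances), and known limitations.
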