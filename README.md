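# mixanalyze

Structural, hydrogen-bond, energetic and transport analysis of molecular
dynamics trajectories of hydrogen-bonded liquid mixtures — the kind of
characterization routinely applied to deep eutectic solvents such as
menthol / fatty-acid binaries, where the interplay of donor–H⋯acceptor
networks, local solvation structure and transport coefficients decides
whether a mixture is a useful solvent.

The package reads orthorhombic-box trajectories (XYZ with box metadata,
multi-MODEL PDB with CRYST1, CHARMM DCD) bound to a plain-text topology
sidecar (species, masses, partial charges, Lennard-Jones parameters,
bonds, donor/acceptor sites), and computes:

- **Structure** — site–site radial distribution functions
  `g(r) = ⟨Σᵢⱼ δ(r − rᵢⱼ)⟩ / (ρ N)`, coordination numbers
  `N = 4πρ ∫₀^r_shell r² g(r) dr`, angular distribution functions,
  combined radial/angular and radial/radial distributions (the plots
  hydrogen-bond criteria are read off), spatial distribution functions in
  a body-fixed molecular frame, and the particle-density (`Dens`) value at
  the first solvation-shell minimum.
- **Hydrogen bonds** — geometric two-criteria detection (H⋯A distance ≤
  r_max AND angle ≥ angle_min, both boundaries closed), per-frame count
  series, the Gaussian fit
  `F(X) = a/(σ√2π) · exp(−(X − X̄)²/2σ²)` of the count histogram whose
  `X̄` is the average bond number, and percent occupancy per
  donor–acceptor pair.
- **Energetics** — pairwise non-bonded decomposition
  `E = Σ C qᵢqⱼ/rᵢⱼ + Σ D₀,ᵢⱼ[(R₀,ᵢⱼ/rᵢⱼ)¹² − 2(R₀,ᵢⱼ/rᵢⱼ)⁶]`
  (CHARMM R_min convention, plain cutoff, minimum image), per species
  pair, in kcal/mol and kJ/mol.
- **Transport** — center-of-mass mean-square displacements (FFT
  accelerated, all time origins), the β(t) = d log₁₀MSD/d log₁₀t profile
  that localizes the diffusive regime, Einstein self-diffusion
  coefficients `D = limₜ MSD/6t`, bond-vector reorientation correlation
  functions `C(τ) = ⟨û(t)·û(t+τ)⟩`, and Green–Kubo shear viscosity
  `η = (V/k_BT) ∫₀^∞ ⟨P_xy(0)P_xy(t)⟩ dt` from the off-diagonal pressure
  tensor (with a virial evaluator for trajectories carrying velocities).

Because production MD trajectories are too large to ship, the package
includes first-class synthetic-trajectory generators with closed-form
ground truth — ideal gas (g ≡ 1), Brownian motion (MSD = 6Dt), ballistic
motion (β = 2), rotational diffusion (C(τ) = e^(−2D_rτ)), geometry- and
schedule-controlled hydrogen-bond dimers, a Metropolis Monte-Carlo
Lennard-Jones fluid, and an Ornstein–Uhlenbeck pressure-tensor series
(η = (V/k_BT)·σ_P²·τ_c) — so every estimator is validated against an
analytic answer.

## Worked example

```r
library(mixanalyze)

# a dimer fixture: 20 donor-H...acceptor pairs, bonded in 60% of frames
traj <- gen_hbond_dimers(20, n_frames = 50, r0 = 2.0, theta0 = 155,
                         occupancy = 0.6, seed = 42)

rdf <- compute_rdf(traj, "ACC:OA", "DON:HD", bin_width = 0.05, r_max = 6)
rdf$r[which.max(rdf$g)]
#> [1] 1.975          # the H...O contact peak sits at 2 A

series <- count_series(traj, hbond_criteria(r_max = 2.5, angle_min = 130))
glance(series)
#> # A tibble: 1 x 4
#>   n_frames mean_bonds sd_bonds max_bonds
#> 1       50         12     9.90        20

attr(percent_occupancy(series), "class_mean")
#> [1] 60             # percent of frames each ever-bonded pair is bonded

# transport: Brownian particles with D = 1 A^2/ps
est <- estimate_diffusion(compute_msd(gen_brownian(200, 40, D = 1, dt = 0.1,
                                                   n_frames = 500, seed = 42)))
est
#> <diffusion> D = 1.008 A^2/ps (1008 A^2/ns) +/- 0.00065, window [0.4, 24.6] ps

# Green-Kubo viscosity of an OU pressure series (closed form 0.2302 mPa s)
ou <- gen_ou_pressure(n_steps = 2e5, dt = 0.05, sigma_P = 100, tau_c = 1,
                      volume = 1e4, temperature = 323, seed = 42)
green_kubo_viscosity(ou)
#> <viscosity> eta = 0.2297 mPa s (truncated at 5.25 ps, zero-crossing; 3 components averaged)
```

The interpretation: the RDF peak at 2 Å is the hydrogen-bond contact
distance; the mean of 12 bonds across 20 pairs at 60 % occupancy matches
the construction; the Einstein estimate recovers the generator's
diffusion coefficient within 1 %; and the Green–Kubo integral reproduces
the Ornstein–Uhlenbeck closed form within 0.3 %.

Every result object is a tibble (or carries tibbles) with `tidy()`,
`glance()` and `autoplot()` methods, so analyses compose with dplyr and
ggplot2 pipelines.

## Command line

A thin CLI wraps the same functions (installed at `exec/mixanalyze`, or
call `mixanalyze_cli()` directly):

```sh
mixanalyze simulate hbond_dimers --seed 1 --n 20 --frames 50 --out fix
mixanalyze info fix.xyz fix.topology.yaml
mixanalyze rdf fix.xyz fix.topology.yaml --ref ACC:OA --partner DON:HD --rmax 6 --out rdf.csv
mixanalyze hbond fix.xyz fix.topology.yaml --criteria 2.5,130 --out hb
mixanalyze viscosity --series ou.csv --policy zero-crossing --out visc
```

Outputs are CSV with a one-line JSON metadata header, JSON summaries, and
Gaussian-cube files for spatial density grids.

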