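---
title: "Methods: structural and transport analysis of eutectic-mixture trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural and transport analysis of eutectic-mixture trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixanalyze)
```

# Scope and data model

`mixanalyze` characterizes molecular dynamics trajectories of
hydrogen-bonded liquid mixtures — the menthol / fatty-acid class of
hydrophobic eutectic solvents is the motivating system — through the
standard toolbox: radial, angular, combined and spatial distribution
functions, geometric hydrogen-bond statistics, non-bonded energy
decomposition, and transport estimators (Einstein diffusion, bond-vector
reorientation, Green–Kubo viscosity).

A trajectory is a constant-atom-count sequence of frames with an
**orthorhombic** periodic box; anything else is rejected at read time.
Orthorhombic cells keep the minimum-image convention exact and cheap
(`delta - L * floor(delta/L + 0.5)`, each component in `[-L/2, L/2)`),
and they are what NPT equilibrations of isotropic liquids produce.
Internal units are fixed throughout: Å, ps, amu, kcal/mol, elementary
charge, Kelvin. Conversions (kJ/mol, Å²/ns, mPa·s, Pa) happen only at
the reporting layer, so unit errors cannot accumulate mid-pipeline.
CHARMM-convention force-field parameters (well depth ε in kcal/mol,
R_min/2 in Å) are native in this system.

Coordinates are treated as **wrapped** on input. Unwrapping is an
explicit, separate step (`unwrap()`): structural estimators need wrapped
coordinates plus minimum image, dynamics needs continuous paths, and
keeping the two conventions from mixing silently is worth one extra
function call. `compute_msd()` additionally refuses input whose
inter-frame jumps reach half a box length, the signature of wrapped
coordinates.

The atom→molecule map is derived from topology block structure: molecules
are contiguous atom runs, species blocks in declared order, which is how
packed mixture boxes are built in practice.

# Synthetic trajectories as ground truth

Production trajectories of these mixtures are tens of nanoseconds of
thousands of atoms; nothing of that size can ship with a package, and no
public accession exists for the systems of interest. Validation therefore
rests on generators whose answers are known in closed form:

| generator | emulates | exact property |
|---|---|---|
| `gen_ideal_gas()` | structureless fluid | g(r) ≡ 1 |
| `gen_brownian()` | free diffusion, known D | per-axis increment variance 2·D·dt; MSD = 6Dt |
| `gen_ballistic()` | inertial streaming | MSD = ⟨v²⟩t², β ≡ 2 |
| `gen_rotor()` | rotational diffusion, known D_r | C(τ) = exp(−2·D_r·τ) |
| `gen_hbond_dimers()` | donor–H⋯acceptor contacts | per-frame bond labels exact by construction |
| `gen_lj_fluid()` | structured liquid (first peak / shoulder / minimum) | configurational energy cross-checks the energetics module |
| `gen_ou_pressure()` | off-diagonal pressure fluctuations | η = (V/k_BT)·σ_P²·τ_c |

Design points worth recording:

- Every generator is a pure function of its seed, and each embeds its
  ground truth (D, D_r, bond schedule, σ_P, τ_c) in the output metadata
  rather than side files, so a test cannot pair data with the wrong
  truth.
- The dimer generator places pairs on a lattice with spacing larger than
  twice the detection distance, so pairs never cross-talk; "broken"
  frames displace the acceptor beyond `2·r_max`. With jitter kept
  strictly inside/outside the criteria margins, detection against the
  embedded labels must be exact (F1 = 1), which is the acceptance
  condition for the detector.
- The Lennard-Jones fluid uses Metropolis Monte Carlo, not MD: only
  configurational structure matters for RDF/shell tests, and MC avoids
  thermostat machinery entirely. The pair potential is the same
  R_min-form 12-6 the energetics module evaluates, with the same plain
  cutoff, so sampled-configuration energies agree to 1e-9. In the
  reduced-unit Metropolis acceptance the well depth cancels against the
  reduced temperature, so the ideal-gas limit is reached by setting
  ε = 0 exactly (every move accepted), not by letting ε → 0.
- The rotor generator produces unit-vector series, not fake diatomic
  coordinates: the reorientation estimator consumes vectors, and
  wrapping them in atoms would add nothing. Per step each vector rotates
  about a random perpendicular axis by an angle of variance `4·D_r·dt`
  (two angular degrees of freedom × 2·D_r·dt), which yields the
  first-rank decay rate 2·D_r in the small-step regime `D_r·dt ≪ 1`.
- The Ornstein–Uhlenbeck series uses the exact AR(1) discretization
  (coefficient `exp(−dt/τ_c)`), so its autocorrelation is exponential at
  every lag, not only asymptotically.

What these fixtures do **not** emulate: real force-field anisotropy,
intramolecular flexibility, NPT box fluctuations, long-range (Ewald)
electrostatics, and the coupling between hydrogen bonding and transport.
Passing tests certify the estimators, not any claim about real
menthol / fatty-acid thermodynamics.

# Structural estimators

**RDF.** Counts of reference–partner minimum-image distances are
normalized by `n_frames · n_ref · ρ · V_shell(k)` with exact spherical
shell volumes `(4/3)π(r³_{k+1} − r³_k)` rather than `4πr²Δr`; the latter
biases the first bins where the H-bond peak lives. The partner density ρ
counts only partners actually available to a reference atom (self and —
by default — same-molecule partners excluded), which makes the
ideal-gas limit exactly 1 rather than (N−1)/N. Intramolecular pairs are
excluded by default because the quantities of interest are intermolecular
site–site correlations; a flag restores them. Defaults: bin width
0.05 Å, `r_max = min(box)/2` (minimum-image validity bound) — fine
enough to separate a 2 Å contact peak from a 3 Å shoulder.

**First minimum and coordination number.** The solvation-shell boundary
is the first local minimum after the first local maximum on a 5-bin
moving-average copy of g(r), ties broken toward smaller r; raw
histograms at desk-scale sampling are too noisy for raw extremum
scanning. A maximum must exceed `min_peak = 1.05` to count as a shell
peak — a structureless fluid's statistical ripple crosses 1 constantly,
and treating it as a shell would be a false positive; genuinely
structured liquids have first peaks well above this. The coordination
number integrates `4πρ r² g(r)` by the trapezoid rule on bin centers
with an interpolated endpoint, accurate to ≪ 0.5 % at the default bin
width.

**ADF / CDF.** The angular distribution histograms the angle at the
middle atom of distance-gated triples, normalized to unit mass
(2° bins). Combined radial/angular distributions support both angle
conventions found in practice — donor–H⋯A at the hydrogen, and
H⋯A–X at the acceptor with X the acceptor's bonded heavy atom — and
every output records which was used. The raw-count marginals of a CDF
are required (and tested) to equal the 1D histograms of the same gated
pair set *exactly*, which pins down every binning and boundary
convention. One numerical subtlety: R's vector sums accumulate in
extended precision while the compiled histogram kernels sum in doubles;
distances are therefore computed with plain double accumulation
(`x² + y² + z²` left to right, and `-ffp-contract=off` on the compiled
side) so that an observation landing exactly on a bin edge bins
identically on both paths.

The radial/radial CDF quantifies bridge motifs (two like molecules
joined by one bridging molecule): per bridge site, the nearest
qualifying partner on each axis, with the second axis forced onto a
molecule different from the first — one observation per bridge per
frame.

**SDF.** Partner density is accumulated in a body-fixed frame: origin at
anchor 1, x toward anchor 2, xy-plane through anchor 3, right-handed.
Visualization tools define such frames in various undocumented ways, so
this one is fixed, documented, and pinned by a rotation-invariance test.
Anchors collinear beyond a 1e-6 cross-product tolerance are an error
naming molecule and frame. Values are densities (Å⁻³); grid mass times
voxel volume equals the mean in-region partner count per frame per
reference molecule to 1e-6 relative (tested), and grids export to
Gaussian cube (voxel vectors converted to bohr per that standard). The
`Dens` summary is the particle density ρ·g(r) at the first minimum of
the radial particle-density curve, using the same minimum detector as
the RDF; it is reported in Å⁻³ with no claim about matching any other
tool's unlabeled scale.

# Hydrogen bonds

Detection uses two separate geometric criteria (one distance, one angle)
with **closed** boundaries: r ≤ r_max and angle ≥ angle_min both count at
equality. The closed convention is a documented choice; the literature
is usually silent about the boundary, and a bond at exactly the
threshold is still a bond under a criterion read off a distribution
plot. Defaults r ≤ 2.5 Å, donor–H⋯A angle ≥ 130°; named presets carry
the tighter per-site-pair values used for menthol / fatty-acid site
pairs (2 Å/150°, 2 Å/135°, 2.25 Å/150°). Presets are data, not code:
criteria of this kind are derived per pair from combined-distribution
plots, so they belong in a table the user can override.

The average bond number is obtained by least-squares fitting the
normalized count histogram with `F(X) = a/(σ√2π)·exp(−(X−X̄)²/2σ²)`
(Levenberg–Marquardt, initialized at the sample mean/SD; unit-width
integer bins). The amplitude is reported but unused downstream. A
zero-variance series is a degenerate distribution and errors with advice
to report the constant.

Percent occupancy is `100 · frames_bonded / n_frames` per
(donor molecule+site, acceptor molecule+site) pair. The class-level
number is the mean over pairs that bond in at least one frame;
never-bonded pairs are excluded from the mean rather than averaged in as
zeros — the aggregation is recorded in every output header because
published single percentages per site pair rarely state it.

# Energetics

The pair model is Coulomb `C·qᵢqⱼ/r` with `C = 332.0637` kcal·Å/mol
(the `e²/4πε₀` conversion, verified in tests against an independent
constant computation) plus the 12-6 form
`D₀[(R₀/r)¹² − 2(R₀/r)⁶]`, whose minimum is exactly −D₀ at R₀.
Combining rules are geometric for well depth and arithmetic for R_min —
the CHARMM convention implied by the R_min functional form. Truncation
is a plain cutoff (12 Å conventionally) with no shift, switch or Ewald
sum: this is a pairwise *analysis* decomposition, not a reproduction of
an MD engine's PME electrostatics, and the limitation is recorded in
output metadata. 1-2 and 1-3 bonded pairs are excluded from
intramolecular sums; intermolecular tables are unaffected. Means are
reported per species pair in both kcal/mol and kJ/mol.

# Transport

**MSD.** Mass-weighted molecular centers of mass (hydrogens included),
all time origins at stride 1, with an FFT path (the standard
`S1 − 2·S2` decomposition, autocorrelation via zero-padded FFT) that is
required to match the direct double loop to 1e-8 relative. The default
maximum lag is half the trajectory: longer lags average too few origins
to be worth plotting. A cancellation guard zeroes FFT residues below
`1e-10` of the mean squared coordinate so static input yields an exactly
zero MSD.

**β and the diffusive window.** β is the centered finite difference of
log₁₀MSD against log₁₀t (exact for power laws, hence the 1e-6 closed-form
checks at β = 1 and 2). The diffusive regime is the longest contiguous
run with |β − 1| ≤ 0.1 — the tolerance is this package's choice, as no
standard value exists — and runs shorter than 3 lags are treated as
smoothing noise, not a regime. `D` is the OLS slope over that window
divided by 6, with its standard error; a fixed window (e.g. the tail
fifth of a long run, mirroring the common convention of fitting the last
nanoseconds of a long trajectory) can be imposed instead. Without a
diffusive region the estimator raises a typed error carrying the β
profile, rather than fitting a meaningless slope.

**VRD.** The reorientation function is reported as the normalized
first-rank autocorrelation with C(0) = 1, which is what
decaying-from-one correlation plots show; unnormalized variants with
ensemble-size prefactors are ambiguous across the literature, and the
normalized form is the one with a clean closed form under rotational
diffusion. The decay rate is fitted by nonlinear least squares on
`exp(−kτ)` over C ≥ 0.1 (below that the tail is noise).

**Green–Kubo viscosity.** Unnormalized all-origins autocorrelations of
the three off-diagonal pressure components are averaged — the three are
statistically equivalent for an isotropic liquid and averaging cuts the
estimator variance about threefold (tested across seeds) — then
trapezoid-integrated. The plateau is read at the first zero crossing of
the averaged ACF: beyond it the integrand of a finite series is
noise-dominated and the running integral random-walks. With no crossing
inside `max_lag`, a warning is issued and the fixed-lag value reported.
The unit chain (input in atm or kcal/(mol·Å³); V in Å³; T in K; output
in mPa·s) is pinned by a test that rebuilds the conversion from SI
constants independently. The virial evaluator supplies the tensor from
trajectories with velocities (kinetic term from momenta, pair term from
the energetics forces); external engine output can be supplied as CSV
instead.

# Problem sizes

The validation suite and the acceptance script use, deliberately, sizes
a laptop handles in seconds: 1000 uniform particles × 200 frames for the
normalization bound; 500 Brownian particles × 1000 frames (D recovered
within 5 %); 2000 rotors × 400 frames (rate within 10 %); 10⁶
Ornstein–Uhlenbeck steps at dt = τ_c/20 (η within 10 % of the closed
form); ≤ 20-atom frames for the exhaustive pair-loop equalities; ≤ 500
particles for Monte-Carlo equilibration. These sizes were chosen so the
statistical error of each estimator sits comfortably inside its stated
tolerance, which the fixed seeds make reproducible.

# Known limitations

- Orthorhombic boxes only; no triclinic support anywhere.
- Plain-cutoff electrostatics; no PME/Ewald, so absolute Coulomb sums
  differ from engine-reported long-range energies.
- No hydrogen-bond lifetime/autocorrelation analysis (occupancy only),
  no second-rank (P₂) reorientation, no Einstein–Helfand viscosity
  route, no bonded-term energetics.
- The DCD reader handles CHARMM-style files with a unit-cell block and
  no fixed atoms; DCD writing is out of scope.
- Estimator tolerances quoted above are statistical statements about the
  synthetic fixtures at the stated sizes, not guarantees for arbitrary
  real trajectories.
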