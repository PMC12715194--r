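---
title: "Methods: quantifying cold sensing through water-protein interactions"
output: rmarkdown::html_vignette
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coldscan)
```

# The scientific question and the chain of methods

Cold-activated channels such as the TRPM8 receptor gate with enthalpy
and entropy changes far larger than ordinary conformational changes can
supply. One mechanistic proposal is that gating redistributes
buried/exposed states of specific residues: cooling orders the
hydration shell around exposed side chains, so the hydrogen-bonding
energetics of tens of water molecules per subunit become the
thermodynamic engine of cold sensing. Testing that picture requires a
chain of quantitative methods, each of which this package implements
and tests:

* detect candidate residues by hydroxyl-radical footprinting MS;
* measure cold sensitivity (gating ΔH) of side-chain mutants at those
  residues by patch clamp and van't Hoff analysis;
* correlate ΔH with side-chain hydrophobicity (SCH) per site, and ask
  whether the sign pattern matches the hypothesis;
* show the isolated sensing domain itself undergoes a two-state cold
  transition (CD melt, tryptophan fluorescence);
* bound the energy available from hydration-shell changes, and check
  it against the measured gating enthalpy;
* corroborate with ensemble descriptors (RMSF, radial Rg, water
  contacts) on simulated coordinate ensembles.

# Footprinting quantification

## Model

Hydroxyl radicals generated in situ oxidize solvent-exposed side
chains; DIA MS quantifies each peptide's oxidized and unmodified forms
as summed MS1+MS2 intensities. The chain is pure ratio arithmetic:

* oxidation efficiency `Oxi% = I_oxi / (I_oxi + I_naked)`;
* relative oxidation `Oxi%_O / (Oxi%_C + Oxi%_F)` against the
  untreated (C) and Fe-EDTA-only (F) controls, summed without
  renormalisation, controls taken at the same temperature;
* fold change `FC = RelOxi(4 °C) / RelOxi(30 °C)`;
* calls at strict thresholds: FC > 1.20 more exposed, FC < 0.83 more
  buried, boundaries inclusive of neither.

Assumptions worth stating: only singly oxidized peptides are
attributable to a residue, so multiply oxidized records are filtered
out (their unmodified partners are kept — they are the denominator for
every site the peptide reports); the "naked" partner of an oxidized
record is the unmodified peptide with the same sequence and span
(charge states summed), which keeps each peptide pool's bookkeeping
self-contained; per-replicate FCs are averaged (mean ± s.e.m.), with a
pooled-intensity alternative behind `method = "pooled"`.

## The 0.83–1.00 band

The thresholds are strict inequalities, so an FC of 0.87 — a burial
*trend* — classifies as "unchanged". This is deliberate: the ±20 %
window exists to absorb measurement noise, and softening it
case-by-case would make the screen irreproducible. Downstream
consistency analysis still uses the sign of FC − 1, so such sites can
participate in the quadrant statistic while failing the screen cutoff.
Thresholds are arguments everywhere they are used.

## Noise propagation

The generator applies independent multiplicative lognormal noise to
every intensity record (`noise_cv`, default 0.10 — label-free MS
intensities are positive and roughly lognormal). Because one FC
combines six intensity ratios, a 10 % record-level CV compounds to
roughly 25 % FC noise per replicate; with three replicates the
across-study mean FC stays calibrated to within a few percent, but
individual unchanged residues cross the ±20 % window at an appreciable
rate. `analysis/01_footprint_screen.R` shows both regimes side by
side. This is a property of the ratio arithmetic, not of the
implementation, and it is why replicate counts and s.e.m. columns are
carried through the report.

# Gating thermodynamics

Currents at +80 mV are normalised to the saturating (1 mM) menthol
current, taken as maximal opening, giving Po; the two-state
equilibrium constant is Keq = Po/(1 − Po) (the conventional
open/closed equilibrium; menthol-normalised Po is the default
construction). The van't Hoff fit is ordinary least squares of ln Keq
on 1/T with R = 1.98720425 × 10⁻³ kcal/(mol·K): slope −ΔH/R, intercept
ΔS/R. Cold-activating channels yield negative ΔH and ΔS; no sign
convention is imposed.

Numerical choices: Po is clipped into (ε, 1−ε) with ε = 10⁻⁴ so ln Keq
stays finite, and clipped points are *excluded* from the fit by default
(`drop_clipped = TRUE`) — a clipped point's ln Keq is an artifact of
the guard, and keeping it silently biases the slope when the ramp
saturates. The count of clipped points is reported. A user-specified
Celsius window restricts the fit to the linear van't Hoff region; all
thermodynamic arithmetic is in Kelvin, Celsius only at I/O boundaries.

The stability curve `ΔG(T) = ΔH₀ + ΔCp(T−T₀) − ΔS₀T − TΔCp ln(T/T₀)`
has second derivative −ΔCp/T: a positive gating ΔCp bends ΔG downward
(an inverted-U curve whose two zero crossings delimit heat- and
cold-activated regimes — the shape usually described as the convex
stability curve), a negative ΔCp bends it the other way. The tests
assert exactly this sign structure on a 263–323 K grid.

# Two-state melts and emission shifts

The melt model is van't Hoff two-state with linear native/transited
baselines: `signal(T) = b_f(T)(1−f) + b_u(T)f` with
`f(T) = 1/(1 + exp[(ΔH/R)(1/T − 1/T_mid)])`; a cold-induced transition
has negative ΔH, and f(T_mid) = 0.5 by construction. The
heat-capacity change of the transition is fixed at zero — over a
40 °C window with a single transition the data cannot constrain it.
Fitting is Levenberg–Marquardt (`minpack.lm::nlsLM`) with data-derived
starts (midpoint from the half-signal temperature, baselines from the
coolest/warmest quintiles); asymptotic 95 % CIs are reported. The fit
is invariant to affine rescaling of the signal axis, which is why the
melt can be fit on raw ellipticity or on mean residue ellipticity
(`[θ]_MR = 100·θ/(C·N·l)`) interchangeably.

At 3 % noise (relative to the transition amplitude) a single 21-point
melt determines ΔH to about ±8 kcal/mol and carries a small (~0.3 °C)
finite-sample skew in T_mid; because the measurement design this
emulates always uses at least three biological replicates, the
acceptance checks average three replicate melts per study before
fitting, which removes the skew and recovers ΔH = −44 ± 2 kcal/mol and
T_mid = 31.3 ± 0.3 °C as medians over 100 studies.

Emission peaks are located by the spectrum argmax refined with a
quadratic fit over a ±3-point window (sub-nm precision on 1-nm
sampling; plateaus of equal maxima resolve to the plateau centroid,
and a vertex escaping the window falls back to the grid argmax).
Shifts are reported against the highest-temperature spectrum, negative
= blue shift.

# Hydrophobicity slope and consistency statistic

For each candidate site, functional mutants give a set of (SCH, ΔH)
pairs; the slope factor is the OLS slope of ΔH on SCH. Both built-in
scales (the translocon insertion scale and the OmpLA water-to-bilayer
scale) are oriented so hydrophobic residues carry lower transfer free
energies; under this orientation the hypothesis predicts positive
slopes at sites that become exposed in the cold and negative slopes at
sites that become buried. A site is *consistent* when it falls in the
first or third quadrant of the (slope, FC−1) plane; fc = 1 or slope =
0 is indeterminate and is excluded from proportions (and counted).
Proportions are aggregated among sites whose |slope| exceeds a
threshold — magnitude filtering by default, because both signs carry
information; a signed mode exists. The exact numeric values of
published hydrophobicity scales vary slightly between sources; the
embedded values are the commonly reproduced ones, and any custom
20-residue scale can be supplied. Missing (non-functional) mutants are
simply absent; no imputation.

# Hydration energetics

Each water entering or leaving a residue's first hydration shell is
assumed to make or break one hydrogen bond of 1.5–9.5 kcal/mol — the
span of published estimates for water hydrogen-bond strengths — so a
change of Δn waters maps to the range (1.5Δn, 9.5Δn) kcal/mol per
subunit, times four for the homotetramer. Fractional Δn (MD ensemble
averages) are accepted. The sufficiency check compares the range's
upper bound to the *magnitude* of the gating enthalpy (which is
negative for cold activation), with equality counting as sufficient.
These are deliberately order-of-magnitude bounds; no claim is made
about which bonds or how many per water.

# Ensemble descriptors

Ensembles are M snapshots of Cα positions for a tetramer plus optional
water oxygens. Superposition is Kabsch (SVD with the determinant
constrained to +1, so mirror images keep a residual rather than being
reflected), computed once against the designated reference (the
initial structure), not iteratively to the mean; the rigid transform
is applied to the snapshot's waters as well. RMSF is evaluated
per atom and averaged over the four equivalent subunit positions; for
isotropic Gaussian fluctuations of per-axis σ it converges to σ√3.
Fractional change `(RMSF_cold − RMSF_warm)/RMSF_cold` uses the cold
ensemble as denominator, with a 20 % band separating specific quieting
from nonspecific thermal effects. Radial Rg is the mean in-plane
distance of a residue's Cα to the channel axis (z by default);
negative cold−warm changes mean packing. Water contacts count oxygens
strictly within a cutoff of any Cα copy of the residue — 3.5 Å by
default (first hydration shell); the cutoff is configurable because
published contact definitions vary, and the Cα is a stand-in for the
residue at coarse resolution (an all-atom path applies when models
carry side chains). Ensembles round-trip through multi-model PDB
(MODEL/ENDMDL, waters as HOH oxygens).

# The synthetic-data generators

Every generator is seeded and admits a zero-noise mode in which its
matched estimator recovers the generating parameters to numerical
precision — the round-trip properties the test suite enforces
(footprint FC exactly; ΔH/ΔS to 10⁻⁶ relative; melt parameters to
10⁻⁶; RMSF to the σ√3 limit within 2 % at M = 10⁴; water counts
exactly). Ground truth is returned as a sidecar table, never mixed
into the input schema, so downstream stages cannot read it.

What they emulate: the three-condition (C/F/O) × two-temperature
(4/30 °C) × ≥3-replicate design with one tryptic-like peptide per
probed residue; two-state gating and melt curves from chosen
thermodynamic parameters; Gaussian emission bands with linear peak
drift; ring-geometry tetramer ensembles with isotropic fluctuations
and waters planted strictly inside the contact cutoff of target
residues (placed relative to the snapshot's own Cα so counts are exact
under fluctuation).

What they do not emulate — and hence what passing tests do *not* show
about real data: chromatography and spectral interference, incomplete
sequence coverage and missing values, peptides carrying several
oxidizable residues with correlated signals, rundown and leak in
recordings, aggregation or irreversibility in melts, and actual MD
physics (solvent structure, correlated motions). The chain's
arithmetic and statistics are validated; instrument- and
sample-specific artifacts are upstream of its scope.

# Study conditions and problem sizes

The package's default conditions mirror the motivating study: 4 vs
30 °C, three biological replicates, FC thresholds 1.20/0.83, melt
truth ΔH = −44 kcal/mol and T_mid = 31.3 °C, gating ΔH around −100
kcal/mol (within the measured −57.8 to −112 range), ring ensembles of
20 residues × 4 subunits. The analysis scripts use 120-residue screens
with 33 planted changes, 100-study melt ensembles, and M = 10⁴
snapshots for the RMSF limit — sizes at which every stochastic check
stabilises while the full suite runs in well under a minute. Per-stage
seeds are fanned out from one study seed by fixed offsets so any stage
can be regenerated in isolation.

# Known limitations

* Site localization within multiply oxidizable peptides is not scored;
  the single-oxidation filter is the only attribution rule.
* The Keq construction from menthol-normalised Po assumes menthol
  saturation truly maximises Po; a Boltzmann-conductance alternative
  is not implemented.
* Melt fits assume two-state behaviour with ΔCp = 0; intermediates or
  baseline curvature will surface as fit diagnostics, not as model
  extensions.
* Hydration energetics are bounds, not free-energy calculations;
  dielectric-scaled electrostatics and force-field decompositions are
  out of scope.
* The consistency statistic treats sites independently; no correction
  for shared mutants or correlated measurement error across sites.
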