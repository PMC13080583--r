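---
title: "Models and methods for RS-domain interaction analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for RS-domain interaction analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsdomain)
```

# Scope

`rsdomain` implements the quantitative layer of an RS-domain interaction
study: binding isotherm fits for fluorescence-polarization (FP)
titrations, two-state unfolding free-energy fits from Tyr/Trp emission
ratios, and a geometric interaction census on coordinate ensembles. It
deliberately does **not** run molecular dynamics, predict structures, or
model any wet-lab step: the census consumes coordinate ensembles (here,
multi-model PDB files), wherever they come from.

# The ligand-depletion binding isotherm

FP assays for RS-domain pairs use a labelled probe at 10 nM — the same
order as many of the measured dissociation constants — so the common
hyperbolic isotherm (which assumes free titrant ≈ total titrant) is
biased. `eval_isotherm()` therefore uses the exact single-site solution,
a quadratic in the bound-probe concentration:

$$\theta = \frac{(P_T+L_T+K_D) - \sqrt{(P_T+L_T+K_D)^2 - 4P_TL_T}}{2L_T},
\qquad FP = F_{min} + (F_{max}-F_{min})\,\theta .$$

Assumptions: one binding site, fast equilibrium, polarization linear in
bound fraction. As $L_T \to 0$ the expression reduces to
$P_T/(P_T+K_D)$; the code switches to this analytic limit at $L_T = 0$
rather than dividing by zero.

**Fitting.** `fit_isotherm()` runs Levenberg–Marquardt least squares
(`minpack.lm::nlsLM`) over $(K_D, F_{min}, F_{max})$, unweighted because
replicate spreads in these assays are approximately homoscedastic in mP.
Starting values are $F_{min} = \min(FP)$, $F_{max} = \max(FP)$, and $K_D$
at the titrant concentration nearest half-span — robust for monotone
curves. $K_D$ is bounded to $(10^{-3}, 10^9)$ nM purely as a numerical
guard; the determinability classification, not the bound, handles weak
binders. Replicates are fitted independently and summarised as
mean ± SD of the per-replicate $K_D$ estimates; with a single replicate
the asymptotic standard error is reported instead, and the `kd_sd_kind`
field records which definition applies.

**Determinability.** An affinity is reported as
"too weak to be determined" when (1) the optimiser fails, or (2) the
fitted $K_D$ exceeds the top titrant concentration (the estimate would be
pure extrapolation), or (3) the fitted span $F_{max}-F_{min}$ is below 3×
the residual RMS (no significant signal). The rule that fired is kept in
the result.

# Spectral deconvolution and the two-state unfolding fit

Protein emission spectra between 280 and 400 nm are modelled as the sum
of a tyrosine and a tryptophan band, each a four-parameter asymmetric
log-normal (amplitude, peak position, FWHM, asymmetry $\rho > 1$) with a
finite support edge at $a = \lambda_m - H\rho/(\rho^2-1)$ — the standard
band shape of protein fluorescence spectroscopy. `deconvolute_spectrum()`
constrains the Tyr peak to 295–312 nm and the Trp peak to 325–360 nm;
these physical emission windows prevent the optimiser from swapping
bands, and permuted initial guesses are reordered before fitting so the
result is invariant.

The FirbY-W readout is the Tyr/Trp intensity ratio. Whether "intensity"
means fitted peak height or integrated band area is an open convention;
both are implemented in `compute_firby_ratio()` and **peak intensity is
the default**, matching the plain reading of "intensity ratio". The area
variant is one argument away for sensitivity analysis.

The ratio as a function of urea concentration $x$ follows the two-state
linear-extrapolation model

$$\mathrm{FirbY\text{-}W}(x) =
  \frac{D\,e^{(mx-\Delta G)/RT} + N}{e^{(mx-\Delta G)/RT} + 1}$$

with $R = 1.987\times10^{-3}$ kcal mol⁻¹ K⁻¹ and $T = 295$ K by default
(the measurement temperature for these systems). The curve passes
through $(N+D)/2$ exactly at the midpoint $C_m = \Delta G/m$ and is
monotone for $m > 0$; unfolding raises the ratio when $D > N$.

**Fitting.** `fit_unfolding()` is least squares over
$(\Delta G, m, N, D)$. A destabilised protein with $\Delta G < 0$ has its
transition midpoint below 0 M urea, so the native baseline is never
sampled and the default starts can land in a local minimum. The fit
therefore falls back to a coarse multi-start over midpoint
(−2 to 7 M) and m-value (0.5–2 kcal mol⁻¹ M⁻¹) whenever the first
residual is not numerically zero relative to the signal span, keeping the
noiseless round trip exact for both stable (ΔG ≈ +1.9) and destabilised
(ΔG ≈ −0.4 kcal/mol) regimes. Flat series (span below 3× a
second-difference noise estimate) and fits whose m-value collapses are
flagged non-identifiable rather than reported.

# The interaction census

**Salt bridges.** Donors are the arginine guanidinium nitrogens
(NE/NH1/NH2) and lysine NZ; acceptors are the aspartate/glutamate
carboxylates and the phosphoserine oxygens (O1P/O2P/O3P and OG). No
universal distance criterion exists for MD census work; the package
defaults to 4.0 Å between donor N and acceptor O, a common convention,
and the cutoff is configurable. Events are counted at **residue-pair
granularity** — one event per (donor residue, acceptor residue) pair per
frame regardless of how many atom contacts it makes — because
per-residue profiles are most naturally residue-pair counts.

**Hydrogen bonds.** Heavy-atom distance ≤ 3.5 Å plus a D–H···A angle
within 45° of linear, the standard MD-analysis default. Hydrogens must be
explicit and are matched to donor heavy atoms by proximity (same
residue, ≤ 1.25 Å), which makes the detector independent of hydrogen
naming conventions; a frame without hydrogens raises a capability error
instead of silently returning nothing. Residue pairs already counted as
salt bridges in the same frame are excluded so the two categories never
double-count an ion pair.

**Stacking.** Searched among Arg and the aromatics, with centroid
distance ≤ 4.5 Å and a plane-angle threshold of 20°. The angle is
interpreted as the angle **between the two group planes** (via their
normals): unlike a normal-to-centroid-vector definition it remains
well-defined for the symmetric Arg–Arg (cation–cation) case. Planes are
fit by SVD; a degenerate (collinear) group raises a geometry error for
that residue. Tryptophan contributes both rings but events are
deduplicated per residue pair, so a Trp partner counts once.

**Census bookkeeping.** Each event is labelled intra- or interchain;
intra + inter = total per kind is an invariant checked in the tests.
`summarize_frames()` averages counts per frame over a trailing window —
1000 frames per 150 ns at the 150 ps snapshot interval used throughout.
`per_residue_profile()` credits **every participating residue on the
profiled chain** (both residues of an intrachain event); the alternative
single-credit convention would halve intrachain contributions, and the
choice is recorded in the output metadata. `backbone_rmsd_series()` uses
Kabsch superposition (via bio3d) and flags equilibration when the
trailing-window RMSD slope is below 0.002 Å/ns.

# The synthetic-data module

The generators define the study conditions under which the package is
validated:

* Titrations: 2-fold dilutions from 8000 nM (14–15 points), probe 10 nM,
  homoscedastic Gaussian noise in mP (5 mP for the noisy-recovery tests,
  matching typical triplicate spreads).
* Spectra: 280–400 nm at 1 nm; Tyr band 303/34 nm (peak/FWHM), Trp band
  350/60 nm, asymmetries ≈ 1.45–1.48 — representative of protein
  emission. The Tyr amplitude is set so the generated peak ratio equals
  the two-state model exactly at each urea concentration.
* Sequences: stylised flavors — pure RS repeats (SRSF1-like), RS clusters
  with a Gly/Ser linker (U2AF1-like), and RS interleaved with RE/RD
  dipeptides (BAD1-like, net positive). Net charge uses Arg/Lys +1,
  Asp/Glu −1, phosphoserine −2 (neutral pH).
* Coordinate ensembles: **planted-interaction fixtures**, not physical
  conformations. Residues are simplified to a backbone trace plus one
  idealised functional group (charged-group centre, or ring centroid with
  its plane), laid out on a coarse grid (24 Å residue spacing, chains
  40 Å apart) with the functional groups of each planted pair brought
  together at staggered anchors. Planted geometries satisfy the detector
  criteria with wide margins (salt bridge 3.0 vs 4.0 Å; H-bond 2.9 vs
  3.5 Å and 180° vs ≥135°; stack 3.8 vs 4.5 Å and 0° vs ≤20°), and all
  non-planted site pairs are separated by several Å beyond every cutoff.
  Per-frame jitter translates each residue rigidly by a Gaussian vector
  truncated at 40% of the smallest margin (0.24 Å), so a pairwise
  distance can change by at most 0.48 Å and **no label can ever flip**:
  the stored ground truth is provably exact on every frame. Rigid
  translation leaves plane angles untouched, which is why rotational
  jitter is excluded.

Because each residue may join at most one planted interaction and side
chains are placed independently of the backbone, these fixtures prove
detector correctness and bookkeeping — they do not emulate excluded
volume, rotamer statistics, water, or genuine conformational ensembles.
Passing the planted-truth tests therefore validates the census machinery,
not any physical claim about real trajectories.

The rank fixtures (`generate_rank_complexes()`) encode the charge-driven
ordering of complex stability as a synthetic property: partner chains of
decreasing total net charge (BAD1-like +16, U2AF1-like +8, SRSF1-like
+3, using flavor-specific repeat counts) receive proportionally many
planted interchain phosphoserine–Arg salt bridges (round(charge/2)),
and the test asserts that detector-recovered interchain totals reproduce
the ordering. Total net charge, rather than per-residue charge density,
drives the planted counts; this mirrors the charge-based rationale for
the ordering while remaining a pure bookkeeping property on synthetic
data — it is **not** a re-simulation of the physical systems.

# Numerical choices and degenerate inputs

* All RNG flows through a single seed per generator call
  (`withr::with_seed`), so identical seed + parameters give bit-identical
  output and `noise_sd = 0` gives noiseless output.
* `eval_isotherm()` clamps tiny negative discriminants and bounds θ to
  [0, 1] against round-off; `eval_unfolding_ratio()` returns the
  denatured baseline when the exponential overflows.
* Multi-model PDB reading goes through `bio3d::read.pdb(multi = TRUE)`;
  inconsistent atom counts across models are a format error, unknown
  residue names produce a warning and contribute no side-chain sites.
  Writing emits fixed-format ATOM records (occupancy 1.00, B 0.00), so
  coordinates round-trip at the PDB fixed-point resolution (0.001 Å).
* Pipeline runs (`run_pipeline()`) fan a single global seed out to
  stages by fixed offsets and quarantine wall-clock timestamps to the
  log file, making report bundles byte-identical for identical
  config + seed.

# Problem sizes

The validation suite uses deliberately compact designs: 14–15-point
titrations, 15-point unfolding series, 121-point spectra, planted
complexes of 2–16 residues with 3–10 frames (1100 frames only for the
window-accounting check), 50–60 random frames for oracle comparison, and
~70 Monte-Carlo replicates per affinity for calibration. These sizes keep
every statistical check well-powered for the properties asserted while
the full suite runs in well under a minute.

# Known limitations

* Binding: single-site model only; no competition/displacement formats,
  no anisotropy↔polarization conversion, no global multi-curve fits.
* Unfolding: strictly two-state with flat baselines; no sloped-baseline
  or three-state models, no thermal melts.
* Census: multi-model PDB is the only trajectory dialect (no DCD/XTC);
  hydrogen-bond detection requires explicit hydrogens (no geometric
  hydrogen inference); cation-π is restricted to arginine, as the
  stacking search covers Arg and aromatics only.
* The synthetic complexes validate detectors and accounting, not
  conformational thermodynamics; absolute interaction counts from real
  ensembles depend on force field and sampling and are outside what the
  fixtures can certify.
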