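# rsdomain

Quantitative analysis of phosphorylation-dependent interactions between
arginine/serine-rich (RS) domains of pre-mRNA splicing factors.

SR proteins (SRSF1–SRSF12) and SR-related proteins such as U2AF1 and U1-70K
carry low-complexity RS domains whose serines are heavily phosphorylated in
cells. Binding between a phosphorylated RS domain and an unphosphorylated
one — driven largely by phosphoserine–arginine salt bridges — underlies
early spliceosome assembly. `rsdomain` packages the three quantitative
workflows used to characterise such systems:

1. **Ligand-depletion binding isotherms.** Fluorescence-polarization (FP)
   titrations with the labelled probe at concentrations comparable to the
   dissociation constant are fit with the exact quadratic isotherm

   FP = F_min + (F_max − F_min) · θ,
   θ = [(P_T + L_T + K_D) − √((P_T + L_T + K_D)² − 4 P_T L_T)] / (2 L_T),

   where P_T is total titrant, L_T total probe and K_D the dissociation
   constant. Fits that fail to converge, extrapolate K_D beyond the
   titration range, or show no significant signal span are classified
   "too weak to be determined".

2. **Two-state unfolding free energies.** Tyrosine and tryptophan emission
   bands (280–400 nm) are deconvoluted with four-parameter asymmetric
   log-normal band shapes; their peak-intensity ratio (FirbY-W) as a
   function of urea concentration x is fit with

   FirbY-W(x) = [D·e^((mx−ΔG)/RT) + N] / [e^((mx−ΔG)/RT) + 1],

   yielding the unfolding free energy ΔG (kcal/mol) and urea m-value, with
   N and D the native/denatured baselines (R = 1.987×10⁻³ kcal mol⁻¹ K⁻¹,
   T = 295 K by default).

3. **Interaction census on coordinate ensembles.** Multi-model PDB
   ensembles (with `SEP` phosphoserine support) are scanned per frame for
   salt bridges (Arg/Lys N to Asp/Glu/phosphoserine O, ≤ 4.0 Å),
   hydrogen bonds (donor–acceptor ≤ 3.5 Å, D–H···A ≥ 135°, salt-bridged
   pairs excluded) and stacking interactions among Arg and aromatics
   (centroid ≤ 4.5 Å, inter-plane angle ≤ 20°; classified π-π, cation-π,
   cation-cation). Events are partitioned intra- vs interchain, averaged
   per frame over a trailing analysis window (1000 frames per 150 ns at
   the standard 150 ps snapshot spacing), aggregated across replicate
   simulations, and summarised as per-residue salt-bridge profiles.
   Backbone RMSD after Kabsch superposition provides an equilibration
   check.

A synthetic-data module generates every input the pipeline consumes —
titrations, spectra series, RS-repeat sequences with phosphoserine marks,
and multi-frame two-chain coordinate sets with *planted, exactly counted*
interactions — so each stage is testable end to end without instrument or
trajectory data.

## Worked example

Fit a noisy triplicate FP titration (true K_D = 200 nM, probe 10 nM,
2-fold dilutions from 8000 nM, 5 mP noise):

```r
library(rsdomain)
gen <- gen_config(seed = 42, noise_sd = 5, n_replicates = 3)
cur <- generate_titration(kd = 200, probe_lt = 10, fmin = 50, fmax = 250,
                          top = 8000, n_points = 14, gen = gen)
fit_isotherm(cur)
#> <rs_binding_fit>
#>   Kd      : 202.7 nM (sd 10.9, replicate)
#>   Fmin    : 49.67 mP
#>   Fmax    : 250.5 mP
#>   repl.   : 3, residual rms 5.19 mP
```

The recovered K_D (202.7 ± 10.9 nM across replicates) matches the
generating 200 nM within one standard deviation; the baselines recover the
generating 50/250 mP window.

Census on a planted two-chain complex (two interchain phosphoserine–Arg
salt bridges and one interchain hydrogen bond, 10 jittered frames):

```r
spec <- planted_complex_spec(
  chain_a_seq = c("arg", "ser", "arg"),
  chain_b_seq = c("sep", "asn", "glu"),
  planted_salt_bridges = list(c("A", 1, "B", 1), c("A", 3, "B", 3)),
  planted_hbonds = list(c("A", 2, "B", 2)),
  n_frames = 10)
traj <- build_planted_complex(spec, gen_config(seed = 1, noise_sd = 0.08))
subset(as.data.frame(summarize_frames(traj)), mean_per_frame > 0)
#>          kind  span mean_per_frame
#> 6 salt_bridge inter              2
#> 7       hbond inter              1
```

The detected per-frame means equal the planted ground truth exactly on
every frame.

A YAML-configured end-to-end run is available through `run_pipeline()` or
the thin wrapper `inst/scripts/rs-pipeline.R`.

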