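# lipidgate

Trajectory post-processing for lipid-hydrolysing enzymes with multi-pocket
active sites, built around the fatty acid amide hydrolase (FAAH) channel
system.

FAAH hydrolyses fatty acid amides — anandamide fastest, oleamide and
palmitoylethanolamide (PEA) progressively slower — and the structural basis
of that selectivity lives in how each substrate's acyl chain moves among the
cavities of the catalytic site: the membrane-access (MA) channel, the
acyl-chain-binding (AB) cavity, and the transition (T) region between them,
gated by the "dynamic paddle" residues Phe432 and Trp531. lipidgate turns a
topology + multi-model PDB trajectory into the quantities this analysis
runs on:

* **Pocket occupancy** — per-frame distances *d*<sub>MA</sub>,
  *d*<sub>AB</sub>, *d*<sub>T</sub> from the chain-tail centre of mass to
  the channel residue groups, classified by strict cutoffs (MA if
  *d*<sub>MA</sub> < 6 Å ∧ *d*<sub>AB</sub> > 6 Å; AB for the mirror rule;
  else T if *d*<sub>T</sub> < 5 Å; NB when everything exceeds 12 Å), plus
  unbinding-episode detection.
* **Acyl-chain shape** — Applegate–Glomset classes from the torsion profile
  ω along the chain (elongated Ex/Uex, hooked J/J′, curved U/Hx/Hx-A/B),
  with an end-to-end-ratio fallback for saturated chains.
* **Gating dihedrals** — the paddle torsions φF/φW about the Cα–Cβ axis,
  binned into open (~160°) / closed (~65°) MA-gate states, with
  dwell-qualified transition counting.
* **Pre-reactive states** — near-attack geometry (attack distance and
  Bürgi–Dunitz-like angle to the catalytic serine, oxyanion-hole H-bonds)
  evaluated per frame from configurable criteria.
* **Statistics** — equilibration-aware occupancy percentages, pre-reactive
  cross-tabs, MA↔AB transfer counts, per-monomer comparison and pooling,
  polar φ-versus-distance records; JSON/CSV reports; ggplot2 views.
* **Kinetics** — Michaelis–Menten fits (v = V<sub>max</sub>·S/(K<sub>m</sub>+S)),
  competition-assay exponential decays (y = A·e<sup>−kt</sup>), and
  selectivity ratios k₁/k₂ with propagated errors.
* **Synthetic trajectories** — a seeded generator (Markov pocket hopping,
  kinematic chains realising shape labels, von Mises gating mixtures,
  injected pre-reactive flags) providing exact ground truth for every stage.

All tabular results are tibbles; fitted objects support `tidy()`/`glance()`
and `autoplot()`.

## Worked example

Generate a 5,000-frame synthetic trajectory that emulates a wild-type
FAAH/anandamide run (stationary occupancy 24/69/7% over MA/T/AB, pre-reactive
injection 10/40/5%), then run the full pipeline:

```r
library(lipidgate)

cfg    <- generator_config(seed = 42, n_frames = 5000)
sim    <- generate_trajectory(cfg)
report <- run_pipeline(sim$trajectory, default_pipeline_config(0))
report
#> <pipeline_report> 1 monomer(s)
#> -- monomer A --
#>   occupancy (%): MA 24.3, T 69.4, AB 6.3, NB 0.0, UNASSIGNED NA
#>   pre-reactive: 30.0% of 4999 equilibrated frames
```

The occupancy percentages recover the configured stationary distribution
(24/69/7) to within sampling error, and the overall pre-reactive percentage
matches the analytic expectation Σ π·p = 30.35%. Per-frame labels,
distances, paddle angles, shape classes and polar records are in
`report$monomers$A`; `write_report_json(report, "report.json")` emits the
machine-readable bundle.

Kinetics from a simulated triplicate saturation assay at the six-point
design (3.3–50 µM), 2% multiplicative noise, generating K<sub>m</sub> = 5.26 µM:

```r
fit <- fit_michaelis_menten(
  simulate_mm_assay(Vmax = 2.4, Km = 5.26, noise_sd = 0.02,
                    replicates = 3, seed = 42))
generics::tidy(fit)
#> # A tibble: 2 × 3
#>   term  estimate std.error
#>   <chr>    <dbl>     <dbl>
#> 1 Vmax      2.41    0.0268
#> 2 Km        5.23    0.231
```

Real trajectories enter through `read_trajectory("traj.pdb")` (multi-model
PDB; atoms matched by chain/resid/name) with region residues, cutoffs,
paddle residues and pre-reactive criteria declared in a YAML
`pipeline_config`.

## Vignette

`vignettes/lipid-gating-analysis.Rmd` documents the models and conventions:
the cutoff rules and their geometric rationale, the shape taxonomy and its
configurable thresholds, the near-attack criterion set, what the synthetic
generator does and does not emulate, and the numerical choices behind the
fits.
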