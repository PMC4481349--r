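---
title: "Multi-pocket occupancy, gating dihedrals and pre-reactive geometry: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-pocket occupancy, gating dihedrals and pre-reactive geometry: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

lipidgate post-processes molecular dynamics trajectories of lipid-hydrolysing
enzymes whose catalytic site is built from several connected cavities. The
reference system is fatty acid amide hydrolase (FAAH): substrates reach the
catalytic serine through a membrane-access (MA) channel, an adjacent
acyl-chain-binding (AB) cavity helps accommodate the acyl tail, and the two
are joined by a transition (T) region guarded by a "dynamic paddle" of two
aromatic side chains (Phe432 and Trp531) whose rotamer flips open and close
the MA channel. The package quantifies, frame by frame, where the substrate
tail sits, what shape its acyl chain takes, what the paddle is doing, and
whether the active-site geometry is catalytically competent, then aggregates
these into the occupancy percentages, cross-tabulations and transfer counts
used to compare substrates.

```{r setup}
library(lipidgate)
```

## Pocket occupancy

For each frame we compute three distances from the centre of mass of the
last `tail_n_atoms` (default 3) heavy atoms of the acyl chain:

* `dMA` — minimum over the MA-channel residues (Asp403, Ile407, Arg486,
  Ile530) of the distance to each residue's centre of mass;
* `dAB` — likewise for the AB-channel residues (Tyr335, Glu373, Arg428,
  Phe527);
* `dT` — likewise for the T-region residues (Phe381, Phe432, Trp531).

Classification applies strict cutoffs in a fixed order: not-bound (NB) if
all three distances exceed `nb_threshold` (12 Å); MA if `dMA < 6` Å and
`dAB > 6` Å; AB if `dMA > 6` Å and `dAB < 6` Å; T if neither pocket rule
fires and `dT < 5` Å; UNASSIGNED otherwise. The 6/6/5 Å cutoffs reflect the
geometry of the channel system: the MA and AB centres of mass sit ~16/17 Å
apart, roughly 6 Å of which belongs to each channel, leaving a ~4–5 Å
interface. Equality with a cutoff fails the condition, so the rule chain is
deterministic on every input.

Two distance modes are provided because two conventions coexist in practice:
`com_per_residue` (the default; distance between group centres of mass,
matching the prose definition above) and `atom_pair` (minimum interatomic
distance, the quantity computed by `g_mindist`-style tools). For real side
chains the two differ by roughly 1–3 Å; cutoffs are calibrated for the
default mode and should be revisited if the other is used.

Two reporting denominators are likewise available: `renormalize = TRUE`
(default) takes percentages over the assigned labels (MA/T/AB/NB), the
convention of occupancy bar charts that sum to 100% over pockets, while
`renormalize = FALSE` includes UNASSIGNED frames in the denominator.
UNASSIGNED frames are always counted and reported either way.

The NB threshold is a package choice: 12 Å is comfortably beyond the pocket
cutoffs but inside the scale at which a substrate is unambiguously in the
bilayer (the synthetic NB anchor sits 25 Å from the channel axis).
`detect_unbinding()` reports maximal NB runs; runs shorter than `min_dwell`
(default 10 frames = 0.1 ns at the default 10 ps spacing) are flagged as
transient excursions rather than unbinding events, suppressing
classification flicker at pocket boundaries.

## Acyl-chain shape taxonomy

Unsaturated acyl chains are classified in the Applegate–Glomset taxonomy
from the torsion profile along the chain: one angle per sliding 4-atom
window. A window is *trans* when its absolute torsion is at least 150°;
everything else (gauche, 30–90°; cis, below 30°) is *non-trans*. Contiguous
non-trans blocks determine the fine class:

| blocks | position | fine | coarse |
|---|---|---|---|
| none | — | Ex | elongated |
| one, single window | anywhere | Uex | elongated |
| one, longer | wholly in a terminal third | J (block sum > 0) / J′ (< 0) | hooked |
| one, longer | central | U | curved |
| two or more | both halves / first / second | Hx / Hx-A / Hx-B | curved |

The 150/90/30° state boundaries, the terminal-third rule and the
first-half/second-half split of Hx-A/B are the package's published,
configurable defaults, chosen so the classes are mutually exclusive and
exhaustive; the J vs J′ distinction uses the sign of the block's torsion
sum. Saturated chains carry no double bond to anchor a torsion pattern, so a
geometric fallback is provided (`policy = "end_to_end"`): elongated when the
end-to-end/contour ratio is at least 0.75; hooked when the ratio is below
0.75 and the largest inter-segment bend sits in a terminal 35% of the chain;
curved otherwise. Under the fallback the fine class is `NA`.

Windows whose inner triple is collinear have no defined torsion; they are
recorded as missing and treated as trans (a straight window cannot witness a
bend). When more than 20% of a profile is missing the classification is
refused and the frame lands in an explicit `unclassified` bin rather than
biasing a class.

## Gating dihedrals and pre-reactive states

The paddle torsion φ is the side-chain dihedral about the Cα–Cβ axis,
reported in 0–360°: φF for the Phe-like gate, φW for the Trp-like partner.
The default quadruple is N–Cα–Cβ–Cγ (χ1); a C–Cα–Cβ–Cγ policy is available
since the axis alone does not fix the reference atom. Dihedrals follow the
IUPAC sign convention (cis 0°, trans 180°) and agree with the bio3d and
MDTraj implementations to numerical precision. Gate states bin φF: CLOSED in
45–85° (bracketing the ~65° crystallographic rotamer), OPEN in 140–200°
(bracketing the ~160° open rotamer), INTERMEDIATE otherwise; both bins are
configurable.

Pre-reactive (near-attack) conformations are frames satisfying a
configurable set of geometric criteria, combined with AND by default. The
shipped defaults express serine-hydrolase near-attack geometry — attack
distance Ser-Oγ to substrate carbonyl carbon ≤ 4.0 Å, a Bürgi–Dunitz-like
attack angle of 75–115° at the carbonyl carbon, and the two oxyanion-hole
H-bond distances (backbone N of the two glycines to the carbonyl oxygen)
≤ 3.5 Å. These numeric bounds are package defaults for near-attack geometry,
not values taken from any specific study; every bound, atom reference and
the AND/OR combination rule is configurable, and the per-criterion measured
values are returned so a user can audit exactly which condition failed in
any frame.

Transfer counting (MA↔AB and gate CLOSED↔OPEN) uses a dwell-qualified
automaton: frames of "in transit" states (T and UNASSIGNED for pockets;
INTERMEDIATE for the gate) are dropped, the remaining stream is run-length
compressed — so a qualified run may be assembled from segments separated by
transit frames — and an event is counted when consecutive dwell-qualified
runs differ. Dwell-qualified NB episodes reset the pocket automaton (an
unbound substrate has left the channel system), while sub-dwell NB flicker
is treated like transit. This makes transfer counts invariant to inserting
UNASSIGNED frames inside a qualified run, which we test explicitly.

## The synthetic-trajectory generator

Microsecond trajectories of ~200,000-atom membrane systems are not
redistributable at desk scale, so validation rests on a generator that
emulates the statistical structure the analysis assumes, with exact ground
truth:

* the pocket state follows a 4-state Markov chain; the default stationary
  distribution (24, 69, 7, 0)% over (MA, T, AB, NB) mirrors the wild-type
  FAAH/anandamide occupancy pattern, with T dominant;
* the substrate tail is placed at the current state's pocket anchor plus
  isotropic Gaussian noise (σ = 0.8 Å); anchors sit on a 16.5 Å MA–AB axis
  with T midway and NB 25 Å off-axis, and residue-offset directions are
  perpendicular to the axis so pocket separation is not eroded;
* the acyl chain is built by an internal-coordinate (NeRF) kinematic chain
  whose window torsions realise an emitted shape label (all-trans for
  elongated, a terminal gauche block for hooked, a central gauche block for
  curved, each with 5° angular noise);
* paddle Cγ atoms are placed so the computed φF/φW equal draws from
  per-state von Mises mixtures (concentration 50, ≈ 8° circular spread,
  matching tight experimental rotamer modes; the T state is bimodal across
  the open and closed modes);
* pre-reactive flags are injected per state with probabilities
  (0.10, 0.40, 0.05, 0) for (MA, T, AB, NB), and marker atoms are placed to
  satisfy or violate the default criteria accordingly;
* the default self-transition probability is 0.70 per 10 ps frame. This
  keeps Markov dwell structure while bounding the Monte Carlo error of a
  20,000-frame run: the effective sample size is about
  n(1 − a)/(1 + a) ≈ 3,500, so stationary occupancy is recoverable to well
  under two percentage points — a variance budget fixed at design time, not
  tuned to any particular draw.

Everything is driven by one integer seed through a local RNG stream (the
caller's RNG state is untouched), and identical seeds give bit-identical
output. Fixtures round-trip through multi-model PDB (1 mÅ fixed-point
precision), a truth CSV and a YAML copy of the generator configuration that
regenerates the fixture exactly.

What the generator does **not** emulate: forces, sterics, the membrane,
realistic dwell times (real pocket residences span tens of nanoseconds),
coupling between shape and pocket beyond the emission table, and correlated
noise. Passing the recovery tests therefore demonstrates that the pipeline
measures what it claims on data with known structure — not that any
particular enzyme behaves this way. Absolute occupancy percentages from real
microsecond simulations are expressly out of reach of desk-scale validation.

## Enzyme kinetics

Saturation assays are fitted to v = Vmax·S/(Km + S) by Levenberg–Marquardt
nonlinear least squares started from the Hanes–Woolf linearisation (S/v
regressed on S); competition assays to y = A·exp(−k·t), optionally plus a
plateau, started from a log-linear regression on the positive signal. Fits
are unweighted by default, with optional 1/y weighting behind a flag;
convergence tolerances are tightened (1e-12) so noiseless data are recovered
to numerical precision. The optimiser being Levenberg–Marquardt rather than
Gauss–Newton matters for the decay fits at high noise, where `nls()`
frequently fails to converge. A fitted decay rate within two standard errors
of zero is flagged rather than reported silently, and selectivity ratios
k₁/k₂ carry a first-order (delta-method) standard error.

Simulated assays use the six-point concentration design 3.3, 6.25, 12.5, 25,
33, 50 µM and the time design 0, 5, 15, 30 min in triplicate, with
multiplicative Gaussian noise — the designs of the corresponding wet-lab
protocols. Published Km values (5.26 µM anandamide-like, 12.53 µM PEA-like)
and a 5.6-fold rate ratio serve as realistic generating parameters for
recovery studies; raw assay data are not published, so they are never used
as fitting targets.

## Numerical choices and conventions

* Distances in Å, times in ns (assay times in min), angles in degrees
  everywhere; radians never cross an interface.
* Dihedrals live in (−180, 180] with the IUPAC sign convention and are
  invariant under full order reversal; mirroring flips the sign. Presentation
  layers that need 0–360° (the paddle module) convert with `wrap_360()`.
* Atomic masses default from the element symbol (IUPAC standard atomic
  weights); a topology may override any atom's mass.
* Coordinates are taken as written in the PDB file. Periodic-boundary
  re-imaging and unwrapping are preprocessing requirements, not performed
  here, as is trajectory alignment (none of the computed quantities needs
  superposition).
* The equilibration cutoff is strict (`time > cutoff`) and defaults to
  150 ns for real trajectories; synthetic fixtures generated at
  stationarity use 0.
* Percentages are reported at full precision in machine outputs and rounded
  to one decimal in printed summaries.

## Problem sizes

The shipped validation uses 20,000-frame synthetic trajectories (200 ns at
the default 10 ps spacing) for occupancy, pre-reactive and shape recovery,
a 125,000-point distance grid for the classifier, and 1,000-replicate Monte
Carlo studies for the kinetics recovery — sizes at which the sampling
tolerances derived above hold with margin while the whole suite runs in a
few minutes on one core.

## Interface notes and limitations

The package's interface is its functions: every stage takes and returns
tibbles (or a light trajectory container), composes with the pipe, and is
driven either directly or through a YAML `pipeline_config`; `run_pipeline()`
plus the JSON/CSV writers provide the scripted entry point, and
`scripts/acceptance.R` in the source tree is a worked example of scripting
the whole analysis.

Known limitations: no periodic-boundary handling; no block-averaged or
bootstrap error bars on real-trajectory statistics (the recovery tolerances
here are generator-derived); the torsion-state and near-attack thresholds
are field-plausible defaults rather than transferable constants, and should
be calibrated per system; binary trajectory formats (XTC/DCD) require
conversion to multi-model PDB upstream.
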