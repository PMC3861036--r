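---
title: "Quantifying early-stage chemical unfolding from MD trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying early-stage chemical unfolding from MD trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ureatraj)
```

## The measurement problem

When a folded protein is placed in a concentrated urea solution, the first
stages of denaturation are subtle: the chain stays compact, most native
contacts persist, and the interesting signal lives in *kinetics* — how long
individual contacts stay broken, how long urea molecules reside in the first
solvation shell, how the solvent composition around the protein deviates
from the bulk. `ureatraj` implements the trajectory-analysis battery needed
to quantify this regime: global structure descriptors, native-contact
kinetics, solvation-shell statistics, geometric hydrogen-bond analysis, and
flexibility/transport metrics, plus a synthetic-trajectory generator that
provides exact ground truth so every analysis can be validated without an MD
engine.

## Structure descriptors

Per frame, the package computes RMSD to a reference after optimal rigid
superposition (Kabsch, SVD-based, proper rotation enforced; two collinear
points are accepted as a degenerate but well-defined case), radius of
gyration, TM-score, Shrake–Rupley solvent-accessible surface area, and a
three-state secondary-structure assignment.

**TM-score.** TM = (1/L) Σ 1/(1 + (dᵢ/d₀)²) with d₀ = 1.24(L−15)^{1/3} −
1.8, requiring L ≥ 16 so d₀ > 0. Because the compared conformations come
from one trajectory, the residue correspondence is the identity and no
alignment search is needed. After a Kabsch fit on all CA atoms, an optional
refinement re-fits on the residues currently closer than d₀ and iterates
while the score improves; this simple hill-climb is a lower bound of the
exhaustive TM-align optimum, which is the conservative direction for an
unfolding read-out.

**SASA.** Shrake–Rupley with a 1.4 Å probe and 960 quasi-uniform sphere
points per atom (a deterministic golden-spiral lattice, so results are
reproducible and converge within 2% of a 4000-point evaluation). Radii are
Bondi values (C 1.70, N 1.55, O 1.52, S 1.80 Å), configurable. SASA is
computed on heavy atoms only, matching trajectories with implicit or
stripped hydrogens. The polar/apolar split is by residue class — polar +
charged versus hydrophobic residues — not per-atom chemistry, because the
quantity of interest is the exposure of apolar *residues* during unfolding.
Condition series are normalized by the mean of the native-state water run,
so 1.0 means "as exposed as the native ensemble".

**Secondary structure.** A reduced DSSP: backbone H-bonds are scored with
the Kabsch–Sander electrostatic model, E = 0.084(1/r_ON + 1/r_CH − 1/r_OH −
1/r_CN)·332 kcal/mol, bond if E < −0.5 kcal/mol, with the amide H rebuilt
1 Å from N opposite the bisector of N→C(prev) and N→CA when absent. Helices
(H) come from runs of i→i+4 turns, strands (E) from parallel/antiparallel
bridge ladders of length ≥ 2, everything else is coil (C). 3₁₀/π helices
fold into H and turns/bends into C, because the downstream quantity is a
native-secondary-structure fraction, not an 8-state assignment. Different
DSSP implementations disagree at helix termini and short bridges; small
secondary-structure-content differences against other tools are expected.

**Native-structure indexes.** S2 is the fraction of natively H/E residues
that keep their native label; S3 the fraction of native contacts present.
Both are 1 in the native state and fall towards 0. The *global structure
index* combines them; since the combination rule is a modelling choice, two
modes are provided — the mean of S2 and S3 (default) and S3 alone — and
every output is labelled with the mode used.

## Native-contact kinetics

A residue pair is in contact in a frame when any two heavy atoms across the
pair are closer than 3.5 Å. *Native* contacts are those present in strictly
more than 80% of a native-state reference run (water, room temperature).
Pairs with sequence separation |i−j| < 3 are excluded: nearest neighbours
are trivially always in contact and would dilute S3. Neither choice is
universal, so both the cutoff (4.5 Å alternative) and the separation are
arguments, not constants.

Opening statistics treat each native contact as a two-state signal: an
opening is a maximal run of contact-absent frames, its duration the run
length times the frame spacing. Comparing two conditions, a contact is
classified as "longer-opening" in one of them when its mean opening time
differs by strictly more than 0.1 ns — the margin used to call a contact's
flexibility changed. Per-residue lost-contact time is the mean, over the
native contacts a residue participates in, of the percentage of frames the
contact is broken (an occupancy-deficit variant relative to the reference
run is provided). Cross-condition correlations of lost time use the Pearson
estimator with a two-sided t-distribution p-value.

**Sampling resolution matters.** A contact signal observed every dt misses
openings shorter than dt and merges openings separated by closed gaps
shorter than dt. For exponential dwells at rate k both effects bias the
measured mean upward by roughly dt·k/2 + dt·k (miss + merge) — about +15%
at dt·k = 0.1. The kinetics fixtures therefore sample at dt·k = 0.02, where
the residual bias (~3%) is well inside the recovery tolerances. Users
analysing real trajectories should check dt against the fastest contact
kinetics they care about; the package reports event counts so this is
visible.

## Solvation shells and urea preference

Shell membership is per solvent *molecule*: a molecule is in the first
solvation shell (FSS) when any of its heavy atoms is within 5 Å of any
protein heavy atom, bulk when all are beyond 6 Å, intermediate otherwise
(the 5–6 Å band belongs to neither, exactly as two one-sided cutoffs
imply). The water/urea ratio is reported per frame and two ways in summary:
the mean of per-frame ratios, and the count-pooled ratio (total water count
over total urea count across frames). With few urea molecules in the shell
the per-frame ratio is a ratio of small counts and its mean is biased
upward by roughly 1/E[count]; the pooled estimator does not have this
problem and is the one used for recovery checks.

CC_UW, the urea-preference coefficient, is the time-averaged count of
protein–urea heavy-atom pairs within 3.5 Å divided by the same count
against water, per residue or per group (polarity class, backbone/side
chain, core/non-core). It is reported raw; normalization by the bulk
urea:water atom ratio is an option for cross-concentration comparisons.
Core residues are defined by relative solvent accessibility in the native
frame (per-residue SASA over the residue type's maximum accessibility,
threshold 0.25).

Residence events are maximal runs of frames in which one solvent molecule
keeps at least one heavy-atom contact (< 3.5 Å) with the target, optionally
merging sub-tolerance gaps. The long-residence report ranks molecules by
their longest event and exports per-molecule residue × frame contact maps.

Interaction energies between a urea molecule and the protein are direct-sum
cutoff Coulomb (332.0636·qᵢqⱼ/r) plus Lennard-Jones with Lorentz–Berthelot
mixing at a 9 Å cutoff, from a user-supplied per-atom (q, σ, ε) table. No
Ewald summation and no long-range corrections: these are per-molecule
*diagnostics* of relative binding energetics, not simulation energies, and
are documented as approximate.

## Hydrogen bonds

A bond requires donor–acceptor heavy distance ≤ 3.50 Å and donor–H–acceptor
angle ≥ 120°. The angle convention is the package's reading of "120°
cutoff": bonds more linear than 120° are accepted. Tools differ here, so
the convention is a switch (`convention = "ADH"` tests the angle at the
donor instead). Donors are N/O atoms with an attached hydrogen (bonded =
same residue, within 1.25 Å); the backbone amide H is rebuilt geometrically
when absent; prolines do not donate. Acceptors are oxygens plus the HIS
imidazole nitrogens; sulfur is excluded by default. Occupancy filtering
keeps bonds whose total detected time exceeds 0.5 ns — the "stable contact"
criterion — and the partition reports urea vs water shares, donor vs
acceptor roles per species, and backbone vs side-chain protein sides, each
summing to 100%.

## Flexibility and transport

RMSF is computed after superposing every frame onto the mean structure
(fit to frame 1, average, re-fit to the average), per residue as the
unweighted mean over heavy atoms. Pseudo-B-factors use the isotropic
Debye–Waller relation B = (8π²/3)·RMSF². The side-chain stiffness
comparison superposes both conditions on the backbone and counts residues
whose side-chain RMSF is strictly smaller; ties (identical inputs) count as
not stiffer. Time-lag RMSD averages RMSD(t, t+τ) over all window starts,
the reference always being the first frame of the window.

MSD uses per-molecule centers of mass and all overlapping time origins
(an independent-origin mode exists for error estimation); wrapped periodic
coordinates are unwrapped by minimum-image displacement accumulation, which
requires that no molecule moves more than half a box per frame (checked,
error otherwise). The Einstein estimate D = slope/6 comes from a
least-squares line over 10–50% of the maximum lag — late enough to avoid
start-up transients, early enough that the long-lag tail (few independent
samples) does not dominate. The fit range is an argument and the output
always carries slope, intercept and R², so fit-range sensitivity is never
hidden.

## The synthetic generator: what it emulates, and what it does not

`synthesize_trajectory()` realizes a scripted, kinematic model of the study
system — it is a test harness with exact ground truth, **not** an MD
engine:

- **Contacts** follow exact two-state Markov (telegraph) schedules realized
  geometrically: paired beads sit at 3.0 Å when closed and 8.0 Å when open,
  so contact detection recovers the schedule bit for bit.
- **Unfolding** is a deterministic dihedral-space interpolation of an ideal
  helix (φ,ψ from (−57°,−47°) to (−180°,−180°)). The path runs through the
  β/PPII quadrant; the (+180°,+180°) representation of the same endpoint
  would pass through the compact left-handed-helix region and transiently
  re-form contacts, which is why the negative branch is the default.
- **Solvent** molecules are rigid point sets (water: one heavy O + 2 H;
  urea: four heavy pseudo-atoms) undergoing Brownian motion with prescribed
  D (per-axis steps N(0, √(2·D·dt))), wrapped in an orthorhombic box. The
  default D values (1.0 and 0.5 Å²/ns) are deliberately slow scaled-down
  values chosen so that shell crossings are resolved at the default frame
  spacing; fixtures that need fast shell turnover set D explicitly.
- **First-shell urea enrichment** multiplies the urea stationary density by
  a factor f inside the FSS, via Metropolis-adjusted steps (kinetic mode)
  or direct rejection sampling of independent frames (equilibrium mode, the
  right tool for composition statistics since it maximizes independent
  samples per frame). The default urea pseudo-molecule is spatially compact
  (heavy-atom offsets scaled far below chemical bond lengths): with
  molecule-level shell membership, a spatially extended species has a
  larger effective shell volume than a point-like one, which alone would
  shift the FSS ratio away from the bulk ratio even at f = 1 and break the
  null calibration. Chemically proportioned planar urea (with N–H
  hydrogens) is used when hydrogen-bond geometry matters.
- **Sticky urea** is a jump process: on entering the FSS of a target
  residue a molecule is tethered at contact distance (2.9 Å, small jitter)
  with a set capture probability, dwells an exponential time at rate
  k_off, then jumps to just outside the shell so the residence event ends
  cleanly and re-binding requires diffusing back in. A designated long
  binder can be scripted for ranking tests. Ground-truth event logs are
  emitted alongside.

None of this has thermodynamic realism: no forces, no temperature, no
water structure, no cooperativity. Passing recovery tests therefore shows
that the *measurement machinery* is correct and calibrated — not that any
scientific conclusion about real proteins follows. On real trajectories the
user still owns equilibration, sampling adequacy and force-field caveats.

## Problem sizes and determinism

The shipped tests and analysis scripts use: telegraph kinetics with 10–25
contacts over 250 ns at dt = 0.02 ns (1000–3000 opening events; at 25
contacts the S3 standard error is ~0.006, so a 0.02 recovery band is a
3-sigma bound); solvation
boxes of 600 water + 100 urea (6:1) around a 27-bead solute in a 50 Å box,
120 independent frames; sticky-urea runs of 25 urea over 60 ns (~600
residence events); diffusion fixtures of 100 walkers × 1000 frames. These
sizes put the stochastic recovery checks comfortably inside their
tolerances (relative standard errors of a few percent) while keeping the
full suite in the minutes range on one core. Everything random flows from a
single recorded seed; regenerating a bundle from its spec is bit-identical,
and `run_pipeline()` writes summaries with no timestamps so repeated runs
are byte-identical.

## Known limitations

- Orthorhombic boxes only (minimum-image); truncated-octahedron cells must
  be re-wrapped upstream.
- The TM-score refinement is a local hill-climb, not the TM-align search;
  scores are lower bounds (self-comparisons are exactly 1).
- The 3-state secondary-structure reduction ignores 3₁₀/π distinctions and
  bridges of length 1.
- Energy decomposition is cutoff-based; absolute values are not comparable
  to Ewald-based engine energies.
- XTC input is not supported (PDB and DCD are); no topology building,
  protonation or force-field parameter assignment.
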