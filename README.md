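# ureatraj

Trajectory metrics for the **early stages of chemical (urea) unfolding of
proteins**, for computational biophysicists analysing MD simulations of
proteins in water/urea boxes. In this quasi-native regime the protein stays
compact and the signal is kinetic and compositional: which native contacts
break and for how long, how urea concentrates in the first solvation shell,
which urea molecules reside long enough near the hydrophobic core to matter,
and how solvent viscosity shows up in side-chain fluctuations and diffusion.

## What it computes

**Structure descriptors** (per frame): RMSD after Kabsch superposition;
radius of gyration; Shrake–Rupley SASA with a polar/apolar split by residue
class and normalization by the native-state water run; TM-score,

&nbsp;&nbsp;TM = (1/L) Σᵢ 1/(1 + (dᵢ/d₀)²),&nbsp; d₀ = 1.24(L−15)^⅓ − 1.8;

a reduced 3-state DSSP (Kabsch–Sander H-bond energy E = 0.084(1/r_ON +
1/r_CH − 1/r_OH − 1/r_CN)·332 < −0.5 kcal/mol); and the native-structure
indexes **S2** (fraction of native H/E labels retained) and **S3** (fraction
of native contacts present), combined into a global structure index that
tracks unfolding from 1 (native) towards 0.

**Native-contact kinetics**: residue–residue contacts (any heavy-atom pair
< 3.5 Å, |i−j| ≥ 3), native set = contacts present > 80% of a reference
water run; opening-time statistics per contact; classification of contacts
whose mean opening time shifts by more than |0.1| ns between conditions;
per-residue lost-contact time and its cross-condition Pearson correlation.

**Solvation analysis**: per-molecule shell assignment (FSS ≤ 5 Å, bulk
> 6 Å), water/urea ratios per shell; the urea-preference coefficient CC_UW
(urea:water atomic contact ratio) by residue, polarity class,
backbone/side-chain, or core/non-core; solvent residence events with
long-residence ranking and per-molecule contact maps; cutoff
Coulomb + Lennard-Jones energy decomposition for bound urea.

**Hydrogen bonds**: geometric detection (D–A ≤ 3.50 Å, D–H–A ≥ 120°),
occupancy filtering at 0.5 ns, and the urea/water × donor/acceptor ×
backbone/side-chain partition.

**Dynamics**: per-residue RMSF and pseudo-B-factors (B = 8π²/3·RMSF²),
side-chain stiffness comparison between conditions, time-lag RMSD, MSD and
the Einstein diffusion coefficient D = slope/6 with fit diagnostics.

**Synthetic ground truth**: `synthetic_spec()` / `synthesize_trajectory()`
generate toy proteins (ideal helix, β-hairpin, bead chains) with telegraph
contact schedules or scripted dihedral unfolding, Brownian water/urea with
prescribed diffusion constants, first-shell urea enrichment, and sticky
urea with exponential residence kinetics — with every schedule, rate and
event logged, so each analysis is validated against exactly known answers.

## Worked example

Generate a scripted unfolding of a 16-residue helix and track the structure
indexes:

```r
library(ureatraj)
b <- synthesize_trajectory(synthetic_spec(
  seed = 20251001, dt_ns = 0.1, n_frames = 60,
  protein = list(n_residues = 16, schedule = list(type = "interpolate"))))

native_ss <- assign_ss(traj_frame(b$traj, 1), b$system)
s2 <- s2_series(b$traj, b$system, native_ss)
tl <- contact_timeline(b$traj, b$system)        # 3.5 A heavy-atom contacts
ref <- tl; ref$presence <- tl$presence[, 1, drop = FALSE]
s3 <- s3_series(tl, native_contact_set(ref, 0))
structure_index(s2$values, s3$values)[c(1, 30, 60)]
```

The run prints (stage 2 of the analysis workflow):

```
helix unfolding, 16 residues, 60 frames:
  RMSD       0.00 ->  9.98 Angstrom
  TM-score   1.00 ->  0.01
  S2 1.00 -> 0.00, S3 1.00 -> 0.00, structure index 1.00 -> 0.00
```

i.e. the native frame scores 1.0 on every index, and the fully extended
endpoint has lost all native secondary structure and contacts, with RMSD
rising to ~10 Å — the descriptors move monotonically as the scripted
unfolding proceeds. Telegraph contact fixtures are recovered the same way
(stage 3):

```
symmetric telegraph (k = 1/ns): S3 long-run mean 0.5187 (expect 0.5)
  pooled mean opening time 0.980 ns over 1228 events (expect 1 ns)
shift classification (|0.1| ns margin): 30% longer in A, 0% in B, 30% total (scripted: 30/0/30)
```

## Analysis workflow

The `analysis/` directory holds the numbered study drivers; each is a thin
script over the package functions and writes its tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate.R` | builds the synthetic study bundles (ground truth under `scratch/`) |
| `02_structure_metrics.R` | structure descriptors along the scripted unfolding |
| `03_contact_kinetics.R` | S3, opening times, shift classification, lost-time correlation |
| `04_solvation.R` | shell ratios, CC_UW, residence events, long-binder ranking |
| `05_hbonds_dynamics.R` | H-bond occupancy/partition, Einstein diffusion, side-chain stiffness |
| `06_report.R` | `run_pipeline()` orchestration and fold-group aggregation |

Run them in order from the repository root: `Rscript analysis/01_simulate.R`
and so on.

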