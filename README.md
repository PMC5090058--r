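# tomodock

Tomographic docking scans of deep binding pockets in R.

Conventional molecular docking treats a binding site as one holistic search
space, so a ligand can be reported as binding at the bottom of a deep pocket
even when the route down is blocked. `tomodock` implements *tomographic
docking*: a cubic search space is slid along the pocket's depth axis in
fixed increments (by default an 18 Å cube advanced in 1 Å steps along the
receptor's principal axis of inertia), an independent docking experiment is
run at every step, and the resulting best-pose-per-step series is analysed
for engagement plateaus, pose transitions, and the receptor residues that
newly enter the search space when transitions happen. On the auxin receptor
TIR1 this style of analysis separates the hormone indole-3-acetic acid from
its inactive look-alike tryptophan and points at an engagement niche near
the pocket mouth and a mid-depth "molecular filter" of selectivity
residues.

The package provides, for a receptor `R`, pocket definition `P` and
ligand `L`:

* structure I/O for PDB and AutoDock PDBQT (charges, atom types), residue
  selection and rigid transforms;
* pocket geometry: inertia-tensor principal axes, scan-axis selection with
  ambiguity detection, pocket depth between mouth/bottom reference
  residues, frame alignment so boxes advance purely in depth;
* scan planning: the ordered box sequence from above the mouth to below the
  bottom, plus per-step atom/residue inclusion tables;
* engines: an adapter for an external AutoDock Vina binary (production)
  and a deterministic built-in rigid-body engine over a transparent
  pairwise clash + pharmacophore-matched Gaussian potential (desk scale,
  fully offline);
* the scan runner (`run_scan()`, seeded per step × repetition) and the
  best-pose reduction (`best_pose_per_step()`);
* analysis: depth/orientation/niche metrics, significant-change flags,
  plateau grouping, selectivity-filter candidate identification
  (`identify_filter()`) and binder/non-binder classification
  (`classify_ligand()`);
* a synthetic planted-truth generator (`make_toy_pocket()`,
  `make_toy_ligands()`) producing a tubular pocket with a known niche,
  constriction filter and base site plus one ligand that can reach the base
  and one that cannot — so the entire pipeline is testable with no
  downloads and no external binary.

## Worked example

```r
library(tomodock)

spec <- toy_pocket_spec(seed = 1)          # planted toy system
toy  <- make_toy_pocket(spec)
ligs <- make_toy_ligands(spec)

ax   <- scan_axis(toy$receptor, toy$pocket)
al   <- align_to_axis(toy$receptor, ligs$passing, ax)
plan <- build_scan(al$receptor, toy$pocket,
                   scan_config(repetitions = 5, exhaustiveness = 8, seed = 1))
plan
#> <scan_plan: 14 steps, edge 18.0 A, step 1.0 A, leading face z 0.28..13.28 A>

traj <- best_pose_per_step(run_scan(al$receptor, al$ligand, plan, n_poses = 3))
m <- step_metrics(traj, al$receptor, al$ligand, toy$truth$ring_atoms, toy$niche)
f <- flag_changes(m, traj, rmsd_tol = 2.0)
round(m[c(1, 5, 10, 14), c("score", "depth", "orientation_angle")], 2)
#>    score depth orientation_angle
#> 1  -6.17 -0.42             87.97
#> 5  -6.19 -0.62             85.33
#> 10 -8.77  9.11             89.12
#> 14 -8.77  9.11             89.12

incl <- inclusion_table(al$receptor, plan, toy$pocket)
identify_filter(incl, f, toy$niche)
#> Filter residue candidates:
#>  chain resi resn steps new_atoms polarity n_triggers
#>      A   30  FLT    10         6    polar          1
#>      A   29  FLT    10         5    polar          1

classify_ligand(m, f, base_depth = toy$truth$base_depth)
#> binder-like  [niche engagement (perpendicular, tail in niche): TRUE;
#>               reaches base depth: TRUE (final depth 9.11 A)]
```

Reading: the ligand engages the niche immediately (score −6.2, depth
≈ −0.4 Å, ring ~88° from the pocket base — i.e. perpendicular), holds that
pose for nine steps, then descends in one transition to the base
(score −8.8, depth ≈ 9.1 Å). The only residues contributing three or more
newly included atoms at the transition are the two planted constriction
rings — the molecular filter. The blocked ligand runs the same pipeline and
comes out `non-binder-like` (it never leaves the mouth). A command-line
front end with `fixtures`, `scan` and `analyze` subcommands is installed at
`system.file("cli", "tomodock.R", package = "tomodock")`.

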