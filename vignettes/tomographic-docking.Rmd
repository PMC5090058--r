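---
title: "Tomographic docking: scanning a deep binding pocket slice by slice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tomographic docking: scanning a deep binding pocket slice by slice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tomodock)
```

## The idea

Conventional docking treats a binding site as a single search space: the
engine reports the best-scoring placement anywhere inside one box. For deep,
tube-like pockets this overlooks everything a ligand must negotiate on the
way in — a pose at the bottom is reported as viable even when the route to
it is blocked. Tomographic docking instead slides a cubic search space along
the pocket's depth axis in fixed increments, runs an independent docking
experiment at every step, and analyses the resulting pose series. Because
the box at step $k$ only exposes the receptor atoms reachable at that depth,
the series reconstructs a plausible engagement pathway: where the pose stops
changing (a *plateau*), which residues newly enter the search space when it
does change, and whether the ligand ever reaches the pocket base.

The motivating system is the auxin receptor TIR1, whose binding pocket is a
deep cavity in a leucine-rich-repeat solenoid. The natural hormone
indole-3-acetic acid (IAA) binds at the pocket base; its biosynthetic
precursor tryptophan is structurally similar yet inactive. A depth-resolved
scan distinguishes the two by their behaviour part-way down the pocket, and
points to an *engagement niche* near the mouth and a mid-depth *molecular
filter* of residues that admit correctly oriented binders and block others.

## The scan

Given a receptor, a pocket definition (lining residue ranges plus one
mouth and one bottom reference residue), and a ligand, the pipeline is:

1. **Axis.** `principal_axes()` builds the inertia tensor of the receptor
   (mass-weighted by element, about the centroid) and `scan_axis()` selects
   the principal axis most nearly parallel to the vector from the mouth
   reference centroid to the bottom reference centroid, sign-oriented toward
   the bottom. The choice is deterministic; when two axes are equally
   aligned, or the selected moment is degenerate, an error asks for an
   explicit `axis_override`. `pocket_depth()` reports the mouth-to-bottom
   reference distance under a heavy-atom-centroid convention (default) and a
   CA-to-CA alternative, since published depth figures rarely state which
   atom pair they used.
2. **Frame.** `align_to_axis()` rotates the working frame so the scan axis
   is exactly $+z$ and the mouth centroid is the origin. Docking boxes can
   then stay world-axis-aligned — the convention external engines expect —
   while their centers advance purely in depth. The rigid transform is
   returned so every output can be mapped back.
3. **Plan.** `build_scan()` places box 1 so its leading (deepest) face is
   tangent to the deepest mouth-reference atom, with the lateral center on
   the mouth centroid, then advances the center by `step` along $+z$ until
   the first box whose interior contains every bottom-reference atom. Box
   membership is closed-boundary (face contact counts); the number of steps
   is emergent from the geometry, not fixed. The defaults mirror the
   published protocol: an 18 Å cube (always larger than the engine's 8 Å
   interaction cutoff), 1 Å steps, 100 repetitions per step, search
   exhaustiveness 16.
4. **Scan.** `run_scan()` executes `repetitions` independent docking runs
   per box, with per-run seeds derived as `seed + 1000*step + repetition`,
   so any single run is reproducible in isolation. Per-step results can be
   persisted and reused across interrupted runs. `best_pose_per_step()`
   reduces the result to the lowest-scoring pose per step; exact ties break
   toward the lowest repetition index then pose rank, which makes the
   reduction invariant to the order repetitions are stored in.
5. **Analysis.** `inclusion_table()` records the first step at which every
   pocket-lining heavy atom enters the box (never-included atoms carry
   sentinel step 0, exported as "none"). `step_metrics()` computes per-step
   depth (ligand centroid $z$), ring orientation (angle between the
   least-squares ring-plane normal and the scan axis: 0° = ring parallel to
   the pocket base, 90° = perpendicular), and niche engagement (any tail
   atom within the niche cutoff of a niche residue atom). `flag_changes()`
   marks steps where depth, orientation, or in-frame RMSD against the
   previous best pose exceeds a threshold; `plateaus()` merges unflagged
   runs with their preceding flagged step into an ordered partition;
   `identify_filter()` and `classify_ligand()` turn these into the
   headline outputs.

## The filter rule and the classifier

A residue is a **filter candidate** when it contributes at least
`min_new_atoms` newly included heavy atoms at a flagged step — one where the
docked pose actually changed — or within `window` steps before it. Residues
whose atoms arrive only during a plateau are excluded: by then the pose has
settled, so those atoms cannot have driven a transition. Step 1 never
triggers candidates; its inclusions describe the initial box contents, not
scan progression. Niche residues meeting the rule are reported separately
rather than as filter members. Candidates are ranked by the number of
triggering steps, then by atom count, and each carries a short rationale
naming its polarity and triggering steps.

`classify_ligand()` labels a trajectory **binder-like** when (a) some
plateau of at least two steps shows the tail engaged in the niche with the
ring within `angle_tol` of perpendicular, and (b) the final plateau's mean
depth reaches `base_depth`. Both criteria are reported individually. This is
a heuristic pose-series label — a statement about the reconstructed
pathway, not a binding-affinity prediction.

Thresholds are deliberately plain configuration, reported in outputs:
depth 0.5 Å, in-frame RMSD 1.0 Å, orientation 20°, `min_new_atoms` 3,
`window` 1, niche contact 4.0 Å (a typical polar-contact distance). The
source analyses flag changes qualitatively, so these defaults are package
choices, not published constants.

## Engines

The method is engine-agnostic orchestration, so the engine is a contract:
`dock(receptor, ligand, box, params)` returns at least one pose, sorted by
ascending score, centroids inside the box. Two implementations ship.

The **external adapter** (`vina_adapter()`) drives an AutoDock Vina binary:
it writes a config file (cube center and size, exhaustiveness, seed,
`num_modes`), invokes the binary, and parses `REMARK VINA RESULT` scores and
MODEL coordinates back into poses. This is the production path for real
receptors, and the scan defaults above are the full-fidelity protocol.

The **built-in engine** (`toy_search()`) exists so that every pipeline stage
is testable on one CPU with no binary and no downloads. It is a rigid-body
docking engine over a transparent surrogate potential (`toy_score()`): a sum
over receptor–ligand atom pairs within 8 Å of a soft-sphere clash penalty
$C\,\max(0, r_\mathrm{min} - d)^2$ plus, for pharmacophore-matched pairs
(donor–acceptor, aromatic–aromatic, apolar–apolar), a Gaussian attraction
$-A\,e^{-(d - d_0)^2/w}$ with $A{=}1$, $C{=}10$, $r_\mathrm{min}{=}2.5$ Å,
$d_0{=}3$ Å, $w{=}1$ Å². Atoms whose label is `inert` interact only
sterically. These constants are fixture conventions, not physical claims.
The search combines a deterministic pharmacophore grid (every compatible
atom-pair alignment between ligand and receptor, crossed with spins about
the pair axis and offset directions), seeded single-anchor and uniform
random restarts in numbers proportional to the exhaustiveness, and
rigid-body coordinate-descent refinement with a shrinking step schedule.
Refinement candidates are chosen per pharmacophore site and by spatial
diversity, so a strong site cannot starve a weaker one. Identical inputs
and seed give bit-identical results; the caller's RNG state is preserved.
The grid stage is needed because a Gaussian of width 1 Å² creates basins
far too narrow for uniform restarts to find reliably.

## The synthetic planted-truth system

`make_toy_pocket()` and `make_toy_ligands()` generate a receptor and ligand
pair in which every feature the analysis is supposed to detect is planted by
construction:

* a tube of inert wall carbons (radius 5.5 Å, base plane at 13 Å) with a
  whole-ring mouth residue and a bottom reference residue;
* an **engagement niche**: a vertical slot of two acceptor pairs whose
  spacing matches the ligands' donor pair, flanked by inert corridor
  columns. Only a tail held vertically in the slot plane contacts all four
  acceptors, which forces the attached ring perpendicular to the base —
  the orientation signature the classifier looks for. Inert blockers under
  the niche exclude the mirrored engagement with the ring pointing down
  the pocket;
* a **constriction filter**: two six-atom nitrogen rings at reduced radius,
  at depths 7.4 and 8.2 Å — the band the ligand ring sweeps through during
  its descent, so they enter the search box exactly at the flagged steps;
* a **base site** of two three-fold acceptor rings that a ligand standing
  on the axis contacts at the optimum distance, making the base well
  clearly deeper than the niche; inert pincers pin the ring-plane azimuth
  of base poses so score-degenerate spins do not masquerade as pose
  changes;
* an inert **floor** below the base acceptors.

The passing ligand is a six-carbon aromatic ring with a short polar tail
(linker, two donors); the blocked ligand is identical plus three apolar
tail atoms beyond the tip. When the blocked ligand's tip contacts the base
acceptors its tail end penetrates the floor's clash shell, and tilted
approaches drive its ring into the constriction — so under the surrogate
potential it can engage the niche but never profitably reach the base. Wall
rings are split into two-atom residues so that bookkeeping residues stay
below any sensible candidate threshold, while the planted filter rings (six
atoms each) stand out. The emitted receptor is rigidly rotated and
translated by a seeded motion, so axis determination and frame alignment do
real work in every test.

Desk-scale study conditions used by the tests and the acceptance script:
5 repetitions per step, exhaustiveness 8, 3 poses per run, three seeds; the
geometry yields a 14-step scan, and the full two-ligand, three-seed pipeline
runs in about three minutes on one CPU. One analysis threshold differs from
the package default there: the change-detection RMSD is set to 2.0 Å
because the built-in search reproduces score-degenerate poses only to about
1.5 Å in the niche's flat tilt mode; a threshold below the search's
reproducibility radius reports sampling noise, not pose changes. Depth and
angle thresholds keep their defaults.

What passing these tests shows — and what it does not: the pipeline
recovers planted plateaus, transitions, filter residues and binder/
non-binder labels from a system whose ground truth is known. The toy system
has none of the messiness of real receptors: no conformational flexibility,
no solvent, no partial charges, a smooth potential, and planted sites that
are cleanly separated in energy. Results on real structures inherit all the
usual caveats of the external docking engine.

## Worked example

```{r example, eval = FALSE}
spec <- toy_pocket_spec(seed = 1)
toy  <- make_toy_pocket(spec)
ligs <- make_toy_ligands(spec)

ax   <- scan_axis(toy$receptor, toy$pocket)
al   <- align_to_axis(toy$receptor, ligs$passing, ax)
cfg  <- scan_config(repetitions = 5, exhaustiveness = 8, seed = 1)
plan <- build_scan(al$receptor, toy$pocket, cfg)

res  <- run_scan(al$receptor, al$ligand, plan, n_poses = 3)
traj <- best_pose_per_step(res)
m    <- step_metrics(traj, al$receptor, al$ligand,
                     toy$truth$ring_atoms, toy$niche)
f    <- flag_changes(m, traj, rmsd_tol = 2.0)
plot(traj, flags = f)

incl <- inclusion_table(al$receptor, plan, toy$pocket)
identify_filter(incl, f, toy$niche)
classify_ligand(m, f, base_depth = toy$truth$base_depth)
```

On the planted system this prints a niche plateau over the early steps
(depth about −0.4 Å, orientation near 90°, tail in niche), a single descent
transition around step 10 to a final plateau at depth ≈ 9.1 Å, the two
planted constriction residues as the only filter candidates, and a
binder-like classification; the blocked ligand stays at the mouth and is
labelled non-binder-like.

## Numerical choices and degenerate inputs

* Inertia is mass-weighted by element masses by default (unit-mass option
  provided); collinear structures are rejected.
* Alternate locations keep the highest-occupancy conformer (first on tie);
  waters are stripped on request; hydrogens are kept on parse but excluded
  from inclusion accounting by default.
* Closed-boundary box membership means face-contact atoms count; this can
  change new-atom counts by ±1 and is therefore fixed, documented
  behaviour rather than an option.
* A bottom reference already inside box 1 still yields a two-step scan; a
  bottom reference that never enters the box within ten pocket depths is
  reported as a misoriented axis.
* The pharmacophore labels of toy structures survive PDB round-trips via a
  `<file>.labels.tsv` sidecar, since the PDB format has no such field.
* Engine repetitions that fail are recorded and skipped; only a step with
  no surviving repetition aborts a scan.

## Limitations

The receptor is rigid throughout; side-chain flexibility is outside the
current scope. The built-in engine treats the ligand as rigid too —
torsional flexibility is delegated to the external engine. The classifier
is a two-criterion heuristic on a best-pose series; it does not estimate
affinities, and its thresholds should be re-examined for pockets whose
geometry differs substantially from a tube. Reproducing the published
TIR1/IAA/tryptophan results end to end requires the external engine, the
downloaded receptor structure and prepared ligands (see the README's
reproduction notes); the test suite deliberately covers the desk-scale
planted system instead.
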