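---
title: "Kinetic discrimination of docking decoys: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic discrimination of docking decoys: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(decoysieve)
```

## The problem

Rigid-body docking programs produce ranked lists of candidate poses
("decoys") for a protein--protein complex.  Scoring functions often
cannot tell a near-native pose from a well-packed but wrong one.  The
observation this package builds on is kinetic: on the binding
free-energy landscape, the correctly bound state sits at the bottom of a
basin confined by barriers, while most high-scoring decoys sit in
shallow or unconfined regions.  Run unbiased dynamics from each pose
and watch what happens:

* **unstable decoys** diffuse away from their starting structure;
* **metastable decoys** hold at room temperature but escape when the
  temperature is raised stepwise (the temperature ladder);
* the **near-native pose** stays put through the whole ladder;
* poses **inside the native funnel** drift *toward* the reference
  structure and bind, even when they start several Angstroms away.

Two independent trajectories that start from dissimilar poses and end in
nearly identical structures are strong evidence for a shared free-energy
minimum: this *funnel signature* identifies the best model even when no
experimental reference exists.

## The protocol

`assess_decoy()` runs the per-model classification.  Its inputs are a
trajectory, the starting pose, an optional reference structure, and an
`assessment_config()`:

| parameter | default | meaning |
|---|---|---|
| `drift_threshold` | 2.5 Å | sustained RMSD from the start that counts as escape |
| `native_band` | 1.4 Å | RMSD to the reference that counts as native |
| `dwell_frames` | 5 | consecutive frames required to sustain an event |
| `base_temperature` | 303 K | room-temperature segment |
| `ladder_step` | 30 K | rung increment |
| `max_temperature` | 390 K | top of the ladder |
| `ladder_dwell` | 12 ns | dwell per elevated rung |

Two presets mirror the two regimes the thresholds come from: `"g3"`
(2.5/1.4 Å, a very rigid complex) and `"efb"` (3.2/2.5 Å); an
`"efb_positive"` variant uses a 2.0 Å band for calling positives.
Escapes and binding events both require `dwell_frames` consecutive
frames, so single-frame spikes never count; this is the reproducible
analogue of reading events off smoothed RMSD traces.  A binding event is
an entry into the native band that persists -- brief excursions are
tolerated, but a sustained exit (`dwell_frames` frames out of band)
cancels the event and a later sustained re-entry is required.  A model
with a binding event is labelled `CONVERGED_TO_REFERENCE` and this
overrides the drift labels, because any pose that slides down the funnel
from a wrong start necessarily exceeds the drift threshold on the way.
`CONVERGED_TO_REFERENCE` additionally requires the final frame inside
the band, so the verdict's summary statistics are internally consistent.

All RMSDs are computed by `rmsd_series()`: each frame is superposed onto
the reference with the Kabsch algorithm over a *fit selection* and
measured over a *measure selection*.  The defaults fit on the receptor
chain's C-alpha atoms and measure over all C-alpha atoms, which anchors
the receptor frame and makes ligand drift visible.  Both selections are
explicit arguments, so a ligand-only reading is one flag away; outputs
record the selections used.  No mass weighting is applied.

Reference-free identification uses `pair_table()` +
`flag_funnel_signature()` + `nominate_best_model()`: all model pairs are
compared at the start and at the trajectory endpoints (final saved
frame; a tail-average is deliberately not the default), and a pair is
flagged when its endpoints are close (`final_rmsd <= native_band`) *and*
it moved substantially together (`delta_rmsd <= -2` Å).  The delta
cutoff separates genuinely converging pairs from stable near-duplicates
-- two copies of the same wrong pose show a low final RMSD but near-zero
change, the classic false positive.  The -2 Å default is our choice; the
flag is monotone in both cutoffs, so loosening never removes evidence.
Models are ranked by flagged-pair count, then mean final RMSD.

## The surrogate simulator

All-atom solvated MD of a docking cohort costs hundreds of GPU-days, so
the package ships a statistical surrogate that reproduces the *kinetic
phenotypes* the analysis consumes, not the physics that produces them.
The ligand is a rigid body (translation + unit quaternion) moving over a
designed free-energy landscape; the receptor is fixed.  Distances mix
translation and orientation through one metric,

$$ d(q_1, q_2)^2 = \lVert t_1 - t_2 \rVert^2 + (\lambda\,\theta)^2, $$

with $\theta$ the geodesic rotation angle and $\lambda = 10$ Å/rad so
that orientational offsets register in RMSD on the same scale as
translational ones for the ~8 Å ligand template.  The potential is a sum
of attractive Gaussian wells in this metric plus a quartic confinement
wall (stiffness 1 kcal mol$^{-1}$ Å$^{-4}$) that keeps unbound ligands
in a finite box.  Dynamics is overdamped (first-order) Langevin:

$$ t \leftarrow t - \frac{\Delta t}{\gamma_t}\nabla_t U
   + \sqrt{2 k_B T \Delta t / \gamma_t}\,\xi, $$

with the analogous body-frame rotation-vector update for the
orientation.  We chose first-order rather than inertial dynamics because
at desk scale only landscape exploration matters, and the overdamped
form makes two exact validation oracles available: the stationary
distribution is the Boltzmann density (checked against numerical
quadrature) and free diffusion obeys the Einstein relation
(slope $6 k_B T/\gamma_t$).  Energy conservation is *not* expected and
not tested.  All randomness flows through R's RNG, so a seed makes runs
bit-reproducible.

### Integration validity

Per step, both the deterministic drift *and* the thermal noise amplitude
(in the combined metric, so rotational noise counts as $\lambda\sigma$)
must stay below one fifth of the narrowest well's width; otherwise the
discrete update itself hops barriers and every well leaks regardless of
depth.  `simulate_trajectory()` validates this at the schedule's top
temperature and refuses to run with a too-coarse `dt`.  The defaults
(`dt` = 5e-4 ns, `gamma_t` = 0.3, `gamma_r` = 0.7) satisfy the bound for
all shipped landscapes with margin.

### The default landscape

A single Gaussian cannot be both the *stiff bound minimum* (the
reference trajectory should fluctuate around ~1 Å RMSD and survive
390 K) and the *broad basin* decoys slide down.  The default landscape
therefore superposes three ingredients (one extra well label, `funnel`,
beyond the native/trap vocabulary):

| well | depth (units of $k_B\,303$ K) | width (Å) | role |
|---|---|---|---|
| native (origin) | 28 | 2.5 | stiff bound minimum |
| funnel (co-centered) | 13 | 7 | long-range basin |
| 2 traps (32 Å, 33 Å away) | 19 | 1.7 | metastable decoy sites |

Depths are far larger than the naive "a few $k_BT$" because escape from
a well in this 6-degree-of-freedom metric has a very large Kramers
prefactor: narrow wells make attempt rates of order
$(\mathrm{width})^2/D \sim 10^{-1}$ ns, so a 6 $k_BT$ well evaporates in
well under a nanosecond.  The depths above were calibrated once, before
any acceptance checks were written, so that the four designed phenotypes
occur on the protocol's time scale: unstable poses drift past 2.5 Å
within a few ns at 303 K; traps hold 303 K for tens of ns but escape on
the upper rungs (measured 12 ns escape fractions ~0.04/0.12/0.42/0.50
at 303/333/363/390 K); funnel-interior poses bind during the run; the
native pose holds the entire ladder inside the native band.  Trap
centers sit beyond the funnel's capture range so that a decoy escaping a
trap at 390 K only rarely converts into a late binding event.

`make_benchmark_set()` plants decoys by class: `native` at the native
center plus jitter; `trap` at trap centers plus jitter; `unstable`
uniform over the flat region at least five widths from every well with
uniform random orientation; `funnel_interior` at 2--4 funnel widths from
the center with the offset split between translation (15--40%) and
orientation.  The orientation-dominant split encodes the docking
scenario the funnel class models -- an anchored but tilted pose that
pivots into place -- and matters kinetically: a pose that must *find*
the site translationally from far away is a different (and much slower)
experiment than one already anchored in the basin.

### The ladder schedule

`ladder_schedule()` defaults to 32 ns at 303 K, then 12 ns rungs at 333
and 363 K and 20 ns at 390 K, i.e. 30 K increments with a longer top
rung -- the escalating-temperature protocol the assessment expects.
Frame spacing defaults to 0.1 ns (200 steps); it is a free parameter
because saving intervals are conventions of the trajectory source, not
of the analysis.

## What the synthetic data does and does not show

The generator reproduces the statistical structure the analysis assumes:
diffusive drift, thermally activated escape with Arrhenius temperature
dependence, down-funnel convergence, and rigid-body rendering into
coordinates so the whole pipeline runs through its public file formats.
It does **not** contain solvent, atomistic forces, internal flexibility,
electrostatics, or realistic absolute time scales (its nanoseconds are
effective units; the calibrated diffusion constant is orders of
magnitude faster than a solvated protein's, precisely so that desk-scale
runs traverse the same event sequence as ~100 ns all-atom MD).  Passing
the shipped checks therefore validates the *analysis logic and the
simulator's statistical mechanics*, not any claim about a real complex.
Real trajectories also break rigid-body assumptions (partial unfolding
at 390 K is a known failure mode of harsh ladders) -- the package
analyses whatever coordinates it is given and cannot detect unfolding.

## Numerical choices

* Kabsch superposition via SVD with the determinant sign correction;
  degenerate (collinear) inputs are errors, not best-effort fits.
* Quaternions are scalar-first, canonicalized to non-negative scalar
  part; geodesic angles use $2\arccos(\lvert q_1\cdot q_2\rvert)$ so the
  double cover collapses.
* Atom correspondence between differently ordered topologies is by
  (chain, resid, name) triple; partial overlap is an error, never a
  silent intersection.
* Pair-table ties (equal final RMSD) break lexicographically on model
  ids; nomination ties on flagged-pair count break on mean final RMSD.
* `temperature_at()` is right-continuous; the escape temperature of an
  event at a segment boundary is the segment being entered.
* Escape/binding dwell filtering uses run-length encoding over the
  (strictly thresholded) in/out indicator; series shorter than
  `dwell_frames` are errors.

## Problem sizes used in the shipped checks

The validation suite runs entirely on synthetic data generated at test
time: superposition oracles on 50 random pairs of up to 8 atoms,
stationary-distribution checks on a $10^6$-step single-well run,
diffusion checks on 10 replicates of 10 ns, ladder physics on 50
replicates per rung, and label recovery/nomination on 20 seeded
benchmarks of 10 decoys (1 native, 2 funnel-interior, 3 trap, 4
unstable) under the full 76 ns ladder.  The same computations, re-seeded
from the command line, are what `scripts/acceptance.R` reports.

## Known limitations

* The funnel class's recovery rate (~0.9) is the binding race between
  rotational alignment and translational wander; benchmarks drawn with
  other seeds fluctuate by a few percent around it.
* A trap decoy that escapes at 390 K and then finds the funnel late is
  labelled `CONVERGED_TO_REFERENCE` -- a "wrong" label against the
  planted truth, but arguably the physically correct verdict.
* The confinement wall makes the unbound state artificially recurrent;
  binding fractions from unstable starts are therefore upper bounds on
  the unconfined analogue.
* No free-energy estimation is attempted anywhere: every output is a
  kinetic classification.
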