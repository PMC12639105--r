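---
title: "A potential-switching coarse-grained model of ring-motor translocation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A potential-switching coarse-grained model of ring-motor translocation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`ringmotor` simulates a hexameric ring motor (the replicative helicase
architecture: six AAA+ subunits around a central channel) translocating
3'→5' along single-stranded DNA, unwinding duplex DNA at a replication
fork, and colliding with a nucleosome. The motor is driven by *potential
switching*: the system cycles through four DNA-binding states, and at each
switch the state-dependent part of the energy function is replaced abruptly
while the dynamics continue. Everything else — electrostatics, excluded
volume, base pairing, stacking, nucleosome contacts — is always on and
never changes across switches.

Each state engages four of the six subunits (labelled 2–7 in the Mcm
convention, ring adjacency 5-3-7-4-6-2):

| state | engaged subunits | registry offset (nt) |
|-------|------------------|----------------------|
| 1     | 2, 3, 5, 6       | 0                    |
| 2     | 2, 3, 5, 7       | 1                    |
| 3     | 3, 4, 6, 7       | 7                    |
| 4     | 7, 4, 6, 2       | 9                    |

An engaged subunit grips two consecutive nucleotides through its pore-loop
bead. The per-subunit grip ranks are chosen so that every transition of the
forward cycle 1→2→3→4→1 moves each *shared* subunit's loop down the channel
by exactly the printed step size (1, 6, 2 and 3 nt respectively; 12 nt per
full cycle), while the 3-state shortcut 3→1 leaves subunits 3 and 6 in
conflict: subunit 6's grip implies a +5 nt forward resolution, subunit 3's
a −7 nt backward one. Which subunit keeps its grip is decided by the
dynamics, not scripted — this is the asymmetric hand-over-hand mechanism
and its stochastic idling branch. The registry tables are one consistent
solution to the printed step sizes; the per-subunit nucleotide registers
are not uniquely determined by them (the closure constraints fix only the
differences), and the same staircase polarity is assumed in all four
states.

## How translocation emerges

Three ingredients make directional stepping an outcome rather than an
input:

1. **Switchable hydrogen-bond wells.** Each engaged loop carries two
   Gaussian wells (depth `eps_hb` = 40 kBT, width 0.5 lu) that bind
   tracked-strand phosphates as *dynamic bonds*: a well binds the nearest
   eligible phosphate, holds that partner while strained, breaks beyond
   `r0 + 3σ`, and then re-binds the nearest free phosphate after a
   refractory release of 2000 steps. Partners are exclusive (no two wells
   share a phosphate). Sliding is therefore possible but costs breaking
   work, and grip identity persists across switches — which is exactly what
   lets an anchor subunit drag DNA while others release and re-capture.

2. **Slow loop conformations.** A switch abruptly replaces each loop's
   position target (a capped-force harmonic restraint: harmonic within
   0.5 lu, constant pull of `k_native × dcap` = 20 kBT/lu beyond). The loop
   beads carry a large effective mass (they stand in for whole subunit
   domains), so they creep to their new staircase positions over a few
   thousand steps, escorting their gripped phosphates, instead of snapping
   there and shearing their bonds off.

3. **Contact maturation.** A freshly engaged well is inert for 4000 steps
   and then ramps to full depth over a further 4000 ("contacts form as the
   new conformation relaxes"). Without this, newly engaged subunits pin the
   old registry and jam the escort; with it, holders lock the registry only
   after the coordinated drag has finished, and they are mature by the next
   switch, when they may themselves become anchors.

Under the 4-state cycle every transition's shared subunits agree on the
drag direction, and all replicates translocate forward with steps close to
1, 6, 2, 3 nt. Under the 3-state cycle the 3→1 transition is a genuine
tug-of-war; runs split between forward resolutions and idling cycles whose
3→1 step is close to −(1+6) nt, with the anchor identity (subunit 6
forward, subunit 3 backward) read off the trajectories by
`anchor_identity()`.

### Known limitation: partial 3→1 resolutions

In the toy system the 3→1 tug frequently resolves by *both* anchors
yielding partway (each loses its grip while strained near the leash limit),
which truncates the forward branch's 3→1 step to about +2–3 nt instead of
the ideal +5 and leaves forward-classified cycle totals around 9–10 nt
rather than 12. The idling branch reaches about −5 to −6 nt. The 4-state
cycle, the controls, the step asymmetry, the anchor statistics and the
fork coupling are quantitatively in line with the full-scale reference
behaviour; the under-completion of the conflicted transition is the main
known gap of the desk-scale stand-in and is discussed in the README's
reproduction notes.

## Force field and units

Reduced units: length in bead diameters (1 lu ≈ 5 Å, so the 10 Å clogging
threshold is 2 lu), energy in kBT at 300 K. The timestep 0.1 and friction
0.843 are dimensionless Langevin parameters; the model reports steps, not
physical time (the physical mapping of coarse-grained time is not
well-defined). DNA uses three beads per nucleotide (phosphate, sugar,
base). Key terms and defaults (every value is an `ff_params()` key and a
config key):

* Backbone: harmonic bonds (k = 50) with rest length 0.58 lu; cosine
  bending with k = 2 (ssDNA, persistence a few nt) or 30 within duplex
  regions (B-form rod).
* ssDNA rise in the channel 0.7 lu/nt; duplex rise 1.1 lu/bp (strain-free
  for the stiff straight duplex).
* Base pairing: Morse wells, depth 8 (A·T) and 16 (G·C) kBT, width
  α = 4 lu⁻¹; a pair is flagged broken at the distance where the well
  retains 5% of its depth (`bp_break_distance()`). The GC/AT depth ratio
  and the absolute scale are calibrated so duplexes are stable at
  temperature 1 while the motor's drive (about 20 kBT/lu per anchor) can
  unwind A·T pairs more easily than G·C ones.
* Electrostatics: Debye–Hückel at 0.3 M monovalent salt, dielectric 72.2,
  T = 300 K; phosphate charge −0.6 e for intra-DNA pairs and −1.0 e for
  protein–DNA pairs (counterion release on binding); cutoff at five Debye
  lengths with energy shift.
* Excluded volume: truncated-shifted r⁻¹² with a linearised core below
  0.85 σ, so deep thermal overlaps stay integrable at the chosen timestep;
  per-bead strengths combine geometrically, with the ring wall and the
  nucleosome core moderately harder (`eps_ev_wall`) than the polymers.
* Pore geometry: lining radius 1.2 lu — single-stranded DNA passes on the
  axis, duplex DNA cannot enter, and two strand segments cannot sit side
  by side inside the channel (which also forbids strand fold-backs inside
  the pore).

## The switching engine

BAOAB Langevin integration runs in compiled code; the scheduler alternates
`interval`-step segments with potential switches. The toy default interval
is 12 000 steps: it was chosen as the smallest interval at which the
post-switch displacement and energy reach a plateau before the next switch
(the relaxation slope test in the engine test suite); the escort phase of
the largest (6 nt) transition takes roughly 4000–6000 steps. Velocities are
drawn from Maxwell–Boltzmann at assembly only and carried across switches;
coordinates and velocities are untouched at the switch instant. The
timestep halves automatically (and is logged) if any force would move a
bead catastrophically far; in production runs this does not trigger.

Determinism: all randomness is derived from explicit integer seeds (an
internal SplitMix64 stream in the integrator, R's RNG for sequence and
placement), so identical scenario + protocol + seed reproduce trajectories
bitwise.

## What the generator emulates — and what it does not

The synthetic-topology module stands in for cryo-EM-derived models: a rigid
six-subunit ring with one mobile pore loop per subunit, four reference
states with the engaged sets and printed step sizes above, a Y-fork with
the subunit-3 loop 7 nt from the junction, a 14-site nucleosome (half-
integer superhelical locations −6.5…+6.5, 10 bp per SHL unit, graded well
depths: 4 kBT at the outer sites, 8 at ±4.5, 10 inward, so the entry sites
breathe thermally while the inner turn stays wrapped), and simplified
factor bodies (RPA tiling the lagging strand with a configurable footprint;
a fork-protection-complex body whose positive patch grips the parental
duplex electrostatically and can be switched off; inert Ctf4/Mrc1
placeholders; FACT as a tethered domain with an acidic tail that occupies
the exposed H2A/H2B patch). Passing tests on these structures show that the
*mechanism* — switching-driven, anchor-mediated, sequence-sensitive
translocation — is reproduced; they do not show sequence-specific
nucleosome energetics, real protein flexibility, or atomistic contact
geometry, all of which are deliberately out of scope.

Toy scale is the default everywhere: 60-nt ssDNA with the ring at
nucleotide 30, fork arms of 16/8/8 bp with 12/18 nt single-stranded
regions, 6–20 replicates per condition in the test and acceptance runs.
Full-scale geometry (495-nt ssDNA, 168/113/285 bp fork arms) remains
constructible behind the registry's `scale = "full"` flag but is excluded
from routine testing.

## Numerical and design choices

* **Displacement metric.** Displacement is the index of the nucleotide
  whose phosphate currently occupies the subunit-3 loop's State-1 home
  site — a fixed point in the ring frame — with hysteretic tie-breaking
  (0.3 lu) against chatter at half-integer crossings. A loop-attached
  reference would conflate the loop's own staircase sweep with DNA motion;
  the fixed-site definition measures registry advance, which is what the
  printed per-transition steps describe.
* **Step sizes** are measured on segment-tail means (last 10% of each
  segment) to suppress post-switch transients; steps telescope exactly to
  the net displacement by construction.
* **Clogging** is the per-frame minimum distance between lagging-strand
  backbone beads (the single-stranded arm plus any newly unpaired parental
  nucleotides) and the channel interior below the pore mouth; the threshold
  is the 10 Å equivalent (2 lu).
* **Unwrapping extent** requires contiguity from the nucleosome entry end;
  transient inner bubbles are not counted. A fully wrapped nucleosome
  reports the sentinel −7.
* **Degenerate inputs**: all-tied groups in the Wilcoxon–Mann–Whitney
  comparison return p = 0.5 and d = 0, flagged; zero-variance coupling
  correlations return NA with a warning; assemblies with steric clashes
  (minimum inter-body distance below 0.8 × the radius sum) refuse to build.
* The distal parental terminus carries a positional anchor (k = 3 per
  bead) standing in for the megabase of chromatin beyond the toy substrate;
  without it the short parental stub can ride down beside the ring instead
  of being unwound. Displacement metrics are relative and unaffected.
* RPA wells on the lagging strand are deliberately strong (6 kBT per
  nucleotide across a body) so occupancy persists for entire runs,
  mirroring the scaled single-stranded-binding affinity of the reference
  model.

## Worked example

```{r example}
library(ringmotor)

asm <- build_ssdna_scenario(n_nt = 60, ring_position_nt = 30, seed = 1)
asm <- relax(asm, seed = 1)
traj <- run_protocol(asm, switch_protocol(c(1, 2, 3, 4)), seed = 1)
per_transition_steps(traj)

reg <- experiment_registry()
res <- run_experiment(reg$ss_4state, n_replicates = 5)
res$aggregate
```

## Reproducing the study numbers

`scripts/acceptance.R` re-runs the four ssDNA switching schemes (20
replicates each) and the three fork sequence conditions from scratch and
writes the per-transition means, cycle totals, control outcomes and the
displacement/unwinding correlation as JSON. See the README for the exact
invocation.
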