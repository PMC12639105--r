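# ringmotor

Coarse-grained, potential-switching Langevin simulation of a hexameric
ring-motor helicase: 3'→5' translocation along ssDNA by an asymmetric
hand-over-hand mechanism, duplex unwinding at a replication fork, and
nucleosome navigation, together with the trajectory metrics that
characterise them.

## Who this is for

Structural/computational biologists who want a desk-scale, fully seeded
reimplementation of the switching-motor simulation methodology: a toy
hexameric ring whose four DNA-binding states (engaged subunit sets
{2,3,5,6}, {2,3,5,7}, {3,4,6,7}, {7,4,6,2} in the Mcm numbering) are cycled
by abruptly replacing the state-dependent potentials — loop–phosphate
hydrogen-bond wells and loop conformational targets — while electrostatics,
excluded volume and base pairing stay fixed.

## The model in brief

In state *s*, four pore loops grip eight consecutive nucleotides of the
tracked strand in a spiral staircase; the registry offsets along the cycle
are Δ = {0, 1, 7, 9} nt, fixed by the printed per-transition step sizes

* 1→2: 1 nt, 2→3: 6 nt, 3→4: 2 nt, 4→1: 3 nt (4-state cycle, 12 nt total)
* 3→1 shortcut: +5 nt when subunit 6 anchors, −7 nt when subunit 3 anchors

Each step equals the axial travel of the subunit that keeps its grip
through the switch; whether it keeps it is decided by the Langevin dynamics
of dynamic-bond wells (bind nearest, hold under strain, break, release,
re-bind), not by a script. The observable is the index of the nucleotide at
a fixed ring-frame reference site (the subunit-3 loop's State-1 position),
in nucleotides, positive toward 5'.

Scenario generators build the ring, ssDNA, a Y-fork (subunit-3 loop 7 nt
from the junction; AT/GC-graded Morse base pairing), a 14-contact-site
nucleosome (half-integer superhelical locations, fork junction 22 bp
upstream of a chosen SHL) and simplified RPA / fork-protection-complex /
Ctf4 / Mrc1 / FACT bodies. Everything is generated in code from seeds; no
external data.

## Worked example

```r
library(ringmotor)

asm  <- build_ssdna_scenario(n_nt = 60, ring_position_nt = 30, seed = 1)
asm  <- relax(asm, seed = 1)
traj <- run_protocol(asm, switch_protocol(c(1, 2, 3, 4)), seed = 1)
per_transition_steps(traj)
#>   from_state to_state step_size anchor_subunit
#> 1          1        2         1              2
#> 2          2        3         6              3
#> 3          3        4         2              4
#> 4          4        1         2              2
#> attr net_displacement: 11, outcome: "forward"
```

One 4-state switching cycle moves the motor ~11–12 nt toward 5' in four
unequal steps; the `anchor_subunit` column names the subunit whose
loop–phosphate grip persisted through each switch. A 3-state protocol
(`switch_protocol(c(1, 2, 3))`) splits stochastically between forward runs
and idling runs whose 3→1 transition steps backward.

Higher-level drivers: `experiment_registry()` holds every named, seeded
study condition (`ss_3state`, `ss_4state`, `ss_reversed`,
`ss_control_conformation_only`, the two-state scan, `fork_*` sequence and
factor conditions, `nuc_shl*` collisions); `run_experiment()` runs the
replicates and aggregates outcome counts, per-transition means, unwinding,
clogging and unwrapping summaries; `compare_experiments()` applies the
one-tailed Wilcoxon–Mann–Whitney test with Cohen's d.

A command-line wrapper is installed as `exec/ringmotor`
(`ringmotor experiment ss_4state --replicates 5 --outdir out`).

## Package layout

* `R/topology_*.R`, `R/scenarios*.R`, `R/factors.R` — synthetic structure
  generators
* `R/energetics.R`, `src/core.cpp` — force field and BAOAB integrator
* `R/engine.R` — relaxation, switching scheduler, trajectories
* `R/metrics.R` — displacement, step tables, unwinding, clogging,
  unwrapping, capture, contact probabilities, densities, statistics
* `R/experiments.R` — seeded registry and replicate aggregation
* `R/io.R`, `R/cli.R` — config, PDB/CSV/JSON/OpenDX writers, CLI
* `vignettes/potential-switching-motor.Rmd` — the model, its parameters,
  and the reasoning behind the numerical choices
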