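---
title: "Evolved solutions, exhaustive semantics, and the reliability gap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolved solutions, exhaustive semantics, and the reliability gap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evoreliab)
```

# The question

Evolutionary search routinely delivers solutions that are perfect on the
task they were selected for and opaque everywhere else.  This package
implements two classical experiments that make the phenomenon measurable:

1. **Genetic programming of a wall-following robot.**  Boolean control
   programs over 12 named variables are evolved until the robot, dropped
   anywhere in a closed grid labyrinth, finds the wall and follows it all
   the way round.
2. **Size-penalized neuroevolution of logic gates.**  Populations of
   trained one-hidden-layer networks evolve under the fitness
   $F_\lambda = Q(G) - \lambda\,\sigma(G)$, which trades task performance
   $Q$ against network size $\sigma$, toward minimal AND and XOR
   implementations.

The connecting instrument is an exhaustive semantic test: a control
program is a boolean function of 12 variables, so its entire semantics is
a **truth vector** of $2^{12} = 4096$ bits.  Programs that solve the
training task equally perfectly can still differ on a large fraction of
those states.  On the three champion programs packaged here (transcribed
from their published rendering; see *Fixtures* below) the counts are
1,216 disagreements between the second and third and more than 2,000
between the first and each of the others; champions evolved by this
package's own GP engine are individually verified perfect on their
labyrinth and likewise disagree pairwise.  Outside the world they were
selected in, champions are not interchangeable.

# The boolean program dialect

Programs use `If[c, t, f]`, `&&`, `||`, `!`, `True`, `False` and the 12
variables: eight space-fixed wall sensors (`n`, `ne`, `e`, `se`, `s`,
`sw`, `w`, `nw` — each true when the adjacent cell in that compass
direction is wall) and four candidate-move indicators (`north`, `east`,
`south`, `west`).  `!` binds tighter than `&&`, which binds tighter than
`||`; both binary operators associate left; the evaluator is a full
recursion (no short-circuit semantics are observable: expressions are
pure).

The canonical enumeration order fixes assignment $i$ ($i = 0,\dots,4095$)
as the 12-bit binary expansion of $i$ with `n` as the most significant
bit and `west` the least.  Disagreement counts are invariant to this
order; fixing it makes truth vectors exchangeable between implementations
and is what `write_truth_vector()` records in its header.

```{r}
sols <- printed_solutions()
disagreement_matrix(sols)$matrix
```

# Controller semantics

The published experiment treats a program as boolean-valued, yet the robot
needs one of four moves.  The package reconciles the two with
**candidate-move interrogation**: for each direction in the fixed priority
order north, east, south, west, the program is evaluated on the 8 sensor
bits plus a one-hot indicator on that direction's variable; the first
direction answered `True` is taken, otherwise the robot stays.  This is a
reconstruction — the published account does not say how the four
non-sensor variables enter evaluation during control.  The alternative
(that they encode the previous move) cannot be excluded from the text; we
chose interrogation because it makes a single boolean function a complete
controller and uses exactly the 12-variable state space the exhaustive
test enumerates.  The choice does not affect the disagreement counts
above, which compare programs as raw boolean functions.

Movement physics, fixed before any experiment: (row, column) coordinates
with north decreasing the row; blocked or off-grid moves are no-ops that
still consume a step; the robot "visits" a wall cell by standing
8-adjacent to it, and fitness is the count of distinct wall cells visited
during a journey of fixed length.  A program is **perfect** when from
every free starting cell it covers every wall cell touching the free
region within a budget of four times the wall-cell count (comfortably
more than one perimeter lap).

# The GP experiment

`evolve_gp()` runs the generational loop: fitness-proportionate
("wheel-of-fortune") parental choice, subtree crossover (uniform node
choice), subtree-replacement mutation, elitism, and a verified-perfection
stopping rule.  Defaults, and why:

| parameter | default | rationale |
|---|---|---|
| population | 200 | large enough to find perfect followers on the 12×12 labyrinth in most seeds; small enough for minutes-per-run |
| generations cap | 500 | runs that succeed typically do so far earlier |
| crossover / mutation prob. | 0.9 / 0.25 | crossover-dominated search; the generous mutation rate keeps progress alive late in runs, when proportional selection has little fitness spread left |
| primitive bias (IF, AND, OR, NOT vs terminal) | 4:4:4:2:2 | biased toward function symbols so random programs have computational depth; exact weights are a free choice |
| initial depth | ramped 2–6 | standard mix of shallow and deep initial trees |
| tree-size cap | 120 nodes | ≈3× the packaged reference follower; without a tight cap runs bloat into slow, stagnant populations |
| journey length / starts | 150 steps, 10 frozen random starts | 150 exceeds the labyrinth's free-cell count, so a journey realises the controller's full reachable coverage; freezing the starts per run makes fitness deterministic and runs reproducible |

Fitness evaluation is exact and fast because the world is static: each
free cell's sensor state is precomputed, a program is compiled once per
evaluation into a 256-entry move table (bit-packed evaluation of all
sensor × direction combinations), and the induced successor map makes a
journey a deterministic orbit: coverage for *every* starting cell at once
is computed exactly by pointer doubling over the successor map with
packed wall-cell bitsets.  The table-driven path is tested against the
naive step-by-step simulator.

A hand-written reference wall-follower ships as a program fixture: it
circulates clockwise around any wall it touches and marches north through
open space.  It is the engine-level oracle (known-perfect, known full
coverage) and proof that the search space contains compact perfect
solutions (53 nodes).

# The neuroevolution experiment

Networks have 2 inputs, 30 hidden units and one output; neurons have zero
intrinsic threshold, with thresholds realised as bias connections whose
inputs are clamped to 1, and all connections (biases included) count in
the size measure $\sigma$ = nonzero connections / $(4H + 1)$.  The
training nonlinearity is a plain sigmoid (the published account fixes
thresholds-as-biases but not the activation); predictions binarize at
0.5.  $Q = 1 - \mathrm{MSE}$ over the four truth-table rows keeps the
selection wheel informative before any member is exact; exactness is
checked separately by binarization.

Each generation every member is trained by batch gradient descent with
its architecture fixed (gradients of pruned connections are masked), then
rated by $F_\lambda$; parents are drawn by a wheel of fortune on
$F - \min F + \varepsilon$ (since $F$ can be negative), recombined by a
single cut of the flattened genome (input→hidden weights column-major by
hidden unit, then hidden biases, then hidden→output weights, then the
output bias), mutated (each live weight perturbed with probability 0.3 by
Gaussian noise of SD 0.4) and pruned (|w| < 0.1 set to exactly zero).
Population 20, 25 generations, 60 epochs per generation at rate 2:
training is cumulative across generations, so every member sees some
1,500 gradient steps over a run — ample for convergence on four-pattern
tasks — while a full study (two gates × four λ values × ten seeds) stays
in the minutes range.  The prune magnitude and mutation scale were chosen
by watching σ trajectories: 0.05 pruned too little for mutation noise of
useful size, 0.1 with SD-0.4 mutation makes pruning an effective
sparsification channel without destroying exact members (a damaged
offspring retrains or is outcompeted).

The champion of a run is the highest-$F$ member *that exactly implements
the gate*; if none appears, the best non-exact member is returned,
flagged.  Minimality is asserted relatively, not absolutely: the exact
minimal topologies cannot be recovered from the published figures, so the
tests check that median champion σ decreases along
$\lambda \in \{0, 0.05, 0.1, 0.2\}$ (Spearman trend over 40 runs per
gate), that XOR champions always keep ≥ 2 active hidden units (XOR is not
linearly separable, and without input→output shortcuts one hidden unit
yields only $h$, $\neg h$ or a constant), and that under size pressure
AND champions are usually no larger than XOR champions.  An optional
weight-decay term during learning (the "cost applied directly on the
learning" variant) is deliberately not implemented; pruning plus
selection is the only sparsification channel, which keeps the two
experiments' mechanisms cleanly separated.

# Fixtures and the Sol1 transcription

The three champion programs are packaged as frozen text fixtures
(checksummed in the test suite; any edit fails until the anchors are
re-verified).  Sol2 and Sol3 are printed twice in the source; one copy
each is kept.  Sol1's printed form ends with a dangling `", ||south"`
after its closing parenthesis.  Two bracket-balanced readings exist:

* **drop the fragment** (adopted): Sol1 ends at `...]]&&south&&e)`;
  disagreements with Sol2/Sol3 are 2,328 and 2,312 — both above 2,000,
  matching the counts reported alongside the programs;
* **attach `||south` as a top-level disjunct** (shipped for audit as
  `sol1_alt_disjunct.txt`): disagreements become 2,000 and 1,568,
  contradicting the reported "more than 2,000" for both pairs.

Since the reported counts function as a checksum on the transcription,
the package adopts the first reading; the verbatim printed string is kept
in `sol1_raw.txt` so the judgment can be audited.  The Sol2–Sol3 count of
1,216 is unaffected by this choice, and both Sol1 readings are exposed
via `printed_solutions(alt_sol1 =)`.

One consequence of working from transcriptions: the printed champions
are *compared* as boolean functions but not *re-certified* as
wall-followers — their original maze and the exact convention coupling
boolean output to moves are not recoverable, and under this package's
reconstructed physics they behave as ordinary imperfect controllers on
the fixture maze.  The perfect-yet-non-equivalent dissociation is
therefore demonstrated on champions this package evolves itself (each
verified with `is_perfect()` before comparison).

The reference labyrinths are representative, not reproductions (the
published maze geometry is not recoverable): a 12×12 closed ring with an
internal spur (47 wall cells, 97 free cells, every wall cell reachable),
and a C-shaped open wall inside a free apron.  `random_world()` provides
seeded random maps with a guaranteed wall seed and a connected free
region (non-largest free components are converted to wall, so realised
wall density can exceed the nominal rate).

# What the synthetic worlds do and do not show

The generator and fixtures emulate the *structure* of the study —
discrete space-fixed sensing, deterministic physics, exhaustive
enumerability — not any empirical robot.  Passing tests therefore show
that the evolutionary dynamics and the semantic dissociation behave as
described under these idealised conditions; they say nothing about noisy
sensors, continuous space, or labyrinths larger than the fixtures.  Two
further caveats: perfection is verified on the training labyrinth only —
the open labyrinth exists precisely to exhibit the regime where behaviour
is *not* pinned down by training; and because GP runs are stochastic, the
test suite asserts success in a majority of seeds, not in every seed.

# Numerical and degenerate-input conventions

* Truth vectors are exact logical computations; no tolerances anywhere in
  the equivalence machinery.
* Roulette selection falls back to uniform when total fitness is 0 (GP)
  and shifts $F$ by $-\min F + 10^{-6}$ (networks); an empty population
  is an error.
* Blocked moves are no-ops; a journey of length 0 is a single-state
  trajectory; `If` requires exactly three arguments and parse errors name
  a character position.
* Offspring exceeding the GP size cap revert to their first parent;
  network crossover requires identical architectures.
* Training raises an error on non-finite activations (divergent learning
  rate) rather than silently continuing.

# Reproducibility

Every stochastic routine consumes R's global RNG and every run-level
entry point (`evolve_gp()`, `evolve_networks()`, `run_full_pipeline()`)
seeds it from its config, so identical configs give byte-identical
champions, histories and reports.  The analysis scripts under `analysis/`
re-run the whole study at the sizes quoted above and write their tables
under `results/`.
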