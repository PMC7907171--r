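# evoreliab

Evolutionary search happily produces solutions that are perfect on the task
they were selected for and unconstrained everywhere else.  `evoreliab`
implements two classical experiments that make this measurable, plus the
exhaustive semantic test that connects them:

* **Genetic programming of a wall-follower.**  Boolean control programs
  over 12 named variables — eight space-fixed wall sensors (`n`, `ne`,
  `e`, `se`, `s`, `sw`, `w`, `nw`) and four candidate-move indicators
  (`north`, `east`, `south`, `west`) — are evolved with
  fitness-proportionate selection, subtree crossover and mutation until
  the robot, dropped on any free cell of a closed grid labyrinth, reaches
  the wall and follows it all the way round.
* **Size-penalized neuroevolution of logic gates.**  Populations of
  trained one-hidden-layer networks (2 inputs, 30 hidden units, 1 output,
  thresholds as bias connections) evolve under
  *F*<sub>λ</sub> = *Q*(*G*) − λσ(*G*), where *Q* = 1 − MSE on the gate's
  truth table and σ is the fraction of unpruned connections: λ = 0
  tolerates fully connected solutions, larger λ drives the population
  toward the sparsest networks that still implement AND or XOR exactly.
* **Exhaustive equivalence.**  A control program is a boolean function of
  12 variables, so its whole semantics is a *truth vector* over
  2^12 = 4096 assignments; `disagreement_count()` and
  `disagreement_matrix()` count the states on which two programs differ.
  Zero disagreement = semantic equivalence (De Morgan-style rewriting
  cannot distinguish the programs); anything else quantifies how much of
  a program's behaviour the training task never pinned down.

The package ships transcriptions of three published champion programs
(Sol1–Sol3) as frozen text fixtures.  All three were reported as
flawless wall-followers in the world they were evolved in, yet Sol2 and
Sol3 disagree on 1,216 of the 4,096 states, and Sol1 disagrees with
each of them on more than 2,000 — outside the task that selected them,
the champions are three different functions.  The same dissociation is
re-derived from scratch: champions this package evolves on its own
labyrinth are individually verified perfect from every starting cell
and still disagree pairwise on over a thousand states.

## Worked example

```r
library(evoreliab)

sols <- printed_solutions()
disagreement_matrix(sols)
#> <reliability_report> 3 programs, pairwise disagreements out of 4096 states:
#>      sol1 sol2 sol3
#> sol1    0 2328 2312
#> sol2 2328    0 1216
#> sol3 2312 1216    0
```

1,216 disagreements is 29.7% of the state space, between two programs
that solved the same task equally perfectly.  (The published maze and
the exact convention coupling a program's boolean output to moves are
not recoverable, so the printed trio is compared semantically; the
perfect-yet-different dissociation is verified directly on this
package's own evolved champions, below.)

```r
r0 <- evolve_networks(evo_config(lambda = 0,   seed = 1), gate_truth_tables()$xor)
r1 <- evolve_networks(evo_config(lambda = 0.1, seed = 1), gate_truth_tables()$xor)
#> lambda=0.0: exact=TRUE sigma=0.711 (86 of 121 connections)
#> lambda=0.1: exact=TRUE sigma=0.554 (67 of 121 connections)
```

Both champions implement XOR exactly on all four truth-table rows; the
penalized run buys the same behaviour with 19 fewer connections.

To evolve a wall-follower from scratch:

```r
world <- reference_labyrinths()$closed
run <- evolve_gp(gp_config(seed = 2), world)
run$perfect        # TRUE: full wall coverage from every free start
run$champion       # an opaque boolean program, typically ~100 nodes
```

Champions evolved under different seeds all pass `is_perfect()` on the
training labyrinth, yet `disagreement_matrix()` over them is strictly
positive off the diagonal — behavioural identity on the task, semantic
non-equivalence off it.

## Repository layout

* `R/`, `inst/extdata/` — the package: boolean-program grammar and
  evaluator, grid world and robot physics, GP engine, neuroevolution
  engine, reliability analysis, and the frozen fixtures (program
  transcriptions, labyrinth maps, a hand-written reference
  wall-follower).
* `analysis/01_printed_solutions.R` … `04_full_report.R` — numbered
  drivers that run the study at its reported sizes and write tables
  under `results/`.
* `vignettes/evolved-solution-reliability.Rmd` — the methods vignette:
  model, parameters, design decisions, limitations.

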