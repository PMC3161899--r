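---
title: "Hill-climbing evolutionary search on the 2D HP lattice: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hill-climbing evolutionary search on the 2D HP lattice: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

The hydrophobic–polar (HP) model reduces a protein to a chain of two residue
classes, H (hydrophobic) and P (polar), embedded as a self-avoiding walk on
the square lattice. Two residues are *topological neighbours* when they sit
on adjacent lattice points (horizontally or vertically) without being
consecutive in the chain; every H–H topological contact contributes −1 to
the energy and all other contacts contribute nothing. The native structure
is taken to be the conformation of minimum energy, i.e. maximum H–H contact
count. Even in this abstraction the minimisation problem is NP-hard, which
is why stochastic search is the tool of choice.

A conformation is encoded with absolute moves: a chromosome of $n-1$
symbols over $\{L, U, R, D\}$, each giving the lattice displacement of a
residue from its predecessor ($L=(-1,0)$, $R=(+1,0)$, $U=(0,+1)$,
$D=(0,-1)$), with residue 1 anchored at the origin. Decoding never fails:
a colliding walk is returned flagged invalid, because the crossover repair
needs to inspect partial walks. The fitness of an individual is exactly its
energy.

```{r}
library(hpfold)
s <- hp_sequence("HHHPHPPPPPH")
hp_energy(s, "RRUURURDDD")
hp_energy(s, "RULURURDDD")
```

## The pull move

The mutation primitive is the pull move. At residue $i$ with coordinates
$(x_i, y_i)$, let $L$ be a free point diagonally adjacent to residue $i$
and orthogonally adjacent to residue $i+1$, and let $C$ be the fourth
corner of the square formed by $L$, $(x_i,y_i)$ and $(x_{i+1},y_{i+1})$.
The move is legal when $C$ is free or already holds residue $i-1$. In the
latter case only residue $i$ hops to $L$; in the former, residue $i$ moves
to $L$, residue $i-1$ to $C$, and residues $i-2$ down to 1 are dragged two
places up the chain, each step stopping as soon as connectivity is
restored. The termini get degenerate *end moves*: residue 1 (or $n$) may
hop to any free point diagonal to it and adjacent to its only neighbour,
with no corner condition and no dragging. When a position admits two
candidate $L$ locations the steepest-ascent operator evaluates both and
keeps the better, rather than sampling one — the neighbourhood is treated
as "at least $n$ chromosomes", in keeping with the steepest-ascent intent.

```{r}
enumerate_pull_moves("RRUURURDDD", 3)
apply_pull_move("RRUURURDDD", 3, c(3, 1))
```

A consequence of dragging **only toward residue 1** (the definition adopted
here, and the one the transformation's pseudocode states) is that the move
class is *not* closed under inversion: a corner-free pull that dragged the
head cannot be undone by any single pull move, because the reverse
operation would have to drag residues toward the tail. Single-residue
relocations (corner equals predecessor, end moves) are always reversible.
The completeness/reversibility theorem for pull moves holds for the
bidirectional class; adding tail-directed pulls would roughly double the
neighbourhood and is deliberately out of scope. This does not affect the
benchmark results reported by the package, but it is the honest boundary
of what the implemented neighbourhood can reach in one step.

## The operators

**Steepest-ascent hill-climbing mutation.** A random individual becomes the
current hilltop. Each iteration evaluates the full pull-move neighbourhood;
if the best neighbour strictly improves the energy it becomes the hilltop,
otherwise the climbed individual is written back into its population slot
(asynchronously, within the same generation) and a fresh random individual
is selected. The final hilltop is written back when the `hc` budget runs
out. One *iteration* is one full neighbourhood sweep.

**Random hill-climbing (RHC) mutation.** One position is sampled uniformly,
one legal pull move there is sampled uniformly, and the move is accepted
only on strict improvement. "No further improvement" is operationalised as
`patience` consecutive failed samples (default: the sequence length $n$);
a single failed sample would be far too weak a certificate of local
optimality, while $n$ failures make every position likely to have been
probed.

**Collision-avoiding one-point crossover.** An offspring copies the first
`cut` genes from one parent and then follows the other parent's genes,
substituting a uniformly random non-colliding direction whenever the
inherited gene would collide; a walk with no free direction marks that
offspring failed. Cut points are drawn uniformly on $1..n-2$: the cut at
$n-1$ would copy a parent verbatim and waste a draw, so it is excluded.

**Hill-climbing crossover.** For a random pair of parents the incumbent
`best_o` starts as the better parent. Each of the `hc` iterations draws
`k` cut points (two offspring each); if the best offspring strictly beats
the incumbent, it is RHC-mutated and the better of (offspring, mutant)
replaces the *worse* member of the pair in place, the climb continuing
with the updated pair. Otherwise a fresh random pair is selected and the
incumbent is re-initialised from it ("the same steps" applied to the new
pair). Because an insertion must strictly beat the better parent, the
population minimum is non-increasing under this operator. Ties never
trigger replacement anywhere: strictness prevents plateau cycling.

**Diversification.** Every `kd` generations the population is partitioned
by exact energy; within each energy group a single deterministic pass in
population order clusters individuals to the first leader within Hamming
distance $< (n-1)/4$ (the threshold is used as a real number, e.g. 4.75
for $n = 20$, with strict comparison — the formula is taken literally and
no rounding rule is stated anywhere). Per cluster the leader (lowest
index) survives and every other member is replaced by a fresh random valid
chromosome improved by one RHC pass. Leader clustering was chosen over
transitive closure because it is reproducible, order-deterministic and
free of chaining ambiguity. Newly injected individuals are not re-checked
against survivors; the procedure is a replacement sweep, not a fixed
point iteration.

## Variants and the engine

* `EAHCD` — hill-climbing crossover, then steepest-ascent mutation, then
  (every `kd`-th generation) diversification;
* `EAHC` — the same without diversification;
* `EAD` / `EA` — a plain generational pass with and without
  diversification: per individual, crossover with probability 0.8 (mate by
  binary tournament, the focal individual always the first parent, the
  best valid offspring replacing the focal individual only if strictly
  better) and a single random pull move with probability 0.2, accepted
  only on strict improvement. The replace-if-better rule is the package's
  own choice — the plain variants have no stated survivor selection, and
  strict elitism keeps all four variants comparable.

Defaults follow the benchmark setting: population 100, 300 generations,
`hc = 100`, `k = 50`, `kd = 30` (10% of the generation count). The
variant-comparison experiments instead diversify every generation; pass
`kd = 1` for that setting — both values are printed settings, so neither
is hard-coded. Diversification triggers when the 1-based generation index
is divisible by `kd`.

Every source of randomness goes through R's RNG, so `set.seed()` (or the
`seed` argument of `hp_fold()`) makes a run bit-reproducible. Traces are
generation-stamped rather than wall-clock-stamped so that summaries are
hardware-independent; elapsed time is reported per fit for convenience.
An optional `stop_at` energy stops a run as soon as the population best
reaches it (used when only the best-of-$m$-runs energy is of interest),
and `time_limit` truncates cleanly at a generation boundary.

## Initialization as the synthetic-data source

There is no external data: the "data" of every experiment are random
self-avoiding walks. Each chromosome is grown step by step with a uniform
choice among the directions leading to a free point, restarting from
scratch on dead ends. This emulates an unfolded, unbiased starting
ensemble. Two caveats follow. First, growth-with-restart is not exactly
uniform over all self-avoiding walks (walks with many near-dead-end
prefixes are slightly over-represented); no claim in the package depends
on exact SAW uniformity, and the first gene is exactly uniform, which is
what the initialization test checks. Second, benchmark HP strings are
designed instances, not natural sequences — passing tests say the search
reproduces the published lattice benchmarks, not that it predicts real
protein structures.

## Run statistics

`best_to_date()` computes, on a generation grid, the envelope statistics
of best-to-date energy over replicate runs (count, min, mean, variance,
max). `signed_t()` compares two such summaries with Welch's two-sample
$t$ on the (n, mean, variance) triples; Welch was preferred over a pooled
estimate because the run counts contributing at a given time may differ.
The sign convention is "positive means the first algorithm is poorer
(higher mean energy)". Degenerate inputs are defined explicitly: zero
variance on both sides gives 0 for equal means and a signed infinity
otherwise. `population_free_energy()` computes
$F = -kT \ln \sum_i e^{-E_i/kT}$ over the final population with the
log-sum-exp trick, counting duplicated conformations with their
multiplicity; $F = E$ for a single conformer, $F = E - kT\ln m$ for $m$
degenerate ones, and $F \to \min E$ as $kT \to 0^+$.

## Problem sizes used by the shipped tests

The test suite exercises the full algorithm at the benchmark setting on
the instances where convergence is fast (S1–S7 with early stop at the
target energy, 10 seeds) and uses reduced populations, budgets and
generation counts for property and invariant checks (for example,
validity fuzzing uses chained single moves across all eight benchmark
lengths, and the energy oracle comparison uses 1,000 random conformations
per length). These sizes are the package's choice of a thorough but
routinely runnable suite; the full-scale S8 run is left to the user (see
the README), since most of its runs end at −39 rather than the optimum
−42 and each takes the longest of all instances.

## Known limitations

* Square lattice, 2D, two-letter alphabet only; no triangular/FCC/3D
  lattices and no real amino-acid alphabets.
* Head-directed pulls only (see above): the move class is not closed
  under inversion, and the neighbourhood is smaller than the full
  bidirectional pull-move class.
* The plain EA/EAD variants fill in unstated details (survivor selection,
  per-individual operator order) with the documented choices; they are
  meant as ablation baselines, not as reference implementations of any
  particular classical GA.
* Free-energy monitoring treats the final population as the conformer
  ensemble; it is a summary of sampling quality, not a thermodynamic
  estimate for the chain.
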