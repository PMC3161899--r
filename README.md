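# hpfold

Protein structure prediction in the two-dimensional hydrophobic–polar (HP)
square-lattice model, using an evolutionary algorithm whose genetic
operators are driven by hill climbing.

## The problem and the method

In the HP model a protein is a chain of H (hydrophobic) and P (polar)
residues embedded as a self-avoiding walk on the square lattice. Residues
that are lattice-adjacent but not chain-consecutive are topological
neighbours, and each H–H topological contact contributes −1 to the energy

```
E(c) = − #{ (i, j) : i + 1 < j, |x_i − x_j| + |y_i − y_j| = 1, s_i = s_j = H }
```

The prediction task — find the conformation of minimum `E` — is NP-hard
even in this abstraction, and is the standard proving ground for folding
metaheuristics.

`hpfold` evolves a fixed-size population of conformations encoded as
absolute-move chromosomes (n−1 symbols over L/U/R/D):

* **mutation** is the *pull move* (a residue hops diagonally to a free
  point, dragging predecessors until the chain reconnects), applied in a
  steepest-ascent hill-climbing loop over the full move neighbourhood;
* **recombination** is a collision-avoiding one-point crossover applied in
  a hill-climbing loop (`k` random cut points per iteration; an offspring
  that strictly beats the better parent is improved further by random
  hill climbing and asynchronously replaces the worse parent);
* **diversification** periodically replaces Hamming-similar individuals
  of equal energy (distance < (n−1)/4) with fresh random conformations.

The four variants `EAHCD`, `EAHC`, `EAD`, `EA` switch the hill-climbing
operators and the diversification stage on and off for ablation studies.
The eight standard 20–64 residue 2D benchmark instances (S1–S8) ship with
the package together with their best known energies. See the vignette
(`vignettes/hp-lattice-folding.Rmd`) for the full account of the model,
the operators and the design decisions.

## A worked example

```r
library(hpfold)
seq4 <- hp_instance("S4")
seq4
#> HP sequence [S4] - n = 36 residues, 16 hydrophobic
#>   PPPHHPPHHPPPPPHHHHHHHPPHHPPPPHHPPHPP

fit <- hp_fold(seq4, seed = 11, stop_at = -14)
summary(fit)
#> HP fold (EAHCD) - S4, 36 residues
#>   best energy: -14  (best known: -14)
#>   best chromosome: UUULDLULLULURRDRURDRRULUUULDDLULDLL
#>   generations run: 268  [stopped at target]
#>   final population energy: min -14, avg -11.13, var 2.11, max -5
#>   strict improvements of the population best: 7
#>   target energy first reached at generation 268
#>   elapsed: 1.24 s
```

The fit reached the best known energy for S4 (−14, i.e. 14 H–H contacts)
after 268 generations of this seed; `coef(fit)` returns the chromosome,
`plot(fit)` the best-to-date trace, and
`plot(decode_chromosome(coef(fit)), sequence = seq4)` draws the folded
chain with its H–H contacts.

Replicate runs and the envelope statistics used to compare variants:

```r
runs <- hp_fold_multi("S1", n_runs = 10, seed_base = 1, stop_at = -9)
summary(runs)
#> Runs: 10
#> Final best energy: min -9, avg -9, var 0, max -9
#> Median first-hit generation (target reached): 3

best_to_date(runs, grid = c(1, 2, 5))
#>   T  n min  avg       var max
#> 1 1 10  -9 -7.9 0.5444444  -7
#> 2 2 10  -9 -8.3 0.2333333  -8
#> 3 5 10  -9 -8.9 0.1000000  -8
```

All ten seeds reach the S1 optimum (−9), with a median first hit at
generation 3 — short chains converge almost immediately. `signed_t()`
compares two such envelope tables (positive = first algorithm poorer) and
`population_free_energy()` summarises a population by
F = −kT·log Σ exp(−E/kT).

A thin command-line front-end over the same functions is installed at
`inst/cli/hpfold.R`:

```sh
Rscript inst/cli/hpfold.R run --instance S5 --variant EAHCD --seed 7 --runs 10 --out out/
Rscript inst/cli/hpfold.R bench --instances S6 --variants EAHCD,EA --runs 25 --out out/
```

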