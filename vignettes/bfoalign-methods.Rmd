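---
title: "Foraging-based multiple sequence alignment: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Foraging-based multiple sequence alignment: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bfoalign)
```

## The optimization model

Multiple sequence alignment (MSA) arranges $n$ sequences into an
$n \times m$ matrix $A$ whose entries are residues or the gap character
`-`, so that homologous positions share columns. Under the sum-of-pairs
objective the problem is NP-complete, which motivates metaheuristics that
search the space of complete alignment matrices directly rather than
building one progressively from pairwise alignments.

`bfoalign` treats each candidate matrix as a *bacterium* in a foraging
population:

* **Chemotaxis (tumble).** A move inserts a fixed number of gaps, each at
  a uniformly chosen row and intra-row position, then re-pads the matrix
  to rectangular. Gap insertion is the only move operator, so every
  bacterium always gap-strips back to the exact input sequences — the
  feasibility invariant every operator in the package preserves.
* **Swim.** The gap-deletion counter-move: a fixed number of gaps, chosen
  uniformly among existing gap positions, are removed. It exists because
  pure gap insertion saturates matrices with gaps over hundreds of
  iterations.
* **Swarming.** Bacteria interact through a Gaussian attraction–repulsion
  term (below), added to the alignment score to form fitness.
* **Reproduction.** Each iteration the worst bacterium is replaced by a
  copy of the best (one-for-one; the count is a configuration knob),
  keeping the population size constant.

Elimination–dispersal, part of the canonical foraging heuristic, is
deliberately absent: the developed algorithm this package implements does
not use it.

## Scoring

The alignment objective is a BLOSUM62 sum-of-pairs score. For each column,
all $\binom{n}{2}$ unordered row pairs are evaluated — the "list of pairs"
that makes the evaluation embarrassingly parallel — and summed:

* residue–residue pairs use the BLOSUM62 log-odds entry (the table is
  vendored as a plain-text NCBI-format asset and parsed at load);
* indel pairs (one gap) subtract a penalty of 0.1;
* gap–gap pairs score 0 — they carry no homology information, and all-gap
  columns are removed outright by column cleaning;
* `X` and `*` score 0 against everything; under the DNA alphabet `N` is
  the any-base code and also scores 0, while under the protein alphabet
  `N` is asparagine and uses its matrix entries.

DNA inputs are scored through the same BLOSUM62 lookup on the letters
`A`, `C`, `G`, `T` (all valid amino-acid codes). This is a modeling quirk
inherited from the method this package implements — one evaluator serves
both genetic and protein sets — and should be read as a relative, not
biologically calibrated, objective for DNA.

A scored $n \times m$ matrix costs $m\binom{n}{2}$ pair lookups; the
closed form is exposed as `count_pairs()` (e.g. 100 sequences × 100
columns × 100 matrices = 49,500,000 pairwise evaluations, 13.75 h at
1 ms/pair sequentially, ≈52 min on 16 workers under linear scaling —
`pair_eval_seconds()`).

## Swarm interaction

For bacterium $k$ in a population of $S$ with coordinates $\theta^i$, the
interaction is

$$g_k = \sum_{i=1}^{S} -d_{attr}\,
  e^{-w_{attr}\lVert\theta^k-\theta^i\rVert^2}
  + \sum_{i=1}^{S} h_{repel}\,
  e^{-w_{repel}\lVert\theta^k-\theta^i\rVert^2},$$

and fitness is the BLOSUM score plus $g_k$. Two numerical conventions are
fixed so that tests can be exact:

* **The self-term $i=k$ is included** (the sums run over all $i$). It
  contributes the constant $-d_{attr}+h_{repel}$ per bacterium and cannot
  change rankings.
* **Coordinates are one-dimensional**: a bacterium's coordinate is its
  scalar BLOSUM score. The interaction formula was written for continuous
  search spaces and no published mapping to alignment matrices exists; the
  scalar-score embedding is the minimal choice consistent with
  per-bacterium score tables, and it makes bacteria of similar alignment
  quality interact most strongly. The true dimensionality used by the
  original implementation is not recoverable; this is a documented
  decision, not a claim.

With $d_{attr}=h_{repel}$ and $w_{attr}=w_{repel}$ the two sums cancel
identically for any population — a closed-form limit the test suite checks
to $10^{-12}$.

## The three variants

| | chemotaxis | swim | scoring | best reported | NFE counting |
|---|---|---|---|---|---|
| `run_bfoa` | tumble/iter | — | raw | per iteration | $+2S^2$/iter |
| `run_bfoad` | tumble/iter | yes (50 under scheme K) | raw | per iteration | $+2S^2$/iter |
| `run_bfoadtp` | tumble/iter (elites skip) | yes (1) | normalized (mean per pair) | global best | $+S$/iter |

The base variant reports each *iteration's* best with no elitism, so its
best-fitness trace may worsen as gaps accumulate — the decay is a genuine
behavioral signature, reproduced in the tests. The elitist variant adds:
elites carried unchanged (and protected from replacement — necessary for
the boundary case elitism = population to actually freeze the
population), global-best reporting (monotone non-decreasing trace),
normalized scoring, and per-matrix NFE counting. "Swim = 1" in its
configuration is implemented as one gap deletion per iteration.

Two counting conventions for the number of function evaluations (NFE)
coexist deliberately: `per_interaction` adds $2S^2$ per population
evaluation (one attraction and one repulsion term per ordered pair);
`per_matrix` adds $S$. For population 8 the latter gives the exact
sequences 8, 16, 24, … (elitist variant) and 16, 24, 32, … for the GA,
whose first generation is counted twice (initial evaluation plus first
selection).

Whether the original algorithm re-inserts the full tumble count every
iteration or only at initialization is ambiguous; chemotaxis that never
moves is not chemotaxis, so gaps are re-inserted every iteration by
default and `tumble_each_iter = FALSE` exposes the init-only reading.

## The Genetic Algorithm baseline

`run_ga` uses roulette selection on shifted fitness
($f - \min f + \delta$, so negative scores are legal), two-point
crossover on the column axis, and a 0.3-probability gap-edit mutation.
Swapping a column block between two different gap patterns breaks the
feasibility invariant, so children are repaired by re-threading each
row's original residues through the child's gap pattern (surplus residue
slots become gaps; missing residues are appended). The GA's chromosome
encoding was never published; this matrix-with-column-blocks
reconstruction is ours. GA fitness is the normalized BLOSUM score only —
the swarm term is a foraging concept — and cross-algorithm comparability
comes from z-standardization, which is scale-free.

## Run analysis

* `zscore_trace` standardizes a run by its own mean and **population**
  standard deviation (the divisor is not specified in the source method;
  `sd_type = "sample"` is available).
* `convergence_iteration` thresholds the *running maximum* at a fraction
  of the run's best (default 95%), min-max normalizing first when the
  trace spans non-positive values, where a percentage of the best is
  ill-defined.
* `threshold_nfe` pools both algorithms' per-run best fitnesses, takes
  the median (midpoint for the even pool) as the threshold of interest,
  and reports each run's cumulative NFE at first crossing; runs that
  never cross are discarded. Discards are exactly the runs whose best is
  below the threshold.
* `compare_runs` gates on Shapiro–Wilk normality (both samples $p>0.05$
  → Welch t-test, else Mann–Whitney U) and always reports Cohen's
  $d = (\bar b - \bar a)/s_{pooled}$.

## Synthetic families: what they emulate and what they do not

`generate_family()` simulates a homologous family as one uniform-random
ancestor plus independently mutated descendants: per-site substitutions
(hit sites resample uniformly over the alphabet, so a fraction
$(|\Sigma|-1)/|\Sigma|$ of hits actually change) and truncated-geometric
indels, which produce the length variation real homolog sets show.
Defaults — 8 sequences, 60-residue ancestor, substitution rate 0.1, indel
rate 0.05, maximum indel length 5 — give a small family with enough
shared signal that the gap-free arrangement of a zero-rate family is
provably the score optimum (a sanity anchor the tests use). There is no
phylogeny, no rate heterogeneity, no conserved domains: passing tests
demonstrate the operators' contracts and the optimizers' behavioral
signatures on such families, not alignment accuracy on real biological
data.

One consequence of these desk-scale conditions is worth stating plainly:
with 60-residue sequences, inserting 100 gaps per iteration is a massive
perturbation, so on these fixtures the GA (which edits one gap at a time)
reaches higher normalized fitness than the elitist foraging variant, and
the threshold-of-interest comparison discards the foraging runs rather
than the GA runs. On the long NCBI gene sets the method was designed for,
the same tumble intensity is a moderate move. The acceptance script
reports this comparison as computed; the behavioral contracts (monotone
elitist trace, base-variant decay, exact NFE ladders) are
scale-independent and hold throughout.

## Numerical and reproducibility choices

* All stochastic operators draw from R's global RNG; every run function
  seeds it from its configuration, and chemotaxis is applied serially, so
  a fixed seed gives bit-identical traces for **any** worker count.
  Parallel scoring accumulates partial sums in a fixed partition order.
* Ties in best/worst selection break to the lowest index.
* A matrix whose columns are all gaps cleans to a legal zero-width
  matrix; scoring it is an error (degenerate alignment).
* Score tables are recomputed from scratch every iteration; nothing is
  cached across iterations except the elitist variant's global best.
* Problem sizes in the test suite and acceptance script (families of 4–8
  sequences, 30–60 residues; 30-run comparisons at population 8 and 200
  iterations) were chosen as the smallest sizes at which every behavioral
  signature is observable.

## Known limitations

* Single-machine parallelism only (forked workers); no distributed
  execution.
* BLOSUM62 only; no affine gap model — the indel penalty is flat per
  pair.
* The scalar swarm embedding discards all structural information about an
  alignment beyond its score; bacteria with equal scores are
  indistinguishable to the interaction term.
* The GA is a faithful small baseline, not a tuned competitor.
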