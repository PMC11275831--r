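---
title: "Modeling morphogenesis with neuroevolved cellular automata"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling morphogenesis with neuroevolved cellular automata}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncamorph)
```

## The model

`ncamorph` simulates a minimal form of developmental biology: a fixed
`Nx x Ny` grid of cells must collectively *grow into* and *maintain* a
target pattern of discrete cell types, starting from evolved initial
conditions, while every update is disturbed by noise. The substrate is a
neural cellular automaton (NCA): every cell runs an identical small neural
controller, perceives only its own state and its 8 Moore neighbors, and can
do nothing but propose additive updates to its own state.

Each cell $i$ carries a real state vector $c_i \in \mathbb{R}^{N_C}$ with
$N_C = N_G + N_H$: the first $N_G$ entries are *type indicators* and the
remaining $N_H$ entries are hidden channels freely usable for intercellular
signaling. The expressed cell type is the argmax over the indicator
entries (ties break toward the lowest index, a measure-zero event under
noise but fixed for determinism). A developmental step updates all cells
synchronously:

$$ c_i(t+1) = \mathrm{clip}\big(c_i(t) + g_i \, a_i(t) + \xi_i,\; l_c\big) $$

where $a_i$ is the controller's proposed action (clipped to
$l_a = [-1, 1]$), $g_i \sim \mathrm{Bernoulli}(P_D)$ gates whether the
proposed action is actually *executed* in the environment, and $\xi_i$ is a
vector of $N_C$ i.i.d. $\mathcal{N}(0, \xi_c^2)$ deviates. States are
clipped to $l_c = [-3, 3]$ after every step. Three modeling points deserve
emphasis:

* **Noise is unconditional.** The noise term applies whether or not the
  action executes; with $P_D = 0$ the tissue still drifts passively. This
  is what makes the direct-encoding limit fragile at high noise.
* **The decision probability $P_D$ interpolates encodings.** At $P_D = 0$
  (or with agency disabled outright) the genome's initial states map
  directly onto the phenotype: a direct encoding. At $P_D = 1$ every
  proposed action executes: a fully reliable multi-scale competency
  architecture.
* **Perception is permutation invariant.** Each of the 9 perceived states
  is embedded by a shared bias-free linear-`tanh` sensor and the 9
  embeddings are *averaged*. A cell therefore cannot tell its neighbors
  apart — or even itself from its neighbors — and no convolutional spatial
  filter exists anywhere in the model.

### Controllers

Two controller families are provided (see `controller_spec()`), sized so
that their functional genomes roughly balance the 256 structural genes of
the default 8x8, $N_C = 4$ grid:

| architecture | sensor | controller copy | parameters at R = 1 |
|---|---|---|---|
| FF | bias-free 4 -> 24 linear + tanh | bias-free 24 -> 4 linear | 96 + 96 = 192 |
| RGRN | bias-free 4 -> 16 linear + tanh | 16 -> 4 recurrent tanh core (memory m = 4) + 4 -> 4 linear output with bias | 64 + 100 = 164 |

The exact layer shapes are a package convention chosen as the minimal
layout reproducing these two parameter counts; all dimensions are
configurable. The RGRN memory is private per cell (neighbors never see
it), is zeroed at the start of every rollout, and one internal controller
cycle runs per developmental step by default (`cycles` raises this).

The *redundancy number* R stacks R independently parameterized copies of
the controller on top of the one shared sensor stage; their outputs are
averaged *before* the single action clip, so exactly one bounded action
enters the state update. Averaging pre-clip keeps the R copies able to
cancel one another — the error-correcting-code intuition behind the knob.

### Genome

A genome (`genome()`) is the concatenation of a structural part (all
initial cell states, `Nj x NC` values), a functional part (the flat
controller weights) and optionally a scalar *competency gene* decoded to
$P_D = \tfrac12(\tanh(x^{(C)}) + 1)$ after clipping $x^{(C)}$ to
$[-3, 3]$. The decoder is symmetric, so the L2 penalty used when the gene
is evolved (rate 0.01 on the *entire* flat genome) biases neither toward
minimal nor maximal competency.

### Fitness

A trajectory of $t_D$ steps is scored (`fitness()`) as

$$ r = (2 n_G - N_j) + r_T\, n_T - r_S\, n_S - r_{L2} \sum_k x_k^2 $$

with $n_G$ the correct cells at the final step, $n_T$ the number of
*post-update* steps $k \in \{1..t_D\}$ at which the entire map equals the
target, and $n_S$ the number of consecutive state pairs
$(k, k+1),\; k \in \{0..t_D-1\}$ at which all types stagnate *while the
pattern differs from the target*. Defaults are $r_T = 0.25$,
$r_S = 0.5$. Two counting conventions are deliberate:

* $n_T$ excludes the initial state. With $t_D = 25$ the attainable maximum
  is $64 + 0.25 \cdot 25 = 70.25$ on the 8x8 task; counting $t_0$ would
  give 70.5 and contradict that analytic maximum.
* $n_S$ penalizes only *suboptimal* stagnation. Holding the correct
  pattern frozen is the desired behavior (morphostasis) and is rewarded
  through $n_T$, never penalized; this resolves the apparent tension
  between the stagnation discount and the maintenance reward. The
  $(t_0, t_1)$ pair is included in the count.

The evolutionary selection criterion is $F$, the mean of $N_E = 8$
replicate rollouts with independent noise and gating realizations
(`evaluate_genome()`). *Structural fitness* (`structural_fitness()`)
re-evaluates a genome under the identical protocol — same noise level,
same replicate count — but with all agency disabled; it measures what the
initial states achieve on their own and is logged every generation.

## The evolutionary driver

`evolve()` wraps a self-contained (mu/mu_w, lambda)-CMA-ES
(`cma_init()`/`cma_ask()`/`cma_tell()`; sphere, Rosenbrock and ellipsoid
convergence tests back it) around the flat genome, with population
$N_P = 96$ and up to $N_M = 2000$ generations at full study scale. Design
choices that were genuinely open:

* **Unbounded search, clipped phenotype.** Rather than bounding the search
  space, the structural genes are clipped to $l_c$ at compile time and the
  competency gene inside its decoder. This matches how the model text
  phrases all range limits (as clipping) and keeps CMA-ES assumptions
  clean.
* **Replicate seeds are redrawn each generation** and shared across the
  generation's candidates (common random numbers reduce selection noise);
  the seeds of the best individual are logged, so its $F$ is exactly
  re-scorable (`run_log$best_rep_seeds`).
* **Solve detection** uses the best-ever averaged fitness crossing the
  threshold (64 for the 8x8 tasks, i.e. full correctness), with a
  configurable post-solve `patience` (default 0: stop at the crossing).
  Runs that never cross are *censored*; sweep aggregates enter them at the
  generation budget and always report the censoring fraction alongside.
* **`mode = "direct"`** disables all actions but keeps the functional
  genes in the search vector, so the direct- and multi-scale searches
  share one search-space dimensionality — the comparison isolates the
  encoding, not the dimension.
* **Warm starts** (`warm_start_evolve()`) initialize the CMA-ES mean at a
  pre-evolved genome with a reduced step size, leaving both structural and
  functional genes mutable. The default `warm_sigma = 0.3` is set by a
  displacement argument: re-targeting a flag flips dozens of structural
  genes across most of the `[-3, 3]` state range, and a CMA-ES mean moves
  $O(\sigma)$ per coordinate per generation, so few-generation transfers
  need $\sigma \approx 0.3$; at $\sigma = 0.1$ the same adaptation stays
  frozen near its origin for tens of generations.
* **Transfer solve detection** follows the correctness-score convention:
  the adaptation optimizes the ordinary shaped fitness, but a transfer
  counts as solved when the replicate-averaged correctness term
  $2 n_G - N_j$ of the generation-best individual reaches $N_j$
  (`ea_config(solve_metric = "correctness")`).

## Determinism and numerics

Every rollout consumes one random stream in a fixed per-step order — first
the `Nj` gate uniforms, then the `Nj x NC` noise normals — *independently*
of $P_D$, $\xi_c$, and whether agency is enabled. Changing one knob
therefore never reshuffles the realization of another, and phenotypic and
structural evaluations of the same seed see identical noise.

The compiled engine (Rcpp) is checked for *bit-exact* equality against a
pure-R per-cell reference loop across random architectures, grids and
noise levels. This is only possible because both implementations perform
the same IEEE operation sequence; the C++ is compiled with
`-ffp-contract=off` so no fused multiply-adds break the agreement. The
synchronous two-phase update (all perceptions read the pre-step state)
makes the result independent of cell visitation order by construction.

Boundary conditions are fixed: off-grid positions contribute a virtual
boundary cell of constant zero state to the 9-way perception mean. The
alternative (averaging over fewer, real-only neighbors) is exposed via the
`neighborhood()`/engine convention but not used; zero-state virtual cells
keep the aggregation count constant and embed to exactly zero under the
bias-free sensor. Degenerate configurations ($\xi_c = 0$, $P_D \in
\{0, 1\}$, 1x1 grids) are valid and covered by tests. RGRN memory updates
are not gated by default — gating models the unreliable *execution* of an
action in the environment, not a failure of the cell's internal
computation — but `gate_memory = TRUE` flips this interpretation.

## What the experiments emulate — and what they do not

The built-in flag targets (`make_flag_pattern()`) are fixed 8x8
rasterizations (the czech hoist triangle uses the rule *blue iff
col <= min(row, 7 - row)*, 20/22/22 cells per type); published figures of
such tasks show them only as insets, so the exact pixelation is a package
convention and none of the qualitative results depend on it. Arbitrary
rasters load from plain-text grid files.

The desk-scale experiment profile (2x2 single-type targets, $N_P = 16$,
$N_M = 300$, $N_E = 4$, 10 replicates per sweep cell, $t_D$ kept at 25)
is the package's default for tests and interactive exploration; it
reproduces the qualitative competency-vs-noise trend — under developmental
noise 0.5, searches with $P_D = 0.5$ solve in a few generations while
direct encoding needs an order of magnitude more — in minutes on one CPU.
Full-scale runs (8x8 czech, $N_P = 96$, $N_M = 2000$, $N_E = 8$) take
hours per sweep cell; single-run generation counts at that scale are
one-off stochastic outcomes, not test surfaces.

The shipped genome `inst/extdata/genomes/czech_rgrn_pd1_noise025.txt` is
an RGRN solution of the 8x8 czech task pre-evolved by this package at
full scale ($P_D = 1$, $\xi_c = 0.25$, $N_P = 96$, $N_E = 8$, master
seed 2024), stopped when the solve threshold was first crossed
(generation 113) -- the same stopping rule the sweeps use, which keeps
the solution competency-reliant (its structural fitness is negative). It
seeds the transfer experiments and can be regenerated with:

```{r pretrain, eval = FALSE}
czech <- make_flag_pattern("czech")
log <- evolve(czech, controller_spec("rgrn"), czech$spec,
              env_config(noise_sigma = 0.25, pd = 1), fitness_weights(),
              ea_config(seed = 2024), verbose = TRUE)
save_genome(log$best_genome, "czech_rgrn_pd1_noise025.txt")
```

Two practical lessons from building that fixture are worth recording.
First, a run left to converge far beyond the solve threshold (to the
fitness maximum 70.25) turns into a pure target-attractor: its phenotype
becomes invariant to small genome perturbations, so a warm-started search
on a *new* target sees zero fitness variance and cannot move — converged
morphostasis solutions transfer poorly, freshly solved morphogenesis
solutions transfer well. Second, the feedforward and recurrent
architectures solve the czech task about equally well, but the recurrent
solutions we examined adapted to new flags several times faster.

Passing tests on this model show that the *mechanisms* behave as specified
— they do not show anything about real biological tissue. The model has no
cell division, migration or death; the grid and cell count are fixed; the
noise is i.i.d. Gaussian per channel with no spatial or temporal
correlation; and selection acts only on the system-level phenotype score,
never on per-cell signals. Scaling is a further limitation: the structural
genome grows linearly with the cell count, so very large grids would need
an indirect encoding of the initial states, which is out of scope here.

## A worked desk-scale example

```{r sweep, eval = FALSE}
tgt <- target_pattern(matrix(0L, 2, 2), grid_spec(2, 2), "blue")
plan <- sweep_plan(pd_values = c(0, 0.5), noise_values = c(0, 0.5),
                   redundancy_values = 1, archs = "ff",
                   replicates = 10, profile = "desk", seed = 5)
run_sweep(plan, tgt)$summary
#>    pd noise mean_generations sd_generations censoring_fraction n_runs
#> 1 0.0   0.0              2.4       1.173788                  0     10
#> 3 0.0   0.5             21.4       7.501111                  0     10
#> 2 0.5   0.0              1.0       0.000000                  0     10
#> 4 0.5   0.5              3.4       1.505545                  0     10
```

Read along the noise 0.5 column: granting the cells a 50% chance of
executing their proposed updates cuts the expected search length roughly
six-fold relative to the passive direct encoding — the core qualitative
claim the full-scale sweeps make, visible already at toy scale.
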