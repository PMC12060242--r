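---
title: "Ensembles of diverse genomic prediction models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensembles of diverse genomic prediction models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Genomic selection predicts trait phenotypes of unphenotyped lines from
genome-wide markers. No individual prediction model wins consistently across
traits, populations and split ratios; this package studies the alternative of
*naively averaging* a diverse set of predictors, and quantifies *why* the
average wins through the diversity decomposition of squared error. For a set
of $N$ model prediction vectors $M_i$ and observations $V$,

$$(\bar M - V)^2 \;=\; \frac{1}{N}\sum_i (M_i - V)^2 \;-\; \frac{1}{N}\sum_i (M_i - \bar M)^2,$$

per record: ensemble error = average error − prediction diversity. The
diversity term is non-negative, so the equal-weight ensemble can never be
worse than the average model, and is strictly better whenever models
disagree. `dpt_decompose()` reports each term averaged over test records
(MSE scale); averaging preserves the identity by linearity.

Because the empirical dataset the decomposition was originally demonstrated
on is external, everything here is exercised on simulated biparental BC1S4
RIL populations with *known* trait architectures, which turns the headline
claims into testable parameter-recovery statements.

## The simulated world

`simulate_marker_map()`, `simulate_ril_population()`,
`assign_trait_architecture()`, `simulate_phenotypes()` and
`inject_missing()` generate the inputs. Fixed modelling choices:

* **Pedigree.** F1 backcrossed once to the recurrent parent, then four
  selfing generations by single-seed descent (BC1S4). Expected donor allele
  frequency is $1/4$ and expected residual heterozygosity
  $\tfrac12 (\tfrac12)^4 = 0.03125$; both are asserted in tests with
  sampling tolerances.
* **Meiosis.** Crossovers are a Poisson process on the cM scale (Haldane
  map, no interference) — the simplest assumption consistent with a genetic
  map; nothing downstream depends on interference.
* **Dosage coding.** Count of donor (teosinte-like) alleles, 0/1/2; the
  recurrent parent is all-zero. This makes allele-frequency invariants
  directly checkable.
* **Default desk profile.** 5 populations × 250 RILs × 300 markers on 5
  chromosomes (~60 markers/chromosome after pruning-scale reduction),
  mirroring the published population sizes and post-pruning panel sizes.
* **Traits.** A near-additive ("days to anthesis"-like) trait uses additive
  QTL only. The epistatic ("tiller number"-like) trait adds
  additive-by-additive pairs with the centered product rule
  $\beta_{ij}(x_i-1)(x_j-1)$ (a `complementary` rule,
  $\beta_{ij}\,\mathbf 1[x_i>0 \wedge x_j>0]$, is also available). The
  generative model for epistasis is not specified by the source study; the
  product rule is the standard additive-by-additive form. The default
  epistatic world used in acceptance testing is 3 additive QTL
  (effect SD 1) plus 4 pairs (effect SD 2), i.e. a majority of genetic
  variance from interactions — that is what "a trait shaped by epistatic
  interactions" means operationally here, chosen once, before any test was
  run against it.
* **Heritability.** Residual variance is set from the realized genetic
  variance so that $\mathrm{Var}(g)/(\mathrm{Var}(g)+\mathrm{Var}(e))$ hits
  the target $h^2$ exactly in expectation; `target_h2 = 1` means a
  noise-free trait.
* **Environments.** Two environments enter as additive main effects only —
  no G×E is simulated, matching the deferral of G×E modelling in the study
  design. Records are the unit of splitting after concatenation.

What a green test does **not** establish: real GBS data have genotyping
error, segregation distortion, missing phenotypes and trait architectures
that are not a handful of sampled QTL; claims about the real traits cannot
be made from this simulator.

## Preprocessing chain

* **Missingness filter**: drop SNPs with *more than* 10% missing calls —
  exactly 10% is kept; the boundary is tested.
* **Imputation**: (a) most frequent dosage per column (ties → lower dosage,
  a documented deterministic choice); (b) flanking-marker rule — agreeing
  flanks win, otherwise the bp-closest flank (equidistant → left), single
  flank at chromosome ends, and RILs with an entirely missing chromosome are
  removed and reported.
* **LD pruning**: within each chromosome a 30,000 bp window is anchored at
  the left-most unpruned marker and advanced 5 markers at a time; within a
  window, pairs with $r^2 > 0.8$ lose the member with lower MAF (tie → later
  position). Passes repeat until nothing is removed, which makes the
  operation a fixed point of itself — pruning a pruned panel removes
  nothing. The external tool originally used mixes bp- and marker-count
  units in its window specification; the semantics here honour both numbers
  but are documented rather than asserted as equivalent to that tool.
  Zero-variance columns cannot enter a correlation pair and are kept.
* **Splits** are record-level (a RIL's two environment records may straddle
  train/test), matching a concatenate-then-split order of operations.

## The six predictors

All models implement one contract: `fit(X, y, hyper, seed)` →
`predict(model, X_new)`, reproducible from the seed. The environment
indicator column (`.env`) is a fixed effect in the linear models and an
ordinary feature in the machine-learning models.

* **rrBLUP** — marker effects i.i.d. normal with common variance. Default
  fitting is the closed-form REML mixed-model solve on the spectral
  decomposition of $XX'$ (deterministic, fast); a Gibbs sampler
  (`method = "gibbs"`, 12,000 iterations / 2,000 burn-in in the paper-style
  profile) targets the same estimand. With a fixed variance ratio the
  estimate equals the explicit ridge closed form to $10^{-6}$ (tested).
* **BayesB** — per-marker spike-and-slab: point mass at zero with
  probability $\pi$ (Beta prior, updated), scaled-t slab via per-marker
  scaled-inv-$\chi^2$ variances (df 5, scales derived from `var(y)` and an
  a-priori marker $R^2$ of 0.5, the conventional defaults of the reference
  software whose exact settings were not published).
* **RKHS** — Gaussian kernel $\exp(-h\,d^2)$ on mean squared dosage
  distance; default bandwidth is the median heuristic
  $h = 1/\mathrm{median}(d^2)$ since only "a fixed bandwidth" is stated.
  Fitted by the same REML machinery (kernel in place of $XX'$) or by a Gibbs
  sampler on the kernel eigenbasis.
* **Random forest** — bootstrap-aggregated regression trees grown to purity,
  variance-reduction splits, `mtry = p/3`, 1,000 trees by default.
* **ε-SVR** — RBF kernel, dual solved by an SMO-type maximal-violating-pair
  algorithm; defaults `C = 1`, `ε = 0.1`, `gamma = 1/(p·Var(X))` mirror the
  common library defaults. Tests check the solution against an independent
  quadratic-program oracle and the KKT conditions.
* **GAT** — per record, a heterogeneous star graph: marker nodes with
  directed edges into one phenotype node, no marker-marker edges, one
  attention head, three layers (1 → 20 → 20 → 1), LeakyReLU slope 0.01 on
  attention logits, ELU activations, trained 50 epochs with AdamW
  (lr 0.005, weight decay 0, batch 8) on the standardized response.

Two GAT design points deserve records. First, a marker node's feature is its
dosage *and its identity* (a one-hot indicator): with anonymous scalar
features, attention over a star graph is permutation-invariant across
neighbours — the network provably could not learn that a *specific* SNP
matters, nor support per-SNP attribution. Under one-hot identities the
source projection collapses to `w·x_j + U[,j]` and the attention logit to
`c·x_j + e_j + (target term)`, which is the form trained here (same function
class, fewer redundant parameters). Second, the output layer applies the
identity rather than a saturating activation: an ELU-bounded output cannot
predict below −1 on the standardized scale, which is indefensible for
regression. Head-averaging at the output layer is trivial with one head.
Backpropagation is hand-derived and verified against finite differences to
$10^{-6}$ in the tests.

## Ensemble and attribution

`ensemble_average()` is the equal-weight mean (a weight vector exists for
API compatibility but only uniform weights are studied). Marker effects per
model: fitted coefficients (rrBLUP/BayesB); Monte-Carlo permutation Shapley
values (RKHS/SVR; background = training rows, 64 permutations per test RIL
by default — exhaustive enumeration is infeasible at $p \approx 300$ but the
sampler is checked against full enumeration on ≤6-feature toys);
normalised impurity importance (RF); integrated gradients (GAT; all-zero
dosage baseline = "no donor allele" reference, m = 128 steps,
completeness checked within 1%). Shapley and IG are element-wise and
averaged over test RILs.

## Experiment orchestration

`run_experiment()` executes the factorial populations × traits × ratios
(0.8/0.65/0.5) × replicates; each cell's seed is a stable 31-bit hash of
(master seed, population, trait, ratio, replicate), so results are
bit-reproducible and independent of execution order. The full published
scale (500 replicates per ratio, 6 models) is hours of compute; the test
suite exercises the bookkeeping with registered stub models at the full
replication counts and the real models at a documented desk profile
(1,500/500 MCMC iterations, 100 trees, 20–30 epochs). Tied best models are
all credited in the win-percentage table (a row can then exceed 100%), a
documented choice where the original tie-handling is unstated.

Standard errors of the decomposition terms are pooled across all scenarios
of a trait, following the "across 7,500 scenarios" caption convention.

## Numerical notes and limitations

* REML optimises the variance ratio on $\log\delta \in [-14, 14]$ by
  Brent search; zero-variance responses short-circuit to a constant
  predictor with a warning in every model.
* The SMO solver stops at a $10^{-6}$ KKT violation (configurable) with an
  iteration cap; degenerate cases (constant $y$) terminate immediately with
  all coefficients at zero.
* Modal-imputation ties, equidistant flanks, LD-prune MAF ties and
  best-model ties all have documented deterministic resolutions (see above).
* MCMC posterior means at the desk profile (1,500/500) agree with the REML
  route to high correlation but are not asserted numerically against any
  published chain — prior hyperparameters beyond iteration counts were
  never published.
* No hyperparameter tuning, no ensemble weight optimisation, no G×E, no
  cross-population prediction: all are out of scope by design.
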