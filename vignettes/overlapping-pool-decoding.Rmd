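---
title: "Decoding overlapping sequencing pools: models and methods"
author: "pooldecode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding overlapping sequencing pools: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pooldecode)
```

## The problem

Sequencing many individuals over a small genomic region is dominated by
per-sample library preparation cost, not by sequencing capacity.  An
overlapping-pool design mixes each sample into several pools, prepares
one library per pool, and *decodes* the pool-level read counts back to
individual samples.  The design is a binary matrix $A \in \{0,1\}^{T
\times N}$ ($T$ pools, $N$ samples, $A_{tj} = 1$ iff sample $j$ is in
pool $t$).  Classical group-testing decoders threshold the pool results
to presence/absence and therefore only work for rare variants: a common
variant is present in every pool and carries no combinatorial signal.
This package implements a likelihood-based framework that works with
the full counts, and two applications:

* **genotyping** both rare and common biallelic variants, using
  genotype-imputation output as external information that makes common
  variants decodable at all; and
* **fusion-gene carrier detection** in pooled tumor RNA, where each
  carrier additionally has an unknown expression level.

## Information-theoretic bounds on the number of pools

With thresholded (presence/absence) pool results there are at most
$2^T$ distinguishable outcomes against $3^N$ genotype vectors, so
decoding *all* genotypes requires $T > N\log_2 3 \approx 1.585N$ —
more pools than samples, defeating the purpose.  Full counts reduce
this to $T > N\log 3 / \log 2N$, and restricting to a rare variant of
frequency $\alpha$ gives $T \ge -N\alpha\log_2\alpha$ (thresholded)
or $T \ge -N\alpha\log\alpha / \log 2N$ (counts).
`min_pools_lower_bound()` evaluates all four.  The practical reading:
rare variants are decodable from few pools, common variants are not —
unless external information (here: imputation) breaks the bound by
making the *residual* between truth and prediction sparse.

`generate_random_design()` draws each row with exactly
$\lfloor N/2\rfloor$ ones, the density for which random designs are
near-optimal.  Two departures from a plain uniform draw: duplicated
rows are redrawn (a duplicate pool carries no information), and a
sample that landed in no pool is given a slot by moving a single 1 out
of a column with spare coverage, preserving row sums — an uncovered
sample would be undecodable by construction.

`local_search_optimize()` then hill-climbs for `n_iters` iterations.
Each iteration proposes two sub-moves, both realized as a swap of a 0
and a 1 within one row so that row sums are invariant: a *row move*
(random row, random 0/1 swap, judged on row separation) and a *column
move* (a random column drawn from the closest column pairs exchanges
an entry with a differing column in the same row, judged on column
separation).  The objective is the pair (minimum pairwise Hamming
distance, $-$number of pairs attaining it), compared
lexicographically: accepting plateau moves that reduce the number of
closest pairs is what separates duplicated columns within a 1000-swap
budget, which matters because two samples with identical
pool-membership columns are mutually indistinguishable to every
decoder downstream.  A sub-move is accepted only if its own objective
does not decrease *and* the other view's minimum distance stays at or
above its value on entry, so the returned design dominates the input
in both minima.  The published experiments use 1000 iterations; that
is the package default.

## Noise model and simulator

Three noise sources enter the read-count model (`noise_params()`):

* **Concentration noise** $\sigma_p$ (default 0.05): each non-zero
  design entry becomes $\hat A_{tj} = \max(0, 1 + N(0, \sigma_p))$ —
  samples are never pipetted in exactly equal amounts.  The decoder
  can recover $\hat A$ from a calibration panel
  (`estimate_concentrations()`, per-pool non-negative least squares on
  known genotypes); the simulator hands the realized $\hat A$ to the
  decoder directly, i.e. calibration is assumed accurate.
* **Coverage dispersion**: per-individual coverage $m_i \sim
  \Gamma(\text{shape} = 6.3, \text{mean} = \lambda)$, the empirical
  dispersion of Illumina sequencers.  $\lambda$ is the expected reads
  *per chromosomal copy*; a diploid individual contributes $2\lambda$
  on average.
* **Sequencing error** $\varepsilon$: each read is assigned to the
  wrong allele class with constant probability $\varepsilon$
  (binomial thinning in both directions).

`simulate_genotype_pools()` offers two read-generation conventions.
The default draws each individual's reads once ($R^1_i \sim
\text{Pois}(m_i g_i)$, $R^0_i \sim \text{Pois}(m_i(2-g_i))$) and mixes
them, $Y^k = \hat A R^k$ — the literal pooled-material reading, in
which one individual's coverage fluctuation appears coherently in all
of their pools.  `per_pool = TRUE` instead draws independent Poisson
reads in every (pool, individual) cell with mean $\hat
A_{tj}\lambda g_j$, which is exactly the independence structure the
decoder's likelihood assumes.  The benchmark driver defaults to the
per-pool model (`read_model = "per_pool"`): under the mixed
convention the coherent Gamma fluctuations (CV $\approx 0.4$) are
misattributed by any per-pool Poisson likelihood, and whole-site
accuracy collapses for *any* decoder of this family — the published
operating characteristics are only attainable when the simulation
noise matches the model the method itself states.  Both conventions
remain available for experimentation.

### Synthetic imputation priors

Real pipelines obtain per-individual genotype probabilities
$h_i(0..2)$ from an imputation engine run against a reference panel.
`simulate_imputation_priors()` is a calibrated synthetic stand-in:
with probability `concordance` the modal genotype is the truth,
otherwise a different genotype drawn by Hardy-Weinberg weight; mass
`confidence` sits on the mode and the remainder is split by
Hardy-Weinberg weight.  With `concordance = 0.955` the probability
that a 100-individual site is modally correct everywhere is
$0.955^{100} \approx 0.01$, reproducing the whole-site baseline of the
cohort experiments the defaults emulate.  `confidence` defaults to
0.95, a typical average posterior certainty for common-variant
imputation.  What this generator does *not* reproduce is the
calibration structure of real imputation output, where wrong calls
tend to carry visibly lower confidence and sit in linkage-poor
regions; synthetic wrong modes are as confident as right ones, which
makes them strictly harder to override than real ones.  Passing tests
therefore say nothing about linkage-disequilibrium-driven error
clustering in real data.

## The composite likelihood

Candidate genotype vectors $G$ are scored by the product (sum in logs)
of three independently specified terms (`composite_loglik()`):

* $f^{HW}$: the Hardy-Weinberg probability of the genotype counts at
  the allele frequency $\hat p$ estimated as the unweighted mean of
  per-pool minor-read fractions (`estimate_allele_freq()`).  The
  multinomial coefficient is omitted — it does not change the argmax
  over labelled vectors.
* $f^{noise}$: pool $t$'s minor count is Poisson with mean
  $\sum_j \hat A_{tj}\lambda\,[(1-\varepsilon)g_j +
  \varepsilon(2-g_j)]$, and the major count symmetrically; both allele
  classes are scored.  The $\varepsilon$ mixing is on by default
  (`error_adjust`), matching the simulator's thinning.  Mixed counts
  are generally non-integer: they are rounded by default, or evaluated
  with the gamma-function continuation (`continuous = TRUE`).
* $f^{imp}$: $\sum_i \log h_i(g_i)$ when a prior is available.

Zero-probability situations (a heterozygote at $\hat p = 0$, a
positive count with zero mean) yield a $-\infty$ sentinel rather than
an error.  Component weights are exposed and default to 1.

## LP decoding of genotypes

The pools should roughly satisfy $\lambda\hat A G = Y^1$, so the
decoder (`decode_lp()`) solves

$$\min_{0 \le x \le 2}\; \sum_t\bigl|\lambda(\hat A x)_t - y_t\bigr|
  \;+\; \beta\lambda \sum_i\,|x_i - I_i|$$

where $I$ is the imputation *dosage* $h_i(1) + 2h_i(2)$ (the
continuous expectation, not the rounded mode) and $\beta$ (default 1)
trades count fit against prior anchoring; the $\lambda$ scaling makes
the two terms commensurate, since a unit change of one genotype moves
roughly $\lambda$ reads in each of that sample's pools.  Rare variants
use the zero vector as anchor (`decode_rare()`), which is the
sparsity-promoting special case.  The $\ell_1$ objective is linearized
with slack variables; as a box-constrained $\ell_1$ regression it is
solved exactly by the Frisch–Newton interior-point method
(`quantreg::rq.fit.fnc`), and the attained optimum is reported as
`lp_objective` — a valid lower bound on the objective of every integer
genotype vector, which the test suite verifies directly.

### From fractional solution to genotypes

The LP solution is continuous.  `round_and_refine()` converts it to
integers in stages, all scored by the composite likelihood:

1. coordinates with fractional part outside $[0.2, 0.8]$ are rounded
   to the nearest integer;
2. the remaining ambiguous coordinates — at most `max_enum` (20) of
   them, nearest to half-integer first — are resolved by exhaustive
   enumeration of floor/ceiling combinations (the enumeration is
   evaluated incrementally: means, genotype counts and prior terms are
   affine in the bit pattern);
3. a *polish* pass applies, repeatedly, the best single-coordinate
   change or joint change of a pair of suspect coordinates (those whose
   LP value was not essentially integral) until no move improves the
   score; pair moves matter because two samples with similar columns
   can carry compensating errors that preserve every pool sum;
4. `restarts` (default 8 standalone, 4 per start inside `decode_lp()`)
   basin-hopping rounds perturb a few suspect
   coordinates at random and re-polish, keeping the best result, with
   the imputation modal vector tried as an alternative start.  The
   perturbations draw from a fixed internal stream, so decoding is
   deterministic given its inputs.

By default `decode_lp()` additionally refines the fractional solutions
of two LP variants — major-allele counts included in the fit, and a
four-fold stronger anchor — and returns whichever refinement the
composite likelihood prefers (`multi_start`).  Different anchor
strengths land the discrete search in different basins, and the
composite arbitrates; the reported `lp_objective` always belongs to
the primary LP.

Stages 3–4 and the multi-start address a real failure mode observed
during development:
designs of this family contain small-support integer vectors $v$ with
$\hat A v \approx 0$, so configurations wrong in 6–10 coordinated
genotypes can fit the counts almost as well as the truth, and no
sequence of one- or two-coordinate improvements connects them.  During
refinement the scorer drops terms common to every candidate (the
Poisson normalization and the constant $\mu^0_t + \mu^1_t$), which is
exact for comparisons and several-fold faster.

## Fusion-gene carrier detection

RNA from $N$ tumors is pooled; reads spanning exon junctions of two
different genes are counted per pool.  Carrier status is binary but
each carrier $j$ has an unknown relative expression $e_j$, constant
across pools, drawn log-uniformly on $[1, 10]$ in the simulator
("concentrations differ by up to a factor of 10" with the unit
baseline); pool counts are $Y = A(e \circ g)\lambda$ plus background.
The simulator default draws each carrier's reads once and mixes them
(`mixing = "per_individual"`, the $Y = AH$ convention); sequencing
error contributes spurious chimeric reads as per-pool Poisson
background at rate $\varepsilon\lambda$ (`error_model = "per_pool"`).
A per-sample background variant ($\varepsilon\lambda$ per pooled
sample, so background grows with pool size) is available; it makes
low-coverage detection essentially impossible and does not correspond
to the published operating points.

`detect_fusion()` runs the pipeline:

1. **Enumeration** of all carrier sets of size $1..k$ (default
   $k = 3$; $\sum_j\binom{100}{j} = 166{,}750$ sets).
2. **Least-squares screen** (`fit_expression_ls()`): for each set, fit
   $[\lambda A^*\,|\,\mathbf 1]\,x \approx Y$ by pseudo-inverse, where
   $A^*$ keeps the carrier columns and the all-ones column absorbs a
   shared per-pool error term; rank on the $\ell_2$ residual.  The
   screen runs in compiled code against a precomputed Gram matrix (one
   small solve per set) and keeps the best 100 candidates *of each set
   size*: larger sets always fit at least as well, so a single joint
   top-100 would contain only maximal-size sets and the true smaller
   set could never reach the next stage.
3. **Grid refinement** (`grid_search_refine()`): each survivor's
   expression values are optimized coordinate-wise over multiplicative
   grids (21 points spanning a factor 2, two sweeps, then one zoom
   pass at the previous grid spacing), under a Poisson likelihood with
   the background term above.  Expression is constrained to the
   plausible fold range $[1, 10]$ — without the lower bound an extra
   carrier with $e \to 0$ is a free parameter and candidate sets of
   different sizes are not comparable.
4. **Selection** by AIC: refined log-likelihood minus one per carrier
   (each expression level is a free parameter).  Two disjoint columns
   whose union equals a single carrier's column reproduce the counts
   exactly and tie in raw likelihood; parsimony resolves such ties
   toward the smaller set.  Residual ties fall back to
   smaller-set-then-lexicographic order.

All-zero counts produce an explicit no-call (empty carrier set).

## Benchmarks, seeds and problem sizes

`run_benchmark()` wires simulate→decode cycles under an
`experiment_config()`; a site or trial counts as correct only if
*every* genotype is right, or the *exact* carrier set is called.
Accuracy is reported with an exact binomial 95% CI.  A master seed
spawns per-trial substreams through `derive_seed()` (an affine map to
a 31-bit stream), so any trial is reproducible in isolation.  The
standard grids (`benchmark_genotyping_grid()`,
`benchmark_fusion_grid()`) run 100 sites or trials per configuration
at the published parameter points: 100 individuals; 36 or 30 pools at
coverage 150 and error 0.005 for genotyping; 4–10 pools, coverage
4–28, error 0.01, 1–3 carriers for fusion.  At these sizes a
genotyping site decodes in about a second and a fusion trial in under
one, so a full table sweep is minutes on one CPU.  The test suite runs
the same pipelines at these sizes.

## Known limitations

* The genotype decoder's likelihood assumes per-pool independent
  Poisson counts.  Under the mixed read convention with
  Gamma-dispersed coverage, whole-site accuracy degrades sharply; a
  decoder that models the shared per-individual coverage would need
  to deconvolve $R$ from $T < N$ equations, which is out of scope.
* Refinement is a heuristic search; the brute-force oracle
  (`brute_force_decode()`, $N \le 12$) shows it finds the composite
  argmax in the large majority of small instances, but hard sites
  with near-null design vectors can remain at suboptimal local
  optima.
* Fusion decoding assumes one fusion at a time, at most $k$ carriers,
  and expression inside a known fold range; the AIC constant (1 per
  carrier) is a model-selection convention, not a fitted quantity.
* The synthetic imputation prior is calibrated only in its marginal
  concordance; it has no linkage structure and its wrong modes are as
  confident as its right ones.
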