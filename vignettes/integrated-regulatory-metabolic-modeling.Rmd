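---
title: "Integrated regulatory-metabolic modeling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated regulatory-metabolic modeling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idream)
```

## The modeling problem

Constraint-based metabolic models predict growth from network stoichiometry
alone: flux balance analysis (FBA) maximises flux through a biomass reaction
subject to steady-state mass balance $S v = 0$ and per-reaction bounds
$lb \le v \le ub$. Plain FBA is blind to transcriptional regulation — it
cannot say anything about what happens when a transcription factor (TF) is
deleted, because TFs carry no flux. This package implements a family of
integration schemes that convert a TF$\to$gene influence network into
*probabilistic* flux constraints, so that TF-knockout growth phenotypes and
TF$\times$enzyme genetic interactions become predictable quantities.

The central quantity is a **retention probability**
$\Pr(\text{gene ON} \mid \text{TF OFF})$ for every regulated gene. When a TF
is deleted, each affected reaction's attainable flux range (its effective
$V_{max}$, obtained by flux variability analysis) is scaled by the retention
probability of its gating genes: the constraint is $V_{max} \cdot p$.
Growth under the knockout is then re-optimised by FBA.

Three variants differ in where the probability comes from:

* **PROM** — the classical conditional probability estimated from binarized
  expression: the fraction of TF-OFF samples in which the target is ON.
  Every edge of the supplied network is constrained this way.
* **IDREAM** — only edges that are both *inferred* from expression (with a
  bootstrap false discovery rate, below) and supported by *direct* binding
  evidence are constrained. A direct activator edge retains only FDR worth
  of activity after the TF is lost; a direct repressor edge retains
  $1 - \mathrm{FDR}$; indirect edges are left unconstrained.
* **IDREAM_hybrid** — direct edges as in IDREAM; indirect edges fall back
  to the PROM conditional probability.

The package is organised in the classic R modeling idiom: `idream()` is the
fitting function that assembles the constraint map (it needs the model, the
network, and — for the PROM-style variants — expression data), and the
fitted object answers through `predict()` (TF-knockout growth ratios),
`coef()` (the constraint map at gene or reaction level), `print()` and
`summary()`. Everything else — inference, FBA/FVA, scanning, statistics,
generators — is an exported function behind that surface.

## Bootstrap inference of the influence network

`infer_network()` is a desk-scale, per-gene sparse-regression replacement
for ensemble regulatory network inference. For each target gene it fits a
lasso of the target's expression on all candidate TF expressions, once per
random sample subset (default 200 subsets; tests and examples use 50), plus
a final fit on the full data set used only for sign and coefficient
reporting. The per-edge FDR is

$$\mathrm{FDR} = 1 - \frac{\text{subset models selecting the TF}}{\text{number of subset models}},$$

so a TF selected in 191 of 200 models has FDR $1 - 191/200 = 0.045$. Edges
with FDR at or below 0.05 (the default cutoff) enter the network. The FDR
doubles as the activator retention probability: the fraction of models *not*
finding the TF is read as the fraction of the target's activity that does
not depend on it.

Design choices in this module, made once and kept:

* **Subset construction.** Each subset draws $\lceil 63.2\% \rceil$ of the
  samples without replacement (`subset_fraction = 0.632`, the expected
  coverage of a bootstrap resample). The size is exposed because nothing in
  the estimator forces this number; the FDR is computed over however many
  subset models were fitted, never including the full-data model.
* **Regularization.** Within each subset the lasso penalty is chosen by
  5-fold cross-validation with the one-standard-error rule
  (`glmnet::cv.glmnet`, `lambda.1se`). The 1-SE rule is deliberately
  conservative: a false TF that sneaks into one subset's model at a tiny
  coefficient is cheap, but an edge must be selected in $\ge 95\%$ of
  subsets to pass the FDR cutoff, so per-subset sparsity directly controls
  the false-edge rate.
* **Sign.** Activator/repressor status is the sign of the marginal Pearson
  correlation between TF and target over all samples
  (`classify_sign()`; a sample mask can restrict this to a
  condition-relevant subset). An exactly zero correlation or a constant
  series is surfaced as an error, never silently resolved.
* **Evidence.** Inferred edges are born `indirect`. `annotate_evidence()`
  upgrades an edge to `direct` when a reference network (standing in for a
  curated binding-evidence database) lists the same (TF, target) pair as
  direct. Which evidence codes count as "direct" is the caller's decision;
  the column is never interpreted beyond the two tokens.

## From gene probabilities to flux bounds

Gene-level probabilities reach reactions through the gene-protein-reaction
(GPR) rules, with `and` mapped to `min` (a complex is as available as its
scarcest subunit) and `or` to `max` (isozymes back each other up); genes
outside the map and reactions without a GPR count as probability 1. When
several targets of one TF gate the same reaction through different GPR
leaves, this propagation resolves the combination — there is no
multiplicative stacking.

The scaled bound uses the flux range from FVA at
`fraction_of_optimum = 0` — the attainable range given all other network
constraints, with no requirement that growth stays optimal. This is a
configuration knob (`fraction_of_optimum`) because the choice is genuinely
open; 0 is the default because the constraint is meant to cap what the
reaction *could ever* carry, not what it carries at the optimum. For a
reaction with forward range max $V_{max} > 0$ the upper bound becomes
$p \cdot V_{max}$; a reversible reaction's reverse bound is scaled the same
way toward zero ($lb' = p \cdot V_{min}$ when $V_{min} < 0$). A direction
that FVA already pins to zero stays at zero regardless of $p$ — constraints
never resurrect a dead reaction.

**Soft vs hard constraints.** In hard mode the scaled bounds are strict; an
infeasible mutant LP is reported as zero growth with a flag, never as an
exception. The default is soft mode: fluxes may exceed a scaled bound at a
linear objective penalty of $\kappa \cdot g_{wt} / |V_{max}|$ per unit of
violation (per-reaction normalisation keeps the penalty commensurate with
growth units). The default $\kappa = 10$ was chosen so that on the toy
networks the penalty strictly dominates the marginal biomass return of one
unit of violating flux: at $\kappa = 1$ the two rates can tie exactly on a
linear pathway (one unit of bottleneck flux buys one unit of biomass and
costs one penalty unit), leaving the LP with a degenerate face of optima and
the reported growth at the mercy of pivoting order. $\kappa = 10$ removes
the tie while keeping the soft mode's defining property — growth never drops
below the hard-mode value, and the two converge as $\kappa \to \infty$
(verified to $10^{-4}$ in the tests). Structural gene deletions are never
softened: a GPR that evaluates to false pins the reaction to zero outright.

**Single-knockout semantics.** Only the deleted TF's edges constrain a
simulation. In double perturbations (`double_deletion_growth()`,
`scan_synthetic_pairs()`) the gene deletion enters the GPR propagation with
probability 0 *alongside* the TF's probabilities, so deleting one isozyme
exposes the TF's constraint on its partner — the mechanism that generates
synthetic (negative/aggravating) interactions. A pair is called synthetic
when its variation statistic

$$\mathrm{variation} = \frac{(\mathrm{Diff1} + \mathrm{Diff2})/2}{g_{wt}},
  \qquad \mathrm{Diff1} = g_{TF} - g_{double},\;
  \mathrm{Diff2} = g_{gene} - g_{double}$$

is strictly above 0.9 while both singles retain at least 95% of wild-type
growth. The strict inequality follows the "greater than 90%" reading; the
retention guard is inclusive ($\ge$).

## The LP solver

No linear-programming backend is assumed: `fba()`, `fva()` and the
soft-constraint problems run on an internal dense two-phase simplex
(Dantzig pricing with a switch to Bland's rule against cycling; primal
feasibility $10^{-9}$ at the solver, $10^{-6}$ at the assertion level). The
problems this package generates are tens of reactions, where a full-tableau
simplex is exact and fast. Degenerate alternate optima are accepted: only
objective values are contractual, never flux vectors. The test suite
cross-checks every fixture against an independent interior-point/simplex
implementation (SciPy's HiGHS interface, driven through the system Python)
to $10^{-6}$, and property tests assert mass balance, bound satisfaction,
FVA bracketing and deletion monotonicity.

## The synthetic benchmark and what it can show

`make_fixture()` generates the standard benchmark used by the recovery
tests: a toy metabolic network (12 serial capacity-limited steps, every
third gated by a two-gene complex, 4 isozyme-gated steps, 3 parallel branch
segments, intake bound 10), a planted regulon of 5 TFs with 8 target genes
each (signed influence $\pm 2$, 70% activators, half the edges labelled
`direct`), and a 200-sample expression compendium with additive Gaussian
noise (sd 0.2), 6 pure-noise decoy genes and a TF clamped to its observed
minimum in 20% of samples (so the OFF state actually occurs and
binarization stays meaningful).

The ground truth defines `direct` as *causal on enzyme availability*:
knocking out a TF removes the products of its direct activator targets
(applied as GPR-aware gene losses, then FBA), while `indirect` edges shape
expression but not enzyme function. This is exactly the asymmetry the
IDREAM scheme is built to exploit, and the generated data reproduce the
method's qualitative claims: the IDREAM variant recovers the planted growth
ratios (pooled correlation $\ge 0.8$, AUC at the 0.5 defect threshold
$\ge 0.9$ over ten seeds), and scores a higher AUC than the PROM variant,
which also constrains indirect and repressor targets and accordingly
predicts spurious defects.

The generator is linear-Gaussian because the inference stage is a sparse
linear regression — it is a deliberately favorable case, with `noise_sd`,
`effect_size` and decoy count as the difficulty dials. Passing recovery
tests on it demonstrates that the pipeline is implemented correctly, not
that it would perform equally on real compendia, whose shared-batch
covariance, nonlinearity, and indirect-correlation structure the generator
intentionally omits.

Problem sizes throughout the test suite (50 bootstrap subsets, ten seeds,
100 network permutations, against production defaults of 200 subsets and
500 permutations) were chosen as the smallest that leave the recovery
margins comfortable; all of them are parameters, so any user can re-run the
same checks at larger sizes.

## Evaluation statistics

`evaluate_predictions()` bundles the scoring used for knockout phenotype
benchmarks: Matthews correlation across a sweep of growth-defect thresholds
(a knockout is defect iff ratio strictly below the threshold), Pearson
correlation with p-value, sums of squared error, mean absolute residual and
rank-based AUC. Numerical conventions worth stating:

* An MCC denominator with a zero factor returns 0 (the standard convention)
  but carries a `zero_denominator` attribute; sweep thresholds where the
  *observed* calls are single-class are reported `NA` ("undefined"), never
  silently 0.
* Because the normalisation behind a single "normalized SSE" is not
  canonical, the report emits raw SSE, SSE$/n$ and
  SSE$/\sum(o_i - \bar o)^2$, each labelled.
* `permutation_test()` takes the whole pipeline as a closure and permutes
  either expression (each gene's row independently, keeping the gene count
  fixed; a whole-matrix shuffle is available by flag) or the network (each
  TF's connections redrawn from the target pool, keeping TF and gene counts
  and per-edge annotations). The p-value is the fraction of permutations
  whose MCC exceeds the observed one; with $n$ permutations its resolution
  is $1/n$, so small $n$ can only bound, not measure, significance.
* `fisher_z_compare()` implements the normal comparison of two
  correlations, $z = \operatorname{atanh}(r)$,
  $\mathrm{SE} = \sqrt{1/(n_1-3) + 1/(n_2-3)}$, two-tailed.

## Degenerate inputs and edge cases

* A TF absent from the network predicts ratio 1 by definition.
* A constant target gene yields an empty regulator selection (not an
  error); a constant series in sign classification is an error.
* PROM probabilities with fewer than `min_off_samples = 5` TF-OFF samples
  are left unconstrained (probability 1) with a warning rather than
  estimated from noise.
* Readers reject invariant violations (bound inversions, duplicate edges,
  out-of-range probabilities, non-finite expression) instead of repairing
  them; errors name the offending record.
* Gene identifiers are case-sensitive opaque strings; no systematic/common
  name mapping is attempted.

## Known limitations

* The simplex is dense; genome-scale models (thousands of reactions) would
  need a sparse LP backend. The module contracts would not change.
* SBML ingestion covers Level 3 core plus the `fbc` gene-association and
  flux-bound constructs — enough for models exported by standard
  constraint-based toolchains — and is read-only.
* The inference stage fits each target independently; it does not model
  biclusters, conditions, or temporal structure, and its FDR is a
  stability-selection frequency, not a frequentist error rate.
* Binarization-based PROM probabilities are only as good as the OFF-state
  coverage of the compendium; the `threshold_quantile = 1/3` default is the
  conventional lower tertile and is exposed as configuration.
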