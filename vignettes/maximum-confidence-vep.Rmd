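---
title: "Maximum-confidence aggregation and co-distillation for variant effect prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maximum-confidence aggregation and co-distillation for variant effect prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maxvep)
```

## The model

A sequence scorer assigns each position `t` of a protein a probability
distribution over the 20 canonical amino acids. The effect of substituting
amino acid `a` for the wild-type letter `wt_t` is scored by the
log-likelihood ratio

$$\mathrm{LLR}(t, a) = \log p(x_t = a \mid x) - \log p(x_t = wt_t \mid x),$$

computed from a single forward pass on the wild-type sequence
(wild-type-marginal scoring). Natural logarithms are used throughout.
Higher scores are more benign; the wild-type entry is exactly zero by
construction. The per-protein object is an `L x 20` grid (`llr_matrix`);
rows whose wild-type letter falls outside the canonical alphabet (X, U, B,
Z, ...) are masked rather than failing the protein, and log-probabilities
are floored at `log(1e-12)` so degenerate one-hot scorers stay finite.

Proteins longer than a scorer's context window (default 1022 residues, the
classic single-sequence transformer limit) are segmented into sliding
windows with 511-residue overlap; the last window is anchored to end at the
protein's final residue. When windows are stitched back, each position
keeps the score from the window in which it is most central, ties going to
the earlier window. The combination rule for the overlap is not uniquely
determined by the windowing scheme itself; most-central assignment was
chosen because it maximizes bidirectional context for every position, and
the equivalence `segmented == direct` for proteins within one window is
tested bit-for-bit.

## Maximum-confidence aggregation

Given `M` aligned score grids for one protein, the maximum-confidence
aggregate takes the elementwise minimum — for each variant, the prediction
of the model most confident that the wild-type residue is required:

```{r}
fam <- generate_family(8, 100, seed = 1)
sc <- make_blindspot_scorers(fam, detectability = list(A = "domainA",
                                                       B = "domainB"))
stack <- score_stack(list(A = score_llr(sc$A, fam$proteins[1, ]),
                          B = score_llr(sc$B, fam$proteins[1, ])))
agg <- aggregate_min(stack)
model_contributions(agg)
```

Averaging (`aggregate_mean()`) is the usual alternative and is also the
rule used to merge two finished models into a combined predictor (the
elementwise mean of their grids). Argmin bookkeeping breaks ties toward the
lowest model index, so contributions are deterministic; wild-type columns
are carried through aggregation but excluded from contributions, means and
filtering statistics.

Training-set curation uses the same grids: each segment is summarized by
the minimum aggregated score over its variant positions *excluding the
first* (the initiator methionine, which is trivially intolerant in most
annotations and would dominate the statistic), and segments whose minimum
sits above the 95th percentile of that distribution — segments where even
the most damaging predicted variant looks neutral — are dropped. The
percentile uses the linear-interpolation convention (`quantile(type = 7)`),
stated explicitly because the rule is sensitive to it at small segment
counts.

## When does the minimum beat the average?

The theory module models the scores conditional on the true class:
pathogenic and benign LLRs of `N` scorers are i.i.d. Gaussian with class
means `mu_p <= mu_b` and standard deviations `sigma_p`, `sigma_b`. Two
quantities govern everything: the separation `mu_b - mu_p` and the
dispersion ratio `sigma_p / sigma_b`. For a single scorer and for the
averaging aggregator the ROC AUC has closed forms
(`Phi(sep / sqrt(sigma_p^2 + sigma_b^2))`, with variances divided by `N`
for averaging). For the minimum, the aggregate score per variant is the
smallest of `N` draws, an order statistic with density
`N phi((x-mu)/sigma)/sigma (1 - Phi((x-mu)/sigma))^(N-1)`; the AUC
`P(min_benign > min_pathogenic)` is computed by adaptive quadrature of the
pathogenic minimum density against the benign minimum survival function
over a ±10-sd window (absolute tolerance `1e-8`). A seeded Monte-Carlo
oracle (`mc_auc()`, `mc_auc_pair()`) is the arbiter for the quadrature:
the test suite checks agreement within 0.005 at one million draws per
class.

```{r}
regime_map(separations = c(0.5, 1, 2), sigma_ratios = c(1, 4),
           n_models = 10)
```

With equal class dispersions, averaging is never beaten by the minimum
(beyond the 1e-3 tie tolerance); when pathogenic scores are several times
more dispersed than benign ones — exactly the signature complementary
blind spots produce — the minimum wins by a wide margin. AUC is always
`P(benign-scored above pathogenic)` with half credit for ties.

## Co-distillation

One round of co-distillation: all students score all proteins, the stacks
are aggregated (min or mean) into one fixed target grid per protein, each
target is shifted by a per-student constant so its pooled mean over
unmasked non-wild-type entries matches that student's own pooled mean (this
keeps each student's score scale stable), and every student then trains
independently toward the shared targets with a masked MSE loss (wild-type
and masked entries excluded). Targets are precomputed and frozen for the
round — the simplification that lets each student train independently —
rather than re-aggregated online; an online variant would recompute targets
each step and is deliberately out of scope.

The shipped students are window-linear scorers: like a language model they
predict a per-position logit for every amino acid — a linear function of
the one-hot encoding of the wild-type letters in a window of `radius`
residues (plus an intercept and, optionally, one indicator per position for
fixed-length protein families) — and emit
`LLR(t, a) = logit(t, a) - logit(t, wt_t)`. Wild-type zeros hold by
construction and the map stays linear in the weights, so full-batch
gradient descent with heavy-ball momentum (defaults: learning rate 0.5,
momentum 0.9, velocity reset at the start of each training run) converges
quickly and deterministically. The positional indicators are the capacity
knob: with them a student can represent any profile-style target exactly;
without them it is capacity-limited to local sequence context. Anything
implementing `score_llr()` and `student_fit_step()` — including a
heavyweight neural scorer — can be dropped in.

Multi-round schedules (`run_schedule()`) continue each round from the
students' previous-round state, written as aggregator tags per round
(e.g. `c("min", "mean")`). The per-round budget of 40 epochs used in the
demo and the study conditions deliberately does not saturate training, so
a follow-up round genuinely continues learning; with a saturating budget
the second round's targets equal the students' own converged scores and
nothing changes. Teacher-to-student knowledge distillation
(`knowledge_distill()`) is the same machinery with a single fixed teacher
and no mean shift, reporting held-out Spearman correlation between student
and teacher scores before and after training.

## What the synthetic data emulates — and what it does not

`generate_family()` draws per-column amino-acid distributions:
Dirichlet-distributed high-entropy columns in the background (concentration
5 by default — realistic surface-position variability) and consensus-mixture
columns inside domains (`conservation` 0.9 by default: the consensus letter
carries 90% of the mass). Ground truth per-position *sensitivity* is one
minus the normalized column entropy. Family members are drawn i.i.d. per
column — a star phylogeny; real families have phylogenetic correlation,
indels and length variation that this generator deliberately omits.

`make_blindspot_scorers()` estimates position-specific profiles from the
family's column counts (pseudocount 0.5) but replaces the columns of domains
*masked* for a scorer with the uniform distribution — that scorer emits
LLR exactly 0 there, a stylized version of a model that never learned a
domain. Two scorers with complementary masks reproduce the phenomenon that
motivates maximum confidence: each base scorer is nearly blind to half the
signal (AUC barely above 0.5 on labeled variants), the min-aggregate sees
all of it. The construction also yields the variance asymmetry the theory
needs: cross-model dispersion is much larger at pathogenic positions
(where one model says damaging and another says neutral) than at benign
ones (all models near zero).

Labeled variants get pathogenicity probability `0.03 + 0.94 * sensitivity`
(so both classes occur at realistic rates) with optional label noise and a
deterministic threshold rule for separability tests; benign variants draw
higher synthetic allele frequencies (Beta(2, 20)) than pathogenic ones
(Beta(1, 200)) and 10% of frequencies are missing, mirroring population
databases. DMS assays are a monotone function of ground-truth fitness plus
Gaussian noise; `inverted = TRUE` makes variants deviate from the wild-type
value in a random direction, so only the `abs(x - WT)` transform recovers
the deleteriousness signal. Summary statistics follow
`beta_v = gamma * severity_v + e`, `e ~ N(0, se^2)`, with severity affine
in sensitivity and clipped to `[0, 1]`; the gene-level missense p-value is
a Fisher combination of the per-variant p-values — a *synthetic surrogate*
for a SKAT-O-style test, labeled as such, since the real test needs
individual-level genotypes. The pLoF burden direction is tied to `gamma`
so direction-concordance is well defined.

Passing tests on these generators show the machinery is correct under the
assumed statistical structure; they do not show that any particular real
scorer has Gaussian class-conditional scores, independent ensemble members,
or blind spots of this stylized form.

## Evaluation suite conventions

* **Orientation** — scores are benign-high everywhere. Calibration
  (`calibrate_scores()`) fits a logistic regression on a class-balanced
  sample (default 1000 variants) and maps scores to the probability of
  *pathogenic*, so 0.5 is the induced classification threshold and the
  pathogenic class mean sits above 0.5 on separable data.
* **AUC** — Mann-Whitney with average ranks (ties get half credit);
  undefined (error) on single-class input. Balanced bootstrap AUC draws
  `resample_size / 2` per class with replacement.
* **Per-gene AUC** — genes need at least 10 labeled variants and both
  classes; per-gene balancing subsamples the majority class to
  `min(n_p, n_b)` without replacement.
* **Accuracy-coverage** — variants with calibrated scores inside
  `(0.5 - t, 0.5 + t)` are excluded per threshold `t`; accuracy is the mean
  of per-class accuracies on the remainder, repeated over calibration
  resamples (bands at ±2 sd).
* **Binary metrics** — AUC, average-precision AUPRC (implemented step-wise,
  tested against a hand oracle), accuracy, F1, MCC, and diagnostic odds
  ratio with a +0.5 continuity correction applied to all cells when any
  cell is zero.
* **DMS** — per-assay Spearman with average-rank ties; constant assays are
  skipped with a warning; the aggregate is an unweighted mean with an
  optional per-protein grouping hook (real benchmark weighting schemes live
  in external scripts, so the hook is the contract here). Win rates use
  strict inequality, so ties credit neither model, and the rank score uses
  ascending average ranks.
* **MAF** — `min(AF, 1 - AF)` with missing frequencies set to 0: a variant
  absent from the population database is treated as maximally rare, which
  is the conservative choice for rare-disease filtering.
* **Association** — Pearson correlation (standardized slope) between
  per-variant scores and effect sizes with the two-sided product-moment
  test; no multiple-testing adjustment (the benchmark reports raw
  per-pair p-values); p-values floored at `1e-300` before `-log10`;
  direction concordance among pairs with regression `p < 0.1`; the
  allele-frequency baseline is the same regression on `log10(MAF + 1e-6)`.

## Numerical choices and degenerate inputs

Quadrature uses `stats::integrate` on a ±10-sd window (tolerance `1e-8`);
beyond that window the order-statistic integrand is below machine
precision for any `N` up to the hundreds. Gradient descent on the
window-linear students is stable at learning rate 0.5 because the one-hot
design matrix bounds the loss curvature; non-finite losses abort training
with a clear error rather than propagating NaNs. Empty stacks, single-class
AUC inputs, constant regressors, all-masked grids, zero-epoch configs,
overlap ≥ window, and re-applied WT transforms all error early with
descriptive messages. Calibration on perfectly separable data triggers
`glm` convergence warnings by construction; these are muffled because the
fitted monotone map is still exactly what the procedure requires.

## Problem sizes

The shipped study conditions are families of 12 proteins of length 120 with
two conserved domains, 40 labeled variants per protein at 5% label noise,
40-epoch co-distillation rounds, 300-epoch knowledge distillation, 20-spec
theory checks at one million Monte-Carlo draws per class, and 2000 null
gene-phenotype pairs for the type-I-error check. These sizes make every
property measurable with comfortable statistical margins while the entire
suite runs in a few minutes on a single CPU.

## Known limitations

The theory treats ensemble members as independent; real model families are
correlated, which shrinks the effective `N` and the benefit of both
aggregators. The window students cannot extrapolate positional knowledge to
proteins longer than their training length (positions beyond the indicator
block fall back to local context only). The synthetic allele-frequency
spectrum is a convenience, not a population-genetics model; and the
Fisher-combination gene p-value is a stand-in whose null behavior differs
from SKAT-O under variant correlation.
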