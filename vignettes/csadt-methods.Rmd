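---
title: "Crow-search wrapper feature selection: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Crow-search wrapper feature selection: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csadt)
```

## The problem and the method

Diagnostic feature tables — vocal measurements, handwriting-trace
descriptors and the like — often carry hundreds of columns of which only a
few discriminate patients from controls. `csadt` selects such a subset by
*wrapper* search: candidate subsets are scored by actually training and
evaluating a classifier on them, and a metaheuristic proposes the
candidates.

The metaheuristic is the **crow search algorithm (CSA)**. A flock of $N$
crows lives in a continuous box $[X_{\min}, X_{\max}]^d$, one coordinate
per feature. Each crow $i$ remembers the best position it has found
($m^i$). At every iteration each crow picks another crow $j$ uniformly at
random and either

* **follows** it (probability $1 - AP$):
  $x^{i} \leftarrow x^{i} + r_i \cdot fl \cdot (m^{j} - x^{i})$, with
  $r_i \sim U(0,1)$ drawn fresh per move, or
* **escapes** (probability $AP$, the *awareness probability*): the
  followed crow notices pursuit and the mover relocates uniformly in the
  box.

Proposals leaving the box are rejected (the crow stays put); memories are
replaced on strict improvement only. With flight length $fl \le 1$ the
follow move searches the segment between the crow and the followed
memory; $fl > 1$ can overshoot it, giving more global moves.

Continuous positions become feature subsets through an S-shaped
**transfer function with a random threshold**. Each coordinate $x$ maps
to $\sigma(x) = 1/(1+e^{-x})$, then to a bit by comparing one fresh
uniform draw against it. The package's default direction follows the
method's printed rule, under which $P(\text{bit}=1) = 1 - \sigma(x)$
(negative coordinates mean "select"); the conventional direction
($P(\text{bit}=1) = \sigma(x)$) is available as
`direction = "standard"`. The two are mirror encodings — negating the
position swaps them — so the choice fixes a sign convention, not the
reachable subsets.

Each mask $R$ is scored by the wrapper fitness, minimised by the search:

$$\text{Fitness}(R) = \alpha\,\gamma_R(D) \;+\; \beta\,\frac{|R|}{|N|},$$

where $\gamma_R(D)$ is the error rate of a classifier trained on the
masked training partition and evaluated on the masked evaluation
partition, $|R|/|N|$ is the selected-feature fraction, and
$\alpha + \beta = 1$. The inner classifier is a CART decision tree by
default; k-NN, naive Bayes, an MLP, SVMs and a random forest are
available for comparison tables.

Before searching, every feature column is min–max normalised:
$v \mapsto \text{new}_{\min} + \frac{v - \min_x}{\max_x - \min_x}
(\text{new}_{\max} - \text{new}_{\min})$.

## Parameters that matter

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `crows` ($N$) | flock size | 20 | common CSA benchmark setting |
| `iterations` | CSA iterations | 100 | budget $N(iter+1)$ classifier fits |
| `flight_length` ($fl$) | follow-step multiplier | 2 | mixes local and overshooting moves |
| `awareness_prob` ($AP$) | escape probability | 0.1 | mostly exploitation, some diversity |
| `bound` | continuous box half-width | 4 | $\sigma(\pm4)\approx0.018/0.982$: near-deterministic bits without flat saturation |
| `alpha` / `beta` | fitness weights | 0.99 / 0.01 | classification quality must dominate; parsimony breaks ties |
| `holdout_fraction` | evaluation partition | 0.2 | stratified; frozen per run |

The source method never reports its own $N$, iteration count, $fl$, $AP$
or $\alpha/\beta$; the defaults above are the standard settings of the
surrounding literature and are all exposed as arguments.

## Numerical and design choices

* **Minimisation convention.** The memory-update rule is sometimes
  printed in a maximisation form; the fitness being error-plus-penalty
  forces minimisation, so memories are replaced when the new fitness is
  *strictly lower*. Ties keep the old memory (stability, no extra
  evaluations).
* **Frozen split.** The evaluation split is drawn once per run from its
  own seed and reused for every fitness call. A stochastic split would
  make the objective noisy and the best-memory trace non-monotone;
  freezing it makes every mask comparable and the whole run
  deterministic. k-fold evaluation (`protocol = "kfold"`) averages the
  error over stratified folds under the same freezing rule.
* **Empty masks.** An all-zero mask cannot train a classifier. The
  default policy scores it at the worst possible fitness
  ($\alpha + \beta = 1$) without training, preserving the fitness's
  functional form; `empty_mask_policy = "repair"` instead sets one random
  bit.
* **Constant columns.** Min–max normalisation divides by the observed
  range; a zero-range column maps to `new_min` with a warning, keeping
  the transform total and deterministic.
* **Reported mask.** The returned mask is the best mask actually
  evaluated, recorded at evaluation time. Re-binarizing the best memory
  row afterwards would draw new thresholds and could report a mask the
  optimizer never scored.
* **Seed discipline.** One master seed derives independent child seeds
  for the generator, the split and the optimizer stream; within the
  optimizer, draws occur in a fixed order (initial positions; then per
  iteration and crow: followed-crow choice, awareness draw, step fraction
  or escape coordinates; then binarization thresholds during evaluation).
  Identical seeds reproduce runs byte-for-byte, including written JSON
  reports. The decision tree runs with internal cross-validation disabled
  (`xval = 0`) so fitting consumes no randomness.
* **Normalisation scope.** Fitted on the full table by default, matching
  the usual practice for these pipelines; fitting on training rows only
  and applying with `clip = TRUE` is supported where leakage hygiene is
  preferred.

## What the synthetic generator emulates — and what it does not

`generate_synth()` builds binary-labelled tables from Gaussian
class-conditionals: informative columns whose class means sit
`class_separation` within-class standard deviations apart, optional
redundant columns (affine copies of informative ones plus jitter at 10%
of the source standard deviation — detectable but not trivial
redundancy), and pure-noise columns. Labels can be flipped at a stated
rate. Ground-truth informative indices travel with the table, which is
what makes selection quality testable at all. `emulate_profile()`
reproduces the *shapes* of four public Parkinson's-disease feature tables
(voice 194×23, spiral and meander 264×15, speech 756×754) with 20%
informative columns.

Real vocal and handwriting features are none of this: they are
correlated in blocks, heavy-tailed, and class-imbalanced, and their
informative set is not crisply defined. Passing tests on the generator
therefore demonstrate that the algorithm and its formulas are implemented
correctly and that the search finds objective optima — not that any
particular clinical accuracy will be reached on real tables.

A consequence worth understanding: with several *mutually redundant*
informative columns, the fitness optimum keeps only a small informative
subset — one separated column already classifies well, and $\beta$
rewards dropping the rest. "Recovering all informative columns" and
"optimising the wrapper fitness" are different goals, and this package
optimises the latter; the exhaustive-oracle test (all $2^{10}-1$ masks on
a 10-feature table) confirms the search reaches the true optimum of the
stated objective.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run, among smaller cases: the
5-dimensional sphere benchmark ($N=20$, 200 iterations, 20 seeds) against
an equal-budget random search; the exhaustive oracle on a 150-sample,
10-feature table (1023 masks, then 10 selection runs at $N=15$, 60
iterations); and a recovery study on a 200-sample, 20-feature table
(10 selection runs at the package defaults). These sizes were chosen so
each property is measured with enough replicates to be stable while a
full run stays comfortably interactive.

## Known limitations

* Binary classification only; multi-class labels are rejected.
* No adaptive $fl$/$AP$ schedules, V-shaped transfer functions or
  deterministic-threshold binarization.
* No nested cross-validation or hyperparameter tuning of the inner
  classifier; the wrapper's holdout accuracy is an optimistic estimate of
  generalisation because the same split drives the search.
* The subset-size penalty is linear; no Pareto treatment of the
  accuracy/parsimony trade-off.

## A worked example

```{r example, eval = FALSE}
g <- generate_synth(n_samples = 150, n_informative = 4, n_noise = 8,
                    class_separation = 3, seed = 5)
df <- as.data.frame(g$table$x)
df$label <- g$table$y

fit <- csadt(label ~ ., df, crows = 10, iterations = 30, seed = 5)
summary(fit)
coef(fit)          # 0/1 mask over the 12 columns
plot(fit)          # non-increasing best-fitness trace
predict(fit, df[1:5, ])
```
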