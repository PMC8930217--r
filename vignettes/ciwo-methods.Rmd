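---
title: "Chaotic invasive weed optimization for gene selection: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chaotic invasive weed optimization for gene selection: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Two-class microarray gene-expression studies pair a few dozen tissue
samples with thousands of measured genes. With p >> n, most classifiers
overfit badly unless the gene set is first reduced. `ciwo` implements a
wrapper feature selector built on invasive weed optimization (IWO) with a
chaotic initialization, and a plain two-hidden-layer feedforward network
trained by RMSprop as the downstream classifier. Everything in between —
preprocessing, evaluation protocol, file formats, and a synthetic data
generator with known ground truth — is included so the whole pipeline can
be exercised and validated offline.

```{r, eval = FALSE}
library(ciwo)
ds <- generate_dataset(synthetic_spec(effect_size = 3, seed = 42))
report <- repeated_evaluation(ds, n_iterations = 5, base_seed = 7)
report
```

## Preprocessing cascade

`run_preprocess()` applies, in order: log transform (base 2, pseudocount
1; expression intensities are right-skewed and the log makes them
roughly symmetric), replicate collapsing (rows sharing a gene id are
averaged over non-missing entries), per-gene mean imputation, a
flat-pattern filter (variance below 1e-6 on the log scale, i.e.
numerically constant rows), and per-gene standardization to mean 0 and
unit *population* SD (divisor n, so the postcondition is exact). The
filter runs before standardization so zero-variance rows never reach a
division. Centering is per gene, not per sample: per-gene scaling is
what removes the scale differences between genes that would otherwise
dominate any distance-based classifier; the choice is configurable
through `step_order` if a different convention is needed.

One consequence worth knowing: standardization divides each gene by its
pooled SD across *all* samples, and for a truly differential gene that
pooled SD includes the between-class separation. A gene with
standardized shift d ends up with shift `d / sqrt(1 + d^2/4)` after the
cascade. This is inherent to unsupervised per-gene scaling, affects all
downstream stages equally, and is one reason reported effect sizes in
this vignette refer to the generated (pre-scaling) values.

## The selection model

A candidate subset is a "weed": a continuous position in `[0,1]^N`
thresholded at 0.5 into a binary gene mask. The search iterates:

1. **Ranking and reproduction.** Weeds are ranked by fitness (1 = best)
   and spawn `Round(s_min + (s_max - s_min) (N - rank)/(N - 1))`
   offspring (rounding half-up so results are platform-independent).
2. **Dispersal.** Offspring scatter around the parent with per-dimension
   Gaussian noise whose SD decays from `sigma_initial` to `sigma_final`
   as `((max_iter - iter)/max_iter)^n`, clipped back into the unit cube.
   Early iterations explore; late ones refine.
3. **Competitive exclusion.** When the population exceeds `p_max`, only
   the `p_max` best survive (ties broken by fewer selected genes, then
   insertion order), so the incumbent best always survives — the best
   fitness in the history is non-increasing by construction.

The initial population is drawn by modulating uniform positions with
consecutive values of the logistic map `x' = u x (1 - x)` at `u = 4`,
which is chaotic and ergodic on (0,1). Start values 0.25, 0.5, and 0.75
are rejected because the map collapses there (0.75 is a fixed point; 0.5
maps to 1 and then sticks at 0). Chaotic modulation is a cheap way to
decorrelate the initial masks without a second RNG stream.

**Fitness.** `alpha * err + beta * |Y|/|T|`, with `err` the stratified
5-fold cross-validated misclassification rate of an inner classifier on
the candidate genes Y, and `|T|` the total gene count. Defaults
`alpha = 0.99`, `beta = 0.01`: accuracy dominates and the size term
breaks ties toward smaller subsets. The empty mask is defined to have
`err = 1` rather than being an error, so the search space is closed and
the exhaustive oracle can share the convention. The default inner
classifier is nearest class centroid — deterministic and cheap, which
matters because the fitness is called thousands of times; a small
network (`inner_classifier = "dnn"`) is available for final-stage runs.
Whether the error term is training, hold-out, or CV error was an open
choice; CV was chosen as the standard wrapper-selection practice.
Fold assignments are fixed by `cv_seed` for the whole run so fitness is
a deterministic function of the mask. Ranks are recomputed each
iteration over the surviving population.

Default budget: `n_weed = 10`, `s_min = 0`, `s_max = 5`,
`sigma_initial = 0.5`, `sigma_final = 0.01`, `n = 3`, `p_max = 30`,
`max_iter = 50`. These follow the orders of magnitude customary in the
IWO literature and complete in minutes on a laptop at 2135 genes.
Repeated masks are served from a cache, so the reported evaluation
count is fitness *requests*, not unique model fits.

### What wrapper fitness does and does not optimize

A property users should understand before interpreting selected gene
lists: the CV error term *saturates*. On a dataset with a strong planted
signal, a handful of informative genes already drives the empirical CV
error to exactly zero, after which the fitness is indifferent between
masks that contain eight informative genes and masks that contain four
of them plus lucky noise genes — and the size penalty then actively
prefers the *smaller* set. Consequently the selector is a good
*classifier-support* finder and a poor *complete-gene-set* finder: its
precision (selected genes that are truly informative) is high on strong
signals, but its recall of the full planted set is bounded by however
few genes suffice for zero CV error. Better optimization of this
fitness lowers recall further. This is a property of the objective, not
of the optimizer, and it is shared by all wrapper selectors with
error-plus-size objectives; the acceptance suite measures it honestly
rather than hiding it.

## The classifier

A fully connected network with two ReLU hidden layers (default widths
64 and 32) and a 2-way softmax output. Losses: negative log-likelihood
`-log p[t]` (default, floored at 1e-12) or squared error
`||t - p||^2/2`; backpropagation uses the combined softmax delta
`p - onehot(t)` for NLL and the full softmax Jacobian for the squared
loss. Weights start from a scaled-uniform fan-in scheme,
`U(-sqrt(6/fan_in), sqrt(6/fan_in))`, biases at zero.

Training uses RMSprop: `G <- beta G + (1 - beta) g*g`,
`theta <- theta - alpha g / sqrt(G + eps)`, with `beta = 0.9`,
`alpha = 1e-3`, `eps = 1e-8`. Note the first steps from `G = 0` are
nearly sign updates of magnitude `~ alpha / sqrt(1 - beta)`; with many
uninformative inputs this moves noise weights as much as signal
weights, which is why the remaining hyperparameters lean conservative.

Epochs (200) and batch size (8) are package choices; nothing forces
them. The batch size is deliberately small: expression cohorts have
tens of samples, the network carries no explicit regularizer (no
dropout or weight decay by design), and small-batch gradient noise is
the one implicit regularizer available. Shuffling is seeded per epoch,
so training histories are bit-reproducible; ties in the predicted
class go to the lower class index.

## Evaluation protocol

`repeated_evaluation()` interprets "iterations" as repeated seeded
stratified hold-out: for each iteration a 70/30 stratified split is
drawn, feature selection runs on the training split only, the network
trains on the selected genes of the training split, and the test split
is scored once. Sensitivity, specificity, precision, accuracy, and
F-score (harmonic mean of precision and sensitivity) are reported as
percentages per iteration plus their arithmetic average; ROC/AUC is
computed by threshold sweep and trapezoid rule on the pooled test-set
probabilities. The tumor class is treated as positive. Preprocessing is
applied once to the full matrix before splitting; every step is
label-free, so no class information can leak — the test suite verifies
that permuting test labels leaves the selected mask and trained weights
bit-identical. Metrics are kept at full precision internally and
rounded to two decimals only in CSV export. Degenerate 0/0 metric
denominators yield 0 with a warning.

## The synthetic generator

`generate_dataset()` draws gene g in sample j as
`Normal(mu_g + s_g * delta_class, noise_sd)` with baseline
`mu_g ~ Normal(6, 1)` on the log2 scale. Informative genes get
`|s_g| = effect_size * noise_sd / 2` with the class direction
`delta = +/-1`, so the between-class standardized mean difference is
`effect_size`; the sign of `s_g` alternates across informative genes so
no single global mean filter can recover them. `raw_scale = TRUE`
exponentiates (base 2) to produce the right-skewed positive intensities
the log-transform step expects. Contamination is injected on top:
near-constant rows overwrite non-informative genes, replicated ids add
one noisy extra copy each (drawn from non-informative, non-flat genes so
the ground-truth set stays well-defined under collapsing), and missing
cells are set completely at random — matching the assumption behind
mean imputation. Defaults mirror a 2135-gene, 52-tumor/50-normal
prostate cohort with 50 informative genes, 1% missingness, 5 replicated
ids, and 10 flat genes.

What the generator does *not* emulate: probe-level physics (background,
saturation), batch effects, correlated gene modules, or informative
missingness. Passing tests therefore demonstrate correctness of the
algorithms under a clean additive model, not performance on any real
cohort.

## Numerical and degenerate-input choices

* Population SD (divisor n) in standardization; exact mean-0/SD-1
  postcondition.
* Rounding half-up in the seed-count formula (IEEE round-to-even would
  make offspring counts platform-dependent in edge cases).
* Logistic-map iterates are clipped to `[0, 1]` against round-off
  excursions; positions are clipped after dispersal.
* `sigma_final = 0` and `max_iter = 0` are accepted (pure endpoint
  cases); a singleton population has no rank spread and must be
  special-cased to `s_max` by callers of `seeds_for_rank()`.
* Exhaustive search refuses more than 16 genes (2^N masks).
* An all-missing gene row, a zero-SD row reaching standardization, and
  a mask/matrix length mismatch are hard errors naming the offender.
* All RNG use is seeded and scoped: functions restore the caller's RNG
  state, so library calls never perturb user scripts.

## Problem sizes used by the test suite

The suite validates the search against exhaustive enumeration on 8-10
gene problems (100 restarts), planted-gene recovery on 200-gene/120
sample cohorts (10 seeds), and the full pipeline on one
2135-gene/102-sample dataset with 5 hold-out iterations — sizes chosen
so the complete suite runs in a few minutes on a single core while
still covering the study-scale matrix shape.

## Known limitations

* Wrapper recall saturation, discussed above: selected gene lists are
  small support sets, not exhaustive differential-expression calls —
  use a filter statistic (e.g. moderated t) if completeness matters.
* The fitness overfits its fixed CV folds by construction; a held-out
  confirmation split is advisable before biological follow-up.
* The network has no regularizer beyond small batches and is meant for
  the post-selection feature space (tens to hundreds of genes), not the
  raw matrix.
* Only the logistic map is implemented for initialization; other
  chaotic maps are an extension point, and the scalarized fitness means
  no Pareto front over error/size is produced.
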