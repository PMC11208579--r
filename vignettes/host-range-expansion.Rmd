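---
title: "Modelling host-range expansion in parasitic mites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling host-range expansion in parasitic mites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acarange)
```

## The problem

Permanently parasitic mites complete their whole life cycle on a mammalian
host and disperse only by body contact. Most described species are recorded
from a single host species; a minority are multi-host generalists, and it is
the generalists that matter epidemiologically: they can jump to livestock,
wildlife and humans. `acarange` models the probability that an observed
single-host mite is — or will become — multi-host, from traits of the mite,
its host(s) and the environment, and provides a companion model for whether
a *pair of hosts* shares mites as a function of their phylogenetic distance
and geographic overlap.

Two statistical nuisances dominate this problem and shape the package:

* **Class imbalance.** Observed single-hosts outnumber multi-hosts roughly
  71:29. A naive classifier buys accuracy by calling everything
  single-host.
* **Unobserved multi-hosts.** A "single-host" label may only reflect thin
  sampling. Poorly studied species are the most likely to be mislabelled,
  so label noise is correlated with publication effort. Treating the
  single-host class as *unlabeled* rather than negative is one principled
  response (positive-unlabeled learning).

## The host-range model

The outcome for mite $i$ is $y_i \in \{0,1\}$ (multi-host). The model is a
binomial GLM on 13 predictors,

$$\mathrm{logit}\, \Pr(y_i = 1) = \mathbf{x}_i^\top \beta,$$

where $\mathbf{x}_i$ contains dummy-coded mite traits (host-immunity
contact level, ecto/endoparasitism, single/multi biogeographic region,
dispersal stage, precopulatory guarding), two *host availability* counts,
averaged host traits (litter size, log body mass, domestication), two
climate terms and a habitat-disturbance proxy. Three continuous predictors
— log body mass, mean monthly precipitation and mean monthly temperature
(in 0.1 °C units) — enter as natural cubic splines with two degrees of
freedom, giving a 19-column design including the intercept.

The two availability counts are the model's ecological core:

* `n_CPH_max` — co-distributed potential hosts: the number of *other*
  mammals whose range Jaccard overlap $J = |A \cap B|/|A \cup B|$ with the
  mite's host strictly exceeds 0.5; for multi-host mites, the maximum over
  observed hosts.
* `n_PSH10_max` — phylogenetically similar potential hosts: the number of
  other mammals at patristic distance strictly below 10; again the maximum
  over observed hosts.

Both cutoffs are strict ("exceeding 0.5", "smaller than 10"), a host never
counts itself, and the maximum over a mite's hosts is used because the
best-connected host is the most plausible bridge to a new one.

### Aggregation choices for multi-host mites

Continuous host traits are averaged on the raw scale and log transforms
applied afterwards (`log(mean(mass))`, not `mean(log(mass))`); the order of
operations is a genuine free choice and both are defensible — the
raw-then-log order is the package default because the averaged quantity
("the typical host") is what the log then linearises. Domestication is
aggregated with a logical OR: one domesticated host suffices to create the
anthropogenic contact opportunity the variable is meant to capture. Human
population density is logged as $\log(x+1)$ so hosts of entirely unpeopled
ranges remain usable.

### Spline and fitting details

With `df = 2` the natural-spline basis has one interior knot at the
training median and boundary knots at the training extremes; beyond the
boundary knots every basis column is exactly linear. Knots are *frozen*
from the training partition and reused when transforming holdout or
forecast rows, so no information leaks from evaluation data into the basis.
Fitting is iteratively reweighted least squares (relative deviance change
below $10^{-8}$, at most 100 iterations); Wald standard errors come from
the inverse Fisher information, and the likelihood, deviance and AIC are
case-weighted Bernoulli quantities, so doubling all weights doubles the
deviance without moving the estimates. Rank-deficient designs are refused
with the offending columns named; suspected separation is flagged on the
fit rather than silently penalised, keeping estimates comparable to
standard GLM output. Confidence intervals are Wald by default; profile
likelihood intervals are available via `odds_ratios(fit, method =
"profile")` since the reporting convention for published intervals of this
kind is usually unstated.

## Five strategies against imbalance and label noise

`fit_strategy()` implements five ways to fit the same 19-column model:

| name | mechanism |
|------|-----------|
| `none` | baseline GLM on the imbalanced data |
| `weighted` | case weight $0.2 + 0.8\,[\text{pubs} \ge 10]$, down-weighting under-studied species |
| `down` | majority class subsampled *without* replacement to minority size |
| `up` | minority class resampled *with* replacement to majority size |
| `pu_ada` | positive-unlabeled AdaSampling over a radial-kernel SVM |

The AdaSampling loop treats observed multi-hosts as the only trusted
labels. Unlabeled (observed single-host) rows start at positive-class
probability 0.5; each round they enter the training sample as negatives
with their current negative-class probability, an SVM with probability
calibration is fitted, and their probabilities are updated from its
predictions, until the largest change falls below $10^{-3}$ or `iterations`
(default 10) rounds elapse. The single-model variant is implemented; an
ensemble variant would average over rounds but the single model keeps the
final scores directly interpretable.

Strategies are compared with repeated stratified cross-validation (default
5 folds × 5 repeats) in which resampling or weighting is applied **only to
each fold's training portion** — assessment folds are never touched — and
with a final refit on the whole training set evaluated on an unmodified
holdout split (by default 1024:421, i.e. a 70.9 % train share, drawn as a
simple random split). Selection ranks by cross-validated AUC with F1 as
the tie-break. The metric suite treats *multihost* as the positive class;
AUC confidence intervals use the DeLong rank-based variance (the
`bootstrap` alternative was deliberately left out of scope).

## Forecasting and enrichment

`forecast_report()` scores the combined train-plus-holdout population with
unmodified features, builds the confusion matrix at cutoff 0.5 (strictly
greater), and extracts the *risk group*: observed single-hosts with score
strictly above a threshold (default 0.7). Per host order $o$ and threshold
$t$ the enrichment is

$$\Delta_o(t) = 100\cdot\frac{\#\{\text{risk group in } o\}}{\#\text{risk group}}
  - 100\cdot\frac{\#\{\text{single-hosts in } o\}}{\#\text{single-hosts}},$$

so each $\Delta$ column sums to zero and an order with no risk-group
members scores exactly $-$baseline. Single-host mites inherit their one
host's order; multi-host mites are excluded from the baseline because the
table concerns single-hosts only.

## The mite-sharing model

The bipartite mite-host table is projected onto hosts: an edge joins every
unordered host pair sharing at least one mite; hosts with no sharing
partner are excluded. For every pair of kept hosts the model regresses the
binary sharing indicator on a df = 2 natural spline of the patristic
distance, a linear geographic-overlap term, and a raw distance × overlap
interaction:

$$\mathrm{logit}\,\Pr(\text{share}) = \beta_0 + \mathrm{ns}(PD, 2)\gamma
  + \beta_1\, GO + \beta_2\, (PD \cdot GO).$$

The interaction uses the *raw* distance, not the spline basis, following
the printed model formula convention `ns(PD,2) + GO + PD:GO` (the stray
term in such formulas is read as the intercept). Distances above 300 — the
marsupial–placental gap — are recoded to 178, the largest within-placental
distance, so the model cannot overfit an empty region; values in
(178, 300], which should not occur, are left unchanged with a warning
rather than silently extended beyond the stated rule. Because pair counts
are massively concentrated at (large distance, zero overlap), pairs are
binned (distance width 20 on [0, 180], overlap width 0.1 on [0, 1]) and
each bin subsampled to at most 1000 pairs before fitting; the bin edges are
defaults exposed in `bin_spec()` since no canonical edges exist.
Predictions carry delta-method standard errors,
$se_p = p(1-p)\,se_\eta$.

## The synthetic-data generator

Real curated mite-mammal data cannot ship with the package, so every
downstream stage is exercised against a generator with known ground truth
(`generative_spec()`, `simulate_dataset()`). What it emulates:

* **Phylogeny** — a pure-birth ultrametric tree rescaled to a maximum
  patristic distance of 178. A birth-death-style tree is used rather than a
  coalescent one because its longer terminal branches reproduce the sparse
  close-relative structure of a species-level supertree (typically 0–3
  congeners within distance 10, not dozens).
* **Ranges** — contiguous grid-cell blobs; with probability `p_cluster`
  (default 0.7) a host's range is seeded next to its closest placed
  relative's, inducing the real-data correlation between relatedness and
  sympatry; most host pairs end up with zero overlap.
* **Host traits** — climate and human-density fields are smooth functions
  of the range centroid plus noise, so spatially close hosts share
  climates and the spline terms are estimable. At least two domesticated
  hosts are guaranteed per assemblage (a 5 % Bernoulli draw otherwise), as
  in any realistic mammal fauna, which also keeps the domestication dummy
  estimable in small simulations.
* **Labels** — the true multi-host probability is
  `plogis(c + x'beta)` with `beta` defaulting to the preferred host-range
  model's point estimates and the intercept `c` calibrated by root-finding
  so the population rate equals `multihost_base_rate` (default 0.286,
  matching the 71:29 imbalance). With all-zero coefficients the rate is the
  base rate exactly.
* **Extra hosts** — true multi-hosts gain 1–`k_max` extra hosts sampled
  with weight $e^{-PD/\tau}(1 + GO)$, $\tau = 25$ by default, so extra
  hosts are close relatives and sympatrics. $\tau$ has no empirical
  anchor and is deliberately exposed as a `generative_spec()` argument.
* **Label noise** — each non-primary host link is observed with
  probability $\text{pubs}/(\text{pubs} + 5)$; the primary host is always
  observed. True multi-hosts that lose all extra links become *planted
  unobserved multi-hosts*, concentrated among poorly studied species.

What it does **not** emulate: taxonomic structure in mite traits
(phylogenetic autocorrelation of feeding mode), real range shapes or
climate fields, heterogeneous per-study detection, and the curation noise
of a literature-derived database. Passing tests on synthetic data
therefore demonstrate the *machinery* — identifiability, leak-free
evaluation, directional behaviour of the strategies under plausible label
noise — not field validity on real mite records.

## Problem sizes and numerical tolerances used in validation

The package's test suite validates each numerical core against an
independent oracle (brute-force likelihood maximisation, concordant-pair
AUC counting, double-loop Jaccard and projection scans, a truncated-power
spline construction), and runs three simulation studies sized for stable
conclusions: host-range coefficient recovery on 20 replicates of 5000
noise-free mites requiring pooled 2-standard-error coverage of at least
90 % (measured coverage is the nominal ~95 %; per-coefficient-per-replicate
coverage is binomial, so the pooled rate is the stable statistic);
sharing-model recovery on 20 replicates of 20 000 pairs under the same
rule; and a directional study on 10 replicates of 1200 mites with planted
label noise, requiring down-sampling and PU sensitivity for the multi-host
class to beat the baseline in at least 8 of 10 replicates while baseline
specificity exceeds its sensitivity. The 1200-mite size gives each holdout
~70 positives, enough that per-replicate sensitivity differences reflect
the strategies rather than metric noise.

## Worked example

```{r example, eval = FALSE}
spec <- generative_spec(n_hosts = 120, n_mites = 1200, seed = 1)
sim <- simulate_dataset(spec)
features <- build_feature_table(sim$assoc_observed, sim$mites, sim$hosts,
                                sim$tree, sim$ranges)
split <- train_test_split(features, 1024 / 1445, seed = 1)
cmp <- compare_strategies(split$train, split$test,
                          config = pipeline_config(folds = 5L, repeats = 2L),
                          seed = 1)
cmp$ranking$table
model <- cmp$models[[cmp$chosen]]
orders <- mite_host_orders(sim$assoc_observed, sim$hosts)
forecast_report(model, features, unname(orders[features$mite_id]))
```

## Known limitations

* Hosts absent from the phylogeny or range file are reported and dropped;
  no grafting onto the tree is attempted (how such hosts were handled
  upstream in real analyses is unknown, so the conservative option is
  exposure, not imputation).
* The PU implementation is the single-model AdaSampling variant with fixed
  SVM hyperparameters; no kernel or cost tuning is done inside the loop.
* Enrichment deltas are undefined (NA, with a warning) for a threshold
  whose risk group is empty rather than extrapolated.
* `predict_sharing()` refuses inputs outside the recoded distance range
  [0, 178] and overlap range [0, 1]; it does not extrapolate.
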