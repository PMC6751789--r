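---
title: "Consensus ICA deconvolution: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus ICA deconvolution: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Bulk expression profiles are mixtures. A biopsy contains tumour cells,
stromal and immune infiltrate, and adjacent normal tissue, and the
measured profile of each sample is a weighted superposition of the
transcriptional programmes active in those populations. `cicada` models a
features-by-samples matrix $E_{nm}$ (log-scale expression of $n$ genes or
miRNAs in $m$ samples) as a product of $k$ statistically independent
source signals:

$$E_{nm} = S_{nk} \times M_{km}$$

where the columns of $S$ (*metagenes*) hold each feature's contribution to
one component and the rows of $M$ (*metasamples*, or weight rows) hold
that component's involvement in each sample. Unlike non-negative
factorisations, both matrices are signed, and the sign and order of
components are arbitrary up to convention.

Identifiability rests on the classic ICA assumptions: sources are mutually
independent and non-Gaussian (at most one Gaussian source is tolerated).
Transcriptional programmes fit this well — a cell-type signature is a
sparse, heavy-tailed pattern over genes, far from Gaussian. The estimation
engine is the FastICA fixed-point algorithm (logcosh contrast, symmetric
extraction of all components at once, whitening via the SVD of the sample
second-moment matrix), implemented in the package itself and validated
against ground-truth mixtures in the test suite.

## Why consensus

A single ICA run depends on its random initialisation, and some components
are not reproducible. `consica()` therefore repeats the decomposition `nt`
times, each time excluding one uniformly drawn sample (leave-one-out
resampling, so each run also sees a perturbed cohort), aligns every run to
a standard run by greedy matching on absolute metagene correlation
(resolving the permutation and sign ambiguity), and averages the aligned
metagenes into a consensus $S$. The mean squared correlation between the
aligned run metagenes and the consensus metagene is the component's
*stability* $R^2 \in [0,1]$: reproducible components score near 1, noise
directions visibly lower. Production analyses use hundreds to a thousand
runs; the package's own checks use tens, which is where the
stability separation already appears at the problem sizes below.

Two details of the consensus are genuine design choices, since averaging
run matrices leaves them open:

* **Excluded-sample weights.** Each resampled run lacks one sample's
  weights. Every run's full weight matrix is recomputed by least-squares
  projection of the complete matrix onto the run's metagenes
  (`project_weights()`), so the average is over complete matrices.
* **Consensus weights.** The consensus $M$ is the projection of $E$ onto
  the consensus $S$ rather than the average of per-run weights. The two
  agree in the noiseless case; projection guarantees the factorisation
  identity $E \approx S M$ holds for the reported pair.
* **Normalisation.** FastICA fixes source variance only up to convention,
  so consensus metagenes are rescaled to unit standard deviation and the
  scale absorbed into $M$. A fixed convention makes stability values and
  top-contributor thresholds comparable across components and runs.
* **Convergence.** The fixed-point iteration uses tolerance `1e-4` and up
  to 1000 iterations (both configurable). Runs that stop at the iteration
  cap still enter the consensus by default: deliberately over-decomposed
  fits (choosing $k$ above the effective source count is a standard probe)
  rarely reach tolerance in the excess directions, and their instability
  is precisely what the stability metric exists to expose. The strict
  alternative — discard non-converged runs, abort when more than half fail
  — is available via `use_runs = "converged"`.
* **Determinism.** The master seed drives two sub-streams (exclusion
  sequence, per-run initialisations), so a fit is bitwise reproducible
  given `(k, nt, seed)` regardless of how runs are scheduled.

## Preprocessing heterogeneous inputs

The decomposition assumes inputs on a comparable log-like scale, and the
`io_preprocess` functions provide the standard route:

* `filter_features()` — soft count filter, strictly greater than
  `min_value` in at least `min_samples` samples (defaults 1000 and 1 for
  mRNA; use `min_value = 0` for miRNA, i.e. at least one read).
* `log_transform()` — $\log_2(x + 1)$ by default. The pseudocount is
  configurable; 1 is the common convention for count data.
* `invert_ct()` — qPCR Ct tables become expression-like via
  $36 - \mathrm{Ct}$, with missing values and Ct above the detection limit
  replaced by the limit (36 cycles), so undetected miRNAs score 0.
* `harmonize_to_reference()` — microarray intensities have a very
  different dynamic range from RNA-seq log-counts; an affine map fitted by
  robust moment matching (median/MAD of the pooled value distributions;
  mean/sd available via `method = "sd"`) brings a new cohort onto the
  reference scale. Robust moments are the default because microarray
  pools are routinely heavy-tailed.
* `concat_datasets()` — column-binds cohorts on the feature intersection
  and emits batch labels. Joint decomposition of a large discovery cohort
  with a small investigation cohort is deliberate: the cross-platform
  offset is itself a near-constant signal over features and ICA isolates
  it in a dedicated component instead of letting it contaminate the
  biological ones. The batch-isolation check below tests exactly this.

Missing values outside Ct tables are rejected at load time rather than
imputed; imputation policy is the caller's responsibility.

## Significance of contributing features

Within a metagene the bulk of features is approximately normal background;
the features that drive the component sit in the tails. `top_contributors()`
scores each feature as $z = (s - \mathrm{median}(s)) /
(1.4826\,\mathrm{MAD}(s))$ — robust centre and scale, so the outliers being
tested do not inflate the background estimate; the 1.4826 factor makes MAD
consistent for a normal — converts to two-sided normal p-values, adjusts
by Benjamini–Hochberg across the component's features, and reports
features with adjusted $p <$ 0.01 split into positive and negative
contributors. Two-sided tails are used because both signs are reported and
meaningful. A constant metagene (MAD 0) is an error, not a silent empty
result.

Component sign is arbitrary, so components are oriented
(`orient_components()`) to put the informative side on top: with gene-set
enrichment available, the side with the stronger best enrichment goes
positive; without it, the side with more significant contributors. miRNA
components, which lack useful set annotation, are instead oriented by
their most-correlated mRNA component (`orient_mirna_by_link()`): a strong
negative weight correlation ($r < -0.5$ by default; "strong" is a
convention, exposed as a parameter) flips the component. All orientation
operations negate a metagene column and its weight row together, leaving
$S \times M$ unchanged, and are idempotent.

Annotation against user-supplied resources is deliberately generic: a
hypergeometric over-representation test for GMT gene sets or miRNA
cytoband sets (`hypergeometric_enrichment()`, BH across sets), and
highest-absolute-correlation matching against reference signature matrices
of cell-type profiles (`best_signature_match()`). No annotation databases
are bundled.

## Survival: per-component screen and the risk score

`cox_per_component()` fits one univariable Cox proportional-hazards model
per weight row, on weights standardised to unit variance so log-hazard
ratios (LHR) are per standard deviation of component involvement and
comparable across components. The log-rank (score) test p-values are BH
adjusted across the $k$ components. The risk score standardises weights by
definition; the same standardisation is applied inside the Cox fit for
coherence — LHR magnitudes are otherwise scale-dependent and meaningless
to compare.

The risk score of sample $j$ combines every significant component:

$$RS_j = \sum_{i=1}^{k} H_i\, R^2_i\, M^{*}_{ij}$$

with $H_i$ the LHR where the adjusted p is below 0.05 and 0 otherwise,
$R^2_i$ the component stability (so unstable components are down-weighted
even when nominally significant), and $M^{*}_{ij}$ the weight standardised
by the *discovery-cohort* mean and sd of that weight row. The
standardisation parameters are frozen in the model object and reused when
scoring new cohorts — recomputing them on a validation set would leak its
distribution into the score. The score is invariant to the ICA sign
convention (flipping a component flips both its LHR and its standardised
weights), additive over significant components, and identically zero when
nothing passes the threshold. For two-group displays the package splits at
the median score (`risk_groups()`); the median is a convention, stated as
such.

Weight-based classification (`classify_and_validate()`) trains a random
forest with default hyperparameters on weight columns and reports
leave-one-out cross-validated accuracy, per-class sensitivity/specificity
and out-of-fold vote fractions. `select_num_components()` chooses $k$ by
nested cross-validation: hold out 20% of samples, decompose the remainder
at each candidate $k$, score LOOCV accuracy, and take the smallest $k$
within one standard error of the best — the one-standard-error rule
favours the parsimonious end of a typically flat accuracy profile.

## Linking layers and projecting new samples

`link_components()` correlates weight rows of two decompositions (mRNA and
miRNA layers, or one layer against itself) over shared samples and keeps
pairs with $r^2$ strictly above 0.25 (i.e. $|r| > 0.5$) as edges;
`cluster_components()` reports connected components of that graph. Nothing
finer than connected components is computed — the linking evidence is a
thresholded correlation, and community detection would suggest structure
the statistic does not support.

For a new sample, raw weights are not comparable across components (they
are neither centred nor scaled), so `ranking_score()` re-expresses a
weight as its quantile position within the discovery cohort: the fraction
of discovery weights below it, mid-rank for ties, clamped to 0 below the
discovery minimum and 1 above the maximum. A score near 0.5 means the new
sample is unremarkable for that component. The mid-rank tie convention and
the denominator $m$ are stated choices; no density smoothing is applied.

## The synthetic-data generator

`simulate_mixture()` generates the conditions the model assumes, with
ground truth retained: unit-scale Laplace sources (the simplest
super-Gaussian family satisfying ICA identifiability; a sparse-spike
variant mimics marker-gene metagenes), standard-normal mixing weights,
additive Gaussian noise, and optionally an additive per-feature offset on
a trailing sample block emulating a cross-platform cohort shift. In the
batch scenarios used for validation the offset sd is 3 — the same order as
the marginal biological signal sd ($\sqrt{2k} \approx 3.2$ for the default
five-source scenario) — representing a platform shift comparable to
biological variation, as observed when cohorts from different assays are
pooled. `simulate_survival()` draws exponential event times with hazard
$\propto \exp(\beta w)$ on a chosen component's standardised weights, with
uniform censoring whose horizon is tuned by bisection to the requested
censoring fraction. `simulate_labels()` derives binary (sign) or ternary
(tertile) classes from a driver component, with optional label noise.

What the generator does *not* emulate matters for interpreting green
tests: real data have correlated (not independent) programmes, count-level
noise rather than additive Gaussian noise, batch effects that are not
purely additive, and far murkier effective source counts. Passing the
recovery checks shows the machinery is correct under the model's own
assumptions; it does not certify performance on any particular cohort.

## Validation problem sizes

The package's validation suite runs on deliberately modest sizes, chosen
so the full battery stays in the minutes range while every property has
room to fail: source recovery on $2000 \times 100$ matrices with five
sources, noise sd 0.1, $nt = 20$ over ten seeds; reproducibility
comparisons at $nt = 2$ versus $nt = 50$ on over-decomposed ($k = 7$)
noisy five-source data; survival recovery at $m = 300$ with 30% censoring
over 100 replicates; calibration of the significance model on 5000-feature
null metagenes over 100 replicates. `scripts/acceptance.R` recomputes the
same quantities from scratch at these sizes and writes them as JSON.

## Known limitations

* $k$ is not estimated automatically from information criteria;
  `select_num_components()` optimises a classification objective, which
  requires labels.
* The FastICA core extracts all components symmetrically; deflation-mode
  extraction is not offered.
* Runs execute sequentially; results are defined to be identical to
  sequential execution for any scheduling, which is the portable contract,
  and no GPU or multi-process backend is shipped.
* No annotation content (GO, pathway, cytoband databases) is bundled;
  enrichment is only as good as the user-supplied sets.
* Cox screening is univariable by design; no penalised or multivariable
  survival models, and no competing-risks handling.
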