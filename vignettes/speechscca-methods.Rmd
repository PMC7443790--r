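---
title: "Linking speech features to clinical and brain measures with sparse CCA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking speech features to clinical and brain measures with sparse CCA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speechscca)
```

## The analysis this package implements

Individuals at clinical high risk (CHR) for psychosis show subtle
disturbances in the semantic and syntactic organization of natural speech.
This package implements a complete, testable pipeline for studying how
automatically derived linguistic features covary with clinical symptom
scores and with brain structural and functional-connectivity measures:

1. **Linguistic features** from raw interview transcripts: amount-of-speech
   statistics (minimum, maximum, mean and sample standard deviation of words
   per sentence), semantic coherence of consecutive sentences under a latent
   semantic analysis (LSA) space, and Penn Treebank part-of-speech tag
   relative frequencies.
2. **Brain features**: within-network cohesiveness and hub-centred network
   integration from resting-state node time series grouped by a six-network
   atlas (LAN, DMN, ECN, SAL, SMN, AN), and validated morphometry tables
   (68 Desikan–Killiany cortical thickness + 20 subcortical volume features).
3. **Site harmonization** of the imaging blocks by parametric empirical-Bayes
   location/scale adjustment (ComBat).
4. **Sparse canonical correlation analysis** (sCCA) by penalized matrix
   decomposition (PMD), with sparsity chosen by grid search and inference by
   a permutation test against the null distribution of *maximal* canonical
   correlations.

A synthetic-data module generates transcripts, time-series panels,
morphometry and metadata with known ground truth, so that every stage — and
the pipeline end to end — is testable without access to clinical data.

## The sparse CCA model

Given two z-scored blocks $X\ (n \times p_1)$ and $Y\ (n \times p_2)$
sharing subject order, a canonical mode is a pair of weight vectors
$(u, v)$ maximizing the penalized cross-block covariance

$$\max_{u, v}\; u^\top X^\top Y v
  \quad \text{s.t.}\quad \|u\|_2 = 1,\ \|u\|_1 \le c_1,\
  \|v\|_2 = 1,\ \|v\|_1 \le c_2 ,$$

solved by alternating soft-thresholded power iterations on $M = X^\top Y$
(`pmd_rank1()`), initialized at the leading singular pair of $M$.  Each
update projects a gradient direction onto the intersection of the L2 sphere
and the L1 ball (`l1_unit_project()`); the threshold is found by bisection
to $10^{-10}$, and when the budget is below what any spread over tied
maxima can achieve, ties break by index order (one-hot solution).  The
reported canonical correlation $r$ is the Pearson correlation of the
subject scores $Xu$ and $Yv$.  With the budgets at their maxima
($c_i = \sqrt{p_i}$) the constraint is inactive and the mode equals the
leading singular pair of $M$ — a property the test suite checks to
$10^{-6}$.

**Sparsity selection.** `grid_search_sparsity()` fits every point of a
$10 \times 10$ grid linear on $[1, \sqrt{p_i}]$ (the feasible range of the
L1 budget) and keeps the point with maximal $r$, ties going to the sparser
model.  This "maximal correlation" rule is the selection criterion of the
analysis the package reproduces.  Users should know its character: the
in-sample $r$ of a PMD fit generally *increases* with the budgets, so on
data whose cross-block signal is weak relative to dimensionality the rule
selects dense models and inflates $r$.  The permutation test below is
constructed to remain valid under exactly this optimism.

**Inference.** `permutation_test()` permutes the rows of one block
(default: the second), re-runs the *entire* grid search per permutation,
and records the maximal $r$ over the grid.  The p-value is the paper-style
$k/N$: the fraction of permutations whose maximal correlation exceeds the
observed one.  Because the null statistic carries the same selection
optimism as the observed statistic, the test is calibrated — the suite
verifies a type-I error inside the binomial band around 0.05 at 200
replicates — and is "explicitly corrected" for the sparsity search.  The
$(k+1)/(N+1)$ estimator is reported alongside as `p_plus_one` for users who
require strictly positive p-values.

**Further modes.** After mode 1, the cross-product is deflated
($M \leftarrow M - d\,uv^\top$, $d = u^\top M v$) and refitted at the
mode-1 sparsity; each further mode gets an unadjusted permutation p-value
against its own deflated null.  Re-searching sparsity per deflated mode
would change the mode-1 null and is deliberately not done; the choice is
configurable in code.

**Indicator columns.** Group (diagnosis) and handedness indicators can be
appended to the language block (`append` argument of `scca()`), z-scored
with the rest, so a group effect on the mode expresses itself as a weight.
Appended indicators are exempt from the degenerate-feature filter: a 46/22
diagnosis split has a 68% modal share and would otherwise always be
removed.  Diagnosis is coded CHR = 1, HI = 0.

## Linguistic features

Sentences are split on runs of terminal punctuation (so an ellipsis is one
boundary) with an abbreviation and decimal guard; tokens are whitespace
fields with edge punctuation stripped.  Transcripts are assumed
pre-filtered to participant speech; a speaker-prefix filter is available
but off by default.

The LSA space is built from the analysis corpus itself (default
$k = 50$, log-entropy weighting of the term–sentence count matrix), since
no external reference space ships with the package; the space can be
persisted (`write_semantic_space()`) and its manifest hashed for
reproducibility.  A sentence vector is the mean of its in-vocabulary word
vectors; coherence is the cosine of consecutive sentence vectors.  Pairs
involving an all-out-of-vocabulary sentence are *skipped and counted*, not
scored zero — a zero vector has no direction, and scoring it would plant
spurious minima in exactly the tail statistics the analysis reports.

Part-of-speech tagging uses the package's deterministic lexicon +
suffix-rule tagger over the 36 Penn Treebank word-level tags: a closed-class
lexicon (determiners, pronouns, prepositions, conjunctions, modals,
wh-words, interjections, common verbs with irregular forms), morphological
suffix rules for unknown words, proper-noun detection for mid-sentence
capitalized tokens, and a default of NN.  Tags outside the configured
tagset pool into an `other` bucket so frequencies always sum to 1.  The
synthetic transcript generator draws from this same lexicon, which makes
tag ground truth exact on synthetic data; on real English the tagger is
cruder than a trained statistical tagger, which is the main caveat when
applying the package outside simulation.

**Degenerate-feature filter.** Before analysis, any feature whose modal
value is shared by *strictly more than* half the cohort is dropped
(`drop_degenerate_features()`, threshold configurable).  A modal share of
exactly one half is retained.  The filter runs cohort-wide on the raw
language block, before z-scoring, matching the order of the original
analysis; the filter is idempotent.

## Brain features

Cohesiveness of a network is the mean Fisher-z-transformed Pearson
correlation over all unordered within-network node pairs; integration is
the Fisher z of the correlation between two networks' node-average series.
Correlations are clipped to $\pm(1 - 10^{-7})$ before `atanh` so duplicated
series stay finite.  Reading "the correlation between the average
time-series of each pair of networks" literally yields 15 integration pairs
and 21 measures for six networks, contradicting the printed count of 11;
the package therefore uses a *hub-centric* topology — the language network
paired with each of the other five — giving $6 + 5 = 11$ measures, and
offers `all_pairs = TRUE` for the literal reading.  Statistics are
granularity-agnostic: nodes may be voxels or parcels (fixtures use 10–50
nodes per network).

Morphometry tables are validated against a schema assigning each feature a
role; the default is the 68-feature Desikan–Killiany thickness set plus 20
subcortical volumes (10 bilateral structures).  Values must be positive;
missing values fail hard unless mean imputation is requested.

## Site harmonization

`combat_fit()` implements the parametric empirical-Bayes location/scale
model: feature-wise least-squares standardization (batch indicators plus
optional protected covariates), per-batch location $\hat\gamma$ and scale
$\hat\delta^2$, normal and inverse-gamma priors with method-of-moments
hyperparameters across features, and conditional posterior updates iterated
to convergence (absolute change $< 10^{-6}$, cap 200).  Two deliberate
numerical choices:

* **Population denominators** ($1/n$ pooled, $1/n_b$ per batch) rather than
  $n-1$: with a single batch the standardize/restore round trip is then an
  exact identity, a useful degenerate-case contract.
* **Exact grand-mean restoration**: after adjustment each feature's grand
  mean is restored exactly via a per-feature offset frozen at fit time.  A
  common shift across batches cannot reintroduce a batch effect, and it
  makes harmonization mean-preserving by construction.

Empirical-Bayes shrinkage deliberately leaves a small residual per-feature
batch contrast (about half the sampling noise of $\hat\gamma$); batch
removal should therefore be judged on aggregate batch statistics, which is
how the tests phrase it.  Fitting and applying are separate (`combat_fit()`
/ `combat_apply()`, or the `predict` method), the model serializes to JSON
for audit, and unseen batches or mismatched features are classed errors.
Only imaging blocks are harmonized in the standard pipeline; language and
clinical blocks are not.  Whether diagnosis should be protected during
harmonization is left to the user (`covariates`); the default harmonizes
without covariates.

## The synthetic-data generators

`generate_transcripts()` samples sentences from six part-of-speech
templates (declarative, question, fragment, conjunctive, subordinate,
interjection-initial) over a vocabulary partitioned into topics.
Consecutive sentences keep their topic with probability $1 -$ `drift`, so
drift directly controls measurable semantic coherence; `complexity`
reweights the conjunctive/subordinate templates, moving coordinating and
subordinating conjunction, pronoun, past-verb and adverb frequencies —
the same feature families the analysis reports as syntactic complexity.
Sentence lengths are centred on their target by adjective/noun padding
that deliberately does not touch the conjunction frequencies.

`generate_linked_blocks()` plants a sparse canonical mode: a latent score
$s$ drives $X$ through a unit sparse weight vector $w_x$ and a correlated
score $t = \rho s + \sqrt{1-\rho^2}\,e$ drives $Y$ through $w_y$.  Noise is
standard normal *projected orthogonally to the planted weight within each
block*, which makes $\rho$ exactly the population canonical correlation of
the planted mode.  With isotropic (unprojected) noise the score noise
attenuates the population correlation to $\rho/2$, which entangles the
generator's nominal $\rho$ with an arbitrary attenuation factor; the
orthogonal design keeps "planted $\rho$" meaningful.  Optional batch
location/scale effects and a group mean shift are applied afterwards.

A caution the package's own tests document: at $n = 200$, $p_1 = p_2 =
100$, the leading singular value of the noise part of $X^\top Y$
concentrates near $\sqrt{n}(\sqrt{p_1} + \sqrt{p_2}) \approx 282$, above
the planted signal $n\rho < 200$ for every $\rho < 1$.  In that regime the
max-correlation selection rule chooses dense models and support recovery
by the selected mode fails *by construction* — not because of an
implementation defect.  Recovery succeeds when the planted component
dominates (e.g. $p = 20$, $n = 200$, $\rho = 0.8$, where fits at the true
sparsity attain full support recall), and the corresponding test asserts
exactly that regime.

`generate_timeseries_panels()` uses a per-network one-factor model: node
series share a network factor with loading $\sqrt{a}$ where
$a =$ `within_r`, so the expected within-network pair correlation is
`within_r` exactly; network factors share a hub factor whose loading is
calibrated so the hub-to-network mean-series correlation is approximately
`between_r` (the calibration accounts for the $(1-a)/n$ noise floor of
node averaging).  With `within_r = 0.5` and $T = 2000$ the measured
cohesiveness matches $\operatorname{atanh}(0.5) \approx 0.549$ within 0.05.

`generate_morphometry()` draws thickness around 2.5 mm (sd 0.15) and
structure-specific subcortical volumes (sd 8% of the mean), truncated at
5% of the mean so positivity is guaranteed; a latent score can be loaded
onto chosen features.

`write_study_fixture()` ties everything together into an on-disk study —
46 CHR + 22 HI by default, matching the cohort sizes of the study design
the package reproduces — in which one latent subject score drives
transcript drift and complexity, network cohesiveness, ten morphometry
features and five clinical items at cross-block correlation $\rho = 0.7$,
with site location/scale effects on the imaging blocks.  `truth.json`
records every planted parameter, including the list of linguistic features
the latent drives (frozen from an independent $n = 300$ calibration draw
of the generator).

## The pipeline

`run_study()` executes: transcript reading → LSA space → linguistic matrix
→ connectivity/morphometry ingestion → inner join of subjects across all
sources (every exclusion logged with a reason) → ComBat per imaging block
(batch = site) → cohort-wide degenerate filter on the language block → one
`scca()` per configured analysis.  The default analyses mirror the study
design: language–clinical within CHR only; language (+ diagnosis and
handedness indicators) against connectivity, and against morphometry, in
the whole sample.  Results serialize to JSON and TSV with a manifest
(package version, seeds, subject counts, per-analysis summaries); two runs
of the same configuration and seed are byte-identical, which the tests
assert at the file level.

## What passing tests do and do not show

The generators produce Gaussian noise, template-grammar speech over a
closed vocabulary, one-factor network dynamics and independent-feature
morphometry.  Passing tests therefore demonstrate correctness of the
statistical machinery (operators, calibration, determinism, recovery where
mathematically feasible) — not that the pipeline will find, or fail to
find, particular effects in real clinical data.  Real speech has richer
syntax than the six templates, real tag frequencies need a trained tagger,
real site effects are not purely location/scale, and real brain-language
covariation is not rank-1.

## Problem sizes and runtime choices

The test suite fixes its problem sizes for fast, deterministic runs:
permutation calibration uses 200 replicates of 200 permutations at
$n = 60$, $p = 10 + 10$ (the binomial 95% band for a 5% test at this
replication is roughly [0.02, 0.09]); the planted-recovery checks use
$n = 200$ with $p = 20$ and $p = 100$; end-to-end study fixtures use 14–68
subjects with $T = 60$–150 timepoints and 60–1000 permutations.  The
compiled PMD core (Rcpp/RcppArmadillo) re-runs the full grid search per
permutation in microseconds, which is what makes the per-permutation
maximal-statistic null practical at these replication levels.  Production
analyses should use the full `n_perm = 10000` default of `study_config()`.
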