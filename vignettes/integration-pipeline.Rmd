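---
title: "Ensemble-lasso integration of paired omics layers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble-lasso integration of paired omics layers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ianet)
```

## The model

ianet infers statistical associations between the analytes of two omics
layers measured on the same conditions — e.g. protein levels (RPPA) against
transcript levels (RNAseq), or transcripts against chromatin accessibility
(ATACseq) — without any prior network knowledge. The working model is
linear: with `Y` the response layer (analytes x conditions) and `X` the
predictor layer,

$$ Y = \beta X + \delta, $$

and each row k of `Y` is fitted independently by lasso regression,
minimizing

$$ \sum_{i=1}^{C}\Big(Y_{ki} - \sum_j \beta_{kj} X_{ji} -
\delta_k\Big)^2 + \lambda \sum_j |\beta_{kj}| $$

over the C conditions. The penalty \(\lambda\) is chosen per fit as the
grid point with minimum 4-fold cross-validated mean squared prediction
error. One such sweep over all response rows gives one sparse coefficient
matrix; the whole sweep is replicated many times (10,000 in production use)
with different cross-validation fold assignments, and the entries inferred
non-zero in at least half of the replicates form the **Robust Lasso
Coefficient Matrix** (RLCM), valued by the mean of their non-zero
occurrences. Fold assignment is the only stochastic element of the fit, so
the ensemble measures how stable each selected coefficient is under
resampling of the penalty-selection procedure — a stability-selection-style
filter.

Three notational conventions matter in practice:

* The objective above carries no \(1/(2C)\) factor. The glmnet backend uses
  that scaling internally, so ianet converts penalties both ways
  (\(\lambda_{glmnet} = \lambda / (2C)\)) and reports all \(\lambda\) in
  the unscaled units of the objective above.
* Penalty selection is *minimum* mean CV error, not the 1-SE rule.
* The retention rule is `occurrence >= ceiling(min_frequency *
  n_replicates)`, i.e. exactly half counts as retained at the default
  `min_frequency = 0.5`.

## Preprocessing

Each input matrix is variance-filtered (keep the `ceiling(fraction * R)`
rows of largest raw sample variance; conventionally 10% for transcriptomic
and chromatin layers, 20% for the smaller proteomic layer), then
column-centered, row-centered, and row-scaled to unit Euclidean norm, in
that order. The centering steps remove per-condition and per-analyte
offsets; the normalization puts all analytes on a common scale so the
penalty treats them comparably and the fit reflects the *shape* of each
profile across conditions. It also drives the fitted offsets
\(\delta_k\) toward zero: on preprocessed inputs they stay below 1e-6.

Two numerical notes:

* "Row normalized" is implemented as unit L2 norm. Unit variance would be
  the other defensible reading; L2 was chosen because it makes the
  penalized objective comparable across rows, and it differs from unit
  variance only by the constant \(\sqrt{C-1}\) once rows are centered.
* This three-step preprocessing is **not** idempotent: rescaling rows by
  unequal factors breaks the column-centering, so running it twice changes
  values (only for matrices with 3 or more columns; with 2 columns every
  centered row is proportional to (1, -1) and a second pass is a no-op).
  The pipeline therefore applies it exactly once per model run, *after*
  any column exclusion — a leave-one-group-out run re-preprocesses the
  reduced matrices rather than inheriting the full-data scaling, which is
  also what keeps its offsets negligible.
* Rows whose norm collapses below 1e-10 after centering (e.g. rows that
  are constant offsets of the column means) would normalize to NaN; they
  are dropped and reported instead.
* The variance filter is applied to the values as given; any
  assay-specific transform is assumed to have happened upstream. Ties are
  broken by input order, and `ceiling` guarantees at least one survivor
  for any positive fraction.

## Leave-one-group-out (LOGO)

Condition columns carry group labels (a ligand treatment, a time-point
family, a patient subtype). `run_logo()` drops one group's columns from
both layers, re-preprocesses, and re-runs the full ensemble. The
associations that *depend* on that group are the symmetric difference of
the FULL and LOGO consensus supports: entries that vanish when the group
is removed (`full_only`) and entries that appear only without it
(`logo_only`). Entries present in both supports — even with different
coefficients — are not group-dependent and are excluded. Support
comparison is at exact-zero level; the frequency filter has already done
the thresholding. FULL and LOGO ensembles use independent master seeds,
recorded in the provenance attributes; the comparison is of supports, so
shared seed streams are not required.

## Gene-level integration and ranking

`build_ian()` merges the retained associations of one or two layer pairs
into a gene-level network: each association whose coefficient magnitude
exceeds a threshold becomes an edge between the gene symbols of its two
analytes, nodes coalesce analytes of the same gene across assays (an
association between two analytes of one gene becomes a self-edge), and
parallel edges between the same gene pair are kept. Two named thresholds
are shipped: `display` (0.01), for keeping visualizations readable, and
`comparison` (0.1), for quantitative network comparisons and enrichment
exports. Edges are undirected at gene level; the response-versus-predictor
orientation of the underlying analytes is preserved in the edge table.

`rank_genes()` scores gene k as

$$ \alpha_k = \frac{\sum_{e \ni k} |\beta_e|}{n_1 n_2 n_3}, $$

the sum over incident edges of the coefficient magnitudes, normalized by
the product of the layer sizes (the number of possible cross-layer
associations). Two readings of the printed formula are possible —
magnitude-of-sum versus sum-of-magnitudes; ianet defaults to
\(\sum|\beta|\) (consistent with edge weights being magnitudes) and offers
`mode = "abs_of_sum"` for the other. The inner sums range over the edges
incident to gene k: that is the only reading that yields gene-specific
scores. The denominator is constant within a run, so it never changes the
ranking order; it is kept for score comparability. Ties are broken
alphabetically so the output order is deterministic. The ranking exports
as a GSEA preranked `.rnk` file (headerless gene/score TSV, descending);
running GSEA, Reactome enrichment or EnrichmentMap themselves is out of
scope — ianet only emits their input formats.

## The shuffled-input null

`null_experiment()` re-runs the identical ensemble on a shuffled copy of
the inputs and compares the per-replicate non-zero coefficient counts via
the two-sample Kolmogorov–Smirnov distance. The default shuffle permutes
each row independently across columns: this preserves every analyte's
marginal distribution (and therefore its variance, so a pre-selection
variance filter retains the same rows) while destroying exactly the
cross-analyte alignment the lasso exploits. Whole-matrix and
within-column granularities are available for sensitivity checks.
`post_selection` shuffles the already-filtered matrices; `pre_selection`
shuffles first and filters afterwards. The KS p-value reported is the
classical asymptotic series with small-sample correction; on strongly
separated count distributions it underflows toward zero, and ianet reports
the exact D alongside it rather than claiming an exact zero.

Overlap with a known-interaction list is counted per retained association
(several analyte pairs hitting the same known gene pair each count), with
the number of distinct known pairs hit attached as an attribute.

## The synthetic benchmark

`generate_synthetic()` draws a predictor layer of i.i.d. standard-normal
profiles and a response layer `Y = B X + noise` with a planted sparse `B`.
The default spec — 20 response analytes, 50 predictors, 24 conditions in 6
groups of 4, 30 planted entries with magnitudes in 0.8–1.2 and noise SD
0.1 — is the package's standard desk-scale benchmark: strong, sparse,
well-separated effects on matrices small enough that a 100-replicate
ensemble runs in about a minute. Synthetic gene symbols map several
analytes to shared genes so the network stages exercise node coalescing
and self-edges.

Group-restricted effects ("blocks") are planted differently from global
ones, for an identifiability reason worth recording. A coefficient active
on only 4 of 24 columns is visible to the all-conditions fit only through
the fraction of its predictor's energy that falls in those columns; for an
i.i.d. normal predictor that fraction is a \(\chi^2_4\) share — recovery
of any specific planted entry would be a coin flip no matter how large the
effect. Real context-specific associations do not look like that: the
responsive transcript itself is induced in the responsive conditions. The
generator therefore (i) scales each block predictor's active-group columns
by `block_activity` (default 3), (ii) couples it to a dedicated response
row that carries no global associations, and (iii) keeps block predictors
distinct. Under this design the FULL run detects the block reliably, the
LOGO run on the active group cannot (its evidence is gone), and the
symmetric difference attributes the entries to the right group.

What the generator does *not* emulate: count-type noise
(negative-binomial RNAseq, zero inflation), assay-specific normalizations,
correlated predictors, batch structure, or nonlinear regulation. Passing
the benchmark shows the machinery — preprocessing, penalized selection,
consensus, differencing, network assembly — is correct on data satisfying
the model's own assumptions; it does not certify recovery rates on real
omics data.

## Selection behavior and its limits

Minimum-CV-error lasso is known to over-select: it keeps the true support
(recall is essentially 1 on the benchmark) plus a halo of
small-magnitude false positives, and because those extras are driven by
the data rather than by the fold assignment, the cross-replicate frequency
filter does not remove them. On the standard benchmark the raw consensus
support is several times larger than the planted support, while almost all
false entries carry coefficients an order of magnitude below the true
ones. This is why the pipeline's quantitative analyses apply the
`comparison` magnitude threshold (0.1) on top of the frequency rule, and
why `score_recovery()` takes a `coef_threshold` argument: the acceptance
script reports recovery both ways rather than pretending the raw support
is clean. Precision of the raw support, not recall, is the quantity to
watch when adapting the pipeline to new data.

## Problem sizes and runtime choices

The test-suite and acceptance-script runs use the benchmark spec above
with 100 replicates (recovery, 3 seeds), 40 replicates per arm (null
comparison, 5 seeds), and a 12-analyte x 20-predictor, 12-condition,
3-group variant with 25 replicates for the LOGO recovery study (10 seeds)
— sizes at which the full suite completes on a single CPU in minutes while
keeping at least two conditions per fold in every reduced run. Production
runs on real data use the same code paths with `n_replicates = 10000` and
are embarrassingly parallel across replicates; replicate seeds are
counter-derived from the master seed, so results do not depend on
evaluation order.

## Reproducibility

Every stochastic step — fold assignment, synthetic generation, shuffling —
derives from one master seed through a counter-based stream, and all
writers emit full-precision text (`%.17g`), so re-running any stage with
the same inputs and configuration reproduces its artifacts byte-for-byte.
The command-line front end records a manifest (configuration, seeds, input
digests) next to every artifact bundle.
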