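---
title: "Methods: model, partitioning, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: model, partitioning, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the model and
its assumptions, the missing-not-at-random (MNAR) machinery, every tunable
parameter that matters, what the synthetic-data generator does and does not
emulate, and the places where the design was genuinely open and a choice
had to be made.

## The data model

The central object is a proteins × samples matrix `X` of log-scale,
reference-normalized TMT protein intensities, with `NA` marking missing
quantifications. The package applies no transformation on read (an
optional `log2` flag exists for raw-scale input): upstream TMT pipelines
already emit normalized log-ratios, and all downstream mathematics (fold
changes as mean differences, Gaussian imputation widths in sd units)
assumes that scale.

Multi-cohort matrices are built by `join_cohorts()`: rows are the union of
the cohorts' protein sets, columns are the concatenated samples, and a
protein unmeasured in a cohort is missing in all of that cohort's columns
(structural missingness). `filter_matrix()` then removes non-biological
samples — ids containing any of `RefInt, QC, pool, pooled, reference, NCI,
NX, ref` — and proteins quantified in fewer than 18 samples. Keyword
matching is case-insensitive *substring* matching (so `ref` subsumes
`RefInt`); whole-token matching would be defensible too, but substring is
the conservative direction for excluding control channels, and the keyword
list is a user-visible argument. Duplicate protein ids are an error, not
aggregated: inputs are expected to be already rolled up to protein level.

## MNAR partitioning

Held-out evaluation must respect the left-censored missingness mechanism:
a test set drawn uniformly (MCAR) would over-represent the easy,
well-observed intensity range. The partitioner therefore draws, for every
present entry `X[i,j]`, a random threshold

    T[i,j] ~ Normal(q_0.25(X), (1.1 * sd(X))^2)

where the quantile and sd are computed over present entries only. Entries
with `X[i,j] < T[i,j]` — low relative to their random cutoff — undergo a
Bernoulli(0.61) trial: success sends them to the test set, failure to
training. Entries at or above their threshold always train.

**Comparison direction.** With the direction as implemented, the test set
is *left-skewed* relative to the training set and captures 20% of present
entries on centered data: for i.i.d. Normal input, `X - T` is Normal with
mean `-q_0.25` and variance `1 + 1.1^2`, so

    P(test) = Phi(q_0.25 / sqrt(1 + 1.1^2)) * 0.61  ≈  Phi(-0.454) * 0.61  ≈  0.198.

The opposite direction (low entries always train) would produce a
right-skewed test set of roughly 41% — inconsistent with both the intended
left-censoring semantics and the 20% share, which is why this package uses
the low-to-test direction. The closed form above doubles as the test
oracle for the partitioner.

**Calibration.** `calibrate_bernoulli_p()` solves for the Bernoulli
probability hitting a target test share analytically: the per-entry
censoring probability `P(x < T) = 1 - Phi((x - center)/sd)` is averaged
over present entries, and `p = target / mean censoring probability`,
clipped to [0, 1]. Only this one degree of freedom is calibrated; the
center quantile (0.25) and sd multiplier (1.1) are fixed distribution
shape parameters. An unreachable target (larger than the mean censoring
probability) is an error that reports the achievable maximum.

**Validation split.** `mcar_validation_split()` moves a uniformly random
10% of training entries into a validation mask. This split is deliberately
MCAR — it exists to monitor convergence, not to emulate missingness — and
is carved *out of* the training mask so validation loss is never trained
on.

**Biased batches.** Training batches (size 128) are drawn from training
entries with replacement; a uniformly drawn candidate is accepted outright
when its value falls below a fresh draw from the same threshold
distribution, and with probability 0.5 otherwise. Pooled over batches the
sampled intensities are left-shifted relative to the full training set.
The acceptance probabilities (1.0 below threshold, 0.5 above) are this
package's choice: the qualitative contract is the left shift, and the
rejection construction makes the shift exactly the one induced by the
threshold distribution. A `biased = FALSE` override samples uniformly,
which is how the sampler is validated (pooled draws must then be
indistinguishable from the training distribution).

## The model and its training

`init_model()` draws protein factors `W` (proteins × p) and sample factors
`H` (s × samples) i.i.d. Normal(0, 1/n_factors) — variance scaled so the
perceptron's inputs are O(1) on the log-intensity scale — and perceptron
weights uniform on ±1/sqrt(fan-in) with zero biases. The perceptron has
`n_hidden_layers` layers of `n_nodes_per_layer` nodes with leaky-ReLU
activations (negative slope 0.1) and a *linear, unclamped* scalar output:
log-intensities are unbounded, and no normalization, dropout, or weight
decay is used anywhere.

Training minimizes batch MSE with Adam (learning rate 0.001, β₁ = 0.9,
β₂ = 0.999, ε = 1e-8), updating `W`, `H` and the perceptron jointly; the
forward and backward passes are hand-vectorized over the batch, and
embedding gradients are scatter-added onto the rows/columns the batch
touches. One *epoch* is `ceil(|train| / batch_size)` batches — enough
with-replacement draws to cover the training set in expectation, since a
with-replacement sampler has no natural epoch boundary. All computation is
CPU-based; the matrices this package targets do not need an accelerator.

After each epoch the full validation MSE is recorded and two stopping
criteria are consulted (`check_convergence()`):

1. **Tolerance.** The ratio `(best - current) / best` of validation MSEs
   is computed each epoch against the best of the *previous* epochs; if it
   stays below 0.001 for 10 successive epochs, training stops. The
   difference is signed, exactly as specified — a worsening epoch also
   qualifies — so this criterion detects "no meaningful improvement", and
   a strong improvement resets the count.
2. **Rank-sum.** Once 15 epochs are available, a one-sided Wilcoxon
   rank-sum test compares the five most recent validation MSEs against
   the five from epochs n−14…n−10; p < 0.05 for "the older window is
   smaller" means validation error has started rising, and training
   stops. The test is exact when there are no ties (complete separation
   of the two windows gives p = 1/C(10,5) ≈ 0.004) and uses the
   tie-corrected normal approximation otherwise.

The returned parameters are those of the *best-validation* epoch, not the
last: the rank-sum criterion by construction fires only after validation
error has already risen. A hard cap (`max_epochs`, default 500) is a
safety net the criteria normally preempt.

Two small-data caveats surfaced while validating the trainer and are worth
knowing about. On very small training sets (hundreds of entries) an epoch
is only a handful of Adam steps, and the tolerance criterion — faithfully
signed — can halt training while per-epoch improvements are still large in
absolute terms but small relative to a still-poor best loss; raising the
learning rate (e.g. 0.01) or shrinking the batch is the right response,
and the package's own small-matrix tests do exactly that. The defaults are
sized for matrices with tens of thousands of training entries and up.

## Ensembling

`fit_ensemble()` trains `n_models` members (default 10) and averages their
full-matrix predictions entrywise — an unweighted arithmetic mean, which
by convexity of squared error can never be worse on a fixed target set
than the average member (this Jensen bound is asserted in the tests on
every run). Members differ in three ways: hyperparameters (sampled
uniformly without replacement from the search grid — protein and sample
factors in {64, 128, 256, 512, 1024}, hidden layers {1, 2, 4}, nodes
{512, 1024, 2048}, 225 combinations — unless an explicit config list is
given), derived seeds (`seed + member index`; the base seed is the only
user-visible randomness), and private MCAR validation splits of the shared
training mask. Members train sequentially; the seed isolation means a
parallel scheduler would be free to reproduce the identical result, but
none is shipped.

## Baselines

`gaussian_sample_impute()` replicates the downshifted-Gaussian procedure
popularized by Perseus: per sample column with observed mean μ and sd σ,
missing entries are drawn from Normal(μ − 1.8σ, (0.3σ)²). Width 0.3 and
downshift 1.8 are the conventional defaults and are exposed as arguments.
Statistics are per column (per MS sample), matching the column-wise
convention of `column_min_impute()`, which replaces missing values with
the lowest observed quantification of the sample. Both baselines preserve
observed entries bitwise and are deterministic given a seed (column-min
needs none). A constant column (σ = 0) imputes to μ; a column with fewer
than two observed values is an error rather than a silent guess.

## Evaluation

`test_mse()` scores predictions at held-out entries, overall and per
cohort (a cohort with no test entries is reported `NA`, never 0).
`per_protein_residual()` aggregates a protein's test-entry residuals as
the mean absolute residual by default; root-mean-square and a signed mean
(for residual scatter plots) are available because the aggregation is a
presentation choice, not a modeling one. `fraction_better()` compares two
methods' per-protein residuals, restricted to proteins where either
residual exceeds 0.25 so that near-perfectly-predicted proteins do not
inflate the statistic; ties count as "not better", making the statistic
conservative and ensuring complementary fractions sum to at most 1.

## Downstream analyses

**Differential expression.** `run_de()` pairs tumor with non-tumor
samples of the same patient, runs two-sided paired t-tests on the paired
differences, adjusts p-values with Benjamini-Hochberg across the tested
proteins, and calls a protein up (down) when adjusted p < 0.01 and the
log2 fold change exceeds 0.5 (falls below −0.5). The fold-change cut is
applied to the *absolute* value with the sign setting the direction, since
both up- and down-regulated sets are of interest. Proteins with more than
50% missingness *before* imputation are excluded up front — imputation
cannot manufacture evidence for proteins that were mostly unobserved.
Patients lacking either member of the pair are dropped; in no-imputation
mode, pairs are dropped per protein and proteins left with fewer than two
pairs get `NA` p-values outside the BH family. BH itself and the t-tests
are delegated to `stats::p.adjust(method = "BH")` and `stats::t.test()`;
the package's tests verify the BH step against an independent hand-written
step-up implementation.

**Complex co-expression.** `complex_correlations()` asks whether proteins
annotated to the same complex co-vary more than random protein pairs,
restricted to one cohort's tumor samples and to proteins under 50%
pre-imputation missingness. Within-complex Spearman correlations (mid-rank
based, pairwise-complete when the input still has missing values) are
computed for every deduplicated within-complex pair; an equally sized
background set is sampled uniformly from pairs that are not within any
complex. The two sets of coefficients are compared with a Welch two-sample
t-test: the two sets have no natural pairing, so a paired test is not
available. One estimation caveat matters at small scale: with a low-rank
generative signal, the *true* correlation of a random protein pair is
itself dispersed (its cosine-similarity spread scales like 1/sqrt(rank)),
so a background mean over a single cohort's ~100 pairs carries sampling
noise of several hundredths regardless of data quality. The package's
acceptance test therefore pools the per-cohort correlation sets over all
simulated cohorts before comparing means, mirroring how a multi-cohort
analysis would report the statistic.

## The synthetic generator

`simulate_cohorts()` exists so every other module can be tested against
known ground truth without any download. It emulates, on a
reference-normalized log2 scale:

* a shared low-rank signal (`latent_rank` 5, unit scale) — co-regulation
  across proteins and samples;
* correlated protein blocks (10 complexes of 5 members, loading 0.8 on a
  shared factor) — protein complexes;
* per-cohort (sd 0.3) and per-plex (sd 0.1) column offsets — residual
  batch effects after reference normalization, deliberately modest because
  the emulated inputs are already normalized;
* planted tumor-vs-non-tumor shifts (30 proteins, 1.0 log2 units, upward
  by default) on annotated tumor columns;
* i.i.d. Gaussian measurement noise (sd 0.3);
* left-censored missingness: each measured cell goes missing with
  probability `plogis(-slope * (x - c))` (slope 2), with the midpoint `c`
  calibrated by bisection so the overall missing fraction — structural
  missingness from partially overlapping protein panels plus censoring —
  matches the target (default 0.30) in expectation. The logistic form is a
  generator convenience; the package's *normative* MNAR mechanism is the
  thresholds-matrix partitioner above, and the generator only needs the
  qualitative intensity–missingness relationship.

Paired tumor/non-tumor samples share their patient's latent factors (both
the low-rank and the complex factors), so paired differences isolate the
planted shift plus noise — which is precisely the property that makes a
paired design powerful on real data. The default configuration is 4
cohorts × 300 proteins × 40 samples with all cohorts measuring the same
panel; lowering `shared_protein_fraction` produces the structural
missingness of partially overlapping panels (and the missing-fraction
target then must exceed the structural floor, or the generator errors).

What the generator does *not* emulate: peptide-level effects and protein
roll-up, instrument noise models, intensity-dependent variance,
non-Gaussian heavy tails, correlated (non-independent) censoring within a
plex, and real proteome-scale effective rank. Passing tests on this
generator therefore demonstrate that the machinery is correct and that the
model recovers planted low-rank structure under left-censored missingness
— not that any particular accuracy level will transfer to a given real
dataset.

## Numerical and testing choices

* All randomness is routed through a seed-scoped RNG helper that restores
  the caller's RNG state; every pipeline stage is bit-reproducible given
  (data, parameters, seed).
* Missingness calibration tolerances: the generator's bisection runs 60
  iterations (midpoint resolution far below measurement noise); realized
  missing fractions match targets to well under 0.01 at the default matrix
  size, and the tests size their matrices so Monte-Carlo noise stays below
  the tolerance being checked.
* Degenerate inputs are errors, not guesses: empty joins, all-missing
  matrices, fully-missing columns, unreachable calibration targets,
  non-finite training losses, and predictions that are non-finite at
  missing positions all abort with a diagnostic.
* Test problem sizes: the partition-distribution checks use a 1,000 × 200
  standard-normal matrix (200,000 entries, Monte-Carlo se ≈ 0.001 on the
  test share); the model-vs-baseline comparison trains a 3-member ensemble
  (p = s = 16, one hidden layer of 64 nodes, ≤ 200 epochs) on the default
  4 × 300 × 40 simulation; differential-expression recovery uses one
  cohort of 40 patient pairs with 30 planted shifts. These sizes were
  chosen so each check is a multi-sigma statement rather than a coin flip.

## Known limitations

* The trainer is a vectorized pure-R implementation sized for desk-scale
  matrices (hundreds of proteins × hundreds of samples); proteome-scale
  matrices (tens of thousands of proteins, thousands of samples) would
  want a compiled or GPU backend.
* The biased-batch acceptance rule is a documented stand-in for an
  unspecified mechanism; only its left-shift property is contractual.
* The tolerance stopping criterion is signed as specified, which on
  slowly-improving small problems can stop training early (see above).
* `fraction_better` and the residual aggregation are presentation-level
  statistics; their thresholds (0.25) are conventions, not fitted values.
* Imputed values are model estimates, not measurements: downstream DE
  calls on imputed matrices are hypothesis-generating, and the package
  deliberately reports pre-imputation missingness alongside every DE call
  so users can weigh the evidence.
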