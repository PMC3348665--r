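---
title: "PRMT methods: model, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PRMT methods: model, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents what the package computes, the assumptions baked
into each step, why each default was chosen, and the numerical conventions
a careful user (or re-implementer) needs to know.

# The model

## From reads to relative enzyme capacity

The input is a metagenome annotation: for each sample, a count of reads
assigned to each enzyme function (EC number). The central modeling
assumption is that these counts are a usable proxy for the community's
*relative capacity* to catalyze the corresponding reactions. That assumption
is weakest where annotation is weakest (promiscuous EC numbers, unannotated
enzymes, lateral coverage biases), which is why every downstream output is
framed as relative and directional, never absolute.

`compute_eac()` transforms counts to enzyme activity counts (EAC). The
default transform is `log2(count + 1)`:

* read counts are heavy-tailed; on a log scale a 2-fold change of an
  abundant enzyme counts the same as a 2-fold change of a rare one;
* the `+1` keeps zero counts finite and maps them to an EAC of exactly 0.

A `raw` transform is available for sensitivity analysis. Under `raw` with no
quantile step the pipeline is linear in the counts, which makes certain
invariances exact at the count level (see below).

## Quantile normalization

Samples differ in sequencing depth and annotation yield. Before comparison,
`quantile_normalize()` forces every sample's EAC vector onto one common
distribution: the reference distribution is the element-wise mean of each
sample's sorted vector, and each value is replaced by the reference value
at its rank.

Numerical conventions that matter:

* **Tie rule.** Tied values within one sample all receive the *mean of the
  reference values spanning their tied ranks*. For tie-free data this is
  identical to `limma::normalizeQuantiles` (the test suite checks exact
  agreement to 1e-12); for ties deeper than 2-way the two implementations
  can differ slightly, because limma interpolates where we average. Ties
  are common here (many enzymes share a zero count), so the rule is part
  of the contract and is tested directly.
* The transformation is idempotent and invariant to sample order.
* A single sample cannot be quantile-normalized; the function refuses
  rather than silently passing data through.

## The Environmental Metabolome Matrix (EMM)

`build_connectivity()` counts, for each metabolite × enzyme cell, the number
of directed reactions of that enzyme producing the metabolite minus the
number consuming it. Key choices:

* **Stoichiometry is discarded.** Coefficients in reaction equations are
  stripped on parsing. The read counts themselves are far noisier than a
  factor of 2 or 3 in stoichiometry, and keeping coefficients would let a
  handful of polymerization reactions dominate rows.
* **Reversible reactions enter both directions.** A reversible reaction
  contributes +1 and −1 to the same cell, i.e. nothing, *in the raw
  connectivity*. Consequently an enzyme all of whose reactions are
  reversible has an all-zero column, and PRMT scores are **exactly**
  invariant to its abundance — bit-for-bit, not merely to tolerance. The
  acceptance tests assert this with `expect_identical`. (At the *count*
  level the invariance is exact only under the `raw` transform without
  quantile normalization, because quantile normalization lets one enzyme's
  counts move every enzyme's normalized values.)
* **Currency metabolites are excluded up front.** Water, protons,
  nucleotide phosphates, NAD(P)(H), FAD and CoA connect to so many
  reactions that they would dominate every score while predicting nothing.
  The shipped blacklist deliberately *excludes* orthophosphate and
  pyrophosphate: phosphate is a real environmental analyte one may want to
  track. Pass your own list to `apply_metabolite_blacklist()` to tighten
  or loosen this.

`normalize_emm()` rescales each metabolite row so positive entries sum to
+1 and negative entries to −1. Each metabolite thus has one unit of
production capacity and one unit of consumption capacity to distribute over
its enzymes; metabolites with many neighbors are not automatically more
variable than metabolites with few.

## PRMT scores

For sample *x* with normalized EAC vector `nEAC_x` and a reference vector
(default: the element-wise mean over all samples),

```
PRMT_x = -(M %*% (nEAC_x - nEAC_ref))
```

The leading minus sign implements the **consumption-positive** convention:
a positive score means the community is predicted to consume relatively
more of the metabolite than the reference community.
`sign_convention = "production-positive"` flips this. With the mean
reference, scores sum to zero across samples by construction — the scores
are strictly comparative.

# Correlation analysis

Measured parameters (environmental metabolite concentrations, taxon
abundances, subsystem abundances) are first mapped to
`log_relative_abundance()`: `log2(value / series mean)`. Pearson
correlation is invariant to the affine part, so the base of the logarithm
is immaterial; the log matters because abundances are ratio-scale.

**Why Pearson and not Spearman.** With the intended problem size of 3–10
samples, rank correlations are nearly degenerate (with n = 3 Spearman takes
only the values ±1 and ±0.5), so Pearson on log scale is used throughout.
The permutation null below makes no normality assumption about the data, so
Pearson's parametric fragility is not inherited by the strong/weak calls.

**The resampling null.** `build_null()` repeats, for a configurable number
of iterations (default 10,000): pick one series at random from each set,
permute the sample order of the second uniformly at random, record the
Pearson correlation. With *n* samples there are only *n*! distinct
permutations; with n = 3 the null is supported on at most 6 values per
pair, and the test suite verifies the support matches exhaustive
enumeration and that the six permutations are drawn uniformly. This
granularity is a real limitation at n = 3: the 5th percentile of such a
null is coarse, and users should read "strong" as "extreme relative to
what shuffling could produce", not as a calibrated p-value.

**Strong calls.** `classify_strong()` flags a correlation as strong when
it is ≤ the 5th or ≥ the 95th percentile of the null (inclusive
boundaries, type-7 quantiles — R's default). Inclusivity matters because
with a discrete null the observed value can *equal* a percentile exactly.

**No multiple-testing correction is applied.** The method screens
thousands of (metabolite, parameter) pairs against a 10% two-sided band,
so roughly 10% of pairs are expected to be flagged under the null — the
self-null calibration test asserts exactly that. The flags are a screen
for follow-up, not hypothesis tests; treating them as FDR-controlled
discoveries would be a misreading, and the package deliberately does not
dress them up as such.

**Joint band probability.** For *k* correlations all falling in a band
`[lo, hi]`, `joint_band_probability()` fits a normal distribution to the
null (mean and standard deviation of the resampled values) and returns
`(Φ((hi−μ)/σ) − Φ((lo−μ)/σ))^k`. This assumes independence across the *k*
pairs and a roughly normal null — both approximations; the quantity is a
rough-plausibility number for statements like "six taxa all correlate in
the same narrow band", not an inferential probability.

**Subnetworks.** `extract_correlated_subnetworks()` keeps only
metabolite–metabolite edges whose *both* endpoints are strongly correlated
with a given taxon, then reports connected components. Requiring both
endpoints avoids chaining a genuine signal through an unflagged hub.

# The synthetic fixture generator

The generator exists so the pipeline can be validated against known ground
truth; it emulates the *statistical shape* of EC-annotated metagenome
counts, not any particular biome.

The count model for enzyme *e* in sample *s* is

```
lambda_es = B_e * 2^(N(0, sample_sdlog2)) * fold_es
count_es ~ Poisson(lambda_es)
```

* `B_e ~ lognormal(count_meanlog = 2, count_sdlog = 1.5)` is a per-enzyme
  baseline shared across samples: real enzymes have characteristic
  abundances, and without this shared baseline a per-cell-independent
  model has no sample-to-sample correlation for a planted signal to stand
  out against.
* The per-sample lognormal factor (`sample_sdlog2 = 0.5`, i.e. ~1.4-fold
  typical wobble) models biological and depth variation.
* Poisson sampling produces natural zero counts for rare enzymes (about
  9% of cells at the defaults) without an artificial dropout process.
  `sparsity` adds extra missingness-at-random on top if wanted, and
  defaults to 0.
* `fold_es` multiplies the intensity for enzymes consuming (or producing)
  a planted metabolite in a planted sample.

**Detectability-based planting.** `plantable_metabolites()` returns
metabolites whose consuming-minus-producing connectivity is net-signed in
the requested direction *and* whose relevant enzymes have expected
baseline coverage of at least `min_baseline = 4` reads. Planting a signal
on an enzyme with an expected 0.1 reads is unrecoverable by any method;
the filter encodes "the signal must be in principle detectable", which is
the property the recovery tests are entitled to assume. With fold-8
signals at the default sizes (100 metabolites, 200 enzymes, 3 samples),
sign recovery is essentially perfect (≥ 95/100 required, 100/100
typical — see `scripts/acceptance.R` output).

`generate_parameters()` links measured parameters to PRMT scores as
`value = 2^(slope * score + N(0, noise_sd))`, so at `noise_sd = 0` the
log relative abundance is exactly affine in the score and the Pearson
correlation is ±1.

All generation is seed-deterministic: the same `fixture_spec` always
yields byte-identical tables (sub-seeds are derived for catalog, counts
and parameters so that adding parameter links never perturbs the counts).

# Problem sizes and performance

The implementation targets study-scale data: hundreds to a few thousand
metabolites, a few thousand enzyme functions, 3–50 samples. The EMM is a
dense base-R matrix — at 2,000 × 3,000 that is 48 MB and a matrix-vector
product per sample, far below any performance concern, so no sparse-matrix
dependency is taken. The only intentionally expensive step is the
resampling null (10,000 iterations of a length-*n* correlation), which
runs in seconds.

# Reproducibility conventions

* Every writer emits provenance headers (`# prmt version`, `# seed`,
  `# config-hash`, `# timestamp`); `--no-timestamp` / `timestamp = FALSE`
  yields byte-identical reruns, which the tests assert.
* Numeric output is formatted with 15 significant digits, enough to
  round-trip doubles through text in practice (the suite checks EMM
  round-trips to 1e-12).
* All random procedures take explicit seeds and save/restore the caller's
  RNG state, so library calls never perturb a user's session RNG.
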