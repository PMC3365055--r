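---
title: "Models and methods behind melacross"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind melacross}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`melacross` compares the transcriptomes of fish pigment-cell tumors with
human melanoma microarray data to extract expression changes conserved
across species. This vignette explains the statistical machinery, the
choices made where the design was genuinely open, and what the synthetic
validation does and does not demonstrate about real data.

## The study design the package assumes

The sequencing arm has four sample groups with one library each: a benign
hyperpigmented-skin reference (HP, biologically a pool of several
siblings) and three tumor types — an exophytic xanthoerythrophoroma (XE),
an invasive metastatic melanoma (MM) and a uveal melanoma (UM). The human
arm is a two-group microarray design, 18 nevi vs 19 melanomas. Both
designs are emulated by the synthetic generator; nothing in the analysis
code is tied to these exact labels or sizes except defaults.

## RNA-seq quantification

RPKM is the classical 10^9·C/(L·N). The expression gate defaults to
RPKM ≥ 2 and is *inclusive*: a transcript sitting exactly on the threshold
counts as expressed, so boundary values are treated as signal. Presence
and absence calls use the raw gate with no pseudocount; ratio-type
quantities (fold filters, MA values, log fold changes) use a configurable
pseudocount ε (default 1 RPKM or 1 normalized count) so on/off transcripts
get finite values — presence and fold are deliberately separated because
an on/off transcript is better reported as a presence call than as an
arbitrary large ratio.

Size factors are median-of-ratios to the per-transcript geometric-mean
pseudo-reference, computed over transcripts with positive counts in every
sample (the standard convention; rows containing zeros carry no usable
ratio for every sample). Base means are means of count/size-factor, gated
strictly at > 10 because that gate is conventionally quoted as "base mean
above 10".

## Differential expression without replicates

With one library per condition, a per-condition variance cannot be
estimated. The package therefore fits a single mean–variance relationship
v(m) = m + α·m² across *all* samples pooled ("blind"): per-gene excess
variance (sample variance of normalized counts minus the size-factor-aware
shot-noise term m·mean(1/s_j)) is regressed through the origin on m², with
two reweighting passes (weights 1/v(m)², which an initial unweighted pass
seeds) and α clipped at 0. Because real between-group signal inflates the
pooled variance, the fitted α errs high in non-null data — a deliberate
conservative bias for no-replicate testing. The shot-noise term reduces to
the plain mean when all size factors are 1; using it keeps the estimator
unbiased when library sizes differ.

The test conditions on the total K = K_A + K_B of a gene's counts in the
two conditions. Under the null the common per-unit expression is
q = K/(S_A + S_B) with S the summed size factors; condition totals get
mean q·S and variance summed from per-sample v(q·s_j), and the p-value is

> p = Σ over splits a+b=K with P(a,b) ≤ P(observed) of P(a,b), divided by
> Σ over all splits of P(a,b),

with P(a,b) the product of the two (negative-binomial, or Poisson when
α = 0) probabilities. The summation is exact; only for totals above
20 000 is it restricted to a ±40-standard-deviation window whose omitted
tail mass is far below the 10⁻¹² working precision. Ties in P(a,b) are
resolved with a log-space tolerance of 10⁻⁷ so mathematically tied splits
are never separated by floating-point noise, and the condition pair is
canonicalized before summation so that swapping the two conditions returns
the bitwise-identical p-value.

Calling rules: |log2FC| > 2 strictly (log base 2 throughout; the
pseudocounted, size-factor-normalized group means define the ratio), group
base mean > 10 strictly, and p < 0.05 — the p criterion is dropped in
`fc_only` mode, which mirrors single-sample screening where a p-value
against a blindly fitted variance is advisory at best (the package logs a
calibration note in that mode). No multiple-testing correction is applied
to the calls; a Benjamini–Hochberg column is emitted for information only,
because the calling convention thresholds raw p-values.

## The microarray arm

Quantile normalization replaces each sample's sorted values by the mean of
all samples' sorted values; ties within a sample receive the average of
the normalized values over the tied ranks, which keeps the procedure
deterministic. Probe-level tables are collapsed to gene symbols either by
keeping the probe with the highest mean intensity (default — the brightest
probe usually has the best signal-to-noise) or by averaging.

The moderated t-test shrinks per-gene pooled variances s² (d = n₁+n₂−2
degrees of freedom) toward a prior: s̃² = (d0·s0² + d·s²)/(d0 + d). The
prior is estimated from the empirical distribution of log s² by moment
matching: E[log s²] and Var[log s²] are linear in digamma/trigamma terms
of d/2 and d0/2, so d0 comes from a Newton inversion of the trigamma
function and s0² from the corrected mean. When the trigamma equation has
no positive solution the prior is treated as exact (d0 = ∞, every
posterior equals s0²). The statistic t̃ = Δmean/(s̃·√(1/n₁+1/n₂)) is
referred to a t distribution on d0 + d degrees of freedom. In the d0 → 0
limit this is the ordinary pooled t-test, which the test suite verifies,
and on shared data the whole procedure agrees with the `limma` reference
implementation to numerical precision — `limma` serves only as a
cross-check, never as the implementation. Two conventions are adopted
from common practice: when the prior is exact (d0 = ∞) its scale s0² is
the arithmetic mean of the s², and the total degrees of freedom are
capped at the pooled residual df, since the prior cannot carry more
information than the data that estimated it. Intensities are assumed log2;
values exceeding 50 trigger a logged heuristic warning that can be
overridden.

Array calls require a *linear* fold change strictly above 2 (equivalently
|log2FC| > 1) and p < 0.05. Whether the fold rule is linear or log-scale
is genuinely ambiguous in common usage; linear is chosen and the threshold
exposed.

## Isoform switches: the RC statistic

For each gene annotated with more than one transcript, per-group mean
RPKM profiles are computed for each transcript (samples averaged within a
group first), each expressed transcript's profile is Pearson-correlated
with the gene-mean profile, and RC is the range (max − min) of those
correlations, so RC ∈ [0, 2]. RC > 1 means at least two isoforms move in
clearly different directions — an isoform switch. The four-way partition
is: *not expressed* (no transcript passes the gate in any group),
*single transcript* (exactly one does), *differential* (RC > 1),
*same direction* (RC ≤ 1 or undefined).

Open choices, decided as follows:

* **Correlation kind** — Pearson by default (the profiles are means on a
  ratio scale); Spearman is available, but with only four group values a
  rank correlation takes very few distinct values and is even noisier.
* **Scope of the gate** — "not expressed" is read as "in no group,
  including the benign reference"; a `tumor_groups_only` scope is exposed
  because the narrower reading is also defensible.
* **Unexpressed isoforms** — excluded from both the correlation set and
  the gene mean (default), since a profile that is entirely below the
  expression gate contributes only noise to the mean.
* **Degenerate profiles** — a zero-variance profile has no defined
  correlation and is dropped rather than assigned 0; if fewer than two
  defined correlations remain, RC is undefined and the gene falls in
  *same direction*.

With four points, RC is intrinsically noisy: at the default synthetic
counting noise (dispersion 0.1, i.e. ~30% CV) planted switches are
detected with only ~50% sensitivity. The ≥95% sensitivity/specificity
property holds when the RPKM coefficient of variation is at or below
about 10% of the profile signal, and the test suite checks it exactly
there. Specificity additionally requires that non-switch genes have *some*
real across-group variation — a perfectly flat gene's mean profile is pure
noise and its isoform correlations are meaningless, which is why the
generator gives every gene mild group-level biological variation.

## Cross-species joining

Gene symbols are harmonized by upper-casing at read time. Fish genes map
to human symbols through an explicit ortholog table; a species suffix
(the teleost "a"/"b" paralog convention) is only ever resolved through a
table row, never guessed from the symbol text. When two fish paralogs hit
one human symbol, the default `any_call` policy lets any called paralog
represent the symbol (ties broken by larger |log2FC|) — paralogs often
show subtype-specific expression, and requiring both copies to agree
would discard exactly the interesting cases. `max_fold` and `best_p`
policies are available. Only symbols present in both result sets are
kept; the join size and the species-exclusive counts are logged.

Conserved signatures are the symbols called in the same direction in both
species. Signature ("motif") overlaps count shared symbols whose linear
fold exceeds the threshold strictly in *all* supplied tumor contrasts
(proliferative/invasive motif convention) or in *at least one* (the
cross-fish comparison convention). Over-representation uses the upper-tail
hypergeometric probability with the expected count n·K/N reported
alongside.

## The synthetic generator

`simulate_study()` emulates the assumed statistical structure: NB counts
with dispersion α (default 0.1) at log-normal baseline expression
(median ≈ 20 concentration units ≈ RPKM), transcript lengths uniform in
500–5000 bp, per-sample depth factors, the reference pooled from five
virtual siblings (counts summed), 1–3 isoforms per gene, planted 8-fold
tumor effects (150 up, 150 down by default), half of them conserved in the
human arm, 100 human-only effects, 10% paralog duplicates, Gaussian log2
intensities with σ = 0.5 and one or two probes per gene. Planted switch
genes get two isoforms with asymmetric anti-correlated group profiles
whose correlation gap is exactly 2 before noise; the gene-mean profile
keeps a clean monotone trend so the statistic has something to detect.
Per-gene, per-group log-normal biological factors (CV 0.25 by default)
make non-switch genes realistically non-flat; they are not applied to
switch genes, whose profiles *are* their planted biology. All randomness
derives from one master seed (with fixed offsets for the human arm and
the signature draws), and same-seed runs are byte-identical.

What passing the synthetic suite shows: the estimators recover the
parameters of the model they assume, the statistics match independent
oracles exactly, both tests are calibrated under their nulls, and the full
chain recovers planted signals at the stated noise levels. What it cannot
show: robustness to features real data have and the generator does not —
batch effects, GC/length biases beyond the RPKM correction,
probe-sequence artifacts, annotation errors, and biological variance
structure richer than a single dispersion plus a group-level CV.

## Problem sizes and numerical choices

The default simulated study uses 8 000 fish genes (~10 000 transcripts)
and ~7 000 human probes — large enough for stable hyperparameter
estimation and small enough that the full chain runs in about a minute on
one CPU. Validation studies use 2 000 genes for dispersion recovery and
calibration, 5 000 genes for array-null calibration, 1 000 multi-isoform
genes for the RC oracle sweep, and 800 genes at low noise for switch
recovery. Calibration and recovery runs switch off the sibling pooling,
the group-level CV and multi-isoform aggregation (single-isoform
configuration) because they test the pure NB model: pooling sums five
draws and halves the apparent dispersion, and gene-level aggregation of
independent isoforms likewise dilutes it — both would bias a parameter-
recovery check that is meant to exercise the estimator, not the design.

Numerical conventions worth knowing: p-values are clamped into
(0, 1]; a total count of zero gives p = 1 by convention; the NB test's
tie tolerance and summation window are described above; results tables are
written as TAB-separated text with "." as decimal mark and round-trip
doubles bit-exactly (17-significant-digit formatting on write, and R's
correctly rounded `strtod` parser on read — fast TSV float parsers can be
off by one unit in the last place).

## Known limitations

* The no-replicate p-value inherits everything the blind variance fit
  assumes; with planted signal present it is conservative, and in
  single-sample mode it is advisory.
* RC with four groups is noisy (see above); no significance measure is
  attached to RC, matching the thresholding convention RC > 1.
* Probe collapsing by brightest probe ignores probe-specific
  cross-hybridization; the `mean` alternative trades that for dilution.
* The ortholog join is only as good as the supplied mapping table; no
  network lookups are performed by design.
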