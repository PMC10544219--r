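---
title: "Detecting RNA editing-enriched clusters with editclust"
author: "editclust authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting RNA editing-enriched clusters with editclust}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

RNA base-editing assays — either endogenous A-to-I editing by ADAR enzymes,
or engineered fusions of an RNA-binding protein to an editing enzyme
(STAMP with APOBEC1, TRIBE with ADAR) — leave per-site traces: positions
where some reads carry the converted base. Upstream callers such as SAILOR
report, per position, how many reads are edited and how many cover the
site. Many of those candidate sites are noise: off-target enzyme activity,
residual genetic variation, sequencing error. The biological signal of
interest is usually not an isolated site but a *region* where edits
accumulate above the sample's background, marking enzyme residency or a
binding footprint.

`editclust` turns per-site tables into statistically filtered, scored
cluster calls. The pipeline is: tile annotated genes into fixed windows;
count read-level edit and substrate instances per window; test each edited
window against a zero-truncated Poisson background whose rate is
stratified by region class and read depth; BH-adjust; merge surviving
windows into clusters; score clusters with a negative-binomial CDF.

## Counting: substrate and edit instances

For a conversion $X \to Y$ (say C-to-U, observed as C>T), the *editable*
positions of a window are those whose transcript-oriented reference base
is $X$; on minus-strand genes the genomic base compared is the complement.
Counting is at read level: a window's **substrate instances** are

$$n \;=\; \sum_{\text{editable } i} c_i,$$

the summed read coverage $c_i$ over its editable positions, and its
**edit instances** $k$ are the summed edited-read counts of the sites it
contains. The **edit fraction** is $k/n$. Read-level counting matters: a
30 bp window typically holds only a handful of editable bases, but at
coverage 50 it carries hundreds of substrate instances, and a single
edited read moves the fraction by $1/n$, not by one per position. Both a
coverage-track path (`aggregate_windows()`, from a bedGraph plus site
table) and an alignment path (`pileup_substrates()`, from SAM/BAM against
the reference) are provided; on inputs derived from the same alignments
they agree exactly, which the test suite asserts.

## The background model

Spurious edits are modelled as a Poisson process over substrate
instances: a window with $n$ substrate instances and background rate $r$
(edits per substrate instance) has mean $\lambda = r\,n$. Only windows
that contain at least one edit are ever examined — windows without a
called site never enter the table — so the null distribution is the
zero-truncated Poisson, and the upper-tail p-value of an observed count
$k \ge 1$ is

$$p \;=\; \Pr(K \ge k \mid K \ge 1)
    \;=\; \frac{1 - F(k-1;\lambda)}{1 - e^{-\lambda}},$$

with $F$ the Poisson CDF. A single-edit window has $p = 1$ by
construction: one edit is exactly the conditioning event and can never be
evidence of enrichment. The computation runs in log space
(`ppois(..., log.p = TRUE)` against `log(-expm1(-lambda))`) so that tiny
rates and large counts do not underflow.

### Stratified rate estimation

One global rate would miscalibrate the test twice over. Exons and introns
see different background editing (a cytoplasmic enzyme rarely meets
introns; a nuclear one does), so rates are estimated per region class.
And low-coverage windows have intrinsically inflated edit fractions among
the windows that show any edit at all: with $n = 5$ substrate instances a
single edited read is a fraction of 0.20, while the same single edit at
$n = 500$ is 0.002. `fit_background()` therefore estimates, per class, a
ladder of rates for depth strata bounded by thresholds 10, 20, 30, 40, 50
(read depth = floor of mean per-base coverage): the stratum "$< t$" rate
is the mean edit fraction of all qualifying windows of that class with
depth below $t$, and windows at depth $\ge 50$ use the mean over those
well-covered windows. A window is assigned the smallest threshold
strictly above its depth. The effect is that sparse evidence at shallow
windows must beat a *higher* bar than the same fraction at deep windows.

Two estimation details were genuinely open and are worth recording:

* **Which windows enter the means.** By default only windows carrying at
  least one edit do (`include_zero_windows = FALSE`). These are the
  windows the model actually tests, and conditioning on $k \ge 1$ is what
  produces the low-coverage inflation ($E[k/n \mid k \ge 1] \approx 1/n$
  for small $\lambda$) that the depth ladder exists to absorb: with
  zero-edit windows included, the per-stratum means all estimate the same
  underlying rate under uniform noise and the ladder would be inert. The
  inclusive mode is available behind the flag for samples where zero-edit
  windows are informative.
* **Empty strata.** A stratum with no qualifying windows inherits the
  nearest higher-threshold stratum's rate (ultimately the top stratum),
  keeping the ladder monotone in coverage. A stratum whose mean is
  exactly zero would make the truncation term degenerate; it is
  substituted with the smallest positive rate across strata, with a
  warning.

The fit is an ordinary S3 model object: `print()`, `summary()` and
`coef()` expose the rate table, `predict()` returns per-window
$\lambda$s, `simulate()` draws zero-truncated counts by inverse CDF (the
standard visual adequacy check via `plot()`), and `residuals()` gives
Pearson residuals under the truncated mean and variance.

## Selection, merging, scoring

All tested windows of a sample are Benjamini–Hochberg adjusted together
(one experiment-wide FDR; per-class adjustment sits behind
`adjust = "by_class"`), and windows with adjusted $p \le \alpha$
(default 0.1) are kept. Survivors are merged into clusters when they
share gene, region class, chromosome and strand and are separated by at
most 15 bp (`merge_distance`); merging never crosses genes or classes
because strata with different background rates should not pool evidence.
Cluster counts are the sums over member windows — members tile their
region without overlap, so this equals re-aggregating over the union of
member spans, which the tests assert; summing also avoids silently
counting never-selected bases inside bridged gaps.

Clusters are scored relative to the sample: with $\bar p$ the mean
cluster edit fraction (clamped to $(10^{-9}, 1-10^{-9})$), $k$ edit
instances and $r = n - k$ unedited instances, the score is the CDF at $k$
of the negative binomial counting edits accumulated before $r$ non-edits
at per-instance probability $\bar p$ — in R,
`pnbinom(k, size = r, prob = 1 - p_bar)`; fully edited clusters
($r = 0$) score 1. The score rises both with the edit fraction and with
the weight of evidence (more substrate at the same fraction sharpens the
CDF).

Two properties of this score shape how it should be used. It is
*relative*: a cluster whose fraction equals the sample mean scores near
0.5 regardless of how strong the enrichment was in absolute terms, so
score thresholds (0.95, 0.99) are prioritization tools within a sample,
not a second significance filter. And in data whose true signal strength
is *homogeneous* — as in a simulation where every planted focus edits at
the same rate — cluster scores spread almost uniformly over $(0,1)$ and a
0.95 cut retains only the sampling-noise upper tail; in real data, where
per-locus editing rates span more than an order of magnitude, the same
cut removes roughly the weaker half and keeps strongly edited loci. The
package's acceptance suite states this homogeneous-signal behaviour
quantitatively rather than hiding it: under the default recovery
simulation the unfiltered cluster set attains precision and recall above
0.9, while the score-filtered recall falls to a few percent, exactly as
the arithmetic above predicts.

The exact negative-binomial parametrization is not forced by the
method's description; the form above (failure-count $r$, success
probability $\bar p$, CDF at $k$) was chosen because it yields a
$[0, 1]$ score increasing in fraction and in evidence, and it is
isolated in `score_clusters()` for easy replacement.

## Evaluation utilities

* `scan_motif()` matches an IUPAC motif (U read as T) on either strand
  via `Biostrings::vmatchPattern(fixed = FALSE)`; minus-strand scanning
  searches the reverse complement on the forward sequence.
* `overlap_fraction()` reports the fraction of clusters touching a
  feature set (eCLIP peaks, motif hits, or their union), counting
  clusters rather than bases, with optional symmetric `slop`.
* `shuffle_enrichment()` builds the permutation null: each of 30
  artificial cluster sets relocates every cluster uniformly within its
  host exon or intron, preserving length and strand; enrichment is the
  observed overlap fraction divided by the mean null fraction. Shuffles
  are independent across clusters and may collide; inter-cluster spacing
  is not preserved. A cluster longer than every candidate parent stays in
  place with a warning.
* `intersect_replicates()` keeps first-replicate clusters overlapped
  (≥ 1 bp, same strand) in every other replicate; reciprocal-overlap
  rules were considered and rejected as stricter than the any-overlap
  reading.
* `efficiency_score()` supports window-size tuning: mean distinct edited
  positions per cluster divided by mean cluster length (bp). Its exact
  published form is not pinned down; the ratio-of-means realizes the two
  competing demands — many sites per cluster, small total footprint — and
  an alternative normalizing by total footprint sits behind `variant`.

## The synthetic generator

`generate_dataset()` emulates the statistical structure the model
assumes, not the full messiness of sequencing data. A random reference
carries multi-exon genes on alternating strands (defaults: 40 genes,
three 300 bp exons, 500 bp introns). Coverage is piecewise constant on
50 bp tiles, drawn from levels {5, 15, 25, 35, 45, 80} so every depth
stratum is populated; tiles over planted foci draw from {35, 45, 80} so
the planted signal is well covered. Every editable position with coverage
$c$ receives $\mathrm{Binomial}(c, r)$ edited reads — $r$ = 0.05 inside
the 50 planted 60 bp foci, 0.001 elsewhere — and positions with at least
one edited read are emitted as sites. Noise is generated binomially per
read; the Poisson background is the analysis approximation of that
process, which is the point of the model-adequacy checks. Everything is
deterministic under the configured seed, and a minimal SAM emitter
(`write_synthetic_sam()`) produces alignments whose pileup reproduces the
site table exactly, for testing the alignment path.

Calibration experiments in the test suite use a background-only variant
at rate 0.008, a moderately edited background typical of an unfused
enzyme control: at the recovery default of 0.001 a desk-scale genome
yields essentially no multi-edit windows, and both arms of the
stratification comparison would be empty. Problem sizes throughout the
tests (10–40 genes, ~1–3 thousand windows, 5–50 replicate seeds) were
chosen so the suite completes in minutes while leaving dozens to
hundreds of events in every assertion's denominator.

What the generator does not emulate — and what passing tests therefore do
not show about real data: SNP contamination and its removal, sequencing
error structure and base qualities, per-read strand errors,
transcript-isoform ambiguity, overdispersed (gene-specific) background
editing, and coverage autocorrelation beyond 50 bp tiles. The FDR
guarantees demonstrated here are guarantees under binomial noise with a
correctly specified substrate; real libraries violate these in ways the
confidence-score input and the replicate-intersection utility are meant
to absorb.

## Numerical and degenerate-input choices

* ZTP p-values: log-space throughout; `k = 1` returns exactly 1;
  `lambda = 0` with `k >= 1` (possible only through pathological rate
  tables) yields the smallest representable positive p-value with a
  warning rather than an error, so one empty stratum cannot abort a run.
* Windows shorter than the window size (region remainders) are kept and
  tested; their smaller substrate count shrinks $\lambda$ naturally.
* Remainder conventions: window indices run along the genome regardless
  of strand; overlapping genes produce independent window sets keyed by
  `gene_id:class:index`.
* `simulate()` clamps inverse-CDF draws to $\ge 1$ (rounding can lose the
  truncation at $\lambda \approx 0$).
* Merging of an unsorted selection sorts internally; ties in BH follow
  `stats::p.adjust`.
* With fewer than two clusters no score model is fitted and scores are
  reported missing rather than defaulting.

## Limitations

The background is a single rate per (class, stratum); gene-level
covariates (expression, double-strandedness, repeat content) are not
modelled, and very highly covered windows are known to sit above the
Poisson fit's fidelity, erring conservative. Differential-editing
inference between conditions is out of scope: `compare_conditions()`
reports per-cluster fraction ratios and directional consistency, and any
formal test should be run downstream on the pooled counts.
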