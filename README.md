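# editclust

Detection of RNA editing-enriched genomic clusters from strand-resolved
per-site edit tables, using a coverage-stratified zero-truncated Poisson
background model.

## Who this is for

RNA base-editing experiments — engineered RBP–editing-enzyme fusions
(STAMP/APOBEC1, TRIBE/ADAR) as well as endogenous ADAR A-to-I editing —
yield per-site tables from callers such as SAILOR: for each candidate
position, the number of edited reads and total reads. Individual sites are
noisy (off-target editing, residual SNPs, sequencing error); the unit of
biological interest is a *region* where edits accumulate above the
sample's background. `editclust` is for analysts who have a site table, a
coverage track, a reference and a gene annotation, and want statistically
filtered, scored cluster calls plus the evaluation machinery around them
(motif/feature overlap, permutation nulls, replicate intersection,
window-size tuning).

## The model

Genes are tiled into fixed windows (default 30 bp) separately over exons
(unioned across transcripts) and introns. For a conversion X>Y, a window's
**substrate instances** are the read-level count
*n* = Σ coverage over positions whose transcript-oriented base is X, its
**edit instances** *k* are the summed edited reads of contained sites, and
its edit fraction is *k/n*. Since only windows containing an edit are
examined, each edited window is tested against a **zero-truncated
Poisson** null,

  p = P(K ≥ k | K ≥ 1) = [1 − F(k−1; λ)] / (1 − e^(−λ)),  λ = r·n,

where the background rate *r* (edits per substrate instance) is estimated
separately per region class (exon/intron) and per read-depth stratum
(thresholds 10/20/30/40/50): shallow windows, whose edit fractions are
inflated by conditioning on ≥ 1 edit, are held to the mean fraction of
similarly shallow windows. P-values are Benjamini–Hochberg adjusted across
all tested windows; windows with adjusted p ≤ 0.1 are merged into clusters
across gaps of at most 15 bp (never across genes, classes or strands).
Each cluster is scored with the negative-binomial CDF
`pnbinom(k, size = n − k, prob = 1 − p̄)`, where p̄ is the sample's mean
cluster edit fraction — a relative, within-sample prioritization score in
[0, 1].

A fully self-contained synthetic generator (`generate_dataset()`) plants
high-rate editing foci on a binomial background and is used for
calibration, parameter-recovery and determinism checks.

## Worked example

```r
library(editclust)

cfg <- simulation_config(seed = 7)   # 40 genes, 50 planted foci, C>T
ds  <- generate_dataset(cfg, dir = "example")

rc  <- run_config(annotation = ds$paths$annotation,
                  reference  = ds$paths$reference,
                  sites      = ds$paths$sites,
                  coverage   = ds$paths$coverage,
                  out_dir    = "example/out")
res <- run_end_to_end(rc)
#> stage windows: tiling annotation
#> stage tabulate: aggregating edit and substrate instances
#> stage model: fitting background and testing windows
#> stage clusters: merging and scoring
#> done: 2560 windows, 623 tested, 50 clusters

print(res$fit)
#> Stratified zero-truncated Poisson background model
#>   region classes: exon, intron
#>   depth strata:   < 10, < 20, < 30, < 40, < 50, top
#>   rate estimation: edited windows only
#>   training windows: 2559 ( 623 edited )

head(as.data.frame(res$clusters)[, c("seqnames", "start", "end", "strand",
                                     "gene_id", "region_class",
                                     "edit_fraction", "score")], 5)
#>   seqnames start  end strand gene_id region_class edit_fraction     score
#> 1     chrS  4911 4970      + gene003       intron    0.05299145 0.8240168
#> 2     chrS  5381 5470      + gene003         exon    0.04096386 0.2276392
#> 3     chrS  7391 7450      - gene004         exon    0.03930131 0.1616138
#> 4     chrS  9491 9520      + gene005         exon    0.04722222 0.6128628
#> 5     chrS  9551 9580      + gene005         exon    0.03809524 0.3112415

rec <- evaluate_recovery(res$clusters, ds$foci)
sprintf("precision %.2f recall %.2f f1 %.3f", rec$precision, rec$recall,
        rec$f1)
#> [1] "precision 1.00 recall 0.98 f1 0.990"

efficiency_score(res$clusters)
#> [1] 0.1988304
```

The 50 called clusters sit on the planted foci (precision 1.00, recall
0.98): the zero-truncated Poisson filter discards the ~500 background
windows that carried only sporadic edits. Cluster edit fractions hover
near the planted focus rate of 0.05, and the scores — which rank each
cluster's fraction against the sample mean — spread across (0, 1) because
every planted focus edits at the same rate; in real data, where per-locus
rates vary widely, high scores isolate the strongly edited loci.

Stage tables (`windows.bed`, `window_stats.tsv`, `rates.tsv`,
`window_tests.tsv`, `clusters.bed`, `run_report.txt`) are written to the
output directory; reruns with the same inputs and configuration are
byte-identical.

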