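---
title: "Methods: dose-dependent cistrome comparison and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dose-dependent cistrome comparison and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model behind each stage of
`cistromedose`, the conventions and tunable parameters, what the
synthetic-data generator does and does not emulate, and the design
choices made where more than one reasonable convention exists.

## The analysis problem

A ligand-activated transcription factor (the motivating case is the
androgen receptor in a prostate-cancer cell line) binds thousands of
genomic sites with a wide spectrum of affinities. A competitive
antagonist does not silence this binding landscape uniformly: as dose
increases, occupancy is lost preferentially at weak sites, so the
treated cistromes form a nearly nested series that terminates, at full
antagonism, near the binding pattern seen without agonist at all. The
package quantifies this process and couples it to expression changes to
classify the genes the factor directly activates or represses.

## Coordinates and containers

All coordinates are 0-based half-open (BED convention) internally; BED
is read and written natively and MACS-style 1-based tables are converted
on read. A `CistromeSet` is a per-condition peak table (interval,
summit, binding score, fold enrichment, unique id). Overlap between
peaks means sharing at least 1 bp; half-open adjacency does not count.
Overlap algebra is delegated to `GenomicRanges`.

## High-confidence filtering against swapped-channel negatives

Peak callers emit many marginal calls. The filter keeps peaks whose
binding score **and** fold enrichment meet joint cutoffs (defaults 500
and 20, on the score scale of a `-10 log10 p`-style caller). The
defaults correspond to calibration against *negative peaks* — peaks
called after swapping the ChIP and control channels, which measure
technical noise only. In `thresholds = "auto"` mode the cutoffs are
derived from the supplied negative set directly: the smallest round
values strictly exceeding every negative peak (scores rounded up to the
next multiple of 10, fold enrichments to the next integer). Rounding
makes the calibrated cutoffs stable against single marginal negative
peaks while guaranteeing that no negative peak survives its own
calibration. Filtering is monotone in both cutoffs.

## Robust per-site signal and fold changes

Tag 5' positions are extended `extension` bp in the 3' direction
(default 200 bp, the midpoint of typical chromatin fragment sizes;
configurable because the appropriate value depends on library
preparation) and counted into fixed `bin_size = 32` nt bins. The signal
of a site is the one-step Tukey biweight of the bins overlapping the
site by at least 1 bp:

* `m = median(x)`, `s = median(|x − m|)` (raw, unscaled MAD),
* `u_i = (x_i − m) / (c·s + ε)` with `c = 5`, `ε = 1e−4`,
* `w_i = (1 − u_i²)²` when `|u_i| < 1`, else 0,
* signal `= Σ w_i x_i / Σ w_i`.

These constants follow the dominant one-step biweight convention in
microarray signal processing. Two consequences worth knowing: with
`s = 0` (more than half the bins identical) any bin off the median gets
zero weight, so isolated outliers are dropped entirely; and for tightly
clustered data the estimate is close to, but not exactly, the
arithmetic mean (the bisquare weights still vary slightly within the
band). The "bins overlapping by ≥ 1 bp" rule avoids empty-bin edge
cases for peaks shorter than one bin.

Cross-condition comparison uses signed fold changes
`f = r if r ≥ 1 else −1/r` of the two signals, so magnitudes are
symmetric about 1 and sign carries direction. When either signal is 0 a
pseudocount of 0.5 is added to both before the ratio, keeping fold
changes finite while preserving their order. Trends along the
binding-strength spectrum are displayed as a moving average (window 100
sites) with a least-squares line over the smoothed series.

Sites are ordered by descending binding score, ties by descending fold
enrichment, remaining ties by coordinate — a stable, documented total
order.

## The percent-impact metric

"Maximum" and "minimum" binding are defined by the untreated
high-agonist and agonist-free cistromes. The *differential* sites are
the maximum-cistrome sites with no overlap in the minimum cistrome;
percent impact of a treated cistrome is

> 100 × (differential sites with no overlap in the treated cistrome) /
> (differential sites).

Treated = maximum gives 0; treated = minimum gives 100; for nested
treated sets the metric is monotone in dose. Impact is deliberately
binary (presence/absence by overlap) rather than a signal-ratio
threshold: it counts differentially *occupied* sites, and peak
boundaries shift between independent calls, which overlap matching
absorbs. The signal-ratio view is available separately through
`site_fold_changes()`. If the minimum set is not in fact a subset of
the maximum set the function warns and proceeds on the differential
sites as defined.

## Conservation profiling

Conservation is sampled every 100 bp from each summit to ±10 kb (201
points): the value at a position is the score of the covering conserved
element, or 0 outside all elements — a point lookup, not a window
average, matching how element tracks are defined. Mean profiles over a
cistrome peak at the summit when functional elements are
summit-centered. For the binary conserved/non-conserved classification
a site is conserved when its summit is covered; association with
regulation mode uses the two-tailed Fisher exact test (degenerate
margins return p = 1 by convention).

## Motif statistics

PWMs are column-stochastic 4×w matrices with a 0.01 pseudocount per
cell (small enough to preserve specificity, large enough to keep
log-odds finite). Scanning is a plain log2-odds scan of both strands;
reverse-strand windows are scored on the reverse complement and
reported at their position on the input strand; windows containing
non-ACGT bases are skipped. The default score threshold is 60% of the
PWM's maximal achievable log-odds against the background — an
absolute-bits option is exposed, and the matched-background Z-score
analyses in this package pass an absolute threshold chosen so that
background hit counts are non-degenerate (a threshold so strict that
random groups contain no hits makes the Z denominator zero; the
function flags this with a warning rather than fabricating a finite
value). The background is taken from the scanned sequences' composition
unless supplied.

Specificity is a Z-score against 100 random groups of the same number
of sequences of the same lengths from the same chromosomes:
`Z = (n_bound − μ)/σ` over the group hit counts, reproducible
bit-for-bit given the seed. Element-pair spacing is the
middle-to-middle distance between co-occurring hits within 10–50 bp,
histogrammed with the modal distance reported (smallest on ties).
A palindromic PWM — one equal to its reverse complement transform —
is the signature of a factor binding as a head-to-head dimer, and its
hits come in equal-scoring +/− pairs at the same position.

Ab initio motif discovery is out of scope; the package instead provides
`extract_summit_sequences()` (strongest 2500 sites, trimmed to 500 bp
around the summit) to feed external discovery tools, plus MEME-minimal
and TSV PWM I/O to bring the result back in.

## Expression integration

Differential-expression tables carry signed-ratio fold changes and
q-values from upstream microarray/RNA analysis (their production —
normalization, moderated tests — is consumed, not reimplemented). A
gene is significant when any probe passes `q < 0.05` and `|FC| > 1.5`
(both strict); genes whose passing probes disagree in direction are
excluded. Genes associate with peaks whose summit lies within 25 kb of
a TSS — summit rather than peak edge because the summit carries the
signal maximum, and inclusive at the boundary ("within" read as ≤);
multi-transcript genes use their nearest TSS. Direct activation targets
= impacted binding ∩ down-regulated; direct repression targets =
impacted binding ∩ up-regulated. "Impacted" means present in the
untreated maximum high-confidence cistrome but absent (no ≥ 1 bp
overlap) from the treated cistrome at the stated dose.

The packaged qPCR table is correlated on the raw scale by default (a
log option exists): the raw-scale Pearson R on the 11 complete rows
reproduces the published concordance, which is how the default was
fixed. The published p-value for that correlation corresponds to the
one-sided tail of the test; `qpcr_concordance()` therefore reports both
sidednesses.

For genome-wide profile concordance, signed-ratio fold changes are
mapped to log2 scale before correlating (so +2 and −2 are symmetric);
d-scores are correlated as-is.

## Signature enrichment

Signatures are intersected with the gene universe before testing; the
default universe is the expression platform's gene set, which is what
makes "expected" overlap fractions meaningful. Enrichment p is the
upper cumulative hypergeometric tail; multiple testing uses Storey
q-values with π0 estimated at a single fixed λ = 0.5
(`π0 = min(1, mean(p > λ)/(1 − λ))`), deterministic and smoother-free;
forcing `pi0 = 1` yields exactly Benjamini–Hochberg. The exported
network keeps signatures with q below the FDR cutoff as nodes (weight =
signature size) and connects pairs by `−log10` of their pairwise
overlap hypergeometric p, dropping non-enriched (p = 1) edges.

## The synthetic-data generator

The generator's defaults define the study conditions the validation
runs under:

* genome: 4 chromosomes × 5 Mb; 2000 sites on a jittered grid
  (guaranteeing separation while keeping placement random), width
  400 bp;
* affinities log-normal (meanlog 0, sdlog 0.5) — a long-tailed
  spectrum of binding strengths;
* five conditions with occupancy-quantile thresholds 0 (agonist-only
  reference), 0.2592, 0.5184, 0.8554 (three antagonist doses) and
  0.864 (agonist-free minimum). A site is occupied when its affinity
  reaches the condition's threshold, flipped with probability 0.02
  independently per site and condition. The dose quantiles were set so
  the planted impacts are about 30%, 60% and 99% of the differential
  sites — a saturating dose-response curve whose top dose drives
  binding essentially from maximum to minimum, and the minimum quantile
  so that roughly 14% of sites persist without agonist;
* tag tracks: Poisson bins with background mean 2 per 32-nt bin (about
  the genome-wide density of a 50M-read experiment) plus
  `enrichment_gain × affinity` at occupied sites. Sites below a
  condition's threshold retain a residual
  `(affinity/threshold)^2` fraction of their enrichment — mass-action
  style depletion, so sites further below threshold lose
  proportionally more signal. This is what produces the observed
  pattern that fold-change magnitude grows along descending binding
  strength: with all-or-nothing loss the reference signal of a strong
  lost site would dominate the ratio and invert the gradient;
* emitted scores/fold enrichments are linear in affinity
  (`510 + 350·a`, `21 + 10·a`, small Gaussian noise), spanning roughly
  500–3100 and 20–45, comfortably above the default cutoffs; 300
  negative peaks per condition are placed clear of true sites with
  scores strictly below the cutoffs, so auto-calibration always
  excludes them;
* conservation: elements of width 300 and score 0.85 centered on
  occupied summits;
* sequences (optional, as genome synthesis dominates run time): a
  15-bp perfectly palindromic element centered on each summit plus a
  7-bp partner element 15 bp away middle-to-middle, with per-base
  consensus mutation rates shrinking with affinity rank so stronger
  sites carry cleaner motifs;
* expression: 1000 genes, 40% linked one-to-one to sites with TSS
  0.5–20 kb from the summit; genes whose linked site is lost respond
  with log2 magnitudes ~N(1.3, 0.35) (clear of the 1.5-fold cutoff in
  expectation), signed by regulation mode; all other genes are null
  with d-scores ~N(0, 1) and uniform p-values; q-values come from the
  package's own Storey procedure on the resulting mixture.

Randomness uses one root seed with named substreams per emission step,
so adding a condition never perturbs earlier draws and every emission
is reproducible in isolation.

**What the generator does not emulate** — and hence what passing
recovery tests do and do not show: mappability artifacts, duplicate
reads and GC bias; peak-boundary jitter between conditions (emitted
intervals are exact, so overlap matching is never stressed by
half-shifted peaks); correlated occupancy noise; probe-level expression
structure beyond one probe per gene; repeats and compositional
heterogeneity in the genome background. Recovery of planted parameters
therefore validates the statistical logic of the pipeline, not its
robustness to alignment-level artifacts of real sequencing data.

## Validation problem sizes

The test suite validates parameter recovery at 2000 sites / 1000 genes
(the generator defaults) for impact, targets and trend; 200
sequence-bearing sites on a 2 × 2 Mb genome for spacing, conservation
geometry and motif Z (sparse enough that neighboring sites' conserved
elements contribute < 0.02 to the profile tails); exhaustive
enumeration oracles for every hypergeometric configuration with
universe ≤ 12 and all 2×2 Fisher tables with cell counts ≤ 4; and 1000
random vectors (a quarter constructed to have MAD = 0) for the
biweight. Smaller per-module fixtures are built inline in the tests.

## Annotation conventions

Peak annotation uses precedence promoter > exonic > intronic >
intergenic (a peak overlapping both promoter and exon counts as
promoter), with promoters as strand-aware windows −1000/+100 around
each TSS. These are fixed documented conventions chosen for
reproducibility; commercial annotation taxonomies are not reproduced.
Enrichment per category is the observed peak fraction over the genomic
background fraction of that category under the same precedence, `NA`
when a category covers no background.

## Known limitations

* The percent-impact reading — binary loss of overlap-matched presence —
  is one committed interpretation of "impact on differentially occupied
  sites"; a signal-ratio variant can be built from
  `site_fold_changes()` but is not the reported metric.
* Auto-calibrated cutoffs depend on the negative set being a faithful
  noise model; a contaminated negative set inflates the cutoffs.
* The Z-score's matched background controls for sequence length and
  chromosome, not for local composition (GC, repeats).
* The q-value π0 estimate at a single λ is slightly conservative for
  strongly non-uniform p-value distributions.
* File-based pipeline runs cover the filtering/impact/target stages;
  signal, conservation and motif stages require binned tracks and
  genome sequence, which the file mode does not currently ingest.
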