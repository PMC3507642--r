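# cistromedose

Dose-dependent cistrome comparison for nuclear-receptor antagonists, with
transcriptome integration.

When a transcription factor such as the androgen receptor (AR) is
inhibited by a small-molecule antagonist, its genome-wide set of binding
sites (its *cistrome*) does not collapse uniformly: weaker sites are lost
first, and the surviving sites are the strongest ones — the same pattern
seen when the hormonal ligand itself is scarce. `cistromedose` packages
the analysis needed to quantify that process from ChIP-seq-style data and
to connect it to gene expression:

- **High-confidence filtering.** Peaks are kept when their binding score
  and fold enrichment jointly exceed cutoffs calibrated against
  "negative" peaks called with the ChIP and control channels swapped — a
  technical-noise yardstick with no biological meaning.
- **Robust per-site signal.** Tag densities in fixed 32-nt bins are
  combined over each site with the one-step Tukey biweight
  (`u_i = (x_i − m)/(c·s + ε)` with `m` the median, `s` the raw MAD,
  `c = 5`; weights `(1 − u_i²)²` inside `|u_i| < 1`, else 0), so isolated
  noisy bins do not distort the site's signal. Cross-condition changes
  are reported as signed fold changes: the ratio `r` when `r ≥ 1`, else
  `−1/r`.
- **The percent-impact dose metric.** With "maximum" and "minimum"
  cistromes defined by the untreated high- and low-agonist conditions,
  the *differential* sites are those present in the maximum but not the
  minimum (≥ 1 bp overlap). The percent impact of a dose is the
  percentage of differential sites absent from the treated cistrome:
  0 at maximum binding, 100 when treatment reduces binding to the
  minimum pattern.
- **Sequence context.** Summit-anchored phastCons-style conservation
  profiles; log-odds PWM scanning of a palindromic hormone-response
  element and its partner motif; matched-background specificity Z-scores
  (`Z = (n_bound − μ_random)/σ_random` over 100 length- and
  chromosome-matched random sequence groups); middle-to-middle element
  spacing histograms.
- **Cistrome–transcriptome integration.** Genes are associated with
  peaks within 25 kb of their TSS. *Direct activation targets* are genes
  with antagonist-impacted binding whose expression falls
  (FDR < 0.05, |FC| > 1.5); *direct repression targets* have impacted
  binding and rising expression. Target lists are tested against GMT
  gene-signature collections with the cumulative hypergeometric
  distribution and Storey q-values.
- **Synthetic experiments with known truth.** A generator emits complete
  dose-series data sets — binned tag tracks, positive and
  swapped-channel peak sets, conserved elements, motif-bearing
  sequences, and coupled expression tables — from a configurable ground
  truth, so the whole pipeline can be validated by parameter recovery.

## Worked example

A complete synthetic dose series (2000 sites, five conditions, 2%
occupancy noise) analysed end to end:

```r
library(cistromedose)
report <- run_pipeline(run_config(synthetic = list(seed = 1)))
print(report)
#> RunReport
#>   stages: filter, impact, signal, conservation, targets
#>   high-confidence sites:
#>   R1881plus antag_0.1uM   antag_1uM  antag_10uM  R1881minus
#>        1962        1463         962         317         300
#>   percent impact by dose:
#>     condition n_sites percent_impact
#> 1 antag_0.1uM    1463       30.95381
#> 2   antag_1uM     962       59.74805
#> 3  antag_10uM     317       96.82064
#>   direct targets: 159 activation, 163 repression
```

Reading the output: the antagonist removes binding sites
dose-dependently (1962 → 317 high-confidence sites), and at the top dose
the percent impact approaches 100 — binding has been reduced nearly to
the low-agonist minimum. The fold-change trend along descending binding
strength is strongly positive (`report$trend$spearman_rho` = 0.83),
i.e. weaker sites experience larger signal losses, and the classifier
recovers the planted direct targets almost perfectly
(`report$targets$sensitivity` = 0.98, precision 1.00).

The packaged qPCR validation table (12 ChIP-enriched regions assayed
against a gene-desert negative control) reproduces the concordance
between peak-caller score and independent enrichment measurements:

```r
conc <- qpcr_concordance(ar_qpcr_sites())
round(c(r = conc$r, p = conc$p_one_sided, n = conc$n), 5)
#>       r       p       n
#> 0.86986 0.00025 11.00000
qpcr_fold_filter(ar_qpcr_sites(), 3)
#> [1] 12
```

All 12 regions exceed 3-fold enrichment, and the correlation over the 11
regions with a binding score is R = 0.87.

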