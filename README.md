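# dupliTE

Transposable elements (TEs) accumulate around genes and recruit
chromatin-level silencing that can spill over onto their neighbors.
`dupliTE` asks what that means for **duplicated genes** — human gene
families with exactly two functional copies: do the two copies sit in
similar TE neighborhoods more often than chance, and is a shared TE
neighborhood associated with better-conserved histone modification
levels, DNA methylation, and expression?

The package is a complete, tested re-implementation of that analysis
chain for epigenomics/regulatory-genomics researchers:

* **TE neighborhood metrics** — for each gene, insertion *density*
  (insertions/bp) and nucleotide *coverage* (fraction of bases in the
  union of TE intervals) over the gene body ± 2 kb flanks.
* **Five TE categories** — TE-free by rule (density = coverage = 0), then
  PAM k-medoids (k = 4) on raw (density, coverage) for the rest, labels
  ordered by medoid density: TE-very-poor → TE-very-rich.
* **Epigenetic summaries** — per gene × cell type: mean fold enrichment
  for six histone marks (enrichment × covered bases / gene length), and a
  length-weighted methylation mean with hypo (< 0.25) / hyper (> 0.75)
  status calls.
* **Expression divergence** — FPKM → TPM
  (`TPM_i = FPKM_i / ΣFPKM × 10⁶` per cell type), expressed flag at
  FPKM ≥ 0.5, and the Manhattan divergence between family members

  ```
  d_m = 1/2 Σ_k | g1_k/Σg1 − g2_k/Σg2 |        (total variation, in [0,1])
  ```

* **Family statistics** — dS-based age classes (young < 1 ≤ middle-age
  < 2 ≤ old), the 15-cell unordered pair-context table over the five
  categories with a Pearson goodness-of-fit statistic and Monte-Carlo
  p-value `(1 + #{X²_sim ≥ X²_obs})/(B + 1)` from B = 2000 multinomial
  resamples, within-family Spearman correlations with Benjamini–Hochberg
  q-values, and Kolmogorov–Smirnov / Kruskal–Wallis comparisons.
* **Synthetic data generator** — a seeded, statistically controlled
  input bundle (genes, Poisson TE insertions, families with dS/dN,
  copula-correlated enrichment and methylation tracks, Dirichlet
  expression profiles) so the whole pipeline runs and is validated with
  no external downloads.

## Worked example

The headline test runs straight from tabulated category counts. Feeding
the duplicated genes' category marginals and the 15 observed family pair
counts:

```r
library(dupliTE)
res <- from_printed_tables(
  marginals   = c(109, 713, 915, 729, 374),
  pair_counts = c(20,
                  36, 121,
                  18, 220, 169,
                  13, 143, 229, 110,
                  2, 72, 110, 124, 33),
  B = 2000, seed = 1)
round(res$statistic, 2)        # 226.52
signif(res$p.value, 4)         # 0.0004998  (= 1/2001, the smallest attainable)
round(100 * res$same_fraction, 1)  # 31.9
```

The chi-squared of 226.52 says the observed pairings are far from what
independent category draws would produce; the Monte-Carlo p-value hits
the B = 2000 floor of 1/2001; and 31.9% of families have both copies in
the same TE-neighborhood category.

A fully synthetic end-to-end run:

```r
bundle <- simulate_te_dataset(generator_config(seed = 1))
report <- run_pipeline(bundle, pipeline_config(seed = 1))
report$category_distribution   # gene counts per TE category
report$pair_context            # observed table, chi-squared, Monte-Carlo p
head(report$correlations)      # within-family Spearman rho / p / q
write_report(report, "report") # TSV + JSON artifacts with seeds echoed
```

And the hand-sized fixture whose every number is hand-computed:

```r
fx <- worked_fixture()
te_environment(fx$bundle$genes, fx$bundle$tes)[1, c("density", "coverage")]
#   density coverage
# 1   4e-04      0.2
family_divergence(fx$bundle$fpkm, fx$bundle$families)$d_m
# 0.5 1.0 0.0
```

A thin CLI wrapping the same functions ships in `inst/cli/dupliTE.R`
(subcommands `simulate`, `analyze`, `from-printed-tables`).

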