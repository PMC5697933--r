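# dailoc — somato-dendritic mRNA localization analysis

Neurons place specific mRNAs into their dendrites for local translation.
When the two compartments of hippocampal CA1 — the cell-body layer
(stratum pyramidale, SP) and the apical-dendrite layer (stratum radiatum,
SR) — are microdissected and sequenced separately, each gene gets a
**dendritic accumulation index**

    DAI_g = mean FPKM_g(SR) / mean FPKM_g(SP)

with DAI > 1 meaning dendritic enrichment. `dailoc` implements, for anyone
analysing such layer-resolved (or more generally compartment-resolved)
RNA-seq designs:

* FPKM and DAI quantification with strict zero-expression handling;
* classification of transcripts into dendritically enriched (D-mRNA),
  somatically enriched (S-mRNA) and non-significant sets — per-gene
  SP-vs-SR test on log2(FPKM + 0.125), Benjamini–Hochberg FDR, DAI > 1 /
  DAI < 1 split, and removal of genes on cell-type exclusion lists;
* genotype comparison of localization asymmetry: per-genotype variance s²
  of log2 DAI over the D ∪ S set, the two-sided variance-ratio test
  F0 = s²_control / s²_cKO, per-class selectivity correlations |r| between
  baseline DAI and the relative DAI (cKO/control), and selection of
  D-mRNAs with relative DAI < 0.8 ("reduced dendritic localization");
* hypergeometric GO over-representation with an annotation-restricted
  universe and BH control;
* a negative-binomial simulator of the whole design (4 groups × 3
  replicates, ~6,000 genes plus contaminants, zero-sum log-DAI ground
  truth, knockout effect calibrated to a true variance ratio ≈ 1.78) so
  every stage can be validated against planted truth.

The modelling interface is classic R: `dai_fit()` returns a `dai_fit`
object with `print`, `summary`, `coef` and `plot` (MA plot) methods;
`run_pipeline()` drives the same analysis from tab-separated files on disk.

## Worked example

```r
library(dailoc)

cfg <- sim_config(n_genes = 2000, n_contaminant_genes = 100,
                  library_size_per_sample = 2e6, seed = 3)
sim <- simulate_dataset(cfg)
contam <- sim$truth$gene_id[sim$truth$true_class == "contaminant"]
fit <- dai_fit(sim$matrix, exclusions = contam)
summary(fit)
#> Somato-dendritic localization analysis
#>   2100 genes; reference genotype: control; alpha = 0.05
#>   D-mRNAs: 266  S-mRNAs: 331  non-significant: 1403
#>   excluded: 100  unexpressed: 0
#>   variance of log2 DAI (D u S, n = 597): s2_control = 3.243, s2_cKO = 1.852
#>   variance-ratio test: F0 = 1.752, two-sided p = 1.08e-11
#>   selectivity |r|: D-mRNAs 0.1732, S-mRNAs 0.2051
#>   D-mRNAs with relative DAI < 0.8: 173
```

Reading the output: of 2100 simulated genes, 266 are called dendritic and
331 somatic in the control genotype (the 100 known contaminants were removed
by the exclusion list). Over those 597 classified genes the variance of
log2 DAI drops from 3.24 in controls to 1.85 in the conditional knockout —
a variance ratio F0 = 1.75 with p ≈ 1e-11, the genome-wide signature of
collapsing somato-dendritic asymmetry — and 173 D-mRNAs lose more than 20%
of their dendritic accumulation. `plot(fit, genotype = "control")` draws the
MA plot with D- and S-mRNAs accentuated.

## Package layout

* `R/simulate.R` — `sim_config()`, `simulate_dataset()`, `apply_ko_effect()`,
  `write_fixture()`
* `R/io.R` — tab-separated readers/writers, exclusion lists, GO annotation
* `R/quantify.R` — `compute_fpkm()`, `compute_dai()`, `relative_dai()`,
  `ma_coordinates()`
* `R/classify.R` — `test_layer_enrichment()`, `bh_adjust()`, `classify_genes()`
* `R/asymmetry.R` — `dai_variance()`, `variance_f_test()`,
  `selectivity_correlation()`, `select_reduced_d_mrnas()`
* `R/enrichment.R` — `hypergeom_upper_tail()`, `go_enrichment()`
* `R/fit.R`, `R/pipeline.R` — the `dai_fit` model object and `run_pipeline()`

The methods vignette (`vignettes/dai-localization-methods.Rmd`) documents
the model, the generator's assumptions and the numerical choices in detail.
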