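# methnoise

**Does gene body DNA methylation suppress transcriptional noise?**

`methnoise` is an R package for epigenomics analysts who want to relate
nucleotide-resolution DNA methylation (whole-genome bisulfite calls) to
transcriptional noise measured from replicate expression arrays. It
implements the complete analysis path — bisulfite call aggregation,
replicate curation, noise estimation, variance decomposition, and a
multicollinearity-screened regression suite — together with a synthetic
data generator with planted, recoverable effect sizes that validates every
stage.

## The model

Transcriptional noise of gene *g* is approximated by the coefficient of
variation of its intensity across replicate arrays of one tissue,
CV = sd/mean. The core model is

```
log CV_g = β0 + β1·log(abundance_g) + β2·m_body(g) + β3·m_prom(g)
         + β4·log(length_g) + ε_g
```

where `m_body` is the mean fractional methylation, `c/(c+t)` per CpG, over
the TE-masked gene body (longest transcript), and `m_prom` over the window
1,500 bp upstream to 500 bp downstream of the strand-aware TSS. The suite
fits this by OLS (with VIFs per term), by Huber / bisquare / Hampel
M-estimation, and by median (τ = 0.5) quantile regression; a sequential-SS
ANOVA adds an individual factor and its interaction with body methylation.
For nested technical-within-biological replicate designs, the per-gene
total sum of squares is decomposed exactly into

```
SS_total = SS_bio + SS_tech,   SS_bio = n_tech · Σ_i (ȳ_i − ȳ̄)²,
                               SS_tech = Σ_ij (y_ij − ȳ_i)²
```

and the biological component is modelled separately
(`fit_biological_model()`, `fit_technical_adjusted_model()`).

## Worked example

A fully synthetic scenario: 1,000 genes with planted effects
(abundance −0.55, body methylation −0.30, promoter +0.25, length 0) on
log CV, sequenced at 30× CpG coverage and expressed on 12 arrays.

```r
library(methnoise)
cfg   <- sim_config(n_genes = 1000, n_arrays = 12, seed = 1)
sc    <- simulate_scenario(cfg)
meth  <- feature_methylation(sc$calls, sc$annotations$genes,
                             sc$annotations$tes)
noise <- expression_noise(quantile_normalize(qc_filter(sc$expression)$matrix))
d <- merge(merge(noise, meth, by = "gene_id"),
           sc$truth[c("gene_id", "length")], by = "gene_id")
d$log_length <- log(d$length)
fit_ols(log_cv ~ log_abundance + body_meth + promoter_meth + log_length, d)
```

```
<methnoise_fit: ols, n = 996>
          term  estimate      se        t         p   vif
   (Intercept)  1.252309 0.11549  10.8437 5.736e-26    NA
 log_abundance -0.525468 0.00833 -63.0830 0.000e+00 1.194
     body_meth -0.352752 0.05307  -6.6464 4.950e-11 1.097
 promoter_meth  0.281280 0.05230   5.3780 9.397e-08 1.112
    log_length  0.007167 0.01079   0.6641 5.068e-01 1.018
Adjusted R-squared: 0.8425
```

All planted effects come back with the right sign and magnitude from the
fully simulated data: noise falls with abundance and with gene body
methylation, rises with promoter methylation, and is flat in length; no
VIF approaches the conventional alarm level of 5. The nested-replicate
decomposition tells the same story for the purely biological variance
component:

```r
nest <- decompose_replicates(sc$nested)
fit_biological_model(nest, d[c("gene_id", "log_abundance",
                               "body_meth", "promoter_meth")])
#>      body_meth  -1.5148  (p = 8.1e-05)   promoter_meth 1.9309 (p = 4.2e-07)
```

`run_pipeline(run_config(seed = 1))` runs everything end to end for a
two-tissue scenario (a more-methylated, quieter tissue A versus tissue B),
writing every stage artefact plus a checksummed `manifest.json`. A thin
command-line wrapper with the same verbs lives in `inst/cli/methnoise.R`.

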