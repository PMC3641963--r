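---
title: "Modelling transcriptional noise from DNA methylation: methods and design"
author: "methnoise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling transcriptional noise from DNA methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methnoise)
```

## The scientific question

Gene bodies of vertebrate genomes are heavily methylated, and a
long-standing hypothesis holds that this methylation suppresses spurious
intragenic transcription and hence *transcriptional noise* — the
variability of a gene's expression among replicate measurements of
equivalent cell populations. methnoise implements the statistical machinery
needed to test this hypothesis on bulk data: noise is approximated by the
coefficient of variation (CV = sd/mean) of a gene's intensity across
replicate expression arrays of one tissue, and log CV is modelled as a
linear function of expression abundance, gene body methylation (with
transposable elements masked), promoter methylation and log gene length.
The expected signature, if the hypothesis holds, is a negative body
methylation coefficient and — as observed empirically — a positive promoter
methylation coefficient, after controlling for the dominant negative
dependence of noise on abundance.

## From bisulfite calls to per-gene methylation

Per-CpG input is a table of 'C' (methylated) and 'T' (converted) read
counts; the fractional methylation of a site is `c/(c+t)`, undefined below
`min_coverage` total reads (default 1: no threshold beyond being observed).
Per-gene features are built as follows:

* the transcription unit is the **longest transcript** of each gene (ties
  broken by the lexicographically smallest transcript id, for determinism);
* the **promoter** spans 1,500 bp upstream to 500 bp downstream of the
  strand-aware TSS, clipped at the chromosome start;
* **TE intervals** are merged and masked out of gene bodies; body
  methylation is the unweighted mean of per-site fractions over non-TE body
  CpGs, TE methylation over the TE portion, promoter methylation over the
  (unmasked) promoter window.

Three readings of ambiguous points are fixed here as package policy: the
mean is over per-site fractions rather than pooled read counts (an
"average of the mapped cytosines", which weights sites equally); plus- and
minus-strand cytosines are independent sites (no dyad merging); and
promoter windows are *not* TE-masked, since masking is defined for gene
bodies. Promoter windows that overlap the first 500 bp of a gene body
contribute those CpGs to both features; the ambiguity is noted rather than
resolved, and the synthetic generator quantifies its effect (below).

## Noise estimation from replicate arrays

Replicate arrays of one tissue are curated in two steps. First an
iterative, worst-first QC filter: Pearson correlations between arrays are
computed on log2 intensities (log2 because intensity distributions are
heavy-tailed), and while any array's median correlation with the others is
at or below the threshold (default 0.8) the worst array is removed. The
iterative form makes the outcome deterministic and independent of array
order; the removal trail is reported. Second, quantile normalization
within the tissue (via limma), which forces all arrays onto the common
mean-order-statistic distribution; ties receive the mean reference value
over their rank span. CV is then computed per gene on the normalized,
unlogged intensities with the sample (n−1) standard deviation, and CV and
gene length enter the models on the natural-log scale (the base only
rescales coefficients). Whether CV should use logged intensities is
genuinely open; unlogged is chosen because the CV is defined on the
original measurement scale.

## The regression suite

`fit_ols()` provides the main fit with classical inference, adjusted R²,
and variance inflation factors, `VIF_j = 1/(1 − R²_j)`, computed from the
inverse predictor correlation matrix and checked in tests against the
auxiliary-regression definition; fits warn when any VIF exceeds 5, the
conventional multicollinearity alarm (TE *length* is excluded from the
default models for exactly this reason, though it can be added by hand).
Robustness is assessed three ways:

* **M-estimators** (`fit_m_estimator()`): IRLS with MAD-rescaled residuals
  under Huber (c = 1.345), Tukey bisquare (c = 4.685) or Hampel
  (a, b, c = 2, 4, 8) losses — the standard 95%-efficiency constants, since
  no others are prescribed by the problem. The IRLS core is MASS::rlm;
  exact-fit data short-circuits to the least-squares solution because a
  zero MAD scale is degenerate for IRLS.
* **Median regression** (`fit_quantile()`): the check loss is minimized by
  epsilon-smoothed IRLS (floor 1e-6 on |residual|), then *polished* by
  enumerating p-point exact interpolations among the smallest residuals —
  a check-loss minimizer is a basis solution of the equivalent linear
  program, so this recovers the exact vertex. Tests verify the objective
  against brute-force enumeration of all basis solutions at n ≤ 50.
  Standard errors come from a seeded xy-pair bootstrap (default 200
  replicates).
* **Sequential ANOVA** (`fit_individual_anova()`): the
  individual-by-body-methylation interaction is tested with Type I sums of
  squares in a fixed term order (abundance, length, body, promoter,
  individual, interaction). Sequential SS is an interpretive choice — the
  SS type is not prescribed — and is stated in the output.

Raw p values are reported throughout (no multiplicity correction by
default; Benjamini–Hochberg can be applied downstream), and all fits are
complete-case with dropped-row counts recorded.

## Separating biological from technical variation

With `n_tech` technical replicates nested in each of `n_bio` biological
samples, the total sum of squares per gene partitions exactly:

$$\sum_{ij}(y_{ij}-\bar{\bar y})^2 \;=\;
  n_{tech}\sum_i(\bar y_i-\bar{\bar y})^2 \;+\;
  \sum_{ij}(y_{ij}-\bar y_i)^2,$$

the biological and technical sums of squares. (The technical term is the
within-sample deviation — the unique expression making the identity hold;
tests enforce it to 1e-10 relative on random tables.) Model 1 regresses
log SS_bio on abundance and methylation; model 2 regresses log SS_total on
the same predictors plus log SS_tech, isolating the biological signal by
conditioning. The log transform is applied because sums of squares are
positive and right-skewed; genes with a zero SS are dropped from the log
fits with a warning.

## What the synthetic generator emulates

`sim_config()` fixes the study conditions once; all generators derive
named sub-streams from one root seed, so identical configurations are
bit-reproducible.

* **Truth**: abundance is log-normal (sdlog 1.2 around 300 intensity
  units); body methylation ~ Beta(3.5, 1.5) (heavily methylated bodies,
  mean 0.7, but with realistic spread), promoter ~ Beta(0.8, 3)
  (predominantly hypomethylated), TE ~ Beta(9, 1.5); a Gaussian copula
  couples body (+0.3) and promoter (−0.3) methylation to log abundance so
  VIFs exceed 1, as in real tissue. log CV is the planted linear predictor
  (defaults: intercept 1.5, abundance −0.55, body −0.30, promoter +0.25,
  length 0) plus N(0, 0.15) residual — the residual scale chosen so the
  fitted model's adjusted R² lands near 0.9, the regime the method is
  meant for.
* **Annotations**: non-overlapping gene bodies on a toy chromosome with
  intergenic gaps wide enough (≥3.5 kb) that promoter windows never touch
  a neighbour; ~30% of genes get a strictly nested second transcript to
  exercise longest-transcript selection; TEs are 200-bp blocks kept
  i.i.d. with probability `te_fraction` (default 0.35), so TE coverage of
  body bases converges to that fraction.
* **Methylome**: CpG sites at 10/kb; Poisson(30) coverage with
  zero-coverage sites emitted (exercising the missing-data path); C reads
  binomial at the enclosing feature's truth. Site truth within a feature
  is constant by default, keeping the aggregation oracle exact; Beta
  heterogeneity sits behind `site_heterogeneity`. Where features overlap,
  truth priority is promoter > TE > body, so measured promoter methylation
  is unbiased while body aggregates inherit a small contamination from the
  500 bp of promoter inside the body — the price of not resolving the
  membership ambiguity, visible as a slight attenuation of body recovery.
* **Expression**: replicate intensities are log-normal with the exact
  moment parameterisation matching the gene's true mean and CV — a
  positive-support stand-in, not an inference about real intensity noise.
* **Nested replicates**: `y_ij = mean + b_i + e_ij` with log σ²_bio linear
  in abundance, body and promoter methylation (defaults −0.5, −2.0, +1.5)
  and log σ²_tech in abundance only (−0.25), reflecting that technical
  variation tracks expression level but not methylation. The methylation
  effects on σ²_bio are deliberately strong: with the 2×2 balanced layout
  the biological SS has a single degree of freedom, so its log carries
  χ²₁-sized noise (sd ≈ 2.2) and only effects of order 1 are detectable at
  a few thousand genes — the arithmetic that sized these defaults.

What the generator does **not** emulate: probe-level artefacts, batch
effects, cross-hybridisation, spatially structured methylation (CpG
islands, shores), or the correlation of TE content with gene age. Passing
parameter-recovery tests therefore show the *estimators* are correct under
the stated model, not that real tissue obeys it.

## Validation design

The test suite is oracle-first: interval arithmetic is checked against
per-base membership loops, feature aggregation against per-site loops,
VIF against auxiliary regressions, median regression against full basis
enumeration, the exact Mann–Whitney tail against complete rank-assignment
enumeration, and the decomposition against its algebraic identity. On top
sit calibration runs: planted coefficients recovered within ±0.05 at 5,000
genes; the Poisson count-noise slope of log CV on log mean within ±0.05 of
−1/2; type-I control of the methylation terms (α = 0.01 exceedances in at
most a binomially-allowed share of 100 null runs); robustness ordering
under 10% gross contamination of high-leverage responses (contamination is
placed on the highest-leverage points because response shifts independent
of the design corrupt only the intercept, making a slope comparison
uninformative); and a null individual-by-methylation interaction in at
least 90 of 100 runs. Problem sizes (hundreds to a few thousand genes, 10
to 20 arrays, 100-replicate batteries) were chosen to make each check
statistically decisive at interactive runtimes.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_genes = 1000, n_arrays = 12, seed = 1)
sc <- simulate_scenario(cfg)
meth <- feature_methylation(sc$calls, sc$annotations$genes,
                            sc$annotations$tes)
noise <- expression_noise(quantile_normalize(qc_filter(sc$expression)$matrix))
d <- merge(merge(noise, meth, by = "gene_id"),
           sc$truth[c("gene_id", "length")], by = "gene_id")
d$log_length <- log(d$length)
fit_ols(log_cv ~ log_abundance + body_meth + promoter_meth + log_length, d)
```

Or end-to-end, with all artefacts and a checksummed manifest written to
disk:

```{r pipeline, eval = FALSE}
res <- run_pipeline(run_config(seed = 1, n_genes = 500), out_dir = "run1")
res$results$tissueA$fits$main
```

## Known limitations

* The CV-of-arrays proxy conflates biological and technical variation;
  the decomposition models mitigate but cannot eliminate this without a
  nested design.
* Only balanced nested layouts are decomposed; unbalanced designs would
  need REML-style variance components, which are out of scope.
* The exact Mann–Whitney tail requires tie-free data and a smaller sample
  of ≤ 20; otherwise a tie-corrected normal approximation is used.
* Quantile-regression standard errors are bootstrap-based and therefore
  seeded; analytic sandwich estimates are not provided.
* `qc_filter` computes correlations on log2(x + 1); the +1 offset guards
  zero intensities and is immaterial at array scale.
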