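# sigdecon

Cell-type transcriptional signatures from heterogeneous RNA-seq reference
collections, bulk deconvolution, and survival-association analysis — with a
planted-truth simulation benchmark that scores the whole chain.

## What it does

Tumor bulk RNA-seq mixes the transcriptomes of many cell types. To ask
whether the abundance of a particular immune phenotype (say, an activated NK
cell state) predicts patient outcome, one needs (i) signatures that
distinguish closely related phenotypes, (ii) a deconvolution step that turns
bulk profiles into cell-type fractions, and (iii) survival statistics on
those fractions. `sigdecon` implements the full chain:

* **Abundance model** — per (cell type, gene), counts are negative binomial,
  `Var = μ + φμ²`, with per-replicate effective library sizes (TMM × CPM)
  and a gene-level log-normal prior shared across cell types. The
  one-dimensional posterior of log μ is integrated on a grid; incomplete
  reference collections (a gene missing for some cell types) are handled by
  prior inheritance rather than imputation.
* **Marker selection** — for every ordered pair of sibling cell types at each
  hierarchy level, genes are ranked by the credible gap
  `ci_low(a) − ci_high(b)`; the top 5 / 10 / 20 genes per pair at levels
  1 / 2 / 3 are pooled into the marker list, and the signature matrix is the
  posterior mean abundance of the markers per leaf type.
* **Deconvolution** — linear-kernel ν-SVR (the CIBERSORT algorithm) over a
  ν grid {0.25, 0.5, 0.75}, negative coefficients clipped, fractions on the
  simplex, with RMSE/correlation diagnostics.
* **Survival** — median-split stratification (single and two-factor),
  Kaplan–Meier curves, log-rank tests, BH adjustment across the screened
  family, multiple Cox regression (Efron ties) on logit fractions, and
  gene–fraction correlation matrices.
* **Benchmark** — survival-coupled Dirichlet proportions
  (`logit(m[v]) = logit(1/K) + S·z`), in-silico mixtures with optional
  foreign-cell contamination `P`, half-sample censoring, Cox p-values pooled
  into an ROC/AUC against the planted variable cell type.
* **Synthetic data & validation** — an NB generator with planted markers and
  a cell-type hierarchy makes every stage testable offline; marker-restricted
  PCA plus silhouette scores sanity-check signatures.

## Worked example

```r
library(sigdecon)

hier <- benchmark_hierarchy()                 # 8 leaf types, 3 levels
ref  <- generate_reference(generative_spec(seed = 42), hier)
sig  <- derive_signature(ref)$signature
dim(sig)
#> [1] 81  8

# deconvolve noiseless mixtures of the signature profiles
set.seed(7)
props <- matrix(rgamma(5 * 8, 1), 5); props <- props / rowSums(props)
colnames(props) <- colnames(sig)
est <- deconvolve(sig %*% t(props), sig)
round(mean(abs(est$fractions - props)), 4)
#> [1] 0

# survival-association benchmark at one condition
pool  <- generate_clinical(500, seed = 11)
bench <- run_benchmark(ref, sig, pool,
                       conditions = data.frame(N = 250, S = 1, P = 0),
                       runs_per_condition = 63, seed = 5)
bench$summary
#>     N S P       auc n_runs seed
#> 1 250 1 0 0.9685059     63    5
```

The AUC is the area under the ROC curve obtained by pooling, over 63
simulation runs, the per-cell-type Cox p-values (scored as 1 − p) against
the planted variable cell type: 0.97 means the pipeline almost always ranks
the truly survival-coupled phenotype above the unrelated ones at N = 250
samples and slope S = 1 with no foreign contamination.

See `vignettes/methods.Rmd` for the model details, parameter defaults and
design decisions.

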