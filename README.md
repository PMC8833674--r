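# geno2lnc

Identify circulating long noncoding RNAs (lncRNAs) associated with
gallbladder-cancer (GBC) risk when no single cohort carries expression and
outcome together. The package implements a three-stage design that stitches
three independent datasets:

1. **Tissue preselection** — in a staged tissue cohort (gallstones → dysplasia
   → carcinoma, `GS < Dys < GBC`), find transcripts whose log2 TPM expression
   changes monotonically along the progression sequence, using two-sided
   permutation Jonckheere–Terpstra (J–T) tests (Benjamini–Hochberg FDR) *and*
   a boosted three-class classifier's relative feature importance. A
   transcript is carried forward iff (i) J–T FDR < 0.05 and importance above
   the median, (ii) it is an annotated, non-duplicated lncRNA, (iii) it has
   nonzero MAD expression in serum, (iv) it has candidate cis-eQTLs in the
   database table.
2. **cis-eQTL validation** — in a serum + genotype cohort, validate candidate
   SNP–transcript pairs with robust (Huber, c = 1.345) linear regression

   `log2 expression ~ SNP + age + gender + 10 genetic PCs`       (per SNP)

   under four penetrance encodings (additive, three-genotype, dominant,
   recessive), then pick the multi-SNP prediction model minimizing a robust
   AIC (RAIC) over all SNP subsets.
3. **Genotype-based association** — in a genotype-only case–control cohort,
   impute expression as `ŷ = Σᵢ βᵢ Aᵢ` (discrete, because genotypes are) and
   estimate the odds ratio per log2 expression unit with robust logistic
   regression (Cantoni–Ronchetti quasi-likelihood, Huber c = 1.2):

   `status ~ predicted log2 expression + age + gender + 10 genetic PCs`

Supporting machinery: log2-TPM normalization, MAD filtering, two-pass
quantile normalization, PCA + Mahalanobis-depth sample exclusion (depth
`1/(1+d²)`, lowest 5% excluded), genotype QC (MAF/call-rate filters,
method-of-moments IBD kinship, greedy relatedness pruning, windowed LD
pruning at r² > 0.1, eigenstrat-normalized genetic PCA), and a
synthetic-data generator that plants known trends, eQTLs and odds ratios so
every stage is testable without restricted patient data.

## Worked example

A scaled synthetic study (150 transcripts instead of 7500, 3000 SNPs instead
of genome-wide) with 6 planted trend transcripts, one planted cis-eQTL each,
and a true odds ratio of 1.25 per log2 unit:

```r
library(geno2lnc)
cfg <- sim_config(seed = 1, n_transcripts = 150, n_trend = 6,
                  prop_silent = 0.5, n_snps = 3000,
                  n_true_eqtls_per_transcript = 1)
sim <- simulate_study(cfg)

## stage 1: tissue preselection
expr     <- counts_to_log2tpm(sim$tissue)
filtered <- mad_filter(expr)
norm     <- quantile_normalize_two_pass(filtered$expr)
keep     <- pca_depth_exclude(norm, frac = 0.05)
trend    <- jt_permutation_test(keep$expr, n_perm = 999, seed = 1)
clf      <- train_stage_classifier(keep$expr, grid_size = 5, seed = 1)
sel      <- select_candidates(trend, clf, sim$serum, sim$candidates)
```

```
# transcripts detected: 150 | MAD = 0: 75 | samples kept: 93
  transcript_id jt_statistic jt_expected p_value    fdr  direction
1      lnc00001         2460        1437   0.001 0.0125 increasing
2      lnc00002          594        1437   0.001 0.0125 decreasing
AUC: 0.94 | mean per-class error: 0.1
candidates after the four criteria: 6
```

98 tissue samples enter; the 5 with the lowest Mahalanobis depth are
excluded (93 kept). All 6 planted transcripts pass the four criteria.

```r
## stage 2: genotype QC + eQTL validation
filt <- snp_sample_filter(sim$geno_eqtl)
rel  <- relatedness_prune(ibd_kinship(filt$geno), filt$geno)
g2   <- geno2lnc:::subset_geno(filt$geno, samples = rel$kept)
g3   <- geno2lnc:::subset_geno(g2, snps = ld_prune(g2))
pcs  <- genetic_pca(g3, k = 10)
gk   <- geno2lnc:::subset_geno(filt$geno,
                               samples = depth_exclude_genetic(pcs)$kept)
cand <- sim$candidates[sim$candidates$transcript_id %in% sel$selected, ]
val  <- validate_candidates(sim$serum, gk, sim$serum_covars, cand,
                            pcs = pcs$scores)
model <- select_prediction_model(sim$serum, val$validated, gk,
                                 sim$serum_covars, pcs = pcs$scores,
                                 transcript = sel$selected[1])
model
```

```
eqtl_model for lnc00001 - RAIC 85.4089
   snp02874 ( dominant ) beta = 0.755
   snp02821 ( recessive ) beta = -0.505
  adj r2 full: 0.317  ref: 0.207
```

The RAIC-best model explains 32% of serum variance versus 21% for the
covariate-only reference model. (Note the realistic imperfections: the
planted additive eQTL won with a dominant encoding, and one decoy SNP slipped
through validation.)

```r
## stage 3: genotype-based association
pred <- predict_expression(sim$geno_assoc, model)
pcs_assoc <- genetic_pca(sim$geno_assoc, k = 10)
associate(pred, sim$status, sim$assoc_covars, pcs = pcs_assoc$scores)
```

```
OR = 1.161 per log2 unit (95% CI 0.901-1.495), p = 0.248; 498 cases / 2410 controls
```

The Wald CI covers the planted odds ratio 1.25; at ~500 cases a single
replicate is underpowered for OR 1.25, which is why the recovery experiments
below average over many replicates.

The same flow runs end-to-end from one JSON config with caching and a
manifest:

```r
run_pipeline(list(out_dir = "run", seed = 1))
```

or from the shell via the installed CLI wrapper:

```sh
Rscript inst/scripts/geno2lnc pipeline --config cfg.json --seed 1
```

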