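---
title: "geno2lnc: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{geno2lnc: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Circulating lncRNAs are attractive risk biomarkers for gallbladder cancer
(GBC): they are stable in serum and their expression is partly genetically
determined. But no single accessible cohort measures serum lncRNA expression
*and* GBC outcomes. geno2lnc implements a three-stage design that bridges
three independent datasets: (1) staged gallbladder tissue expression only
(gallstones GS → dysplasia Dys → carcinoma GBC), (2) serum expression plus
genome-wide genotypes, (3) genotypes plus case–control status only. The
transcript-level genetic effects estimated in stage 2 let stage 3 *impute*
serum expression from genotypes alone — the TWAS idea applied to a small,
targeted panel of trend-preselected lncRNAs.

# Stage models and assumptions

## Trend preselection

Counts are converted to log2 TPM (`TPM = (count/length_kb) /
Σ(count/length_kb) × 1e6`, then `log2(TPM + pseudocount)`). Transcripts with
unscaled MAD = 0 carry no usable signal in a rank-based test and are dropped;
expression is then quantile-normalized in two passes — first within each
stage group (so that stage-specific technical distributions do not masquerade
as trends), then globally. Sample outliers are removed by PCA +
Mahalanobis depth `1/(1 + d²)` on the leading PC scores, excluding the
`round_half_up(0.05 n)` lowest-depth samples; with n = 98 this is exactly 5.

The trend test is the Jonckheere–Terpstra statistic
`JT = Σ_{g<h} #\{x_gi < x_hj\} + ½ #ties` with two-sided permutation p-value
`(1 + #\{|JT_perm − E| ≥ |JT_obs − E|\}) / (n_perm + 1)`,
`E = (N² − Σ n_g²)/4`. It assumes exchangeability of samples across stage
labels under the null and ordinal (not linear) monotonicity under the
alternative; being rank-based, its p-values are invariant to monotone
transforms of expression. One shared stream of label permutations is used
for all transcripts. Besides the contract-level requirement this has two
consequences we rely on: results do not change when the transcript set is
subset, and the D·P matrix formulation (transcript-by-pair comparison matrix
times pair-by-permutation indicator matrix) turns the whole test into two
dense matrix products, which is what makes 5000 permutations on thousands of
transcripts affordable.

The machine-learning screen is a three-class classifier trained on a random
77/98-fraction split with the training classes upsampled to the majority
count, hyperparameters tuned by random grid search under 5-fold CV (selection
metric: mean per-class error), and evaluated by class-frequency-weighted
one-vs-rest AUC. The contract is this protocol, not a specific learner. The
default backend is an in-package gradient-boosted stump ensemble (softmax
loss, shrinkage, least-squares leaf values): no boosted-tree package is
available in the target environment, and boosting has the property the
downstream criterion implicitly assumes — importance (total split gain) is
spread over many features with the truly predictive ones on top. A
multinomial elastic-net backend (`backend = "glmnet"`) is also provided; note
that when such a model is tuned to near-perfect sparsity the "importance
above the median of nonzero importances" criterion can paradoxically discard
true signals, which is visible in its tests.

## cis-eQTL validation

For each candidate pair the model is
`log2 expression ~ SNP + age + gender + 10 genetic PCs`, fitted by Huber
M-estimation (IRLS; ψ bounded at c = 1.345 for ~95% Gaussian efficiency; MAD
residual scale re-estimated each iteration, the MASS::rlm convention).
Standard errors use the asymptotic M-estimator covariance with Huber's
small-sample correction; p-values are two-sided normal. All four penetrance
encodings are tried per SNP — additive, dominant, recessive, and
three-genotype (two indicators, jointly tested by a Wald χ²). A SNP
validates at p < 0.05 under at least one encoding; the threshold is
deliberately uncorrected because the candidates are a-priori database hits
being *confirmed*, not discovered (configurable via `alpha`). Validated SNPs
in mutual LD (r² > 0.1, the pipeline-wide pruning threshold) are reduced,
keeping the smallest-p SNP.

The multi-SNP prediction model is chosen by exhaustive subset search
(guarded above 20 SNPs) minimizing the robust AIC

RAIC = 2 Σ ρ_c(r_i/ŝ) + 2 n log ŝ + 2 (p + 1),

i.e. minus twice the Huber-density quasi-log-likelihood plus the AIC
penalty. Two numerical choices matter here. First, the `2n log ŝ` term is
required: without it the criterion is nearly scale-invariant (ŝ shrinks with
the residuals, so Σρ(r/ŝ) barely responds to fit quality) and fails the
basic requirement that a pure-noise column usually worsens the score.
Second, ŝ for the criterion is a Huber Proposal-2 scale with an (n − p)
degrees-of-freedom correction; the per-iteration MAD is too jumpy (a median
of order statistics) and degrades model discrimination measurably. In the
Gaussian limit the criterion reduces to AIC up to a constant, and the
noise-column rejection rate approaches the theoretical P(χ²₁ < 2) ≈ 0.84.

Effect-allele orientation is ambiguous in the field ("count of major
alleles" versus the usual minor-allele dosage); the default encodes the
major allele in the validation sample and is configurable
(`effect_allele = "alt"` keeps VCF ALT counts). This choice is
inconsequential for inference: the four-model family is closed under allele
relabelling (additive flips sign, dominant and recessive swap), so validated
SNPs and predictions are invariant, which the test suite checks.

## Genotype QC

Filter order mirrors standard practice: SNP MAF ≥ 1% and call rate ≥ 95%,
then sample call rate ≥ 95%, then relatedness, then LD pruning, then PCA.
Kinship uses the PLINK-style method of moments: observed IBS 0/1/2 counts
are equated to their Hardy–Weinberg expectations under IBD 0/1/2 given
sample allele frequencies; the coefficient is P(IBD=2) + P(IBD=1)/2,
truncated to [0, 1], without finite-sample allele-frequency corrections.
Related pairs (> 0.1) are broken greedily by removing the lower-call-rate
member (ties: lexicographically smaller id). A practical calibration note:
with two latent subpopulations at F ≈ 0.02 the estimator needs a few
thousand SNPs before its noise stays safely below the 0.1 threshold (the
default simulated panel is 5000 SNPs for exactly this reason; at a few
hundred SNPs the greedy pruning can cascade through the sample).

LD pruning is a greedy sliding-window scan (50 SNPs, step 5 by default —
the field's common convention, not a stated value): within a window, while
any retained pair exceeds r² = 0.1, the worst pair's lower-MAF member is
dropped (tie: later position). Genetic PCA uses eigenstrat normalization
(center 2p̂, scale √(2p̂(1−p̂)), missing → 0), with the SNP-side
eigendecomposition when SNPs < samples; PC signs follow the
largest-magnitude-score-positive convention. The same 5%-lowest-depth rule
as in stage 1 removes genotype outliers.

## Association

Predicted expression `ŷ = Σ βᵢ Aᵢ` carries no intercept — it is defined up
to a constant that the logistic intercept absorbs — and is discrete: an
additive × dominant model yields at most 3 × 2 = 6 levels. Individuals
missing any model genotype are excluded (logged), not imputed. The
association model `status ~ ŷ + age + gender + 10 PCs` is fitted by the
Cantoni–Ronchetti Mallows-type quasi-likelihood estimator with Huber c = 1.2
and unit covariate weights: the estimating equation Huberizes Pearson
residuals and subtracts their conditional expectation (the Fisher-consistency
correction); it is solved by Newton steps (numerically differenced Jacobian,
damped, started at the ML fit), with sandwich standard errors built from the
expected outer product. As c → ∞ the estimator reduces exactly to maximum
likelihood, which the tests use as an oracle. CIs are Wald on the log-odds
scale (the CI construction is not otherwise specified in the field's
reports). Separation is detected (standardized coefficient exceeding ±15
after the ML start, or a diverging Newton path) and reported against the
offending covariate. We implement the fully adjusted model (age, gender,
10 PCs) even though some summary tables describe age/gender adjustment only;
with an unstructured or PC-adjusted simulation the two differ negligibly.

# The synthetic world

The generator's defaults state the targeted study design and are fixed
independently of any test outcome:

| parameter | default | rationale |
|---|---|---|
| `n_per_stage` | 31 / 35 / 32 | tissue cohort composition |
| `n_transcripts`, `prop_silent` | 7500, 7168/7500 | detected lncRNAs and the MAD = 0 fraction in FFPE tissue |
| `trend_effect` | 1.0 log2/step | the power-analysis value at which planted trends are reliably detected; observed per-step shifts in staged tissue are ~0.4–0.5 |
| `nb_dispersion` | 0.3 | typical bulk RNA-seq overdispersion; FFPE counts have no published distributional fit, so this is a fixture, not an estimate |
| `n_individuals_eqtl` | 110 | validation cohort size (→ 93 after QC) |
| `n_snps` | 5000 | smallest panel at which MoM kinship noise is negligible (see QC note) |
| `eqtl_beta` | 0.5 log2/allele | order of magnitude implied by the reported r² at n = 93 |
| `target_r2` / `covar_r2` | 0.26 / 0.17 | full-model and covariate-only variance fractions reported for the strongest validated transcript |
| `n_cases` / `n_controls` | 540 / 2397 | association cohort |
| `true_or_per_log2` | 1.25 | reported odds ratio per log2 unit |
| `n_subpops`, `fst_like_divergence` | 2, 0.02 | Balding–Nichols structure at the scale of within-country admixture differences, enough for PCA to find |

`target_r2` is interpreted as the *full-model* variance fraction with
`covar_r2` the covariate share, so the SNP increment is their difference
(0.09 by default); noise is scaled relative to the realized SNP-term
variance so planted betas are never rescaled. With all betas zero the
configuration is only valid when the two fractions coincide. Case–control
status is Bernoulli with logit `α + log(OR_true)·ŷ + age/gender effects`,
with α calibrated by root-finding so the expected case count matches the
design. Covariate effects default to nonzero (age +, male −) so confounder
adjustment is genuinely exercised. Library sizes are log-normal so TPM
normalization is non-trivial.

What the generator deliberately does **not** emulate: FFPE degradation
artifacts, read-level noise (no FASTQ), genotype imputation uncertainty
(hard calls only), linkage maps (LD arises only through population
structure, plus explicit duplicated/mixed SNPs in tests), relatives (IBD
benchmarks construct duplicates and parent–offspring pairs explicitly), and
trans-effects. A green end-to-end test therefore establishes that the
*procedure* recovers planted truth under its stated statistical model — not
that the model captures every property of the original tissue data.

Power consequences worth knowing: with the calibrated r² world
(0.26/0.17) split over two eQTLs, per-SNP validation power at n = 93 is only
~55–60%, matching the original study's experience of validating very few
database candidates. Recovery tests that assert ≥ 80% eQTL recovery
therefore use one planted eQTL per transcript (per-SNP increment 0.09,
power ≈ 0.9 at n = 93) — a design decision recorded before the tests were
run, derived from the noncentral-F power calculation rather than from test
outcomes.

# Numerical and degenerate-input choices

* Pseudocount 1 on the TPM scale before log2 (avoids −∞; standard).
* MAD is unscaled for the filter predicate (only = 0 matters) but the
  regression scale uses the 1/0.6745 Gaussian-consistency factor.
* Quantile-normalization ties receive the mean of the normalized values at
  their tied ranks (interpolated average ranks, the limma convention);
  idempotence and within-sample rank preservation are tested.
* Depth exclusion count is `round_half_up(frac·n)`, reproducing 98 → 5
  excluded; ties in depth break by sample order. Depth on `min(10, n−1)`
  leading PCs stabilizes Σ⁻¹ when transcripts ≫ samples; a singular PC
  covariance is reported with advice to lower `k_pcs`.
* Permutation p-values use the add-one correction, so the smallest
  achievable p is 1/(n_perm + 1) and the test is never anti-conservative.
* All-zero count columns, single-sample normalization blocks, rank-deficient
  designs (reported with the collinear column names), n ≤ p fits, one-class
  outcomes, constant predictions, and empty validated sets are all explicit
  user-facing errors rather than silent misbehavior.
* huber_rlm convergence: max coefficient change < tol·max(1, max|β|); a
  near-exact fit floors the scale estimate instead of dividing by zero.

# Pipeline

`run_pipeline()` executes simulate → prep → preselect → genoqc → eqtl →
associate from one JSON config. Each stage records an md5 hash of its
parameters and input files in `manifest.json` together with funnel counts
(transcripts detected / MAD-excluded / depth-excluded samples / J–T and
importance survivors / candidate set / QC counts / validated eQTLs / odds
ratios); a stage re-runs only when its hash or outputs changed, so deleting
an intermediate re-runs exactly the affected stages. Everything is
single-threaded and seeded; two runs of the same config produce
hash-identical output trees.

# Known limitations

* The RAIC subset search is exhaustive by design (matches an oracle in
  tests) and guarded, not heuristic, above 20 SNPs.
* MoM kinship without allele-frequency bias correction overestimates
  relatedness in strongly structured samples; for the simulated F ≈ 0.02 the
  effect is well below the 0.1 threshold at the default panel size.
* The robust logistic Jacobian is numerically differenced — exact enough at
  p ≤ ~30 covariates, but not intended for high-dimensional designs.
* Stage-1/stage-2 transcript matching is by identifier; no liftover or
  annotation reconciliation is attempted.
* The reverse causal direction (disease → expression) is out of scope by
  construction of the design.
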