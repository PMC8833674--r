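# Parameter-recovery experiments: repeated simulate -> analyse cycles that
# verify the estimators recover the effect sizes the generator planted.

stub_truth <- function(ids = "lnc00001") {
  structure(list(trend_transcript_ids = ids,
                 trend_direction = setNames(rep("increasing", length(ids)),
                                            ids),
                 eqtl_map = NULL, true_or = NA_real_),
            class = "synthetic_truth")
}

#' Odds-ratio recovery experiment
#'
#' Repeatedly: simulate an association-set genotype panel, plant a two-SNP
#' (additive + dominant) expression model, impute genotype-based expression,
#' draw case-control status at the configured true odds ratio per log2 unit,
#' compute genetic PCs, and fit the robust logistic association model.
#' Returns the per-replicate odds-ratio estimates so bias and CI coverage can
#' be assessed.
#'
#' @param n_reps number of replicates (default 200).
#' @param seed base seed; replicate seeds are derived from it.
#' @param cfg a [sim_config()]; `n_cases`, `n_controls`,
#'   `true_or_per_log2` and the genotype-panel fields are honoured. The
#'   default panel is scaled to 200 SNPs to keep the per-replicate PCA cheap.
#' @param n_pcs genetic PCs included in the association model.
#' @return data.frame(or, ci_lower, ci_upper, p_value), one row per
#'   replicate, with the true odds ratio as attribute `true_or`.
#' @export
simulate_or_recovery <- function(n_reps = 200L, seed = 1L,
                                 cfg = sim_config(seed = seed, n_snps = 200L),
                                 n_pcs = 10L) {
  seeds <- derive_seeds(seed, 2L * n_reps)
  n_total <- cfg$n_cases + cfg$n_controls
  truth <- plant_eqtls(stub_truth(), gen_genotypes(cfg, n = 2L), cfg)
  model <- truth_as_model(truth, "lnc00001")
  out <- vector("list", n_reps)
  for (b in seq_len(n_reps)) {
    geno <- gen_genotypes(cfg, n = n_total, seed = seeds[2 * b - 1L],
                          prefix = "a")
    pcs <- genetic_pca(geno, k = n_pcs)
    cc <- gen_case_control(geno, model, covars = NULL, cfg,
                           seed = seeds[2 * b])
    res <- associate(cc$predicted, cc$status, cc$covars, pcs = pcs$scores,
                     n_pcs = n_pcs)
    out[[b]] <- data.frame(or = res$or, ci_lower = res$ci_lower,
                           ci_upper = res$ci_upper, p_value = res$p_value)
  }
  res <- do.call(rbind, out)
  attr(res, "true_or") <- cfg$true_or_per_log2
  attr(res, "n") <- n_total
  res
}

#' Variance-explained (r-squared) recovery experiment
#'
#' Repeatedly: simulate an eQTL validation panel of `n` individuals, generate
#' serum expression whose full systematic part explains `cfg$target_r2` of
#' the variance (covariates alone `cfg$covar_r2`), and fit the full robust
#' linear model (planted SNP encodings + age + gender + `n_pcs` PCs) and the
#' covariate-only reference model, recording both adjusted r-squared values.
#'
#' @param n_reps replicates (default 200).
#' @param seed base seed.
#' @param cfg a [sim_config()].
#' @param n sample size of each simulated validation panel (default 93, the
#'   post-QC size of the targeted study).
#' @param n_pcs genetic PCs in the model.
#' @return data.frame(adj_r2_full, adj_r2_ref); attributes `target_r2`,
#'   `covar_r2`.
#' @export
simulate_r2_recovery <- function(n_reps = 200L, seed = 1L,
                                 cfg = sim_config(seed = seed,
                                                  n_snps = 300L),
                                 n = 93L, n_pcs = 10L) {
  seeds <- derive_seeds(seed + 1L, 2L * n_reps)
  truth <- plant_eqtls(stub_truth(), gen_genotypes(cfg, n = 2L), cfg)
  em <- truth$eqtl_map[["lnc00001"]]
  out <- vector("list", n_reps)
  for (b in seq_len(n_reps)) {
    geno <- gen_genotypes(cfg, n = n, seed = seeds[2 * b - 1L],
                          prefix = "v")
    serum <- gen_serum_expression(geno, truth, covars = NULL, cfg,
                                  seed = seeds[2 * b])
    pcs <- genetic_pca(geno, k = n_pcs)
    ids <- rownames(geno$dosage)
    Z <- covariate_design(serum$covars, pcs$scores, n_pcs,
                          sample_ids = ids)
    enc <- do.call(cbind, lapply(seq_len(nrow(em)), function(i) {
      d <- geno$dosage[ids, em$snp_id[i]]
      d[is.na(d)] <- round(mean(d, na.rm = TRUE))
      e <- encode_penetrance(d, em$model[i])
      colnames(e) <- paste0(em$snp_id[i], "_", colnames(e))
      e
    }))
    y <- serum$expr["lnc00001", ids]
    full <- huber_rlm(y, cbind(Z, enc))
    ref <- huber_rlm(y, Z)
    out[[b]] <- data.frame(adj_r2_full = full$adj_r2,
                           adj_r2_ref = ref$adj_r2)
  }
  res <- do.call(rbind, out)
  attr(res, "target_r2") <- cfg$target_r2
  attr(res, "covar_r2") <- cfg$covar_r2
  res
}
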