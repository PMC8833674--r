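# Synthetic-data generators: determinism, planted structure, file round trips.

small_cfg <- function(seed = 1, ...) {
  args <- list(seed = seed, n_transcripts = 60, n_trend = 6,
               prop_silent = 0.5, n_snps = 300, n_cases = 60,
               n_controls = 240, n_per_stage = c(GS = 30, Dys = 30, GBC = 30))
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

test_that("sim_config validates its invariants", {
  expect_error(sim_config(n_trend = 100, n_transcripts = 50), "n_trend")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_config(target_r2 = 1.2), "target_r2")
  expect_error(sim_config(covar_r2 = 0.5, target_r2 = 0.3), "covar_r2")
  expect_error(sim_config(nb_dispersion = -1), "dispersion")
})

test_that("generators are pure functions of (cfg, seed)", {
  cfg <- small_cfg(seed = 11)
  a <- gen_tissue_counts(cfg)
  b <- gen_tissue_counts(cfg)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$covars, b$covars)
  g1 <- gen_genotypes(cfg)
  g2 <- gen_genotypes(cfg)
  expect_identical(g1$dosage, g2$dosage)
  # different individual seed, same panel
  g3 <- gen_genotypes(cfg, seed = 99L)
  expect_identical(g1$snps, g3$snps)
  expect_false(identical(g1$dosage[1:5, 1:20], g3$dosage[1:5, 1:20]))
})

test_that("planted trends reach J-T significance; null world is calibrated", {
  cfg <- small_cfg(seed = 21, trend_effect = 1.0)
  tis <- gen_tissue_counts(cfg)
  expr <- counts_to_log2tpm(tis$counts)
  tr <- jt_permutation_test(expr$values[tis$truth$trend_transcript_ids, ],
                            tis$counts$stage, n_perm = 499, seed = 1)
  expect_gt(mean(tr$p_value < 0.05), 0.8)

  # trend_effect = 0: planted transcripts behave like nulls
  cfg0 <- small_cfg(seed = 22, trend_effect = 0, n_transcripts = 300,
                    n_trend = 150, prop_silent = 0)
  tis0 <- gen_tissue_counts(cfg0)
  expr0 <- counts_to_log2tpm(tis0$counts)
  tr0 <- jt_permutation_test(expr0$values[tis0$truth$trend_transcript_ids, ],
                             tis0$counts$stage, n_perm = 399, seed = 2)
  expect_gt(mean(tr0$p_value < 0.05), 0.01)
  expect_lt(mean(tr0$p_value < 0.05), 0.10)
})

test_that("genotype MAFs track the requested frequency", {
  cfg <- sim_config(seed = 5, n_snps = 400, maf_range = c(0.3, 0.3),
                    n_subpops = 1, fst_like_divergence = 0,
                    n_individuals_eqtl = 400, geno_missing_rate = 0)
  g <- gen_genotypes(cfg)
  expect_true(all(abs(g$maf - 0.3) < 0.03 + 3 * sqrt(0.3 * 0.7 / 800)))
  expect_lt(mean(abs(g$maf - 0.3)), 0.03)
})

test_that("two diverged subpopulations separate on genetic PC1", {
  cfg <- sim_config(seed = 6, n_snps = 2000, n_subpops = 2,
                    fst_like_divergence = 0.02, n_individuals_eqtl = 120)
  g <- gen_genotypes(cfg)
  pcs <- genetic_pca(g, k = 5)
  subpop <- attr(g, "subpop")
  auc <- max(
    sum(rank(pcs$scores[, 1])[subpop == 1]) ,
    sum(rank(-pcs$scores[, 1])[subpop == 1]))
  n1 <- sum(subpop == 1); n0 <- sum(subpop == 2)
  auc <- (auc - n1 * (n1 + 1) / 2) / (n1 * n0)
  expect_gt(auc, 0.9)
})

test_that("VCF round-trips and parses with a standard-conformant reader", {
  cfg <- small_cfg(seed = 31)
  g <- gen_genotypes(cfg, n = 25)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(g, path)
  g2 <- read_vcf(path)
  expect_identical(unname(g2$dosage), unname(g$dosage))
  expect_identical(g2$snps$pos, g$snps$pos)
  skip_if_not_installed("VariantAnnotation")
  vcf <- suppressWarnings(VariantAnnotation::readVcf(path))
  gt <- VariantAnnotation::geno(vcf)$GT
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt))
  dos[gt == "0/0"] <- 0L; dos[gt == "0/1"] <- 1L; dos[gt == "1/1"] <- 2L
  expect_identical(unname(t(dos)), unname(g$dosage))
})

test_that("serum expression hits the planted variance decomposition", {
  cfg <- small_cfg(seed = 41)
  g <- gen_genotypes(cfg)
  truth <- geno2lnc:::plant_eqtls(gen_tissue_counts(cfg)$truth, g, cfg)
  # noiseless limit: planted betas recovered
  cfg_hi <- small_cfg(seed = 41, target_r2 = 0.9999, covar_r2 = 1e-6)
  s <- gen_serum_expression(g, truth, covars = NULL, cfg_hi)
  t1 <- names(truth$eqtl_map)[1]
  em <- truth$eqtl_map[[t1]]
  X <- cbind(1, do.call(cbind, lapply(seq_len(nrow(em)), function(i) {
    d <- g$dosage[, em$snp_id[i]]
    d[is.na(d)] <- round(mean(d, na.rm = TRUE))
    encode_penetrance(d, em$model[i])
  })))
  b <- qr.solve(X, s$expr[t1, ])
  expect_equal(unname(b[-1]), em$beta, tolerance = 0.02)

  # all betas zero with target_r2 > covar_r2 is unreachable
  truth0 <- truth
  for (t in names(truth0$eqtl_map)) truth0$eqtl_map[[t]]$beta <- 0
  expect_error(gen_serum_expression(g, truth0, covars = NULL, cfg),
               "unreachable")
  # but is fine when target_r2 == covar_r2 (no SNP share)
  cfg_eq <- small_cfg(seed = 41, target_r2 = 0.17, covar_r2 = 0.17)
  expect_silent(s0 <- gen_serum_expression(g, truth0, covars = NULL, cfg_eq))
})

test_that("case-control generation calibrates the case fraction", {
  cfg <- sim_config(seed = 51, n_snps = 200, n_cases = 540, n_controls = 2397)
  g <- gen_genotypes(cfg, n = 2937, seed = 7, prefix = "a")
  truth <- list(eqtl_map = list(lncA = data.frame(
    snp_id = colnames(g$dosage)[1:2], model = c("additive", "dominant"),
    beta = c(0.5, -0.5))))
  mdl <- geno2lnc:::truth_as_model(truth, "lncA")
  cc <- gen_case_control(g, mdl, covars = NULL, cfg)
  expect_lt(abs(sum(cc$status) - 540), 3.5 * sqrt(540 * (1 - 540 / 2937)))
  cc2 <- gen_case_control(g, mdl, covars = NULL, cfg)
  expect_identical(cc$status, cc2$status)
})

test_that("candidate table contains truth plus decoys and round-trips", {
  cfg <- small_cfg(seed = 61)
  g <- gen_genotypes(cfg)
  truth <- geno2lnc:::plant_eqtls(gen_tissue_counts(cfg)$truth, g, cfg)
  n_true <- sum(vapply(truth$eqtl_map, nrow, integer(1)))
  tab0 <- gen_candidate_table(truth, g, n_decoys = 0)
  expect_identical(nrow(tab0), n_true)
  tab <- gen_candidate_table(truth, g, n_decoys = 4)
  expect_identical(nrow(tab), n_true + 4L * length(truth$eqtl_map))
  path <- withr::local_tempfile(fileext = ".tsv")
  geno2lnc:::write_tsv(tab, path)
  back <- geno2lnc:::read_tsv(path)
  expect_identical(back$transcript_id, tab$transcript_id)
  expect_identical(back$snp_id, tab$snp_id)
})

test_that("planted-signal monotonicity: stronger trends never lose power", {
  effects <- c(0.3, 0.8, 1.5)
  power <- vapply(effects, function(ef) {
    cfg <- small_cfg(seed = 71, trend_effect = ef, n_trend = 10,
                     n_transcripts = 40)
    tis <- gen_tissue_counts(cfg)
    expr <- counts_to_log2tpm(tis$counts)
    tr <- jt_permutation_test(expr$values[tis$truth$trend_transcript_ids, ],
                              tis$counts$stage, n_perm = 199, seed = 3)
    mean(tr$p_value < 0.05)
  }, numeric(1))
  expect_true(all(diff(power) >= 0))
})
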