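# Penetrance encodings, Huber IRLS regression, RAIC, candidate validation
# and multi-SNP model selection.

test_that("encode_penetrance implements the four models", {
  d <- c(0L, 1L, 2L, NA)
  expect_equal(encode_penetrance(d, "additive")[, 1], c(0, 1, 2, NA))
  expect_equal(encode_penetrance(d, "dominant")[, 1], c(0, 1, 1, NA))
  expect_equal(encode_penetrance(d, "recessive")[, 1], c(0, 0, 1, NA))
  tg <- encode_penetrance(c(0L, 1L, 2L), "three_genotype")
  expect_equal(unname(tg), cbind(c(0, 1, 0), c(0, 0, 1)))
  expect_error(encode_penetrance(d, "codominant"))
  expect_error(encode_penetrance(c(0L, 3L), "additive"), "dosages")
})

test_that("huber_rlm: consistency, OLS limit, bounded outlier influence", {
  set.seed(30)
  n <- 60
  X <- cbind(`(Intercept)` = 1, x = rnorm(n))
  y <- 1 + 2 * X[, "x"] + rnorm(n)
  f <- huber_rlm(y, X)
  expect_lt(abs(f$coefficients["x"] - 2), 3 * f$se["x"])
  expect_true(f$converged)

  # c -> Inf reproduces the OLS closed form
  ols <- solve(crossprod(X), crossprod(X, y))
  f_inf <- huber_rlm(y, X, huber_c = 1e6)
  expect_equal(unname(f_inf$coefficients), unname(drop(ols)),
               tolerance = 1e-6)

  # one corrupted response: robust fit moves far less than OLS does
  set.seed(31)
  X2 <- cbind(1, x = rnorm(50))
  y2 <- 0.5 + X2[, "x"] + rnorm(50, sd = 0.5)
  y2c <- y2; y2c[8] <- y2c[8] + 100
  b_clean <- solve(crossprod(X2), crossprod(X2, y2))[2]
  b_ols <- solve(crossprod(X2), crossprod(X2, y2c))[2]
  b_rob <- huber_rlm(y2c, X2, huber_c = 1.345)$coefficients[2]
  expect_lt(abs(b_rob - b_clean), 0.1 * abs(b_ols - b_clean))

  # rank deficiency names the collinear column
  X3 <- cbind(X2, dupx = X2[, "x"])
  expect_error(huber_rlm(y2, X3), "dupx")
  expect_error(huber_rlm(y2[1:2], X2[1:2, ]), "more observations")
})

test_that("huber_rlm agrees with the MASS::rlm oracle", {
  skip_if_not_installed("MASS")
  set.seed(32)
  n <- 93
  X <- cbind(1, a = rnorm(n), b = rbinom(n, 2, 0.3))
  y <- 2 + 0.5 * X[, "a"] - 0.3 * X[, "b"] + rnorm(n)
  y[1:4] <- y[1:4] + 8
  f <- huber_rlm(y, X, huber_c = 1.345)
  m <- MASS::rlm(y ~ a + b, data = data.frame(a = X[, "a"], b = X[, "b"]),
                 psi = MASS::psi.huber, k = 1.345, maxit = 200)
  expect_equal(unname(f$coefficients), unname(coef(m)), tolerance = 1e-3)
})

test_that("RAIC penalizes pure-noise columns and recovers the true model", {
  set.seed(33)
  n <- 93
  B <- 200
  worse <- 0
  diffs <- numeric(B)
  for (b in seq_len(B)) {
    x <- rnorm(n); z <- rnorm(n)
    y <- 1 + x + rnorm(n)
    f1 <- huber_rlm(y, cbind(1, x = x))            # true nested model
    f2 <- huber_rlm(y, cbind(1, x = x, z = z))     # + pure-noise column
    worse <- worse + (raic(f2) > raic(f1))
    diffs[b] <- raic(f2) - raic(f1)
  }
  expect_gte(worse / B, 0.8)
  expect_gt(mean(diffs), 0)
})

sim_validation_world <- function(seed, n = 93, beta = 0.5, maf = 0.3,
                                 noise_sd = 0.8, n_decoys = 6) {
  set.seed(seed)
  m <- n_decoys + 1L
  dos <- hwe_dosage(n, m, maf)
  g <- make_geno(dos)
  covars <- flat_covars(rownames(g$dosage))
  y <- 3 + beta * dos[, 1] + 0.01 * covars$age + rnorm(n, sd = noise_sd)
  serum <- matrix(y, 1, n, dimnames = list("lncT", rownames(g$dosage)))
  cand <- data.frame(transcript_id = "lncT", snp_id = colnames(g$dosage))
  list(geno = g, covars = covars, serum = serum, cand = cand)
}

test_that("validate_candidates flags planted eQTLs, controls decoys", {
  hits <- 0; decoy_rate <- numeric(0)
  for (b in 1:25) {
    w <- sim_validation_world(400 + b)
    val <- validate_candidates(w$serum, w$geno, w$covars, w$cand,
                               pcs = NULL, n_pcs = 0)
    hits <- hits + ("m0001" %in% val$validated$snp_id)
    dec <- subset(val$fits, snp_id != "m0001" & model == "additive")
    decoy_rate <- c(decoy_rate, mean(dec$p_value < 0.05))
  }
  expect_gte(hits / 25, 0.9)
  expect_lt(mean(decoy_rate), 0.12)
})

test_that("validation decisions are invariant to allele-label swap", {
  w <- sim_validation_world(77)
  g_flip <- w$geno
  g_flip$dosage <- 2L - g_flip$dosage
  g_flip$snps$ref <- "G"; g_flip$snps$alt <- "A"
  g_flip <- geno2lnc:::refresh_geno_meta(g_flip)
  v1 <- validate_candidates(w$serum, w$geno, w$covars, w$cand, n_pcs = 0)
  v2 <- validate_candidates(w$serum, g_flip, w$covars, w$cand, n_pcs = 0)
  # "major allele" orientation: identical fits regardless of REF/ALT labels
  expect_equal(v1$fits$p_value, v2$fits$p_value, tolerance = 1e-8)
  expect_identical(v1$validated$snp_id, v2$validated$snp_id)
})

test_that("perfect-LD validated SNPs are reduced to one", {
  w <- sim_validation_world(88, beta = 0.8)
  dos <- w$geno$dosage
  dos[, 2] <- dos[, 1]                       # decoy 2 = perfect copy of eQTL
  g <- make_geno(dos)
  val <- validate_candidates(w$serum, g, w$covars, w$cand, n_pcs = 0)
  expect_identical(sum(val$validated$snp_id %in% c("m0001", "m0002")), 1L)
  # candidate SNP absent from genotypes is untestable, not an error
  cand2 <- rbind(w$cand, data.frame(transcript_id = "lncT",
                                    snp_id = "ghost"))
  val2 <- validate_candidates(w$serum, g, w$covars, cand2, n_pcs = 0)
  expect_identical(val2$untestable$snp_id, "ghost")
})

test_that("select_prediction_model finds the exhaustive RAIC minimum", {
  set.seed(34)
  n <- 93
  dos <- hwe_dosage(n, 6, 0.3)
  g <- make_geno(dos)
  covars <- flat_covars(rownames(g$dosage))
  y <- 2 + 0.6 * dos[, 1] + 0.7 * (dos[, 2] >= 1) + rnorm(n, sd = 0.7)
  serum <- matrix(y, 1, n, dimnames = list("lncT", rownames(g$dosage)))
  cand <- data.frame(transcript_id = "lncT", snp_id = colnames(g$dosage))
  val <- validate_candidates(serum, g, covars, cand, n_pcs = 0)
  expect_true(all(c("m0001", "m0002") %in% val$validated$snp_id))
  mdl <- select_prediction_model(serum, val$validated, g, covars, n_pcs = 0)
  picked <- vapply(mdl$snps, `[[`, character(1), "snp_id")
  expect_true(all(c("m0001", "m0002") %in% picked))
  expect_gt(mdl$r2_full, mdl$r2_ref)

  # brute-force oracle: refit every subset independently and compare minima
  Z <- geno2lnc:::covariate_design(covars, NULL, 0)
  k <- nrow(val$validated)
  raics <- vapply(seq_len(2^k - 1), function(mask) {
    ss <- which(bitwAnd(mask, 2^(seq_len(k) - 1)) > 0)
    Xs <- do.call(cbind, lapply(ss, function(j) {
      d <- g$dosage[, val$validated$snp_id[j]]
      if (!val$validated$effect_is_alt[j]) d <- 2L - d
      e <- encode_penetrance(d, val$validated$model[j])
      colnames(e) <- paste0("s", j, "_", colnames(e))
      e
    }))
    huber_rlm(y, cbind(Z, Xs))$raic
  }, numeric(1))
  expect_equal(mdl$raic, min(raics), tolerance = 1e-6)

  # zero validated SNPs is a guided error
  expect_error(select_prediction_model(serum, val$validated[0, ], g, covars,
                                       transcript = "lncT", n_pcs = 0),
               "no validated")
  # combinatorial guard
  fake <- val$validated[rep(1, 25), ]
  fake$snp_id <- sprintf("m%04d", 1:25)
  expect_error(select_prediction_model(serum, fake, g, covars, n_pcs = 0),
               "allow_large")
})

test_that("eqtl_model JSON round-trips", {
  m <- toy_model(c("snpA", "snpB"), c("additive", "three_genotype"),
                 list(0.5, c(0.2, 0.9)))
  path <- withr::local_tempfile(fileext = ".json")
  m$raic <- 123.4; m$adj_r2_full <- 0.26; m$adj_r2_ref <- 0.17
  write_eqtl_model(m, path)
  m2 <- read_eqtl_model(path)
  expect_identical(m2$transcript_id, m$transcript_id)
  expect_equal(m2$snps[[2]]$beta, c(0.2, 0.9))
  expect_equal(m2$raic, 123.4)
})
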