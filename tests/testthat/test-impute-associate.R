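# Expression imputation from genotypes and robust logistic association.

test_that("predict_expression computes sum(beta * encoding)", {
  g <- make_geno(matrix(c(2L, 1L,
                          1L, 1L,
                          0L, 2L,
                          NA, 1L), 4, 2, byrow = TRUE))
  m <- toy_model(c("m0001", "m0002"), c("additive", "dominant"),
                 c(0.5, -1.0))
  pred <- predict_expression(g, m)
  expect_equal(pred$predicted, c(0.5 * 2 - 1, 0.5 - 1, 0 - 1, NA))
  # all-zero betas predict zero
  m0 <- toy_model(c("m0001", "m0002"), c("additive", "dominant"), c(0, 0))
  expect_equal(predict_expression(g, m0)$predicted[1:3], rep(0, 3))
  expect_error(predict_expression(g, structure(list(snps = list()),
                                               class = "eqtl_model")),
               "empty")
  expect_error(predict_expression(g, toy_model("zzz", "additive", 1)),
               "absent")
})

test_that("distinct predicted levels never exceed the encoding-level bound", {
  # additive (3 levels) x dominant (2 levels) with non-collapsing betas: 6
  combos <- as.matrix(expand.grid(0:2, 0:2))
  storage.mode(combos) <- "integer"
  g <- make_geno(combos)
  m <- toy_model(c("m0001", "m0002"), c("additive", "dominant"),
                 c(0.5, -1.1))
  pred <- predict_expression(g, m)
  expect_identical(length(unique(round(pred$predicted, 9))), 6L)

  set.seed(40)
  for (b in 1:20) {
    models <- sample(c("additive", "dominant", "recessive",
                       "three_genotype"), 2, replace = TRUE)
    betas <- lapply(models, function(mm) {
      rnorm(if (mm == "three_genotype") 2 else 1)
    })
    mdl <- toy_model(c("m0001", "m0002"), models, betas)
    pr <- predict_expression(g, mdl)
    bound <- prod(ifelse(models %in% c("dominant", "recessive"), 2, 3))
    expect_lte(length(unique(round(pr$predicted, 9))), bound)
  }
})

test_that("robust_logistic reduces to ML as c grows and stays calibrated", {
  set.seed(41)
  n <- 200
  X <- cbind(1, x = rnorm(n), z = rbinom(n, 1, 0.5))
  y <- rbinom(n, 1, plogis(-0.3 + 0.7 * X[, "x"]))
  rob <- robust_logistic(y, X, huber_c = 1e6)
  ml <- suppressWarnings(glm.fit(X, y, family = binomial()))
  expect_equal(unname(rob$coefficients), unname(ml$coefficients),
               tolerance = 1e-4)

  # null covariate: |beta| < 3 SE in >= 95% of replicates
  set.seed(42)
  inside <- 0
  for (b in 1:80) {
    Xb <- cbind(1, x = rnorm(300))
    yb <- rbinom(300, 1, 0.5)
    f <- robust_logistic(yb, Xb, huber_c = 1.2)
    inside <- inside + (abs(f$coefficients["x"]) < 3 * f$se["x"])
  }
  expect_gte(inside / 80, 0.95)

  expect_error(robust_logistic(rep(1, 50), cbind(1, rnorm(50))),
               "both classes")
  # perfect separation is reported against the offending covariate
  xs <- c(rnorm(30, -4), rnorm(30, 4))
  ys <- rep(c(0, 1), each = 30)
  expect_error(robust_logistic(ys, cbind(1, sep = xs), huber_c = 1.2),
               "separation")
})

test_that("associate: OR scale, covariate recoding invariance, guards", {
  set.seed(43)
  n <- 800
  dos <- hwe_dosage(n, 2, 0.3)
  g <- make_geno(dos)
  mdl <- toy_model(c("m0001", "m0002"), c("additive", "dominant"),
                   c(0.5, 0.5))
  pred <- predict_expression(g, mdl)
  covars <- flat_covars(pred$sample_id)
  lp <- log(1.6) * pred$predicted - 1
  status <- setNames(rbinom(n, 1, plogis(lp)), pred$sample_id)
  res <- associate(pred, status, covars, n_pcs = 0)
  expect_true(res$ci_lower < res$or && res$or < res$ci_upper)
  expect_gt(res$or, 1)

  # affine recoding of age / gender leaves the prediction OR unchanged
  covars2 <- covars
  covars2$age <- (covars2$age - 50) / 10
  covars2$gender <- 1 - covars2$gender
  res2 <- associate(pred, status, covars2, n_pcs = 0)
  expect_equal(res2$or, res$or, tolerance = 1e-8)

  # doubling the model betas halves the slope per predicted-log2 unit
  mdl2 <- toy_model(c("m0001", "m0002"), c("additive", "dominant"),
                    c(1.0, 1.0))
  pred2 <- predict_expression(g, mdl2)
  res3 <- associate(pred2, status, covars, n_pcs = 0)
  expect_equal(log(res3$or), log(res$or) / 2, tolerance = 1e-6)

  # constant prediction cannot be tested
  mdl0 <- toy_model(c("m0001", "m0002"), c("additive", "dominant"), c(0, 0))
  expect_error(associate(predict_expression(g, mdl0), status, covars,
                         n_pcs = 0), "constant")
})

test_that("permuted status yields a null OR with covering CI", {
  set.seed(44)
  n <- 600
  g <- make_geno(hwe_dosage(n, 2, 0.3))
  mdl <- toy_model(c("m0001", "m0002"), c("additive", "dominant"),
                   c(0.6, -0.4))
  pred <- predict_expression(g, mdl)
  covars <- flat_covars(pred$sample_id)
  cover <- 0
  for (b in 1:40) {
    status <- setNames(sample(rep(c(0L, 1L), c(450, 150))), pred$sample_id)
    res <- associate(pred, status, covars, n_pcs = 0)
    cover <- cover + (res$ci_lower <= 1 && 1 <= res$ci_upper)
  }
  expect_gte(cover / 40, 0.875)
})

test_that("report tables carry the expected layout", {
  set.seed(45)
  n <- 45
  stage <- factor(rep(c("GS", "Dys", "GBC"), each = 15),
                  levels = c("GS", "Dys", "GBC"), ordered = TRUE)
  m <- matrix(rnorm(3 * n), 3, n,
              dimnames = list(c("lncA", "lncB", "lncC"),
                              sprintf("s%03d", 1:n)))
  m["lncA", ] <- m["lncA", ] + 0.8 * as.integer(stage)
  expr <- expression_matrix(m, stage = stage)
  trend <- jt_permutation_test(expr, n_perm = 199, seed = 1)
  covars <- data.frame(sample_id = colnames(m),
                       age = round(runif(n, 40, 80)),
                       gender = rbinom(n, 1, 0.3))
  t1 <- report_stage_table(expr, trend, covars, n_perm = 99, seed = 1)
  expect_setequal(unique(t1$stratum),
                  c("All", "Women", "Men", "Age<60", "Age>=60"))
  expect_identical(nrow(t1), 15L)
  a_all <- t1[t1$stratum == "All" & t1$transcript_id == "lncA", ]
  expect_gt(a_all$diff_gbc_vs_gs, 0)

  # Table-2 layout: a transcript with no validated eQTL gets dash rows (NA)
  serum <- matrix(rnorm(2 * 30), 2, 30,
                  dimnames = list(c("lncA", "lncB"), sprintf("v%02d", 1:30)))
  validation <- list(validated = data.frame(transcript_id = "lncA",
                                            snp_id = "m0001"))
  models <- list(lncA = structure(list(snps = list(list(snp_id = "m0001")),
                                       adj_r2_full = 0.26),
                                  class = "eqtl_model"))
  cand <- data.frame(transcript_id = c(rep("lncA", 3), rep("lncB", 2)),
                     snp_id = sprintf("m%04d", 1:5))
  t2 <- report_validation_table(serum, validation, models, cand)
  expect_identical(t2$n_candidates, c(3L, 2L))
  expect_true(is.na(t2$n_validated[t2$transcript_id == "lncB"]))
  expect_true(is.na(t2$adj_r2[t2$transcript_id == "lncB"]))
  expect_equal(t2$adj_r2[t2$transcript_id == "lncA"], 0.26)

  # regenerating a report from the same inputs is identical
  t2b <- report_validation_table(serum, validation, models, cand)
  expect_identical(t2, t2b)
})
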