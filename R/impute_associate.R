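# Stage three: genotype-based expression imputation and robust logistic
# case-control association.

#' Predict (impute) log2 serum expression from genotypes
#'
#' `predicted = sum_i beta_i * A_i` with `A_i` the penetrance encoding of the
#' individual's genotype at model SNP i. No intercept or covariate term
#' enters: predictions are meaningful up to a constant, which the logistic
#' intercept absorbs. Individuals missing any model SNP get `NA`. Because
#' genotypes are discrete, the number of distinct predicted values is at most
#' the product of encoding-level counts (3 for additive / three-genotype, 2
#' for dominant / recessive).
#'
#' @param geno a [genotype_matrix()].
#' @param model an `eqtl_model`.
#' @return data.frame(sample_id, predicted, genotype_key).
#' @export
predict_expression <- function(geno, model) {
  if (!length(model$snps)) stop_user("empty prediction model")
  ids <- rownames(geno$dosage)
  pred <- numeric(length(ids))
  miss <- rep(FALSE, length(ids))
  keys <- matrix("", length(ids), length(model$snps))
  for (j in seq_along(model$snps)) {
    s <- model$snps[[j]]
    if (!s$snp_id %in% colnames(geno$dosage)) {
      stop_user("model SNP ", s$snp_id, " absent from genotype data")
    }
    d <- geno$dosage[, s$snp_id]
    if (!isTRUE(s$effect_is_alt)) d <- 2L - d
    miss <- miss | is.na(d)
    keys[, j] <- ifelse(is.na(d), "?", as.character(d))
    enc <- encode_penetrance(d, s$model)
    contrib <- as.vector(enc %*% s$beta)
    contrib[is.na(contrib)] <- 0
    pred <- pred + contrib
  }
  pred[miss] <- NA_real_
  data.frame(sample_id = ids, predicted = pred,
             genotype_key = apply(keys, 1, paste, collapse = "/"),
             stringsAsFactors = FALSE)
}

#' Robust logistic regression (Mallows quasi-likelihood)
#'
#' Cantoni–Ronchetti robust estimator for the binomial GLM: Pearson
#' residuals are Huberized at `huber_c` and the estimating equation
#' `sum_i [psi_c(r_i) - E psi_c(r_i)] * sqrt(V_i) * x_i = 0`
#' (the expectation term is the Fisher-consistency correction) is solved by
#' Newton iterations with a numerically differenced Jacobian, started at the
#' maximum-likelihood fit. Standard errors are sandwich:
#' `cov = A^{-1} Q A^{-T} / n` with `A` the expected derivative and
#' `Q = (1/n) sum_i E[(psi_c(r_i) - E psi_c)^2] V_i x_i x_i'`.
#' As `huber_c -> Inf` the estimator reduces to maximum likelihood.
#'
#' @param y 0/1 response (both classes required).
#' @param X design matrix including intercept.
#' @param huber_c tuning constant (default 1.2).
#' @param max_iter,tol Newton iteration cap and score tolerance.
#' @return a `robust_glm_fit`: coefficients, se, p_values, cov, n, converged.
#' @export
robust_logistic <- function(y, X, huber_c = 1.2, max_iter = 50L, tol = 1e-8) {
  X <- as.matrix(X)
  keep <- complete.cases(X) & !is.na(y)
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  if (length(unique(y)) < 2L) stop_user("both classes must be present")
  n <- nrow(X); p <- ncol(X)
  check_full_rank(X)

  score <- function(beta) {
    eta <- as.vector(X %*% beta)
    mu <- plogis(eta)
    V <- mu * (1 - mu)
    sV <- sqrt(V)
    r <- (y - mu) / sV
    r1 <- (1 - mu) / sV                     # residual if y = 1
    r0 <- -mu / sV                          # residual if y = 0
    m <- huber_psi(r1, huber_c) * mu + huber_psi(r0, huber_c) * (1 - mu)
    crossprod(X, (huber_psi(r, huber_c) - m) * sV)
  }

  separation_error <- function(beta) {
    sds <- apply(X, 2, sd); sds[sds == 0] <- 1
    j_bad <- which.max(abs(beta * sds))
    stop_user("separation detected: coefficient for '",
              colnames(X)[j_bad], "' diverges")
  }
  start <- suppressWarnings(glm.fit(X, y, family = binomial()))
  beta <- start$coefficients
  sds0 <- apply(X, 2, sd); sds0[sds0 == 0] <- 1
  if (max(abs(beta * sds0)) > 15) separation_error(beta)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    U <- score(beta)
    if (!all(is.finite(U))) separation_error(beta)
    if (max(abs(U)) < tol * n) { converged <- TRUE; break }
    # numerically differenced Jacobian (p is small)
    J <- matrix(0, p, p)
    h <- pmax(1e-6, 1e-6 * abs(beta))
    for (j in seq_len(p)) {
      bp <- beta; bm <- beta
      bp[j] <- bp[j] + h[j]; bm[j] <- bm[j] - h[j]
      J[, j] <- (score(bp) - score(bm)) / (2 * h[j])
    }
    step <- tryCatch(solve(J, -U), error = function(e) NULL)
    if (is.null(step)) break
    if (max(abs(step)) > 10) step <- step * 10 / max(abs(step))  # damp
    beta <- beta + as.vector(step)
    if (max(abs(beta)) > 100) separation_error(beta)
  }
  names(beta) <- colnames(X)

  eta <- as.vector(X %*% beta)
  mu <- plogis(eta)
  V <- mu * (1 - mu)
  sV <- sqrt(V)
  r1 <- (1 - mu) / sV; r0 <- -mu / sV
  m <- huber_psi(r1, huber_c) * mu + huber_psi(r0, huber_c) * (1 - mu)
  vphi <- (huber_psi(r1, huber_c) - m)^2 * mu +
    (huber_psi(r0, huber_c) - m)^2 * (1 - mu)
  Q <- crossprod(X, vphi * V * X) / n
  J <- matrix(0, p, p)
  h <- pmax(1e-6, 1e-6 * abs(beta))
  for (j in seq_len(p)) {
    bp <- beta; bm <- beta
    bp[j] <- bp[j] + h[j]; bm[j] <- bm[j] - h[j]
    J[, j] <- (score(bp) - score(bm)) / (2 * h[j])
  }
  A <- -J / n
  Ainv <- solve(A)
  covb <- Ainv %*% Q %*% t(Ainv) / n
  dimnames(covb) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(covb))
  structure(list(coefficients = beta, se = se,
                 p_values = 2 * pnorm(-abs(beta / se)),
                 cov = covb, fitted = mu, n = n, huber_c = huber_c,
                 converged = converged),
            class = "robust_glm_fit")
}

#' Association between imputed expression and disease status
#'
#' Robust logistic regression of case/control status on predicted log2
#' expression, age, gender and the first `n_pcs` genetic PCs. The odds ratio
#' is per log2 expression unit with a Wald 95% CI on the log-odds scale.
#' Individuals with a missing prediction are excluded (and counted).
#'
#' @param pred output of [predict_expression()].
#' @param status named 0/1 vector (1 = case).
#' @param covars data.frame(sample_id, age, gender).
#' @param pcs genetic PC scores or `NULL`.
#' @param n_pcs PCs to adjust for (default 10).
#' @param huber_c tuning constant (default 1.2).
#' @return an `association_result`: transcript_id, or, ci_lower, ci_upper,
#'   p_value, n_cases, n_controls, n_dropped, fit.
#' @export
associate <- function(pred, status, covars, pcs = NULL, n_pcs = 10L,
                      huber_c = 1.2) {
  ids <- pred$sample_id[!is.na(pred$predicted)]
  n_dropped <- sum(is.na(pred$predicted))
  ids <- intersect(ids, names(status))
  ids <- intersect(ids, covars$sample_id)
  if (!is.null(pcs)) ids <- intersect(ids, rownames(as.matrix(pcs)))
  pv <- setNames(pred$predicted, pred$sample_id)[ids]
  if (sd(pv) == 0) {
    stop_user("predicted expression is constant; no variation to test")
  }
  Z <- covariate_design(covars, pcs, n_pcs, sample_ids = ids)
  X <- cbind(Z[, 1, drop = FALSE], predicted = pv, Z[, -1, drop = FALSE])
  fit <- robust_logistic(status[ids], X, huber_c = huber_c)
  b <- fit$coefficients["predicted"]
  se <- fit$se["predicted"]
  structure(list(transcript_id = attr(pred, "transcript_id") %||% NA_character_,
                 or = exp(unname(b)),
                 ci_lower = exp(unname(b - 1.96 * se)),
                 ci_upper = exp(unname(b + 1.96 * se)),
                 p_value = unname(fit$p_values["predicted"]),
                 n_cases = sum(status[ids] == 1),
                 n_controls = sum(status[ids] == 0),
                 n_dropped = n_dropped, huber_c = huber_c, fit = fit),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("OR = %.3f per log2 unit (95%% CI %.3f-%.3f), p = %.3g; %d cases / %d controls\n",
              x$or, x$ci_lower, x$ci_upper, x$p_value, x$n_cases,
              x$n_controls))
  invisible(x)
}

# ---- report tables ---------------------------------------------------------

strata_list <- function(covars, age_cut = 60) {
  list(All = rep(TRUE, nrow(covars)),
       Women = covars$gender == 0,
       Men = covars$gender == 1,
       `Age<60` = covars$age < age_cut,
       `Age>=60` = covars$age >= age_cut)
}

#' Stage-wise expression report (Table-1 layout)
#'
#' Per transcript and stratum (All, Women, Men, Age<60, Age>=60): trend-test
#' FDR, median (5th; 95th percentile) log2 expression in the GS group, and
#' robust-regression estimates of the Dys-vs-GS and GBC-vs-GS differences
#' with Wald 95% CIs.
#'
#' @param expr tissue [expression_matrix()] (normalized, stage-labelled).
#' @param trend [jt_permutation_test()] output for the same matrix (used for
#'   the "All" stratum; per-stratum FDRs are recomputed with the same
#'   settings on the stratum subset).
#' @param covars tissue covariates (sample_id, age, gender).
#' @param transcripts transcripts to report (default: all rows).
#' @param n_perm,seed settings for the per-stratum trend tests.
#' @return data.frame in Table-1 layout.
#' @export
report_stage_table <- function(expr, trend, covars,
                               transcripts = rownames(expr$values),
                               n_perm = 1000L, seed = 1L) {
  covars <- covars[match(colnames(expr$values), covars$sample_id), ]
  strata <- strata_list(covars)
  out <- list()
  for (st in names(strata)) {
    sel <- strata[[st]]
    sub <- expr$values[transcripts, sel, drop = FALSE]
    stage <- droplevels(expr$stage[sel])
    fdr <- if (st == "All") {
      setNames(trend$fdr, trend$transcript_id)[transcripts]
    } else if (nlevels(stage) >= 2 && all(table(stage) >= 2)) {
      tt <- jt_permutation_test(sub, stage, n_perm = n_perm, seed = seed)
      setNames(tt$fdr, tt$transcript_id)[transcripts]
    } else setNames(rep(NA_real_, length(transcripts)), transcripts)
    for (t_id in transcripts) {
      y <- sub[t_id, ]
      gs <- y[stage == "GS"]
      qs <- if (length(gs)) quantile(gs, c(0.05, 0.5, 0.95)) else rep(NA, 3)
      X <- cbind(`(Intercept)` = 1, dys = as.numeric(stage == "Dys"),
                 gbc = as.numeric(stage == "GBC"))
      fit <- tryCatch(huber_rlm(y, X), gl_user_error = function(e) NULL,
                      error = function(e) NULL)
      fmt <- function(f, term) {
        if (is.null(f)) return(c(NA_real_, NA_real_, NA_real_))
        c(f$coefficients[term], f$coefficients[term] - 1.96 * f$se[term],
          f$coefficients[term] + 1.96 * f$se[term])
      }
      d1 <- fmt(fit, "dys"); d2 <- fmt(fit, "gbc")
      out[[length(out) + 1L]] <- data.frame(
        stratum = st, transcript_id = t_id, fdr = unname(fdr[t_id]),
        gs_median = unname(qs[2]), gs_p5 = unname(qs[1]),
        gs_p95 = unname(qs[3]),
        diff_dys_vs_gs = d1[1], diff_dys_lo = d1[2], diff_dys_hi = d1[3],
        diff_gbc_vs_gs = d2[1], diff_gbc_lo = d2[2], diff_gbc_hi = d2[3],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Validation summary report (Table-2 layout)
#'
#' Per transcript: serum expression median (5th; 95th pct), number of
#' candidate eQTLs, validated eQTLs, predictor SNPs and the best model's
#' adjusted r-squared. Transcripts with no validated SNP get `NA` ("dash")
#' entries.
#'
#' @param serum_expr serum expression matrix.
#' @param validation [validate_candidates()] output.
#' @param models named list of `eqtl_model`s (may omit transcripts).
#' @param candidates the candidate table.
#' @return data.frame in Table-2 layout.
#' @export
report_validation_table <- function(serum_expr, validation, models,
                                    candidates) {
  sm <- expr_values(serum_expr)
  transcripts <- unique(candidates$transcript_id)
  rows <- lapply(transcripts, function(t_id) {
    qs <- if (t_id %in% rownames(sm)) {
      quantile(sm[t_id, ], c(0.05, 0.5, 0.95))
    } else rep(NA_real_, 3)
    nv <- sum(validation$validated$transcript_id == t_id)
    mdl <- models[[t_id]]
    data.frame(transcript_id = t_id,
               serum_median = unname(qs[2]), serum_p5 = unname(qs[1]),
               serum_p95 = unname(qs[3]),
               n_candidates = sum(candidates$transcript_id == t_id),
               n_validated = if (nv > 0) nv else NA_integer_,
               n_predictors = if (!is.null(mdl)) length(mdl$snps) else NA_integer_,
               adj_r2 = if (!is.null(mdl)) mdl$adj_r2_full else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Association report (Table-3 layout)
#'
#' Per transcript: median predicted log2 expression, odds ratio, 95% CI and
#' p-value.
#'
#' @param results named list of `association_result`s.
#' @param predictions named list of [predict_expression()] outputs.
#' @return data.frame in Table-3 layout.
#' @export
report_association_table <- function(results, predictions) {
  if (!length(results)) {
    return(data.frame(transcript_id = character(0),
                      median_predicted = numeric(0), or = numeric(0),
                      ci_lower = numeric(0), ci_upper = numeric(0),
                      p_value = numeric(0)))
  }
  rows <- lapply(names(results), function(t_id) {
    r <- results[[t_id]]
    pr <- predictions[[t_id]]
    data.frame(transcript_id = t_id,
               median_predicted = median(pr$predicted, na.rm = TRUE),
               or = r$or, ci_lower = r$ci_lower, ci_upper = r$ci_upper,
               p_value = r$p_value, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
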