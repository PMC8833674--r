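# cis-eQTL validation: penetrance encodings, Huber IRLS robust linear
# regression with a robust AIC (RAIC), candidate validation under four
# penetrance models, and exhaustive multi-SNP model selection.

PENETRANCE_MODELS <- c("additive", "three_genotype", "dominant", "recessive")

#' Penetrance encoding of a biallelic genotype
#'
#' `additive` = effect-allele count; `dominant` = 1 if at least one effect
#' allele; `recessive` = 1 if two effect alleles; `three_genotype` = two
#' indicator columns for dosage 1 and dosage 2 (baseline 0). Missing dosages
#' stay `NA` and the fitting functions drop those rows.
#'
#' @param dosages effect-allele dosages in \{0, 1, 2, NA\}.
#' @param model one of `"additive"`, `"three_genotype"`, `"dominant"`,
#'   `"recessive"`.
#' @return numeric matrix with 1 column (2 for `three_genotype`).
#' @export
encode_penetrance <- function(dosages, model) {
  model <- match.arg(model, PENETRANCE_MODELS)
  bad <- !dosages %in% c(0L, 1L, 2L, NA)
  if (any(bad)) stop_user("dosages must be 0, 1, 2 or NA")
  switch(model,
    additive = cbind(add = as.numeric(dosages)),
    dominant = cbind(dom = as.numeric(dosages >= 1)),
    recessive = cbind(rec = as.numeric(dosages == 2)),
    three_genotype = cbind(het = as.numeric(dosages == 1),
                           hom = as.numeric(dosages == 2)))
}

huber_rho <- function(u, c) ifelse(abs(u) <= c, u^2 / 2, c * abs(u) - c^2 / 2)
huber_psi <- function(u, c) pmin(pmax(u, -c), c)

# Huber Proposal-2 scale: s solving sum(psi_c(r/s)^2) = (n - p) * kappa with
# kappa = E psi_c(Z)^2 under Z ~ N(0,1). Smoother in the residuals than the
# MAD, with a degrees-of-freedom correction; used for the RAIC.
proposal2_scale <- function(r, p, huber_c, s0 = median(abs(r)) / 0.6745) {
  n <- length(r)
  kappa <- (2 * pnorm(huber_c) - 1) - 2 * huber_c * dnorm(huber_c) +
    2 * huber_c^2 * (1 - pnorm(huber_c))
  s <- max(s0, 1e-10)
  for (i in 1:100) {
    psi <- huber_psi(r / s, huber_c)
    s_new <- s * sqrt(sum(psi^2) / ((n - p) * kappa))
    if (!is.finite(s_new) || s_new < 1e-10) return(max(s, 1e-10))
    done <- abs(s_new - s) < 1e-10 * s
    s <- s_new
    if (done) break
  }
  s
}

check_full_rank <- function(X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop_user("design matrix is rank deficient; collinear column(s): ",
              paste(bad, collapse = ", "))
  }
}

#' Huber M-estimation linear regression (IRLS)
#'
#' Iteratively reweighted least squares with Huber's psi and a concurrent
#' robust scale (median absolute residual divided by 0.6745, re-estimated
#' each iteration). Standard errors use the asymptotic
#' M-estimator ("Huber sandwich") covariance
#' `K^2 * [s^2 * sum(psi(u)^2) / (n - p)] / mean(psi'(u))^2 * (X'X)^{-1}`
#' with Huber's small-sample correction
#' `K = 1 + p/n * var(psi') / mean(psi')^2`; p-values are two-sided normal.
#' The robust AIC (RAIC) is `2 * sum rho_c(r_i / s) + 2 * n * log(s) +
#' 2 * (p + 1)` — minus twice the Huber-density quasi-log-likelihood plus the
#' usual parameter penalty; `s` here is a Huber Proposal-2 scale with a
#' degrees-of-freedom correction, so fits of different sizes to the same
#' response are comparable (Gaussian limit: AIC up to a constant).
#'
#' @param y response vector.
#' @param X design matrix including the intercept column.
#' @param huber_c tuning constant (default 1.345, 95% Gaussian efficiency).
#' @param max_iter,tol IRLS iteration cap and coefficient-change tolerance.
#' @return a `robust_fit`: coefficients, se, p_values, cov, scale, raic, r2,
#'   adj_r2, fitted, residuals, n, converged, huber_c.
#' @export
huber_rlm <- function(y, X, huber_c = 1.345, max_iter = 100L, tol = 1e-8) {
  X <- as.matrix(X)
  keep <- complete.cases(X) & !is.na(y)
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop_user("need more observations than coefficients")
  check_full_rank(X)
  beta <- qr.solve(X, y)
  converged <- FALSE
  s <- 1
  for (it in seq_len(max_iter)) {
    r <- y - as.vector(X %*% beta)
    s <- median(abs(r)) / 0.6745            # MAD about zero, Gaussian-consistent
    if (s < 1e-10) s <- max(1e-10, sqrt(mean(r^2)))  # near-exact fit
    u <- r / s
    w <- ifelse(abs(u) <= huber_c, 1, huber_c / abs(u))
    beta_new <- solve(crossprod(X, w * X), crossprod(X, w * y))
    delta <- max(abs(beta_new - beta))
    beta <- as.vector(beta_new)
    if (delta < tol * max(1, max(abs(beta)))) { converged <- TRUE; break }
  }
  names(beta) <- colnames(X)
  r <- y - as.vector(X %*% beta)
  u <- r / s
  psi <- huber_psi(u, huber_c)
  psip <- as.numeric(abs(u) <= huber_c)
  mpsip <- mean(psip)
  K <- 1 + p / n * var(psip) / mpsip^2
  kappa <- K^2 * s^2 * sum(psi^2) / (n - p) / mpsip^2
  covb <- kappa * solve(crossprod(X))
  se <- sqrt(diag(covb))
  fitted <- as.vector(X %*% beta)
  r2 <- if (sd(fitted) > 0) cor(fitted, y)^2 else 0
  s_q <- proposal2_scale(r, p, huber_c, s0 = s)
  structure(list(coefficients = beta, se = se,
                 p_values = 2 * pnorm(-abs(beta / se)),
                 cov = covb, scale = s, scale_q = s_q,
                 raic = 2 * sum(huber_rho(r / s_q, huber_c)) +
                   2 * n * log(s_q) + 2 * (p + 1),
                 r2 = r2,
                 adj_r2 = 1 - (1 - r2) * (n - 1) / (n - p),
                 fitted = fitted, residuals = r, n = n, p = p,
                 huber_c = huber_c, converged = converged),
            class = "robust_fit")
}

#' @export
print.robust_fit <- function(x, ...) {
  cat("robust_fit (Huber c =", x$huber_c, ", n =", x$n, ")\n")
  print(data.frame(beta = x$coefficients, se = x$se, p = x$p_values))
  cat("scale:", signif(x$scale, 4), " RAIC:", signif(x$raic, 6),
      " adj r2:", signif(x$adj_r2, 3), "\n")
  invisible(x)
}

#' Robust AIC of a fitted model
#' @param fit a `robust_fit`.
#' @return the RAIC value.
#' @export
raic <- function(fit) {
  if (!isTRUE(fit$converged)) warning("RAIC of a non-converged fit")
  fit$raic
}

# Joint Wald chi-square test for a set of coefficients.
wald_joint <- function(fit, cols) {
  b <- fit$coefficients[cols]
  V <- fit$cov[cols, cols, drop = FALSE]
  stat <- as.numeric(t(b) %*% solve(V, b))
  pchisq(stat, df = length(cols), lower.tail = FALSE)
}

# Effect-allele dosage under the requested orientation. "major": the effect
# allele is the major allele in this sample (flip if ALT is the minor one);
# "alt": keep ALT counts (the generator's planted orientation).
effect_dosage <- function(geno, snp_id, orientation = c("major", "alt")) {
  orientation <- match.arg(orientation)
  d <- geno$dosage[, snp_id]
  p_alt <- mean(d, na.rm = TRUE) / 2
  effect_is_alt <- orientation == "alt" || p_alt > 0.5
  list(dosage = if (effect_is_alt) d else 2L - d,
       effect_is_alt = effect_is_alt)
}

#' Validate candidate cis-eQTLs under four penetrance models
#'
#' For each candidate (transcript, SNP) pair and each penetrance model, fits
#' `log2 expression ~ SNP + age + gender + 10 PCs` by [huber_rlm()]. A SNP is
#' validated if its SNP term reaches `p < alpha` under at least one model
#' (joint Wald test of both indicators for `three_genotype`). Validated SNPs
#' in mutual LD are then reduced: ordered by best p-value, a SNP is kept only
#' if its r-squared with every already-kept SNP of the same transcript is
#' <= `r2_prune`.
#'
#' @param serum_expr serum log2 [expression_matrix()] or matrix.
#' @param geno QC-filtered [genotype_matrix()].
#' @param covars data.frame(sample_id, age, gender).
#' @param candidates data.frame(transcript_id, snp_id).
#' @param pcs genetic PC scores (rows named by sample) or `NULL`.
#' @param n_pcs PCs to adjust for (default 10).
#' @param alpha per-SNP validation threshold (default 0.05, uncorrected:
#'   candidates are a priori database hits).
#' @param effect_allele `"major"` (default) or `"alt"` orientation.
#' @param r2_prune LD threshold among validated SNPs (default 0.1).
#' @param huber_c tuning constant for the linear fits.
#' @return list: `fits` (one row per transcript x SNP x model), `validated`
#'   (winning model per retained SNP), `untestable` (candidate SNPs absent
#'   from the genotypes), `n_candidates` per transcript.
#' @export
validate_candidates <- function(serum_expr, geno, covars, candidates,
                                pcs = NULL, n_pcs = 10L, alpha = 0.05,
                                effect_allele = "major", r2_prune = 0.1,
                                huber_c = 1.345) {
  sm <- expr_values(serum_expr)
  ids <- intersect(colnames(sm), rownames(geno$dosage))
  ids <- intersect(ids, covars$sample_id)
  if (!is.null(pcs)) ids <- intersect(ids, rownames(as.matrix(pcs)))
  if (length(ids) < 20L) stop_user("too few aligned samples (", length(ids), ")")
  Z <- covariate_design(covars, pcs, n_pcs, sample_ids = ids)

  candidates <- unique(as.data.frame(candidates)[, c("transcript_id", "snp_id")])
  testable <- candidates$snp_id %in% colnames(geno$dosage) &
    candidates$transcript_id %in% rownames(sm)
  untestable <- candidates[!testable, , drop = FALSE]
  candidates <- candidates[testable, , drop = FALSE]

  rows <- list()
  for (i in seq_len(nrow(candidates))) {
    t_id <- candidates$transcript_id[i]
    s_id <- candidates$snp_id[i]
    y <- sm[t_id, ids]
    ed <- effect_dosage(geno, s_id, effect_allele)
    d <- ed$dosage[ids]
    for (model in PENETRANCE_MODELS) {
      enc <- encode_penetrance(d, model)
      if (any(apply(enc, 2, function(col) var(col, na.rm = TRUE) == 0))) {
        next                                # genotype class absent
      }
      colnames(enc) <- paste0("snp_", colnames(enc))
      fit <- tryCatch(huber_rlm(y, cbind(Z, enc), huber_c = huber_c),
                      gl_user_error = function(e) NULL)
      if (is.null(fit)) next
      snp_cols <- colnames(enc)
      p_snp <- if (length(snp_cols) > 1L) {
        wald_joint(fit, snp_cols)
      } else fit$p_values[snp_cols]
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = t_id, snp_id = s_id, model = model,
        beta = fit$coefficients[snp_cols[1]],
        se = fit$se[snp_cols[1]],
        p_value = unname(p_snp), raic = fit$raic, r2 = fit$r2,
        n = fit$n, effect_is_alt = ed$effect_is_alt,
        stringsAsFactors = FALSE)
    }
  }
  empty_fits <- data.frame(transcript_id = character(0),
                           snp_id = character(0),
                           model = character(0), beta = numeric(0),
                           se = numeric(0), p_value = numeric(0),
                           raic = numeric(0), r2 = numeric(0),
                           n = integer(0), effect_is_alt = logical(0))
  fits <- if (length(rows)) do.call(rbind, rows) else empty_fits
  rownames(fits) <- NULL

  validated <- do.call(rbind, lapply(split(fits, fits$transcript_id),
                                     function(ft) {
    best <- do.call(rbind, lapply(split(ft, ft$snp_id), function(fs) {
      fs[which.min(fs$p_value), , drop = FALSE]
    }))
    best <- best[best$p_value < alpha, , drop = FALSE]
    if (!nrow(best)) return(best)
    best <- best[order(best$p_value), , drop = FALSE]
    kept <- character(0)
    for (j in seq_len(nrow(best))) {
      s_j <- best$snp_id[j]
      if (length(kept)) {
        r2 <- suppressWarnings(
          cor(geno$dosage[ids, s_j],
              geno$dosage[ids, kept, drop = FALSE],
              use = "pairwise.complete.obs"))^2
        if (any(r2 > r2_prune, na.rm = TRUE)) next
      }
      kept <- c(kept, s_j)
    }
    best[best$snp_id %in% kept, , drop = FALSE]
  }))
  if (is.null(validated)) validated <- empty_fits
  rownames(validated) <- NULL
  list(fits = fits, validated = validated, untestable = untestable,
       n_candidates = table(candidates$transcript_id))
}

#' Select the multi-SNP prediction model by RAIC
#'
#' Enumerates every non-empty subset of the validated SNPs for one transcript
#' (each SNP entering with its winning penetrance encoding), fits
#' `log2 expression ~ SNPs + age + gender + 10 PCs` by [huber_rlm()], and
#' returns the subset with the lowest RAIC together with the full-model and
#' covariate-only ("reference") r-squared.
#'
#' @param serum_expr serum [expression_matrix()] or matrix.
#' @param validated the `validated` data.frame from [validate_candidates()],
#'   restricted to one transcript (or with a `transcript` argument).
#' @param geno [genotype_matrix()].
#' @param covars data.frame(sample_id, age, gender).
#' @param pcs genetic PC scores or `NULL`.
#' @param n_pcs PCs to adjust for.
#' @param transcript transcript id (required if `validated` covers several).
#' @param max_snps combinatorial guard (default 20); more validated SNPs
#'   require `allow_large = TRUE`.
#' @param allow_large override the guard.
#' @param huber_c tuning constant.
#' @return an `eqtl_model`: transcript_id, snps (snp_id, model, beta(s),
#'   effect_is_alt), raic, fit, r2_full, adj_r2_full, r2_ref, subset_raics.
#' @export
select_prediction_model <- function(serum_expr, validated, geno, covars,
                                    pcs = NULL, n_pcs = 10L,
                                    transcript = NULL, max_snps = 20L,
                                    allow_large = FALSE, huber_c = 1.345) {
  if (!is.null(transcript)) {
    validated <- validated[validated$transcript_id == transcript, , drop = FALSE]
  } else {
    transcript <- unique(validated$transcript_id)
    if (length(transcript) != 1L) {
      stop_user("validated table covers several transcripts; pass `transcript`")
    }
  }
  if (!nrow(validated)) {
    stop_user("no validated SNPs for ", transcript,
              ": nothing to select (transcript cannot be carried forward)")
  }
  if (nrow(validated) > max_snps && !allow_large) {
    stop_user(nrow(validated), " validated SNPs exceed the combinatorial ",
              "guard (", max_snps, "); set allow_large = TRUE to enumerate")
  }
  sm <- expr_values(serum_expr)
  ids <- intersect(colnames(sm), rownames(geno$dosage))
  ids <- intersect(ids, covars$sample_id)
  if (!is.null(pcs)) ids <- intersect(ids, rownames(as.matrix(pcs)))
  y <- sm[transcript, ids]
  Z <- covariate_design(covars, pcs, n_pcs, sample_ids = ids)

  enc_list <- lapply(seq_len(nrow(validated)), function(j) {
    d <- geno$dosage[ids, validated$snp_id[j]]
    if (!validated$effect_is_alt[j]) d <- 2L - d
    enc <- encode_penetrance(d, validated$model[j])
    colnames(enc) <- paste0(validated$snp_id[j], "_", colnames(enc))
    enc
  })

  k <- nrow(validated)
  subsets <- lapply(seq_len(2^k - 1L), function(mask) {
    which(bitwAnd(mask, 2^(seq_len(k) - 1L)) > 0)
  })
  fits <- lapply(subsets, function(ss) {
    Xs <- do.call(cbind, enc_list[ss])
    tryCatch(huber_rlm(y, cbind(Z, Xs), huber_c = huber_c),
             gl_user_error = function(e) NULL)
  })
  raics <- vapply(fits, function(f) if (is.null(f)) Inf else f$raic, numeric(1))
  best <- which.min(raics)
  fit <- fits[[best]]
  ss <- subsets[[best]]
  ref_fit <- huber_rlm(y, Z, huber_c = huber_c)

  snps <- lapply(ss, function(j) {
    cols <- colnames(enc_list[[j]])
    list(snp_id = validated$snp_id[j], model = validated$model[j],
         beta = unname(fit$coefficients[cols]),
         effect_is_alt = validated$effect_is_alt[j])
  })
  structure(list(transcript_id = transcript, snps = snps,
                 raic = fit$raic, fit = fit,
                 r2_full = fit$r2, adj_r2_full = fit$adj_r2,
                 r2_ref = ref_fit$r2, adj_r2_ref = ref_fit$adj_r2,
                 subset_raics = raics, subsets = subsets),
            class = "eqtl_model")
}

#' @export
print.eqtl_model <- function(x, ...) {
  cat("eqtl_model for", x$transcript_id, "- RAIC", signif(x$raic, 6), "\n")
  for (s in x$snps) {
    cat("  ", s$snp_id, "(", s$model, ") beta =",
        paste(signif(s$beta, 3), collapse = ", "), "\n")
  }
  cat("  adj r2 full:", signif(x$adj_r2_full, 3),
      " ref:", signif(x$adj_r2_ref, 3), "\n")
  invisible(x)
}

#' Serialize / deserialize an eqtl_model as JSON
#' @param model an `eqtl_model`.
#' @param path file path.
#' @return path / model.
#' @export
write_eqtl_model <- function(model, path) {
  payload <- list(transcript_id = model$transcript_id,
                  raic = model$raic,
                  adj_r2_full = model$adj_r2_full,
                  adj_r2_ref = model$adj_r2_ref,
                  snps = lapply(model$snps, function(s) {
                    s[c("snp_id", "model", "beta", "effect_is_alt")]
                  }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_eqtl_model
#' @export
read_eqtl_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  structure(list(transcript_id = payload$transcript_id,
                 raic = payload$raic,
                 adj_r2_full = payload$adj_r2_full,
                 adj_r2_ref = payload$adj_r2_ref,
                 snps = lapply(payload$snps, function(s) {
                   s$beta <- as.numeric(unlist(s$beta))
                   s
                 })),
            class = "eqtl_model")
}
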