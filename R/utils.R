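# Internal helpers shared across modules.

#' @importFrom stats cov mahalanobis median pnorm pchisq plogis rnorm rbinom
#'   rnbinom runif rbeta qnorm cor sd uniroot var prcomp quantile setNames
#'   complete.cases binomial glm.fit coef predict
#' @importFrom utils head combn
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_user <- function(...) {
  stop(structure(class = c("gl_user_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# round-half-up, used for the depth-exclusion count (98 samples -> 5 excluded)
round_half_up <- function(x) floor(x + 0.5)

# unscaled median absolute deviation: median(|x - median(x)|)
mad0 <- function(x) median(abs(x - median(x)))

row_mads <- function(m) apply(m, 1L, mad0)

# Mahalanobis depth 1/(1 + d^2) of rows of `scores` w.r.t. their own
# mean/covariance.  Singular covariance is a user-facing condition: fewer PCs
# are needed.
mahalanobis_depth <- function(scores) {
  scores <- as.matrix(scores)
  ctr <- colMeans(scores)
  S <- cov(scores)
  ok <- tryCatch({
    d2 <- mahalanobis(scores, ctr, S)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) {
    stop_user("PC-score covariance is singular; reduce the number of PCs ",
              "used for depth (k_pcs).")
  }
  1 / (1 + d2)
}

# Exclude the round_half_up(frac * n) samples with lowest depth.
# Ties broken by original order (earlier sample excluded first).
depth_cut <- function(depth, ids, frac) {
  n <- length(depth)
  n_excl <- round_half_up(frac * n)
  if (n_excl <= 0) {
    return(list(kept = ids, excluded = character(0), depth = depth))
  }
  ord <- order(depth, seq_len(n))
  excl <- ids[ord[seq_len(n_excl)]]
  list(kept = setdiff(ids, excl), excluded = excl, depth = depth)
}

# One-vs-rest AUC from the rank-sum formula.
auc_binary <- function(score, positive) {
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Design matrix for the covariate ("reference") part of Eqs. 1 and 3:
# intercept + age + gender + the first n_pcs genetic PCs.
covariate_design <- function(covars, pcs = NULL, n_pcs = 10L,
                             sample_ids = covars$sample_id) {
  covars <- as.data.frame(covars)
  idx <- match(sample_ids, covars$sample_id)
  if (anyNA(idx)) {
    stop_user("covariates missing for samples: ",
              paste(head(sample_ids[is.na(idx)], 5), collapse = ", "))
  }
  X <- cbind(`(Intercept)` = 1,
             age = covars$age[idx],
             gender = covars$gender[idx])
  if (!is.null(pcs) && n_pcs > 0L) {
    pm <- as.matrix(pcs)
    k <- min(n_pcs, ncol(pm))
    pidx <- match(sample_ids, rownames(pm))
    if (anyNA(pidx)) {
      stop_user("PC scores missing for samples: ",
                paste(head(sample_ids[is.na(pidx)], 5), collapse = ", "))
    }
    P <- pm[pidx, seq_len(k), drop = FALSE]
    colnames(P) <- paste0("PC", seq_len(k))
    X <- cbind(X, P)
  }
  rownames(X) <- sample_ids
  X
}

write_tsv <- function(x, path) {
  data.table::fwrite(as.data.frame(x), path, sep = "\t", quote = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t"))
}

# Stable small-integer seed stream derived from a base seed.
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
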