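# Trend preselection: Jonckheere-Terpstra permutation tests, BH FDR, a
# boosted-classifier importance screen, and the four preselection criteria.

#' Jonckheere-Terpstra statistic
#'
#' `JT = sum over ordered group pairs (g < h) of #\{(i, j): x_gi < x_hj\} +
#' 0.5 * #ties`. The null mean is `(N^2 - sum n_g^2) / 4`.
#'
#' @param values numeric vector.
#' @param stage_labels ordered factor (>= 2 non-empty levels).
#' @return the JT statistic (scalar).
#' @export
jt_statistic <- function(values, stage_labels) {
  g <- as.ordered(stage_labels)
  lev <- levels(droplevels(g))
  if (length(lev) < 2) stop_user("JT needs >= 2 non-empty ordered groups")
  jt <- 0
  for (a in seq_len(length(lev) - 1)) {
    xa <- values[g == lev[a]]
    for (b in (a + 1):length(lev)) {
      xb <- values[g == lev[b]]
      jt <- jt + sum(outer(xa, xb, "<")) + 0.5 * sum(outer(xa, xb, "=="))
    }
  }
  jt
}

jt_null_mean <- function(stage_labels) {
  n_g <- table(droplevels(as.factor(stage_labels)))
  (sum(n_g)^2 - sum(n_g^2)) / 4
}

# All ordered sample-index pairs (s, u), s != u; JT for a label assignment is
# D %*% p where D[t, (s,u)] = 1(x_ts < x_tu) + 0.5 * 1(==) and
# p[(s,u)] = 1(label(s) < label(u)).
jt_pair_index <- function(N) {
  eg <- expand.grid(s = seq_len(N), u = seq_len(N))
  eg[eg$s != eg$u, ]
}

#' Jonckheere-Terpstra permutation trend test
#'
#' Two-sided permutation p-values: `p = (1 + #\{perm: |JT_perm - E| >=
#' |JT_obs - E|\}) / (n_perm + 1)` with `E` the null mean. One shared stream
#' of label permutations is used for all transcripts, so results do not
#' change when the transcript set is subset. BH FDRs are attached.
#'
#' @param expr an [expression_matrix()] or transcripts-x-samples matrix.
#' @param stage_labels ordered factor; defaults to the matrix's stage.
#' @param n_perm number of permutations (default 5000).
#' @param seed permutation seed.
#' @return data.frame(transcript_id, jt_statistic, jt_expected, p_value, fdr,
#'   direction).
#' @export
jt_permutation_test <- function(expr, stage_labels = NULL, n_perm = 5000L,
                                seed = 1L) {
  X <- expr_values(expr)
  if (is.null(stage_labels) && inherits(expr, "expression_matrix")) {
    stage_labels <- expr$stage
  }
  g <- as.ordered(stage_labels)
  if (length(g) != ncol(X)) stop_user("one stage label per sample required")
  if (n_perm < 1) stop_user("n_perm must be >= 1")
  N <- ncol(X)
  Tn <- nrow(X)
  glev <- as.integer(g)
  pairs <- jt_pair_index(N)
  npair <- nrow(pairs)
  E <- jt_null_mean(g)

  set.seed(seed)
  perms <- replicate(n_perm, sample.int(N))   # N x n_perm, shared stream

  p_obs <- as.numeric(glev[pairs$s] < glev[pairs$u])
  obs <- rep(NA_real_, Tn)
  exceed <- numeric(Tn)

  # chunk transcripts so the T x N(N-1) comparison matrix stays small
  chunk_rows <- max(1L, floor(4e6 / npair))
  perm_chunk <- max(1L, min(n_perm, floor(4e6 / npair)))
  for (r0 in seq(1L, Tn, by = chunk_rows)) {
    rows <- r0:min(Tn, r0 + chunk_rows - 1L)
    A <- X[rows, pairs$s, drop = FALSE]
    B <- X[rows, pairs$u, drop = FALSE]
    D <- (A < B) + 0.5 * (A == B)
    obs[rows] <- as.vector(D %*% p_obs)
    dev_obs <- abs(obs[rows] - E)
    for (c0 in seq(1L, n_perm, by = perm_chunk)) {
      cols <- c0:min(n_perm, c0 + perm_chunk - 1L)
      gp <- matrix(glev[perms[, cols]], nrow = N)  # permuted labels
      P <- (gp[pairs$s, , drop = FALSE] < gp[pairs$u, , drop = FALSE]) * 1
      JTp <- D %*% P
      exceed[rows] <- exceed[rows] +
        rowSums(abs(JTp - E) >= dev_obs - 1e-9)
    }
  }
  p <- (1 + exceed) / (n_perm + 1)
  ids <- rownames(X) %||% sprintf("t%05d", seq_len(Tn))
  data.frame(transcript_id = ids,
             jt_statistic = obs,
             jt_expected = E,
             p_value = p,
             fdr = bh_fdr(p),
             direction = ifelse(obs >= E, "increasing", "decreasing"),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR
#'
#' Step-up procedure: `q_(i) = min_(j >= i) p_(j) * m / j`, capped at 1 and
#' mapped back to input order.
#'
#' @param p_values p-values in (0, 1].
#' @return FDR (q) values in input order.
#' @export
bh_fdr <- function(p_values) {
  m <- length(p_values)
  if (!m) return(numeric(0))
  o <- order(p_values, decreasing = TRUE)
  q <- pmin(1, cummin(p_values[o] * m / seq(m, 1)))
  q[order(o)]
}

upsample_balance <- function(idx_by_class) {
  target <- max(lengths(idx_by_class))
  unlist(lapply(idx_by_class, function(ix) {
    if (length(ix) == target) ix
    else c(ix, sample(ix, target - length(ix), replace = TRUE))
  }), use.names = FALSE)
}

mean_per_class_error <- function(truth, predicted) {
  mean(vapply(levels(truth), function(cl) {
    mean(predicted[truth == cl] != cl)
  }, numeric(1)))
}

#' Train the three-class stage classifier and extract importances
#'
#' Implements the model-selection protocol of the preselection screen:
#' random train/test split, class balancing by upsampling with replacement to
#' the majority-class count, random hyperparameter grid search with k-fold
#' cross-validation, best model = lowest CV mean per-class error, test-set
#' weighted one-vs-rest AUC, and per-feature relative importance scaled to a
#' maximum of 1. The gradient-boosting backend is pluggable; the default
#' backend is a multinomial elastic net (glmnet) whose grid spans the mixing
#' and penalty parameters.
#'
#' @param expr an [expression_matrix()] or transcripts-x-samples matrix.
#' @param stage_labels factor (>= 3 classes present); defaults to the
#'   matrix's stage.
#' @param split_frac training fraction (default 77/98 as in the targeted
#'   study design).
#' @param cv_folds CV folds (default 5).
#' @param grid_size random grid candidates (default 10).
#' @param seed seed controlling split, upsampling, folds and grid.
#' @param backend `"gbt"` (default; in-package gradient-boosted stumps) or
#'   `"glmnet"` (multinomial elastic net).
#' @return list: `importance` data.frame (transcript_id, importance, sorted
#'   descending), `auc` (weighted OvR test AUC), `mean_per_class_error`,
#'   `cv_folds`, `seed`, `best` hyperparameters, `n_selected` features with
#'   nonzero importance.
#' @export
train_stage_classifier <- function(expr, stage_labels = NULL,
                                   split_frac = 77 / 98, cv_folds = 5L,
                                   grid_size = 10L, seed = 1L,
                                   backend = c("gbt", "glmnet")) {
  backend <- match.arg(backend)
  X <- t(expr_values(expr))                 # samples x features
  if (is.null(stage_labels) && inherits(expr, "expression_matrix")) {
    stage_labels <- expr$stage
  }
  y <- factor(stage_labels, ordered = FALSE)
  if (nlevels(droplevels(y)) < 3) stop_user("need >= 3 classes present")
  n <- nrow(X)
  set.seed(seed)
  train_idx <- sort(sample.int(n, round(split_frac * n)))
  test_idx <- setdiff(seq_len(n), train_idx)
  if (nlevels(droplevels(y[train_idx])) < nlevels(y)) {
    stop_user("a class is absent from the training split; re-seed or ",
              "enlarge split_frac")
  }
  by_class <- split(train_idx, y[train_idx])
  bal_idx <- upsample_balance(by_class)
  Xtr <- X[bal_idx, , drop = FALSE]
  ytr <- y[bal_idx]

  if (backend == "gbt") {
    grid <- data.frame(eta = runif(grid_size, 0.05, 0.4),
                       n_rounds = sample(40:100, grid_size, replace = TRUE))
    fit_fun <- function(X, y, i) fit_gbt(X, y, eta = grid$eta[i],
                                         n_rounds = grid$n_rounds[i])
    class_fun <- function(fit, X) predict_gbt(fit, X, type = "class")
    prob_fun <- function(fit, X) predict_gbt(fit, X, type = "response")
    imp_fun <- function(fit) fit$gain
  } else {
    grid <- data.frame(alpha = runif(grid_size),
                       lambda = 10^runif(grid_size, -3, -0.5))
    fit_fun <- function(X, y, i) {
      fit <- glmnet::glmnet(X, y, family = "multinomial",
                            alpha = grid$alpha[i])
      fit$s <- grid$lambda[i]
      fit
    }
    class_fun <- function(fit, X) {
      factor(predict(fit, X, s = fit$s, type = "class"), levels(y))
    }
    prob_fun <- function(fit, X) predict(fit, X, s = fit$s,
                                         type = "response")[, , 1]
    imp_fun <- function(fit) {
      co <- coef(fit, s = fit$s)
      Reduce(`+`, lapply(co, function(m) abs(as.matrix(m)[-1, 1])))
    }
  }

  folds <- sample(rep_len(seq_len(cv_folds), nrow(Xtr)))
  cv_err <- vapply(seq_len(grid_size), function(i) {
    errs <- vapply(seq_len(cv_folds), function(f) {
      tr <- folds != f
      if (nlevels(droplevels(ytr[tr])) < nlevels(y)) return(NA_real_)
      fit <- fit_fun(Xtr[tr, , drop = FALSE], ytr[tr], i)
      pr <- class_fun(fit, Xtr[!tr, , drop = FALSE])
      mean_per_class_error(droplevels(ytr[!tr]), factor(pr, levels(y)))
    }, numeric(1))
    mean(errs, na.rm = TRUE)
  }, numeric(1))
  best <- which.min(cv_err)

  fit <- fit_fun(Xtr, ytr, best)
  imp_raw <- imp_fun(fit)
  imp <- imp_raw[imp_raw > 0]
  if (length(imp)) imp <- imp / max(imp)
  importance <- data.frame(transcript_id = names(imp), importance = imp,
                           stringsAsFactors = FALSE)
  importance <- importance[order(-importance$importance), , drop = FALSE]
  rownames(importance) <- NULL

  Xte <- X[test_idx, , drop = FALSE]
  yte <- droplevels(y[test_idx])
  pred_class <- factor(class_fun(fit, Xte), levels(y))
  prob <- prob_fun(fit, Xte)
  aucs <- vapply(levels(yte), function(cl) {
    auc_binary(prob[, cl], yte == cl)
  }, numeric(1))
  w <- as.vector(table(yte)[levels(yte)]) / length(yte)
  list(importance = importance,
       auc = sum(w * aucs, na.rm = TRUE),
       mean_per_class_error = mean_per_class_error(yte, pred_class),
       cv_folds = cv_folds, seed = seed, backend = backend,
       best = as.list(grid[best, ]),
       cv_errors = cv_err,
       n_selected = length(imp))
}

#' Apply the four preselection criteria
#'
#' A transcript is selected iff it (i) has trend-test FDR < `fdr_max` and
#' relative importance above the median of nonzero importances, (ii) is
#' annotated as a lncRNA and not duplicated, (iii) has nonzero MAD log2
#' expression in the serum validation set, and (iv) appears in the candidate
#' cis-eQTL table.
#'
#' @param trend output of [jt_permutation_test()].
#' @param importance output of [train_stage_classifier()] (or its
#'   `importance` data.frame).
#' @param serum_expr serum [expression_matrix()] or matrix (validation set).
#' @param candidate_table data.frame with `transcript_id` (and `snp_id`).
#' @param annotation optional data.frame(transcript_id, is_lncrna); by
#'   default every transcript is an annotated lncRNA.
#' @param fdr_max FDR threshold for criterion (i) (default 0.05).
#' @return list(selected = ids passing all four, criteria = per-transcript
#'   logical matrix with one column per criterion).
#' @export
select_candidates <- function(trend, importance, serum_expr, candidate_table,
                              annotation = NULL, fdr_max = 0.05) {
  imp <- if (is.data.frame(importance)) importance else importance$importance
  if (anyDuplicated(trend$transcript_id) || anyDuplicated(imp$transcript_id)) {
    stop_user("duplicated transcript ids within an input (id collision)")
  }
  ids <- trend$transcript_id
  imp_v <- setNames(imp$importance, imp$transcript_id)[ids]
  imp_v[is.na(imp_v)] <- 0
  med <- median(imp$importance[imp$importance > 0])
  crit_i <- trend$fdr < fdr_max & imp_v > med

  if (is.null(annotation)) {
    annotated <- rep(TRUE, length(ids))
  } else {
    ann <- setNames(as.logical(annotation$is_lncrna),
                    annotation$transcript_id)[ids]
    annotated <- !is.na(ann) & ann &
      !(ids %in% annotation$transcript_id[duplicated(annotation$transcript_id)])
  }
  crit_ii <- annotated & !duplicated(ids)

  sm <- expr_values(serum_expr)
  serum_mad <- setNames(row_mads(sm), rownames(sm))[ids]
  crit_iii <- !is.na(serum_mad) & serum_mad > 0

  crit_iv <- ids %in% candidate_table$transcript_id

  criteria <- cbind(jt_and_importance = crit_i, annotated_unique = crit_ii,
                    serum_mad_nonzero = crit_iii, in_candidate_table = crit_iv)
  rownames(criteria) <- ids
  list(selected = ids[rowSums(criteria) == 4L], criteria = criteria)
}
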