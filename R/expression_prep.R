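# Expression preprocessing: counts -> log2 TPM, MAD filtering, two-pass
# quantile normalization, and PCA + Mahalanobis-depth sample exclusion.

#' Counts to log2 TPM
#'
#' TPM for transcript t in sample s is `(count / length_kb) / sum_t(count /
#' length_kb) * 1e6`; the stored value is `log2(TPM + pseudocount)`. Each
#' sample's TPM column sums to 1e6 before the log.
#'
#' @param counts a [count_matrix()].
#' @param pseudocount added on the TPM scale before log2 (default 1).
#' @return an [expression_matrix()] in state `raw-log2`.
#' @export
counts_to_log2tpm <- function(counts, pseudocount = 1) {
  stopifnot(inherits(counts, "count_matrix"))
  rate <- counts$counts / (counts$lengths / 1000)
  tot <- colSums(rate)
  if (any(tot == 0)) {
    stop_user("sample(s) with all-zero counts: ",
              paste(colnames(counts$counts)[tot == 0], collapse = ", "))
  }
  tpm <- sweep(rate, 2, tot, "/") * 1e6
  expression_matrix(log2(tpm + pseudocount), stage = counts$stage,
                    norm_state = "raw-log2")
}

#' MAD filter
#'
#' Removes transcripts whose unscaled median absolute deviation
#' `median(|x - median(x)|)` is zero (no usable variability).
#'
#' @param expr an [expression_matrix()].
#' @return list(expr = filtered matrix, excluded = dropped transcript ids).
#' @export
mad_filter <- function(expr) {
  stopifnot(inherits(expr, "expression_matrix"))
  keep <- expr$mads > 0
  excluded <- rownames(expr$values)[!keep]
  out <- expression_matrix(expr$values[keep, , drop = FALSE],
                           stage = expr$stage, norm_state = expr$norm_state)
  list(expr = out, excluded = excluded)
}

# Quantile-normalize one block of columns: each column's sorted values become
# the across-column mean of order statistics; tied values receive the mean of
# the normalized values at their tied (average) ranks, by interpolation.
qn_block <- function(x) {
  n <- nrow(x)
  srt <- apply(x, 2L, sort)
  ref <- rowMeans(srt)
  apply(x, 2L, function(col) {
    r <- rank(col, ties.method = "average")
    lo <- floor(r); hi <- ceiling(r)
    (ref[lo] + ref[hi]) / 2
  })
}

#' Quantile normalization (optionally within groups)
#'
#' With `groups = NULL` all samples form one block; otherwise each group is
#' normalized separately. The study scheme is two-pass: first within stage
#' groups, then globally (see [quantile_normalize_two_pass()]).
#'
#' @param expr an [expression_matrix()].
#' @param groups factor of length `ncol` (e.g. stage labels) or `NULL`.
#' @return a normalized [expression_matrix()]; `norm_state` advances to
#'   `group-QN` (grouped) or `global-QN` (global).
#' @export
quantile_normalize <- function(expr, groups = NULL) {
  stopifnot(inherits(expr, "expression_matrix"))
  x <- expr$values
  new_state <- if (is.null(groups)) "global-QN" else "group-QN"
  if (expr$norm_state == "global-QN" && new_state == "group-QN") {
    stop_user("normalization state only moves forward ",
              "(group-QN before global-QN)")
  }
  if (is.null(groups)) {
    if (ncol(x) < 2) stop_user("quantile normalization needs >= 2 samples")
    out <- qn_block(x)
  } else {
    groups <- as.factor(groups)
    if (length(groups) != ncol(x)) stop_user("one group label per sample")
    out <- x
    for (g in levels(groups)) {
      idx <- which(groups == g)
      if (length(idx) < 2) {
        stop_user("group '", g, "' has fewer than 2 samples")
      }
      out[, idx] <- qn_block(x[, idx, drop = FALSE])
    }
  }
  dimnames(out) <- dimnames(x)
  expression_matrix(out, stage = expr$stage, norm_state = new_state)
}

#' @rdname quantile_normalize
#' @export
quantile_normalize_two_pass <- function(expr) {
  if (is.null(expr$stage)) stop_user("two-pass normalization needs stage labels")
  quantile_normalize(quantile_normalize(expr, groups = expr$stage),
                     groups = NULL)
}

#' PCA + Mahalanobis-depth sample exclusion
#'
#' PCA on sample expression profiles; Mahalanobis depth `1 / (1 + d^2)` is
#' computed on the first `k_pcs` PC scores and the `round_half_up(frac * n)`
#' samples with lowest depth are excluded (98 samples at 5% -> 5 excluded,
#' 93 kept).
#'
#' @param expr an [expression_matrix()].
#' @param frac fraction of samples to exclude (default 0.05).
#' @param k_pcs PCs used for the depth (default `min(10, n - 1)`).
#' @return list(kept, excluded, scores, depth, expr = matrix restricted to
#'   kept samples).
#' @export
pca_depth_exclude <- function(expr, frac = 0.05, k_pcs = NULL) {
  stopifnot(inherits(expr, "expression_matrix"))
  X <- t(expr$values)                       # samples x transcripts
  n <- nrow(X)
  if (is.null(k_pcs)) k_pcs <- min(10L, n - 1L)
  if (n < k_pcs + 1L) stop_user("need at least k_pcs + 1 samples")
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(k_pcs), drop = FALSE]
  depth <- mahalanobis_depth(scores)
  cut <- depth_cut(depth, rownames(X), frac)
  keep_idx <- match(cut$kept, colnames(expr$values))
  kept_expr <- expression_matrix(
    expr$values[, keep_idx, drop = FALSE],
    stage = if (is.null(expr$stage)) NULL else expr$stage[keep_idx],
    norm_state = expr$norm_state)
  list(kept = cut$kept, excluded = cut$excluded, scores = scores,
       depth = depth, expr = kept_expr)
}
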