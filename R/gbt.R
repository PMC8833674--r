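# Minimal multiclass gradient boosting with depth-1 stumps (softmax /
# multinomial deviance, shrinkage, least-squares leaf values). This is the
# default backend for the stage classifier: like the boosted-tree models used
# for this kind of screen, it spreads small nonzero importance over many
# features while concentrating gain on the truly predictive ones.

fit_gbt <- function(X, y, eta = 0.1, n_rounds = 60L) {
  X <- as.matrix(X)
  y <- factor(y)
  n <- nrow(X); p <- ncol(X); K <- nlevels(y)
  Y <- matrix(0, n, K)
  Y[cbind(seq_len(n), as.integer(y))] <- 1
  ord <- apply(X, 2L, order)                # per-feature sort orders, once
  Xsort <- matrix(X[cbind(as.vector(ord), rep(seq_len(p), each = n))], n, p)
  splittable <- rbind(Xsort[-n, , drop = FALSE] !=
                        Xsort[-1, , drop = FALSE],
                      rep(FALSE, p))        # no split between tied values
  Fm <- matrix(0, n, K)
  stumps <- vector("list", n_rounds * K)
  gain_by_feature <- numeric(p)
  idx_split <- seq_len(n - 1L)
  for (m in seq_len(n_rounds)) {
    Pm <- exp(Fm - apply(Fm, 1L, max))
    Pm <- Pm / rowSums(Pm)
    for (k in seq_len(K)) {
      r <- Y[, k] - Pm[, k]
      Rs <- matrix(r[ord], n, p)
      CS <- apply(Rs, 2L, cumsum)
      S <- sum(r)
      left <- CS[idx_split, , drop = FALSE]
      cnt <- idx_split
      gain <- left^2 / cnt + (S - left)^2 / (n - cnt) - S^2 / n
      gain[!splittable[idx_split, , drop = FALSE]] <- -Inf
      best <- arrayInd(which.max(gain), dim(gain))
      i_s <- best[1]; j_s <- best[2]
      g <- gain[i_s, j_s]
      if (!is.finite(g) || g <= 0) next
      thr <- (Xsort[i_s, j_s] + Xsort[i_s + 1L, j_s]) / 2
      lv <- left[i_s, j_s] / i_s
      rv <- (S - left[i_s, j_s]) / (n - i_s)
      is_left <- X[, j_s] <= thr
      Fm[, k] <- Fm[, k] + eta * ifelse(is_left, lv, rv)
      gain_by_feature[j_s] <- gain_by_feature[j_s] + g
      stumps[[(m - 1L) * K + k]] <- c(k = k, j = j_s, thr = thr,
                                      lv = lv, rv = rv)
    }
  }
  stumps <- stumps[!vapply(stumps, is.null, logical(1))]
  structure(list(stumps = stumps, eta = eta, levels = levels(y),
                 features = colnames(X),
                 gain = setNames(gain_by_feature, colnames(X))),
            class = "gbt_fit")
}

predict_gbt <- function(fit, X, type = c("response", "class")) {
  type <- match.arg(type)
  X <- as.matrix(X)[, fit$features, drop = FALSE]
  K <- length(fit$levels)
  Fm <- matrix(0, nrow(X), K)
  for (s in fit$stumps) {
    Fm[, s["k"]] <- Fm[, s["k"]] +
      fit$eta * ifelse(X[, s["j"]] <= s["thr"], s["lv"], s["rv"])
  }
  Pm <- exp(Fm - apply(Fm, 1L, max))
  Pm <- Pm / rowSums(Pm)
  colnames(Pm) <- fit$levels
  if (type == "response") Pm else
    factor(fit$levels[max.col(Pm, ties.method = "first")], fit$levels)
}
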