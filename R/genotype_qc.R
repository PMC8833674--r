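# Genotype QC: MAF / call-rate filters, method-of-moments IBD kinship,
# relatedness pruning, LD pruning, eigenstrat-normalized genetic PCA and
# depth-based outlier exclusion.

#' SNP and sample filters
#'
#' SNPs are kept iff MAF >= `maf_min` (computed on non-missing calls) and
#' call rate >= `snp_callrate_min`; samples are then kept iff their call rate
#' (over the retained SNPs) is >= `sample_callrate_min`. SNP filter runs
#' before the sample filter.
#'
#' @param geno a [genotype_matrix()].
#' @param maf_min minimum MAF (default 0.01).
#' @param snp_callrate_min minimum SNP call rate (default 0.95).
#' @param sample_callrate_min minimum sample call rate (default 0.95).
#' @return list(geno = filtered matrix, report = data.frame of counts,
#'   dropped_snps, dropped_samples).
#' @export
snp_sample_filter <- function(geno, maf_min = 0.01, snp_callrate_min = 0.95,
                              sample_callrate_min = 0.95) {
  keep_snp <- !is.na(geno$maf) & geno$maf >= maf_min &
    geno$snp_callrate >= snp_callrate_min
  dropped_snps <- colnames(geno$dosage)[!keep_snp]
  g <- subset_geno(geno, snps = colnames(geno$dosage)[keep_snp])
  keep_sample <- g$sample_callrate >= sample_callrate_min
  dropped_samples <- rownames(g$dosage)[!keep_sample]
  g <- subset_geno(g, samples = rownames(g$dosage)[keep_sample])
  if (ncol(g$dosage) == 0L || nrow(g$dosage) == 0L) {
    stop_user("no SNPs or samples left after filtering")
  }
  report <- data.frame(
    n_snps_in = ncol(geno$dosage), n_snps_kept = ncol(g$dosage),
    n_samples_in = nrow(geno$dosage), n_samples_kept = nrow(g$dosage))
  list(geno = g, report = report, dropped_snps = dropped_snps,
       dropped_samples = dropped_samples)
}

#' Method-of-moments IBD kinship
#'
#' PLINK-style estimator: per pair, observed counts of identity-by-state
#' (IBS) 0/1/2 over jointly non-missing SNPs are equated to their
#' Hardy-Weinberg expectations under IBD states 0/1/2 given the sample allele
#' frequencies, giving P(IBD = z); the kinship ("PI-HAT") coefficient is
#' `P(IBD=2) + P(IBD=1)/2`, truncated to \[0, 1\]. No finite-sample
#' allele-frequency correction is applied.
#'
#' @param geno a [genotype_matrix()] (>= 100 SNPs recommended; warns below).
#' @param min_shared pairs with fewer jointly non-missing SNPs are flagged
#'   unreliable (default 50).
#' @return list: `coeff` symmetric matrix of coefficients (self ~ 1),
#'   `n_shared` matrix, `unreliable` logical matrix.
#' @export
ibd_kinship <- function(geno, min_shared = 50L) {
  X <- geno$dosage
  n <- nrow(X); m <- ncol(X)
  if (m < 100L) warning("fewer than 100 SNPs; IBD estimates will be noisy")
  p <- colMeans(X, na.rm = TRUE) / 2
  poly <- p > 0 & p < 1
  X <- X[, poly, drop = FALSE]
  p <- p[poly]; q <- 1 - p
  # expected IBS-class probabilities given IBD state
  e0_0 <- 2 * p^2 * q^2
  e1_0 <- 4 * p^3 * q + 4 * p * q^3
  e2_0 <- p^4 + q^4 + 4 * p^2 * q^2
  e1_1 <- 2 * p^2 * q + 2 * p * q^2
  e2_1 <- p^3 + q^3 + p^2 * q + p * q^2

  ids <- rownames(geno$dosage)
  # indicator matrices; NA -> FALSE so missing genotypes never count
  NM <- !is.na(X)
  A0 <- (!is.na(X)) & X == 0L; A0[is.na(A0)] <- FALSE
  A1 <- (!is.na(X)) & X == 1L; A1[is.na(A1)] <- FALSE
  A2 <- (!is.na(X)) & X == 2L; A2[is.na(A2)] <- FALSE
  mode(NM) <- "numeric"; mode(A0) <- "numeric"
  mode(A1) <- "numeric"; mode(A2) <- "numeric"
  N2m <- tcrossprod(A0) + tcrossprod(A1) + tcrossprod(A2)
  N0m <- A0 %*% t(A2) + A2 %*% t(A0)
  n_sh <- NM %*% t(NM)
  N1m <- n_sh - N0m - N2m
  # per-pair expectation sums restricted to jointly non-missing SNPs
  esum <- function(e) (NM * rep(e, each = n)) %*% t(NM)
  E0 <- esum(e0_0); E10 <- esum(e1_0); E20 <- esum(e2_0)
  E11 <- esum(e1_1); E21 <- esum(e2_1)
  z0 <- ifelse(E0 > 0, N0m / E0, 0)
  z0 <- pmin(pmax(z0, 0), 1)
  z1 <- ifelse(E11 > 0, (N1m - z0 * E10) / E11, 0)
  z1 <- pmin(pmax(z1, 0), 1)
  z2 <- ifelse(n_sh > 0, (N2m - z0 * E20 - z1 * E21) / n_sh, 0)
  z2 <- pmin(pmax(z2, 0), 1)
  s <- z0 + z1 + z2
  z1 <- ifelse(s > 0, z1 / s, 0)
  z2 <- ifelse(s > 0, z2 / s, 0)
  coeff <- pmin(pmax(z2 + z1 / 2, 0), 1)
  dimnames(coeff) <- list(ids, ids)
  n_shared <- matrix(as.integer(n_sh), n, n, dimnames = list(ids, ids))
  list(coeff = coeff, n_shared = n_shared,
       unreliable = n_shared < min_shared)
}

#' Relatedness pruning
#'
#' Greedy: while any pair exceeds `threshold`, remove the member with the
#' lower call rate (tie: the lexicographically smaller id is removed) and
#' re-examine the remaining pairs. The returned sample set contains no pair
#' above the threshold.
#'
#' @param kin output of [ibd_kinship()].
#' @param geno the [genotype_matrix()] the kinship was computed on.
#' @param threshold IBD coefficient threshold (default 0.1).
#' @return list(kept, removed).
#' @export
relatedness_prune <- function(kin, geno, threshold = 0.1) {
  K <- kin$coeff
  ids <- rownames(K)
  callrate <- setNames(geno$sample_callrate[ids], ids)
  active <- ids
  removed <- character(0)
  repeat {
    Ka <- K[active, active, drop = FALSE]
    Ka[lower.tri(Ka, diag = TRUE)] <- NA
    over <- which(Ka > threshold, arr.ind = TRUE)
    if (!nrow(over)) break
    pair <- c(active[over[1, 1]], active[over[1, 2]])
    cr <- callrate[pair]
    drop <- if (cr[1] != cr[2]) pair[which.min(cr)] else min(pair)
    removed <- c(removed, drop)
    active <- setdiff(active, drop)
  }
  list(kept = active, removed = removed)
}

#' LD pruning
#'
#' Greedy sliding-window scan per chromosome: within each window of `window`
#' SNPs (advanced by `step`), while any retained pair has squared genotype
#' correlation above `r2_max`, the member of the worst pair with the lower
#' MAF is dropped (tie: the SNP at the later position). The surviving set has
#' no within-window pair with r^2 > `r2_max`.
#'
#' @param geno a [genotype_matrix()] with per-chromosome sorted positions.
#' @param r2_max r-squared threshold (default 0.1).
#' @param window window size in SNPs (default 50).
#' @param step window step in SNPs (default 5).
#' @return kept SNP ids (character).
#' @export
ld_prune <- function(geno, r2_max = 0.1, window = 50L, step = 5L) {
  snps <- geno$snps
  keep <- setNames(rep(TRUE, nrow(snps)), snps$snp_id)
  maf <- geno$maf
  for (chr in unique(snps$chrom)) {
    idx <- which(snps$chrom == chr)
    idx <- idx[order(snps$pos[idx])]
    m <- length(idx)
    for (w0 in seq(1L, max(1L, m - 1L), by = step)) {
      win <- idx[w0:min(m, w0 + window - 1L)]
      repeat {
        cur <- win[keep[snps$snp_id[win]]]
        if (length(cur) < 2L) break
        R <- suppressWarnings(
          cor(geno$dosage[, snps$snp_id[cur], drop = FALSE],
              use = "pairwise.complete.obs"))^2
        R[lower.tri(R, diag = TRUE)] <- NA
        R[is.na(R)] <- 0
        if (max(R) <= r2_max) break
        worst <- which(R == max(R), arr.ind = TRUE)[1, ]
        a <- cur[worst[1]]; b <- cur[worst[2]]
        drop <- if (maf[a] != maf[b]) {
          c(a, b)[which.min(c(maf[a], maf[b]))]
        } else c(a, b)[which.max(snps$pos[c(a, b)])]
        keep[snps$snp_id[drop]] <- FALSE
      }
      if (w0 + window - 1L >= m) break
    }
  }
  names(keep)[keep]
}

#' Genetic PCA (eigenstrat normalization)
#'
#' Dosages are centered by `2 * p_hat` and scaled by
#' `sqrt(2 * p_hat * (1 - p_hat))`; missing genotypes become 0 after
#' centering (mean imputation). The top-`k` eigenvectors of the
#' sample-sample covariance give the scores. Sign convention: each PC's
#' largest-magnitude score is positive.
#'
#' @param geno a filtered, LD-pruned [genotype_matrix()].
#' @param k number of PCs (default 10; must be < number of samples).
#' @return list(scores n x k matrix, eigenvalues, k).
#' @export
genetic_pca <- function(geno, k = 10L) {
  X <- geno$dosage
  n <- nrow(X)
  if (k >= n) stop_user("k must be smaller than the number of samples")
  p <- colMeans(X, na.rm = TRUE) / 2
  use <- p > 0 & p < 1
  X <- X[, use, drop = FALSE]; p <- p[use]
  G <- sweep(X, 2, 2 * p, "-")
  G <- sweep(G, 2, sqrt(2 * p * (1 - p)), "/")
  G[is.na(G)] <- 0
  m <- ncol(G)
  if (m < n) {
    # SNP-side eigendecomposition (cheaper when SNPs < samples):
    # G'G = V D^2 V'  =>  sample eigenvectors U = G V D^{-1}
    eigm <- eigen(crossprod(G), symmetric = TRUE)
    d2 <- pmax(eigm$values, 0)
    keep_k <- seq_len(k)
    U <- G %*% eigm$vectors[, keep_k, drop = FALSE]
    U <- sweep(U, 2, sqrt(pmax(d2[keep_k], 1e-12)), "/")
    eig <- list(values = d2 / m, vectors = U)
  } else {
    eig <- eigen(tcrossprod(G) / m, symmetric = TRUE)
  }
  scores <- eig$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(scores[, j]))
    if (scores[i_max, j] < 0) scores[, j] <- -scores[, j]
  }
  scores <- sweep(scores, 2, sqrt(pmax(eig$values[seq_len(k)], 0)), "*")
  dimnames(scores) <- list(rownames(X), paste0("PC", seq_len(k)))
  list(scores = scores, eigenvalues = eig$values, k = k)
}

#' Depth-based genotype outlier exclusion
#'
#' The expression-side depth rule applied to genetic PC scores: excludes the
#' `round_half_up(frac * n)` individuals with the lowest Mahalanobis depth.
#'
#' @param pcs output of [genetic_pca()] (or a score matrix).
#' @param frac fraction to exclude (default 0.05).
#' @return list(kept, excluded, depth).
#' @export
depth_exclude_genetic <- function(pcs, frac = 0.05) {
  scores <- if (is.list(pcs)) pcs$scores else as.matrix(pcs)
  depth <- mahalanobis_depth(scores)
  depth_cut(depth, rownames(scores), frac)
}
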