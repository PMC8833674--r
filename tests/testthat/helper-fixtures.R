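# Shared fixtures and independent brute-force oracles.

# Brute-force Jonckheere-Terpstra: double loop over all ordered group pairs.
jt_brute <- function(values, groups) {
  g <- as.integer(as.ordered(groups))
  jt <- 0
  n <- length(values)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (g[i] < g[j]) {
        jt <- jt + (values[i] < values[j]) + 0.5 * (values[i] == values[j])
      }
    }
  }
  jt
}

# Brute-force Benjamini-Hochberg step-up: q_(i) = min_{j >= i} p_(j) * m / j.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(p[o][i:m] * m / (i:m)))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Plain genotype_matrix from a dosage matrix (one chromosome, unit spacing).
make_geno <- function(dosage, pos = NULL) {
  n <- nrow(dosage); m <- ncol(dosage)
  if (is.null(rownames(dosage))) rownames(dosage) <- sprintf("s%04d", 1:n)
  snps <- data.frame(snp_id = sprintf("m%04d", seq_len(m)), chrom = "1",
                     pos = pos %||% (seq_len(m) * 1000L),
                     ref = "A", alt = "G", stringsAsFactors = FALSE)
  genotype_matrix(dosage, snps)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# HWE dosages for n samples, m SNPs at allele frequency p.
hwe_dosage <- function(n, m, p = 0.3) {
  matrix(rbinom(n * m, 2L, p), n, m)
}

# Minimal eqtl_model from (snp_id, model, beta) rows; effect allele = ALT.
toy_model <- function(snp_ids, models, betas, transcript = "lncT") {
  structure(list(transcript_id = transcript,
                 snps = mapply(function(s, m, b) {
                   list(snp_id = s, model = m, beta = b, effect_is_alt = TRUE)
                 }, snp_ids, models, betas, SIMPLIFY = FALSE)),
            class = "eqtl_model")
}

# Covariates with zero effect used where the covariate content is irrelevant.
flat_covars <- function(ids) {
  data.frame(sample_id = ids, age = seq(40, 70, length.out = length(ids)),
             gender = rep_len(c(0, 1), length(ids)))
}
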