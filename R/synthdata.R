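# Synthetic-data generator: every statistical structure the three analysis
# stages assume, with planted ground truth for recovery tests.
#
# The defaults encode the study design this pipeline targets: 98 FFPE tissue
# samples (31 gallstone / 35 dysplasia / 32 carcinoma), a 110-individual
# serum + genotype eQTL set, and a 540-case / 2397-control association set
# with a true odds ratio of 1.25 per log2 expression unit.

STAGES <- c("GS", "Dys", "GBC")

#' Simulation configuration
#'
#' Builds the configuration object consumed by all `gen_*()` generators.
#' Defaults reproduce the sample sizes and effect sizes of the gallbladder
#' cancer study design the pipeline targets.
#'
#' @param seed integer; base seed. Every generator is a pure function of the
#'   configuration (same config, same output).
#' @param n_per_stage named integer vector, samples per tissue stage
#'   (`GS`, `Dys`, `GBC`).
#' @param n_transcripts total transcripts in the tissue count matrix.
#' @param n_trend number of transcripts with a planted monotone stage trend
#'   (both directions represented).
#' @param trend_effect planted log2 shift per stage step.
#' @param prop_silent fraction of transcripts that are essentially undetected
#'   (near-zero counts), emulating the large MAD = 0 fraction of FFPE lncRNA
#'   data (7168/7500 in the targeted study).
#' @param nb_dispersion negative-binomial dispersion (1/size) of counts.
#' @param n_individuals_eqtl individuals in the eQTL validation set.
#' @param n_snps SNPs in each generated genotype panel.
#' @param maf_range interval in (0, 0.5] from which ancestral allele
#'   frequencies are drawn.
#' @param n_true_eqtls_per_transcript planted cis-eQTLs per trend transcript
#'   (penetrance models cycle additive, dominant).
#' @param eqtl_beta planted eQTL effect, log2 units per effect-allele unit.
#' @param target_r2 expected variance fraction of serum expression explained
#'   by the full model (SNPs + age + gender); 0.26 in the targeted study.
#' @param covar_r2 expected variance fraction explained by age/gender alone
#'   (the "reference model"); 0.17 in the targeted study. Must be < target_r2
#'   unless all planted betas are zero.
#' @param n_cases,n_controls association-set sample sizes.
#' @param true_or_per_log2 true odds ratio per log2 unit of genotype-based
#'   expression.
#' @param n_subpops discrete subpopulations for genotype structure.
#' @param fst_like_divergence Balding–Nichols F parameter controlling
#'   allele-frequency divergence between subpopulations (0 = none).
#' @param geno_missing_rate per-genotype missingness rate.
#' @return a `sim_config` list, validated.
#' @export
sim_config <- function(seed = 1L,
                       n_per_stage = c(GS = 31L, Dys = 35L, GBC = 32L),
                       n_transcripts = 7500L,
                       n_trend = 36L,
                       trend_effect = 1.0,
                       prop_silent = 7168 / 7500,
                       nb_dispersion = 0.3,
                       n_individuals_eqtl = 110L,
                       n_snps = 5000L,
                       maf_range = c(0.05, 0.5),
                       n_true_eqtls_per_transcript = 2L,
                       eqtl_beta = 0.5,
                       target_r2 = 0.26,
                       covar_r2 = 0.17,
                       n_cases = 540L,
                       n_controls = 2397L,
                       true_or_per_log2 = 1.25,
                       n_subpops = 2L,
                       fst_like_divergence = 0.02,
                       geno_missing_rate = 0.005) {
  cfg <- list(seed = as.integer(seed), n_per_stage = n_per_stage,
              n_transcripts = as.integer(n_transcripts),
              n_trend = as.integer(n_trend), trend_effect = trend_effect,
              prop_silent = prop_silent, nb_dispersion = nb_dispersion,
              n_individuals_eqtl = as.integer(n_individuals_eqtl),
              n_snps = as.integer(n_snps), maf_range = maf_range,
              n_true_eqtls_per_transcript = as.integer(n_true_eqtls_per_transcript),
              eqtl_beta = eqtl_beta, target_r2 = target_r2,
              covar_r2 = covar_r2, n_cases = as.integer(n_cases),
              n_controls = as.integer(n_controls),
              true_or_per_log2 = true_or_per_log2,
              n_subpops = as.integer(n_subpops),
              fst_like_divergence = fst_like_divergence,
              geno_missing_rate = geno_missing_rate)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (!all(STAGES %in% names(cfg$n_per_stage))) {
    stop_user("n_per_stage must be named GS, Dys, GBC")
  }
  counts <- c(cfg$n_per_stage, cfg$n_transcripts, cfg$n_trend,
              cfg$n_individuals_eqtl, cfg$n_snps, cfg$n_cases, cfg$n_controls,
              cfg$n_subpops)
  if (any(counts <= 0)) stop_user("all counts in sim_config must be > 0")
  if (cfg$n_trend > cfg$n_transcripts) {
    stop_user("n_trend (", cfg$n_trend, ") exceeds n_transcripts (",
              cfg$n_transcripts, ")")
  }
  if (cfg$maf_range[1] <= 0 || cfg$maf_range[2] > 0.5 ||
      cfg$maf_range[1] > cfg$maf_range[2]) {
    stop_user("maf_range must lie within (0, 0.5]")
  }
  if (cfg$target_r2 <= 0 || cfg$target_r2 >= 1) {
    stop_user("target_r2 must lie in (0, 1)")
  }
  if (cfg$covar_r2 < 0 || cfg$covar_r2 > cfg$target_r2) {
    stop_user("covar_r2 must lie in [0, target_r2]")
  }
  if (cfg$nb_dispersion <= 0) stop_user("nb_dispersion must be positive")
  if (cfg$true_or_per_log2 <= 0) stop_user("true_or_per_log2 must be positive")
  if (cfg$fst_like_divergence < 0) stop_user("fst_like_divergence must be >= 0")
  invisible(cfg)
}

transcript_ids <- function(n) sprintf("lnc%05d", seq_len(n))

#' Generate staged tissue counts with planted monotone trends
#'
#' Negative-binomial counts for `n_transcripts` transcripts across the ordered
#' stages GS < Dys < GBC. The first `n_trend` transcripts carry a planted
#' log2-mean shift of `+/- trend_effect` per stage step (alternating
#' direction); all other expressed transcripts have stage-independent means,
#' and a `prop_silent` fraction is near-undetected. Library-size factors are
#' log-normal so TPM normalization is non-trivial.
#'
#' @param cfg a [sim_config()].
#' @return list with `counts` (count_matrix: counts, transcript lengths,
#'   ordered stage labels), `covars` (age/gender for the tissue patients) and
#'   `truth` (synthetic_truth record).
#' @export
gen_tissue_counts <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  n_stage <- cfg$n_per_stage[STAGES]
  N <- sum(n_stage)
  stage <- factor(rep(STAGES, times = n_stage), levels = STAGES, ordered = TRUE)
  Tn <- cfg$n_transcripts
  n_silent <- round(cfg$prop_silent * Tn)
  n_inform <- Tn - n_silent
  if (cfg$n_trend > n_inform) {
    stop_user("n_trend exceeds the number of expressed transcripts (",
              n_inform, "); lower prop_silent or n_trend")
  }
  ids <- transcript_ids(Tn)
  step <- as.integer(stage) - 1L            # 0, 1, 2

  base_log2 <- runif(n_inform, 3, 9)        # log2 expected count, expressed set
  dir <- rep(c(1, -1), length.out = cfg$n_trend)
  log2mu <- matrix(rep(base_log2, N), n_inform, N)
  if (cfg$n_trend > 0) {
    trend_shift <- outer(dir * cfg$trend_effect, step)
    log2mu[seq_len(cfg$n_trend), ] <- log2mu[seq_len(cfg$n_trend), ] + trend_shift
  }
  mu <- rbind(2^log2mu,
              matrix(0.05, n_silent, N))
  libfac <- exp(rnorm(N, 0, 0.3))           # log-normal library-size factors
  mu <- sweep(mu, 2, libfac, "*")
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion),
                   nrow = Tn, ncol = N,
                   dimnames = list(ids, sprintf("tissue%03d", seq_len(N))))
  lengths <- sample(200:3000, Tn, replace = TRUE)
  names(lengths) <- ids

  covars <- data.frame(sample_id = colnames(counts),
                       age = round(rnorm(N, 58, 11)),
                       gender = rbinom(N, 1, 0.15))  # 1 = male; mostly women

  truth <- list(trend_transcript_ids = ids[seq_len(cfg$n_trend)],
                trend_direction = setNames(ifelse(dir > 0, "increasing",
                                                  "decreasing"),
                                           ids[seq_len(cfg$n_trend)]),
                eqtl_map = NULL,
                true_or = cfg$true_or_per_log2)
  class(truth) <- "synthetic_truth"

  list(counts = count_matrix(counts, lengths, stage),
       covars = covars, truth = truth)
}

#' Generate structured genotypes
#'
#' Biallelic SNP dosages under Hardy–Weinberg sampling within discrete
#' subpopulations whose allele frequencies diverge from a common ancestral
#' frequency by a Balding–Nichols beta perturbation with parameter
#' `fst_like_divergence`, giving genetic PCA a real axis to find.
#'
#' @param cfg a [sim_config()].
#' @param n number of individuals (default `cfg$n_individuals_eqtl`).
#' @param seed seed for this panel; defaults to `cfg$seed + 1`. Generate the
#'   association panel with a different seed.
#' @param prefix sample-id prefix.
#' @return a [genotype_matrix()] with a `subpop` attribute.
#' @export
gen_genotypes <- function(cfg, n = cfg$n_individuals_eqtl,
                          seed = cfg$seed + 1L, prefix = "ind") {
  validate_sim_config(cfg)
  m <- cfg$n_snps
  # the SNP panel (positions, ancestral and subpopulation frequencies) is a
  # property of the simulated population: fixed by cfg$seed so the eQTL and
  # association panels share coherent SNPs; only individuals vary with `seed`
  set.seed(cfg$seed + 1L)
  p0 <- runif(m, cfg$maf_range[1], cfg$maf_range[2])
  pos <- sort(sample.int(2e8, m))
  Fd <- cfg$fst_like_divergence
  pk <- matrix(p0, cfg$n_subpops, m, byrow = TRUE)
  if (Fd > 0 && cfg$n_subpops > 1L) {
    a <- p0 * (1 - Fd) / Fd
    b <- (1 - p0) * (1 - Fd) / Fd
    for (k in seq_len(cfg$n_subpops)) {
      pk[k, ] <- rbeta(m, a, b)
    }
  }
  set.seed(seed)
  subpop <- rep(seq_len(cfg$n_subpops), length.out = n)
  dos <- matrix(rbinom(n * m, 2L, pk[subpop, ]), n, m)
  if (cfg$geno_missing_rate > 0) {
    dos[runif(n * m) < cfg$geno_missing_rate] <- NA_integer_
  }
  rownames(dos) <- sprintf("%s%04d", prefix, seq_len(n))
  snps <- data.frame(snp_id = sprintf("snp%05d", seq_len(m)),
                     chrom = "1",
                     pos = pos,
                     ref = "A", alt = "G",
                     stringsAsFactors = FALSE)
  colnames(dos) <- snps$snp_id
  g <- genotype_matrix(dos, snps)
  attr(g, "subpop") <- subpop
  g
}

# Planted eQTL architecture for the trend transcripts: models cycle
# additive, dominant (the validated LINC00662 pattern); betas alternate sign.
plant_eqtls <- function(truth, geno, cfg) {
  set.seed(cfg$seed + 2L)
  models <- c("additive", "dominant")
  ids <- truth$trend_transcript_ids
  free <- geno$snps$snp_id
  eqtl_map <- list()
  for (t in ids) {
    k <- cfg$n_true_eqtls_per_transcript
    pick <- sample(free, k)
    free <- setdiff(free, pick)
    eqtl_map[[t]] <- data.frame(
      snp_id = pick,
      model = rep(models, length.out = k),
      beta = cfg$eqtl_beta * rep(c(1, -1), length.out = k),
      stringsAsFactors = FALSE)
  }
  truth$eqtl_map <- eqtl_map
  truth
}

#' Generate covariates (age, gender)
#' @param n number of individuals
#' @param sample_ids sample identifiers
#' @param seed seed
#' @return data.frame(sample_id, age, gender); gender 1 = male.
#' @export
gen_covariates <- function(n, sample_ids = sprintf("ind%04d", seq_len(n)),
                           seed = 1L) {
  set.seed(seed)
  data.frame(sample_id = sample_ids,
             age = round(rnorm(n, 55, 12)),
             gender = rbinom(n, 1, 0.35))
}

#' Generate serum log2 expression from planted eQTLs
#'
#' Expression = sum of planted SNP terms + age/gender effects + Gaussian
#' noise, with the noise variance chosen so that, in expectation, the full
#' systematic part (SNPs + covariates) explains `target_r2` of total variance
#' and the covariate part alone explains `covar_r2` (so the SNP increment is
#' `target_r2 - covar_r2`).
#'
#' @param geno [genotype_matrix()] of the eQTL-set individuals.
#' @param truth `synthetic_truth` with a populated `eqtl_map`.
#' @param covars data.frame(sample_id, age, gender); generated if `NULL`.
#' @param cfg a [sim_config()].
#' @param seed seed (default `cfg$seed + 3`).
#' @return list(expr = transcripts x samples log2 matrix, covars).
#' @export
gen_serum_expression <- function(geno, truth, covars = NULL, cfg,
                                 seed = cfg$seed + 3L) {
  validate_sim_config(cfg)
  if (is.null(truth$eqtl_map)) stop_user("truth carries no eqtl_map")
  set.seed(seed)
  ids <- rownames(geno$dosage)
  n <- length(ids)
  if (is.null(covars)) covars <- gen_covariates(n, ids, seed = seed + 1L)
  idx <- match(ids, covars$sample_id)
  age <- covars$age[idx]; gender <- covars$gender[idx]

  f_snp <- cfg$target_r2 - cfg$covar_r2
  f_cov <- cfg$covar_r2
  f_err <- 1 - cfg$target_r2

  transcripts <- names(truth$eqtl_map)
  expr <- matrix(NA_real_, length(transcripts), n,
                 dimnames = list(transcripts, ids))
  for (t in transcripts) {
    em <- truth$eqtl_map[[t]]
    S <- numeric(n)
    miss <- rep(FALSE, n)
    for (i in seq_len(nrow(em))) {
      if (!em$snp_id[i] %in% colnames(geno$dosage)) {
        stop_user("eqtl_map SNP ", em$snp_id[i], " absent from genotypes")
      }
      d <- geno$dosage[, em$snp_id[i]]
      miss <- miss | is.na(d)
      d[is.na(d)] <- round(mean(d, na.rm = TRUE))  # keep generator total
      enc <- encode_penetrance(d, em$model[i])
      S <- S + as.vector(enc %*% rep(em$beta[i], ncol(enc)))
    }
    vS <- var(S)
    C_raw <- 0.02 * (age - mean(age)) - 0.4 * (gender - mean(gender))
    if (vS > 1e-12) {
      unit <- vS / f_snp
      if (f_snp <= 0) {
        stop_user("target_r2 <= covar_r2 with nonzero planted betas; ",
                  "no noise scaling satisfies both")
      }
    } else {
      if (f_snp > 1e-8) {
        stop_user("target_r2 exceeds covar_r2 but all planted betas are ",
                  "zero: target_r2 unreachable")
      }
      unit <- 1
    }
    v_cov <- f_cov * unit
    v_err <- f_err * unit
    C <- if (var(C_raw) > 0 && v_cov > 0) {
      C_raw * sqrt(v_cov / var(C_raw))
    } else numeric(n)
    baseline <- runif(1, 1, 7)
    expr[t, ] <- baseline + S + C + rnorm(n, 0, sqrt(v_err))
  }
  list(expr = expr, covars = covars)
}

#' Generate case-control status from imputed expression
#'
#' Disease status is Bernoulli with logit `alpha + log(true_or) * predicted
#' expression + age/gender effects`; `alpha` is calibrated by root-finding so
#' the expected number of cases equals `n_cases`.
#'
#' @param geno association-set [genotype_matrix()].
#' @param eqtl_model an `eqtl_model` (see [select_prediction_model()]) or a
#'   plain list with `snps` rows (snp_id, model, beta).
#' @param covars data.frame(sample_id, age, gender); generated if `NULL`.
#' @param cfg a [sim_config()].
#' @param seed seed (default `cfg$seed + 4`).
#' @return list(status named 0/1 vector, covars, predicted).
#' @export
gen_case_control <- function(geno, eqtl_model, covars = NULL, cfg,
                             seed = cfg$seed + 4L) {
  validate_sim_config(cfg)
  set.seed(seed)
  ids <- rownames(geno$dosage)
  n <- length(ids)
  if (is.null(covars)) covars <- gen_covariates(n, ids, seed = seed + 1L)
  pred <- predict_expression(geno, eqtl_model)
  pv <- pred$predicted
  pv[is.na(pv)] <- mean(pv, na.rm = TRUE)
  idx <- match(ids, covars$sample_id)
  lp0 <- log(cfg$true_or_per_log2) * pv +
    0.02 * (covars$age[idx] - mean(covars$age[idx])) -
    0.3 * (covars$gender[idx] - mean(covars$gender[idx]))
  target <- cfg$n_cases / (cfg$n_cases + cfg$n_controls)
  alpha <- uniroot(function(a) mean(plogis(a + lp0)) - target,
                   c(-30, 30))$root
  status <- rbinom(n, 1L, plogis(alpha + lp0))
  names(status) <- ids
  list(status = status, covars = covars, predicted = pred)
}

#' Generate the candidate cis-eQTL table
#'
#' All true (transcript, SNP) pairs from the planted truth plus `n_decoys`
#' null SNPs per transcript, in shuffled row order — emulating the database
#' lookup that seeds the validation stage.
#'
#' @param truth `synthetic_truth` with populated `eqtl_map`.
#' @param geno [genotype_matrix()] supplying decoy SNPs.
#' @param n_decoys decoy SNPs per transcript.
#' @param seed seed.
#' @return data.frame(transcript_id, snp_id).
#' @export
gen_candidate_table <- function(truth, geno, n_decoys = 5L, seed = 1L) {
  if (is.null(truth$eqtl_map)) stop_user("truth carries no eqtl_map")
  set.seed(seed)
  true_snps <- unlist(lapply(truth$eqtl_map, `[[`, "snp_id"), use.names = FALSE)
  rows <- lapply(names(truth$eqtl_map), function(t) {
    em <- truth$eqtl_map[[t]]
    decoy_pool <- setdiff(geno$snps$snp_id, true_snps)
    if (n_decoys > length(decoy_pool)) {
      stop_user("not enough non-eQTL SNPs for ", n_decoys, " decoys")
    }
    decoys <- if (n_decoys > 0) sample(decoy_pool, n_decoys) else character(0)
    data.frame(transcript_id = t, snp_id = c(em$snp_id, decoys),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[sample.int(nrow(out)), , drop = FALSE]
}

#' Simulate all three datasets at once
#'
#' Convenience wrapper: tissue counts (stage 1), eQTL-set genotypes + serum
#' expression (stage 2), association-set genotypes + status (stage 3), a
#' candidate-eQTL table, and the ground-truth record.
#'
#' @param cfg a [sim_config()].
#' @param n_decoys decoy candidate SNPs per transcript.
#' @return named list of all generated pieces.
#' @export
simulate_study <- function(cfg, n_decoys = 5L) {
  tissue <- gen_tissue_counts(cfg)
  geno_eqtl <- gen_genotypes(cfg, n = cfg$n_individuals_eqtl,
                             seed = cfg$seed + 1L, prefix = "eqtl")
  truth <- plant_eqtls(tissue$truth, geno_eqtl, cfg)
  serum <- gen_serum_expression(geno_eqtl, truth, covars = NULL, cfg)
  candidates <- gen_candidate_table(truth, geno_eqtl, n_decoys = n_decoys,
                                    seed = cfg$seed + 5L)
  n_assoc <- cfg$n_cases + cfg$n_controls
  geno_assoc <- gen_genotypes(cfg, n = n_assoc, seed = cfg$seed + 6L,
                              prefix = "assoc")
  true_model <- truth_as_model(truth, transcript = names(truth$eqtl_map)[1])
  cc <- gen_case_control(geno_assoc, true_model, covars = NULL, cfg)
  list(tissue = tissue$counts, tissue_covars = tissue$covars,
       geno_eqtl = geno_eqtl, serum = serum$expr, serum_covars = serum$covars,
       candidates = candidates, geno_assoc = geno_assoc,
       status = cc$status, assoc_covars = cc$covars, truth = truth)
}

# Wrap one transcript's planted eQTLs as a prediction model usable by
# predict_expression() (effect allele = ALT, the generator's convention).
truth_as_model <- function(truth, transcript) {
  em <- truth$eqtl_map[[transcript]]
  if (is.null(em)) stop_user("no planted eQTLs for ", transcript)
  structure(list(transcript_id = transcript,
                 snps = lapply(seq_len(nrow(em)), function(i) {
                   list(snp_id = em$snp_id[i], model = em$model[i],
                        beta = em$beta[i], effect_is_alt = TRUE)
                 })),
            class = "eqtl_model")
}
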