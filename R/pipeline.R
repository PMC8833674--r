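# End-to-end pipeline: simulate -> prep -> preselect -> genoqc -> eqtl ->
# associate, with per-stage caching keyed on input hashes + parameters and a
# reproducibility manifest mirroring the study's funnel counts.

default_pipeline_config <- function() {
  list(out_dir = "geno2lnc_run",
       seed = 1L,
       sim = list(),                        # sim_config() overrides
       n_decoys = 5L,
       pseudocount = 1,
       depth_frac = 0.05,
       k_pcs = 10L,
       n_perm = 5000L,
       fdr_max = 0.05,
       grid_size = 10L,
       cv_folds = 5L,
       maf_min = 0.01,
       snp_callrate_min = 0.95,
       sample_callrate_min = 0.95,
       ibd_threshold = 0.1,
       ld_r2_max = 0.1,
       ld_window = 50L,
       ld_step = 5L,
       n_pcs = 10L,
       eqtl_alpha = 0.05,
       effect_allele = "major",
       huber_c_linear = 1.345,
       huber_c_logistic = 1.2)
}

#' Load a pipeline configuration
#'
#' @param config a named list of overrides, or the path of a JSON file with
#'   the same structure. Unknown keys are an error.
#' @return the merged configuration list.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_user("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  base <- default_pipeline_config()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown)) {
    stop_user("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  base[names(config)] <- config
  base$seed <- as.integer(base$seed)
  base
}

stage_hash <- function(params, input_files = character(0)) {
  file_md5 <- if (length(input_files)) unname(tools::md5sum(input_files)) else character(0)
  digest_input <- paste(jsonlite::toJSON(params, auto_unbox = TRUE,
                                         digits = NA),
                        paste(file_md5, collapse = ""), sep = "|")
  tf <- tempfile(); writeLines(digest_input, tf)
  on.exit(unlink(tf))
  unname(tools::md5sum(tf))
}

manifest_path <- function(out_dir) file.path(out_dir, "manifest.json")

read_manifest <- function(out_dir) {
  p <- manifest_path(out_dir)
  if (file.exists(p)) jsonlite::read_json(p, simplifyVector = TRUE) else list()
}

write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, manifest_path(out_dir), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

# Run `fun` unless the stored stage hash matches and all outputs exist.
run_stage <- function(name, manifest, out_dir, params, inputs, outputs, fun) {
  h <- stage_hash(params, inputs)
  cached <- !is.null(manifest[[name]]) &&
    identical(manifest[[name]]$hash, h) &&
    all(file.exists(file.path(out_dir, outputs)))
  if (cached) {
    message("[", name, "] cached, skipping")
    return(manifest)
  }
  message("[", name, "] running")
  funnel <- fun()
  manifest[[name]] <- list(hash = h, params = params,
                           inputs = as.list(tools::md5sum(inputs)),
                           outputs = outputs, funnel = funnel)
  write_manifest(manifest, out_dir)
  manifest
}

#' Run the full three-stage pipeline
#'
#' Executes simulate (optional) -> prep -> preselect -> genoqc -> eqtl ->
#' associate, writing versioned TSV/JSON outputs and a manifest with input
#' hashes, parameters, the seed, and the per-stage funnel counts. A stage is
#' skipped when its inputs, parameters and outputs are unchanged; deleting an
#' intermediate re-runs only the stages that depend on it.
#'
#' @param config see [pipeline_config()].
#' @param simulate if `TRUE` (default) stage inputs are generated by the
#'   synthetic-data module into `out_dir/sim/`.
#' @return the manifest (invisibly readable at `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config = list(), simulate = TRUE) {
  cfg <- pipeline_config(config)
  out_dir <- cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (d in c("sim", "prep", "preselect", "genoqc", "eqtl", "associate")) {
    dir.create(file.path(out_dir, d), showWarnings = FALSE)
  }
  manifest <- read_manifest(out_dir)
  manifest$config <- cfg
  scfg <- do.call(sim_config, c(list(seed = cfg$seed), cfg$sim))

  sim_files <- file.path("sim", c("counts.tsv", "lengths.tsv", "stages.tsv",
                                  "tissue_covars.tsv", "eqtl.vcf",
                                  "serum.tsv", "serum_covars.tsv",
                                  "candidates.tsv", "assoc.vcf",
                                  "assoc_covars.tsv", "status.tsv",
                                  "truth.json"))
  if (simulate) {
    manifest <- run_stage("simulate", manifest, out_dir,
                          params = unclass(scfg), inputs = character(0),
                          outputs = sim_files, fun = function() {
      sim <- simulate_study(scfg, n_decoys = cfg$n_decoys)
      sd <- file.path(out_dir, "sim")
      write_matrix_tsv(sim$tissue$counts, file.path(sd, "counts.tsv"))
      write_tsv(data.frame(transcript_id = names(sim$tissue$lengths),
                           length = sim$tissue$lengths),
                file.path(sd, "lengths.tsv"))
      write_tsv(data.frame(sample_id = colnames(sim$tissue$counts),
                           stage = as.character(sim$tissue$stage)),
                file.path(sd, "stages.tsv"))
      write_tsv(sim$tissue_covars, file.path(sd, "tissue_covars.tsv"))
      write_vcf(sim$geno_eqtl, file.path(sd, "eqtl.vcf"))
      write_matrix_tsv(sim$serum, file.path(sd, "serum.tsv"))
      write_tsv(sim$serum_covars, file.path(sd, "serum_covars.tsv"))
      write_tsv(sim$candidates, file.path(sd, "candidates.tsv"))
      write_vcf(sim$geno_assoc, file.path(sd, "assoc.vcf"))
      write_tsv(sim$assoc_covars, file.path(sd, "assoc_covars.tsv"))
      write_tsv(data.frame(sample_id = names(sim$status),
                           status = sim$status),
                file.path(sd, "status.tsv"))
      jsonlite::write_json(
        list(trend_transcript_ids = sim$truth$trend_transcript_ids,
             trend_direction = as.list(sim$truth$trend_direction),
             eqtl_map = sim$truth$eqtl_map,
             true_or = sim$truth$true_or),
        file.path(sd, "truth.json"), auto_unbox = TRUE, digits = NA)
      list(n_transcripts = nrow(sim$tissue$counts),
           n_tissue_samples = ncol(sim$tissue$counts),
           n_eqtl_individuals = nrow(sim$geno_eqtl$dosage),
           n_assoc_individuals = nrow(sim$geno_assoc$dosage),
           n_cases = sum(sim$status == 1))
    })
  }

  sd <- file.path(out_dir, "sim")
  # ---- prep ----------------------------------------------------------------
  prep_in <- file.path(sd, c("counts.tsv", "lengths.tsv", "stages.tsv"))
  prep_out <- file.path("prep", c("normalized.tsv", "exclusions.tsv"))
  prep_params <- cfg[c("pseudocount", "depth_frac", "k_pcs")]
  manifest <- run_stage("prep", manifest, out_dir, prep_params, prep_in,
                        prep_out, fun = function() {
    counts_m <- read_matrix_tsv(file.path(sd, "counts.tsv"))
    lengths <- read_tsv(file.path(sd, "lengths.tsv"))
    stages <- read_tsv(file.path(sd, "stages.tsv"))
    cm <- count_matrix(counts_m, setNames(lengths$length,
                                          lengths$transcript_id),
                       factor(stages$stage, levels = STAGES, ordered = TRUE))
    expr <- counts_to_log2tpm(cm, pseudocount = cfg$pseudocount)
    mf <- mad_filter(expr)
    qn <- quantile_normalize_two_pass(mf$expr)
    dx <- pca_depth_exclude(qn, frac = cfg$depth_frac,
                            k_pcs = min(cfg$k_pcs,
                                        ncol(qn$values) - 1L))
    write_matrix_tsv(dx$expr$values, file.path(out_dir, "prep",
                                               "normalized.tsv"))
    write_tsv(data.frame(
      kind = c(rep("transcript_mad0", length(mf$excluded)),
               rep("sample_depth", length(dx$excluded))),
      id = c(mf$excluded, dx$excluded)),
      file.path(out_dir, "prep", "exclusions.tsv"))
    list(n_detected = nrow(expr$values),
         n_mad_zero = length(mf$excluded),
         n_after_mad = nrow(mf$expr$values),
         n_samples_in = ncol(expr$values),
         n_samples_excluded = length(dx$excluded),
         n_samples_kept = length(dx$kept))
  })

  # ---- preselect -----------------------------------------------------------
  presel_in <- c(file.path(out_dir, "prep", "normalized.tsv"),
                 file.path(sd, c("stages.tsv", "serum.tsv",
                                 "candidates.tsv")))
  presel_out <- file.path("preselect", c("trend.tsv", "importance.tsv",
                                         "criteria.tsv", "selected.tsv"))
  presel_params <- cfg[c("n_perm", "fdr_max", "grid_size", "cv_folds", "seed")]
  manifest <- run_stage("preselect", manifest, out_dir, presel_params,
                        presel_in, presel_out, fun = function() {
    m <- read_matrix_tsv(file.path(out_dir, "prep", "normalized.tsv"))
    stages <- read_tsv(file.path(sd, "stages.tsv"))
    stage <- factor(stages$stage[match(colnames(m), stages$sample_id)],
                    levels = STAGES, ordered = TRUE)
    trend <- jt_permutation_test(m, stage, n_perm = cfg$n_perm,
                                 seed = cfg$seed)
    clf <- train_stage_classifier(m, stage, cv_folds = cfg$cv_folds,
                                  grid_size = cfg$grid_size, seed = cfg$seed)
    serum <- read_matrix_tsv(file.path(sd, "serum.tsv"))
    cand <- read_tsv(file.path(sd, "candidates.tsv"))
    sel <- select_candidates(trend, clf, serum, cand, fdr_max = cfg$fdr_max)
    pd <- file.path(out_dir, "preselect")
    write_tsv(trend, file.path(pd, "trend.tsv"))
    write_tsv(clf$importance, file.path(pd, "importance.tsv"))
    write_tsv(data.frame(transcript_id = rownames(sel$criteria),
                         sel$criteria), file.path(pd, "criteria.tsv"))
    write_tsv(data.frame(transcript_id = sel$selected),
              file.path(pd, "selected.tsv"))
    list(n_tested = nrow(trend),
         n_jt_fdr = sum(trend$fdr < cfg$fdr_max),
         n_model_features = clf$n_selected,
         n_importance_above_median =
           sum(clf$importance$importance >
                 median(clf$importance$importance)),
         auc = clf$auc, mean_per_class_error = clf$mean_per_class_error,
         n_pass_all = length(sel$selected))
  })

  # ---- genoqc --------------------------------------------------------------
  qc_in <- file.path(sd, "eqtl.vcf")
  qc_out <- file.path("genoqc", c("kept_snps.tsv", "kept_samples.tsv",
                                  "kinship.tsv", "pcs.tsv", "report.tsv"))
  qc_params <- cfg[c("maf_min", "snp_callrate_min", "sample_callrate_min",
                     "ibd_threshold", "ld_r2_max", "ld_window", "ld_step",
                     "n_pcs", "depth_frac")]
  manifest <- run_stage("genoqc", manifest, out_dir, qc_params, qc_in,
                        qc_out, fun = function() {
    geno <- read_vcf(file.path(sd, "eqtl.vcf"))
    filt <- snp_sample_filter(geno, cfg$maf_min, cfg$snp_callrate_min,
                              cfg$sample_callrate_min)
    kin <- ibd_kinship(filt$geno)
    rel <- relatedness_prune(kin, filt$geno, threshold = cfg$ibd_threshold)
    g2 <- subset_geno(filt$geno, samples = rel$kept)
    pruned <- ld_prune(g2, r2_max = cfg$ld_r2_max, window = cfg$ld_window,
                       step = cfg$ld_step)
    g3 <- subset_geno(g2, snps = pruned)
    pcs <- genetic_pca(g3, k = min(cfg$n_pcs, nrow(g3$dosage) - 1L))
    dx <- depth_exclude_genetic(pcs, frac = cfg$depth_frac)
    qd <- file.path(out_dir, "genoqc")
    write_tsv(data.frame(snp_id = pruned), file.path(qd, "kept_snps.tsv"))
    write_tsv(data.frame(sample_id = dx$kept),
              file.path(qd, "kept_samples.tsv"))
    kin_dt <- data.frame(sample_i = rep(rownames(kin$coeff),
                                        times = ncol(kin$coeff)),
                         sample_j = rep(colnames(kin$coeff),
                                        each = nrow(kin$coeff)),
                         coeff = as.vector(kin$coeff))
    write_tsv(kin_dt[kin_dt$sample_i < kin_dt$sample_j, ],
              file.path(qd, "kinship.tsv"))
    write_tsv(data.frame(sample_id = rownames(pcs$scores), pcs$scores),
              file.path(qd, "pcs.tsv"))
    write_tsv(filt$report, file.path(qd, "report.tsv"))
    list(n_snps_in = ncol(geno$dosage),
         n_snps_after_filter = ncol(filt$geno$dosage),
         n_samples_lowcall = length(filt$dropped_samples),
         n_related_removed = length(rel$removed),
         n_snps_after_ld = length(pruned),
         n_depth_excluded = length(dx$excluded),
         n_final = length(dx$kept))
  })

  # ---- eqtl ----------------------------------------------------------------
  eqtl_in <- c(file.path(sd, c("serum.tsv", "serum_covars.tsv",
                               "candidates.tsv", "eqtl.vcf")),
               file.path(out_dir, "genoqc",
                         c("kept_samples.tsv", "pcs.tsv")),
               file.path(out_dir, "preselect", "selected.tsv"))
  eqtl_out <- file.path("eqtl", c("fits.tsv", "validated.tsv"))
  eqtl_params <- cfg[c("eqtl_alpha", "effect_allele", "huber_c_linear",
                       "n_pcs", "ld_r2_max")]
  manifest <- run_stage("eqtl", manifest, out_dir, eqtl_params, eqtl_in,
                        eqtl_out, fun = function() {
    serum <- read_matrix_tsv(file.path(sd, "serum.tsv"))
    covars <- read_tsv(file.path(sd, "serum_covars.tsv"))
    cand <- read_tsv(file.path(sd, "candidates.tsv"))
    selected <- read_tsv(file.path(out_dir, "preselect",
                                   "selected.tsv"))$transcript_id
    kept <- read_tsv(file.path(out_dir, "genoqc",
                               "kept_samples.tsv"))$sample_id
    pcs_df <- read_tsv(file.path(out_dir, "genoqc", "pcs.tsv"))
    pcs <- as.matrix(pcs_df[, -1]); rownames(pcs) <- pcs_df$sample_id
    geno <- read_vcf(file.path(sd, "eqtl.vcf"))
    geno <- subset_geno(geno, samples = intersect(kept,
                                                  rownames(geno$dosage)))
    cand <- cand[cand$transcript_id %in% selected, , drop = FALSE]
    val <- validate_candidates(serum, geno, covars, cand, pcs = pcs,
                               n_pcs = cfg$n_pcs, alpha = cfg$eqtl_alpha,
                               effect_allele = cfg$effect_allele,
                               r2_prune = cfg$ld_r2_max,
                               huber_c = cfg$huber_c_linear)
    models <- list()
    for (t_id in unique(val$validated$transcript_id)) {
      models[[t_id]] <- select_prediction_model(
        serum, val$validated, geno, covars, pcs = pcs, n_pcs = cfg$n_pcs,
        transcript = t_id, huber_c = cfg$huber_c_linear)
      write_eqtl_model(models[[t_id]],
                       file.path(out_dir, "eqtl",
                                 paste0("model_", t_id, ".json")))
    }
    ed <- file.path(out_dir, "eqtl")
    write_tsv(val$fits, file.path(ed, "fits.tsv"))
    write_tsv(val$validated, file.path(ed, "validated.tsv"))
    list(n_candidate_pairs = nrow(cand),
         n_untestable = nrow(val$untestable),
         n_validated = nrow(val$validated),
         transcripts_with_model = names(models),
         adj_r2 = lapply(models, `[[`, "adj_r2_full"))
  })

  # ---- associate -----------------------------------------------------------
  model_files <- list.files(file.path(out_dir, "eqtl"),
                            pattern = "^model_.*\\.json$", full.names = TRUE)
  assoc_in <- c(file.path(sd, c("assoc.vcf", "assoc_covars.tsv",
                                "status.tsv")), model_files)
  assoc_out <- file.path("associate", "association.tsv")
  assoc_params <- cfg[c("huber_c_logistic", "n_pcs", "maf_min",
                        "snp_callrate_min", "sample_callrate_min")]
  manifest <- run_stage("associate", manifest, out_dir, assoc_params,
                        assoc_in, assoc_out, fun = function() {
    geno <- read_vcf(file.path(sd, "assoc.vcf"))
    covars <- read_tsv(file.path(sd, "assoc_covars.tsv"))
    status_df <- read_tsv(file.path(sd, "status.tsv"))
    status <- setNames(status_df$status, status_df$sample_id)
    pcs <- genetic_pca(geno, k = cfg$n_pcs)$scores
    results <- list(); preds <- list()
    for (mf in model_files) {
      model <- read_eqtl_model(mf)
      pred <- predict_expression(geno, model)
      attr(pred, "transcript_id") <- model$transcript_id
      res <- tryCatch(associate(pred, status, covars, pcs = pcs,
                                n_pcs = cfg$n_pcs,
                                huber_c = cfg$huber_c_logistic),
                      gl_user_error = function(e) NULL)
      if (!is.null(res)) {
        results[[model$transcript_id]] <- res
        preds[[model$transcript_id]] <- pred
      }
    }
    tab3 <- report_association_table(results, preds)
    write_tsv(tab3, file.path(out_dir, "associate", "association.tsv"))
    list(n_models = length(model_files),
         n_tested = length(results),
         or = setNames(lapply(results, `[[`, "or"), names(results)))
  })

  manifest <- read_manifest(out_dir)
  invisible(manifest)
}
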