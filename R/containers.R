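# Lightweight S3 containers: count matrix, log2-expression matrix, genotype
# matrix, plus plain-text (TSV / VCF) readers and writers.

#' Count matrix container
#'
#' @param counts non-negative integer matrix, transcripts x samples.
#' @param lengths named positive transcript lengths in bp.
#' @param stage ordered factor of stage labels (GS < Dys < GBC), one per
#'   sample; may be `NULL` for unstaged data.
#' @return a `count_matrix` object.
#' @export
count_matrix <- function(counts, lengths, stage = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop_user("counts must be non-negative")
  if (is.null(rownames(counts))) stop_user("counts need transcript rownames")
  lengths <- lengths[rownames(counts)]
  if (anyNA(lengths) || any(lengths <= 0)) {
    stop_user("positive lengths required for all transcripts")
  }
  if (!is.null(stage)) {
    if (length(stage) != ncol(counts)) {
      stop_user("one stage label per sample required")
    }
    stage <- as.ordered(stage)
  }
  structure(list(counts = counts, lengths = lengths, stage = stage),
            class = "count_matrix")
}

#' Log2 expression matrix container
#'
#' Carries per-transcript (unscaled) MADs and a normalization-state flag that
#' only moves forward: `raw-log2` -> `group-QN` -> `global-QN`.
#'
#' @param values numeric matrix, transcripts x samples (log2 scale).
#' @param stage ordered stage factor or `NULL`.
#' @param norm_state one of `"raw-log2"`, `"group-QN"`, `"global-QN"`.
#' @return an `expression_matrix` object.
#' @export
expression_matrix <- function(values, stage = NULL,
                              norm_state = "raw-log2") {
  values <- as.matrix(values)
  norm_state <- match.arg(norm_state, c("raw-log2", "group-QN", "global-QN"))
  if (!is.null(stage)) {
    if (length(stage) != ncol(values)) stop_user("one stage label per sample")
    stage <- as.ordered(stage)
  }
  structure(list(values = values, stage = stage, norm_state = norm_state,
                 mads = row_mads(values)),
            class = "expression_matrix")
}

expr_values <- function(x) {
  if (inherits(x, "expression_matrix")) x$values else as.matrix(x)
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$values), "transcripts x",
      ncol(x$values), "samples;", x$norm_state, "\n")
  invisible(x)
}

#' Genotype matrix container
#'
#' Effect-allele (ALT) dosages in \{0, 1, 2, NA\}, samples x SNPs, with SNP
#' metadata and on-construction MAF / call-rate summaries.
#'
#' @param dosage integer matrix samples x SNPs, values 0/1/2/NA.
#' @param snps data.frame(snp_id, chrom, pos, ref, alt).
#' @return a `genotype_matrix` object.
#' @export
genotype_matrix <- function(dosage, snps) {
  dosage <- as.matrix(dosage)
  if (!all(dosage %in% c(0L, 1L, 2L, NA))) {
    stop_user("dosages must be 0, 1, 2 or NA")
  }
  if (is.null(rownames(dosage))) stop_user("dosage needs sample rownames")
  snps <- as.data.frame(snps)
  if (nrow(snps) != ncol(dosage)) stop_user("one snps row per dosage column")
  colnames(dosage) <- snps$snp_id
  g <- structure(list(dosage = dosage, snps = snps), class = "genotype_matrix")
  refresh_geno_meta(g)
}

refresh_geno_meta <- function(g) {
  d <- g$dosage
  p_alt <- colMeans(d, na.rm = TRUE) / 2
  g$maf <- pmin(p_alt, 1 - p_alt)
  g$maf[is.nan(g$maf)] <- NA_real_
  g$snp_callrate <- colMeans(!is.na(d))
  g$sample_callrate <- rowMeans(!is.na(d))
  g
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosage), "samples x", ncol(x$dosage),
      "SNPs\n")
  invisible(x)
}

subset_geno <- function(g, samples = rownames(g$dosage),
                        snps = colnames(g$dosage)) {
  keep_s <- match(samples, rownames(g$dosage))
  keep_m <- match(snps, colnames(g$dosage))
  if (anyNA(keep_s) || anyNA(keep_m)) stop_user("unknown sample or SNP ids")
  g$dosage <- g$dosage[keep_s, keep_m, drop = FALSE]
  g$snps <- g$snps[keep_m, , drop = FALSE]
  refresh_geno_meta(g)
}

#' Write genotypes as VCF v4.2 (GT only)
#'
#' @param geno a [genotype_matrix()].
#' @param path output path (plain text `.vcf`).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, path) {
  gt <- c("0/0", "0/1", "1/1")
  d <- t(geno$dosage)                       # SNPs x samples
  body <- matrix("./.", nrow(d), ncol(d))
  ok <- !is.na(d)
  body[ok] <- gt[d[ok] + 1L]
  header <- c("##fileformat=VCFv4.2",
              "##source=geno2lnc",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(geno$dosage)),
                    collapse = "\t"))
  lines <- paste(geno$snps$chrom, geno$snps$pos, geno$snps$snp_id,
                 geno$snps$ref, geno$snps$alt, ".", ".", ".", "GT",
                 apply(body, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read a GT-only VCF into a genotype matrix
#'
#' Minimal reader for biallelic hard-genotype VCFs as written by
#' [write_vcf()]; any diploid GT separator (`/` or `|`) is accepted and the
#' ALT allele count becomes the dosage.
#'
#' @param path VCF path.
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) stop_user("no #CHROM header line in ", path)
  cols <- strsplit(lines[hdr[1]], "\t")[[1]]
  samples <- cols[-(1:9)]
  body <- strsplit(lines[(hdr[1] + 1):length(lines)], "\t")
  body <- body[lengths(body) == length(cols)]
  mat <- do.call(rbind, body)
  snps <- data.frame(snp_id = mat[, 3], chrom = mat[, 1],
                     pos = as.integer(mat[, 2]), ref = mat[, 4],
                     alt = mat[, 5], stringsAsFactors = FALSE)
  gt <- mat[, -(1:9), drop = FALSE]
  gt <- sub(":.*$", "", gt)                 # GT is the first FORMAT field
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt))
  dos[gt %in% c("0/0", "0|0")] <- 0L
  dos[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  dos[gt %in% c("1/1", "1|1")] <- 2L
  dimnames(dos) <- list(snps$snp_id, samples)
  genotype_matrix(t(dos), snps)
}

#' Write / read a transcripts-x-samples matrix as TSV
#'
#' First column `transcript_id`, remaining columns one per sample.
#' @param m numeric matrix with dimnames.
#' @param path file path.
#' @return path / matrix.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(transcript_id = rownames(m), m, check.names = FALSE)
  write_tsv(df, path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
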