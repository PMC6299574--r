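#' Methylation data container
#'
#' Bundles a samples-by-CpGs matrix of beta values (methylated fraction in
#' \[0, 1\]) with optional per-probe detection p-values. Statistics in this
#' package are run on the M scale (the base-2 logit of beta, see
#' [beta_to_m()]); beta is the storage and reporting scale.
#'
#' @param beta Numeric matrix, samples in rows, CpGs in columns. Row and
#'   column names are used as sample and CpG ids when the id arguments are
#'   missing.
#' @param cpg_ids,sample_ids Character vectors of unique ids.
#' @param detection_p Optional matrix of detection p-values with the same
#'   dimensions as `beta`.
#' @return An object of class `methylation_matrix`.
#' @examples
#' b <- matrix(runif(12, 0.2, 0.8), 3, 4,
#'             dimnames = list(paste0("s", 1:3), paste0("cg", 1:4)))
#' meth <- methylation_matrix(b)
#' dim(m_values(meth))
#' @export
methylation_matrix <- function(beta, cpg_ids = colnames(beta),
                               sample_ids = rownames(beta),
                               detection_p = NULL) {
  beta <- as.matrix(beta)
  if (is.null(cpg_ids)) cpg_ids <- paste0("cg", seq_len(ncol(beta)))
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(nrow(beta)))
  stopifnot(length(cpg_ids) == ncol(beta), length(sample_ids) == nrow(beta))
  if (anyDuplicated(cpg_ids) || anyDuplicated(sample_ids)) {
    abort("CpG and sample ids must be unique")
  }
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) {
    abort("beta values must lie in [0, 1]")
  }
  dimnames(beta) <- list(sample_ids, cpg_ids)
  if (!is.null(detection_p)) {
    detection_p <- as.matrix(detection_p)
    stopifnot(all(dim(detection_p) == dim(beta)))
    dimnames(detection_p) <- dimnames(beta)
  }
  structure(list(beta = beta, detection_p = detection_p),
            class = "methylation_matrix")
}

#' @export
print.methylation_matrix <- function(x, ...) {
  cat("<methylation_matrix> ", nrow(x$beta), " samples x ", ncol(x$beta),
      " CpGs", if (!is.null(x$detection_p)) " (with detection p)", "\n",
      sep = "")
  invisible(x)
}

#' @export
dim.methylation_matrix <- function(x) dim(x$beta)

#' Genotype data container
#'
#' Samples-by-SNPs additive dosages counting the derived allele (or the
#' alternate allele where the ancestral state is unknown), with per-SNP
#' metadata.
#'
#' @param dosage Numeric matrix of 0/1/2 dosages, samples in rows.
#' @param snps A data frame with one row per SNP: `snp_id`, `chr`, `pos`
#'   (1-based bp) and, optionally, `ancestral_known` (logical flag recording
#'   whether the dosage counts a true derived allele).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, snps) {
  dosage <- as.matrix(dosage)
  snps <- tibble::as_tibble(snps)
  stopifnot(all(c("snp_id", "chr", "pos") %in% names(snps)),
            nrow(snps) == ncol(dosage))
  if (anyDuplicated(snps$snp_id)) abort("SNP ids must be unique")
  if (!"ancestral_known" %in% names(snps)) snps$ancestral_known <- FALSE
  colnames(dosage) <- snps$snp_id
  structure(list(dosage = dosage, snps = snps), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", nrow(x$dosage), " samples x ", ncol(x$dosage),
      " SNPs\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Expression data container
#'
#' Samples-by-genes FPKM values for one condition, with gene annotation
#' (TSS anchor for cis windows; `is_tf` flags transcription-factor genes used
#' to restrict trans-meQTL candidate SNPs).
#'
#' @param fpkm Non-negative numeric matrix, samples in rows.
#' @param genes Data frame with `gene_id`, `chr`, `tss` and optional `is_tf`.
#' @param condition Condition label (e.g. `"NS"` or a stimulus name).
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(fpkm, genes, condition = "NS") {
  fpkm <- as.matrix(fpkm)
  if (any(fpkm < 0, na.rm = TRUE)) abort("FPKM values must be non-negative")
  genes <- tibble::as_tibble(genes)
  stopifnot(all(c("gene_id", "chr", "tss") %in% names(genes)),
            nrow(genes) == ncol(fpkm))
  if (!"is_tf" %in% names(genes)) genes$is_tf <- FALSE
  colnames(fpkm) <- genes$gene_id
  structure(list(fpkm = fpkm, genes = genes, condition = condition),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("<expression_matrix> [", x$condition, "] ", nrow(x$fpkm),
      " samples x ", ncol(x$fpkm), " genes\n", sep = "")
  invisible(x)
}

#' Log-scale expression view
#'
#' Returns `log2(1 + FPKM)`, the scale on which eQTL/eQTM associations are
#' tested; the +1 guard tames low-expression noise.
#'
#' @param expr An [expression_matrix()].
#' @return Numeric matrix, samples by genes.
#' @export
log_expression <- function(expr) {
  stopifnot(inherits(expr, "expression_matrix"))
  log2(1 + expr$fpkm)
}

#' Beta to M conversion
#'
#' M is the base-2 logit of the methylated fraction:
#' `M = log2(beta / (1 - beta))`. M values give better detection sensitivity
#' at extreme methylation levels, so all statistics here run on M; beta is
#' kept for effect-size reporting. Boundary values are clamped to
#' `[eps, 1 - eps]` before the logit so M stays finite.
#'
#' @param beta Numeric vector or matrix of methylated fractions in \[0, 1\].
#' @param eps Clamping margin for boundary values (default `1e-6`).
#' @param on_boundary `"clamp"` (warn and clamp, the default) or `"error"`.
#' @return M values, same shape as `beta`.
#' @examples
#' beta_to_m(0.5)  # 0
#' beta_to_m(0.8)  # 2
#' m_to_beta(beta_to_m(0.37))
#' @export
beta_to_m <- function(beta, eps = 1e-6, on_boundary = c("clamp", "error")) {
  on_boundary <- match.arg(on_boundary)
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) {
    abort("beta values must lie in [0, 1]")
  }
  hit <- beta <= 0 | beta >= 1
  if (any(hit, na.rm = TRUE)) {
    if (on_boundary == "error") abort("beta values of exactly 0 or 1")
    warn(paste0(sum(hit, na.rm = TRUE),
                " boundary beta value(s) clamped before logit"))
    beta <- pmin(pmax(beta, eps), 1 - eps)
  }
  log2(beta / (1 - beta))
}

#' @rdname beta_to_m
#' @param m M values (base-2 logit scale).
#' @export
m_to_beta <- function(m) {
  1 / (1 + 2^(-m))
}

#' M-value view of a methylation matrix
#'
#' @param meth A [methylation_matrix()].
#' @inheritParams beta_to_m
#' @return Numeric matrix of M values, samples by CpGs.
#' @export
m_values <- function(meth, eps = 1e-6) {
  stopifnot(inherits(meth, "methylation_matrix"))
  b <- pmin(pmax(meth$beta, eps), 1 - eps)
  log2(b / (1 - b))
}

#' Probe and sample quality-control filter
#'
#' Applies the standard EPIC-style QC sequence, in this fixed order:
#' \enumerate{
#'   \item drop probes carrying any exclusion flag (cross-hybridizing,
#'     sex-chromosome, SNP-overlapping);
#'   \item drop samples for which the fraction of probes with detection
#'     p above `detection_threshold` exceeds `sample_fail_fraction`;
#'   \item drop probes with detection p above `detection_threshold` in one
#'     or more of the remaining samples.
#' }
#' The order matters: a bad sample should not condemn otherwise clean probes.
#' Re-applying the filter to its own output is a no-op.
#'
#' @param meth A [methylation_matrix()] with `detection_p` present (required
#'   when the detection-based steps are to run).
#' @param annot CpG annotation tibble (see [simulate_cohort()]); must contain
#'   `cpg_id` and logical columns `cross_hybridizing`, `sex_chromosome`,
#'   `snp_overlap`. `NULL` skips step 1.
#' @param sample_fail_fraction Maximum tolerated fraction of failing probes
#'   per sample (default 0.05).
#' @param detection_threshold Detection p-value cutoff (default 1e-3).
#' @return A list with `meth` (the filtered [methylation_matrix()]) and
#'   `report`, a tibble counting probes/samples removed at each step.
#' @export
qc_filter <- function(meth, annot = NULL, sample_fail_fraction = 0.05,
                      detection_threshold = 1e-3) {
  stopifnot(inherits(meth, "methylation_matrix"))
  if (sample_fail_fraction <= 0 || sample_fail_fraction >= 1 ||
      detection_threshold <= 0 || detection_threshold >= 1) {
    abort("QC thresholds must lie in (0, 1)")
  }
  if (is.null(meth$detection_p)) {
    abort("qc_filter requires detection p-values")
  }
  beta <- meth$beta
  detp <- meth$detection_p

  # step 1: flagged probes
  n_flagged <- 0L
  if (!is.null(annot)) {
    annot <- tibble::as_tibble(annot)
    flags <- annot$cross_hybridizing | annot$sex_chromosome | annot$snp_overlap
    bad <- annot$cpg_id[which(flags)]
    keep <- !(colnames(beta) %in% bad)
    n_flagged <- sum(!keep)
    beta <- beta[, keep, drop = FALSE]
    detp <- detp[, keep, drop = FALSE]
  }

  # step 2: failing samples
  fail_frac <- rowMeans(detp > detection_threshold)
  keep_s <- fail_frac <= sample_fail_fraction
  n_samples_removed <- sum(!keep_s)
  if (!any(keep_s)) abort("all samples removed by QC")
  beta <- beta[keep_s, , drop = FALSE]
  detp <- detp[keep_s, , drop = FALSE]

  # step 3: probes failing in any remaining sample
  keep_p <- colSums(detp > detection_threshold) == 0L
  n_detect_removed <- sum(!keep_p)
  beta <- beta[, keep_p, drop = FALSE]
  detp <- detp[, keep_p, drop = FALSE]

  report <- tibble::tibble(
    step = c("flagged_probes", "failing_samples", "detection_probes"),
    removed = c(n_flagged, n_samples_removed, n_detect_removed)
  )
  list(meth = methylation_matrix(beta, detection_p = detp), report = report)
}

#' Down-sample one population to equalize group sizes
#'
#' Randomly removes samples from the larger population so both groups have
#' equal size (a seeded utility mirroring the practice of equalizing power
#' between cohorts).
#'
#' @param samples Sample table (tibble with `sample_id`, `population`).
#' @param seed Integer seed for the random draw.
#' @return The sample table restricted to the retained samples.
#' @export
downsample_populations <- function(samples, seed = 1L) {
  samples <- tibble::as_tibble(samples)
  tab <- table(samples$population)
  n_target <- min(tab)
  set.seed(seed)
  keep <- unlist(lapply(names(tab), function(p) {
    idx <- which(samples$population == p)
    sort(sample(idx, n_target))
  }))
  samples[sort(keep), ]
}

#' Read and write sample-by-feature TSV matrices
#'
#' Matrices are written with features in columns, samples in rows, a leading
#' `sample_id` column, and a `# orientation: samples_x_features` header
#' comment.
#'
#' @param x Numeric matrix with row and column names.
#' @param path Output file path.
#' @export
write_matrix_tsv <- function(x, path) {
  df <- tibble::as_tibble(x, rownames = "sample_id")
  writeLines("# orientation: samples_x_features", path)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write feature positions as BED
#'
#' Emits 0-based half-open intervals (the BED convention) from 1-based
#' positions held in memory.
#'
#' @param annot Tibble with `chr`, `pos` and an id column (`cpg_id`,
#'   `snp_id` or `gene_id`/`tss`).
#' @param path Output path.
#' @export
write_positions_bed <- function(annot, path) {
  annot <- tibble::as_tibble(annot)
  id_col <- intersect(c("cpg_id", "snp_id", "gene_id"), names(annot))[1]
  pos_col <- if ("pos" %in% names(annot)) "pos" else "tss"
  bed <- tibble::tibble(
    chrom = annot$chr,
    start = annot[[pos_col]] - 1L,
    end = annot[[pos_col]],
    name = annot[[id_col]]
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
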