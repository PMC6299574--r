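# cis/trans QTL and QTM mapping with dual-test significance, permutation
# FDR, and stepwise conditional fine-mapping.

#' Candidate p-value threshold grid
#'
#' The permutation-FDR threshold is selected from this grid of round
#' thresholds `{1, 5} x 10^-k`, k = 2..12.
#'
#' @return Sorted numeric vector of candidate thresholds.
#' @export
default_p_grid <- function() {
  sort(as.vector(outer(c(1, 5), 10^-(2:12))))
}

.scope_samples <- function(samples, scope) {
  samples <- tibble::as_tibble(samples)
  if (identical(scope, "joint")) return(seq_len(nrow(samples)))
  idx <- which(samples$population == scope)
  if (!length(idx)) abort(paste0("no samples in scope '", scope, "'"))
  idx
}

# Minor allele frequency from dosages.
.maf <- function(dosage) {
  f <- colMeans(dosage) / 2
  pmin(f, 1 - f)
}

#' Map cis associations between a feature matrix and genotypes
#'
#' For every feature (CpG methylation on the M scale, or log2 gene
#' expression), tests all SNPs within `window` bp of the feature anchor
#' (CpG position or gene TSS) with two tests: (a) an additive linear model
#' with covariates (covariate-residualized correlation, the same statistic
#' a matrix-eQTL engine computes) and (b) a Kruskal-Wallis rank test across
#' genotype classes on covariate-residualized values. Both p-values are
#' reported; downstream significance requires both to pass their
#' permutation-derived thresholds. In the joint scope an ancestry indicator
#' is added to the covariates; a population-label scope restricts to that
#' population's samples.
#'
#' SNPs below the minor-allele-frequency floor in the analyzed samples, or
#' with fewer than two genotype classes, are skipped.
#'
#' @param features Samples-by-features numeric matrix (column names are
#'   feature ids), e.g. [m_values()] output or [log_expression()].
#' @param feature_annot Tibble with `chr` and an anchor position for each
#'   feature: columns (`cpg_id`, `pos`) or (`gene_id`, `tss`).
#' @param geno A [genotype_matrix()].
#' @param samples Sample table.
#' @param window Cis window in bp (default 1e5).
#' @param covariates Covariate column names in `samples`.
#' @param scope `"joint"` or one population label.
#' @param maf_min Minor-allele-frequency floor (default 0.05).
#' @return Tibble of class `assoc_result` with columns `feature_id`,
#'   `snp_id`, `distance` (SNP pos minus anchor), `beta` (effect per
#'   derived-allele copy), `p_linear`, `p_kw`, `scope`, `conditional_rank`.
#' @export
map_cis <- function(features, feature_annot, geno, samples, window = 1e5,
                    covariates = character(), scope = "joint",
                    maf_min = 0.05) {
  if (window <= 0) abort("window must be positive")
  features <- as.matrix(features)
  feature_annot <- tibble::as_tibble(feature_annot)
  id_col <- intersect(c("cpg_id", "gene_id", "feature_id"), names(feature_annot))[1]
  anchor_col <- if ("pos" %in% names(feature_annot)) "pos" else "tss"
  idx <- .scope_samples(samples, scope)
  smp <- tibble::as_tibble(samples)[idx, ]
  F_ <- features[idx, , drop = FALSE]
  D <- geno$dosage[idx, , drop = FALSE]

  keep_snp <- .maf(D) >= maf_min
  X <- .design_matrix(smp, covariates, population = identical(scope, "joint"))
  df <- nrow(F_) - ncol(X) - 1L
  qrX <- qr(X)
  F_res <- qr.resid(qrX, F_)
  D_res <- qr.resid(qrX, D)

  snp_pos <- geno$snps$pos
  snp_chr <- geno$snps$chr
  out <- vector("list", ncol(F_))
  for (j in seq_len(ncol(F_))) {
    fid <- colnames(F_)[j]
    a <- feature_annot[feature_annot[[id_col]] == fid, ]
    if (!nrow(a)) next
    cand <- which(snp_chr == a$chr[1] &
                    abs(snp_pos - a[[anchor_col]][1]) <= window & keep_snp)
    if (!length(cand)) next
    # drop SNPs with < 2 genotype classes in scope
    nclass <- apply(D[, cand, drop = FALSE], 2,
                    function(x) length(unique(round(x))))
    cand <- cand[nclass >= 2L]
    if (!length(cand)) next
    lin <- .assoc_columns(F_res[, j], D_res[, cand, drop = FALSE], df)
    pkw <- unname(vapply(cand, function(s) .kw_pvalue(F_res[, j], round(D[, s])),
                         numeric(1)))
    out[[j]] <- tibble::tibble(
      feature_id = fid,
      snp_id = geno$snps$snp_id[cand],
      distance = snp_pos[cand] - a[[anchor_col]][1],
      beta = lin$beta, p_linear = lin$p, p_kw = pkw,
      scope = scope, conditional_rank = 1L
    )
  }
  res <- dplyr::bind_rows(out)
  if (!nrow(res)) {
    res <- tibble::tibble(feature_id = character(0), snp_id = character(0),
                          distance = integer(0), beta = numeric(0),
                          p_linear = numeric(0), p_kw = numeric(0),
                          scope = character(0), conditional_rank = integer(0))
  }
  class(res) <- c("assoc_result", class(res))
  res
}

# Permute rows of a feature matrix within each population.
.permute_within_population <- function(features, samples) {
  idx <- seq_len(nrow(features))
  for (p in unique(samples$population)) {
    w <- which(samples$population == p)
    idx[w] <- w[sample.int(length(w))]
  }
  features[idx, , drop = FALSE]
}

#' Permutation-derived FDR threshold
#'
#' Estimates the false discovery rate of a feature-level mapping by
#' re-running the mapping on datasets with the molecular values permuted
#' within each population (genotypes and covariates stay fixed), keeping
#' the most significant p-value per feature after each permutation. For a
#' candidate threshold t,
#' `FDR(t) = mean over permutations of #{features with min p <= t} /
#' #{observed features with min p <= t}`; the returned threshold is the
#' largest grid value with estimated FDR at or below `fdr_level`.
#'
#' @param features Samples-by-features matrix passed to `mapper`.
#' @param samples Sample table (permutation is stratified by `population`).
#' @param mapper Function taking a feature matrix and returning an
#'   association tibble with `feature_id` and the p-value column `p_col`.
#' @param n_perm Number of permutations (default 100).
#' @param fdr_level Target FDR (default 0.05).
#' @param candidate_grid Candidate thresholds (default [default_p_grid()]).
#' @param seed Integer seed.
#' @param p_col Name of the p-value column to use (default `"p_linear"`).
#' @return A list of class `fdr_threshold`: `p_star` (NA when no grid point
#'   attains the target), `attainable`, `fdr_level`, `n_perm`, `grid` (a
#'   tibble with observed counts, mean null counts and FDR at each
#'   threshold) and `permuted_minima` (n_perm x n_features matrix).
#' @export
permutation_fdr <- function(features, samples, mapper, n_perm = 100,
                            fdr_level = 0.05,
                            candidate_grid = default_p_grid(), seed = 1L,
                            p_col = "p_linear") {
  stopifnot(n_perm >= 10)
  candidate_grid <- sort(candidate_grid)
  samples <- tibble::as_tibble(samples)
  observed <- mapper(features)
  obs_min <- tapply(observed[[p_col]], observed$feature_id, min, na.rm = TRUE)
  seeds <- .child_seeds(seed, n_perm)
  perm_min <- matrix(NA_real_, nrow = n_perm, ncol = length(obs_min))
  for (b in seq_len(n_perm)) {
    set.seed(seeds[b])
    fp <- .permute_within_population(features, samples)
    pr <- mapper(fp)
    pm <- tapply(pr[[p_col]], pr$feature_id, min, na.rm = TRUE)
    perm_min[b, seq_along(pm)] <- pm
  }
  n_obs <- vapply(candidate_grid, function(t) sum(obs_min <= t, na.rm = TRUE),
                  numeric(1))
  mean_null <- vapply(candidate_grid,
                      function(t) mean(rowSums(perm_min <= t, na.rm = TRUE)),
                      numeric(1))
  fdr <- ifelse(n_obs > 0, pmin(mean_null / n_obs, 1), NA_real_)
  ok <- which(!is.na(fdr) & fdr <= fdr_level)
  p_star <- if (length(ok)) max(candidate_grid[ok]) else NA_real_
  structure(list(
    p_star = p_star, attainable = length(ok) > 0, fdr_level = fdr_level,
    n_perm = n_perm,
    grid = tibble::tibble(threshold = candidate_grid, n_observed = n_obs,
                          mean_null = mean_null, fdr = fdr),
    permuted_minima = perm_min
  ), class = "fdr_threshold")
}

#' @export
print.fdr_threshold <- function(x, ...) {
  cat("<fdr_threshold> p* =", format(x$p_star),
      "at FDR", x$fdr_level, "(", x$n_perm, "permutations )\n")
  invisible(x)
}

#' Stepwise conditional fine-mapping of one feature
#'
#' Starting from the lead SNP of a significant cis association, regresses
#' the feature on the genotypes of all current lead SNPs (plus covariates),
#' re-maps the cis window on the residuals, and promotes the best remaining
#' SNP if it still passes `p_star`; iterates until no SNP passes or
#' `max_rank` is reached. The lead SNP at each rank is chosen by smallest
#' linear p, then largest absolute effect, then smallest genomic position.
#'
#' @param feature_id Feature (CpG or gene) id to fine-map.
#' @param features,feature_annot,geno,samples,window,covariates,scope,maf_min
#'   As in [map_cis()].
#' @param p_star Linear-test significance threshold (from
#'   [permutation_fdr()]).
#' @param max_rank Maximum number of independent signals (default 5).
#' @return Tibble of `assoc_result` rows ordered by `conditional_rank`
#'   (empty when no SNP passes at rank 1).
#' @export
stepwise_conditional <- function(feature_id, features, feature_annot, geno,
                                 samples, p_star, window = 1e5,
                                 covariates = character(), scope = "joint",
                                 max_rank = 5, maf_min = 0.05) {
  idx <- .scope_samples(samples, scope)
  smp <- tibble::as_tibble(samples)[idx, ]
  leads <- list()
  cond_snps <- character(0)
  for (rank in seq_len(max_rank)) {
    smp_aug <- smp
    cov_aug <- covariates
    for (s in cond_snps) {
      cn <- paste0(".cond_", s)
      smp_aug[[cn]] <- geno$dosage[idx, s]
      cov_aug <- c(cov_aug, cn)
    }
    res <- map_cis(features[idx, feature_id, drop = FALSE], feature_annot,
                   genotype_matrix(geno$dosage[idx, , drop = FALSE], geno$snps),
                   smp_aug, window = window, covariates = cov_aug,
                   scope = if (identical(scope, "joint")) "joint" else scope,
                   maf_min = maf_min)
    res <- res[!res$snp_id %in% cond_snps & !is.na(res$p_linear), ]
    res <- res[res$p_linear <= p_star, ]
    if (!nrow(res)) break
    pos <- setNames(geno$snps$pos, geno$snps$snp_id)
    ord <- order(res$p_linear, -abs(res$beta), pos[res$snp_id])
    best <- res[ord[1], ]
    best$conditional_rank <- rank
    best$scope <- scope
    leads[[rank]] <- best
    cond_snps <- c(cond_snps, best$snp_id)
  }
  out <- dplyr::bind_rows(leads)
  if (nrow(out)) class(out) <- c("assoc_result", class(out))
  out
}

# Vectorized Kruskal-Wallis of every column of Y against groups g.
.kw_matrix <- function(Y, g) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  grp <- factor(g)
  k <- nlevels(grp)
  if (k < 2L) return(rep(NA_real_, ncol(Y)))
  R <- apply(Y, 2, rank)
  G <- stats::model.matrix(~ 0 + grp)
  ns <- colSums(G)
  S <- crossprod(G, R)
  H <- 12 / (n * (n + 1)) * colSums(S^2 / ns) - 3 * (n + 1)
  C <- apply(Y, 2, function(y) {
    t <- table(y)
    1 - sum(t^3 - t) / (n^3 - n)
  })
  p <- rep(NA_real_, ncol(Y))
  ok <- C > 0
  p[ok] <- pchisq(H[ok] / C[ok], df = k - 1L, lower.tail = FALSE)
  p
}

#' Map trans meQTLs from TF-proximal SNPs
#'
#' Trans mapping restricts the SNP universe to variants plausibly acting
#' through transcription factors: SNPs within `tss_window` of the TSS of an
#' expressed TF gene, plus SNPs detected as cis-eQTLs of those TFs. Each
#' candidate SNP is tested against every CpG at least `trans_min` bp away or
#' on another chromosome, using a Kruskal-Wallis rank test on M values
#' residualized on the covariates and an ancestry indicator.
#'
#' @param meth A [methylation_matrix()] (M values are used).
#' @param cpg_annot CpG annotation tibble (`cpg_id`, `chr`, `pos`).
#' @param geno A [genotype_matrix()].
#' @param gene_annot Gene annotation tibble with `is_tf`, `chr`, `tss`.
#' @param cis_eqtl_records Optional `assoc_result` of cis-eQTLs; SNPs
#'   associated with TF genes are added to the candidate set.
#' @param samples Sample table.
#' @param trans_min Minimum same-chromosome distance (default 1e6).
#' @param tss_window TF-proximity window (default 1e4).
#' @param covariates Covariate columns residualized out before ranking.
#' @param maf_min MAF floor (default 0.05).
#' @return Tibble of class `assoc_result` with `p_kw` per tested pair.
#' @export
map_trans <- function(meth, cpg_annot, geno, gene_annot,
                      cis_eqtl_records = NULL, samples, trans_min = 1e6,
                      tss_window = 1e4, covariates = character(),
                      maf_min = 0.05) {
  gene_annot <- tibble::as_tibble(gene_annot)
  tf <- gene_annot[gene_annot$is_tf, ]
  cand <- logical(nrow(geno$snps))
  for (i in seq_len(nrow(tf))) {
    cand <- cand | (geno$snps$chr == tf$chr[i] &
                      abs(geno$snps$pos - tf$tss[i]) <= tss_window)
  }
  if (!is.null(cis_eqtl_records) && nrow(cis_eqtl_records)) {
    tf_eqtl <- cis_eqtl_records$snp_id[cis_eqtl_records$feature_id %in%
                                         tf$gene_id]
    cand <- cand | geno$snps$snp_id %in% tf_eqtl
  }
  cand <- cand & .maf(geno$dosage) >= maf_min
  if (!any(cand)) abort("empty trans candidate SNP universe")

  samples <- tibble::as_tibble(samples)
  M <- m_values(meth)
  X <- .design_matrix(samples, covariates, population = TRUE)
  M_res <- .residualize(M, X)
  cpg_annot <- tibble::as_tibble(cpg_annot)
  cpg_annot <- cpg_annot[match(colnames(M), cpg_annot$cpg_id), ]

  out <- list()
  for (s in which(cand)) {
    far <- cpg_annot$chr != geno$snps$chr[s] |
      abs(cpg_annot$pos - geno$snps$pos[s]) >= trans_min
    if (!any(far)) next
    g <- round(geno$dosage[, s])
    if (length(unique(g)) < 2L) next
    p <- .kw_matrix(M_res[, far, drop = FALSE], g)
    dist <- ifelse(cpg_annot$chr[far] == geno$snps$chr[s],
                   geno$snps$pos[s] - cpg_annot$pos[far], NA_integer_)
    out[[length(out) + 1L]] <- tibble::tibble(
      feature_id = cpg_annot$cpg_id[far],
      snp_id = geno$snps$snp_id[s],
      distance = dist, beta = NA_real_, p_linear = NA_real_, p_kw = p,
      scope = "joint", conditional_rank = 1L
    )
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("assoc_result", class(res))
  res
}

#' Stimulation fold change of expression
#'
#' Computes the low-expression-guarded log2 fold change
#' `diff = log2((1 + FPKM_stim) / (1 + FPKM_ns))` and `fold = 2^diff`. The
#' +1 pseudocount tames ratios between small FPKM values.
#'
#' @param fpkm_stim,fpkm_ns Non-negative FPKM vectors or matrices of equal
#'   shape.
#' @return List with `diff` (log2 units) and `fold` (ratio), same shape as
#'   the inputs.
#' @examples
#' fold_change(3, 1)  # diff = 1, fold = 2
#' @export
fold_change <- function(fpkm_stim, fpkm_ns) {
  if (any(fpkm_stim < 0, na.rm = TRUE) || any(fpkm_ns < 0, na.rm = TRUE)) {
    abort("FPKM values must be non-negative")
  }
  d <- log2((1 + fpkm_stim) / (1 + fpkm_ns))
  list(diff = d, fold = 2^d)
}

#' Map expression quantitative trait methylation (eQTM)
#'
#' Tests every gene against every CpG within `window` bp of its TSS using
#' Spearman's rank correlation; p-values use the t approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))`. In the joint scope both variables are
#' residualized on an ancestry indicator before ranking (a partial rank
#' correlation); a population scope restricts to those samples. Passing a
#' fold-change matrix (see [fold_change()]) instead of baseline expression
#' maps response QTMs.
#'
#' @param expr_values Samples-by-genes matrix: [log_expression()] output or
#'   a fold-change `diff` matrix.
#' @param gene_annot Tibble with `gene_id`, `chr`, `tss`.
#' @param meth A [methylation_matrix()] (M values are used).
#' @param cpg_annot Tibble with `cpg_id`, `chr`, `pos`.
#' @param samples Sample table.
#' @param window Cis window around the TSS (default 1e5).
#' @param scope `"joint"` or a population label.
#' @return Tibble of class `assoc_result`: `feature_id` (gene), `cpg_id`,
#'   `distance`, `rho_spearman`, `p_spearman`, `scope`. Constant expression
#'   vectors are skipped.
#' @export
map_eqtm <- function(expr_values, gene_annot, meth, cpg_annot, samples,
                     window = 1e5, scope = "joint") {
  expr_values <- as.matrix(expr_values)
  gene_annot <- tibble::as_tibble(gene_annot)
  cpg_annot <- tibble::as_tibble(cpg_annot)
  idx <- .scope_samples(samples, scope)
  smp <- tibble::as_tibble(samples)[idx, ]
  E <- expr_values[idx, , drop = FALSE]
  M <- m_values(meth)[idx, , drop = FALSE]
  if (identical(scope, "joint")) {
    X <- .design_matrix(smp, character(), population = TRUE)
    E <- .residualize(E, X)
    M <- .residualize(M, X)
  }
  n <- nrow(E)
  RM <- apply(M, 2, rank)
  out <- list()
  for (j in seq_len(ncol(E))) {
    gid <- colnames(E)[j]
    a <- gene_annot[gene_annot$gene_id == gid, ]
    if (!nrow(a)) next
    if (sd(E[, j]) == 0) next  # constant expression: skipped
    cand <- which(cpg_annot$chr == a$chr[1] &
                    abs(cpg_annot$pos - a$tss[1]) <= window)
    cand_idx <- match(cpg_annot$cpg_id[cand], colnames(M))
    keep <- !is.na(cand_idx)
    cand <- cand[keep]; cand_idx <- cand_idx[keep]
    if (!length(cand)) next
    re <- rank(E[, j])
    rho <- unname(suppressWarnings(cor(re, RM[, cand_idx, drop = FALSE]))[1, ])
    tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
    out[[length(out) + 1L]] <- tibble::tibble(
      feature_id = gid, cpg_id = cpg_annot$cpg_id[cand],
      distance = cpg_annot$pos[cand] - a$tss[1],
      rho_spearman = rho, p_spearman = p, scope = scope,
      conditional_rank = 1L
    )
  }
  res <- dplyr::bind_rows(out)
  if (!nrow(res)) {
    res <- tibble::tibble(feature_id = character(0), cpg_id = character(0),
                          distance = integer(0), rho_spearman = numeric(0),
                          p_spearman = numeric(0), scope = character(0),
                          conditional_rank = integer(0))
  }
  class(res) <- c("assoc_result", class(res))
  res
}

#' Significant associations under the dual-test rule
#'
#' Cis meQTL/eQTL significance requires the linear and Kruskal-Wallis tests
#' to both pass their thresholds.
#'
#' @param assoc An `assoc_result` tibble from [map_cis()].
#' @param p_star_linear,p_star_kw Thresholds for the two tests (use the
#'   [permutation_fdr()] output of each mapping).
#' @return The subset of rows passing both tests.
#' @export
significant_cis <- function(assoc, p_star_linear, p_star_kw = p_star_linear) {
  keep <- !is.na(assoc$p_linear) & !is.na(assoc$p_kw) &
    assoc$p_linear <= p_star_linear & assoc$p_kw <= p_star_kw
  assoc[keep, ]
}

#' @method tidy assoc_result
#' @export
tidy.assoc_result <- function(x, ...) tibble::as_tibble(x)

#' P-value histogram of an association scan
#'
#' @param object An `assoc_result` tibble.
#' @param p_col Which p-value column to plot.
#' @param ... Unused.
#' @return A ggplot histogram; a flat shape indicates good null calibration.
#' @method autoplot assoc_result
#' @export
autoplot.assoc_result <- function(object, p_col = NULL, ...) {
  if (is.null(p_col)) {
    p_col <- intersect(c("p_linear", "p_kw", "p_spearman"), names(object))[1]
  }
  df <- tibble::as_tibble(object)
  df <- df[!is.na(df[[p_col]]), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[p_col]])) +
    ggplot2::geom_histogram(breaks = seq(0, 1, by = 0.05),
                            fill = "grey40", colour = "white") +
    ggplot2::labs(x = p_col, y = "count") +
    ggplot2::theme_minimal()
}
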