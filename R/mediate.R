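# Trio detection, elastic-net summary variables, quasi-Bayesian causal
# mediation, the partial-correlation comparator, and the simulation
# benchmark comparing the two.

#' Detect SNP--CpG--gene trios
#'
#' A trio is a gene, a set of CpGs and a set of SNPs where each SNP is both
#' an eQTL of the gene and a meQTL of one of the CpGs, and each CpG is an
#' eQTM of the gene. All three association sets should already be filtered
#' at their FDR thresholds. Multiple qualifying SNPs and CpGs for one gene
#' are grouped into a single trio.
#'
#' @param eqtl_records `assoc_result` with `feature_id` = gene, `snp_id`.
#' @param meqtl_records `assoc_result` with `feature_id` = CpG, `snp_id`.
#' @param eqtm_records `assoc_result` with `feature_id` = gene, `cpg_id`.
#' @return Tibble of class `trio_set`: `gene_id`, `snp_ids` and `cpg_ids`
#'   (list-columns), `n_snps`, `n_cpgs`. Empty when no trio qualifies.
#' @export
detect_trios <- function(eqtl_records, meqtl_records, eqtm_records) {
  eqtl <- tibble::tibble(gene_id = eqtl_records$feature_id,
                         snp_id = eqtl_records$snp_id)
  meqtl <- tibble::tibble(cpg_id = meqtl_records$feature_id,
                          snp_id = meqtl_records$snp_id)
  eqtm <- tibble::tibble(gene_id = eqtm_records$feature_id,
                         cpg_id = eqtm_records$cpg_id)
  cand <- dplyr::inner_join(eqtl, meqtl, by = "snp_id",
                            relationship = "many-to-many")
  cand <- dplyr::semi_join(cand, eqtm, by = c("gene_id", "cpg_id"))
  if (!nrow(cand)) {
    out <- tibble::tibble(gene_id = character(0), snp_ids = list(),
                          cpg_ids = list(), n_snps = integer(0),
                          n_cpgs = integer(0))
    class(out) <- c("trio_set", class(out))
    return(out)
  }
  out <- cand |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(snp_ids = list(unique(.data$snp_id)),
                     cpg_ids = list(unique(.data$cpg_id)),
                     .groups = "drop") |>
    dplyr::mutate(n_snps = lengths(.data$snp_ids),
                  n_cpgs = lengths(.data$cpg_ids))
  class(out) <- c("trio_set", class(out))
  out
}

#' Elastic-net summary variable
#'
#' Collapses several correlated predictors (multiple CpGs or SNPs of one
#' trio) into one per-sample summary: a penalized linear fit with elastic-
#' net mixing 0.5 over a lambda path, k-fold cross-validation, and the
#' one-standard-error rule (the largest lambda whose CV error is within one
#' standard error of the minimum). If every coefficient is zero at
#' `lambda.1se`, the fit falls back to `lambda.min` with a warning flag.
#' Single-predictor trios bypass this and use the raw variable.
#'
#' @param target Numeric response vector.
#' @param predictors Numeric matrix with at least two columns.
#' @param mixing Elastic-net mixing parameter alpha (default 0.5).
#' @param n_folds CV folds (default 10).
#' @param seed Integer seed (controls fold assignment).
#' @return List: `summary` (fitted linear combination per sample),
#'   `coefficients` (named, without intercept), `lambda`, `fallback`
#'   (TRUE when `lambda.min` was used).
#' @export
elastic_net_summary <- function(target, predictors, mixing = 0.5,
                                n_folds = 10, seed = 1L) {
  predictors <- as.matrix(predictors)
  if (ncol(predictors) < 2L) abort("need at least 2 predictors")
  if (sd(target) == 0) abort("constant target")
  set.seed(seed)
  cv <- glmnet::cv.glmnet(predictors, target, alpha = mixing,
                          nfolds = n_folds)
  lam <- cv$lambda.1se
  cf <- as.numeric(coef(cv, s = lam))[-1]
  fallback <- FALSE
  if (all(cf == 0)) {
    warn("all coefficients zero at lambda.1se; falling back to lambda.min")
    lam <- cv$lambda.min
    cf <- as.numeric(coef(cv, s = lam))[-1]
    fallback <- TRUE
  }
  pred <- as.numeric(predict(cv, newx = predictors, s = lam))
  list(summary = pred, coefficients = setNames(cf, colnames(predictors)),
       lambda = lam, fallback = fallback)
}

# Core mediation computation on plain vectors/matrices.
# Point estimates are the OLS products (so acme + ade = total exactly);
# quasi-Bayesian draws from the coefficient sampling distributions feed the
# draw summary and the normal-fit p-value.
.mediate_core <- function(expression, geno, meth, covariates = NULL,
                          n_draws = 1000, seed = 1L) {
  n <- length(expression)
  C <- if (is.null(covariates)) NULL else as.matrix(covariates)
  Xm <- cbind(`(Intercept)` = 1, G = geno, C)
  Xo <- cbind(`(Intercept)` = 1, G = geno, M = meth, C)
  .check_full_rank(Xo)
  fit_med <- lm.fit(Xm, meth)
  fit_out <- lm.fit(Xo, expression)
  cov_beta <- function(X, fit) {
    df <- n - ncol(X)
    s2 <- sum(fit$residuals^2) / df
    s2 * chol2inv(chol(crossprod(X)))
  }
  Vm <- cov_beta(Xm, fit_med)
  Vo <- cov_beta(Xo, fit_out)
  a <- fit_med$coefficients[["G"]]
  se_a <- sqrt(Vm[2, 2])
  b <- fit_out$coefficients[["M"]]
  se_b <- sqrt(Vo[3, 3])
  d <- fit_out$coefficients[["G"]]
  se_d <- sqrt(Vo[2, 2])

  if (n_draws < 100) warn("n_draws < 100: the normal fit will be unstable")
  set.seed(seed)
  a_dr <- rnorm(n_draws, a, se_a)
  b_dr <- rnorm(n_draws, b, se_b)
  d_dr <- rnorm(n_draws, d, se_d)
  acme_dr <- a_dr * b_dr
  mu <- mean(acme_dr); sdv <- sd(acme_dr)
  p_acme <- if (sdv > 0) 2 * pnorm(-abs(mu) / sdv) else as.numeric(mu == 0)

  acme <- a * b
  ade <- d
  r2 <- function(x) {
    f <- lm.fit(cbind(1, x), expression)
    1 - sum(f$residuals^2) / sum((expression - mean(expression))^2)
  }
  tibble::tibble(
    acme = acme, ade = ade, total = acme + ade,
    p_acme = p_acme, n_draws = n_draws,
    prop_mediated = acme / (acme + ade),
    acme_draw_mean = mu, acme_draw_sd = sdv,
    ade_draw_mean = mean(d_dr), ade_draw_sd = sd(d_dr),
    r2_meth = r2(meth), r2_geno = r2(geno),
    alpha_path = a, beta_path = b
  )
}

#' Quasi-Bayesian causal mediation for one trio
#'
#' Decomposes the total effect of the genetic summary variable X on
#' expression Y into a direct part and a part mediated by methylation M:
#' `rho(X -> Y) = tau + alpha * beta`, where `alpha` is the effect of X on
#' M (mediator model `M ~ X + covariates`) and `beta` the effect of M on Y
#' (outcome model `Y ~ X + M + covariates`). The average causal mediation
#' effect (ACME) is the product `alpha * beta`; for this linear
#' specification `acme + ade = total` holds exactly. Uncertainty is
#' quasi-Bayesian: `n_draws` coefficient vectors are sampled from each
#' model's estimated sampling distribution, the per-draw products form the
#' ACME distribution, and a normal fitted to the draws (mean/sd) gives the
#' two-sided p for the null `alpha * beta = 0`.
#'
#' @param trio One row of a [detect_trios()] result, carried through for
#'   ids; or NULL when calling with raw vectors.
#' @param expression Numeric expression vector (log2 scale).
#' @param geno_summary,meth_summary Per-sample scalar summaries (raw dosage
#'   and M value for single-SNP/CpG trios, [elastic_net_summary()]
#'   predictions otherwise).
#' @param covariates Optional numeric matrix of covariates used in both
#'   models.
#' @param n_draws Number of quasi-Bayesian draws (default 1000).
#' @param seed Integer seed.
#' @return One-row tibble of class `mediation_result`: `acme`, `ade`,
#'   `total`, `p_acme`, `prop_mediated`, draw summaries, `r2_meth`,
#'   `r2_geno`.
#' @export
mediate_trio <- function(trio = NULL, expression, geno_summary, meth_summary,
                         covariates = NULL, n_draws = 1000, seed = 1L) {
  out <- .mediate_core(expression, geno_summary, meth_summary, covariates,
                       n_draws, seed)
  out <- dplyr::bind_cols(
    tibble::tibble(gene_id = if (!is.null(trio)) trio$gene_id else NA_character_),
    out
  )
  class(out) <- c("mediation_result", class(out))
  out
}

#' Mediation across a trio set with FDR control
#'
#' Runs [mediate_trio()] for every trio, building summary variables with
#' the elastic net where a trio has several SNPs or CpGs, then adjusts the
#' ACME p-values by Benjamini-Hochberg and flags mediated genes at
#' `q_value < fdr_level`.
#'
#' @param trios A [detect_trios()] result.
#' @param expr_values Samples-by-genes matrix (log2 scale).
#' @param geno A [genotype_matrix()].
#' @param meth A [methylation_matrix()].
#' @param covariates Optional covariate matrix.
#' @param n_draws,seed As in [mediate_trio()].
#' @param fdr_level FDR for the mediated flag (default 0.05).
#' @return Tibble of class `mediation_result`, one row per gene, with
#'   `q_value` and `mediated` added.
#' @export
mediate_trios <- function(trios, expr_values, geno, meth, covariates = NULL,
                          n_draws = 1000, seed = 1L, fdr_level = 0.05) {
  expr_values <- as.matrix(expr_values)
  M <- m_values(meth)
  seeds <- .child_seeds(seed, max(nrow(trios), 1L))
  rows <- lapply(seq_len(nrow(trios)), function(i) {
    tr <- trios[i, ]
    cpgs <- tr$cpg_ids[[1]]; snps <- tr$snp_ids[[1]]
    e <- expr_values[, tr$gene_id]
    ms <- if (length(cpgs) > 1L) {
      elastic_net_summary(e, M[, cpgs, drop = FALSE], seed = seeds[i])$summary
    } else {
      M[, cpgs]
    }
    gs <- if (length(snps) > 1L) {
      elastic_net_summary(ms, geno$dosage[, snps, drop = FALSE],
                          seed = seeds[i] + 1L)$summary
    } else {
      geno$dosage[, snps]
    }
    mediate_trio(tr, e, gs, ms, covariates, n_draws, seed = seeds[i] + 2L)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out)) {
    out$q_value <- p.adjust(out$p_acme, method = "BH")
    out$mediated <- out$q_value < fdr_level
  }
  class(out) <- c("mediation_result", class(out))
  out
}

#' @method tidy mediation_result
#' @export
tidy.mediation_result <- function(x, ...) tibble::as_tibble(x)

#' @method glance mediation_result
#' @export
glance.mediation_result <- function(x, ...) {
  tibble::tibble(
    n_trios = nrow(x),
    n_mediated = if ("mediated" %in% names(x)) sum(x$mediated) else NA_integer_,
    mean_prop_mediated = mean(x$prop_mediated[is.finite(x$prop_mediated)])
  )
}

#' First-order partial correlation test
#'
#' Correlation of expression and methylation after removing the linear
#' effect of genotype from both (equivalently, the correlation of the OLS
#' residuals of `E ~ G` and `M ~ G`); p-value from the t transform with
#' n - 3 degrees of freedom. Used as the simple comparator to the
#' mediation test.
#'
#' @param expression,methylation,genotype Numeric vectors of equal length
#'   (n >= 4).
#' @return One-row tibble: `pcor`, `statistic`, `p`.
#' @export
partial_correlation_test <- function(expression, methylation, genotype) {
  n <- length(expression)
  if (n < 4) abort("need at least 4 observations")
  if (sd(expression) == 0 || sd(methylation) == 0 || sd(genotype) == 0) {
    abort("constant input vector")
  }
  r_em <- cor(expression, methylation)
  r_eg <- cor(expression, genotype)
  r_mg <- cor(methylation, genotype)
  pc <- (r_em - r_eg * r_mg) / sqrt((1 - r_eg^2) * (1 - r_mg^2))
  pc <- min(max(pc, -1), 1)
  tstat <- pc * sqrt((n - 3) / max(1 - pc^2, .Machine$double.eps))
  p <- 2 * pt(abs(tstat), df = n - 3, lower.tail = FALSE)
  tibble::tibble(pcor = pc, statistic = tstat, p = p)
}

#' Benchmark mediation against partial correlation on simulated trios
#'
#' For each cell of a variance-share grid, simulates `n_replicates` trios
#' via [simulate_causal_trio()] — half with the cell's mediated share
#' `beta` and half with `beta = 0` (the non-mediated truth, with the same
#' total explained variance) — labels each trio by whether
#' `alpha * beta != 0`, scores it with the mediation ACME p-value and the
#' partial-correlation p-value, and summarises each cell with the
#' Mann-Whitney AUC of both scores plus the sensitivity and specificity of
#' the mediation test at p < 0.05.
#'
#' @param grid Tibble with columns `alpha`, `beta`, `tau`, `gamma` (one row
#'   per cell).
#' @param n_replicates Trios per cell (default 200).
#' @param n_samples Samples per trio (default 156).
#' @param n_draws Quasi-Bayesian draws per mediation (default 1000).
#' @param genotype_freq Allele frequency of the simulated variant.
#' @param seed Integer seed.
#' @return Tibble of class `mediation_benchmark`, one row per cell:
#'   `auc_mediation`, `auc_pcor`, `auc_diff`, `sensitivity`, `specificity`,
#'   `degenerate` (TRUE when the cell had a single truth class).
#' @export
benchmark_mediation <- function(grid, n_replicates = 200, n_samples = 156,
                                n_draws = 1000, genotype_freq = 0.3,
                                seed = 1L) {
  grid <- tibble::as_tibble(grid)
  stopifnot(all(c("alpha", "beta", "tau", "gamma") %in% names(grid)))
  cell_seeds <- .child_seeds(seed, nrow(grid))
  rows <- lapply(seq_len(nrow(grid)), function(ci) {
    g <- grid[ci, ]
    rep_seeds <- .child_seeds(cell_seeds[ci], n_replicates)
    mediated_truth <- rep(c(TRUE, FALSE), length.out = n_replicates)
    p_med <- numeric(n_replicates)
    p_pc <- numeric(n_replicates)
    for (r in seq_len(n_replicates)) {
      b <- if (mediated_truth[r]) g$beta else 0
      tau <- if (mediated_truth[r]) g$tau else g$beta + g$tau
      pr <- sim_params(alpha = g$alpha, beta = b, tau = tau, gamma = g$gamma,
                       n_samples = n_samples, seed = rep_seeds[r],
                       scenario = if (mediated_truth[r]) "mediation"
                                  else "direct_only")
      tr <- simulate_causal_trio(pr, genotype_freq = genotype_freq)
      med <- .mediate_core(tr$expression, tr$genotype_std, tr$methylation,
                           n_draws = n_draws, seed = rep_seeds[r] %% 1000003L)
      p_med[r] <- med$p_acme
      p_pc[r] <- partial_correlation_test(tr$expression, tr$methylation,
                                          tr$genotype)$p
    }
    truth_mixed <- any(mediated_truth & g$alpha * g$beta != 0) &&
      any(!(mediated_truth & g$alpha * g$beta != 0))
    pos <- mediated_truth & g$alpha * g$beta != 0
    tibble::tibble(
      alpha = g$alpha, beta = g$beta, tau = g$tau, gamma = g$gamma,
      auc_mediation = if (truth_mixed) .rank_auc(1 - p_med, pos) else NA_real_,
      auc_pcor = if (truth_mixed) .rank_auc(1 - p_pc, pos) else NA_real_,
      sensitivity = if (any(pos)) mean(p_med[pos] < 0.05) else NA_real_,
      specificity = if (any(!pos)) mean(p_med[!pos] >= 0.05) else NA_real_,
      n_pos = sum(pos), n_neg = sum(!pos),
      degenerate = !truth_mixed
    )
  })
  out <- dplyr::bind_rows(rows)
  out$auc_diff <- out$auc_mediation - out$auc_pcor
  class(out) <- c("mediation_benchmark", class(out))
  out
}

#' AUC-difference surface of the mediation benchmark
#'
#' @param object A [benchmark_mediation()] result.
#' @param ... Unused.
#' @return A ggplot tile plot of `auc_mediation - auc_pcor` over the
#'   (alpha, beta) grid.
#' @method autoplot mediation_benchmark
#' @export
autoplot.mediation_benchmark <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$alpha),
                                   y = factor(.data$beta),
                                   fill = .data$auc_diff)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-0.2, 0.2)) +
    ggplot2::labs(x = expression(alpha), y = expression(beta),
                  fill = "AUC difference") +
    ggplot2::theme_minimal()
}
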