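#' Per-CpG population model fit
#'
#' Fits, by ordinary least squares for each CpG, the model
#' `M ~ population + covariates` on the M scale and returns the population
#' coefficient (the between-group methylation difference in M units), its
#' unscaled standard error, the residual degrees of freedom and residual
#' variance. The returned table feeds [moderate_variance()] for
#' empirical-Bayes shrinkage.
#'
#' @param meth A [methylation_matrix()] (converted to M internally) or a
#'   samples-by-CpGs M-value matrix.
#' @param samples Sample table with a `population` column and any covariate
#'   columns.
#' @param covariates Character vector of covariate column names (e.g.
#'   `c("age", "sv1", "sv2")`).
#' @return A tibble with columns `cpg_id`, `effect`, `se`, `df`, `sigma2`,
#'   plus the per-CpG unscaled standard deviation as attribute
#'   `stdev_unscaled` (a design constant, identical across CpGs).
#' @export
fit_population_model <- function(meth, samples, covariates = character()) {
  M <- if (inherits(meth, "methylation_matrix")) m_values(meth) else as.matrix(meth)
  samples <- tibble::as_tibble(samples)
  stopifnot(nrow(samples) == nrow(M))
  if (min(table(samples$population)) < 2L) {
    abort("at least 2 samples per population are required")
  }
  X <- .design_matrix(samples, covariates, population = TRUE)
  fit <- limma::lmFit(t(M), design = X)
  j <- match("population", colnames(X))
  effect <- fit$coefficients[, j]
  su <- fit$stdev.unscaled[, j]
  sigma2 <- fit$sigma^2
  out <- tibble::tibble(
    cpg_id = colnames(M),
    effect = unname(effect),
    se = unname(su * fit$sigma),
    df = fit$df.residual,
    sigma2 = unname(sigma2)
  )
  attr(out, "stdev_unscaled") <- unname(su)
  out
}

#' Empirical-Bayes variance moderation
#'
#' Shrinks per-CpG residual variances toward a common prior estimated by
#' moment-matching the log variances to a scaled F distribution (the limma
#' empirical-Bayes machinery): the posterior variance is
#' `(d0 * s0^2 + df * s^2) / (d0 + df)` and the moderated t-statistic uses
#' it in place of `s^2`, with `df + d0` degrees of freedom. When all
#' variances are identical the prior degrees of freedom are infinite and
#' the moderated t equals the ordinary t computed at the common variance.
#'
#' @param fit Output of [fit_population_model()].
#' @return The input tibble with added columns `sigma2_post`, `t_moderated`,
#'   `p_raw`, and attributes `d0` (prior degrees of freedom) and `s02`
#'   (prior variance).
#' @export
moderate_variance <- function(fit) {
  stopifnot(is.data.frame(fit), nrow(fit) >= 10)
  su <- attr(fit, "stdev_unscaled")
  sq <- limma::squeezeVar(fit$sigma2, fit$df)
  s_post <- sqrt(sq$var.post)
  t_mod <- fit$effect / (su * s_post)
  df_total <- fit$df + sq$df.prior
  p <- 2 * pt(abs(t_mod), df = pmin(df_total, 1e6), lower.tail = FALSE)
  out <- dplyr::mutate(fit, sigma2_post = sq$var.post, t_moderated = t_mod,
                       p_raw = p)
  attr(out, "stdev_unscaled") <- su
  attr(out, "d0") <- sq$df.prior
  attr(out, "s02") <- sq$var.prior
  out
}

#' Extract differentially methylated sites
#'
#' Applies Benjamini-Hochberg adjustment to the moderated p-values and flags
#' as DMS the CpGs passing both an adjusted-p threshold and a minimum
#' absolute beta-scale mean difference. The effect-size filter runs on raw
#' group means of beta (not the covariate-adjusted M coefficient), and the
#' hypermethylated population is read off the sign of that beta difference.
#'
#' @param results Moderated fit from [moderate_variance()] with a
#'   `delta_beta` column, or the output of [dms_scan()] internals.
#' @param alpha_dms Adjusted p-value threshold (default 0.01).
#' @param delta_min Minimum `|delta_beta|` (default 0.05, i.e. 5%).
#' @param populations The two population labels, in the order matching the
#'   sign of `delta_beta` (positive = first label hypermethylated).
#' @return Tibble with `p_adjusted`, `is_dms` and `hyper_in` added.
#' @export
extract_dms <- function(results, alpha_dms = 0.01, delta_min = 0.05,
                        populations = c("AFB", "EUB")) {
  if (alpha_dms <= 0 || alpha_dms >= 1 || delta_min <= 0 || delta_min >= 1) {
    abort("DMS thresholds must lie in (0, 1)")
  }
  stopifnot("delta_beta" %in% names(results), "p_raw" %in% names(results))
  out <- dplyr::mutate(
    results,
    p_adjusted = p.adjust(.data$p_raw, method = "BH"),
    is_dms = .data$p_adjusted < alpha_dms & abs(.data$delta_beta) > delta_min,
    hyper_in = dplyr::case_when(
      !.data$is_dms ~ "none",
      .data$delta_beta > 0 ~ populations[1],
      TRUE ~ populations[2]
    )
  )
  for (a in c("stdev_unscaled", "d0", "s02")) {
    attr(out, a) <- attr(results, a)
  }
  out
}

#' Differential-methylation scan between populations
#'
#' The full DMS pipeline: per-CpG OLS of M values on population plus
#' covariates, empirical-Bayes variance moderation, BH adjustment, and DMS
#' extraction at `adjusted p < alpha_dms` and `|delta beta| > delta_min`.
#'
#' @inheritParams fit_population_model
#' @inheritParams extract_dms
#' @return A tibble of class `dms_result`, one row per CpG, with columns
#'   `cpg_id`, `effect` (M units), `se`, `t_moderated`, `p_raw`,
#'   `p_adjusted`, `delta_beta` (mean beta of the first population minus the
#'   second), `is_dms`, `hyper_in`. Prior parameters are retrievable via
#'   [glance()].
#' @examples
#' \donttest{
#' spec <- population_spec(n_per_pop = c(20, 20), n_cpgs = 50, n_blocks = 2,
#'                         snps_per_block = 10, n_genes = 5)
#' coh <- simulate_cohort(spec, seed = 1)
#' dms <- dms_scan(coh$meth, coh$samples, covariates = c("age", "sv1", "sv2"))
#' dplyr::count(dms, is_dms)
#' }
#' @export
dms_scan <- function(meth, samples, covariates = character(),
                     alpha_dms = 0.01, delta_min = 0.05) {
  samples <- tibble::as_tibble(samples)
  pops <- levels(factor(samples$population))
  fit <- fit_population_model(meth, samples, covariates)
  fit <- moderate_variance(fit)
  beta <- if (inherits(meth, "methylation_matrix")) meth$beta else m_to_beta(as.matrix(meth))
  in1 <- samples$population == pops[1]
  fit$delta_beta <- colMeans(beta[in1, , drop = FALSE]) -
    colMeans(beta[!in1, , drop = FALSE])
  out <- extract_dms(fit, alpha_dms, delta_min, populations = pops)
  class(out) <- c("dms_result", class(out))
  attr(out, "alpha_dms") <- alpha_dms
  attr(out, "delta_min") <- delta_min
  out
}

#' @method glance dms_result
#' @export
glance.dms_result <- function(x, ...) {
  tibble::tibble(
    n_cpgs = nrow(x),
    n_dms = sum(x$is_dms),
    d0 = attr(x, "d0"),
    s02 = attr(x, "s02"),
    alpha_dms = attr(x, "alpha_dms"),
    delta_min = attr(x, "delta_min")
  )
}

#' @method tidy dms_result
#' @export
tidy.dms_result <- function(x, ...) {
  tibble::as_tibble(x)[c("cpg_id", "effect", "se", "t_moderated", "p_raw",
                         "p_adjusted", "delta_beta", "is_dms", "hyper_in")]
}

#' Volcano plot of a differential-methylation scan
#'
#' @param object A [dms_scan()] result.
#' @param ... Unused.
#' @return A ggplot object: `delta_beta` against `-log10(p_adjusted)` with
#'   DMS highlighted.
#' @method autoplot dms_result
#' @export
autoplot.dms_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta_beta,
                                   y = -log10(.data$p_adjusted),
                                   colour = .data$is_dms)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::labs(x = expression(Delta * beta~"(pop1 - pop2)"),
                  y = expression(-log[10]~"adjusted p"),
                  colour = "DMS") +
    ggplot2::theme_minimal()
}
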