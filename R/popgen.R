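# Population-genetic summaries and population-specificity model selection.

#' Per-SNP derived-allele frequencies, their difference, and FST
#'
#' Computes, from additive dosages, the derived-allele frequency in each
#' population, the frequency difference `delta_daf` (second population
#' minus first, i.e. EUB - AFB under the default labels), and the
#' per-SNP Hudson fixation index in its two-population closed form
#' \deqn{F_{ST} = (p_1 - p_2)^2 / (p_1(1-p_2) + p_2(1-p_1)),}
#' which is 0 at equal frequencies and 1 for a fixed difference. Where the
#' ancestral state is unknown the dosage counts the alternate allele and
#' the record is flagged.
#'
#' @param geno A [genotype_matrix()].
#' @param samples Sample table with `population`.
#' @param populations The two labels, in the order defining the sign of
#'   `delta_daf` (`delta_daf = freq[2] - freq[1]`); defaults to the sorted
#'   labels present.
#' @return Tibble with `snp_id`, `daf_<pop1>`, `daf_<pop2>`, `delta_daf`,
#'   `fst`, `ancestral_known`.
#' @export
allele_frequencies <- function(geno, samples, populations = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"))
  samples <- tibble::as_tibble(samples)
  if (is.null(populations)) populations <- sort(unique(samples$population))
  stopifnot(length(populations) == 2L)
  idx1 <- samples$population == populations[1]
  idx2 <- samples$population == populations[2]
  if (!any(idx1) || !any(idx2)) {
    abort("both populations must have at least one sample")
  }
  p1 <- colMeans(geno$dosage[idx1, , drop = FALSE]) / 2
  p2 <- colMeans(geno$dosage[idx2, , drop = FALSE]) / 2
  out <- tibble::tibble(
    snp_id = geno$snps$snp_id,
    f1 = unname(p1), f2 = unname(p2),
    delta_daf = unname(p2 - p1),
    fst = hudson_fst(p1, p2),
    ancestral_known = geno$snps$ancestral_known
  )
  names(out)[names(out) == "f1"] <- paste0("daf_", tolower(populations[1]))
  names(out)[names(out) == "f2"] <- paste0("daf_", tolower(populations[2]))
  out
}

#' @rdname allele_frequencies
#' @param p1,p2 Allele frequencies in the two populations.
#' @export
hudson_fst <- function(p1, p2) {
  num <- (p1 - p2)^2
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  ifelse(den == 0, 0, unname(num / den))
}

#' Genetic contribution to a population methylation difference (ExpDiff)
#'
#' For a CpG with a meQTL, the expected population difference in
#' methylation attributable to the variant is the meQTL effect of the
#' derived allele times the derived-allele frequency difference; ExpDiff
#' expresses it as a share of the observed difference:
#' \deqn{ExpDiff = \beta \times \Delta DAF / \Delta Meth.}
#' The ratio is deliberately not bounded to \[0, 1\]: genetics can be
#' counteracted or reinforced by independent (e.g. environmental) effects.
#' Records with `delta_meth = 0` are flagged undefined and excluded from
#' summary means.
#'
#' @param records A data frame with columns `beta` (meQTL effect of the
#'   derived allele), `delta_daf` (EUB - AFB frequency difference) and
#'   `delta_meth` (observed EUB - AFB mean methylation difference), plus any
#'   id columns carried through.
#' @return The input tibble with `exp_diff` and `exp_diff_defined` added;
#'   the mean of defined ratios is available via attribute
#'   `mean_exp_diff` and [glance()].
#' @examples
#' exp_diff(data.frame(beta = 0.1, delta_daf = 0.5, delta_meth = 0.05))
#' @export
exp_diff <- function(records) {
  records <- tibble::as_tibble(records)
  stopifnot(all(c("beta", "delta_daf", "delta_meth") %in% names(records)))
  out <- dplyr::mutate(
    records,
    exp_diff_defined = .data$delta_meth != 0,
    exp_diff = ifelse(.data$exp_diff_defined,
                      .data$beta * .data$delta_daf / .data$delta_meth,
                      NA_real_)
  )
  class(out) <- c("exp_diff_result", class(out))
  attr(out, "mean_exp_diff") <- mean(out$exp_diff[out$exp_diff_defined])
  out
}

#' @method glance exp_diff_result
#' @export
glance.exp_diff_result <- function(x, ...) {
  tibble::tibble(
    n = nrow(x),
    n_defined = sum(x$exp_diff_defined),
    mean_exp_diff = attr(x, "mean_exp_diff"),
    median_exp_diff = median(x$exp_diff[x$exp_diff_defined])
  )
}

# Maximized Gaussian log-likelihood of an OLS fit (profiled variance).
.lm_loglik <- function(y, X) {
  fit <- lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  n <- length(y)
  -n / 2 * (log(2 * pi * rss / n) + 1)
}

#' Classify a meQTL effect as shared or population-specific
#'
#' Bayesian model selection among three Gaussian linear models of a CpG's
#' M values:
#' (i) `Meth ~ SNP + Pop` (shared effect),
#' (ii) `Meth ~ SNP_EUB + Pop` (effect only in the second population), and
#' (iii) `Meth ~ SNP_AFB + Pop` (effect only in the first population),
#' where `SNP_EUB` is the dosage in EUB individuals and 0 in AFB (and
#' symmetrically for `SNP_AFB`). All three models have the same number of
#' parameters and are equally likely a priori, so posterior probabilities
#' are the softmax of the maximized log-likelihoods (computed in log space
#' via log-sum-exp). A call of `EUB_specific`/`AFB_specific` requires that
#' model's posterior to exceed `threshold` (default 0.9); otherwise the
#' call is `shared` when model (i) has the top posterior, else
#' `undetermined`.
#'
#' @param meth_vector Numeric M values, one per sample.
#' @param dosage Additive dosages, one per sample.
#' @param samples Sample table with `population`.
#' @param threshold Posterior probability required for a specific call.
#' @param populations The two labels in (AFB, EUB) order; defaults to
#'   sorted labels.
#' @return One-row tibble: `posterior_shared`, `posterior_afb_specific`,
#'   `posterior_eub_specific`, `call`.
#' @export
classify_specificity <- function(meth_vector, dosage, samples,
                                 threshold = 0.9, populations = NULL) {
  samples <- tibble::as_tibble(samples)
  if (is.null(populations)) populations <- sort(unique(samples$population))
  if (sd(meth_vector) == 0) abort("constant methylation vector")
  pop2 <- as.numeric(samples$population == populations[2])
  snp_p2 <- dosage * pop2            # dosage in pop2 (EUB), 0 in pop1
  snp_p1 <- dosage * (1 - pop2)      # dosage in pop1 (AFB), 0 in pop2
  X0 <- cbind(1, pop2)
  ll <- c(
    shared = .lm_loglik(meth_vector, cbind(X0, dosage)),
    eub = .lm_loglik(meth_vector, cbind(X0, snp_p2)),
    afb = .lm_loglik(meth_vector, cbind(X0, snp_p1))
  )
  m <- max(ll)
  post <- exp(ll - m) / sum(exp(ll - m))
  call <- if (post[["eub"]] > threshold) {
    paste0(populations[2], "_specific")
  } else if (post[["afb"]] > threshold) {
    paste0(populations[1], "_specific")
  } else if (which.max(post) == 1L) "shared" else "undetermined"
  tibble::tibble(
    posterior_shared = post[["shared"]],
    posterior_afb_specific = post[["afb"]],
    posterior_eub_specific = post[["eub"]],
    call = call
  )
}
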