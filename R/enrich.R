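# Genomic-context odds-ratio enrichment and LD-aware frequency-matched
# resampling enrichment against GWAS catalogs.

#' Genomic-context enrichment of a CpG set
#'
#' Tests whether a query CpG set is enriched in an annotation category
#' (genic context such as TSS200/Body, or a regulatory flag such as
#' enhancer) against the general distribution of the background CpG
#' universe: a 2x2 table comparing the query's category split against the
#' general distribution of the whole background (query in/out of category
#' vs background in/out of category), Fisher's exact p, and a Woolf
#' logit-interval 95% CI on the odds ratio. Zero cells get the
#' Haldane-Anscombe 0.5 correction for the CI (flagged).
#'
#' @param query_cpgs Character vector of CpG ids; must be a subset of the
#'   background.
#' @param background CpG annotation tibble containing `cpg_id` and the
#'   category column.
#' @param category Name of a logical column of `background`, or a value of
#'   its `context` column.
#' @return One-row tibble: `category`, `odds_ratio`, `ci_low`, `ci_high`,
#'   `p_fisher`, the four table counts `a`,`b`,`c`,`d`, and
#'   `haldane_corrected`.
#' @export
context_enrichment <- function(query_cpgs, background, category) {
  background <- tibble::as_tibble(background)
  if (!length(query_cpgs)) abort("empty query CpG set")
  if (!all(query_cpgs %in% background$cpg_id)) {
    abort("query CpGs must be a subset of the background")
  }
  in_cat <- if (category %in% names(background) &&
                is.logical(background[[category]])) {
    background[[category]]
  } else if ("context" %in% names(background)) {
    background$context == category
  } else {
    abort(paste0("category '", category, "' not found in background"))
  }
  in_q <- background$cpg_id %in% query_cpgs
  a <- sum(in_q & in_cat); b <- sum(in_q & !in_cat)
  c_ <- sum(in_cat); d <- sum(!in_cat)
  p <- fisher.test(matrix(c(a, c_, b, d), 2))$p.value
  corrected <- any(c(a, b, c_, d) == 0)
  if (corrected) {
    ah <- a + 0.5; bh <- b + 0.5; ch <- c_ + 0.5; dh <- d + 0.5
  } else {
    ah <- a; bh <- b; ch <- c_; dh <- d
  }
  or <- (ah * dh) / (bh * ch)
  se_log <- sqrt(1 / ah + 1 / bh + 1 / ch + 1 / dh)
  tibble::tibble(
    category = category,
    odds_ratio = if (b * c_ > 0) (a * d) / (b * c_) else or,
    ci_low = exp(log(or) - 1.96 * se_log),
    ci_high = exp(log(or) + 1.96 * se_log),
    p_fisher = p,
    a = a, b = b, c = c_, d = d,
    haldane_corrected = corrected
  )
}

#' Greedy LD pruning
#'
#' Keeps one SNP per independent locus: SNPs are visited in ascending
#' p-value order (or genomic position when no scores are given) and kept
#' only if their R-squared with every already-kept SNP is below the
#' threshold.
#'
#' @param snps Tibble with `snp_id` and optionally `p` (scores) or `pos`.
#' @param ld Pairwise LD tibble `(snp_a, snp_b, r2)`; treated as symmetric,
#'   absent pairs mean R-squared 0.
#' @param r2_threshold Pruning threshold (default 0.8).
#' @return Character vector of retained SNP ids.
#' @export
ld_prune <- function(snps, ld, r2_threshold = 0.8) {
  snps <- tibble::as_tibble(snps)
  ord <- if ("p" %in% names(snps)) {
    order(snps$p)
  } else if ("pos" %in% names(snps)) {
    order(snps$pos)
  } else {
    seq_len(nrow(snps))
  }
  ids <- snps$snp_id[ord]
  ld <- tibble::as_tibble(ld)
  ld2 <- dplyr::bind_rows(
    ld[, c("snp_a", "snp_b", "r2")],
    tibble::tibble(snp_a = ld$snp_b, snp_b = ld$snp_a, r2 = ld$r2)
  )
  ld2 <- ld2[ld2$r2 >= r2_threshold, ]
  nbr <- split(ld2$snp_b, ld2$snp_a)
  kept <- character(0)
  kept_set <- new.env(hash = TRUE)
  for (s in ids) {
    partners <- nbr[[s]]
    clash <- !is.null(partners) &&
      any(vapply(partners, function(p) !is.null(kept_set[[p]]), logical(1)))
    if (!clash) {
      kept <- c(kept, s)
      kept_set[[s]] <- TRUE
    }
  }
  kept
}

# Assign pooled allele frequencies to 5%-wide bins.
.freq_bin <- function(freq, bin_width = 0.05) {
  pmin(floor(freq / bin_width), floor(1 / bin_width) - 1e-9)
}

#' GWAS-hit enrichment by frequency-matched resampling
#'
#' Tests whether a query SNP set (e.g. LD-pruned meQTLs) overlaps GWAS hits
#' of each parent trait category more than expected. The null is built by
#' resampling, `n_resamples` times, `|query|` SNPs from the LD-pruned
#' background while exactly matching the query's allele-frequency histogram
#' in bins of width `bin_width` (default 5%). The fold enrichment is the
#' observed overlap divided by the mean resampled overlap; the one-sided
#' enrichment p comes from a normal distribution fitted to the resampled
#' counts (method of moments), and the 95% CI from `n_resamples` bootstrap
#' draws of the query set (an independent seeded stream).
#'
#' @param query_snps Character vector of query SNP ids (already LD-pruned).
#' @param gwas_table Tibble `(snp_id, trait, parent_category, p)` of GWAS
#'   hits (pre-filtered at genome-wide significance and LD-expanded).
#' @param background_snps Character vector of background SNP ids (already
#'   LD-pruned; the resampling pool).
#' @param freq Tibble with `snp_id` and the pooled derived-allele
#'   frequency in column `freq` (or the mean of per-population `daf_*`
#'   columns from [allele_frequencies()]).
#' @param n_resamples Number of matched resamples (default 10000).
#' @param bin_width Frequency bin width (default 0.05).
#' @param seed Integer seed; the report is bit-reproducible given the seed.
#' @param categories Categories to test (default: all in `gwas_table`).
#' @param depletion Also report the one-sided depletion p (default FALSE).
#' @return Tibble of class `gwas_enrichment`, one row per category:
#'   `category`, `observed_count`, `resample_mean`, `resample_sd`, `fold`,
#'   `ci_low`, `ci_high`, `p_normal_fit`, `n_resamples`.
#' @export
gwas_enrichment <- function(query_snps, gwas_table, background_snps, freq,
                            n_resamples = 10000, bin_width = 0.05,
                            seed = 1L, categories = NULL,
                            depletion = FALSE) {
  if (!length(query_snps)) abort("empty query SNP set")
  gwas_table <- tibble::as_tibble(gwas_table)
  if (!nrow(gwas_table)) abort("empty GWAS hit table: fold is undefined")
  freq <- tibble::as_tibble(freq)
  if (!"freq" %in% names(freq)) {
    daf_cols <- grep("^daf_", names(freq), value = TRUE)
    if (!length(daf_cols)) abort("freq table needs a 'freq' or daf_* columns")
    freq$freq <- rowMeans(freq[daf_cols])
  }
  fr <- setNames(freq$freq, freq$snp_id)
  if (!all(query_snps %in% names(fr)) || !all(background_snps %in% names(fr))) {
    abort("all query and background SNPs need a frequency")
  }
  qbin <- .freq_bin(fr[query_snps], bin_width)
  bbin <- .freq_bin(fr[background_snps], bin_width)
  by_bin <- split(background_snps, bbin)
  qcount <- table(qbin)
  missing_bins <- setdiff(names(qcount), names(by_bin))
  if (length(missing_bins)) {
    abort(paste0("query frequency bin(s) unrepresented in background: ",
                 paste(as.numeric(missing_bins) * bin_width, collapse = ", ")))
  }
  if (is.null(categories)) categories <- unique(gwas_table$parent_category)
  hit_sets <- lapply(categories,
                     function(ct) unique(gwas_table$snp_id[
                       gwas_table$parent_category == ct]))
  names(hit_sets) <- categories

  # matched resamples: draw per-bin without replacement, count overlaps
  set.seed(seed)
  counts <- matrix(0L, nrow = n_resamples, ncol = length(categories),
                   dimnames = list(NULL, categories))
  for (b in seq_len(n_resamples)) {
    draw <- unlist(lapply(names(qcount), function(bn) {
      pool <- by_bin[[bn]]
      k <- qcount[[bn]]
      if (length(pool) == 1L) rep(pool, k)
      else sample(pool, k, replace = k > length(pool))
    }), use.names = FALSE)
    for (ci in seq_along(categories)) {
      counts[b, ci] <- sum(draw %in% hit_sets[[ci]])
    }
  }

  # bootstrap CI on the fold: independent seeded stream over the query
  set.seed(seed + 104729L)
  res <- lapply(seq_along(categories), function(ci) {
    hs <- hit_sets[[ci]]
    obs <- sum(query_snps %in% hs)
    mu <- mean(counts[, ci]); sdv <- sd(counts[, ci])
    fold <- if (mu > 0) obs / mu else NA_real_
    boot <- vapply(seq_len(n_resamples), function(i) {
      qb <- sample(query_snps, length(query_snps), replace = TRUE)
      if (mu > 0) sum(qb %in% hs) / mu else NA_real_
    }, numeric(1))
    ci_q <- quantile(boot, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
    p_enr <- if (sdv > 0) pnorm(obs, mean = mu, sd = sdv, lower.tail = FALSE)
             else as.numeric(obs <= mu)
    out <- tibble::tibble(
      category = categories[ci], observed_count = obs, resample_mean = mu,
      resample_sd = sdv, fold = fold, ci_low = ci_q[1], ci_high = ci_q[2],
      p_normal_fit = p_enr, n_resamples = n_resamples
    )
    if (depletion) {
      out$p_depletion <- if (sdv > 0) pnorm(obs, mean = mu, sd = sdv)
                         else as.numeric(obs >= mu)
    }
    out
  })
  out <- dplyr::bind_rows(res)
  class(out) <- c("gwas_enrichment", class(out))
  out
}

#' Forest plot of GWAS enrichment folds
#'
#' @param object A [gwas_enrichment()] result.
#' @param ... Unused.
#' @return A ggplot object of fold enrichments with bootstrap CIs.
#' @method autoplot gwas_enrichment
#' @export
autoplot.gwas_enrichment <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fold, y = .data$category)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.2) +
    ggplot2::labs(x = "fold enrichment (obs / expected)", y = NULL) +
    ggplot2::theme_minimal()
}
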