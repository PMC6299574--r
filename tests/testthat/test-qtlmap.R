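cpg_annot_for <- function(meth_or_mat, chr = "chr1", pos = NULL) {
  ids <- colnames(if (inherits(meth_or_mat, "methylation_matrix"))
    meth_or_mat$beta else meth_or_mat)
  tibble::tibble(cpg_id = ids, chr = chr,
                 pos = if (is.null(pos)) seq_along(ids) * 1000L else pos)
}

test_that("a noiseless methylation-dosage pair is overwhelmingly significant", {
  smp <- make_samples(30, 30)
  geno <- make_geno(smp, freqs = c(0.5, 0.3), seed = 4)
  M <- cbind(cg1 = geno$dosage[, 1] * 1.0)
  res <- map_cis(M, tibble::tibble(cpg_id = "cg1", chr = "chr1", pos = 1000L),
                 geno, smp)
  hit <- res[res$snp_id == "rs0001", ]
  expect_lt(hit$p_linear, 1e-10)
  expect_lt(hit$p_kw, 1e-10)
})

test_that("the cis window excludes distant SNPs and bad windows error", {
  smp <- make_samples(20, 20)
  geno <- make_geno(smp, freqs = c(0.5, 0.4), pos = c(1000L, 151000L))
  set.seed(1)
  M <- cbind(cg1 = rnorm(40))
  res <- map_cis(M, tibble::tibble(cpg_id = "cg1", chr = "chr1", pos = 1000L),
                 geno, smp, window = 1e5)
  expect_true("rs0001" %in% res$snp_id)
  expect_false("rs0002" %in% res$snp_id)
  expect_error(map_cis(M, tibble::tibble(cpg_id = "cg1", chr = "chr1",
                                         pos = 1000L),
                       geno, smp, window = -1), "positive")
})

test_that("linear and KW p-values match lm and kruskal.test per pair", {
  smp <- make_samples(25, 25, seed = 8)
  geno <- make_geno(smp, freqs = c(0.4, 0.25, 0.5), seed = 9)
  set.seed(10)
  M <- matrix(rnorm(50 * 3), 50, 3, dimnames = list(NULL, paste0("cg", 1:3)))
  M[, 1] <- M[, 1] + 0.5 * geno$dosage[, 1]
  annot <- cpg_annot_for(M)
  res <- map_cis(M, annot, geno, smp, covariates = c("age", "sv1"))
  X <- model.matrix(~ population + age + sv1, data = smp)
  for (r in sample(nrow(res), 5)) {
    row <- res[r, ]
    y <- M[, row$feature_id]; g <- geno$dosage[, row$snp_id]
    fit <- lm(y ~ g + population + age + sv1, data = smp)
    expect_equal(row$p_linear, summary(fit)$coefficients["g", 4],
                 tolerance = 1e-8)
    expect_equal(row$beta, unname(coef(fit)["g"]), tolerance = 1e-8)
    y_res <- resid(lm(y ~ population + age + sv1, data = smp))
    expect_equal(row$p_kw, kruskal.test(y_res, factor(g))$p.value,
                 tolerance = 1e-8)
  }
})

test_that("the dual-test rule only shrinks the discovery set", {
  smp <- make_samples(30, 30, seed = 12)
  geno <- make_geno(smp, freqs = runif(10, 0.2, 0.8), seed = 13)
  set.seed(14)
  M <- matrix(rnorm(60 * 8), 60, 8, dimnames = list(NULL, paste0("cg", 1:8)))
  M[, 1] <- M[, 1] + geno$dosage[, 2]
  annot <- cpg_annot_for(M)
  res <- map_cis(M, annot, geno, smp)
  both <- significant_cis(res, 1e-3, 1e-3)
  lin_only <- res[!is.na(res$p_linear) & res$p_linear <= 1e-3, ]
  expect_lte(nrow(both), nrow(lin_only))
  expect_true(all(both$p_linear <= 1e-3 & both$p_kw <= 1e-3))
})

test_that("permutation FDR follows the counting rule and its degenerate cases", {
  smp <- make_samples(20, 20, seed = 21)
  geno <- make_geno(smp, freqs = rep(0.5, 4), seed = 22)
  set.seed(23)
  M <- matrix(rnorm(40 * 30), 40, 30, dimnames = list(NULL, paste0("cg", 1:30)))
  # 10% strong planted signals
  for (j in 1:3) M[, j] <- M[, j] + 2 * geno$dosage[, j %% 4 + 1]
  annot <- cpg_annot_for(M)
  mapper <- function(f) map_cis(f, annot, geno, smp)
  thr <- permutation_fdr(M, smp, mapper, n_perm = 20, seed = 30)
  # brute-force re-evaluation of FDR(t) from the returned permutation minima
  obs <- mapper(M)
  obs_min <- tapply(obs$p_linear, obs$feature_id, min)
  for (t in c(1e-6, 1e-4, 1e-2)) {
    n_obs <- sum(obs_min <= t)
    mean_null <- mean(rowSums(thr$permuted_minima <= t, na.rm = TRUE))
    got <- thr$grid$fdr[thr$grid$threshold == t]
    if (n_obs > 0) expect_equal(got, min(mean_null / n_obs, 1))
  }
  expect_true(is.finite(thr$p_star))
  # FDR is monotone non-increasing as the threshold tightens
  fdr_seq <- thr$grid$fdr[!is.na(thr$grid$fdr)]
  expect_true(all(diff(fdr_seq) >= -1e-12))
  # degenerate null: the observed data as every permutation gives FDR ~ 1
  thr_deg <- permutation_fdr(M, smp, function(f) mapper(M), n_perm = 10,
                             seed = 31)
  expect_false(thr_deg$attainable && thr_deg$p_star < 1e-2)
})

test_that("stepwise conditioning separates independent signals and collapses proxies", {
  smp <- make_samples(78, 78, seed = 41)
  n <- nrow(smp)
  set.seed(42)
  g1 <- rbinom(n, 2, 0.5)
  g2 <- rbinom(n, 2, 0.4)          # unlinked second causal SNP
  g3 <- ifelse(runif(n) < 0.975, g1, rbinom(n, 2, 0.5))  # proxy of g1
  noise <- rnorm(n, 0, 0.5)
  dos <- cbind(rs0001 = g1, rs0002 = g2, rs0003 = g3)
  rownames(dos) <- smp$sample_id
  geno <- genotype_matrix(dos, tibble::tibble(
    snp_id = colnames(dos), chr = "chr1", pos = c(1000L, 2000L, 3000L)))
  annot <- tibble::tibble(cpg_id = "cg1", chr = "chr1", pos = 1500L)

  # two independent causal SNPs -> ranks 1 and 2
  M2 <- cbind(cg1 = 1.0 * g1 + 0.8 * g2 + noise)
  steps <- stepwise_conditional("cg1", M2, annot, geno, smp, p_star = 1e-5)
  expect_gte(nrow(steps), 2)
  expect_setequal(steps$snp_id[1:2], c("rs0001", "rs0002"))
  expect_equal(steps$conditional_rank[1:2], c(1L, 2L))

  # one causal SNP plus an R2 ~ 0.95 proxy -> a single rank
  expect_gt(cor(g1, g3)^2, 0.9)
  M1 <- cbind(cg1 = 1.0 * g1 + noise)
  steps1 <- stepwise_conditional("cg1", M1, annot, geno, smp, p_star = 1e-5)
  expect_equal(nrow(steps1), 1)
  expect_equal(steps1$snp_id, "rs0001")

  # null feature -> empty result
  M0 <- cbind(cg1 = rnorm(n))
  steps0 <- stepwise_conditional("cg1", M0, annot, geno, smp, p_star = 1e-5)
  expect_equal(nrow(steps0), 0)
})

test_that("trans mapping enforces the distance rule and recovers a planted hub", {
  smp <- make_samples(78, 78, seed = 51)
  n <- nrow(smp)
  set.seed(52)
  hub <- rbinom(n, 2, 0.5)
  dos <- cbind(rs0001 = hub, rs0002 = rbinom(n, 2, 0.5))
  rownames(dos) <- smp$sample_id
  geno <- genotype_matrix(dos, tibble::tibble(
    snp_id = colnames(dos), chr = c("chr1", "chr1"),
    pos = c(5000L, 2000000L)))
  genes <- tibble::tibble(gene_id = "tf1", chr = "chr1", tss = 6000L,
                          is_tf = TRUE)
  # 15 distant CpGs driven by the hub + 10 null CpGs + one near CpG
  n_cpg <- 26
  M <- matrix(rnorm(n * n_cpg, 0, 0.5), n, n_cpg)
  for (j in 1:15) M[, j] <- M[, j] + 1.0 * hub
  colnames(M) <- sprintf("cg%02d", seq_len(n_cpg))
  cpg_annot <- tibble::tibble(
    cpg_id = colnames(M),
    chr = c(rep("chr2", 15), rep("chr2", 10), "chr1"),
    pos = c(seq_len(25) * 1000L, 500000L)
  )
  meth <- methylation_matrix(m_to_beta(M * 0.2),
                             sample_ids = smp$sample_id)
  res <- map_trans(meth, cpg_annot, geno, genes, samples = smp,
                   covariates = c("age"))
  # the same-chromosome CpG 495 kb away is never tested
  expect_false("cg26" %in% res$feature_id)
  hub_hits <- res[res$snp_id == "rs0001" & res$feature_id %in%
                    sprintf("cg%02d", 1:15), ]
  expect_gte(sum(hub_hits$p_kw < 1e-9), 14)
  # empty candidate universe errors
  expect_error(map_trans(meth, cpg_annot, geno,
                         dplyr::mutate(genes, is_tf = FALSE),
                         samples = smp),
               "empty")
})

test_that("fold change applies the +1 guard", {
  fc <- fold_change(3, 1)
  expect_equal(fc$diff, 1); expect_equal(fc$fold, 2)
  fc0 <- fold_change(5, 5)
  expect_equal(fc0$diff, 0); expect_equal(fc0$fold, 1)
  expect_equal(fold_change(0, 0)$diff, 0)
  expect_error(fold_change(-1, 2), "non-negative")
})

test_that("eQTM mapping is rank-invariant and window-limited", {
  smp <- make_samples(30, 30, seed = 61)
  n <- nrow(smp)
  set.seed(62)
  M <- matrix(rnorm(n * 2), n, 2, dimnames = list(smp$sample_id,
                                                  c("cg01", "cg02")))
  meth <- methylation_matrix(m_to_beta(M))
  # expression = monotone transform of methylation -> |rho| = 1 per scope
  E <- cbind(geneA = exp(M[, 1]))
  gene_annot <- tibble::tibble(gene_id = "geneA", chr = "chr1", tss = 1000L)
  cpg_annot <- tibble::tibble(cpg_id = c("cg01", "cg02"), chr = "chr1",
                              pos = c(2000L, 200000L))
  res <- map_eqtm(E, gene_annot, meth, cpg_annot, smp, scope = "AFB")
  expect_equal(res$rho_spearman[res$cpg_id == "cg01"], 1)
  # the CpG 199 kb from the TSS is outside the 100 kb window
  expect_false("cg02" %in% res$cpg_id)
})

test_that("a planted negative eQTM is detected in most replicates", {
  n <- 156
  hits <- 0L
  n_rep <- 200
  set.seed(63)
  for (r in seq_len(n_rep)) {
    m <- rnorm(n)
    e <- -0.5 / sqrt(1 - 0.5^2) * m + rnorm(n)  # corr = -0.5
    rho <- cor(e, m, method = "spearman")
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(abs(tstat), n - 2, lower.tail = FALSE)
    if (p < 5e-5 && rho < 0) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.9)
})
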