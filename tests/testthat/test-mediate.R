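assoc_stub <- function(feature, predictor, pred_col = "snp_id") {
  out <- tibble::tibble(feature_id = feature)
  out[[pred_col]] <- predictor
  out
}

test_that("trio detection intersects the three association sets", {
  eqtl <- assoc_stub("geneA", "rs1")
  meqtl <- assoc_stub("cg1", "rs1")
  eqtm <- assoc_stub("geneA", "cg1", "cpg_id")
  tr <- detect_trios(eqtl, meqtl, eqtm)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$gene_id, "geneA")
  # shared SNP but CpG not an eQTM of that gene -> no trio
  tr0 <- detect_trios(eqtl, meqtl, assoc_stub("geneB", "cg1", "cpg_id"))
  expect_equal(nrow(tr0), 0)
  # multiple CpGs and SNPs group into a single trio per gene
  eqtl2 <- assoc_stub(rep("geneA", 3), c("rs1", "rs2", "rs3"))
  meqtl2 <- assoc_stub(c("cg1", "cg1", "cg2"), c("rs1", "rs2", "rs3"))
  eqtm2 <- assoc_stub(rep("geneA", 2), c("cg1", "cg2"), "cpg_id")
  tr2 <- detect_trios(eqtl2, meqtl2, eqtm2)
  expect_equal(nrow(tr2), 1)
  expect_equal(tr2$n_cpgs, 2)
  expect_equal(tr2$n_snps, 3)
})

test_that("elastic-net summaries recover signal and flag degenerate fits", {
  set.seed(5)
  n <- 200
  x <- rnorm(n)
  # duplicated collinear predictors
  P <- cbind(a = x, b = x)
  y <- x + rnorm(n, 0, 0.3)
  s <- elastic_net_summary(y, P, seed = 2)
  expect_gt(cor(s$summary, x), 0.99)
  # one informative predictor among 10 noise columns dominates
  P2 <- cbind(info = x, matrix(rnorm(n * 10), n,
                               dimnames = list(NULL, paste0("n", 1:10))))
  y2 <- x + rnorm(n, 0, 0.5)
  s2 <- elastic_net_summary(y2, P2, seed = 3)
  cf <- abs(s2$coefficients)
  expect_gt(cf["info"] / max(cf[-1], 1e-6), 5)
  # independent target triggers the lambda.min fallback
  y3 <- rnorm(n)
  expect_warning(s3 <- elastic_net_summary(y3, P2, seed = 4), "lambda.1se")
  expect_true(s3$fallback)
  expect_error(elastic_net_summary(rep(1, n), P2), "constant")
  expect_error(elastic_net_summary(y, P[, 1, drop = FALSE]), "2 predictors")
})

test_that("the mediation decomposition identity holds exactly", {
  set.seed(11)
  n <- 300
  g <- rbinom(n, 2, 0.4)
  m <- 0.6 * g + rnorm(n)
  e <- 0.5 * m + 0.3 * g + rnorm(n)
  cv <- cbind(age = rnorm(n))
  res <- mediate_trio(NULL, e, g, m, covariates = cv, n_draws = 500, seed = 9)
  # acme + ade = total, and total equals the total-effect regression slope
  expect_equal(res$acme + res$ade, res$total, tolerance = 1e-12)
  tot <- unname(coef(lm(e ~ g + cv))["g"])
  expect_equal(res$total, tot, tolerance = 1e-8)
  expect_true(res$p_acme >= 0 && res$p_acme <= 1)
})

test_that("ACME matches the closed-form product of standardized slopes", {
  p <- sim_params(alpha = 0.49, beta = 1, tau = 0, gamma = 0.25,
                  n_samples = 5000, seed = 13)
  tr <- simulate_causal_trio(p)
  res <- mediate_trio(NULL, tr$expression, tr$genotype_std, tr$methylation,
                      n_draws = 1000, seed = 14)
  expect_equal(res$acme, sqrt(0.49) * sqrt(0.25), tolerance = 0.02)
  expect_lt(res$p_acme, 1e-10)
})

test_that("partial correlation equals the residual-correlation construction", {
  set.seed(21)
  n <- 80
  for (i in 1:5) {
    g <- rnorm(n); m <- 0.5 * g + rnorm(n); e <- 0.3 * m + rnorm(n)
    pc <- partial_correlation_test(e, m, g)
    oracle <- cor(resid(lm(e ~ g)), resid(lm(m ~ g)))
    expect_equal(pc$pcor, oracle, tolerance = 1e-12)
  }
  # E = M exactly, G independent -> pcor = 1
  m <- rnorm(n); g <- rnorm(n)
  expect_equal(partial_correlation_test(m, m, g)$pcor, 1, tolerance = 1e-10)
  expect_error(partial_correlation_test(rep(1, n), m, g), "constant")
  expect_error(partial_correlation_test(1:3, 1:3, 1:3), "4 observations")
})

test_that("mediation across planted trios flags the mediated gene", {
  set.seed(31)
  n <- 156
  g1 <- rbinom(n, 2, 0.5); g2 <- rbinom(n, 2, 0.5)
  m1 <- 0.8 * g1 + rnorm(n, 0, 0.5)
  e_med <- 0.8 * m1 + rnorm(n, 0, 0.5)         # fully mediated gene
  e_null <- 0.5 * g2 + rnorm(n, 0, 0.5)        # direct-only gene
  smp_ids <- sprintf("s%03d", 1:n)
  dos <- cbind(rs1 = g1, rs2 = g2); rownames(dos) <- smp_ids
  geno <- genotype_matrix(dos, tibble::tibble(snp_id = c("rs1", "rs2"),
                                              chr = "chr1",
                                              pos = c(100L, 200L)))
  M <- cbind(cg1 = m1 * 0.3, cg2 = rnorm(n) * 0.3)
  rownames(M) <- smp_ids
  meth <- methylation_matrix(m_to_beta(M))
  E <- cbind(geneA = e_med, geneB = e_null); rownames(E) <- smp_ids
  trios <- detect_trios(
    assoc_stub(c("geneA", "geneB"), c("rs1", "rs2")),
    assoc_stub(c("cg1", "cg2"), c("rs1", "rs2")),
    assoc_stub(c("geneA", "geneB"), c("cg1", "cg2"), "cpg_id")
  )
  res <- mediate_trios(trios, E, geno, meth, n_draws = 1000, seed = 8)
  expect_true(res$mediated[res$gene_id == "geneA"])
  expect_lt(res$p_acme[res$gene_id == "geneA"],
            res$p_acme[res$gene_id == "geneB"])
  # BH q-values are monotone in p
  expect_true(all(diff(res$q_value[order(res$p_acme)]) >= -1e-12))
})

test_that("the benchmark separates high-power regimes and degenerate cells", {
  grid <- tibble::tibble(alpha = 0.8, beta = 0.9, tau = 0.1, gamma = 0.25)
  bench <- benchmark_mediation(grid, n_replicates = 60, n_samples = 1000,
                               n_draws = 300, seed = 17)
  expect_gt(bench$auc_mediation, 0.95)
  expect_gt(bench$auc_pcor, 0.95)
  # beta = 0 everywhere -> no mediated truths, AUC undefined
  grid0 <- tibble::tibble(alpha = 0.5, beta = 0, tau = 1, gamma = 0.25)
  bench0 <- benchmark_mediation(grid0, n_replicates = 20, n_samples = 200,
                                n_draws = 200, seed = 18)
  expect_true(bench0$degenerate)
  expect_true(is.na(bench0$auc_mediation))
})
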