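test_that("sim_params enforces its variance-share invariants", {
  expect_error(sim_params(1.2, 1, 0, 0.25, 100), "\\[0, 1\\]")
  expect_error(sim_params(0.5, 1, 1, 0.9, 100), "noise weight")
  expect_error(sim_params(0.5, 1, 0, 0.25, 5), "at least 10")
  p <- sim_params(0.5, 0.4, 0.2, 0.25, 100)
  expect_false(p$beta_tau_closed)
  expect_true(sim_params(0.5, 0.4, 0.6, 0.25, 100)$beta_tau_closed)
})

test_that("the causal trio construction has unit variances and planted slopes", {
  p <- sim_params(alpha = 0.5, beta = 1, tau = 0, gamma = 0.25,
                  n_samples = 1e5, seed = 11)
  tr <- simulate_causal_trio(p)
  expect_equal(var(tr$methylation), 1, tolerance = 0.02)
  expect_equal(var(tr$expression), 1, tolerance = 0.02)
  # joint regression of E on (G_std, M_std) recovers sqrt(gamma*tau) and
  # sqrt(gamma*beta) within Monte-Carlo error
  fit <- lm(expression ~ genotype_std + methylation_std, data = tr)
  expect_equal(unname(coef(fit)["methylation_std"]), sqrt(0.25 * 1),
               tolerance = 0.02)
  expect_equal(unname(coef(fit)["genotype_std"]), 0, tolerance = 0.02)
  p2 <- sim_params(alpha = 0.4, beta = 0.6, tau = 0.4, gamma = 0.5,
                   n_samples = 1e5, seed = 12)
  tr2 <- simulate_causal_trio(p2)
  fit2 <- lm(expression ~ genotype_std + methylation_std, data = tr2)
  expect_equal(unname(coef(fit2)["methylation_std"]), sqrt(0.5 * 0.6),
               tolerance = 0.02)
  expect_equal(unname(coef(fit2)["genotype_std"]), sqrt(0.5 * 0.4),
               tolerance = 0.02)
  # residual contract: with beta + tau = 1 the unexplained share is 1 - gamma
  expect_equal(var(resid(fit2)), 1 - 0.5, tolerance = 0.02)
})

test_that("degenerate variance shares decouple the planted links", {
  p <- sim_params(alpha = 0, beta = 0.5, tau = 0.5, gamma = 0.5,
                  n_samples = 2e4, seed = 13)
  tr <- simulate_causal_trio(p)
  expect_lt(abs(cor(tr$genotype, tr$methylation)), 0.02)
  p0 <- sim_params(alpha = 0.5, beta = 0.5, tau = 0.5, gamma = 0,
                   n_samples = 2e4, seed = 14, scenario = "null")
  tr0 <- simulate_causal_trio(p0)
  expect_lt(abs(cor(tr0$expression, tr0$genotype)), 0.02)
  expect_lt(abs(cor(tr0$expression, tr0$methylation)), 0.02)
})

test_that("trio and cohort simulations are seed-deterministic", {
  p <- sim_params(0.5, 1, 0, 0.25, 500, seed = 21)
  expect_identical(simulate_causal_trio(p), simulate_causal_trio(p))
  spec <- population_spec(n_per_pop = c(12, 12), n_blocks = 2,
                          snps_per_block = 8, n_cpgs = 20, n_genes = 6)
  c1 <- simulate_cohort(spec, seed = 9)
  c2 <- simulate_cohort(spec, seed = 9)
  expect_identical(c1$geno$dosage, c2$geno$dosage)
  expect_identical(c1$meth$beta, c2$meth$beta)
  expect_identical(c1$expr$NS$fpkm, c2$expr$NS$fpkm)
})

test_that("cohort beta values stay in (0,1) and M round-trips", {
  spec <- population_spec(n_per_pop = c(15, 15), n_blocks = 2,
                          snps_per_block = 10, n_cpgs = 30, n_genes = 8)
  coh <- simulate_cohort(spec, seed = 4)
  b <- coh$meth$beta
  expect_true(all(b > 0 & b < 1))
  expect_equal(m_to_beta(m_values(coh$meth)), b, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("planted effect maps are validated against the layout", {
  spec <- population_spec(n_per_pop = c(10, 10), n_blocks = 2,
                          snps_per_block = 10, n_cpgs = 20, n_genes = 5)
  lay <- cohort_layout(spec, seed = 2)
  expect_error(
    planted_effects(meqtl = tibble::tibble(snp_id = "nope", cpg_id = "cg00001",
                                           effect = 1), layout = lay),
    "unknown SNP")
  # a cis link farther than the window is rejected
  far_cpg <- lay$cpgs$cpg_id[lay$cpgs$chr != lay$snps$chr[1]][1]
  expect_error(
    planted_effects(meqtl = tibble::tibble(snp_id = lay$snps$snp_id[1],
                                           cpg_id = far_cpg, effect = 1),
                    layout = lay),
    "cis window")
})

test_that("a planted cis-meQTL is the top association in its window", {
  spec <- population_spec(n_per_pop = c(78, 78), n_blocks = 2,
                          snps_per_block = 20, n_cpgs = 40, n_genes = 5,
                          meth_noise_sd = 0.5)
  lay <- cohort_layout(spec, seed = 31)
  # pick a SNP/CpG pair on the same block within 100 kb
  pair <- NULL
  for (i in seq_len(nrow(lay$snps))) {
    j <- which(lay$cpgs$chr == lay$snps$chr[i] &
                 abs(lay$cpgs$pos - lay$snps$pos[i]) <= 1e5)
    if (length(j)) { pair <- c(i, j[1]); break }
  }
  eff <- planted_effects(
    meqtl = tibble::tibble(snp_id = lay$snps$snp_id[pair[1]],
                           cpg_id = lay$cpgs$cpg_id[pair[2]], effect = 1.0),
    layout = lay)
  coh <- simulate_cohort(spec, eff, seed = 31, layout = lay)
  res <- map_cis(m_values(coh$meth), lay$cpgs, coh$geno, coh$samples,
                 covariates = c("age", "sv1", "sv2"))
  hit <- res[res$feature_id == lay$cpgs$cpg_id[pair[2]], ]
  best <- hit$snp_id[which.min(hit$p_linear)]
  # best SNP is the planted one or a near-perfect LD proxy of it
  r2 <- cor(coh$geno$dosage[, best],
            coh$geno$dosage[, lay$snps$snp_id[pair[1]]])^2
  expect_gt(r2, 0.8)
})

test_that("a planted delta-beta shift is flagged as DMS", {
  spec <- population_spec(n_per_pop = c(78, 78), n_blocks = 2,
                          snps_per_block = 5, n_cpgs = 60, n_genes = 5)
  lay <- cohort_layout(spec, seed = 32)
  eff <- planted_effects(
    pop_shift = tibble::tibble(cpg_id = "cg00007", delta_beta = 0.2),
    layout = lay)
  coh <- simulate_cohort(spec, eff, seed = 32, layout = lay)
  dms <- dms_scan(coh$meth, coh$samples, covariates = c("age", "sv1", "sv2"))
  expect_true(dms$is_dms[dms$cpg_id == "cg00007"])
  expect_equal(sum(dms$is_dms), 1)
})

test_that("simulated GWAS catalogs respect the hit fraction and LD structure", {
  spec <- population_spec(n_per_pop = c(40, 40), n_blocks = 3,
                          snps_per_block = 30, n_cpgs = 10, n_genes = 4)
  coh <- simulate_cohort(spec, seed = 8)
  cat1 <- simulate_gwas_catalog(coh$geno, n_traits = 6, hit_fraction = 0.2,
                                seed = 3)
  expect_equal(length(unique(cat1$gwas$snp_id)), round(0.2 * 90))
  expect_true(all(cat1$gwas$p < 1e-8))
  expect_true(all(cat1$ld$r2 >= 0.2 & cat1$ld$r2 <= 1))
  # hit_fraction 0 is a degenerate but allowed catalog
  cat0 <- simulate_gwas_catalog(coh$geno, hit_fraction = 0, seed = 3)
  expect_equal(nrow(cat0$gwas), 0)
  expect_error(
    simulate_gwas_catalog(genotype_matrix(matrix(0, 2, 0)[, 0, drop = FALSE],
                                          tibble::tibble(snp_id = character(0),
                                                         chr = character(0),
                                                         pos = integer(0))),
                          seed = 1),
    "empty")
})

test_that("exported VCF round-trips through an independent VCF reader", {
  spec <- population_spec(n_per_pop = c(8, 8), n_blocks = 2,
                          snps_per_block = 6, n_cpgs = 10, n_genes = 4)
  coh <- simulate_cohort(spec, seed = 77)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "genotypes.vcf")))
  v <- vcfR::read.vcfR(file.path(dir, "genotypes.vcf"), verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dos_back <- t(apply(gt, 1, function(x) {
    vapply(strsplit(x, "/"), function(a) sum(a == "1"), numeric(1))
  }))
  expect_equal(unname(dos_back), unname(t(coh$geno$dosage)))
  expect_equal(rownames(dos_back), coh$geno$snps$snp_id)
  d <- read_matrix_tsv(file.path(dir, "dosage.tsv"))
  expect_equal(d, coh$geno$dosage, tolerance = 0,
               ignore_attr = FALSE)
})
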