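#' Parameters of the causal trio simulation
#'
#' The causal simulation builds one SNP--CpG--gene trio from four variance
#' shares: `alpha`, the fraction of methylation variance explained by
#' genotype; `gamma`, the total fraction of expression variance explained by
#' genotype and methylation jointly; and `beta`/`tau`, the mediated and
#' direct shares of that explained fraction. The canonical mediation grid
#' keeps `beta + tau = 1`; relaxing it is permitted (the noise weight simply
#' absorbs the rest) and is recorded in the returned object.
#'
#' @param alpha,beta,tau,gamma Variance shares, each in \[0, 1\];
#'   `gamma * (beta + tau)` must not exceed 1 or the expression noise weight
#'   would be negative.
#' @param n_samples Number of individuals (>= 10).
#' @param seed Integer seed.
#' @param scenario One of `"mediation"` (genotype drives methylation which
#'   drives expression), `"direct_only"` (`beta = 0`), `"independent"`
#'   (`alpha = 0`, no genotype-methylation link) or `"null"` (`gamma = 0`).
#'   Purely a label; the variance shares define the data.
#' @return A `sim_params` list.
#' @export
sim_params <- function(alpha, beta, tau, gamma, n_samples, seed = 1L,
                       scenario = c("mediation", "direct_only",
                                    "independent", "null")) {
  scenario <- match.arg(scenario)
  for (nm in c("alpha", "beta", "tau", "gamma")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1) {
      abort(paste0("'", nm, "' must be a single value in [0, 1]"))
    }
  }
  if (gamma * (beta + tau) > 1 + 1e-12) {
    abort("gamma * (beta + tau) > 1: expression noise weight would be negative")
  }
  if (n_samples < 10) abort("n_samples must be at least 10")
  structure(list(alpha = alpha, beta = beta, tau = tau, gamma = gamma,
                 n_samples = as.integer(n_samples), seed = as.integer(seed),
                 scenario = scenario,
                 beta_tau_closed = isTRUE(all.equal(beta + tau, 1))),
            class = "sim_params")
}

#' Simulate one genotype--methylation--expression trio
#'
#' Implements the causal construction literally:
#' \deqn{G_{std} = (G - \bar G) / sd(G)}
#' \deqn{M = \sqrt{\alpha}\, G_{std} + \sqrt{1 - \alpha}\,\varepsilon}
#' \deqn{M_{std} = (M - \bar M) / sd(M)}
#' \deqn{E = \sqrt{\gamma\beta}\, M_{std} + \sqrt{\gamma\tau}\, G_{std} +
#'       \sqrt{1 - \gamma(\beta + \tau)}\,\zeta}
#' with \eqn{\varepsilon, \zeta} standard-normal residuals. Genotypes are
#' binomial(2, `genotype_freq`) dosages; a monomorphic draw is resampled (or
#' raised as an error when `on_monomorphic = "error"`). Runs with identical
#' parameters and seed are bit-reproducible.
#'
#' @param params A [sim_params()] object.
#' @param genotype_freq Allele frequency for the binomial genotype draw.
#' @param on_monomorphic `"resample"` (default; up to 100 redraws) or
#'   `"error"`.
#' @return A tibble with columns `genotype`, `genotype_std`, `methylation`,
#'   `methylation_std`, `expression`, one row per sample.
#' @examples
#' p <- sim_params(alpha = 0.5, beta = 1, tau = 0, gamma = 0.25,
#'                 n_samples = 200, seed = 7)
#' trio <- simulate_causal_trio(p)
#' round(var(trio$expression), 2)
#' @export
simulate_causal_trio <- function(params, genotype_freq = 0.3,
                                 on_monomorphic = c("resample", "error")) {
  stopifnot(inherits(params, "sim_params"))
  on_monomorphic <- match.arg(on_monomorphic)
  set.seed(params$seed)
  n <- params$n_samples
  g <- rbinom(n, 2L, genotype_freq)
  tries <- 0L
  while (length(unique(g)) < 2L) {
    if (on_monomorphic == "error") abort("monomorphic genotype draw")
    tries <- tries + 1L
    if (tries > 100L) abort("monomorphic genotype after 100 resamples")
    g <- rbinom(n, 2L, genotype_freq)
  }
  g_std <- .standardize(g)
  m <- sqrt(params$alpha) * g_std + sqrt(1 - params$alpha) * rnorm(n)
  m_std <- .standardize(m)
  noise_w <- 1 - params$gamma * (params$beta + params$tau)
  e <- sqrt(params$gamma * params$beta) * m_std +
    sqrt(params$gamma * params$tau) * g_std +
    sqrt(noise_w) * rnorm(n)
  tibble::tibble(genotype = g, genotype_std = g_std, methylation = m,
                 methylation_std = m_std, expression = e)
}

#' Two-population cohort specification
#'
#' Describes the simulated cohort: two ancestry groups (default 78 + 78
#' individuals, mirroring a balanced two-cohort design), SNPs organised in
#' LD blocks, CpGs and genes scattered across those blocks.
#'
#' @param labels Two population names (default `c("AFB", "EUB")`).
#' @param n_per_pop Individuals per population.
#' @param n_blocks Number of independent genomic blocks (one pseudo-
#'   chromosome each).
#' @param snps_per_block,block_length SNP count and physical span (bp) of
#'   each block.
#' @param n_cpgs,n_genes Feature counts, placed uniformly across blocks.
#' @param daf_sd Between-population spread of derived-allele frequencies:
#'   each population's frequency is the shared ancestral frequency plus an
#'   independent Normal(0, `daf_sd`) perturbation, clamped to \[0.01, 0.99\].
#' @param recomb_rate Per-bp probability of switching founder haplotype
#'   between adjacent SNPs (controls within-block LD).
#' @param n_founders Founder haplotypes per block and population.
#' @param meth_noise_sd Residual sd of methylation on the M scale.
#' @param expr_noise_sd Residual sd of log2 expression.
#' @param age_range Sampling range of ages in years.
#' @param tf_fraction Fraction of genes flagged as transcription factors.
#' @return A `population_spec` list.
#' @export
population_spec <- function(labels = c("AFB", "EUB"), n_per_pop = c(78, 78),
                            n_blocks = 4, snps_per_block = 50,
                            block_length = 1e6, n_cpgs = 200, n_genes = 40,
                            daf_sd = 0.12, recomb_rate = 1e-6,
                            n_founders = 8, meth_noise_sd = 0.3,
                            expr_noise_sd = 0.5, age_range = c(20, 50),
                            tf_fraction = 0.15) {
  stopifnot(length(labels) == 2L, length(n_per_pop) == 2L,
            all(n_per_pop >= 2), n_blocks >= 1, snps_per_block >= 1)
  structure(list(labels = labels, n_per_pop = as.integer(n_per_pop),
                 n_blocks = as.integer(n_blocks),
                 snps_per_block = as.integer(snps_per_block),
                 block_length = block_length, n_cpgs = as.integer(n_cpgs),
                 n_genes = as.integer(n_genes), daf_sd = daf_sd,
                 recomb_rate = recomb_rate, n_founders = as.integer(n_founders),
                 meth_noise_sd = meth_noise_sd, expr_noise_sd = expr_noise_sd,
                 age_range = age_range, tf_fraction = tf_fraction),
            class = "population_spec")
}

#' Genomic layout of a simulated cohort
#'
#' Draws SNP, CpG and gene positions (and per-SNP population frequencies)
#' for a [population_spec()]. The layout is deterministic given the seed, so
#' planted-effect maps can reference feature ids before the cohort matrices
#' are generated.
#'
#' @param spec A [population_spec()].
#' @param seed Integer seed.
#' @return A list of tibbles `snps` (snp_id, chr, pos, block, daf_afb,
#'   daf_eub — columns named after the configured labels), `cpgs` (cpg_id,
#'   chr, pos, context/regulatory/exclusion flags, base_beta) and `genes`
#'   (gene_id, chr, tss, is_tf).
#' @export
cohort_layout <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "population_spec"))
  set.seed(seed)
  n_snps <- spec$n_blocks * spec$snps_per_block
  block <- rep(seq_len(spec$n_blocks), each = spec$snps_per_block)
  pos <- as.integer(unlist(lapply(seq_len(spec$n_blocks), function(b) {
    sort(sample.int(spec$block_length, spec$snps_per_block))
  })))
  p0 <- runif(n_snps, 0.05, 0.95)
  clamp <- function(p) pmin(pmax(p, 0.01), 0.99)
  daf1 <- clamp(p0 + rnorm(n_snps, 0, spec$daf_sd))
  daf2 <- clamp(p0 + rnorm(n_snps, 0, spec$daf_sd))
  snps <- tibble::tibble(
    snp_id = sprintf("snp%04d", seq_len(n_snps)),
    chr = paste0("chr", block), pos = pos, block = block,
    daf_pop1 = daf1, daf_pop2 = daf2, ancestral_known = TRUE
  )
  names(snps)[names(snps) == "daf_pop1"] <- paste0("daf_", tolower(spec$labels[1]))
  names(snps)[names(snps) == "daf_pop2"] <- paste0("daf_", tolower(spec$labels[2]))

  cblock <- sample.int(spec$n_blocks, spec$n_cpgs, replace = TRUE)
  ctx <- c("TSS1500", "TSS200", "5UTR", "1stExon", "Body", "ExonBnd", "3UTR")
  cpgs <- tibble::tibble(
    cpg_id = sprintf("cg%05d", seq_len(spec$n_cpgs)),
    chr = paste0("chr", cblock), block = cblock,
    pos = sample.int(spec$block_length, spec$n_cpgs, replace = TRUE),
    context = sample(ctx, spec$n_cpgs, replace = TRUE),
    enhancer = runif(spec$n_cpgs) < 0.2,
    promoter = runif(spec$n_cpgs) < 0.2,
    cross_hybridizing = FALSE, sex_chromosome = FALSE, snp_overlap = FALSE,
    base_beta = runif(spec$n_cpgs, 0.15, 0.85)
  )
  gblock <- sample.int(spec$n_blocks, spec$n_genes, replace = TRUE)
  genes <- tibble::tibble(
    gene_id = sprintf("gene%03d", seq_len(spec$n_genes)),
    chr = paste0("chr", gblock), block = gblock,
    tss = sample.int(spec$block_length, spec$n_genes, replace = TRUE),
    is_tf = runif(spec$n_genes) < spec$tf_fraction
  )
  list(snps = snps, cpgs = cpgs, genes = genes)
}

#' Planted-effect map
#'
#' The ground-truth ledger consumed by [simulate_cohort()] and by the
#' recovery tests downstream. All referenced ids must exist in the layout;
#' cis links must fall within `cis_window` of their feature anchor and trans
#' hub links must span at least 1 Mb or different chromosomes.
#'
#' @param meqtl Tibble `(snp_id, cpg_id, effect)` — effect in M units per
#'   derived-allele copy.
#' @param eqtl Tibble `(snp_id, gene_id, effect)` — log2-expression units
#'   per allele copy.
#' @param eqtm Tibble `(cpg_id, gene_id, effect)` — log2-expression units
#'   per M-scale sd of the CpG.
#' @param pop_shift Tibble `(cpg_id, delta_beta)` — beta-scale mean shift of
#'   the second population relative to the first.
#' @param trans_hub Tibble `(snp_id, cpg_id, effect)` — one row per hub
#'   target CpG.
#' @param stim_links Tibble `(cpg_id, gene_id, effect)` — planted links
#'   between methylation and the stimulated-condition fold change.
#' @param layout Optional [cohort_layout()] against which ids and distances
#'   are validated.
#' @param cis_window Validation window in bp (default 1e5).
#' @return A `planted_effects` list of tibbles.
#' @export
planted_effects <- function(meqtl = NULL, eqtl = NULL, eqtm = NULL,
                            pop_shift = NULL, trans_hub = NULL,
                            stim_links = NULL, layout = NULL,
                            cis_window = 1e5) {
  tb <- function(x, cols) {
    if (is.null(x)) {
      return(tibble::as_tibble(setNames(rep(list(character(0)), length(cols)),
                                        cols)))
    }
    x <- tibble::as_tibble(x)
    stopifnot(all(cols %in% names(x)))
    x
  }
  eff <- structure(list(
    meqtl = tb(meqtl, c("snp_id", "cpg_id", "effect")),
    eqtl = tb(eqtl, c("snp_id", "gene_id", "effect")),
    eqtm = tb(eqtm, c("cpg_id", "gene_id", "effect")),
    pop_shift = tb(pop_shift, c("cpg_id", "delta_beta")),
    trans_hub = tb(trans_hub, c("snp_id", "cpg_id", "effect")),
    stim_links = tb(stim_links, c("cpg_id", "gene_id", "effect"))
  ), class = "planted_effects")
  if (!is.null(layout)) .validate_effects(eff, layout, cis_window)
  eff
}

.validate_effects <- function(eff, layout, cis_window) {
  snp_pos <- setNames(layout$snps$pos, layout$snps$snp_id)
  snp_chr <- setNames(layout$snps$chr, layout$snps$snp_id)
  cpg_pos <- setNames(layout$cpgs$pos, layout$cpgs$cpg_id)
  cpg_chr <- setNames(layout$cpgs$chr, layout$cpgs$cpg_id)
  need <- function(ids, universe, what) {
    bad <- setdiff(ids, universe)
    if (length(bad)) {
      abort(paste0("unknown ", what, " id(s): ", paste(bad, collapse = ", ")))
    }
  }
  need(eff$meqtl$snp_id, layout$snps$snp_id, "SNP")
  need(c(eff$meqtl$cpg_id, eff$pop_shift$cpg_id, eff$eqtm$cpg_id,
         eff$trans_hub$cpg_id, eff$stim_links$cpg_id),
       layout$cpgs$cpg_id, "CpG")
  need(c(eff$eqtl$gene_id, eff$eqtm$gene_id, eff$stim_links$gene_id),
       layout$genes$gene_id, "gene")
  need(c(eff$eqtl$snp_id, eff$trans_hub$snp_id), layout$snps$snp_id, "SNP")
  if (nrow(eff$meqtl)) {
    same <- snp_chr[eff$meqtl$snp_id] == cpg_chr[eff$meqtl$cpg_id]
    d <- abs(snp_pos[eff$meqtl$snp_id] - cpg_pos[eff$meqtl$cpg_id])
    if (any(!same | d > cis_window)) {
      abort("planted cis-meQTL link outside the cis window")
    }
  }
  if (nrow(eff$trans_hub)) {
    same <- snp_chr[eff$trans_hub$snp_id] == cpg_chr[eff$trans_hub$cpg_id]
    d <- abs(snp_pos[eff$trans_hub$snp_id] - cpg_pos[eff$trans_hub$cpg_id])
    if (any(same & d < 1e6)) {
      abort("planted trans hub link closer than 1 Mb on the same chromosome")
    }
  }
  invisible(TRUE)
}

# Founder-haplotype mosaic genotypes for one block and one population.
.sim_block_dosage <- function(n_ind, freqs, pos, recomb_rate, n_founders) {
  n_snp <- length(freqs)
  founders <- matrix(rbinom(n_founders * n_snp, 1L, rep(freqs, each = n_founders)),
                     nrow = n_founders)
  switch_p <- c(0, pmin(1, recomb_rate * diff(pos)))
  hap <- function() {
    idx <- integer(n_snp)
    cur <- sample.int(n_founders, 1L)
    sw <- runif(n_snp) < switch_p
    for (j in seq_len(n_snp)) {
      if (sw[j]) cur <- sample.int(n_founders, 1L)
      idx[j] <- cur
    }
    founders[cbind(idx, seq_len(n_snp))]
  }
  d <- matrix(0L, nrow = n_ind, ncol = n_snp)
  for (i in seq_len(n_ind)) d[i, ] <- hap() + hap()
  d
}

#' Simulate a two-population cohort with planted structure
#'
#' Generates genotype, methylation and expression matrices with known ground
#' truth. Genotypes are drawn per population from the layout's derived-allele
#' frequencies, with LD within each block induced by copying founder
#' haplotypes (switching founders with probability `recomb_rate` per bp).
#' Methylation is built on the M scale as a per-CpG baseline (population
#' baselines differ where a beta-scale shift is planted), plus planted
#' genetic effects, small age and surrogate-variable loadings, and Gaussian
#' noise; it is stored as beta in (0, 1) (out-of-range values are clamped
#' with a warning). Expression is log-normal around a per-gene baseline with
#' planted eQTL and eQTM links; a stimulated condition adds per-gene
#' response shifts and planted response-QTM links.
#'
#' @param spec A [population_spec()].
#' @param effects A [planted_effects()] map (empty by default).
#' @param seed Integer seed; identical inputs give identical matrices.
#' @param layout Optional pre-computed [cohort_layout()]; defaults to
#'   `cohort_layout(spec, seed)`.
#' @return A list of class `sim_cohort`: `geno` ([genotype_matrix()]),
#'   `meth` ([methylation_matrix()]), `expr` (list of
#'   [expression_matrix()] for conditions `NS` and `STIM`), `samples`
#'   (tibble with population, age, sv1, sv2), `layout`, and `truth` (the
#'   effect map actually planted).
#' @export
simulate_cohort <- function(spec, effects = planted_effects(), seed = 1L,
                            layout = NULL) {
  stopifnot(inherits(spec, "population_spec"),
            inherits(effects, "planted_effects"))
  if (is.null(layout)) layout <- cohort_layout(spec, seed)
  .validate_effects(effects, layout, cis_window = 1e5)
  set.seed(seed + 1L)

  n1 <- spec$n_per_pop[1]; n2 <- spec$n_per_pop[2]; n <- n1 + n2
  pop <- rep(spec$labels, c(n1, n2))
  samples <- tibble::tibble(
    sample_id = sprintf("ind%03d", seq_len(n)),
    population = pop,
    age = runif(n, spec$age_range[1], spec$age_range[2]),
    sv1 = rnorm(n), sv2 = rnorm(n)
  )

  # genotypes: per population, per block
  daf_cols <- paste0("daf_", tolower(spec$labels))
  dosage <- matrix(0L, nrow = n, ncol = nrow(layout$snps))
  for (b in seq_len(spec$n_blocks)) {
    in_b <- which(layout$snps$block == b)
    posb <- layout$snps$pos[in_b]
    d1 <- .sim_block_dosage(n1, layout$snps[[daf_cols[1]]][in_b], posb,
                            spec$recomb_rate, spec$n_founders)
    d2 <- .sim_block_dosage(n2, layout$snps[[daf_cols[2]]][in_b], posb,
                            spec$recomb_rate, spec$n_founders)
    dosage[, in_b] <- rbind(d1, d2)
  }
  dimnames(dosage) <- list(samples$sample_id, layout$snps$snp_id)
  geno <- genotype_matrix(dosage, layout$snps)

  # methylation on the M scale
  n_cpg <- spec$n_cpgs
  base_m <- beta_to_m(layout$cpgs$base_beta)
  M <- matrix(rep(base_m, each = n), nrow = n) +
    matrix(rnorm(n * n_cpg, 0, spec$meth_noise_sd), nrow = n)
  cpg_index <- setNames(seq_len(n_cpg), layout$cpgs$cpg_id)
  if (nrow(effects$pop_shift)) {
    for (k in seq_len(nrow(effects$pop_shift))) {
      j <- cpg_index[[effects$pop_shift$cpg_id[k]]]
      b2 <- layout$cpgs$base_beta[j] + effects$pop_shift$delta_beta[k]
      if (b2 <= 0 || b2 >= 1) {
        warn("planted delta-beta pushes beta outside (0,1); clamping")
        b2 <- min(max(b2, 1e-6), 1 - 1e-6)
      }
      shift_m <- beta_to_m(b2) - base_m[j]
      M[pop == spec$labels[2], j] <- M[pop == spec$labels[2], j] + shift_m
    }
  }
  gen_eff <- rbind(effects$meqtl[c("snp_id", "cpg_id", "effect")],
                   effects$trans_hub[c("snp_id", "cpg_id", "effect")])
  if (nrow(gen_eff)) {
    for (k in seq_len(nrow(gen_eff))) {
      j <- cpg_index[[gen_eff$cpg_id[k]]]
      M[, j] <- M[, j] + gen_eff$effect[k] * dosage[, gen_eff$snp_id[k]]
    }
  }
  # nuisance structure the covariate set is meant to absorb
  age_load <- rnorm(n_cpg, 0, 0.005)
  sv1_load <- rnorm(n_cpg, 0, 0.1)
  sv2_load <- rnorm(n_cpg, 0, 0.1)
  M <- M + outer(samples$age - mean(samples$age), age_load) +
    outer(samples$sv1, sv1_load) + outer(samples$sv2, sv2_load)
  beta <- m_to_beta(M)
  out_of_range <- beta <= 0 | beta >= 1
  if (any(out_of_range)) {
    warn(paste0(sum(out_of_range), " beta value(s) clamped to (0,1)"))
  }
  beta <- pmin(pmax(beta, 1e-6), 1 - 1e-6)
  dimnames(beta) <- list(samples$sample_id, layout$cpgs$cpg_id)
  detp <- matrix(0, nrow = n, ncol = n_cpg, dimnames = dimnames(beta))
  meth <- methylation_matrix(beta, detection_p = detp)

  # expression: log2 scale baseline + planted links
  n_gene <- spec$n_genes
  base_l <- runif(n_gene, 2, 8)
  L <- matrix(rep(base_l, each = n), nrow = n) +
    matrix(rnorm(n * n_gene, 0, spec$expr_noise_sd), nrow = n)
  gene_index <- setNames(seq_len(n_gene), layout$genes$gene_id)
  if (nrow(effects$eqtl)) {
    for (k in seq_len(nrow(effects$eqtl))) {
      j <- gene_index[[effects$eqtl$gene_id[k]]]
      L[, j] <- L[, j] + effects$eqtl$effect[k] * dosage[, effects$eqtl$snp_id[k]]
    }
  }
  if (nrow(effects$eqtm)) {
    for (k in seq_len(nrow(effects$eqtm))) {
      j <- gene_index[[effects$eqtm$gene_id[k]]]
      mj <- M[, cpg_index[[effects$eqtm$cpg_id[k]]]]
      L[, j] <- L[, j] + effects$eqtm$effect[k] * .standardize(mj)
    }
  }
  fpkm <- pmax(2^L - 1, 0)
  dimnames(fpkm) <- list(samples$sample_id, layout$genes$gene_id)
  expr_ns <- expression_matrix(fpkm, layout$genes, condition = "NS")

  # stimulated condition: per-gene response + planted response-QTM links
  resp <- rnorm(n_gene, 1, 0.5)
  Ls <- L + matrix(rep(resp, each = n), nrow = n) +
    matrix(rnorm(n * n_gene, 0, spec$expr_noise_sd), nrow = n)
  if (nrow(effects$stim_links)) {
    for (k in seq_len(nrow(effects$stim_links))) {
      j <- gene_index[[effects$stim_links$gene_id[k]]]
      mj <- M[, cpg_index[[effects$stim_links$cpg_id[k]]]]
      Ls[, j] <- Ls[, j] + effects$stim_links$effect[k] * .standardize(mj)
    }
  }
  fpkm_s <- pmax(2^Ls - 1, 0)
  dimnames(fpkm_s) <- list(samples$sample_id, layout$genes$gene_id)
  expr_stim <- expression_matrix(fpkm_s, layout$genes, condition = "STIM")

  structure(list(geno = geno, meth = meth,
                 expr = list(NS = expr_ns, STIM = expr_stim),
                 samples = samples, layout = layout, truth = effects),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("<sim_cohort> ", nrow(x$samples), " samples (",
      paste(table(x$samples$population), collapse = " + "), "), ",
      ncol(x$geno$dosage), " SNPs, ", ncol(x$meth$beta), " CpGs, ",
      ncol(x$expr$NS$fpkm), " genes\n", sep = "")
  invisible(x)
}

#' Simulate a GWAS-catalog-like table and LD table
#'
#' Emits a table of `(snp_id, trait, parent_category, p)` where hit SNPs are
#' drawn preferentially from `enrichment_in` with sampling odds
#' `odds_multiplier`, plus a pairwise R-squared table computed from the
#' simulated dosages within each LD block. These are fixtures for the
#' GWAS-enrichment stage.
#'
#' @param geno A [genotype_matrix()] whose `snps` tibble carries a `block`
#'   column.
#' @param n_traits Number of distinct traits to spread hits over.
#' @param hit_fraction Fraction of the SNP universe that becomes a GWAS hit.
#' @param enrichment_in Character vector of SNP ids to enrich among hits.
#' @param odds_multiplier Sampling-odds multiplier for `enrichment_in`
#'   (1 = no enrichment).
#' @param n_categories Number of parent trait categories (traits are
#'   assigned to categories round-robin).
#' @param r2_floor Minimum R-squared reported in the LD table.
#' @param seed Integer seed.
#' @return A list with `gwas` (tibble snp_id, trait, parent_category, p) and
#'   `ld` (tibble snp_a, snp_b, r2).
#' @export
simulate_gwas_catalog <- function(geno, n_traits = 10, hit_fraction = 0.1,
                                  enrichment_in = character(),
                                  odds_multiplier = 1, n_categories = 4,
                                  r2_floor = 0.2, seed = 1L) {
  stopifnot(inherits(geno, "genotype_matrix"))
  universe <- geno$snps$snp_id
  if (!length(universe)) abort("empty SNP universe")
  if (hit_fraction < 0 || hit_fraction > 1) {
    abort("hit_fraction must lie in [0, 1]")
  }
  set.seed(seed)
  n_hits <- round(hit_fraction * length(universe))
  w <- ifelse(universe %in% enrichment_in, odds_multiplier, 1)
  hits <- if (n_hits > 0) sample(universe, n_hits, prob = w) else character(0)
  traits <- paste0("trait", seq_len(n_traits))
  cats <- paste0("category", ((seq_len(n_traits) - 1L) %% n_categories) + 1L)
  ti <- if (n_hits > 0) sample.int(n_traits, n_hits, replace = TRUE) else integer(0)
  gwas <- tibble::tibble(
    snp_id = hits, trait = traits[ti], parent_category = cats[ti],
    p = 10^(-runif(n_hits, 8.5, 30))
  )
  ld <- ld_table(geno, r2_floor = r2_floor)
  list(gwas = gwas, ld = ld)
}

#' Pairwise LD (R-squared) within blocks
#'
#' @param geno A [genotype_matrix()]; pairs are computed within each `block`
#'   (or within each `chr` when no block column is present).
#' @param r2_floor Only pairs with R-squared at or above this value are
#'   reported.
#' @return Tibble `(snp_a, snp_b, r2)`, symmetric pairs reported once.
#' @export
ld_table <- function(geno, r2_floor = 0.2) {
  stopifnot(inherits(geno, "genotype_matrix"))
  grp <- if ("block" %in% names(geno$snps)) geno$snps$block else geno$snps$chr
  out <- list()
  for (b in unique(grp)) {
    idx <- which(grp == b)
    if (length(idx) < 2L) next
    d <- geno$dosage[, idx, drop = FALSE]
    keep <- apply(d, 2, function(x) sd(x) > 0)
    d <- d[, keep, drop = FALSE]
    if (ncol(d) < 2L) next
    r2 <- cor(d)^2
    pr <- which(upper.tri(r2) & r2 >= r2_floor, arr.ind = TRUE)
    if (nrow(pr)) {
      out[[length(out) + 1L]] <- tibble::tibble(
        snp_a = colnames(d)[pr[, 1]], snp_b = colnames(d)[pr[, 2]],
        r2 = r2[pr]
      )
    }
  }
  if (!length(out)) {
    return(tibble::tibble(snp_a = character(0), snp_b = character(0),
                          r2 = numeric(0)))
  }
  dplyr::bind_rows(out)
}

#' Write a genotype matrix as VCF
#'
#' Emits a minimal VCF v4.2 with hard genotype calls (`GT`) reconstructed
#' from the dosages, one record per SNP. Alleles are written as REF=A,
#' ALT=G placeholders with the ancestral allele recorded in INFO (`AA`);
#' the dosage counts the ALT (derived) allele.
#'
#' @param geno A [genotype_matrix()].
#' @param path Output `.vcf` path (uncompressed).
#' @export
write_genotypes_vcf <- function(geno, path) {
  stopifnot(inherits(geno, "genotype_matrix"))
  n <- nrow(geno$dosage)
  samples <- rownames(geno$dosage)
  if (is.null(samples)) samples <- paste0("sample", seq_len(n))
  gt_codes <- c("0/0", "0/1", "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=popmeth_simulate_cohort",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- vapply(seq_len(ncol(geno$dosage)), function(j) {
    gts <- gt_codes[round(geno$dosage[, j]) + 1L]
    paste(c(geno$snps$chr[j], geno$snps$pos[j], geno$snps$snp_id[j],
            "A", "G", ".", "PASS",
            if (isTRUE(geno$snps$ancestral_known[j])) "AA=A" else "AA=.",
            "GT", gts), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Export a simulated cohort to plain-text files
#'
#' Writes genotypes (VCF and TSV dosage matrix), methylation beta values,
#' per-condition expression, the sample table, feature positions as BED,
#' and the planted ground truth as TSV files under `dir`.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotypes_vcf(cohort$geno, file.path(dir, "genotypes.vcf"))
  write_matrix_tsv(cohort$geno$dosage, file.path(dir, "dosage.tsv"))
  write_matrix_tsv(cohort$meth$beta, file.path(dir, "methylation_beta.tsv"))
  for (cond in names(cohort$expr)) {
    write_matrix_tsv(cohort$expr[[cond]]$fpkm,
                     file.path(dir, paste0("expression_", cond, ".tsv")))
  }
  readr::write_tsv(cohort$samples, file.path(dir, "samples.tsv"))
  write_positions_bed(cohort$layout$cpgs, file.path(dir, "cpgs.bed"))
  write_positions_bed(cohort$layout$snps, file.path(dir, "snps.bed"))
  readr::write_tsv(cohort$layout$cpgs, file.path(dir, "cpg_annotation.tsv"))
  for (nm in names(cohort$truth)) {
    if (nrow(cohort$truth[[nm]])) {
      readr::write_tsv(cohort$truth[[nm]],
                       file.path(dir, paste0("truth_", nm, ".tsv")))
    }
  }
  invisible(dir)
}
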