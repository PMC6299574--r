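# Shared fixture builders; all randomness is seeded by the caller.

# Minimal two-population sample table.
make_samples <- function(n1 = 20, n2 = 20, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    sample_id = sprintf("s%03d", seq_len(n1 + n2)),
    population = rep(c("AFB", "EUB"), c(n1, n2)),
    age = runif(n1 + n2, 20, 50),
    sv1 = rnorm(n1 + n2),
    sv2 = rnorm(n1 + n2)
  )
}

# Methylation matrix with planted M-scale group shifts at selected CpGs.
# shifts: named numeric (cpg index -> delta M for EUB).
make_meth <- function(samples, n_cpgs = 50, noise_sd = 0.3, shifts_m = NULL,
                      base_beta = 0.5, seed = 2) {
  set.seed(seed)
  n <- nrow(samples)
  M <- matrix(beta_to_m(base_beta) + rnorm(n * n_cpgs, 0, noise_sd),
              nrow = n,
              dimnames = list(samples$sample_id,
                              sprintf("cg%05d", seq_len(n_cpgs))))
  if (!is.null(shifts_m)) {
    eub <- samples$population == "EUB"
    for (j in seq_along(shifts_m)) {
      M[eub, as.integer(names(shifts_m)[j])] <-
        M[eub, as.integer(names(shifts_m)[j])] + shifts_m[j]
    }
  }
  methylation_matrix(m_to_beta(M),
                     detection_p = matrix(0, n, n_cpgs))
}

# Genotype matrix of independent SNPs at given frequencies on one chromosome.
make_geno <- function(samples, freqs, pos = NULL, chr = "chr1", seed = 3) {
  set.seed(seed)
  n <- nrow(samples)
  d <- vapply(freqs, function(f) rbinom(n, 2L, f), numeric(n))
  if (is.null(pos)) pos <- seq_along(freqs) * 1000L
  rownames(d) <- samples$sample_id
  genotype_matrix(d, tibble::tibble(
    snp_id = sprintf("rs%04d", seq_along(freqs)),
    chr = chr, pos = pos, ancestral_known = TRUE
  ))
}
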