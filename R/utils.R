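# Internal numerical helpers shared across modules.

# Build a covariate design matrix (with intercept) from a sample table.
# `covariates` are column names of `samples`; `population` adds the binary
# ancestry indicator. Errors on rank deficiency, naming the offending columns.
.design_matrix <- function(samples, covariates = character(),
                           population = FALSE) {
  n <- nrow(samples)
  X <- matrix(1, nrow = n, ncol = 1, dimnames = list(NULL, "(Intercept)"))
  if (population) {
    pop <- as.integer(factor(samples$population)) - 1L
    X <- cbind(X, population = pop)
  }
  for (cv in covariates) {
    if (!cv %in% names(samples)) {
      abort(paste0("covariate '", cv, "' not found in sample table"))
    }
    X <- cbind(X, as.numeric(samples[[cv]]))
    colnames(X)[ncol(X)] <- cv
  }
  .check_full_rank(X)
  X
}

.check_full_rank <- function(X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[qrX$pivot[seq(qrX$rank + 1L, ncol(X))]]
    abort(paste0("design matrix is rank deficient; collinear column(s): ",
                 paste(drop, collapse = ", ")))
  }
  invisible(qrX)
}

# Residualize columns of Y (vector or matrix) on design X via one QR.
.residualize <- function(Y, X) {
  Y <- as.matrix(Y)
  qr.resid(qr(X), Y)
}

# Column-standardize to unit sample sd (denominator n-1); zero-variance
# columns become NA unless `strict`.
.standardize <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    abort("cannot standardize a constant vector")
  }
  (x - mean(x)) / s
}

# Fast marginal association of one residualized feature vector against a
# matrix of residualized predictors: slope, t-based p. `df` is the residual
# degrees of freedom of the full model (n - n_covariates - 1).
.assoc_columns <- function(f_res, G_res, df) {
  G_res <- as.matrix(G_res)
  gss <- colSums(G_res^2)
  fss <- sum(f_res^2)
  xy <- unname(drop(crossprod(G_res, f_res)))
  gss <- unname(gss)
  beta <- xy / gss
  r2 <- xy^2 / (gss * fss)
  r2 <- pmin(r2, 1)
  tstat <- sign(beta) * sqrt(df * r2 / pmax(1 - r2, .Machine$double.eps))
  p <- 2 * pt(abs(tstat), df = df, lower.tail = FALSE)
  # guard degenerate predictors (zero residual variance after adjustment)
  bad <- gss < .Machine$double.eps * nrow(G_res)
  beta[bad] <- NA_real_
  p[bad] <- NA_real_
  list(beta = beta, p = p, t = tstat)
}

# Kruskal-Wallis rank test of a numeric vector across genotype groups,
# with the standard tie correction. Returns NA if fewer than two groups.
.kw_pvalue <- function(y, g) {
  ok <- is.finite(y) & is.finite(g)
  y <- y[ok]; g <- g[ok]
  grp <- factor(g)
  k <- nlevels(grp)
  if (k < 2L) return(NA_real_)
  n <- length(y)
  r <- rank(y)
  rs <- tapply(r, grp, sum)
  ns <- tabulate(grp)
  H <- 12 / (n * (n + 1)) * sum(rs^2 / ns) - 3 * (n + 1)
  ties <- table(y)
  C <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (C <= 0) return(NA_real_)
  pchisq(H / C, df = k - 1L, lower.tail = FALSE)
}

# Mann-Whitney AUC of `scores` for separating labels (TRUE = positive class).
# Higher score must indicate the positive class.
.rank_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Draw a reproducible child seed stream from a master seed.
.child_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max, n)
}
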