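# Independent brute-force oracles used across tests. These deliberately
# re-derive quantities from first principles rather than calling package
# internals.

# Trimmed-mean-of-M-values normalization factors, written directly from the
# published formula: reference = sample whose 75th percentile of
# depth-scaled counts is closest to the mean; M trim 30%, A trim 5%;
# inverse-asymptotic-variance weights; factors rescaled to geometric mean 1.
tmm_oracle <- function(counts) {
  lib <- colSums(counts)
  f75 <- apply(counts, 2, function(x) quantile(x / sum(x), 0.75))
  ref <- which.min(abs(f75 - mean(f75)))
  xr <- counts[, ref] / lib[ref]
  f <- vapply(seq_len(ncol(counts)), function(k) {
    xk <- counts[, k] / lib[k]
    keep <- xk > 0 & xr > 0
    M <- log2(xk[keep] / xr[keep])
    A <- 0.5 * log2(xk[keep] * xr[keep])
    w <- (lib[k] - counts[keep, k]) / (lib[k] * counts[keep, k]) +
      (lib[ref] - counts[keep, ref]) / (lib[ref] * counts[keep, ref])
    n <- length(M)
    loM <- floor(n * 0.3) + 1; hiM <- n + 1 - loM
    loA <- floor(n * 0.05) + 1; hiA <- n + 1 - loA
    keep2 <- rank(M) >= loM & rank(M) <= hiM &
      rank(A) >= loA & rank(A) <= hiA
    if (max(abs(M)) < 1e-6) return(1)
    2^(sum(M[keep2] / w[keep2]) / sum(1 / w[keep2]))
  }, numeric(1))
  f / exp(mean(log(f)))
}

# Triple-loop topological overlap, the definitional form.
tom_oracle <- function(A) {
  n <- nrow(A)
  k <- rowSums(A) - 1
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + A[i, u] * A[u, j]
    D[i, j] <- 1 - (l + A[i, j]) / (min(k[i], k[j]) + 1 - A[i, j])
  }
  D
}

# REML log-likelihood for a two-crossed-random-intercept model with a
# global intercept, optimized directly over the variance components.
reml_two_way_oracle <- function(y, a, b) {
  Za <- model.matrix(~ factor(a) - 1)
  Zb <- model.matrix(~ factor(b) - 1)
  X <- matrix(1, length(y), 1)
  nll <- function(par) {
    v <- exp(par)
    V <- v[1] * tcrossprod(Za) + v[2] * tcrossprod(Zb) +
      v[3] * diag(length(y))
    Vi <- solve(V)
    XtVX <- crossprod(X, Vi %*% X)
    beta <- solve(XtVX, crossprod(X, Vi %*% y))
    r <- y - X %*% beta
    0.5 * (determinant(V)$modulus + determinant(XtVX)$modulus +
             crossprod(r, Vi %*% r))
  }
  fit <- optim(log(c(var(y), var(y), var(y)) / 3), nll,
               method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  v <- exp(fit$par)
  setNames(v / sum(v), c("a", "b", "residual"))
}

# Small balanced cohort for preprocessing tests: counts plus minimal
# metadata built by hand.
toy_cohort <- function(counts, days = NULL, forms = NULL) {
  n <- ncol(counts)
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("S%02d", seq_len(n))
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  meta <- data.frame(
    sample_id = colnames(counts),
    individual_id = paste0("I", rep_len(1:2, n)),
    line_id = paste0("L", rep_len(1:2, n)),
    differentiation_id = paste0("D", seq_len(n)),
    day = if (is.null(days)) rep(25, n) else days,
    form = if (is.null(forms)) rep("control", n) else forms,
    stringsAsFactors = FALSE)
  meta$diagnosis <- ifelse(meta$form == "control", "control", "affected")
  cohort_counts(counts, meta)
}

# Quick cohort -> logFC matrix via the package pipeline at small scale.
small_de_pipeline <- function(sim, group_by = NULL) {
  e <- tmm_normalize(filter_low_expressed(sim$cohort, group_by = group_by))
  fits <- fit_gene_lmm(e, fixed = ~ form * day)
  contrast_all(fits)
}
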