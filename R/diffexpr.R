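#' Per-gene linear mixed model with one random intercept
#'
#' Fits, for every gene, `expr ~ fixed + (1 | random_group)` by REML.
#' Because the random-effect structure is shared across genes, the
#' covariance `V = sigma_e^2 (I + lambda Z Z')` is diagonalized once; the
#' REML criterion is then profiled over the variance ratio `lambda` on a
#' log-spaced grid simultaneously for all genes, which reduces each
#' evaluation to weighted least squares in the rotated basis. When the
#' REML-optimal ratio is zero the fit coincides with ordinary least
#' squares.
#'
#' @param expr an `expr_matrix`, or a bare gene x sample matrix.
#' @param meta sample metadata (defaults to `expr$samples`).
#' @param fixed one-sided formula of fixed effects evaluated in `meta`
#'   (default `~ form * day + sex + batch` plus any ancestry/sequencing PC
#'   columns present).
#' @param random_group metadata column for the random intercept (default
#'   `individual_id`).
#' @param lambda_grid grid of variance ratios profiled over (0 plus
#'   log-spaced values).
#' @return object of class `gene_lmm_fits`: coefficient matrix (gene x p),
#'   per-gene sigma^2, chosen lambda, unscaled coefficient covariances per
#'   grid point, residual df `n - p - q + 1`, and the design metadata
#'   needed to build contrasts.
#' @export
fit_gene_lmm <- function(expr, meta = NULL,
                         fixed = NULL,
                         random_group = "individual_id",
                         lambda_grid = c(0, exp(seq(log(1e-4), log(1e4),
                                                    length.out = 40)))) {
  if (inherits(expr, "expr_matrix")) {
    if (is.null(meta)) meta <- expr$samples
    Y <- expr$values
  } else Y <- as.matrix(expr)
  if (is.null(meta)) stop("meta required")
  if (is.null(fixed)) {
    pcs <- grep("^(ancestry_pc|seq_pc)", names(meta), value = TRUE)
    base <- c("form * day", "sex", "batch")
    base <- base[c(TRUE, "sex" %in% names(meta), "batch" %in% names(meta))]
    fixed <- stats::as.formula(paste("~", paste(c(base, pcs),
                                                collapse = " + ")))
  }
  meta <- droplevels(as.data.frame(meta))
  if ("form" %in% names(meta) && !is.factor(meta$form))
    meta$form <- stats::relevel(factor(meta$form), ref =
      if ("control" %in% meta$form) "control" else levels(factor(meta$form))[1])
  if ("day" %in% names(meta)) meta$day <- factor(meta$day)
  X <- model.matrix(fixed, meta)
  if (qr(X)$rank < ncol(X)) stop("singular fixed-effect design")
  n <- nrow(X); p <- ncol(X)

  g <- factor(meta[[random_group]])
  q <- nlevels(g)
  Z <- model.matrix(~ g - 1)
  K <- tcrossprod(Z)
  eg <- eigen(K, symmetric = TRUE)
  U <- eg$vectors; d <- pmax(eg$values, 0)
  Xs <- crossprod(U, X)
  Ys <- crossprod(U, t(Y))          # n x genes
  n_g <- ncol(Ys)

  # without replicated groups the random intercept is inestimable: the
  # model degenerates to OLS and keeps the OLS residual df
  degenerate <- sum(table(g) >= 2) < 2
  if (degenerate) lambda_grid <- 0

  crit <- matrix(Inf, length(lambda_grid), n_g)
  beta_l <- vector("list", length(lambda_grid))
  rss_l <- vector("list", length(lambda_grid))
  xtwxi_l <- vector("list", length(lambda_grid))
  for (li in seq_along(lambda_grid)) {
    lam <- lambda_grid[li]
    w <- 1 / (1 + lam * d)
    Xw <- Xs * w
    XtWX <- crossprod(Xs, Xw)
    XtWXi <- solve(XtWX)
    B <- XtWXi %*% crossprod(Xw, Ys)            # p x genes
    R <- Ys - Xs %*% B
    rss <- colSums(R * R * w)
    ldV <- sum(log(1 + lam * d))
    ldX <- determinant(XtWX, logarithm = TRUE)$modulus
    crit[li, ] <- (n - p) * log(rss) + ldV + as.numeric(ldX)
    beta_l[[li]] <- B
    rss_l[[li]] <- rss
    xtwxi_l[[li]] <- XtWXi
  }
  pick <- apply(crit, 2, which.min)
  coefs <- matrix(NA_real_, n_g, p, dimnames = list(colnames(Ys),
                                                    colnames(X)))
  sigma2 <- numeric(n_g)
  for (li in unique(pick)) {
    sel <- pick == li
    coefs[sel, ] <- t(beta_l[[li]][, sel, drop = FALSE])
    sigma2[sel] <- rss_l[[li]][sel] / (n - p)
  }
  structure(list(coef = coefs, sigma2 = setNames(sigma2, rownames(coefs)),
                 lambda = setNames(lambda_grid[pick], rownames(coefs)),
                 lambda_index = pick, vcov_unscaled = xtwxi_l,
                 df = if (degenerate) n - p else n - p - q + 1,
                 n = n, p = p, q = q,
                 fixed = fixed, meta = meta, terms = colnames(X)),
            class = "gene_lmm_fits")
}

#' @export
print.gene_lmm_fits <- function(x, ...) {
  cat(sprintf("gene_lmm_fits: %d genes, %d samples, %d fixed terms, df = %d\n",
              nrow(x$coef), x$n, x$p, x$df))
  invisible(x)
}

contrast_vector <- function(fits, form, day) {
  meta <- fits$meta
  if (!form %in% levels(meta$form)) stop("missing form level: ", form)
  if (!as.character(day) %in% levels(meta$day)) stop("missing day: ", day)
  proto <- meta[1, , drop = FALSE]
  two <- rbind(proto, proto)
  two$form <- factor(c(form, levels(meta$form)[1]), levels = levels(meta$form))
  two$day <- factor(as.character(day), levels = levels(meta$day))
  mm <- model.matrix(fits$fixed, rbind(meta, two))
  mm <- mm[nrow(mm) - 1:0, , drop = FALSE]
  drop(mm[1, ] - mm[2, ])
}

#' Wald contrast of one form against control at one day
#'
#' @param fits a `gene_lmm_fits` object whose design includes `form` and
#'   `day` factors with control as the base form level.
#' @param form non-control form level to test.
#' @param day day at which to contrast.
#' @return data frame of `de_result` rows: gene, form, day, logFC, se,
#'   stat (t with residual-df approximation), p, fdr (BH within this
#'   form/day).
#' @export
contrast_form_vs_control <- function(fits, form, day) {
  stopifnot(inherits(fits, "gene_lmm_fits"))
  L <- contrast_vector(fits, form, day)
  est <- drop(fits$coef %*% L)
  se2u <- vapply(fits$vcov_unscaled, function(Vi)
    drop(crossprod(L, Vi %*% L)), numeric(1))
  se <- sqrt(fits$sigma2 * se2u[fits$lambda_index])
  stat <- est / se
  df <- max(fits$df, 1)
  p <- 2 * pt(-abs(stat), df = df)
  data.frame(gene = rownames(fits$coef), form = form, day = day,
             logFC = est, se = se, stat = stat, p = p,
             fdr = p.adjust(p, "BH"), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Contrast every non-control form at every day
#'
#' @param fits a `gene_lmm_fits`.
#' @return row-bound `de_result` table across all (form, day) pairs, BH
#'   applied within each pair.
#' @export
contrast_all <- function(fits) {
  forms <- setdiff(levels(fits$meta$form), levels(fits$meta$form)[1])
  days <- levels(fits$meta$day)
  do.call(rbind, lapply(forms, function(f)
    do.call(rbind, lapply(days, function(d)
      contrast_form_vs_control(fits, f, d)))))
}

#' Fixed-effect meta-analysis of per-form effects
#'
#' Inverse-variance weighted combination per gene and day across forms:
#' `beta = sum(w b) / sum(w)` with `w = 1/se^2`, `se = 1/sqrt(sum w)`,
#' two-sided normal p, BH within each day.
#'
#' @param results `de_result` rows spanning >= 2 forms per gene x day.
#' @param exclude_forms optional forms dropped before pooling.
#' @return data frame: gene, day, beta, se, z, p, fdr.
#' @export
meta_fixed_effect <- function(results, exclude_forms = NULL) {
  res <- results[!(results$form %in% exclude_forms), , drop = FALSE]
  if (any(res$se <= 0)) stop("all standard errors must be positive")
  key <- interaction(res$gene, res$day, drop = TRUE)
  if (min(table(key)) < 2)
    stop("need at least 2 forms per gene and day")
  agg <- do.call(rbind, lapply(split(res, key), function(dd) {
    w <- 1 / dd$se^2
    beta <- sum(w * dd$logFC) / sum(w)
    se <- 1 / sqrt(sum(w))
    data.frame(gene = dd$gene[1], day = dd$day[1], beta = beta, se = se,
               z = beta / se, stringsAsFactors = FALSE)
  }))
  agg$p <- 2 * pnorm(-abs(agg$z))
  agg$fdr <- ave(agg$p, agg$day, FUN = function(p) p.adjust(p, "BH"))
  rownames(agg) <- NULL
  agg
}

#' Summarize dosage behaviour of CNV gene sets
#'
#' For each form with a CNV gene set, counts the tested CNV genes, the
#' fraction whose logFC lies in the dosage-expected direction (negative
#' for deletions, positive for duplications) and the fraction below a
#' stringent FDR.
#'
#' @param results `de_result` rows.
#' @param cnv_gene_sets named list (form -> gene set).
#' @param dosages named numeric (form -> dosage); direction is
#'   `sign(log2(dosage))`.
#' @param fdr_strict stringent FDR threshold (default 0.005).
#' @return data frame: form, n, frac_expected_direction, frac_strict_fdr
#'   (NA when no CNV gene was tested).
#' @export
cnv_dosage_summary <- function(results, cnv_gene_sets, dosages,
                               fdr_strict = 0.005) {
  stopifnot(length(cnv_gene_sets) > 0)
  unknown <- setdiff(names(cnv_gene_sets), unique(results$form))
  if (length(unknown)) stop("unknown form(s): ",
                            paste(unknown, collapse = ", "))
  do.call(rbind, lapply(names(cnv_gene_sets), function(f) {
    dd <- results[results$form == f &
                    results$gene %in% cnv_gene_sets[[f]], , drop = FALSE]
    dirn <- sign(log2(dosages[[f]]))
    if (!nrow(dd))
      return(data.frame(form = f, n = 0L,
                        frac_expected_direction = NA_real_,
                        frac_strict_fdr = NA_real_))
    data.frame(form = f, n = nrow(dd),
               frac_expected_direction = mean(sign(dd$logFC) == dirn),
               frac_strict_fdr = mean(dd$fdr < fdr_strict),
               stringsAsFactors = FALSE)
  }))
}

#' Day of peak mean expression per gene
#'
#' @param expr an `expr_matrix`.
#' @param meta sample metadata (defaults to `expr$samples`).
#' @return data frame: gene, peak_day (ties broken to the earliest day).
#' @export
peak_expression_day <- function(expr, meta = expr$samples) {
  stopifnot(inherits(expr, "expr_matrix"))
  days <- sort(unique(meta$day))
  if (length(days) < 2) stop("need at least 2 days")
  means <- vapply(days, function(d)
    rowMeans(expr$values[, meta$day == d, drop = FALSE]),
    numeric(nrow(expr$values)))
  data.frame(gene = rownames(expr$values),
             peak_day = days[apply(means, 1, which.max)],
             stringsAsFactors = FALSE)
}
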