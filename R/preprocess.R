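#' Remove genes expressed at very low levels
#'
#' A gene is kept for a group when at least `min_frac` of that group's
#' samples have `min_reads` or more reads (the boundary is inclusive: with
#' 10 samples, 3 samples at the threshold keep the gene). With several
#' groups the gene must be kept in every group by default, so a shared
#' gene universe survives; per-day pipelines pass a single day's samples.
#'
#' @param counts a `cohort_counts` object.
#' @param min_reads minimum read count for a sample to support a gene.
#' @param min_frac minimum supporting fraction of a group's samples,
#'   in (0, 1].
#' @param group_by metadata column defining groups, or NULL for one group.
#' @param combine "all" (kept in every group) or "any".
#' @return the filtered `cohort_counts`.
#' @export
filter_low_expressed <- function(counts, min_reads = 10, min_frac = 0.3,
                                 group_by = "day", combine = c("all", "any")) {
  stopifnot(inherits(counts, "cohort_counts"))
  combine <- match.arg(combine)
  if (min_frac <= 0 || min_frac > 1) stop("min_frac must lie in (0, 1]")
  groups <- if (is.null(group_by)) rep("all", ncol(counts$counts))
            else counts$samples[[group_by]]
  if (any(is.na(groups)) || !length(groups)) stop("groups must be non-empty")
  kept_per_group <- vapply(split(seq_len(ncol(counts$counts)), groups),
                           function(idx) {
    frac <- rowMeans(counts$counts[, idx, drop = FALSE] >= min_reads)
    frac >= min_frac
  }, logical(nrow(counts$counts)))
  keep <- if (combine == "all") rowSums(!kept_per_group) == 0
          else rowSums(kept_per_group) > 0
  out <- counts
  out$counts <- counts$counts[keep, , drop = FALSE]
  out$genes <- rownames(out$counts)
  out
}

#' TMM-normalized log2 CPM
#'
#' Normalization factors are the weighted trimmed mean of gene-wise M
#' values against a reference sample (M trim 30%, A trim 5%, reference =
#' sample whose 75th percentile of depth-scaled counts is closest to the
#' mean), computed by [edgeR::calcNormFactors()] and rescaled to geometric
#' mean 1. log2 CPM uses the effective library size (library x factor)
#' with a configurable pseudocount.
#'
#' @param counts a `cohort_counts` object.
#' @param pseudocount added to counts before the log (default 0.5).
#' @return an `expr_matrix` object: list with `values` (gene x sample log2
#'   CPM), `norm_factors`, `lib_sizes`, `offset`, `samples` metadata.
#' @export
tmm_normalize <- function(counts, pseudocount = 0.5) {
  stopifnot(inherits(counts, "cohort_counts"))
  lib <- colSums(counts$counts)
  if (any(lib == 0))
    stop("all-zero sample(s): ",
         paste(colnames(counts$counts)[lib == 0], collapse = ", "))
  nf <- edgeR::calcNormFactors(counts$counts, method = "TMM")
  eff <- lib * nf
  values <- log2(sweep(counts$counts + pseudocount, 2, eff, "/") * 1e6)
  structure(list(values = values, norm_factors = nf, lib_sizes = lib,
                 offset = pseudocount, samples = counts$samples),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples (log2 CPM, pseudocount %g)\n",
              nrow(x$values), ncol(x$values), x$offset))
  invisible(x)
}

#' Flag outlier samples by standardized network connectivity
#'
#' Within each group (default day x form), each sample's connectivity is
#' the sum of its correlations with the other group members; connectivity
#' is standardized within the group and samples with z below `z_cut` are
#' flagged. A single pass is performed; set `iterate = TRUE` to repeat
#' until no sample falls below the cut.
#'
#' @param expr an `expr_matrix`.
#' @param meta sample metadata (defaults to `expr$samples`).
#' @param z_cut standardized connectivity threshold (default -2).
#' @param group_by metadata columns defining groups.
#' @param cor_method correlation estimator for the sample network.
#' @param iterate repeat removal until stable.
#' @return data frame (class `outlier_report`): sample_id, group, k, z,
#'   removed.
#' @export
detect_outliers <- function(expr, meta = expr$samples, z_cut = -2,
                            group_by = c("day", "form"),
                            cor_method = c("pearson", "spearman"),
                            iterate = FALSE) {
  stopifnot(inherits(expr, "expr_matrix"))
  cor_method <- match.arg(cor_method)
  grp <- interaction(meta[group_by], drop = TRUE)
  out <- do.call(rbind, lapply(levels(grp), function(g) {
    idx <- which(grp == g)
    if (length(idx) < 3)
      stop("group ", g, " has fewer than 3 samples")
    active <- idx
    removed <- logical(length(idx))
    names(removed) <- meta$sample_id[idx]
    repeat {
      cm <- cor(expr$values[, active, drop = FALSE], method = cor_method)
      k <- rowSums(cm) - 1
      if (sd(k) == 0) {
        warning("group ", g, ": zero connectivity variance, no outliers")
        z <- rep(0, length(k))
      } else z <- (k - mean(k)) / sd(k)
      bad <- z < z_cut
      res <- data.frame(sample_id = meta$sample_id[active], group = g,
                        k = k, z = z, removed = bad,
                        stringsAsFactors = FALSE)
      if (!iterate || !any(bad) || sum(!bad) < 3) break
      removed[meta$sample_id[active][bad]] <- TRUE
      active <- active[!bad]
    }
    if (iterate && any(removed)) {
      extra <- data.frame(sample_id = names(removed)[removed], group = g,
                          k = NA_real_, z = NA_real_, removed = TRUE,
                          stringsAsFactors = FALSE)
      res <- rbind(extra, res)
    }
    res
  }))
  rownames(out) <- NULL
  class(out) <- c("outlier_report", "data.frame")
  out
}

#' Regress covariates out of an expression matrix
#'
#' Per-gene least-squares residuals on the listed covariates with the gene
#' mean restored, leaving residuals orthogonal to every covariate column.
#'
#' @param expr an `expr_matrix`.
#' @param meta sample metadata (defaults to `expr$samples`).
#' @param covariates character vector of metadata columns to remove.
#' @return an `expr_matrix` with adjusted values.
#' @export
regress_covariates <- function(expr, meta = expr$samples, covariates) {
  stopifnot(inherits(expr, "expr_matrix"), length(covariates) > 0)
  X <- model.matrix(~ ., data = meta[, covariates, drop = FALSE])
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("rank-deficient covariate design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  fit <- lm.fit(X, t(expr$values))
  res <- t(fit$residuals) + rowMeans(expr$values)
  dimnames(res) <- dimnames(expr$values)
  out <- expr
  out$values <- res
  out
}

#' Pairwise reproducibility correlations within day and form
#'
#' One row per unordered sample pair sharing a day and form, with the
#' Spearman correlation of their expression profiles and labels for
#' whether the two samples come from the same line and the same
#' individual.
#'
#' @param expr an `expr_matrix`.
#' @param meta sample metadata (defaults to `expr$samples`).
#' @param method correlation estimator.
#' @return data frame: sample1, sample2, day, form, rho, same_line,
#'   same_individual, label ("same line", "same individual",
#'   "different individuals").
#' @export
reproducibility_correlations <- function(expr, meta = expr$samples,
                                         method = "spearman") {
  stopifnot(inherits(expr, "expr_matrix"))
  grp <- split(seq_len(nrow(meta)), interaction(meta$day, meta$form,
                                                drop = TRUE))
  out <- do.call(rbind, lapply(grp, function(idx) {
    if (length(idx) < 2) return(NULL)
    cm <- cor(expr$values[, idx, drop = FALSE], method = method)
    pr <- t(combn(seq_along(idx), 2))
    i <- idx[pr[, 1]]; j <- idx[pr[, 2]]
    data.frame(sample1 = meta$sample_id[i], sample2 = meta$sample_id[j],
               day = meta$day[i], form = meta$form[i],
               rho = cm[pr],
               same_line = meta$line_id[i] == meta$line_id[j],
               same_individual = meta$individual_id[i] ==
                 meta$individual_id[j],
               stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(sample1 = character(0), sample2 = character(0),
                      day = numeric(0), form = character(0),
                      rho = numeric(0), same_line = logical(0),
                      same_individual = logical(0))
  out$label <- ifelse(out$same_line, "same line",
                      ifelse(out$same_individual, "same individual",
                             "different individuals"))
  rownames(out) <- NULL
  out
}

#' Per-gene variance fractions across metadata terms
#'
#' Fits one variance-component model per gene: random intercepts for
#' categorical terms, fixed effects for continuous terms. The fraction
#' attributed to a categorical term is its variance component over the
#' total; a continuous term contributes the variance of its fitted
#' component. Fractions are non-negative and sum to one per gene.
#'
#' @param expr an `expr_matrix`.
#' @param meta sample metadata (defaults to `expr$samples`).
#' @param terms metadata columns to partition over.
#' @return gene x (terms, residual) matrix of fractions.
#' @export
variance_fractions <- function(expr, meta = expr$samples, terms) {
  stopifnot(inherits(expr, "expr_matrix"), length(terms) > 0)
  is_cat <- vapply(meta[terms], function(x)
    is.character(x) || is.factor(x) || is.logical(x), logical(1))
  for (t in terms[is_cat]) {
    if (length(unique(meta[[t]])) < 2)
      stop("term ", t, " has a single level")
    meta[[t]] <- factor(meta[[t]])
  }
  rand <- terms[is_cat]
  fixed <- terms[!is_cat]
  fml <- stats::as.formula(paste(
    "y ~", paste(c(fixed, sprintf("(1 | %s)", rand), "1"), collapse = " + ")))
  res <- t(apply(expr$values, 1, function(y) {
    dat <- cbind(data.frame(y = y), meta[terms])
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(fml, data = dat, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore"))))
    vc <- as.data.frame(lme4::VarCorr(fit))
    vr <- setNames(vc$vcov, vc$grp)
    fx <- vapply(fixed, function(f) {
      b <- lme4::fixef(fit)
      cols <- grep(paste0("^", f), names(b), value = TRUE)
      if (!length(cols)) return(0)
      var(as.matrix(dat[f]) %*% b[cols])
    }, numeric(1))
    comp <- c(vr[rand], fx, residual = unname(vr["Residual"]))
    names(comp) <- c(rand, fixed, "residual")
    pmax(comp, 0) / sum(pmax(comp, 0))
  }))
  colnames(res) <- c(rand, fixed, "residual")
  res[, c(terms, "residual"), drop = FALSE]
}
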