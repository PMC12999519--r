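#' Build a cell-type signature from a single-cell reference
#'
#' Per-type mean CPM over cells, restricted to the union of the top
#' specificity markers per type.
#'
#' @param reference a `reference_profiles` object (>= 2 types, >= 3 cells
#'   per type).
#' @param n_markers_per_type markers retained per type.
#' @return gene x cell-type signature matrix with a `markers` attribute.
#' @export
build_signature <- function(reference, n_markers_per_type = 50) {
  stopifnot(inherits(reference, "reference_profiles"))
  types <- levels(reference$celltypes)
  if (length(types) < 2) stop("need at least 2 cell types")
  if (any(table(reference$celltypes) < 3))
    stop("every type needs at least 3 cells")
  cpmm <- sweep(reference$counts, 2, colSums(reference$counts), "/") * 1e6
  prof <- vapply(types, function(t)
    rowMeans(cpmm[, reference$celltypes == t, drop = FALSE]),
    numeric(nrow(cpmm)))
  expressed <- rowSums(prof) > 0
  spec <- sweep(prof[expressed, , drop = FALSE], 1,
                rowSums(prof[expressed, , drop = FALSE]), "/")
  markers <- lapply(types, function(t) {
    s <- sort(spec[, t], decreasing = TRUE)
    top <- names(s)[seq_len(min(n_markers_per_type, length(s)))]
    if (max(spec[top, t]) <= 1 / length(types))
      warning("type ", t, " has no distinct markers")
    top
  })
  names(markers) <- types
  sig <- prof[unique(unlist(markers)), , drop = FALSE]
  attr(sig, "markers") <- markers
  sig
}

#' Estimate cell-type proportions by non-negative least squares
#'
#' Each bulk sample's CPM over the signature's marker genes is decomposed
#' on the signature columns by NNLS and renormalized to the simplex.
#' Genes are weighted by the inverse of their signature row mean, the
#' generalized-least-squares weighting for the roughly constant
#' coefficient of variation of expressed genes in bulk RNA-seq; without
#' it, unweighted NNLS on the raw CPM scale is dominated by the few
#' highest-expressed markers.
#'
#' @param bulk gene x sample CPM matrix (linear scale), or an
#'   `expr_matrix` whose log2 values are exponentiated.
#' @param signature gene x cell-type signature from [build_signature()].
#' @return list of class `proportion_estimates`: `proportions`
#'   (sample x type, rows on the simplex), `residual_norm` (on the
#'   weighted scale).
#' @export
estimate_proportions <- function(bulk, signature) {
  B <- if (inherits(bulk, "expr_matrix")) 2^bulk$values else as.matrix(bulk)
  shared <- intersect(rownames(B), rownames(signature))
  if (length(shared) < 10) stop("fewer than 10 shared marker genes")
  S <- signature[shared, , drop = FALSE]
  if (qr(S)$rank < ncol(S)) stop("singular signature matrix")
  B <- B[shared, , drop = FALSE]
  # inverse-row-mean weights (constant-CV noise model), then
  # column-normalize the signature (and rescale the response) so the NNLS
  # solver operates on a well-conditioned problem; undo both afterwards
  rw <- pmax(rowMeans(S), 1e-8)
  S <- S / rw
  B <- B / rw
  cn <- sqrt(colSums(S^2))
  Sn <- sweep(S, 2, cn, "/")
  sol <- lapply(seq_len(ncol(B)), function(j) {
    bscale <- max(B[, j], 1e-12)
    fit <- pracma::lsqnonneg(Sn, B[, j] / bscale)
    x <- fit$x / cn * bscale
    if (sum(x) == 0) x <- rep(1 / ncol(S), ncol(S))
    list(p = x / sum(x), resid = sqrt(sum((B[, j] - S %*% x)^2)))
  })
  props <- do.call(rbind, lapply(sol, `[[`, "p"))
  dimnames(props) <- list(colnames(B), colnames(S))
  resid <- vapply(sol, `[[`, numeric(1), "resid")
  structure(list(proportions = props,
                 residual_norm = setNames(resid, colnames(B))),
            class = "proportion_estimates")
}

#' Adjusted logit transform for proportions
#'
#' `log(p* / (1 - p*))` with `p* = a + (1 - 2a) p`; strictly increasing
#' on \[0, 1\] and finite at the endpoints.
#'
#' @param p proportions in \[0, 1\].
#' @param a adjustment constant (default 0.001).
#' @return transformed values.
#' @export
adjusted_logit <- function(p, a = 0.001) {
  if (any(p < 0 | p > 1)) stop("proportions must lie in [0, 1]")
  ps <- a + (1 - 2 * a) * p
  log(ps / (1 - ps))
}

#' Test cell-proportion changes per form and day
#'
#' Applies the adjusted logit to the proportion matrix and fits, per cell
#' type, the same single-random-intercept mixed model used for gene-level
#' differential expression (`~ form * day` with a random intercept by
#' individual), followed by per-day form-versus-control Wald contrasts
#' and BH adjustment across all contrasts per cell type.
#'
#' @param props a `proportion_estimates` or sample x type matrix.
#' @param meta sample metadata (must include `form`, `day`,
#'   `individual_id`, with control present).
#' @param a adjustment constant for the logit.
#' @return data frame: celltype, form, day, logit_change (as logFC), se,
#'   stat, p, fdr.
#' @export
proportion_association <- function(props, meta, a = 0.001) {
  P <- if (inherits(props, "proportion_estimates")) props$proportions
       else as.matrix(props)
  stopifnot("control" %in% meta$form)
  Y <- t(apply(t(P), 1, adjusted_logit, a = a))  # type x sample
  rownames(Y) <- colnames(P)
  colnames(Y) <- rownames(P)
  fits <- fit_gene_lmm(Y, meta, fixed = ~ form * day,
                       random_group = "individual_id")
  res <- contrast_all(fits)
  names(res)[names(res) == "gene"] <- "celltype"
  res$fdr <- ave(res$p, res$celltype, FUN = function(p) p.adjust(p, "BH"))
  res
}
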