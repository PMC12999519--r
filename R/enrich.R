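two_by_two <- function(set_a, set_b, universe) {
  set_a <- intersect(unique(set_a), universe)
  set_b <- intersect(unique(set_b), universe)
  if (!length(set_a) || !length(set_b)) stop("empty set after harmonization")
  n11 <- length(intersect(set_a, set_b))
  n10 <- length(set_a) - n11
  n01 <- length(set_b) - n11
  n00 <- length(universe) - n11 - n10 - n01
  matrix(c(n11, n01, n10, n00), 2, 2,
         dimnames = list(in_a = c("yes", "no"), in_b = c("yes", "no")))
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' The two-sided p sums the hypergeometric probabilities of all tables
#' (with the observed margins) whose probability does not exceed that of
#' the observed table. The odds ratio is the sample OR
#' `(n11 n00) / (n10 n01)`, with a Haldane 0.5 correction applied to
#' every cell when any cell is zero.
#'
#' @param tab 2x2 integer matrix (rows: in set A yes/no; columns: in set
#'   B yes/no).
#' @return list: `or`, `p`, `table`.
#' @export
fisher_exact_table <- function(tab) {
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0))
  m <- sum(tab[1, ])          # size of set A
  k <- sum(tab[, 1])          # size of set B
  N <- sum(tab)
  x <- tab[1, 1]
  supp <- max(0, m + k - N):min(m, k)
  probs <- dhyper(supp, m, N - m, k)
  p <- sum(probs[probs <= dhyper(x, m, N - m, k) * (1 + 1e-7)])
  tt <- tab
  if (any(tt == 0)) tt <- tt + 0.5
  or <- (tt[1, 1] * tt[2, 2]) / (tt[1, 2] * tt[2, 1])
  list(or = unname(or), p = min(1, p), table = tab)
}

#' Fisher exact enrichment of one gene set in another
#'
#' @param set_a,set_b gene sets (harmonized to the universe).
#' @param universe background genes (must contain both sets' union after
#'   harmonization).
#' @return list: `or`, `p`, `table`.
#' @export
fisher_enrichment <- function(set_a, set_b, universe) {
  fisher_exact_table(two_by_two(set_a, set_b, universe))
}

#' Upper-tail hypergeometric overlap test
#'
#' `P(X >= observed overlap)` for the overlap of two sets drawn from a
#' common universe.
#'
#' @param set_a,set_b gene sets.
#' @param universe background genes.
#' @return upper-tail p value.
#' @export
hypergeometric_overlap <- function(set_a, set_b, universe) {
  set_a <- intersect(unique(set_a), universe)
  set_b <- intersect(unique(set_b), universe)
  if (!length(set_a) || !length(set_b)) stop("empty set after harmonization")
  x <- length(intersect(set_a, set_b))
  if (x > min(length(set_a), length(set_b)))
    stop("overlap exceeds the smaller set: impossible input")
  phyper(x - 1, length(set_a), length(universe) - length(set_a),
         length(set_b), lower.tail = FALSE)
}

#' Cell-type specificity from reference profiles
#'
#' Per-gene share of mean CPM across cell types; each row sums to one.
#'
#' @param reference a `reference_profiles` object.
#' @return gene x cell-type specificity matrix.
#' @export
specificity_from_reference <- function(reference) {
  stopifnot(inherits(reference, "reference_profiles"))
  cpmm <- sweep(reference$counts, 2, colSums(reference$counts), "/") * 1e6
  prof <- vapply(levels(reference$celltypes), function(t)
    rowMeans(cpmm[, reference$celltypes == t, drop = FALSE]),
    numeric(nrow(cpmm)))
  keep <- rowSums(prof) > 0
  sweep(prof[keep, , drop = FALSE], 1, rowSums(prof[keep, , drop = FALSE]),
        "/")
}

#' Bootstrap cell-type enrichment of a gene set
#'
#' Compares the mean specificity of the gene set in each cell type with
#' the mean specificity of `n_boot` random background sets of the same
#' size (drawn without replacement within a draw). The p value uses the
#' add-one rule `p = (1 + #{null >= observed}) / (n_boot + 1)` and is
#' therefore never zero; fold change is observed over the null mean.
#'
#' @param gene_set genes (must all be specificity rows).
#' @param specificity gene x cell-type matrix with rows summing to 1.
#' @param n_boot bootstrap draws.
#' @param seed RNG seed.
#' @return data frame: celltype, observed, null_mean, fold, p, fdr.
#' @export
ewce_bootstrap <- function(gene_set, specificity, n_boot = 100000,
                           seed = 1L) {
  bg <- rownames(specificity)
  gene_set <- unique(gene_set)
  if (!all(gene_set %in% bg))
    stop("gene set must be a subset of the specificity rows")
  m <- length(gene_set)
  if (m > length(bg)) stop("set larger than the background")
  set.seed(seed)
  obs <- colMeans(specificity[gene_set, , drop = FALSE])
  idx <- vapply(seq_len(n_boot), function(i)
    sample.int(length(bg), m), integer(m))
  null <- vapply(colnames(specificity), function(ct) {
    v <- specificity[, ct]
    colMeans(matrix(v[idx], m, n_boot))
  }, numeric(n_boot))
  p <- (1 + colSums(sweep(null, 2, obs, ">="))) / (n_boot + 1)
  fold <- obs / colMeans(null)
  data.frame(celltype = colnames(specificity), observed = obs,
             null_mean = colMeans(null), fold = fold, p = p,
             fdr = p.adjust(p, "BH"), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment within groups
#'
#' @param p p values in (0, 1].
#' @param grouping optional grouping vector; adjustment is applied
#'   within each group.
#' @return adjusted values, monotone and bounded by one.
#' @export
adjust_bh <- function(p, grouping = NULL) {
  if (any(p <= 0 | p > 1 | is.na(p))) stop("p values must lie in (0, 1]")
  if (is.null(grouping)) return(p.adjust(p, "BH"))
  ave(p, grouping, FUN = function(x) p.adjust(x, "BH"))
}
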