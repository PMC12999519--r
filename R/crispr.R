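#' Filter cells by feature count and mitochondrial fraction
#'
#' Keeps cells with strictly more than `min_features` detected genes and
#' a mitochondrial read fraction strictly below `max_mito_frac`.
#'
#' @param counts gene x cell count matrix.
#' @param min_features minimum detected-feature count (exclusive).
#' @param max_mito_frac maximum mitochondrial fraction (exclusive).
#' @param mito_genes mitochondrial gene identifiers; when empty the mito
#'   filter is skipped with a warning.
#' @return the filtered count matrix.
#' @export
cell_qc <- function(counts, min_features = 200, max_mito_frac = 0.10,
                    mito_genes = grep("^MT-", rownames(counts),
                                      value = TRUE)) {
  feats <- colSums(counts > 0)
  keep <- feats > min_features
  if (!length(mito_genes)) {
    warning("empty mitochondrial gene list; mito filter skipped")
  } else {
    mito <- colSums(counts[intersect(mito_genes, rownames(counts)), ,
                           drop = FALSE]) / pmax(colSums(counts), 1)
    keep <- keep & mito < max_mito_frac
  }
  counts[, keep, drop = FALSE]
}

#' Assign cells to gRNA targets
#'
#' Per cell, guides with a UMI count of at least `min_umi` are collected
#' and collapsed to their targets; a cell is assigned when exactly one
#' target remains (several guides of the same target count once). With
#' `level = "guide"` exactly one guide above threshold is required
#' instead.
#'
#' @param grna_umi long data frame: cell, guide, umi.
#' @param guide_map data frame: guide, target, is_ntc.
#' @param min_umi UMI threshold applied per guide before collapsing.
#' @param level "target" (default) or "guide" uniqueness.
#' @return data frame of class `grna_assignment`: cell, target (NA when
#'   unassigned), umi (best supporting count), n_guides (distinct guides
#'   observed in the cell).
#' @export
assign_grnas <- function(grna_umi, guide_map, min_umi = 10,
                         level = c("target", "guide")) {
  level <- match.arg(level)
  unknown <- setdiff(unique(grna_umi$guide), guide_map$guide)
  if (length(unknown))
    stop("unmapped guide(s): ", paste(unknown, collapse = ", "))
  grna_umi$target <- guide_map$target[match(grna_umi$guide,
                                            guide_map$guide)]
  out <- do.call(rbind, lapply(split(grna_umi, grna_umi$cell),
                               function(dd) {
    hi <- dd[dd$umi >= min_umi, , drop = FALSE]
    units <- if (level == "target") unique(hi$target) else hi$guide
    assigned <- length(units) == 1
    data.frame(cell = dd$cell[1],
               target = if (assigned) {
                 if (level == "target") units else hi$target[1]
               } else NA_character_,
               umi = if (nrow(hi)) max(hi$umi) else max(dd$umi),
               n_guides = length(unique(dd$guide)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("grna_assignment", "data.frame")
  out
}

cpm_cells <- function(counts) {
  sweep(counts, 2, pmax(colSums(counts), 1), "/") * 1e6
}

#' Remaining target expression in knockdown cells relative to NTC
#'
#' Per replicate, the ratio of mean CPM of the target gene in cells
#' assigned to that target over the mean in NTC-assigned cells.
#'
#' @param counts gene x cell counts.
#' @param assignments a `grna_assignment`.
#' @param target target gene.
#' @param replicates named vector mapping cells to replicates.
#' @return data frame: replicate, ratio (NA when a replicate lacks
#'   target cells or has zero NTC expression).
#' @export
knockdown_ratio <- function(counts, assignments, target, replicates) {
  stopifnot(target %in% rownames(counts))
  cpmm <- cpm_cells(counts)[target, ]
  asg <- assignments[!is.na(assignments$target), , drop = FALSE]
  asg <- asg[asg$cell %in% colnames(counts), , drop = FALSE]
  reps <- sort(unique(replicates))
  do.call(rbind, lapply(reps, function(r) {
    cells_r <- names(replicates)[replicates == r]
    tc <- asg$cell[asg$target == target & asg$cell %in% cells_r]
    nc <- asg$cell[asg$target == "NTC" & asg$cell %in% cells_r]
    ratio <- if (!length(tc) || !length(nc)) NA_real_ else {
      denom <- mean(cpmm[nc])
      if (denom == 0) NA_real_ else mean(cpmm[tc]) / denom
    }
    data.frame(replicate = r, ratio = ratio, n_target = length(tc),
               n_ntc = length(nc), stringsAsFactors = FALSE)
  }))
}

#' Pseudobulk differential expression of a target versus NTC
#'
#' Counts are summed per (arm, replicate); the per-gene test is a
#' moderated two-sample comparison on log2 CPM pseudobulk profiles
#' (pooled variance shrunken across genes with empirical-Bayes
#' moderation), with BH adjustment. logFC sign is target minus NTC.
#'
#' @param counts gene x cell counts.
#' @param assignments a `grna_assignment`.
#' @param target target gene; cells assigned to it form one arm, cells
#'   assigned NTC the other.
#' @param replicates named vector mapping cells to replicates (>= 2 per
#'   arm).
#' @return data frame: gene, logFC, stat, p, fdr.
#' @export
pseudobulk_de <- function(counts, assignments, target, replicates) {
  asg <- assignments[!is.na(assignments$target), , drop = FALSE]
  arms <- list(target = asg$cell[asg$target == target],
               NTC = asg$cell[asg$target == "NTC"])
  arms <- lapply(arms, intersect, colnames(counts))
  pb <- list()
  grp <- character(0)
  for (a in names(arms)) {
    cells <- arms[[a]]
    rr <- replicates[cells]
    reps <- unique(rr)
    if (length(reps) < 2)
      stop("arm ", a, " has fewer than 2 replicates")
    for (r in reps) {
      pb[[paste(a, r, sep = ".")]] <-
        rowSums(counts[, cells[rr == r], drop = FALSE])
      grp <- c(grp, a)
    }
  }
  pbm <- do.call(cbind, pb)
  lib <- colSums(pbm)
  logcpm <- log2(sweep(pbm + 0.5, 2, lib, "/") * 1e6)
  design <- model.matrix(~ factor(grp, levels = c("NTC", "target")))
  fit <- limma::eBayes(limma::lmFit(logcpm, design))
  tt <- limma::topTable(fit, coef = 2, number = Inf, sort.by = "none")
  data.frame(gene = rownames(tt), logFC = tt$logFC, stat = tt$t,
             p = tt$P.Value, fdr = tt$adj.P.Val, row.names = NULL,
             stringsAsFactors = FALSE)
}
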