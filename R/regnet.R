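#' Harmonize a regulator annotation table to a gene universe
#'
#' Drops duplicate pairs and pairs whose regulator or target falls
#' outside the expression universe, reporting the dropped count.
#'
#' @param annot data frame (regulator, target, high_confidence).
#' @param universe gene identifiers.
#' @return the filtered annotation with a `dropped` attribute.
#' @export
harmonize_annotation <- function(annot, universe) {
  key <- paste(annot$regulator, annot$target)
  annot <- annot[!duplicated(key), , drop = FALSE]
  keep <- annot$regulator %in% universe & annot$target %in% universe
  out <- annot[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- sum(!keep)
  out
}

#' kME-weighted module-to-module regulation score
#'
#' The score of ordered pair U -> V is the sum of kME values (with
#' respect to V's eigengene) of the genes in V that are annotated targets
#' of at least one high-confidence regulator residing in U, divided by
#' the total number of genes in V. Genes regulated by several U
#' regulators are counted once; negative kME values enter as-is.
#'
#' @param modules a `module_set`.
#' @param annot regulator annotation (regulator, target,
#'   high_confidence).
#' @param U,V module ids (U != V).
#' @return the score (non-negative in typical use; bounded by the
#'   maximum own-module kME).
#' @export
module_regulation_score <- function(modules, annot, U, V) {
  stopifnot(inherits(modules, "module_set"))
  if (U == V) stop("U and V must differ")
  lab <- modules$labels
  genes_U <- names(lab)[lab == U]
  genes_V <- names(lab)[lab == V]
  if (!length(genes_V)) stop("module V is empty")
  if (!length(genes_U)) stop("module U is empty")
  hc <- annot[annot$high_confidence & annot$regulator %in% genes_U, ,
              drop = FALSE]
  regulated <- intersect(unique(hc$target), genes_V)
  if (!length(regulated)) return(0)
  sum(modules$kme[regulated, as.character(V)]) / length(genes_V)
}

#' Module regulation graph with mean + 1 SD edge threshold
#'
#' Scores every ordered module pair and declares an edge where the score
#' strictly exceeds one standard deviation above the mean over all
#' ordered pairs (population SD by default). Per-module out-degree and
#' the fraction of other modules regulated are reported.
#'
#' @param modules a `module_set`.
#' @param annot regulator annotation.
#' @param sd_type "population" (n denominator) or "sample" (n - 1).
#' @return list of class `module_regulation_graph`: `scores` (from, to,
#'   score, is_edge), `threshold`, `out_degree` data frame.
#' @export
regulation_graph <- function(modules, annot,
                             sd_type = c("population", "sample")) {
  stopifnot(inherits(modules, "module_set"))
  sd_type <- match.arg(sd_type)
  mods <- sort(unique(modules$labels[modules$labels > 0]))
  if (length(mods) < 2) stop("need at least 2 modules")
  pairs <- expand.grid(from = mods, to = mods)
  pairs <- pairs[pairs$from != pairs$to, ]
  pairs$score <- mapply(function(u, v)
    module_regulation_score(modules, annot, u, v),
    pairs$from, pairs$to)
  mu <- mean(pairs$score)
  sdv <- sd(pairs$score)
  if (sd_type == "population")
    sdv <- sdv * sqrt((nrow(pairs) - 1) / nrow(pairs))
  thr <- mu + sdv
  if (sdv == 0) warning("all scores identical; zero edges")
  pairs$is_edge <- pairs$score > thr
  outdeg <- do.call(rbind, lapply(mods, function(m) {
    e <- pairs$is_edge[pairs$from == m]
    data.frame(module = m, out_degree = sum(e),
               frac_modules_regulated = mean(e))
  }))
  rownames(pairs) <- NULL
  structure(list(scores = pairs, threshold = thr, out_degree = outdeg),
            class = "module_regulation_graph")
}

#' @export
print.module_regulation_graph <- function(x, ...) {
  cat(sprintf("module_regulation_graph: %d ordered pairs, threshold %.4f, %d edges\n",
              nrow(x$scores), x$threshold, sum(x$scores$is_edge)))
  invisible(x)
}

#' Regulator-target expression correlations
#'
#' Spearman correlation across samples for every annotated pair with
#' both genes in the expression matrix, plus the fraction of negative
#' correlations. Pairs with a constant gene are skipped with a note.
#'
#' @param expr an `expr_matrix` or gene x sample matrix.
#' @param annot regulator annotation.
#' @param regulators_in optional module id: restrict to regulators with
#'   that module label (requires `modules`).
#' @param modules optional `module_set` used with `regulators_in`.
#' @return list: `pairs` (regulator, target, rho), `fraction_negative`,
#'   `skipped` pair count.
#' @export
regulator_target_correlations <- function(expr, annot,
                                          regulators_in = NULL,
                                          modules = NULL) {
  V <- if (inherits(expr, "expr_matrix")) expr$values else as.matrix(expr)
  aa <- annot[annot$regulator %in% rownames(V) &
                annot$target %in% rownames(V), , drop = FALSE]
  if (!is.null(regulators_in)) {
    stopifnot(inherits(modules, "module_set"))
    lab <- modules$labels
    aa <- aa[aa$regulator %in% names(lab)[lab == regulators_in], ,
             drop = FALSE]
  }
  skipped <- 0L
  rho <- vapply(seq_len(nrow(aa)), function(i) {
    x <- V[aa$regulator[i], ]; y <- V[aa$target[i], ]
    if (sd(x) == 0 || sd(y) == 0) {
      skipped <<- skipped + 1L
      return(NA_real_)
    }
    cor(x, y, method = "spearman")
  }, numeric(1))
  pairs <- data.frame(regulator = aa$regulator, target = aa$target,
                      rho = rho, stringsAsFactors = FALSE)
  pairs <- pairs[!is.na(pairs$rho), , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs,
       fraction_negative = if (nrow(pairs)) mean(pairs$rho < 0) else NA_real_,
       skipped = skipped)
}

#' Risk genes regulated through the module graph
#'
#' Restricts to genes in downstream (edge-target) modules that are
#' annotated targets of at least one high-confidence regulator in the
#' corresponding upstream module and that belong to a named risk set. A
#' gene targeted by several regulators appears once, with all regulators
#' listed.
#'
#' @param graph a `module_regulation_graph`.
#' @param modules a `module_set`.
#' @param annot regulator annotation.
#' @param risk_sets named list of risk gene sets.
#' @return data frame: gene, module, risk_sets, upstream_module,
#'   regulators (comma-separated).
#' @export
regulated_riskgene_table <- function(graph, modules, annot, risk_sets) {
  stopifnot(inherits(graph, "module_regulation_graph"))
  edges <- graph$scores[graph$scores$is_edge, , drop = FALSE]
  if (!nrow(edges)) stop("graph has no edges")
  if (!nrow(annot))
    return(data.frame(gene = character(0), module = integer(0),
                      risk_sets = character(0), upstream_module = integer(0),
                      regulators = character(0)))
  lab <- modules$labels
  risk_all <- unique(unlist(risk_sets))
  rows <- do.call(rbind, lapply(seq_len(nrow(edges)), function(i) {
    u <- edges$from[i]; v <- edges$to[i]
    regs_u <- intersect(unique(annot$regulator[annot$high_confidence]),
                        names(lab)[lab == u])
    aa <- annot[annot$regulator %in% regs_u, , drop = FALSE]
    g <- intersect(intersect(unique(aa$target), names(lab)[lab == v]),
                   risk_all)
    if (!length(g)) return(NULL)
    do.call(rbind, lapply(g, function(gg) {
      in_sets <- names(risk_sets)[vapply(risk_sets, function(s)
        gg %in% s, logical(1))]
      data.frame(gene = gg, module = v,
                 risk_sets = paste(in_sets, collapse = ","),
                 upstream_module = u,
                 regulators = paste(sort(unique(
                   aa$regulator[aa$target == gg])), collapse = ","),
                 stringsAsFactors = FALSE)
    }))
  }))
  if (is.null(rows))
    rows <- data.frame(gene = character(0), module = integer(0),
                       risk_sets = character(0),
                       upstream_module = integer(0),
                       regulators = character(0))
  rownames(rows) <- NULL
  rows
}
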