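#' Network construction parameters
#'
#' @param beta soft-threshold power (positive integer).
#' @param resamples number of resampled networks for the consensus.
#' @param min_per_form minimum distinct samples per form in every
#'   resample.
#' @param min_module_size smallest allowed module.
#' @param deep_split branch-splitting sensitivity, 0-4.
#' @param cut_height_detect static tree-cut height for branch extraction.
#' @param cut_height_merge eigengene-dissimilarity height below which
#'   modules are merged.
#' @param kme_adopt unassigned genes with a kME at or above this value
#'   are adopted by the best-matching module.
#' @param seed RNG seed for resampling.
#' @return list of class `network_params`.
#' @export
network_params <- function(beta = 6, resamples = 100, min_per_form = 4,
                           min_module_size = 30, deep_split = 4,
                           cut_height_detect = 0.9999,
                           cut_height_merge = 0.1,
                           kme_adopt = 0.3, seed = 1L) {
  stopifnot(beta >= 1, cut_height_detect > 0, cut_height_detect <= 1,
            cut_height_merge > 0, cut_height_merge <= 1,
            deep_split %in% 0:4)
  structure(as.list(environment()), class = "network_params")
}

#' Choose the soft-threshold power for approximate scale-free topology
#'
#' For each candidate power the signed-adjacency connectivities are
#' binned (about 10 bins) and `log10(frequency)` is regressed on
#' `log10(mean connectivity)`; the model fit is reported with the sign of
#' the negative slope. The smallest power reaching `target_r2` is
#' returned, or the power with the best fit plus a warning flag when the
#' target is unreachable.
#'
#' @param expr an `expr_matrix` or gene x sample matrix (>= 30 genes).
#' @param candidate_betas powers scanned.
#' @param target_r2 required signed scale-free fit.
#' @param n_bins connectivity histogram bins.
#' @return list: `beta`, `reached_target`, `fit_table` (beta, r2,
#'   mean_connectivity).
#' @export
pick_soft_threshold <- function(expr, candidate_betas = 1:20,
                                target_r2 = 0.8, n_bins = 10) {
  V <- if (inherits(expr, "expr_matrix")) expr$values else as.matrix(expr)
  if (nrow(V) < 30) stop("need at least 30 genes")
  S <- (1 + cor(t(V))) / 2
  diag(S) <- 0
  fit <- do.call(rbind, lapply(candidate_betas, function(b) {
    k <- rowSums(S^b)
    br <- seq(min(k), max(k), length.out = n_bins + 1)
    bin <- cut(k, breaks = br, include.lowest = TRUE)
    freq <- as.numeric(table(bin))
    km <- tapply(k, bin, mean)
    occ <- freq > 0 & !is.na(km) & km > 0
    if (sum(occ) < 2) stop("fewer than 2 occupied connectivity bins")
    lf <- log10(freq[occ]); lk <- log10(km[occ])
    m <- lm(lf ~ lk)
    r2 <- summary(m)$r.squared * -sign(coef(m)[2])
    data.frame(beta = b, r2 = r2, mean_connectivity = mean(k))
  }))
  ok <- fit$beta[fit$r2 >= target_r2]
  if (length(ok)) {
    list(beta = min(ok), reached_target = TRUE, fit_table = fit)
  } else {
    warning("scale-free target R^2 not reached; using best fit")
    list(beta = fit$beta[which.max(fit$r2)], reached_target = FALSE,
         fit_table = fit)
  }
}

#' Signed co-expression adjacency
#'
#' `a_ij = ((1 + cor(i, j)) / 2)^beta`, diagonal one.
#'
#' @param expr an `expr_matrix` or gene x sample matrix.
#' @param beta soft-threshold power.
#' @return gene x gene adjacency in \[0, 1\].
#' @export
signed_adjacency <- function(expr, beta) {
  V <- if (inherits(expr, "expr_matrix")) expr$values else as.matrix(expr)
  sds <- apply(V, 1, sd)
  if (any(sds == 0))
    stop("constant gene(s): ",
         paste(head(rownames(V)[sds == 0], 5), collapse = ", "))
  A <- ((1 + cor(t(V))) / 2)^beta
  diag(A) <- 1
  A
}

#' Topological overlap dissimilarity
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' the sum over shared neighbours `u != i, j` and `k_i = sum_{u != i}
#' a_iu`; the dissimilarity is `1 - TOM` with zero diagonal.
#'
#' @param adjacency symmetric gene x gene matrix with unit diagonal.
#' @return gene x gene dissimilarity in \[0, 1\].
#' @export
tom_dissimilarity <- function(adjacency) {
  A <- as.matrix(adjacency)
  if (max(abs(A - t(A))) > 1e-10) stop("adjacency must be symmetric")
  # with unit diagonal, (A %*% A)_ij counts the shared-neighbour sum plus
  # both endpoint terms a_ij * (a_ii + a_jj) = 2 a_ij
  L <- A %*% A - 2 * A
  k <- rowSums(A) - 1
  denom <- outer(k, k, pmin) + 1 - A
  tom <- (L + A) / denom
  diag(tom) <- 1
  d <- 1 - tom
  diag(d) <- 0
  dimnames(d) <- dimnames(A)
  d
}

#' Form-balanced resampled consensus TOM dissimilarity
#'
#' Each iteration resamples, within every form, that form's samples with
#' replacement to their original count, re-drawing until at least
#' `min_per_form` distinct samples per form are present; a signed
#' adjacency and TOM dissimilarity are built on the resampled columns and
#' the consensus is the element-wise median across iterations.
#'
#' @param expr an `expr_matrix`.
#' @param meta sample metadata (defaults to `expr$samples`).
#' @param params a [network_params()] object.
#' @param resample set FALSE to skip resampling (plain TOM, one pass).
#' @return gene x gene consensus dissimilarity.
#' @export
consensus_resampled_tom <- function(expr, meta = expr$samples, params,
                                    resample = TRUE) {
  stopifnot(inherits(expr, "expr_matrix"),
            inherits(params, "network_params"))
  if (!resample)
    return(tom_dissimilarity(signed_adjacency(expr, params$beta)))
  set.seed(params$seed)
  forms <- split(seq_len(nrow(meta)), meta$form)
  small <- names(forms)[lengths(forms) < params$min_per_form]
  if (length(small))
    stop("form(s) with fewer than ", params$min_per_form, " samples: ",
         paste(small, collapse = ", "))
  toms <- vector("list", params$resamples)
  for (it in seq_len(params$resamples)) {
    cols <- unlist(lapply(forms, function(idx) {
      repeat {
        s <- sample(idx, length(idx), replace = TRUE)
        if (length(unique(s)) >= params$min_per_form) return(s)
      }
    }), use.names = FALSE)
    toms[[it]] <- tom_dissimilarity(
      signed_adjacency(expr$values[, cols, drop = FALSE], params$beta))
  }
  .matrix_list_median(toms)
}

## branch decomposition of an average-linkage tree: recursively split a
## branch when both children meet the deep-split-scaled size floor
branch_modules <- function(tree, cut_height, min_size, deep_split) {
  n <- length(tree$order)
  floor_split <- max(3, ceiling(min_size * (1 - deep_split / 6)))
  members <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    m <- tree$merge[i, ]
    take <- function(x) if (x < 0) -x else members[[x]]
    members[[i]] <- c(take(m[1]), take(m[2]))
  }
  modules <- list()
  # returns TRUE when at least one module was emitted under the node;
  # a branch that is large enough but whose recursion emitted nothing
  # becomes a module itself, so coherent branches with balanced internal
  # splits are never silently discarded (over-splitting is undone later
  # by the eigengene merge step)
  descend <- function(node) {
    if (node < 0) return(FALSE)
    if (length(members[[node]]) < min_size) return(FALSE)
    m <- tree$merge[node, ]
    s1 <- if (m[1] < 0) 1L else length(members[[m[1]]])
    s2 <- if (m[2] < 0) 1L else length(members[[m[2]]])
    emitted <- if (s1 >= floor_split && s2 >= floor_split) {
      # both branches are substantial: split
      e1 <- descend(m[1]); e2 <- descend(m[2])
      e1 || e2
    } else if (max(s1, s2) >= min_size) {
      # shave the small side off (left for kME adoption) and keep
      # descending the dominant branch
      descend(m[which.max(c(s1, s2))])
    } else FALSE
    if (!emitted)
      modules[[length(modules) + 1]] <<- members[[node]]
    TRUE
  }
  roots <- which(tree$height <= cut_height)
  # maximal nodes below the cut: nodes whose parent is above the cut
  parent <- integer(n - 1)
  for (i in seq_len(n - 1)) {
    m <- tree$merge[i, ]
    if (m[1] > 0) parent[m[1]] <- i
    if (m[2] > 0) parent[m[2]] <- i
  }
  top <- roots[vapply(roots, function(i)
    parent[i] == 0 || tree$height[parent[i]] > cut_height, logical(1))]
  for (node in top) descend(node)
  modules
}

#' Detect modules on a consensus dissimilarity
#'
#' Average-linkage clustering of the consensus dissimilarity; branches
#' below `cut_height_detect` holding at least `min_module_size` genes
#' become modules, recursively split at a sensitivity set by
#' `deep_split`. When expression is supplied, unassigned genes with a
#' best kME of at least `kme_adopt` are adopted, and modules whose
#' eigengene dissimilarity (1 - correlation) falls below
#' `cut_height_merge` are merged iteratively. Labels are relabelled
#' 1..M by decreasing size; 0 marks unassigned genes.
#'
#' @param consensus_diss gene x gene dissimilarity.
#' @param params a [network_params()] object.
#' @param expr optional `expr_matrix` (or matrix) enabling kME adoption
#'   and eigengene merging.
#' @return named integer vector of module labels.
#' @export
detect_modules <- function(consensus_diss, params, expr = NULL) {
  stopifnot(inherits(params, "network_params"))
  n <- nrow(consensus_diss)
  if (params$min_module_size > n)
    stop("min_module_size exceeds the gene count")
  tree <- hclust(as.dist(consensus_diss), method = "average")
  mods <- branch_modules(tree, params$cut_height_detect,
                         params$min_module_size, params$deep_split)
  labels <- integer(n)
  names(labels) <- rownames(consensus_diss)
  for (i in seq_along(mods)) labels[mods[[i]]] <- i
  if (!is.null(expr) && length(mods)) {
    V <- if (inherits(expr, "expr_matrix")) expr$values else as.matrix(expr)
    V <- V[names(labels), , drop = FALSE]
    ms <- module_eigengenes_kme(V, labels)
    un <- labels == 0
    if (any(un)) {
      best <- apply(ms$kme[un, , drop = FALSE], 1, which.max)
      bestv <- ms$kme[cbind(which(un), best)]
      adopt <- bestv >= params$kme_adopt
      labels[which(un)[adopt]] <- as.integer(colnames(ms$kme)[best[adopt]])
    }
    repeat {
      ms <- module_eigengenes_kme(V, labels)
      if (ncol(ms$eigengenes) < 2) break
      dd <- 1 - cor(ms$eigengenes)
      diag(dd) <- Inf
      if (min(dd) >= params$cut_height_merge) break
      ij <- which(dd == min(dd), arr.ind = TRUE)[1, ]
      keep <- as.integer(colnames(dd)[min(ij)])
      drop_ <- as.integer(colnames(dd)[max(ij)])
      labels[labels == drop_] <- keep
    }
  }
  # relabel by decreasing size
  sz <- sort(table(labels[labels > 0]), decreasing = TRUE)
  relab <- setNames(seq_along(sz), names(sz))
  labels[labels > 0] <- relab[as.character(labels[labels > 0])]
  labels
}

#' Module eigengenes and kME
#'
#' The eigengene of a module is the first principal component of its
#' standardized expression submatrix, sign-oriented so the mean kME of
#' the module's own genes is positive; kME is the correlation of every
#' gene with every eigengene.
#'
#' @param expr an `expr_matrix` or gene x sample matrix.
#' @param labels named integer module labels (0 = unassigned).
#' @return object of class `module_set`: `labels`, `eigengenes`
#'   (sample x module), `kme` (gene x module), `var_explained`.
#' @export
module_eigengenes_kme <- function(expr, labels) {
  V <- if (inherits(expr, "expr_matrix")) expr$values else as.matrix(expr)
  labels <- labels[rownames(V)]
  mods <- sort(unique(labels[labels > 0]))
  if (!length(mods)) stop("no modules in labels")
  me <- matrix(NA_real_, ncol(V), length(mods),
               dimnames = list(colnames(V), as.character(mods)))
  ve <- numeric(length(mods))
  for (i in seq_along(mods)) {
    sub <- V[labels == mods[i], , drop = FALSE]
    if (nrow(sub) < 2) stop("module ", mods[i], " has fewer than 2 genes")
    sds <- apply(sub, 1, sd)
    if (any(sds == 0)) stop("module ", mods[i], " contains constant genes")
    Z <- (sub - rowMeans(sub)) / sds
    sv <- svd(Z, nu = 1, nv = 1)
    e <- sv$v[, 1]
    if (mean(cor(t(sub), e)) < 0) e <- -e
    me[, i] <- e
    ve[i] <- sv$d[1]^2 / sum(sv$d^2)
  }
  kme <- cor(t(V), me)
  structure(list(labels = labels, eigengenes = me, kme = kme,
                 var_explained = setNames(ve, as.character(mods))),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  cat(sprintf("module_set: %d modules over %d genes (%d unassigned)\n",
              ncol(x$eigengenes), length(x$labels), sum(x$labels == 0)))
  invisible(x)
}

#' Module-trait association (form and diagnosis)
#'
#' Per module, two linear models on the eigengene: `ME ~ form` (factor
#' with control as base, one beta per level) and `ME ~ diagnosis`. The
#' signed adjusted R is `sign(sum of coefficients) *
#' sqrt(max(adjusted R^2, 0))`; set `signed_r_squared = TRUE` for the
#' signed adjusted R^2 itself. BH is applied across modules within each
#' term.
#'
#' @param eigengenes sample x module matrix.
#' @param meta sample metadata with `form` and `diagnosis` columns.
#' @param signed_r_squared report signed adjusted R^2 instead of its
#'   square root.
#' @return data frame: module, term, beta, p, fdr, signed_adjusted_R.
#' @export
module_trait_association <- function(eigengenes, meta,
                                     signed_r_squared = FALSE) {
  stopifnot("control" %in% meta$form)
  meta$form <- stats::relevel(factor(meta$form), ref = "control")
  small <- names(which(table(meta$form) < 2))
  if (length(small)) {
    warning("dropping form level(s) with < 2 samples: ",
            paste(small, collapse = ", "))
    keep <- !(meta$form %in% small)
    meta <- droplevels(meta[keep, , drop = FALSE])
    eigengenes <- eigengenes[keep, , drop = FALSE]
  }
  meta$diagnosis <- stats::relevel(factor(meta$diagnosis), ref = "control")
  rows <- do.call(rbind, lapply(colnames(eigengenes), function(m) {
    y <- eigengenes[, m]
    sr <- function(fit) {
      s <- summary(fit)
      r <- sqrt(max(s$adj.r.squared, 0))
      if (signed_r_squared) r <- max(s$adj.r.squared, 0)
      sign(sum(coef(fit)[-1])) * r
    }
    f1 <- lm(y ~ form, data = meta)
    s1 <- summary(f1)$coefficients
    lv <- rownames(s1)[-1]
    d1 <- data.frame(module = m, term = sub("^form", "form:", lv),
                     beta = s1[-1, 1], p = s1[-1, 4],
                     signed_adjusted_R = sr(f1), stringsAsFactors = FALSE)
    f2 <- lm(y ~ diagnosis, data = meta)
    s2 <- summary(f2)$coefficients
    d2 <- data.frame(module = m, term = "diagnosis",
                     beta = s2[2, 1], p = s2[2, 4],
                     signed_adjusted_R = sr(f2), stringsAsFactors = FALSE)
    rbind(d1, d2)
  }))
  rows$fdr <- ave(rows$p, rows$term, FUN = function(p) p.adjust(p, "BH"))
  rownames(rows) <- NULL
  rows
}

#' Spline trajectory test of module eigengenes over differentiation
#'
#' Models each eigengene with a quadratic polynomial spline of day
#' (df = 2, degree = 2) and tests, for each form against control, the
#' interaction between the spline basis and the form indicator with an
#' F-test.
#'
#' @param eigengenes sample x module matrix.
#' @param meta sample metadata with `day` and `form`.
#' @return data frame: module, form, F, df1, df2, p, fdr (BH across
#'   module x form).
#' @export
module_trajectory_test <- function(eigengenes, meta) {
  days <- unique(meta$day)
  if (length(days) < 3) stop("need at least 3 distinct days")
  forms <- setdiff(unique(meta$form), "control")
  rows <- do.call(rbind, lapply(colnames(eigengenes), function(m)
    do.call(rbind, lapply(forms, function(f) {
      keep <- meta$form %in% c("control", f)
      dd <- data.frame(y = eigengenes[keep, m],
                       day = meta$day[keep],
                       aff = factor(meta$form[keep] != "control"))
      B <- splines::bs(dd$day, df = 2, degree = 2)
      full <- lm(y ~ B * aff, data = dd)
      red <- lm(y ~ B + aff, data = dd)
      a <- anova(red, full)
      data.frame(module = m, form = f, F = a$F[2], df1 = a$Df[2],
                 df2 = a$Res.Df[2], p = a$`Pr(>F)`[2],
                 stringsAsFactors = FALSE)
    }))))
  rows$fdr <- p.adjust(rows$p, "BH")
  rownames(rows) <- NULL
  rows
}

#' Lightweight module preservation statistics
#'
#' `Z_density` compares the mean within-module adjacency in the test data
#' with a label-permutation null; `Z_connectivity` does the same for the
#' correlation of intramodular connectivities between reference and test.
#' `Z_summary` is their mean.
#'
#' @param expr_ref,expr_test `expr_matrix` or gene x sample matrices with
#'   a shared gene universe of at least 50 genes.
#' @param labels_ref named module labels defined on the reference.
#' @param beta soft power used for both adjacencies.
#' @param n_perm label permutations for the null.
#' @param seed RNG seed.
#' @return data frame: module, n_genes, z_density, z_connectivity,
#'   z_summary; modules with fewer than 3 shared genes are skipped with
#'   a note attribute.
#' @export
module_preservation_lite <- function(expr_ref, labels_ref, expr_test,
                                     beta = 6, n_perm = 100, seed = 1L) {
  Vr <- if (inherits(expr_ref, "expr_matrix")) expr_ref$values else
    as.matrix(expr_ref)
  Vt <- if (inherits(expr_test, "expr_matrix")) expr_test$values else
    as.matrix(expr_test)
  shared <- intersect(rownames(Vr), rownames(Vt))
  if (length(shared) < 50) stop("shared gene universe below 50 genes")
  set.seed(seed)
  lab <- labels_ref[shared]
  Ar <- signed_adjacency(Vr[shared, , drop = FALSE], beta)
  At <- signed_adjacency(Vt[shared, , drop = FALSE], beta)
  mods <- sort(unique(lab[lab > 0]))
  skipped <- character(0)
  stat_pair <- function(l, m) {
    idx <- which(l == m)
    sub <- At[idx, idx, drop = FALSE]
    dens <- mean(sub[upper.tri(sub)])
    kr <- rowSums(Ar[idx, idx, drop = FALSE]) - 1
    kt <- rowSums(At[idx, idx, drop = FALSE]) - 1
    conn <- if (sd(kr) == 0 || sd(kt) == 0) 0 else cor(kr, kt)
    c(dens, conn)
  }
  rows <- do.call(rbind, lapply(mods, function(m) {
    idx <- which(lab == m)
    if (length(idx) < 3) {
      skipped <<- c(skipped, as.character(m))
      return(NULL)
    }
    obs <- stat_pair(lab, m)
    null <- vapply(seq_len(n_perm), function(i)
      stat_pair(sample(lab), m), numeric(2))
    zof <- function(o, nv) {
      # degenerate null (e.g. test == ref makes every connectivity
      # correlation exactly one up to rounding)
      if (sd(nv) < 1e-10 * max(1, abs(mean(nv)))) return(NA_real_)
      (o - mean(nv)) / sd(nv)
    }
    zd <- zof(obs[1], null[1, ])
    zc <- zof(obs[2], null[2, ])
    data.frame(module = m, n_genes = length(idx), z_density = zd,
               z_connectivity = zc,
               z_summary = mean(c(zd, zc), na.rm = TRUE))
  }))
  attr(rows, "skipped") <- skipped
  rows
}
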