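#' Gene x condition logFC matrix from differential-expression rows
#'
#' Conditions are form x day combinations; the matrix is restricted to the
#' genes present in every condition.
#'
#' @param de `de_result` rows (gene, form, day, logFC).
#' @return matrix genes x conditions with columns named `form_day`.
#' @export
condition_logfc_matrix <- function(de) {
  cond <- interaction(de$form, de$day, sep = "_", drop = TRUE)
  per_cond <- split(de, cond)
  shared <- Reduce(intersect, lapply(per_cond, function(d) d$gene))
  if (!length(shared)) stop("empty gene intersection across conditions")
  out <- vapply(per_cond, function(d)
    d$logFC[match(shared, d$gene)], numeric(length(shared)))
  rownames(out) <- shared
  out
}

condition_day <- function(lfc) {
  sub("^.*_", "", colnames(lfc))
}

condition_form <- function(lfc) {
  sub("_[^_]*$", "", colnames(lfc))
}

#' Correlate and cluster condition logFC signatures
#'
#' Spearman correlation between condition columns, then hierarchical
#' clustering of the correlation-matrix rows by Ward linkage (squared
#' increment, "ward.D2") on Euclidean distance.
#'
#' @param lfc matrix from [condition_logfc_matrix()].
#' @param cluster_method hclust agglomeration method.
#' @param distance distance measure over correlation rows.
#' @param cor_method correlation estimator between conditions.
#' @return list with `correlation` (condition x condition) and `tree`
#'   (hclust).
#' @export
correlation_and_cluster <- function(lfc, cluster_method = "ward.D2",
                                    distance = "euclidean",
                                    cor_method = "spearman") {
  if (ncol(lfc) < 3) stop("need at least 3 conditions")
  sds <- apply(lfc, 2, sd)
  if (any(sds == 0))
    stop("constant condition column(s): ",
         paste(colnames(lfc)[sds == 0], collapse = ", "))
  C <- cor(lfc, method = cor_method)
  tree <- hclust(dist(C, method = distance), method = cluster_method)
  list(correlation = C, tree = tree)
}

tree_clusters <- function(tree) {
  n <- length(tree$labels)
  sets <- vector("list", n - 1)
  members <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    m <- tree$merge[i, ]
    take <- function(x) if (x < 0) tree$labels[-x] else members[[x]]
    members[[i]] <- c(take(m[1]), take(m[2]))
    sets[[i]] <- paste(sort(members[[i]]), collapse = "+")
  }
  sets
}

#' Multiscale bootstrap support for condition clusters
#'
#' For each scale r, genes are resampled with replacement to size
#' `ceiling(r * n_genes)` and the conditions re-clustered; BP_r is the
#' frequency with which each original cluster reappears. The
#' approximately unbiased value comes from the weighted least-squares fit
#' `qnorm(1 - BP_r) = v * sqrt(r) + c / sqrt(r)`, with
#' `AU = 1 - pnorm(v - c)`. The bootstrap budget is split evenly across
#' scales; BP is reported at the scale closest to 1. Frequencies of
#' exactly 0 or 1 are clamped to `1/(2B)` and `1 - 1/(2B)` before the
#' probit.
#'
#' @param lfc matrix from [condition_logfc_matrix()] (>= 10 genes).
#' @param n_boot total bootstrap replicates across scales.
#' @param scales relative resampling sizes.
#' @param seed RNG seed.
#' @param cluster_method,distance,cor_method as in
#'   [correlation_and_cluster()].
#' @return list (class `cluster_support`): `tree`, data frame `support`
#'   (cluster members, bp, au), `bp_by_scale` matrix, `n_per_scale`.
#' @export
multiscale_bootstrap <- function(lfc, n_boot = 10000,
                                 scales = seq(0.5, 1.4, by = 0.1),
                                 seed = 1L,
                                 cluster_method = "ward.D2",
                                 distance = "euclidean",
                                 cor_method = "spearman") {
  if (nrow(lfc) < 10) stop("need at least 10 genes")
  set.seed(seed)
  ref <- correlation_and_cluster(lfc, cluster_method, distance, cor_method)
  ref_sets <- unlist(tree_clusters(ref$tree))
  B <- max(1L, ceiling(n_boot / length(scales)))
  n <- nrow(lfc)
  bp <- matrix(0, length(ref_sets), length(scales),
               dimnames = list(ref_sets, paste0("r", scales)))
  for (si in seq_along(scales)) {
    m <- ceiling(scales[si] * n)
    hit <- numeric(length(ref_sets))
    for (b in seq_len(B)) {
      idx <- sample.int(n, m, replace = TRUE)
      sub <- lfc[idx, , drop = FALSE]
      sds <- apply(sub, 2, sd)
      if (any(sds == 0)) next
      tr <- hclust(dist(cor(sub, method = cor_method), method = distance),
                   method = cluster_method)
      hit <- hit + (ref_sets %in% unlist(tree_clusters(tr)))
    }
    bp[, si] <- hit / B
  }
  au <- apply(bp, 1, function(bpr) {
    bpr <- pmin(pmax(bpr, 1 / (2 * B)), 1 - 1 / (2 * B))
    if (all(bpr >= 1 - 1 / (2 * B))) return(1)
    if (all(bpr <= 1 / (2 * B))) return(NA_real_)
    z <- qnorm(1 - bpr)
    w <- B * dnorm(z)^2 / (bpr * (1 - bpr))
    X <- cbind(sqrt(scales), 1 / sqrt(scales))
    fit <- lm.fit(X * sqrt(w), z * sqrt(w))
    1 - pnorm(fit$coefficients[1] - fit$coefficients[2])
  })
  near1 <- which.min(abs(scales - 1))
  structure(list(tree = ref$tree,
                 support = data.frame(cluster = ref_sets,
                                      bp = bp[, near1], au = au,
                                      row.names = NULL,
                                      stringsAsFactors = FALSE),
                 bp_by_scale = bp, n_per_scale = B, scales = scales),
            class = "cluster_support")
}

#' Plain Rand index between two partitions
#'
#' Fraction of the `n(n-1)/2` item pairs on which the two partitions
#' agree (together in both, or apart in both).
#'
#' @param a,b integer/character cluster labels of the same items.
#' @return Rand index in \[0, 1\]; 1 iff the partitions are identical.
#' @export
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  pr <- combn(length(a), 2)
  sa <- a[pr[1, ]] == a[pr[2, ]]
  sb <- b[pr[1, ]] == b[pr[2, ]]
  mean(sa == sb)
}

#' Concordance of clusterings across methods, distances and subsamples
#'
#' For every pair of (method, distance) combinations: the cophenetic
#' correlation (Pearson correlation of cophenetic distance matrices) and
#' the Rand index between `k`-cluster cuts. Additionally, gene
#' subsampling at the requested sizes compares each subsample clustering
#' with the full-gene reference.
#'
#' @param lfc matrix from [condition_logfc_matrix()].
#' @param methods hclust methods to cross.
#' @param distances distance measures to cross.
#' @param subsample_sizes gene subsample sizes (auto-capped with warning).
#' @param n_rep subsample repetitions per size.
#' @param k number of clusters for the Rand-index cut.
#' @param seed RNG seed.
#' @param cor_method condition correlation estimator.
#' @return list with `pairwise` (combo1, combo2, cophenetic_cor,
#'   rand_index) and `subsampling` (size, rep, cophenetic_cor,
#'   rand_index vs the full reference).
#' @export
clustering_concordance <- function(lfc,
                                   methods = c("ward.D", "ward.D2",
                                               "complete", "average",
                                               "mcquitty"),
                                   distances = c("euclidean", "maximum",
                                                 "manhattan", "minkowski"),
                                   subsample_sizes = c(10000, 5000, 2000),
                                   n_rep = 100, k = 2, seed = 1L,
                                   cor_method = "spearman") {
  set.seed(seed)
  C <- cor(lfc, method = cor_method)
  combos <- expand.grid(method = methods, distance = distances,
                        stringsAsFactors = FALSE)
  trees <- lapply(seq_len(nrow(combos)), function(i)
    hclust(dist(C, method = combos$distance[i]),
           method = combos$method[i]))
  names(trees) <- paste(combos$method, combos$distance, sep = "/")
  pairwise <- if (length(trees) < 2) {
    data.frame(combo1 = character(0), combo2 = character(0),
               cophenetic_cor = numeric(0), rand_index = numeric(0))
  } else {
  pairs <- combn(length(trees), 2)
  data.frame(
    combo1 = names(trees)[pairs[1, ]],
    combo2 = names(trees)[pairs[2, ]],
    cophenetic_cor = apply(pairs, 2, function(ij)
      cor(as.vector(cophenetic(trees[[ij[1]]])),
          as.vector(cophenetic(trees[[ij[2]]])))),
    rand_index = apply(pairs, 2, function(ij)
      rand_index(cutree(trees[[ij[1]]], k), cutree(trees[[ij[2]]], k))),
    stringsAsFactors = FALSE)
  }

  sizes <- pmin(subsample_sizes, nrow(lfc))
  if (any(sizes < subsample_sizes))
    warning("subsample sizes capped at the gene count (", nrow(lfc), ")")
  ref_tree <- hclust(dist(C, method = "euclidean"), method = "ward.D2")
  subs <- do.call(rbind, lapply(unique(sizes), function(sz)
    do.call(rbind, lapply(seq_len(n_rep), function(r) {
      idx <- sample.int(nrow(lfc), sz)
      Cs <- cor(lfc[idx, , drop = FALSE], method = cor_method)
      tr <- hclust(dist(Cs, method = "euclidean"), method = "ward.D2")
      data.frame(size = sz, rep = r,
                 cophenetic_cor = cor(as.vector(cophenetic(ref_tree)),
                                      as.vector(cophenetic(tr))),
                 rand_index = rand_index(cutree(ref_tree, k),
                                         cutree(tr, k)))
    }))))
  list(pairwise = pairwise, subsampling = subs)
}

#' Per-day cross-form correlation trend with ANOVA and Tukey HSD
#'
#' For each day, the Spearman correlation of logFC signatures for every
#' unordered pair of forms (`choose(F, 2)` values per day), followed by a
#' one-way ANOVA of correlation by day and Tukey honestly-significant-
#' difference comparisons between days.
#'
#' @param lfc matrix from [condition_logfc_matrix()] with `form_day`
#'   columns.
#' @param cor_method correlation estimator between form signatures.
#' @return list: `rho` (day, form1, form2, rho), `anova` (F, df1, df2, p),
#'   `tukey` (day pair, diff, p_adj).
#' @export
convergence_trend <- function(lfc, cor_method = "spearman") {
  day <- condition_day(lfc)
  form <- condition_form(lfc)
  days <- unique(day)
  if (!anyNA(suppressWarnings(as.numeric(days))))
    days <- days[order(as.numeric(days))]
  if (length(days) < 2) stop("need at least 2 days")
  rho <- do.call(rbind, lapply(days, function(d) {
    cols <- which(day == d)
    if (length(cols) < 2) stop("day ", d, " has fewer than 2 forms")
    pr <- combn(cols, 2)
    data.frame(day = d, form1 = form[pr[1, ]], form2 = form[pr[2, ]],
               rho = apply(pr, 2, function(ij)
                 cor(lfc[, ij[1]], lfc[, ij[2]], method = cor_method)),
               stringsAsFactors = FALSE)
  }))
  rho$day <- factor(rho$day, levels = days)
  fit <- aov(rho ~ day, data = rho)
  an <- anova(fit)
  tk <- TukeyHSD(fit)$day
  list(rho = rho,
       anova = data.frame(F = an$`F value`[1], df1 = an$Df[1],
                          df2 = an$Df[2], p = an$`Pr(>F)`[1]),
       tukey = data.frame(pair = rownames(tk), diff = tk[, "diff"],
                          p_adj = tk[, "p adj"], row.names = NULL,
                          stringsAsFactors = FALSE))
}
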