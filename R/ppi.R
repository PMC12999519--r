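#' Construct an IP-MS bait x prey logFC table
#'
#' @param baits bait protein identifiers (subset of the universe).
#' @param universe detected-protein universe.
#' @param logfc bait x universe matrix; 0 marks undetected or
#'   non-enriched pairs.
#' @return object of class `ipms_table`.
#' @export
ipms_table <- function(baits, universe, logfc) {
  logfc <- as.matrix(logfc)
  stopifnot(nrow(logfc) == length(baits), ncol(logfc) == length(universe),
            all(baits %in% universe))
  dimnames(logfc) <- list(baits, universe)
  structure(list(baits = baits, universe = universe, logfc = logfc),
            class = "ipms_table")
}

#' @export
print.ipms_table <- function(x, ...) {
  cat(sprintf("ipms_table: %d baits x %d detected proteins\n",
              length(x$baits), length(x$universe)))
  invisible(x)
}

#' Read an IP-MS table from long TSV
#'
#' Expects columns bait, prey, logFC; duplicate (bait, prey) accessions
#' are merged by the entry of maximum absolute logFC. Missing pairs are
#' zero.
#'
#' @param path TSV path.
#' @return an `ipms_table`.
#' @export
read_ipms <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("bait", "prey", "logFC") %in% names(d)))
  key <- paste(d$bait, d$prey, sep = "\r")
  d <- d[order(-abs(d$logFC)), ]
  d <- d[!duplicated(paste(d$bait, d$prey, sep = "\r")), ]
  baits <- sort(unique(d$bait))
  universe <- sort(unique(c(d$bait, d$prey)))
  logfc <- matrix(0, length(baits), length(universe),
                  dimnames = list(baits, universe))
  logfc[cbind(match(d$bait, baits), match(d$prey, universe))] <- d$logFC
  ipms_table(baits, universe, logfc)
}

#' Write an IP-MS table to long TSV (non-zero entries)
#'
#' @param table an `ipms_table`.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_ipms <- function(table, path) {
  nz <- which(table$logfc != 0, arr.ind = TRUE)
  d <- data.frame(bait = table$baits[nz[, 1]],
                  prey = table$universe[nz[, 2]],
                  logFC = table$logfc[nz])
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Mean bait-prey logFC connectedness of a protein set
#'
#' Mean over all (bait, member) cells of the logFC table, excluding
#' baits' own entries; zeros for undetected pairs are kept.
#'
#' @param table an `ipms_table`.
#' @param protein_set proteins (subset of the universe).
#' @return the observed mean logFC.
#' @export
connectedness <- function(table, protein_set) {
  stopifnot(inherits(table, "ipms_table"))
  protein_set <- unique(protein_set)
  if (!length(protein_set)) stop("empty protein set")
  if (!all(protein_set %in% table$universe))
    stop("protein set must be within the detected universe")
  vals <- unlist(lapply(table$baits, function(b)
    table$logfc[b, setdiff(protein_set, b)]), use.names = FALSE)
  mean(vals)
}

#' Permutation z test of network connectedness
#'
#' Null sets of the same size are drawn without replacement from the
#' universe excluding the tested set (and excluding baits by default);
#' the z score compares the observed connectedness with the null mean
#' and SD, with a two-sided normal p value.
#'
#' @param table an `ipms_table`.
#' @param protein_set tested proteins.
#' @param n_perm permutations.
#' @param seed RNG seed.
#' @param exclude_set draw the null from the universe minus the tested
#'   set (default) or from the full universe.
#' @param exclude_baits also exclude baits from the null draws.
#' @return data frame of class `connectedness_result`: set_size,
#'   observed, null_mean, null_sd, z, p, n_perm.
#' @export
permutation_z <- function(table, protein_set, n_perm = 10000, seed = 1L,
                          exclude_set = TRUE, exclude_baits = TRUE) {
  stopifnot(inherits(table, "ipms_table"))
  set.seed(seed)
  protein_set <- unique(protein_set)
  obs <- connectedness(table, protein_set)
  pool <- table$universe
  if (exclude_set) pool <- setdiff(pool, protein_set)
  if (exclude_baits) pool <- setdiff(pool, table$baits)
  m <- length(protein_set)
  if (length(pool) < m)
    stop("universe too small to draw size-matched null sets")
  null <- vapply(seq_len(n_perm), function(i)
    connectedness(table, sample(pool, m)), numeric(1))
  mu <- mean(null); sdv <- sd(null)
  if (sdv == 0) {
    warning("null SD is zero; z undefined")
    z <- NA_real_; p <- NA_real_
  } else {
    z <- (obs - mu) / sdv
    p <- 2 * pnorm(-abs(z))
  }
  data.frame(set_size = m, observed = obs, null_mean = mu, null_sd = sdv,
             z = z, p = p, n_perm = n_perm)
}

#' Connectedness of external gene lists against the IP-MS network
#'
#' Each list is harmonized to the detected universe and tested with
#' [permutation_z()]; lists disjoint from the universe are skipped with
#' a note, and BH is applied across the tested lists.
#'
#' @param table an `ipms_table`.
#' @param core_set the core network set (tested first, named "core").
#' @param other_lists named list of protein/gene sets.
#' @param n_perm permutations per list.
#' @param seed RNG seed.
#' @return data frame: list name, set_size, observed, null stats, z, p,
#'   fdr; `skipped` attribute for disjoint lists.
#' @export
cross_list_connectedness <- function(table, core_set, other_lists,
                                     n_perm = 10000, seed = 1L) {
  all_lists <- c(list(core = core_set), other_lists)
  skipped <- character(0)
  rows <- do.call(rbind, lapply(names(all_lists), function(nm) {
    hits <- intersect(all_lists[[nm]], table$universe)
    if (!length(hits)) {
      skipped <<- c(skipped, nm)
      return(NULL)
    }
    cbind(list = nm, permutation_z(table, hits, n_perm = n_perm,
                                   seed = seed))
  }))
  if (!is.null(rows)) rows$fdr <- p.adjust(rows$p, "BH")
  attr(rows, "skipped") <- skipped
  rows
}
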