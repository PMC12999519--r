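#' Write a cohort counts object to disk
#'
#' Persists the counts as MatrixMarket (`counts.mtx`), the gene identifiers
#' (`genes.tsv`, single column with header) and the sample metadata
#' (`samples.tsv`). All tables are tab-separated with a header row.
#'
#' @param cohort a `cohort_counts` object from [simulate_cohort()] or
#'   [read_cohort()].
#' @param dir output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_counts"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(cohort$counts, sparse = TRUE),
                  file.path(dir, "counts.mtx"))
  write.table(data.frame(gene = cohort$genes),
              file.path(dir, "genes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cohort$samples, file.path(dir, "samples.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a cohort counts object written by [write_cohort()]
#'
#' @param dir directory containing `counts.mtx`, `genes.tsv`, `samples.tsv`.
#' @return a `cohort_counts` object.
#' @export
read_cohort <- function(dir) {
  counts <- as.matrix(Matrix::readMM(file.path(dir, "counts.mtx")))
  genes <- read.delim(file.path(dir, "genes.tsv"))$gene
  samples <- read.delim(file.path(dir, "samples.tsv"))
  dimnames(counts) <- list(genes, samples$sample_id)
  cohort_counts(counts, samples)
}

#' Construct a cohort counts container
#'
#' @param counts gene x sample non-negative integer matrix with dimnames.
#' @param samples data frame of sample metadata with a `sample_id` column
#'   matching the counts columns.
#' @return a `cohort_counts` object: list with `counts`, `genes`, `samples`.
#' @export
cohort_counts <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (anyDuplicated(samples$sample_id)) stop("sample ids must be unique")
  if (!all(samples$sample_id %in% colnames(counts)))
    stop("every metadata sample must have a counts column")
  counts <- counts[, as.character(samples$sample_id), drop = FALSE]
  structure(list(counts = counts,
                 genes = rownames(counts),
                 samples = samples),
            class = "cohort_counts")
}

#' @export
print.cohort_counts <- function(x, ...) {
  cat(sprintf("cohort_counts: %d genes x %d samples (%d forms, %d days)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$samples$form)),
              length(unique(x$samples$day))))
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' @param path GMT file (set name, description, tab-separated members).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    parts[-(1:2)]
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  out
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description per-set description column (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(!is.null(names(sets)), all(nzchar(names(sets))))
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write the ground-truth record of a simulation as JSON
#'
#' @param truth a `sim_truth` object.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", force = TRUE)
  invisible(path)
}
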