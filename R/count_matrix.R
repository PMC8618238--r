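#' Construct a validated count matrix
#'
#' Bundles an integer gene x sample read-count matrix with per-gene exonic
#' lengths and per-sample metadata, after validating identifiers and value
#' ranges.
#'
#' @param counts Integer matrix, genes x samples, with gene ids as rownames
#'   and sample ids as colnames.
#' @param lengths_bp Named numeric vector of exonic lengths (bp), one per
#'   gene, names matching rownames of `counts`.
#' @param samples data.frame with at least `sample_id`, `group`,
#'   `replicate`; one row per column of `counts`.
#' @return A list of class `count_matrix` with elements `counts`,
#'   `lengths_bp`, `samples`.
#' @export
count_matrix <- function(counts, lengths_bp, samples) {
  if (!is.matrix(counts)) stop("'counts' must be a matrix", call. = FALSE)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("'counts' needs gene rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate gene ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(counts) | counts < 0 | counts != floor(counts),
               arr.ind = TRUE)
  if (nrow(bad)) {
    stop("counts must be non-negative integers; offending entry: gene ",
         rownames(counts)[bad[1, 1]], ", sample ",
         colnames(counts)[bad[1, 2]], " = ",
         counts[bad[1, 1], bad[1, 2]], call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  if (is.null(names(lengths_bp))) {
    stop("'lengths_bp' must be named by gene id", call. = FALSE)
  }
  miss <- setdiff(rownames(counts), names(lengths_bp))
  if (length(miss)) {
    stop("gene lengths missing for: ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  }
  lengths_bp <- as.numeric(lengths_bp[rownames(counts)])
  names(lengths_bp) <- rownames(counts)
  if (any(lengths_bp < 1)) {
    stop("gene lengths must be >= 1 bp; offending gene: ",
         names(lengths_bp)[which(lengths_bp < 1)[1]], call. = FALSE)
  }
  if (!is.data.frame(samples) || !all(c("sample_id", "group") %in% names(samples))) {
    stop("'samples' must be a data.frame with sample_id and group columns",
         call. = FALSE)
  }
  miss <- setdiff(colnames(counts), samples$sample_id)
  if (length(miss)) {
    stop("sample sheet is missing sample id(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(samples$sample_id, colnames(counts))
  if (length(extra)) {
    stop("sample sheet lists unknown sample id(s): ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  samples <- samples[match(colnames(counts), samples$sample_id), ,
                     drop = FALSE]
  rownames(samples) <- NULL
  structure(list(counts = counts, lengths_bp = lengths_bp,
                 samples = samples), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples (%d groups)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$samples$group))))
  invisible(x)
}

group_samples <- function(x, group) {
  ids <- x$samples$sample_id[x$samples$group == group]
  if (!length(ids)) {
    stop("unknown or empty group: ", group, call. = FALSE)
  }
  ids
}

library_sizes <- function(x) colSums(x$counts)

#' Write a dataset to TSV files
#'
#' Writes `counts.tsv` (first column `gene_id`, then one column per
#' sample), `samples.tsv` and `gene_lengths.tsv` into `dir`. For a
#' simulated dataset, additionally writes `truth.tsv` and `run_info.json`
#' (seed, rule). [load_dataset()] round-trips these files bit-identically.
#'
#' @param x A `count_matrix` or `simulated_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
write_dataset <- function(x, dir) UseMethod("write_dataset")

#' @export
write_dataset.count_matrix <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counts_df <- data.frame(gene_id = rownames(x$counts), x$counts,
                          check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(counts_df, file.path(dir, "counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(x$samples, file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  len_df <- data.frame(gene_id = names(x$lengths_bp),
                       length_bp = as.integer(x$lengths_bp))
  utils::write.table(len_df, file.path(dir, "gene_lengths.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @export
write_dataset.simulated_dataset <- function(x, dir) {
  write_dataset(x$counts, dir)
  utils::write.table(x$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(x$design, file.path(dir, "design.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(seed = x$seed, rule = x$rule),
                       file.path(dir, "run_info.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Load a dataset from TSV files
#'
#' Reads the three TSV files written by [write_dataset()] (or prepared
#' externally in the same layout) and returns a validated
#' [count_matrix()]. Identifier mismatches between the three files raise
#' an error naming the offending records.
#'
#' @param counts_path TSV with `gene_id` column then one column per sample.
#' @param samples_path TSV sample sheet with `sample_id`, `group`, ...
#' @param lengths_path TSV with `gene_id` and `length_bp` columns.
#' @return A `count_matrix`.
#' @export
load_dataset <- function(counts_path, samples_path, lengths_path) {
  for (p in c(counts_path, samples_path, lengths_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  counts_df <- utils::read.delim(counts_path, check.names = FALSE,
                                 stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(counts_df)) {
    stop("counts file must have a gene_id column", call. = FALSE)
  }
  cmat <- as.matrix(counts_df[, setdiff(names(counts_df), "gene_id"),
                              drop = FALSE])
  rownames(cmat) <- counts_df$gene_id
  samples <- utils::read.delim(samples_path, check.names = FALSE,
                               stringsAsFactors = FALSE)
  lens <- utils::read.delim(lengths_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  if (!all(c("gene_id", "length_bp") %in% names(lens))) {
    stop("lengths file must have gene_id and length_bp columns",
         call. = FALSE)
  }
  count_matrix(cmat, stats::setNames(lens$length_bp, lens$gene_id), samples)
}

#' Load a simulated dataset (counts + truth + design) from a directory
#'
#' @param dir Directory written by [write_dataset()] on a
#'   `simulated_dataset`.
#' @return A list with `counts` (count_matrix), `truth`, `design`.
#' @export
load_simulated_dataset <- function(dir) {
  cm <- load_dataset(file.path(dir, "counts.tsv"),
                     file.path(dir, "samples.tsv"),
                     file.path(dir, "gene_lengths.tsv"))
  truth <- utils::read.delim(file.path(dir, "truth.tsv"),
                             stringsAsFactors = FALSE)
  design <- utils::read.delim(file.path(dir, "design.tsv"),
                              stringsAsFactors = FALSE)
  list(counts = cm, truth = truth, design = design)
}
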