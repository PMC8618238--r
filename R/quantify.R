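#' Counts per million
#'
#' @param x A [count_matrix()].
#' @return Numeric matrix of CPM values; every column sums to 1e6.
#' @export
cpm <- function(x) {
  lib <- library_sizes(x)
  if (any(lib == 0)) {
    stop("zero library size in sample(s): ",
         paste(names(lib)[lib == 0], collapse = ", "), call. = FALSE)
  }
  sweep(x$counts, 2, lib, "/") * 1e6
}

#' Reads per kilobase of gene per million mapped reads
#'
#' `rpkm(g, s) = counts(g, s) * 1e9 / (library_size(s) * length_bp(g))`,
#' with the library size taken as the column total of the count matrix.
#'
#' @param x A [count_matrix()].
#' @return Numeric matrix of RPKM values.
#' @export
rpkm <- function(x) {
  lib <- library_sizes(x)
  if (any(lib == 0)) {
    stop("zero library size in sample(s): ",
         paste(names(lib)[lib == 0], collapse = ", "), call. = FALSE)
  }
  x$counts * 1e9 / outer(x$lengths_bp, lib)
}

#' Per-group mean RPKM
#'
#' @param x A [count_matrix()].
#' @param groups Group ids (default: all groups in the sample sheet).
#' @return Matrix genes x groups of mean RPKM across replicates.
#' @export
group_mean_rpkm <- function(x, groups = unique(x$samples$group)) {
  r <- rpkm(x)
  sapply(groups, function(g) {
    rowMeans(r[, group_samples(x, g), drop = FALSE])
  })
}

#' Effective library sizes
#'
#' `method = "median_ratio"` computes DESeq-style size factors — for each
#' sample, the median across genes of the ratio of its count to the
#' gene's geometric mean over all samples (genes with a zero anywhere are
#' excluded) — and anchors their scale to the geometric mean of the raw
#' column totals. This corrects for composition shifts under strongly
#' asymmetric differential expression, which raw totals misattribute to
#' every unchanged gene. `method = "total"` returns the raw column
#' totals.
#'
#' @param x A [count_matrix()].
#' @param method `"median_ratio"` (default) or `"total"`.
#' @return Named numeric vector of per-sample effective library sizes.
#' @export
effective_library_sizes <- function(x, method = c("median_ratio", "total")) {
  method <- match.arg(method)
  tot <- library_sizes(x)
  if (method == "total") return(tot)
  cm <- x$counts
  keep <- rowSums(cm > 0) == ncol(cm)
  if (!any(keep)) return(tot)  # no gene observed everywhere: fall back
  lc <- log(cm[keep, , drop = FALSE])
  gm <- rowMeans(lc)
  sf <- apply(lc, 2, function(col) exp(stats::median(col - gm)))
  sf * exp(mean(log(tot)) - mean(log(sf)))
}

#' Relative expression by the delta-delta-Ct method
#'
#' `2^-ddCt` with
#' `ddCt = (ct_target_test - ct_ref_test) - (ct_target_ctrl - ct_ref_ctrl)`,
#' the standard qPCR relative quantification after normalisation to a
#' reference gene (e.g. actin).
#'
#' @param ct_target_test,ct_ref_test Ct of target and reference gene in the
#'   test condition.
#' @param ct_target_ctrl,ct_ref_ctrl Ct of target and reference gene in the
#'   control condition.
#' @return Fold change (vectorised).
#' @export
ddct_relative_expression <- function(ct_target_test, ct_ref_test,
                                     ct_target_ctrl, ct_ref_ctrl) {
  ct <- cbind(ct_target_test, ct_ref_test, ct_target_ctrl, ct_ref_ctrl)
  if (!all(is.finite(ct))) stop("all Ct values must be finite", call. = FALSE)
  ddct <- (ct_target_test - ct_ref_test) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct)
}

#' Sample-level QC: PCA and hierarchical clustering
#'
#' Pipeline: `log2(CPM + pseudocount)` -> drop genes with zero variance
#' across samples -> per-gene z-score -> PCA of the samples (SVD, centred)
#' -> hierarchical clustering (default complete linkage) of the Euclidean
#' distances between samples. With well-separated groups the replicate
#' pairs merge first, mirroring replicate-concordance dendrograms.
#'
#' @param x A [count_matrix()].
#' @param pseudocount Added before the log (default 1).
#' @param linkage Agglomeration method for [stats::hclust()] (default
#'   `"complete"`).
#' @return A list of class `qc_summary`: `scores` (sample PCA scores),
#'   `var_explained` (fractions, non-increasing, summing to 1), `hclust`,
#'   `dist` (sample distance matrix) and `nearest` (each sample's nearest
#'   other sample).
#' @export
qc_summary <- function(x, pseudocount = 1, linkage = "complete") {
  if (ncol(x$counts) < 2) stop("QC needs >= 2 samples", call. = FALSE)
  l <- log2(cpm(x) + pseudocount)
  v <- apply(l, 1, stats::var)
  l <- l[v > 0, , drop = FALSE]
  if (nrow(l) == 0) stop("no genes with non-zero variance", call. = FALSE)
  z <- (l - rowMeans(l)) / apply(l, 1, stats::sd)
  pca <- stats::prcomp(t(z), center = TRUE, scale. = FALSE)
  ve <- pca$sdev^2 / sum(pca$sdev^2)
  d <- stats::dist(t(z))
  dm <- as.matrix(d)
  diag(dm) <- Inf
  nearest <- colnames(dm)[apply(dm, 1, which.min)]
  names(nearest) <- rownames(dm)
  structure(list(scores = pca$x, var_explained = ve,
                 hclust = stats::hclust(d, method = linkage),
                 dist = as.matrix(d), nearest = nearest),
            class = "qc_summary")
}

#' @export
print.qc_summary <- function(x, ...) {
  cat("QC summary:", nrow(x$scores), "samples\n")
  cat("  PC variance fractions:",
      paste(sprintf("%.3f", utils::head(x$var_explained, 4)),
            collapse = " "), "...\n")
  invisible(x)
}
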