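#' Genes detected in a sample group
#'
#' Default rule: a gene is detected if every replicate of the group has at
#' least `min_reads` reads (`rule = "min_reads"`). Alternative rule
#' `"rpkm_floor"`: mean RPKM across the group's replicates at or above
#' `rpkm_floor`, motivated by the observation that condition-exclusive
#' genes are mostly low-expressed (RPKM < 10).
#'
#' @param x A [count_matrix()].
#' @param group Group id.
#' @param rule `"min_reads"` (default) or `"rpkm_floor"`.
#' @param min_reads Minimum reads per replicate for `"min_reads"`.
#' @param rpkm_floor Mean-RPKM floor for `"rpkm_floor"`.
#' @return Character vector of detected gene ids.
#' @export
detected_genes <- function(x, group, rule = c("min_reads", "rpkm_floor"),
                           min_reads = 1, rpkm_floor = 10) {
  rule <- match.arg(rule)
  ids <- group_samples(x, group)
  if (rule == "min_reads") {
    keep <- rowSums(x$counts[, ids, drop = FALSE] >= min_reads) == length(ids)
  } else {
    keep <- rowMeans(rpkm(x)[, ids, drop = FALSE]) >= rpkm_floor
  }
  rownames(x$counts)[keep]
}

#' Split two gene sets into common and exclusive parts
#'
#' Downstream comparisons keep only the common genes; the
#' condition-exclusive genes are reported and discarded.
#'
#' @param set_a,set_b Character vectors of gene ids.
#' @return List with `common`, `exclusive_a`, `exclusive_b`.
#' @export
common_genes <- function(set_a, set_b) {
  list(common = intersect(set_a, set_b),
       exclusive_a = setdiff(set_a, set_b),
       exclusive_b = setdiff(set_b, set_a))
}

# row-wise log-sum-exp over a matrix that may contain -Inf padding
logsumexp_rows <- function(L) {
  M <- L[, 1]
  if (ncol(L) > 1) for (j in 2:ncol(L)) M <- pmax(M, L[, j])
  r <- log(rowSums(exp(L - M)))
  out <- M + r
  out[M == -Inf] <- -Inf
  out
}

#' Log10 upper-tail hypergeometric probability
#'
#' `log10 P(X >= k)` for `X ~ Hypergeometric(N, m, n)`: drawing `n` genes
#' from a universe of `N` of which `m` are marked, the probability of at
#' least `k` marked draws. Computed entirely in log space via `lchoose`
#' and log-sum-exp, so overlap p-values far below the double-precision
#' underflow limit (log10 p < -2500) are returned exactly where a naive
#' sum would return 0. Vectorised over all four arguments.
#'
#' @param k Observed overlap, `0 <= k <= min(m, n)`.
#' @param m,n Sizes of the two gene sets.
#' @param N Background universe size, `N >= max(m, n)`.
#' @return `log10 P(X >= k)` (<= 0).
#' @export
log_hypergeom_sf <- function(k, m, n, N) {
  L <- max(length(k), length(m), length(n), length(N))
  k <- rep_len(as.numeric(k), L); m <- rep_len(as.numeric(m), L)
  n <- rep_len(as.numeric(n), L); N <- rep_len(as.numeric(N), L)
  if (any(k < 0 | m < 0 | n < 0 | N < 0)) {
    stop("arguments must be non-negative", call. = FALSE)
  }
  if (any(pmax(m, n) > N)) stop("m and n must be <= N", call. = FALSE)
  if (any(k > pmin(m, n))) stop("k must be <= min(m, n)", call. = FALSE)

  out <- numeric(L)
  todo <- which(k > 0)
  if (!length(todo)) return(out)

  upper <- pmin(m, n)
  width <- upper - k + 1
  # process in chunks so the term matrix stays small; within a chunk the
  # matrix is L_c x max(width) padded with -Inf
  ord <- todo[order(width[todo])]
  pos <- 1
  max_cells <- 5e6
  while (pos <= length(ord)) {
    wmax <- 0; last <- pos - 1
    repeat {
      if (last + 1 > length(ord)) break
      w_new <- max(wmax, width[ord[last + 1]])
      if ((last + 2 - pos) * w_new > max_cells && last >= pos) break
      wmax <- w_new; last <- last + 1
    }
    idx <- ord[pos:last]
    pos <- last + 1
    I <- outer(k[idx], 0:(wmax - 1), "+")
    valid <- I <= upper[idx]
    I[!valid] <- 0  # placeholder; masked below
    nr <- length(idx)
    mv <- rep(m[idx], times = wmax); nv <- rep(n[idx], times = wmax)
    Nv <- rep(N[idx], times = wmax); iv <- as.vector(I)
    lp <- matrix(lchoose(mv, iv) + lchoose(Nv - mv, nv - iv) -
                   lchoose(Nv, nv), nrow = nr)
    lp[!valid] <- -Inf
    out[idx] <- logsumexp_rows(lp) / log(10)
  }
  pmin(out, 0)
}

#' Representation factor of a gene-set overlap
#'
#' `rf = k * N / (m * n)`: the observed overlap divided by the overlap
#' expected by chance for independent sets of sizes `m` and `n` drawn from
#' a universe of `N`. `rf = 1` exactly when `k` equals the expectation
#' `m * n / N`.
#'
#' @inheritParams log_hypergeom_sf
#' @return Representation factor (vectorised).
#' @export
representation_factor <- function(k, m, n, N) {
  if (any(m <= 0) || any(n <= 0) || any(N <= 0)) {
    stop("m, n and N must be positive", call. = FALSE)
  }
  k * N / (m * n)
}

#' Overlap statistics for two gene sets
#'
#' @param set_a,set_b Character vectors of gene ids.
#' @param universe_size Background universe size `N`; defaults to the size
#'   of `universe`.
#' @param universe Optional explicit background gene ids.
#' @param alternative `"over"` (default, upper tail: enrichment) or
#'   `"under"` (lower tail: depletion).
#' @return List of class `overlap_result`: `k`, `m`, `n`, `N`, `rf`,
#'   `log10_p`.
#' @export
overlap_test <- function(set_a, set_b, universe_size = NULL,
                         universe = NULL,
                         alternative = c("over", "under")) {
  alternative <- match.arg(alternative)
  if (is.null(universe_size)) {
    if (is.null(universe)) {
      stop("supply universe_size or universe", call. = FALSE)
    }
    universe_size <- length(unique(universe))
  }
  set_a <- unique(set_a); set_b <- unique(set_b)
  k <- length(intersect(set_a, set_b))
  m <- length(set_a); n <- length(set_b)
  if (max(m, n) > universe_size) {
    stop("set larger than universe", call. = FALSE)
  }
  log10_p <- if (alternative == "over") {
    log_hypergeom_sf(k, m, n, universe_size)
  } else {
    # lower tail P(X <= k) via the complement in log space
    stats::phyper(k, m, universe_size - m, n, lower.tail = TRUE,
                  log.p = TRUE) / log(10)
  }
  structure(list(k = k, m = m, n = n, N = universe_size,
                 rf = if (m > 0 && n > 0) representation_factor(k, m, n, universe_size) else NA_real_,
                 log10_p = log10_p),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap: k=%d of m=%d x n=%d in N=%d; RF=%.2f, P=%s\n",
              x$k, x$m, x$n, x$N, x$rf, format_log10_p(x$log10_p)))
  invisible(x)
}

#' Format a log10 p-value as a scientific-notation string
#'
#' @param log10_p Log10 p-value (<= 0).
#' @return String like `"3.8e-2382"`.
#' @export
format_log10_p <- function(log10_p) {
  e <- floor(log10_p)
  mant <- 10^(log10_p - e)
  # keep mantissa in [1, 10)
  fix <- mant >= 9.95
  mant[fix] <- 1; e[fix] <- e[fix] + 1
  sprintf("%.1fe%d", mant, e)
}

#' Partition 2 or 3 gene sets into Venn regions
#'
#' @param sets Named list of 2 or 3 character vectors.
#' @return List of class `venn_partition`: `regions` (named by the
#'   combination of member sets, e.g. `"A"`, `"A&B"`, `"A&B&C"`),
#'   `labels`, `union_size`.
#' @export
venn_partition <- function(sets) {
  if (!is.list(sets) || !(length(sets) %in% 2:3)) {
    stop("'sets' must be a list of 2 or 3 gene sets", call. = FALSE)
  }
  if (is.null(names(sets))) names(sets) <- LETTERS[seq_along(sets)]
  sets <- lapply(sets, unique)
  all_genes <- unique(unlist(sets))
  member <- sapply(sets, function(s) all_genes %in% s)
  if (length(all_genes) == 1) member <- matrix(member, nrow = 1)
  key <- apply(member, 1, function(r) paste(names(sets)[r], collapse = "&"))
  regions <- split(all_genes, key)
  # order: singles, pairs, triple
  ord <- order(lengths(strsplit(names(regions), "&", fixed = TRUE)),
               names(regions))
  structure(list(regions = regions[ord], labels = names(sets),
                 union_size = length(all_genes)),
            class = "venn_partition")
}

#' Summarise a Venn partition by sharing degree
#'
#' Counts genes specific to a single set, shared by exactly two sets and
#' shared by all sets, with percentages of the union reported at one
#' decimal (half-up), the precision used for published gene-set
#' percentages.
#'
#' @param partition A [venn_partition()].
#' @return data.frame with `degree`, `count`, `pct_of_union`.
#' @export
venn_summary <- function(partition) {
  stopifnot(inherits(partition, "venn_partition"))
  deg <- lengths(strsplit(names(partition$regions), "&", fixed = TRUE))
  n_sets <- length(partition$labels)
  counts <- vapply(seq_len(n_sets), function(d) {
    sum(lengths(partition$regions[deg == d]))
  }, numeric(1))
  u <- partition$union_size
  data.frame(
    degree = seq_len(n_sets),
    count = as.integer(counts),
    pct_of_union = round_half_up(100 * counts / u, 1),
    stringsAsFactors = FALSE
  )
}
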