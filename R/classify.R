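#' Cross-tabulate rIIS-dependent genes against TF-regulated genes
#'
#' Overlaps the activated and repressed gene sets of the rIIS comparison
#' with the corresponding sets of a TF-knockdown comparison, direction by
#' direction, each with a representation factor and hypergeometric
#' p-value. The combined fraction of rIIS-dependent genes regulated by the
#' TF is `(k_act + k_rep) / (|rIIS_act| + |rIIS_rep|)`.
#'
#' @param de_riis,de_tf [de_test()] results computed on the same gene
#'   universe.
#' @param universe_size Background `N` for the hypergeometric test;
#'   defaults to the number of genes in `de_riis`.
#' @return List of class `riis_crosstab`: `directions` (data.frame with
#'   `direction`, `k`, `tf_set`, `riis_set`, `rf`, `log10_p`,
#'   `frac_of_tf`, `frac_of_riis`), `combined_fraction_pct` and the raw
#'   integers `combined_num`, `combined_den`.
#' @export
riis_dependence_crosstab <- function(de_riis, de_tf, universe_size = NULL) {
  if (!setequal(de_riis$gene_id, de_tf$gene_id)) {
    stop("DE results are on different gene universes", call. = FALSE)
  }
  if (is.null(universe_size)) universe_size <- length(unique(de_riis$gene_id))
  rows <- lapply(c("activated", "repressed"), function(dir) {
    rset <- de_genes(de_riis, dir)
    tset <- de_genes(de_tf, dir)
    k <- length(intersect(rset, tset))
    ov <- if (length(rset) && length(tset)) {
      overlap_test(tset, rset, universe_size = universe_size)
    } else {
      list(rf = NA_real_, log10_p = 0)
    }
    data.frame(direction = dir, k = k,
               tf_set = length(tset), riis_set = length(rset),
               rf = ov$rf, log10_p = ov$log10_p,
               frac_of_tf = if (length(tset)) k / length(tset) else 0,
               frac_of_riis = if (length(rset)) k / length(rset) else 0,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  num <- sum(tab$k)
  den <- sum(tab$riis_set)
  structure(list(
    directions = tab,
    combined_num = num, combined_den = den,
    combined_fraction_pct = if (den > 0) round_half_up(100 * num / den, 1) else 0
  ), class = "riis_crosstab")
}

#' @export
print.riis_crosstab <- function(x, ...) {
  print(x$directions)
  cat(sprintf("combined: %d/%d = %.1f%% of rIIS-dependent genes\n",
              x$combined_num, x$combined_den, x$combined_fraction_pct))
  invisible(x)
}

#' Reversal-to-control analysis of a TF knockdown
#'
#' Asks how effectively knocking down a TF returns rIIS-altered gene
#' expression to control levels. Analysis is restricted to genes with mean
#' RPKM at or above `rpkm_floor` in every compared group. A rIIS-DE gene
#' counts as "reverted" if, under the default rule, it is NOT differentially
#' expressed between the knockdown and the control at the same thresholds
#' (`rule = "not_de"`); the alternative rule `"fc_band"` requires
#' `|log2 FC(knockdown vs control)| < log2(band)`.
#'
#' @param x A [count_matrix()].
#' @param control_group,riis_group,kd_group Group ids of the control, the
#'   rIIS condition and the TF knockdown (all same temperature context).
#' @param de_riis Optional precomputed rIIS-vs-control [de_test()] result;
#'   recomputed on the eligible genes when NULL.
#' @param fc_threshold,alpha DE thresholds.
#' @param rpkm_floor Expression floor (default 10).
#' @param rule `"not_de"` (default) or `"fc_band"`.
#' @param band Fold-change band for `"fc_band"` (default 1.25).
#' @param ... Passed to [de_test()] (e.g. `prior_df`).
#' @return List of class `reversal_summary`: `summary` (data.frame with
#'   `direction`, `analyzed`, `reverted`, `fraction`), `genes`
#'   (per-gene data.frame with `gene_id`, `direction`, `reverted`),
#'   `eligible` (gene ids passing the RPKM floor).
#' @export
reversal_analysis <- function(x, control_group, riis_group, kd_group,
                              de_riis = NULL, fc_threshold = 1.5,
                              alpha = 0.05, rpkm_floor = 10,
                              rule = c("not_de", "fc_band"), band = 1.25,
                              ...) {
  rule <- match.arg(rule)
  for (g in c(control_group, riis_group, kd_group)) group_samples(x, g)
  gm <- group_mean_rpkm(x, c(control_group, riis_group, kd_group))
  eligible <- rownames(x$counts)[rowSums(gm >= rpkm_floor) == 3]
  if (is.null(de_riis)) {
    de_riis <- de_test(x, comparison_spec("rIIS_vs_control", riis_group,
                                          control_group),
                       fc_threshold = fc_threshold, alpha = alpha,
                       genes = eligible, ...)
  } else {
    de_riis <- de_riis[de_riis$gene_id %in% eligible, , drop = FALSE]
  }
  de_kd <- de_test(x, comparison_spec("kd_vs_control", kd_group,
                                      control_group),
                   fc_threshold = fc_threshold, alpha = alpha,
                   genes = eligible, ...)
  kd_call <- stats::setNames(de_kd$call, de_kd$gene_id)
  kd_l2fc <- stats::setNames(de_kd$log2fc, de_kd$gene_id)
  per_dir <- lapply(c("activated", "repressed"), function(dir) {
    ids <- de_genes(de_riis, dir)
    rev_flag <- if (rule == "not_de") {
      kd_call[ids] == "unchanged"
    } else {
      abs(kd_l2fc[ids]) < log2(band)
    }
    list(df = data.frame(gene_id = ids, direction = dir,
                         reverted = unname(rev_flag),
                         stringsAsFactors = FALSE),
         row = data.frame(direction = dir, analyzed = length(ids),
                          reverted = sum(rev_flag),
                          fraction = if (length(ids)) mean(rev_flag) else NA_real_,
                          stringsAsFactors = FALSE))
  })
  structure(list(
    summary = do.call(rbind, lapply(per_dir, `[[`, "row")),
    genes = do.call(rbind, lapply(per_dir, `[[`, "df")),
    eligible = eligible, rule = rule, rpkm_floor = rpkm_floor
  ), class = "reversal_summary")
}

#' @export
print.reversal_summary <- function(x, ...) {
  print(x$summary)
  invisible(x)
}

#' Quadrant classification of paired fold changes
#'
#' Assigns each common gene to a quadrant by the signs of its log2 fold
#' changes in two comparisons (Q1: +/+, Q2: -/+, Q3: -/-, Q4: +/-).
#' Genes with either log2 fold change exactly zero are excluded from the
#' percentages and reported separately. The same-direction fraction is the
#' Q1 + Q3 share of classified genes.
#'
#' @param log2fc_x,log2fc_y Named numeric vectors of log2 fold changes
#'   (names = gene ids) from comparisons X and Y.
#' @param genes Genes to classify; default the intersection of the names.
#' @return List of class `quadrant_table`: `genes` (per-gene quadrant),
#'   `counts`, `pct` (of classified, one decimal), `ties`,
#'   `same_direction_pct`.
#' @export
quadrant_classify <- function(log2fc_x, log2fc_y,
                              genes = intersect(names(log2fc_x),
                                                names(log2fc_y))) {
  miss <- setdiff(genes, intersect(names(log2fc_x), names(log2fc_y)))
  if (length(miss)) {
    stop("genes absent from a comparison: ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  }
  fx <- log2fc_x[genes]; fy <- log2fc_y[genes]
  quad <- rep(NA_integer_, length(genes))
  quad[fx > 0 & fy > 0] <- 1L
  quad[fx < 0 & fy > 0] <- 2L
  quad[fx < 0 & fy < 0] <- 3L
  quad[fx > 0 & fy < 0] <- 4L
  gdf <- data.frame(gene_id = genes, log2fc_x = unname(fx),
                    log2fc_y = unname(fy), quadrant = quad,
                    stringsAsFactors = FALSE)
  counts <- vapply(1:4, function(q) sum(quad == q, na.rm = TRUE), integer(1))
  names(counts) <- paste0("Q", 1:4)
  ncl <- sum(counts)
  pct <- if (ncl > 0) round_half_up(100 * counts / ncl, 1) else counts * NA_real_
  structure(list(
    genes = gdf, counts = counts, pct = pct, ties = sum(is.na(quad)),
    same_direction_pct = if (ncl > 0) round_half_up(100 * (counts[["Q1"]] + counts[["Q3"]]) / ncl, 1) else NA_real_
  ), class = "quadrant_table")
}

#' @export
print.quadrant_table <- function(x, ...) {
  cat("quadrant counts:", paste(names(x$counts), x$counts, sep = "=",
                                collapse = " "), "\n")
  cat(sprintf("same-direction (Q1+Q3): %.1f%%; ties excluded: %d\n",
              x$same_direction_pct, x$ties))
  invisible(x)
}

#' Combinatorial TF sign patterns and dominance
#'
#' For genes differentially expressed under at least two TF knockdowns and
#' under rIIS, tabulates the sign pattern (per involved TF: + if the TF
#' activates the gene, - if it represses) crossed with the gene's rIIS
#' direction. Per-TF concordance is the fraction of its genes in the table
#' whose rIIS direction matches the TF's direction. The focus TF is
#' flagged dominant when its concordance is the strict maximum and at
#' least `margin`.
#'
#' @param de_by_tf Named list (>= 2 TFs) of [de_test()] results, one per
#'   TF-knockdown comparison.
#' @param de_riis [de_test()] result of the rIIS-vs-control comparison.
#' @param focus_tf Name of the TF tested for dominance (default first).
#' @param margin Minimum concordance for a dominance verdict (default 0.9).
#' @return List of class `dominance_table`: `genes` (per-gene signs and
#'   rIIS direction), `patterns` (grouped sign-pattern rows with counts),
#'   `concordance` (named per-TF), `focus_tf`, `dominant`.
#' @export
dominance_patterns <- function(de_by_tf, de_riis,
                               focus_tf = names(de_by_tf)[1], margin = 0.9) {
  if (!is.list(de_by_tf) || length(de_by_tf) < 2 || is.null(names(de_by_tf))) {
    stop("'de_by_tf' must be a named list of >= 2 DE results", call. = FALSE)
  }
  if (!focus_tf %in% names(de_by_tf)) {
    stop("unknown focus TF: ", focus_tf, call. = FALSE)
  }
  tfs <- names(de_by_tf)
  sign_of <- function(de) {
    s <- ifelse(de$call == "activated", 1L,
                ifelse(de$call == "repressed", -1L, NA_integer_))
    stats::setNames(s, de$gene_id)
  }
  tf_signs <- lapply(de_by_tf, sign_of)
  riis_sign <- sign_of(de_riis)
  riis_de <- names(riis_sign)[!is.na(riis_sign)]

  all_ids <- unique(unlist(lapply(tf_signs, names)))
  smat <- sapply(tf_signs, function(s) s[all_ids])
  rownames(smat) <- all_ids
  n_de <- rowSums(!is.na(smat))
  keep <- all_ids[n_de >= 2 & all_ids %in% riis_de]
  smat <- smat[keep, , drop = FALSE]

  gdf <- data.frame(gene_id = keep, smat,
                    riis_sign = unname(riis_sign[keep]),
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(gdf)[2:(1 + length(tfs))] <- paste0("sign_", tfs)

  pat <- apply(smat, 1, function(r) {
    inv <- which(!is.na(r))
    paste(paste0(tfs[inv], ifelse(r[inv] > 0, "+", "-")), collapse = " ")
  })
  pat_full <- paste0(pat, " | rIIS",
                     ifelse(gdf$riis_sign > 0, "+", "-"))
  tab <- as.data.frame(table(pattern = pat_full),
                       stringsAsFactors = FALSE)
  names(tab)[2] <- "count"
  tab <- tab[order(-tab$count), , drop = FALSE]
  rownames(tab) <- NULL

  conc <- vapply(tfs, function(tf) {
    s <- gdf[[paste0("sign_", tf)]]
    ok <- !is.na(s)
    if (!any(ok)) return(NA_real_)
    mean(s[ok] == gdf$riis_sign[ok])
  }, numeric(1))

  others <- conc[setdiff(tfs, focus_tf)]
  dominant <- is.finite(conc[[focus_tf]]) && conc[[focus_tf]] >= margin &&
    all(conc[[focus_tf]] > others, na.rm = TRUE)
  structure(list(genes = gdf, patterns = tab, concordance = conc,
                 focus_tf = focus_tf, margin = margin, dominant = dominant),
            class = "dominance_table")
}

#' @export
print.dominance_table <- function(x, ...) {
  cat(sprintf("dominance table: %d genes, focus = %s (%s)\n",
              nrow(x$genes), x$focus_tf,
              if (x$dominant) "dominant" else "not dominant"))
  cat("concordance:", paste(names(x$concordance),
                            sprintf("%.3f", x$concordance),
                            sep = "=", collapse = " "), "\n")
  invisible(x)
}
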