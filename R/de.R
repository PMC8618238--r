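#' Define an oriented two-group comparison
#'
#' Comparisons are oriented: fold change > 1 means higher expression in
#' `test_group`, and a gene significantly up in `test_group` is called
#' "activated". The study's convention lists the test group first, e.g.
#' rIIS-C vs C.
#'
#' @param name Short comparison label.
#' @param test_group,baseline_group Group ids from the design; must differ.
#' @return A list of class `comparison_spec`.
#' @export
comparison_spec <- function(name, test_group, baseline_group) {
  if (identical(test_group, baseline_group)) {
    stop("test and baseline group must differ", call. = FALSE)
  }
  structure(list(name = name, test_group = test_group,
                 baseline_group = baseline_group),
            class = "comparison_spec")
}

validate_comparison <- function(x, spec) {
  for (g in c(spec$test_group, spec$baseline_group)) {
    if (!g %in% x$samples$group) {
      stop("comparison '", spec$name, "' references unknown group: ", g,
           call. = FALSE)
    }
  }
  if ("heat_shock" %in% names(x$samples)) {
    hs_t <- unique(x$samples$heat_shock[x$samples$group == spec$test_group])
    hs_b <- unique(x$samples$heat_shock[x$samples$group == spec$baseline_group])
    if (length(hs_t) != 1 || length(hs_b) != 1 || !identical(hs_t, hs_b)) {
      stop("comparison '", spec$name,
           "' mixes heat-shock and normal-temperature groups", call. = FALSE)
    }
  }
  invisible(spec)
}

#' Two-group NB-GLM fold change with library-size offsets
#'
#' `fc(g) = (sum of test counts / sum of test library sizes) /
#'          (sum of baseline counts / sum of baseline library sizes)`.
#' This group-total ratio is the maximum-likelihood mean ratio of a
#' two-group negative-binomial GLM with log link, library-size offsets and
#' shared dispersion (exactly so for equal library sizes or in the Poisson
#' limit), and corrects for differences in library size. A pseudocount is
#' added to a group's count sum only when that sum is zero, keeping the
#' ratio finite without biasing typical genes.
#'
#' @param x A [count_matrix()].
#' @param spec A [comparison_spec()].
#' @param pseudocount Value added to zero group sums (default 0.5).
#' @param genes Optional gene ids to restrict to (default all).
#' @param lib_method Library-size estimator, passed to
#'   [effective_library_sizes()] (default `"median_ratio"`).
#' @return data.frame with `gene_id`, `fc`, `log2fc`.
#' @export
nbglm_fold_change <- function(x, spec, pseudocount = 0.5, genes = NULL,
                              lib_method = "median_ratio") {
  validate_comparison(x, spec)
  st <- group_samples(x, spec$test_group)
  sb <- group_samples(x, spec$baseline_group)
  lib <- effective_library_sizes(x, method = lib_method)
  cm <- x$counts
  if (!is.null(genes)) cm <- cm[genes, , drop = FALSE]
  yt <- rowSums(cm[, st, drop = FALSE])
  yb <- rowSums(cm[, sb, drop = FALSE])
  yt <- yt + pseudocount * (yt == 0)
  yb <- yb + pseudocount * (yb == 0)
  fc <- (yt / sum(lib[st])) / (yb / sum(lib[sb]))
  data.frame(gene_id = rownames(cm), fc = fc, log2fc = log2(fc),
             row.names = NULL, stringsAsFactors = FALSE)
}

# per-group weighted proportion estimate with two-pass moment
# overdispersion and optional moderation toward a common NB dispersion.
# Y: genes x replicates counts; n: replicate library sizes.
# Model: Var(p_i) = p(1-p) * (1/n_i + phi); weights w_i = 1/(1/n_i + phi);
# phat = sum(w p)/sum(w); Vhat = phat(1-phat)/sum(w).
# Moment estimator: solving E[sum w_i (p_i - phat)^2] for phi given
# current weights, clamped at 0, iterated twice. Since phi ~ d * p for an
# NB count model (Var(y) = mu + d mu^2), moderation shrinks the per-gene
# d = phi / p toward the across-gene mean with `prior_df` prior degrees
# of freedom before the final weight pass.
weighted_group_estimate <- function(Y, n, prior_df = 10) {
  k <- length(n)
  P <- sweep(Y, 2, n, "/")
  if (k == 1L) {
    ph <- P[, 1]
    return(list(phat = ph, V = ph * (1 - ph) / n, phi = rep(0, nrow(Y)),
                d_common = 0))
  }
  moment_pass <- function(w) {
    sw <- rowSums(w)
    ph <- rowSums(w * P) / sw
    S <- rowSums(w * (P - ph)^2)
    A <- rowSums(sweep(w, 2, n, "/")) - rowSums(sweep(w^2, 2, n, "/")) / sw
    B <- sw - rowSums(w^2) / sw
    v <- ph * (1 - ph)
    phi_raw <- ifelse(v > 0 & B > 0, (S / v - A) / B, 0)
    list(phat = ph, phi_raw = phi_raw, phi = pmax(0, phi_raw))
  }
  e1 <- moment_pass(matrix(n, nrow(Y), k, byrow = TRUE))
  e2 <- moment_pass(1 / outer(e1$phi, 1 / n, "+"))
  ph <- e2$phat
  ok <- ph > 0 & ph < 1
  d_common <- 0
  if (prior_df > 0 && any(ok)) {
    # unclamped per-gene d for an (approximately) unbiased common estimate
    d_common <- max(0, mean(e2$phi_raw[ok] / ph[ok]))
    d_gene <- ifelse(ok, e2$phi / ph, 0)
    d_mod <- (prior_df * d_common + (k - 1) * d_gene) / (prior_df + (k - 1))
    phi <- ifelse(ok, d_mod * ph, 0)
  } else {
    phi <- e2$phi
  }
  w <- 1 / outer(phi, 1 / n, "+")
  sw <- rowSums(w)
  phat <- rowSums(w * P) / sw
  list(phat = phat, V = phat * (1 - phat) / sw, phi = phi,
       d_common = d_common)
}

#' Weighted beta-binomial proportions test (Baggerley-style)
#'
#' Treats each replicate's gene count as a proportion of its library size
#' and compares weighted group proportions. Within each group, replicate
#' proportions `p_i = y_i / n_i` are combined with weights
#' `w_i = 1/(1/n_i + phi)`, where the overdispersion `phi >= 0` is
#' estimated per gene by a two-pass method of moments on the weighted
#' residual variance and then stabilised by shrinking the per-gene
#' NB-scale dispersion `phi / p` toward its across-gene mean with
#' `prior_df` prior degrees of freedom (set `prior_df = 0` for the pure
#' per-gene estimator). The statistic is
#' `z = (phat_test - phat_base) / sqrt(V_test + V_base)` with
#' `V = phat (1 - phat) / sum(w)`, referred to the standard normal (or a
#' t with `df = total replicates - 2` via `ref_dist = "t"`).
#'
#' When `phi = 0` in both groups the statistic reduces exactly to the
#' unpooled two-proportion z-test on pooled counts. With a single
#' replicate per group the `phi = 0` form is used, with a warning.
#'
#' @param x A [count_matrix()].
#' @param spec A [comparison_spec()].
#' @param prior_df Prior degrees of freedom for dispersion moderation
#'   (default 10).
#' @param ref_dist `"normal"` (default) or `"t"`.
#' @param genes Optional gene ids to restrict to.
#' @param lib_method Library-size estimator, passed to
#'   [effective_library_sizes()] (default `"median_ratio"`).
#' @return data.frame with `gene_id`, `z`, `p_value`, per-group weighted
#'   proportions `p_test`, `p_baseline` and overdispersions `phi_test`,
#'   `phi_baseline`.
#' @export
baggerley_test <- function(x, spec, prior_df = 10,
                           ref_dist = c("normal", "t"), genes = NULL,
                           lib_method = "median_ratio") {
  ref_dist <- match.arg(ref_dist)
  validate_comparison(x, spec)
  st <- group_samples(x, spec$test_group)
  sb <- group_samples(x, spec$baseline_group)
  if (length(st) < 2 || length(sb) < 2) {
    warning("a group has a single replicate; using phi = 0 ",
            "(two-proportion test)", call. = FALSE)
  }
  lib <- effective_library_sizes(x, method = lib_method)
  if (any(lib[c(st, sb)] == 0)) {
    stop("zero library size in compared samples", call. = FALSE)
  }
  cm <- x$counts
  if (!is.null(genes)) cm <- cm[genes, , drop = FALSE]
  gt <- weighted_group_estimate(cm[, st, drop = FALSE], lib[st], prior_df)
  gb <- weighted_group_estimate(cm[, sb, drop = FALSE], lib[sb], prior_df)
  den <- sqrt(gt$V + gb$V)
  diff <- gt$phat - gb$phat
  z <- ifelse(den > 0, diff / den, ifelse(diff == 0, 0, sign(diff) * Inf))
  p <- if (ref_dist == "normal") {
    2 * stats::pnorm(-abs(z))
  } else {
    2 * stats::pt(-abs(z), df = max(length(st) + length(sb) - 2, 1))
  }
  data.frame(gene_id = rownames(cm), z = z, p_value = p,
             p_test = gt$phat, p_baseline = gb$phat,
             phi_test = gt$phi, phi_baseline = gb$phi,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Threshold fold changes and p-values into DE calls
#'
#' A gene is "activated" iff `fc >= fc_threshold` and `p <= alpha`,
#' "repressed" iff `fc <= 1/fc_threshold` and `p <= alpha`, otherwise
#' "unchanged". Boundary values are included, matching the "at least
#' 1.5-fold, p <= 0.05" convention.
#'
#' @param fc Fold changes (test/baseline).
#' @param p p-values.
#' @param fc_threshold Fold-change threshold (default 1.5).
#' @param alpha Significance level (default 0.05).
#' @return Character vector in {"activated", "repressed", "unchanged"}.
#' @export
call_de <- function(fc, p, fc_threshold = 1.5, alpha = 0.05) {
  if (fc_threshold <= 0 || alpha <= 0) {
    stop("thresholds must be positive", call. = FALSE)
  }
  out <- rep("unchanged", length(fc))
  out[fc >= fc_threshold & p <= alpha] <- "activated"
  out[fc <= 1 / fc_threshold & p <= alpha] <- "repressed"
  out
}

#' Full oriented differential-expression test for one comparison
#'
#' Combines [nbglm_fold_change()], [baggerley_test()] and [call_de()],
#' and attaches per-group mean RPKM.
#'
#' @inheritParams baggerley_test
#' @param fc_threshold,alpha Calling thresholds (defaults 1.5 and 0.05).
#' @param pseudocount Passed to [nbglm_fold_change()].
#' @param adjust `"none"` (default; the calling uses standard p-values) or
#'   `"BH"` for Benjamini-Hochberg adjusted calling.
#' @return data.frame of class `de_result`: `gene_id`, `fc`, `log2fc`,
#'   `z`, `p_value` (and `p_adj` if `adjust = "BH"`), `call`,
#'   `mean_rpkm_test`, `mean_rpkm_baseline`. The comparison spec and
#'   thresholds are stored as attributes.
#' @export
de_test <- function(x, spec, fc_threshold = 1.5, alpha = 0.05,
                    genes = NULL, pseudocount = 0.5, prior_df = 10,
                    ref_dist = "normal", adjust = c("none", "BH"),
                    lib_method = "median_ratio") {
  adjust <- match.arg(adjust)
  fcres <- nbglm_fold_change(x, spec, pseudocount = pseudocount,
                             genes = genes, lib_method = lib_method)
  bres <- baggerley_test(x, spec, prior_df = prior_df, ref_dist = ref_dist,
                         genes = genes, lib_method = lib_method)
  stopifnot(identical(fcres$gene_id, bres$gene_id))
  r <- rpkm(x)[fcres$gene_id, , drop = FALSE]
  st <- group_samples(x, spec$test_group)
  sb <- group_samples(x, spec$baseline_group)
  out <- data.frame(
    gene_id = fcres$gene_id, fc = fcres$fc, log2fc = fcres$log2fc,
    z = bres$z, p_value = bres$p_value,
    stringsAsFactors = FALSE
  )
  p_call <- out$p_value
  if (adjust == "BH") {
    out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
    p_call <- out$p_adj
  }
  out$call <- call_de(out$fc, p_call, fc_threshold, alpha)
  out$mean_rpkm_test <- rowMeans(r[, st, drop = FALSE])
  out$mean_rpkm_baseline <- rowMeans(r[, sb, drop = FALSE])
  structure(out, class = c("de_result", "data.frame"),
            comparison = spec,
            fc_threshold = fc_threshold, alpha = alpha)
}

#' Gene sets from a DE result
#'
#' @param de A [de_test()] result.
#' @param direction `"activated"`, `"repressed"` or `"any"` (either call).
#' @return Character vector of gene ids.
#' @export
de_genes <- function(de, direction = c("any", "activated", "repressed")) {
  direction <- match.arg(direction)
  if (direction == "any") {
    de$gene_id[de$call != "unchanged"]
  } else {
    de$gene_id[de$call == direction]
  }
}
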