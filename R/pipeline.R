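#' Default comparison list of the study design
#'
#' The five oriented comparisons: rIIS vs control (both temperatures) and
#' the three TF knockdowns against their rIIS background, heat-shock
#' conditions paired with heat-shock controls only.
#'
#' @return Named list of [comparison_spec()]s (`riis`, `riis_hs`,
#'   `daf16`, `skn1`, `hsf1`).
#' @export
default_comparisons <- function() {
  list(
    riis    = comparison_spec("rIIS-C_vs_C", "rIIS-C", "C"),
    riis_hs = comparison_spec("rIIS-C-HS_vs_C-HS", "rIIS-C-HS", "C-HS"),
    daf16   = comparison_spec("rIIS-C_vs_rIIS-daf16i", "rIIS-C",
                              "rIIS-daf16i"),
    skn1    = comparison_spec("rIIS-C_vs_rIIS-skn1i", "rIIS-C",
                              "rIIS-skn1i"),
    hsf1    = comparison_spec("rIIS-C-HS_vs_rIIS-hsf1i-HS", "rIIS-C-HS",
                              "rIIS-hsf1i-HS")
  )
}

#' Assemble a pipeline configuration
#'
#' @param n_genes Genes to simulate (ignored when `dataset` is given).
#' @param generator A [generator_config()].
#' @param design A design data.frame, default [default_design()].
#' @param combination_rule Simulator rule (default `"daf16_dominant"`).
#' @param dataset Optional pre-loaded [count_matrix()]; when given, no
#'   simulation is run.
#' @param comparisons Named list of [comparison_spec()]s (default
#'   [default_comparisons()]).
#' @param fc_threshold,alpha,rpkm_floor Thresholds (defaults 1.5, 0.05, 10).
#' @param detection_rule Detection rule for [detected_genes()].
#' @param prior_df Moderation prior for [baggerley_test()].
#' @param lib_method Library-size estimator for DE (default
#'   `"median_ratio"`).
#' @param universe_size Hypergeometric background `N`; default the number
#'   of genes in the count matrix.
#' @param focus_tf TF whose dominance is assessed (default `"daf16"`).
#' @param seed Master seed (drives the simulation).
#' @param out_dir Optional output directory for TSV/JSON artefacts.
#' @return List of class `run_config`.
#' @export
run_config <- function(n_genes = 16000, generator = generator_config(),
                       design = default_design(),
                       combination_rule = "daf16_dominant",
                       dataset = NULL,
                       comparisons = default_comparisons(),
                       fc_threshold = 1.5, alpha = 0.05, rpkm_floor = 10,
                       detection_rule = "min_reads", prior_df = 10,
                       lib_method = "median_ratio",
                       universe_size = NULL, focus_tf = "daf16",
                       seed = 1, out_dir = NULL) {
  if (fc_threshold <= 0 || alpha <= 0 || rpkm_floor < 0) {
    stop("thresholds must be positive", call. = FALSE)
  }
  structure(list(
    n_genes = n_genes, generator = generator, design = design,
    combination_rule = combination_rule, dataset = dataset,
    comparisons = comparisons, fc_threshold = fc_threshold, alpha = alpha,
    rpkm_floor = rpkm_floor, detection_rule = detection_rule,
    prior_df = prior_df, lib_method = lib_method,
    universe_size = universe_size,
    focus_tf = focus_tf, seed = seed, out_dir = out_dir
  ), class = "run_config")
}

validate_run_config <- function(config, x) {
  groups <- unique(x$samples$group)
  for (cmp in config$comparisons) {
    for (g in c(cmp$test_group, cmp$baseline_group)) {
      if (!g %in% groups) {
        stop("comparison '", cmp$name, "' references unknown group: ", g,
             call. = FALSE)
      }
    }
  }
  invisible(config)
}

#' Run the full simulate -> quantify -> DE -> overlap -> classify pipeline
#'
#' Executes every stage of the comparative framework on a simulated (or
#' supplied) dataset: QC, common-gene filtering, oriented DE per
#' comparison, common-gene overlap statistics, rIIS-dependence cross-tabs
#' per TF, reversal analysis per TF, TF-vs-rIIS quadrant classification,
#' and the combinatorial dominance tabulation. All randomness comes from
#' the master seed, so the same configuration reproduces the summary
#' byte-identically.
#'
#' @param config A [run_config()].
#' @return List of class `pipeline_result`: `dataset`, `qc`, `de`
#'   (per-comparison), `common` (per-comparison detected/common gene
#'   info), `overlaps`, `crosstabs`, `reversal`, `quadrants`,
#'   `dominance`, and `summary` (plain named list, JSON-serialisable).
#'   When `config$out_dir` is set, per-stage TSVs and `summary.json` are
#'   written there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  # --- data
  if (is.null(config$dataset)) {
    truth <- generate_truth(config$n_genes, config$generator,
                            seed = config$seed)
    sim <- simulate_counts(truth, config$design,
                           combination_rule = config$combination_rule,
                           seed = config$seed)
    x <- sim$counts
  } else {
    sim <- NULL
    x <- config$dataset
  }
  validate_run_config(config, x)
  N <- config$universe_size %||% nrow(x$counts)

  qc <- qc_summary(x)

  # --- per-comparison common-gene filtering and DE
  de <- list(); common <- list(); overlaps <- list()
  for (nm in names(config$comparisons)) {
    cmp <- config$comparisons[[nm]]
    det_t <- detected_genes(x, cmp$test_group, rule = config$detection_rule)
    det_b <- detected_genes(x, cmp$baseline_group,
                            rule = config$detection_rule)
    cg <- common_genes(det_t, det_b)
    common[[nm]] <- list(detected_test = length(det_t),
                         detected_baseline = length(det_b),
                         n_common = length(cg$common),
                         common = cg$common)
    overlaps[[nm]] <- overlap_test(det_t, det_b, universe_size = N)
    de[[nm]] <- de_test(x, cmp, fc_threshold = config$fc_threshold,
                        alpha = config$alpha, genes = cg$common,
                        prior_df = config$prior_df,
                        lib_method = config$lib_method)
  }

  # --- rIIS-dependence cross-tabs (HSF-1 against the heat-shock rIIS set)
  riis_for_tf <- list(daf16 = "riis", skn1 = "riis", hsf1 = "riis_hs")
  crosstabs <- list()
  for (tf in intersect(names(riis_for_tf), names(de))) {
    dr <- de[[riis_for_tf[[tf]]]]
    dt <- de[[tf]]
    shared <- intersect(dr$gene_id, dt$gene_id)
    crosstabs[[tf]] <- riis_dependence_crosstab(
      dr[dr$gene_id %in% shared, ], dt[dt$gene_id %in% shared, ],
      universe_size = N)
  }

  # --- reversal analysis per TF
  rev_groups <- list(
    daf16 = c("C", "rIIS-C", "rIIS-daf16i"),
    skn1  = c("C", "rIIS-C", "rIIS-skn1i"),
    hsf1  = c("C-HS", "rIIS-C-HS", "rIIS-hsf1i-HS")
  )
  reversal <- list()
  for (tf in names(rev_groups)) {
    g <- rev_groups[[tf]]
    if (!all(g %in% x$samples$group)) next
    reversal[[tf]] <- reversal_analysis(
      x, g[1], g[2], g[3], fc_threshold = config$fc_threshold,
      alpha = config$alpha, rpkm_floor = config$rpkm_floor,
      prior_df = config$prior_df, lib_method = config$lib_method)
  }

  # --- quadrant classification: each TF against its rIIS reference
  quadrants <- list()
  for (tf in intersect(names(riis_for_tf), names(de))) {
    dr <- de[[riis_for_tf[[tf]]]]
    dt <- de[[tf]]
    genes <- intersect(de_genes(dr), de_genes(dt))
    if (!length(genes)) next
    quadrants[[tf]] <- quadrant_classify(
      stats::setNames(dt$log2fc, dt$gene_id),
      stats::setNames(dr$log2fc, dr$gene_id), genes)
  }

  # --- dominance tabulation over the three TFs
  tf_names_here <- intersect(c("daf16", "skn1", "hsf1"), names(de))
  dominance <- NULL
  if (length(tf_names_here) >= 2 && "riis" %in% names(de)) {
    dominance <- dominance_patterns(de[tf_names_here], de$riis,
                                    focus_tf = config$focus_tf)
  }

  summary <- list(
    seed = config$seed,
    n_genes = nrow(x$counts), n_samples = ncol(x$counts),
    universe_size = N,
    thresholds = list(fc = config$fc_threshold, alpha = config$alpha,
                      rpkm_floor = config$rpkm_floor,
                      detection_rule = config$detection_rule,
                      prior_df = config$prior_df,
                      lib_method = config$lib_method),
    comparisons = lapply(names(de), function(nm) {
      d <- de[[nm]]
      list(name = attr(d, "comparison")$name,
           n_common = common[[nm]]$n_common,
           overlap_rf = overlaps[[nm]]$rf,
           overlap_log10_p = overlaps[[nm]]$log10_p,
           activated = sum(d$call == "activated"),
           repressed = sum(d$call == "repressed"))
    }),
    crosstabs = lapply(crosstabs, function(ct) {
      list(combined_num = ct$combined_num, combined_den = ct$combined_den,
           combined_fraction_pct = ct$combined_fraction_pct)
    }),
    reversal = lapply(reversal, function(rv) {
      stats::setNames(as.list(rv$summary$fraction), rv$summary$direction)
    }),
    quadrants = lapply(quadrants, function(q) {
      list(same_direction_pct = q$same_direction_pct,
           counts = as.list(q$counts))
    }),
    dominance = if (!is.null(dominance)) {
      list(focus_tf = dominance$focus_tf,
           concordance = as.list(dominance$concordance),
           dominant = dominance$dominant,
           verdict = if (dominance$dominant) dominance$focus_tf else "none")
    }
  )
  names(summary$comparisons) <- names(de)

  res <- structure(list(dataset = if (is.null(sim)) x else sim, qc = qc,
                        de = de, common = common, overlaps = overlaps,
                        crosstabs = crosstabs, reversal = reversal,
                        quadrants = quadrants, dominance = dominance,
                        summary = summary, config = config),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_outputs(res, config$out_dir)
  res
}

write_pipeline_outputs <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_dataset(res$dataset, file.path(dir, "dataset"))
  for (nm in names(res$de)) {
    utils::write.table(as.data.frame(res$de[[nm]]),
                       file.path(dir, paste0("de_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(res$dominance)) {
    utils::write.table(res$dominance$patterns,
                       file.path(dir, "dominance_patterns.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(res$dominance$genes,
                       file.path(dir, "dominance_genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (tf in names(res$reversal)) {
    utils::write.table(res$reversal[[tf]]$summary,
                       file.path(dir, paste0("reversal_", tf, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(res$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("pipeline run: %d genes, %d samples, seed %d\n",
              s$n_genes, s$n_samples, as.integer(s$seed)))
  for (nm in names(s$comparisons)) {
    cc <- s$comparisons[[nm]]
    cat(sprintf("  %-28s common=%5d act=%4d rep=%4d RF=%.2f\n",
                cc$name, cc$n_common, cc$activated, cc$repressed,
                cc$overlap_rf))
  }
  if (!is.null(s$dominance)) {
    cat("  dominance verdict:", s$dominance$verdict, "\n")
  }
  invisible(x)
}
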