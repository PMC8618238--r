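#' Expected counts under the log-linear regulatory model
#'
#' For gene g and sample s with group TF activities `a_TF`,
#' `log2 mu = baseline_log2 + log2(library_size / reference_depth)
#'  + riis * riis_direct_log2 + tf_contribution`, where the TF contribution
#' is `a_daf16*e_daf16 + a_skn1*e_skn1 + a_hsf1*e_hsf1` under
#' `rule = "additive"`. Under `rule = "daf16_dominant"`, for DAF-16-target
#' genes the summed SKN-1 + HSF-1 contribution is clipped so that its
#' magnitude never exceeds `dominance_clip * |a_daf16 * e_daf16|`
#' (`dominance_clip < 1`), so DAF-16 always sets the sign of the total
#' regulatory effect on its targets.
#'
#' @param truth Truth table from [generate_truth()].
#' @param design Design from [default_design()].
#' @param rule `"daf16_dominant"` or `"additive"`.
#' @param reference_depth Depth at which `baseline_log2` is calibrated
#'   (default 2e7).
#' @param dominance_clip Clip factor in [0, 1) for the dominant rule.
#' @return Matrix of expected counts, genes x samples.
#' @export
expected_mu <- function(truth, design, rule = c("daf16_dominant", "additive"),
                        reference_depth = 2e7, dominance_clip = 0.9) {
  rule <- match.arg(rule)
  validate_design(design)
  if (dominance_clip < 0 || dominance_clip >= 1) {
    stop("'dominance_clip' must be in [0, 1)", call. = FALSE)
  }
  ng <- nrow(truth); ns <- nrow(design)
  lmu <- matrix(NA_real_, ng, ns,
                dimnames = list(truth$gene_id, design$sample_id))
  dtar <- truth$effect_daf16 != 0
  for (j in seq_len(ns)) {
    d <- design$a_daf16[j] * truth$effect_daf16
    cc <- design$a_skn1[j] * truth$effect_skn1 +
      design$a_hsf1[j] * truth$effect_hsf1
    if (rule == "daf16_dominant" && any(dtar)) {
      cap <- dominance_clip * abs(d[dtar])
      cc[dtar] <- sign(cc[dtar]) * pmin(abs(cc[dtar]), cap)
    }
    lmu[, j] <- truth$baseline_log2 +
      log2(design$library_size[j] / reference_depth) +
      design$riis[j] * truth$riis_direct_log2 + d + cc
  }
  mu <- 2^lmu
  if (!all(is.finite(mu))) {
    stop("non-finite expected counts; check truth/design values",
         call. = FALSE)
  }
  mu
}

#' Simulate a count matrix with known regulatory ground truth
#'
#' Draws negative-binomial read counts (variance mu + d * mu^2; d = 0 gives
#' the Poisson limit) around the expected counts of [expected_mu()], for
#' every sample of the design. The same (truth, design, rule, seed) always
#' reproduces the counts bit-identically.
#'
#' @inheritParams expected_mu
#' @param combination_rule Passed to [expected_mu()] as `rule`.
#' @param seed Integer seed for the count draw.
#' @return A list of class `simulated_dataset` with elements `counts`
#'   (a [count_matrix()]), `truth`, `design`, `mu` (expected counts),
#'   `seed` and `rule`.
#' @export
simulate_counts <- function(truth, design,
                            combination_rule = c("daf16_dominant", "additive"),
                            seed = 1, reference_depth = 2e7,
                            dominance_clip = 0.9) {
  combination_rule <- match.arg(combination_rule)
  mu <- expected_mu(truth, design, rule = combination_rule,
                    reference_depth = reference_depth,
                    dominance_clip = dominance_clip)
  disp <- rep(truth$dispersion, times = ncol(mu))  # column-major layout
  v_mu <- as.vector(mu)
  counts <- with_seed(seed, {
    x <- numeric(length(v_mu))
    pois <- disp == 0
    if (any(pois)) x[pois] <- stats::rpois(sum(pois), v_mu[pois])
    if (any(!pois)) {
      x[!pois] <- stats::rnbinom(sum(!pois), mu = v_mu[!pois],
                                 size = 1 / disp[!pois])
    }
    x
  })
  cmat <- matrix(counts, nrow(mu), ncol(mu), dimnames = dimnames(mu))
  storage.mode(cmat) <- "integer"
  cm <- count_matrix(
    counts = cmat,
    lengths_bp = stats::setNames(truth$length_bp, truth$gene_id),
    samples = design[, c("sample_id", "group", "replicate", "heat_shock",
                         "rnai_target")]
  )
  structure(list(counts = cm, truth = truth, design = design, mu = mu,
                 seed = seed, rule = combination_rule),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat("Simulated rIIS/TF-knockdown dataset\n")
  cat(sprintf("  %d genes x %d samples, rule = %s, seed = %d\n",
              nrow(x$counts$counts), ncol(x$counts$counts), x$rule,
              as.integer(x$seed)))
  cat(sprintf("  TF targets: daf16 %d, skn1 %d, hsf1 %d\n",
              sum(x$truth$effect_daf16 != 0), sum(x$truth$effect_skn1 != 0),
              sum(x$truth$effect_hsf1 != 0)))
  invisible(x)
}
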