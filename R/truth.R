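#' Configuration for the regulatory ground-truth generator
#'
#' Describes the regulatory architecture imprinted on simulated genes:
#' the fractions of genes targeted by exactly one, two or all three of
#' DAF-16, SKN-1 and HSF-1 (remaining genes are untargeted), the
#' activator:repressor balance, the effect-size and baseline-expression
#' distributions, and the negative-binomial dispersion.
#'
#' The default fractions (27% single-TF, 21% two-TF, 4% three-TF targets)
#' emulate the observed partition of TF-regulated genes in class-1 rIIS
#' mutants, where roughly half of TF-regulated genes are specific to a
#' single factor and only a small minority respond to all three.
#'
#' @param frac_single,frac_double,frac_triple Fractions of genes targeted by
#'   exactly 1, 2 or 3 TFs; must be non-negative and sum to at most 1.
#' @param activator_fraction Fraction of TF-target assignments with positive
#'   sign (TF activates the gene); default 0.5.
#' @param effect_log2_range Range of |log2| effect magnitudes, default
#'   log2(1.5) to log2(8), so every true effect is at least the fold-change
#'   calling threshold.
#' @param baseline_log2_mean,baseline_log2_sd Normal distribution of per-gene
#'   log2 expected counts at the reference sequencing depth.
#' @param dispersion Negative-binomial dispersion d, with
#'   variance = mu + d * mu^2; d = 0 degenerates to Poisson.
#' @param frac_riis_direct Fraction of genes with a TF-independent rIIS
#'   effect.
#' @param riis_direct_log2_range Range of |log2| magnitudes of the direct
#'   rIIS effect.
#' @param length_log_mean,length_log_sd Log-normal parameters for exonic
#'   gene lengths in bp.
#' @param assignment `"deterministic"` (category counts exact, assignments
#'   interleaved) or `"stochastic"` (per-gene multinomial draw).
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(frac_single = 0.27,
                             frac_double = 0.21,
                             frac_triple = 0.04,
                             activator_fraction = 0.5,
                             effect_log2_range = c(log2(1.5), log2(8)),
                             baseline_log2_mean = log2(400),
                             baseline_log2_sd = 2,
                             dispersion = 0.05,
                             frac_riis_direct = 0.05,
                             riis_direct_log2_range = c(log2(1.5), log2(8)),
                             length_log_mean = log(1500),
                             length_log_sd = 0.6,
                             assignment = c("deterministic", "stochastic")) {
  assignment <- match.arg(assignment)
  fr <- c(frac_single, frac_double, frac_triple)
  if (any(fr < 0)) stop("target fractions must be non-negative", call. = FALSE)
  if (sum(fr) > 1) stop("target fractions sum to more than 1", call. = FALSE)
  if (activator_fraction < 0 || activator_fraction > 1) {
    stop("'activator_fraction' must be in [0, 1]", call. = FALSE)
  }
  if (dispersion < 0) stop("'dispersion' must be >= 0", call. = FALSE)
  if (frac_riis_direct < 0 || frac_riis_direct > 1) {
    stop("'frac_riis_direct' must be in [0, 1]", call. = FALSE)
  }
  structure(list(
    frac_single = frac_single, frac_double = frac_double,
    frac_triple = frac_triple,
    activator_fraction = activator_fraction,
    effect_log2_range = effect_log2_range,
    baseline_log2_mean = baseline_log2_mean,
    baseline_log2_sd = baseline_log2_sd,
    dispersion = dispersion,
    frac_riis_direct = frac_riis_direct,
    riis_direct_log2_range = riis_direct_log2_range,
    length_log_mean = length_log_mean, length_log_sd = length_log_sd,
    assignment = assignment
  ), class = "generator_config")
}

tf_names <- function() c("daf16", "skn1", "hsf1")

#' Generate the per-gene regulatory ground truth
#'
#' Assigns each gene a target category (untargeted, or targeted by 1, 2 or
#' 3 TFs), signed log2 effect sizes per TF (+ = the TF activates the gene,
#' - = represses, 0 = not a target), an optional TF-independent rIIS
#' effect, a baseline expression level, a dispersion and an exonic length.
#'
#' Under `assignment = "deterministic"` the category counts are exact
#' (`round(frac * n_genes)`) and TF identities and signs are interleaved so
#' every TF receives an equal share of targets and, at
#' `activator_fraction = 0.5`, equal numbers of activated and repressed
#' targets (within 1 for odd totals). Under `"stochastic"` each gene draws
#' its category independently.
#'
#' @param n_genes Number of genes (>= 1).
#' @param config A [generator_config()].
#' @param seed Integer seed; the same (n_genes, config, seed) always
#'   reproduces the same table.
#' @return A data.frame (truth table) with columns `gene_id`,
#'   `baseline_log2`, `effect_daf16`, `effect_skn1`, `effect_hsf1`,
#'   `riis_direct_log2`, `dispersion`, `length_bp`, `n_tfs`.
#' @export
generate_truth <- function(n_genes, config = generator_config(), seed = 1) {
  if (!inherits(config, "generator_config")) {
    stop("'config' must be a generator_config()", call. = FALSE)
  }
  if (n_genes < 1) stop("'n_genes' must be >= 1", call. = FALSE)
  n_genes <- as.integer(n_genes)

  with_seed(seed, {
    # --- category per gene: number of targeting TFs (0..3)
    if (config$assignment == "deterministic") {
      n1 <- round(config$frac_single * n_genes)
      n2 <- round(config$frac_double * n_genes)
      n3 <- round(config$frac_triple * n_genes)
      if (n1 + n2 + n3 > n_genes) n3 <- n_genes - n1 - n2
      categ <- rep(c(1L, 2L, 3L, 0L), c(n1, n2, n3, n_genes - n1 - n2 - n3))
    } else {
      p0 <- 1 - config$frac_single - config$frac_double - config$frac_triple
      categ <- sample(0:3, n_genes, replace = TRUE,
                      prob = c(p0, config$frac_single, config$frac_double,
                               config$frac_triple))
    }

    # --- which TFs target each gene
    combos2 <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
    member <- matrix(FALSE, n_genes, 3,
                     dimnames = list(NULL, tf_names()))
    i1 <- which(categ == 1L); i2 <- which(categ == 2L); i3 <- which(categ == 3L)
    if (config$assignment == "deterministic") {
      if (length(i1)) {
        pick <- ((seq_along(i1) - 1L) %% 3L) + 1L
        member[cbind(i1, pick)] <- TRUE
      }
      if (length(i2)) {
        pick <- ((seq_along(i2) - 1L) %% 3L) + 1L
        for (j in seq_along(i2)) member[i2[j], combos2[[pick[j]]]] <- TRUE
      }
    } else {
      if (length(i1)) member[cbind(i1, sample(1:3, length(i1), TRUE))] <- TRUE
      if (length(i2)) {
        pick <- sample(1:3, length(i2), TRUE)
        for (j in seq_along(i2)) member[i2[j], combos2[[pick[j]]]] <- TRUE
      }
    }
    if (length(i3)) member[i3, ] <- TRUE

    # --- signed effects per TF
    eff <- matrix(0, n_genes, 3, dimnames = list(NULL, tf_names()))
    for (t in 1:3) {
      tg <- which(member[, t])
      m <- length(tg)
      if (m == 0) next
      # exact activator count, randomly placed: positional alternation
      # would correlate signs across TFs on shared target genes
      s <- if (config$assignment == "deterministic") {
        n_pos <- round(m * config$activator_fraction)
        sample(rep(c(1, -1), c(n_pos, m - n_pos)))
      } else {
        ifelse(stats::runif(m) < config$activator_fraction, 1, -1)
      }
      mag <- stats::runif(m, config$effect_log2_range[1],
                          config$effect_log2_range[2])
      eff[tg, t] <- s * mag
    }

    # --- TF-independent rIIS effect
    direct <- numeric(n_genes)
    dflag <- if (config$assignment == "deterministic") {
      interleave_flags(n_genes, config$frac_riis_direct)
    } else {
      stats::runif(n_genes) < config$frac_riis_direct
    }
    nd <- sum(dflag)
    if (nd > 0) {
      s <- if (config$assignment == "deterministic") {
        sample(rep(c(1, -1), length.out = nd))
      } else {
        ifelse(stats::runif(nd) < 0.5, 1, -1)
      }
      direct[dflag] <- s * stats::runif(nd, config$riis_direct_log2_range[1],
                                        config$riis_direct_log2_range[2])
    }

    truth <- data.frame(
      gene_id = sprintf("g%05d", seq_len(n_genes)),
      baseline_log2 = stats::rnorm(n_genes, config$baseline_log2_mean,
                                   config$baseline_log2_sd),
      effect_daf16 = eff[, "daf16"],
      effect_skn1 = eff[, "skn1"],
      effect_hsf1 = eff[, "hsf1"],
      riis_direct_log2 = direct,
      dispersion = rep(config$dispersion, n_genes),
      length_bp = pmax(round(stats::rlnorm(n_genes, config$length_log_mean,
                                           config$length_log_sd)), 50),
      n_tfs = rowSums(member),
      stringsAsFactors = FALSE
    )
    stopifnot(all(is.finite(truth$baseline_log2)),
              all(truth$length_bp >= 1))
    truth
  })
}
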