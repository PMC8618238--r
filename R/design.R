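#' Sample groups of the seven-condition RNAi study design
#'
#' @return Character vector of the seven group identifiers.
#' @export
design_groups <- function() {
  c("C", "rIIS-C", "rIIS-daf16i", "rIIS-skn1i",
    "C-HS", "rIIS-C-HS", "rIIS-hsf1i-HS")
}

#' Build the default experimental design
#'
#' Encodes the seven-condition knockdown design: control (C) and
#' rIIS-control (rIIS-C) worms at normal temperature, RNAi knockdowns of
#' daf-16 and skn-1 in the rIIS background, and a heat-shock (HS) arm
#' (C-HS, rIIS-C-HS and hsf-1 RNAi under HS) that activates HSF-1.
#'
#' Per-group transcription-factor activities follow the pathway biology:
#' DAF-16 and SKN-1 are nuclear-active only under rIIS (activity 1 in rIIS
#' groups, 0 in controls); HSF-1 has a basal activity at 20 degrees C and
#' full activity after heat shock. RNAi knockdown retains a residual
#' activity (`residual_knockdown`) of the group's pre-knockdown level,
#' modelling efficient but incomplete silencing.
#'
#' @param replicates Biological replicates per group (default 2).
#' @param library_size Expected total read count per sample (default 2e7).
#' @param residual_knockdown Remaining fractional activity of a knocked-down
#'   factor (default 0.1).
#' @param hsf1_basal Basal HSF-1 activity at normal temperature (default 0.2).
#' @return A data.frame with one row per sample: `sample_id`, `group`,
#'   `replicate`, `heat_shock`, `rnai_target`, per-TF activities
#'   (`a_daf16`, `a_skn1`, `a_hsf1`), the rIIS indicator `riis`, and
#'   `library_size`.
#' @export
default_design <- function(replicates = 2, library_size = 2e7,
                           residual_knockdown = 0.1, hsf1_basal = 0.2) {
  if (replicates < 1) stop("'replicates' must be >= 1", call. = FALSE)
  if (residual_knockdown < 0 || residual_knockdown > 1) {
    stop("'residual_knockdown' must be in [0, 1]", call. = FALSE)
  }
  groups <- data.frame(
    group       = design_groups(),
    riis        = c(0, 1, 1, 1, 0, 1, 1),
    heat_shock  = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
    rnai_target = c("EV", "EV", "daf-16", "skn-1", "EV", "EV", "hsf-1"),
    a_daf16     = c(0, 1, residual_knockdown, 1, 0, 1, 1),
    a_skn1      = c(0, 1, 1, residual_knockdown, 0, 1, 1),
    a_hsf1      = c(hsf1_basal, hsf1_basal, hsf1_basal, hsf1_basal,
                    1, 1, residual_knockdown),
    stringsAsFactors = FALSE
  )
  des <- groups[rep(seq_len(nrow(groups)), each = replicates), ]
  des$replicate <- rep(seq_len(replicates), times = nrow(groups))
  des$sample_id <- paste0(des$group, "_r", des$replicate)
  des$library_size <- library_size
  rownames(des) <- NULL
  des[, c("sample_id", "group", "replicate", "heat_shock", "rnai_target",
          "a_daf16", "a_skn1", "a_hsf1", "riis", "library_size")]
}

validate_design <- function(design) {
  need <- c("sample_id", "group", "replicate", "heat_shock",
            "a_daf16", "a_skn1", "a_hsf1", "riis", "library_size")
  miss <- setdiff(need, names(design))
  if (length(miss)) {
    stop("design is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(design$sample_id)) {
    stop("duplicate sample_id in design", call. = FALSE)
  }
  if (any(design$library_size <= 0)) {
    stop("library_size must be positive", call. = FALSE)
  }
  invisible(design)
}
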