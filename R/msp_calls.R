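# MSP result interpretation: validity gating on the ACTB reference,
# fixed-cutoff positivity calls, OR-combined dual-marker calls, and the
# 2^-ddCt relative methylation level against the plasmid calibrator.

#' MSP calling configuration
#'
#' The fixed cutoffs of the assay: a target gene is positive at
#' Ct <= 38; a reaction is valid only if the ACTB reference amplifies at
#' Ct <= 36 (enough human template). For ROC score construction only,
#' NO_AMP is placed at the run length (45 cycles) so Ct scores are
#' totally ordered; calls themselves never coerce NO_AMP to a number.
#' The methylation level of a NO_AMP target is 0 (no detectable
#' methylated template).
#'
#' @param ct_cutoff_target Positivity cutoff for target genes (default 38).
#' @param ct_cutoff_actb Validity cutoff for ACTB (default 36).
#' @param no_amp_ct_for_scoring Ct assigned to NO_AMP in ROC scores
#'   (default 45).
#' @param ml_for_no_amp Methylation level for a NO_AMP target (default 0).
#' @return List of class `call_config`.
#' @export
call_config <- function(ct_cutoff_target = 38, ct_cutoff_actb = 36,
                        no_amp_ct_for_scoring = max_cycles(),
                        ml_for_no_amp = 0) {
  stopifnot(ct_cutoff_target > 0, ct_cutoff_target <= max_cycles(),
            ct_cutoff_actb > 0, ct_cutoff_actb <= max_cycles())
  structure(list(ct_cutoff_target = ct_cutoff_target,
                 ct_cutoff_actb = ct_cutoff_actb,
                 no_amp_ct_for_scoring = no_amp_ct_for_scoring,
                 ml_for_no_amp = ml_for_no_amp),
            class = "call_config")
}

#' Reaction validity from the ACTB reference
#'
#' @param ct_actb ACTB Ct (numeric, `NA` = NO_AMP); vectorised.
#' @param config A [call_config()].
#' @return Logical: valid iff ACTB amplified at or below the cutoff.
#' @export
msp_valid <- function(ct_actb, config = call_config()) {
  !is.na(ct_actb) & ct_actb <= config$ct_cutoff_actb
}

#' Per-gene positivity at the fixed Ct cutoff
#'
#' @param ct Target-gene Ct (numeric, `NA` = NO_AMP); vectorised.
#' @param config A [call_config()].
#' @return Factor `negative`/`positive`: positive iff amplified at
#'   Ct <= cutoff; NO_AMP is negative.
#' @export
gene_positive <- function(ct, config = call_config()) {
  factor(ifelse(!is.na(ct) & ct <= config$ct_cutoff_target,
                "positive", "negative"),
         levels = c("negative", "positive"))
}

#' Relative methylation level, 2^-ddCt
#'
#' `ML = 2^-ddCt` with
#' `ddCt = (Ct_target - Ct_ACTB)_sample - (Ct_target - Ct_ACTB)_calibrator`,
#' the calibrator being the fully methylated positive control. A NO_AMP
#' target returns `ml_for_no_amp` (default 0) without computing.
#'
#' @param ct_target,ct_actb Sample Cts (numeric; `ct_target` may be `NA`
#'   for NO_AMP). Vectorised.
#' @param calib_target,calib_actb Calibrator Cts (finite numerics).
#' @param config A [call_config()].
#' @return Nonnegative methylation level; `ML = 1` when the sample's
#'   delta-Ct equals the calibrator's.
#' @export
methylation_level <- function(ct_target, ct_actb, calib_target, calib_actb,
                              config = call_config()) {
  stopifnot(is.finite(calib_target), is.finite(calib_actb))
  if (any(is.na(ct_actb)))
    stop("ACTB Ct is NO_AMP/missing: sample is invalid upstream, ML undefined",
         call. = FALSE)
  ddct <- (ct_target - ct_actb) - (calib_target - calib_actb)
  ifelse(is.na(ct_target), config$ml_for_no_amp, 2^(-ddct))
}

#' Call one sample from its MSP Ct rows
#'
#' Applies validity gating, per-gene fixed-cutoff calls, the OR
#' combination, methylation levels, and the combined ROC scores
#' (min target Ct with NO_AMP as 45; max ML).
#'
#' @param cts Named numeric vector of the sample's Cts (names in
#'   [assay_genes()], `NA` = NO_AMP). Must include ACTB and >= 1 target.
#' @param calibrator Named numeric vector of calibrator Cts.
#' @param config A [call_config()].
#' @return List of class `call_result`: `sample_id` (unset here), `valid`,
#'   and — when valid — `gene_calls`, `combined_call`, `ml`,
#'   `combined_score_ct`, `combined_score_ml`.
#' @export
call_sample <- function(cts, calibrator, config = call_config()) {
  if (!"ACTB" %in% names(cts))
    stop("missing ACTB row for sample", call. = FALSE)
  targets <- intersect(target_genes(), names(cts))
  if (length(targets) == 0)
    stop("no target-gene rows for sample", call. = FALSE)
  valid <- msp_valid(cts[["ACTB"]], config)
  if (!valid)
    return(structure(list(valid = FALSE, gene_calls = NULL,
                          combined_call = NULL, ml = NULL,
                          combined_score_ct = NULL, combined_score_ml = NULL),
                     class = "call_result"))
  gene_calls <- stats::setNames(gene_positive(cts[targets], config), targets)
  combined <- Reduce(joint_positive, gene_calls)
  ml <- stats::setNames(
    methylation_level(cts[targets], cts[["ACTB"]],
                      calibrator[targets], calibrator[["ACTB"]],
                      config = config),
    targets)
  score_ct <- min(ifelse(is.na(cts[targets]),
                         config$no_amp_ct_for_scoring, cts[targets]))
  structure(list(valid = TRUE, gene_calls = gene_calls,
                 combined_call = combined, ml = ml,
                 combined_score_ct = score_ct,
                 combined_score_ml = max(ml)),
            class = "call_result")
}

#' Call every sample in a Ct table
#'
#' @param x A [ct_table()].
#' @param config A [call_config()].
#' @param markers Marker set to combine over (subset of [target_genes()]);
#'   default both.
#' @return `data.frame`, one row per sample: `sample_id`, `valid`,
#'   `ct_<gene>`, `call_<gene>`, `call_combined`, `ml_<gene>`,
#'   `score_ct`, `score_ml`. Invalid samples keep their Cts but have `NA`
#'   calls/scores; downstream denominators use valid samples only.
#' @export
call_cohort <- function(x, config = call_config(), markers = target_genes()) {
  stopifnot(inherits(x, "ct_table"))
  markers <- match.arg(markers, target_genes(), several.ok = TRUE)
  m <- x$measurements
  ids <- unique(m$sample_id)
  wide <- sapply(assay_genes(), function(g) {
    ct <- rep(NA_real_, length(ids))
    rows <- m$gene == g
    ct[match(m$sample_id[rows], ids)] <- m$ct[rows]
    ct
  })
  if (length(ids) == 1) wide <- matrix(wide, nrow = 1,
                                       dimnames = list(NULL, assay_genes()))
  has_actb <- ids %in% m$sample_id[m$gene == "ACTB"]
  if (!all(has_actb))
    stop("missing ACTB row for sample(s): ",
         paste(ids[!has_actb], collapse = ", "), call. = FALSE)
  valid <- msp_valid(wide[, "ACTB"], config)
  out <- data.frame(sample_id = ids, valid = valid,
                    stringsAsFactors = FALSE)
  for (g in assay_genes()) out[[paste0("ct_", g)]] <- wide[, g]
  for (g in markers) {
    cal <- gene_positive(wide[, g], config)
    cal[!valid] <- NA
    out[[paste0("call_", g)]] <- cal
    ml <- rep(NA_real_, length(ids))
    ml[valid] <- methylation_level(wide[valid, g], wide[valid, "ACTB"],
                                   x$calibrator[[g]], x$calibrator[["ACTB"]],
                                   config = config)
    out[[paste0("ml_", g)]] <- ml
  }
  comb <- Reduce(joint_positive, out[paste0("call_", markers)])
  comb[!valid] <- NA
  out$call_combined <- comb
  ct_m <- as.matrix(out[paste0("ct_", markers)])
  ct_m[is.na(ct_m)] <- config$no_amp_ct_for_scoring
  out$score_ct <- ifelse(valid, apply(ct_m, 1, min), NA_real_)
  ml_m <- as.matrix(out[paste0("ml_", markers)])
  out$score_ml <- ifelse(valid, apply(ml_m, 1, max), NA_real_)
  out
}
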