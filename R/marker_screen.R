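# Island-level methylation, threshold calls, and the complement screen.
#
# The discovery logic: rank every CpG island by how often it is
# hypermethylated (island mean beta > 0.2) within the subset of samples
# where the anchor island is hypomethylated (mean beta <= 0.2). The
# top-ranked island is the candidate complement marker: it recovers the
# cases the anchor misses.

#' Island-level methylation from probe betas
#'
#' The methylation level of a CpG island in a sample is the arithmetic
#' mean beta over the island's probes, missing probes excluded.
#'
#' @param matrix A [beta_matrix()].
#' @param probe_ids Non-empty character vector of probes forming the
#'   island; all must be present in `matrix`.
#' @return Named numeric vector, one level in `[0, 1]` per sample. A
#'   sample with every probe missing gets `NA` with a warning.
#' @export
island_beta <- function(matrix, probe_ids) {
  stopifnot(inherits(matrix, "beta_matrix"))
  if (length(probe_ids) == 0) stop("probe_ids must be non-empty", call. = FALSE)
  absent <- setdiff(probe_ids, rownames(matrix))
  if (length(absent) > 0)
    stop("probe(s) not in matrix: ", paste(absent, collapse = ", "),
         call. = FALSE)
  sub <- unclass(matrix)[probe_ids, , drop = FALSE]
  lv <- colMeans(sub, na.rm = TRUE)
  all_missing <- colSums(!is.na(sub)) == 0
  if (any(all_missing)) {
    warning("all probes missing for sample(s): ",
            paste(colnames(sub)[all_missing], collapse = ", "),
            "; island level reported NA", call. = FALSE)
    lv[all_missing] <- NA_real_
  }
  lv
}

#' Threshold methylation call on an island level
#'
#' Positive iff the level is strictly above the threshold; a level equal
#' to the threshold is negative (the boundary convention of the
#' hypomethylated-selection rule, which keeps `beta_call` and
#' [select_hypomethylated()] an exact partition).
#'
#' @param level Numeric vector of island levels in `[0, 1]` (`NA` allowed).
#' @param threshold Beta threshold, default 0.2.
#' @return Factor with levels `negative`, `positive`; `NA` level gives
#'   `NA` call.
#' @export
beta_call <- function(level, threshold = 0.2) {
  if (any(!is.na(level) & (level < 0 | level > 1)))
    stop("level outside [0, 1]", call. = FALSE)
  factor(ifelse(level > threshold, "positive", "negative"),
         levels = c("negative", "positive"))
}

#' Select anchor-hypomethylated samples
#'
#' @param anchor_levels Named numeric vector from [island_beta()].
#' @param threshold Beta threshold, default 0.2; samples with level
#'   `<= threshold` are selected (`NA` levels never are).
#' @return Character vector of sample ids.
#' @export
select_hypomethylated <- function(anchor_levels, threshold = 0.2) {
  names(anchor_levels)[!is.na(anchor_levels) & anchor_levels <= threshold]
}

#' Genome-wide complement screen
#'
#' For every island in the annotation, computes the percentage of
#' anchor-hypomethylated samples in which that island is hypermethylated
#' (level > `threshold`), and ranks islands by that complement rate
#' (descending; ties broken by gene name ascending).
#'
#' @param matrix A [beta_matrix()].
#' @param annotation A [probe_annotation()] covering the matrix probes.
#' @param hypo_samples Non-empty character vector of sample ids (from
#'   [select_hypomethylated()] on the anchor).
#' @param threshold Beta threshold, default 0.2.
#' @return Object of class `screen_result`: a `data.frame` with columns
#'   `gene`, `island_id`, `n_hypo_samples` (samples with a non-missing
#'   level), `n_complement_positive`, `complement_rate` (%), `rank`.
#' @export
complement_screen <- function(matrix, annotation, hypo_samples,
                              threshold = 0.2) {
  stopifnot(inherits(matrix, "beta_matrix"))
  if (length(hypo_samples) == 0)
    stop("hypo_samples must be non-empty", call. = FALSE)
  absent <- setdiff(hypo_samples, colnames(matrix))
  if (length(absent) > 0)
    stop("sample(s) not in matrix: ", paste(absent, collapse = ", "),
         call. = FALSE)
  ann <- annotation[annotation$probe_id %in% rownames(matrix), , drop = FALSE]
  islands <- unique(ann[c("gene", "island_id")])
  res <- lapply(seq_len(nrow(islands)), function(i) {
    probes <- ann$probe_id[ann$island_id == islands$island_id[i]]
    lv <- suppressWarnings(
      island_beta(matrix, probes)[hypo_samples])
    n_obs <- sum(!is.na(lv))
    n_pos <- sum(lv > threshold, na.rm = TRUE)
    data.frame(gene = islands$gene[i], island_id = islands$island_id[i],
               n_hypo_samples = n_obs, n_complement_positive = n_pos,
               complement_rate = if (n_obs > 0) 100 * n_pos / n_obs else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(-out$complement_rate, out$gene), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("screen_result", class(out))
  out
}

#' OR-combination of two methylation calls
#'
#' A sample is positive if either marker (or both) is positive. A missing
#' call is overridden by a positive partner (positivity is established)
#' but leaves a negative partner undecided (the missing marker could have
#' been positive).
#'
#' @param call_a,call_b Factors/characters with values `positive` /
#'   `negative` / `NA`.
#' @return Factor with levels `negative`, `positive`.
#' @export
joint_positive <- function(call_a, call_b) {
  a <- as.character(call_a); b <- as.character(call_b)
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  out <- ifelse(!is.na(a) & a == "positive" | !is.na(b) & b == "positive",
                "positive",
                ifelse(is.na(a) | is.na(b), NA_character_, "negative"))
  factor(out, levels = c("negative", "positive"))
}

#' Subsite-resolved positivity rate table
#'
#' Tabulates positive/negative calls by bowel subsite and appends a Total
#' row, mirroring the layout of clinical detection-rate tables.
#'
#' @param calls Named factor/character of `positive`/`negative` calls
#'   (names = sample ids). `NA` calls are dropped with a warning.
#' @param records Sample records ([sample_records()]) covering the calls.
#' @param by Grouping column of `records`, default `"location"`.
#' @param decimals Decimals for the percentage, half-up rounded; default 1.
#' @return `data.frame` with columns `location` (or `by`), `n_positive`,
#'   `n_negative`, `n_total`, `rate` (%). Locations with no samples are
#'   omitted; the last row is `Total`.
#' @export
subsite_rate_table <- function(calls, records, by = "location", decimals = 1) {
  calls <- stats::setNames(as.character(calls), names(calls))
  if (is.null(names(calls)))
    stop("calls must be named by sample id", call. = FALSE)
  if (any(is.na(calls))) {
    warning(sum(is.na(calls)), " missing call(s) dropped from rate table",
            call. = FALSE)
    calls <- calls[!is.na(calls)]
  }
  idx <- match(names(calls), records$sample_id)
  if (anyNA(idx))
    stop("sample(s) missing from records: ",
         paste(names(calls)[is.na(idx)], collapse = ", "), call. = FALSE)
  grp <- as.character(records[[by]][idx])
  tab <- table(grp, factor(calls, levels = c("negative", "positive")))
  out <- data.frame(group = rownames(tab),
                    n_positive = as.integer(tab[, "positive"]),
                    n_negative = as.integer(tab[, "negative"]),
                    stringsAsFactors = FALSE)
  out <- rbind(out, data.frame(group = "Total",
                               n_positive = sum(out$n_positive),
                               n_negative = sum(out$n_negative)))
  out$n_total <- out$n_positive + out$n_negative
  out$rate <- round_half_up(100 * out$n_positive / out$n_total, decimals)
  names(out)[1] <- by
  rownames(out) <- NULL
  out
}
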