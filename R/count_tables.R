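# Expansion of published-style count tables (positive/negative per
# subsite) into per-sample calls and records, so that rate tables are
# recomputed by the same operation that serves simulated cohorts.

#' Expand a subsite count table into per-sample calls
#'
#' Takes a table with columns `location`, `n_positive`, `n_negative`
#' (optionally filtered to one `sample_type` upstream) and materialises
#' one pseudo-sample per count, returning the named call vector and the
#' matching sample records expected by [subsite_rate_table()],
#' [sensitivity()] and [specificity()].
#'
#' @param counts `data.frame` with `location`, `n_positive`, `n_negative`.
#' @param group Diagnostic group assigned to the pseudo-samples.
#' @param prefix Sample-id prefix.
#' @return List with `calls` (named factor) and `records`.
#' @export
expand_count_table <- function(counts, group = "CRC", prefix = "X") {
  need <- c("location", "n_positive", "n_negative")
  if (!all(need %in% names(counts)))
    stop("counts must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  loc <- rep(rep(counts$location, 2),
             times = c(counts$n_positive, counts$n_negative))
  call <- rep(c("positive", "negative"),
              times = c(sum(counts$n_positive), sum(counts$n_negative)))
  # interleave back per-location so ids group naturally
  ord <- order(match(loc, counts$location))
  loc <- loc[ord]; call <- call[ord]
  ids <- sprintf("%s%04d", prefix, seq_along(loc))
  list(calls = stats::setNames(
         factor(call, levels = c("negative", "positive")), ids),
       records = sample_records(ids, group, loc, cohort = prefix))
}
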