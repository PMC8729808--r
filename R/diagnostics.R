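# Diagnostic performance: sensitivity/specificity, ROC with DeLong CI and
# Youden-optimal cutoff, Fisher exact / rank tests, and the single- vs
# dual-marker comparison report.

#' Sensitivity and specificity of methylation calls
#'
#' `Sensitivity = positives / valid cases x 100%`;
#' `Specificity = negatives / valid controls x 100%`. Samples with a
#' missing call (invalid MSP reactions) are excluded from the
#' denominator.
#'
#' @param calls Named factor/character of `positive`/`negative` calls
#'   (names = sample ids; `NA` = excluded).
#' @param records Sample records ([sample_records()]).
#' @param case_group,control_group Diagnostic group defining the
#'   denominator.
#' @param decimals Half-up rounding of the percentage; `NULL` = unrounded.
#' @return Percentage in `[0, 100]`.
#' @export
sensitivity <- function(calls, records, case_group = "CRC", decimals = NULL) {
  pct_of_group(calls, records, case_group, count = "positive", decimals)
}

#' @rdname sensitivity
#' @export
specificity <- function(calls, records, control_group = "normal",
                        decimals = NULL) {
  pct_of_group(calls, records, control_group, count = "negative", decimals)
}

pct_of_group <- function(calls, records, group, count, decimals) {
  calls <- stats::setNames(as.character(calls), names(calls))
  idx <- match(names(calls), records$sample_id)
  if (anyNA(idx))
    stop("sample(s) missing from records: ",
         paste(names(calls)[is.na(idx)], collapse = ", "), call. = FALSE)
  in_group <- records$group[idx] == group & !is.na(calls)
  n <- sum(in_group)
  if (n == 0)
    stop("no valid samples in group '", group, "'", call. = FALSE)
  pct <- 100 * sum(calls[in_group] == count) / n
  if (!is.null(decimals)) pct <- round_half_up(pct, decimals)
  pct
}

#' ROC analysis with DeLong CI and Youden-optimal cutoff
#'
#' AUC by rank concordance (ties count 1/2), 95% CI by DeLong's method
#' (or a seeded bootstrap), and the optimal cutoff maximising Youden's
#' `J = sensitivity + specificity - 1` over all observed score values.
#' At ties in J the cutoff with higher sensitivity wins, then the more
#' permissive threshold (higher Ct / lower ML).
#'
#' Orientation expresses which direction is case-like: Ct scores use
#' `"lower"` (more methylated template crosses threshold earlier),
#' methylation-level scores use `"higher"`. A sample scores positive at
#' cutoff `t` when `score <= t` (`"lower"`) or `score >= t` (`"higher"`).
#'
#' @param scores Numeric scores (`NA` dropped with its label).
#' @param is_case Logical, same length: `TRUE` for cases.
#' @param orientation `"lower"` or `"higher"`: the case-like direction.
#' @param ci_method `"delong"` (default) or `"bootstrap"` (2000
#'   resamples).
#' @param conf_level CI level, default 0.95.
#' @param seed Seed for the bootstrap CI.
#' @return Object of class `roc_result`: `auc`, `ci_low`, `ci_high`,
#'   `optimal_cutoff`, `sensitivity_at_cutoff` and
#'   `specificity_at_cutoff` (percent), `orientation`, `n_case`,
#'   `n_control`, and `curve` (a data.frame of threshold/sens/spec).
#' @export
roc_analysis <- function(scores, is_case,
                         orientation = c("lower", "higher"),
                         ci_method = c("delong", "bootstrap"),
                         conf_level = 0.95, seed = 1L) {
  orientation <- match.arg(orientation)
  ci_method <- match.arg(ci_method)
  keep <- !is.na(scores) & !is.na(is_case)
  scores <- scores[keep]; is_case <- as.logical(is_case)[keep]
  if (!any(is_case) || all(is_case))
    stop("need at least one case and one control", call. = FALSE)
  direction <- if (orientation == "lower") ">" else "<"
  r <- pROC::roc(response = is_case, predictor = scores,
                 levels = c(FALSE, TRUE), direction = direction,
                 quiet = TRUE)
  quiet_ci <- function(expr) withCallingHandlers(expr,
    warning = function(w) {
      # degenerate interval on perfect separation is expected, not a fault
      if (grepl("AUC == 1", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  ci <- if (ci_method == "delong") {
    quiet_ci(pROC::ci.auc(r, conf.level = conf_level, method = "delong"))
  } else {
    withr::with_seed(seed,
      pROC::ci.auc(r, conf.level = conf_level, method = "bootstrap",
                   boot.n = 2000))
  }
  # Youden scan over the observed score values.
  thr <- sort(unique(scores))
  pos_at <- function(t) if (orientation == "lower") scores <= t else scores >= t
  sens <- vapply(thr, function(t) mean(pos_at(t)[is_case]), numeric(1))
  spec <- vapply(thr, function(t) mean(!pos_at(t)[!is_case]), numeric(1))
  j <- sens + spec - 1
  best <- which(j > max(j) - 1e-12)
  best <- best[sens[best] > max(sens[best]) - 1e-12]
  # more permissive: larger threshold under "lower", smaller under "higher"
  cut_i <- if (orientation == "lower") max(best) else min(best)
  structure(list(auc = as.numeric(pROC::auc(r)),
                 ci_low = ci[1], ci_high = ci[3],
                 optimal_cutoff = thr[cut_i],
                 sensitivity_at_cutoff = 100 * sens[cut_i],
                 specificity_at_cutoff = 100 * spec[cut_i],
                 orientation = orientation,
                 n_case = sum(is_case), n_control = sum(!is_case),
                 curve = data.frame(threshold = thr, sensitivity = sens,
                                    specificity = spec)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC (%s score is case-like): AUC %.3f (95%% CI %.3f-%.3f)\n",
              x$orientation, x$auc, x$ci_low, x$ci_high))
  cat(sprintf("Youden cutoff %.4g: sensitivity %.1f%%, specificity %.1f%% (%d cases, %d controls)\n",
              x$optimal_cutoff, x$sensitivity_at_cutoff,
              x$specificity_at_cutoff, x$n_case, x$n_control))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  ord <- order(1 - x$curve$specificity, x$curve$sensitivity)
  plot(c(0, 1 - x$curve$specificity[ord], 1),
       c(0, x$curve$sensitivity[ord], 1), type = "l",
       xlab = "1 - specificity", ylab = "sensitivity",
       main = sprintf("AUC = %.3f", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided conditional test: with all margins fixed, the first cell is
#' hypergeometric; the p-value sums the probabilities of every table as
#' or less probable than the observed one. A table with a zero margin
#' carries no information and returns p = 1 with a warning.
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return Two-sided p-value.
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  stopifnot(identical(dim(table), c(2L, 2L)))
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be nonnegative integers", call. = FALSE)
  r1 <- sum(table[1, ]); r2 <- sum(table[2, ])
  c1 <- sum(table[, 1])
  if (r1 == 0 || r2 == 0 || c1 == 0 || sum(table[, 2]) == 0) {
    warning("zero margin: Fisher exact p set to 1", call. = FALSE)
    return(1)
  }
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(table[1, 1], r1, r2, c1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Mann-Whitney U test (two-sided)
#'
#' `U` counts pairs where an `x` value exceeds a `y` value (ties count
#' 1/2). The p-value is exact for small samples (no-tie closed form, or
#' full enumeration of group assignments when feasible) and otherwise a
#' normal approximation with tie correction; samples larger than 25 per
#' the combined size always use the approximation.
#'
#' @param x,y Numeric vectors.
#' @return List with `u` (statistic for `x`) and `p`.
#' @export
mann_whitney_u <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  rk <- rank(pooled)
  u <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(pooled))
  n <- n1 + n2
  if (n <= 25 && !ties) {
    p <- min(1, 2 * min(stats::pwilcox(u, n1, n2),
                        1 - stats::pwilcox(u - 1, n1, n2)))
  } else if (n <= 25 && choose(n, n1) <= 2e5) {
    combs <- utils::combn(n, n1)
    us <- colSums(matrix(rk[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- min(1, 2 * min(mean(us <= u + 1e-9), mean(us >= u - 1e-9)))
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(pooled)
    sigma2 <- n1 * n2 / 12 *
      (n + 1 - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(u = u, p = p)
}

#' Wilcoxon signed-rank test (two-sided, paired)
#'
#' Differences of zero are dropped (error if all are zero). `w` is the
#' sum of ranks of positive differences. Exact p by sign-flip
#' enumeration (a convolution over doubled ranks, valid under ties) for
#' up to 25 nonzero differences, else a normal approximation with tie
#' correction.
#'
#' @param x,y Paired numeric vectors of equal length.
#' @return List with `w` and `p`.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[d != 0]
  if (length(d) == 0)
    stop("all paired differences are zero", call. = FALSE)
  n <- length(d)
  rk <- rank(abs(d))
  w <- sum(rk[d > 0])
  if (n <= 25) {
    # Distribution of W under independent sign flips: convolve the
    # polynomial prod_i (1 + z^(2 r_i)) / 2^n over doubled (integer) ranks.
    r2 <- as.integer(round(2 * rk))
    pmf <- 1
    for (r in r2) {
      shifted <- c(rep(0, r), pmf)
      pmf <- c(pmf, rep(0, r)) + shifted
    }
    pmf <- pmf / 2^n
    w2 <- as.integer(round(2 * w))
    p <- min(1, 2 * min(sum(pmf[seq_len(w2 + 1)]),
                        sum(pmf[(w2 + 1):length(pmf)])))
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(rk)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(w = w, p = p)
}

#' Exact McNemar test for paired detection calls
#'
#' Binomial (exact) McNemar on the discordant pairs; used to compare
#' dual- vs single-marker detection on the same samples, where the OR
#' rule makes one discordant cell structurally zero.
#'
#' @param b,c Discordant counts (first-positive-only, second-positive-only).
#' @return Two-sided p-value (1 when there are no discordant pairs).
#' @export
mcnemar_exact <- function(b, c) {
  n <- b + c
  if (n == 0) return(1)
  min(1, 2 * stats::pbinom(min(b, c), n, 0.5))
}

#' Single- vs dual-marker performance report
#'
#' Evaluates each marker set (anchor alone, complement alone, OR-combined
#' dual) on a Ct cohort: fixed-cutoff sensitivity/specificity and ROC for
#' both indicators (Ct score = min target Ct with NO_AMP at 45, lower is
#' case-like; ML score = max 2^-ddCt, higher is case-like), for each
#' comparison group; plus per-location single vs dual sensitivity with
#' Fisher-exact and exact McNemar p-values.
#'
#' @param x A [ct_table()].
#' @param records Sample records covering the cohort.
#' @param config A [call_config()].
#' @param anchor The single-detection marker for the per-location
#'   comparison (default `"SDC2"`).
#' @param comparisons List of `c(case, control)` group pairs.
#' @param decimals Rounding for reported percentages.
#' @return Object of class `performance_report`: `summary` (one row per
#'   marker set x indicator x comparison) and `by_location` (one row per
#'   case group x location, with `sens_single`, `sens_dual`, `p_fisher`,
#'   `p_mcnemar`).
#' @export
marker_comparison_report <- function(x, records, config = call_config(),
                                     anchor = "SDC2",
                                     comparisons = list(
                                       c("CRC", "normal"),
                                       c("adenoma", "normal"),
                                       c("CRC", "adenoma")),
                                     decimals = 2) {
  marker_sets <- list(SDC2 = "SDC2", TFPI2 = "TFPI2",
                      `SDC2/TFPI2` = c("SDC2", "TFPI2"))
  calls <- lapply(marker_sets, function(m) call_cohort(x, config, markers = m))
  groups_present <- function(g) any(records$group == g)
  comparisons <- Filter(function(cp) groups_present(cp[1]) && groups_present(cp[2]),
                        comparisons)
  summary_rows <- list()
  for (cp in comparisons) {
    for (ms in names(marker_sets)) {
      cc <- calls[[ms]]
      named <- stats::setNames(as.character(cc$call_combined), cc$sample_id)
      grp <- records$group[match(cc$sample_id, records$sample_id)]
      in_cmp <- grp %in% cp & cc$valid
      for (ind in c("Ct", "ML")) {
        sc <- if (ind == "Ct") cc$score_ct else cc$score_ml
        rr <- roc_analysis(sc[in_cmp], grp[in_cmp] == cp[1],
                           orientation = if (ind == "Ct") "lower" else "higher")
        summary_rows[[length(summary_rows) + 1]] <- data.frame(
          group = paste(cp[1], "vs", cp[2]), indicator = ind, markers = ms,
          auc = rr$auc, ci_low = rr$ci_low, ci_high = rr$ci_high,
          cutoff = rr$optimal_cutoff,
          sens = round_half_up(rr$sensitivity_at_cutoff, decimals),
          spec = round_half_up(rr$specificity_at_cutoff, decimals),
          sens_fixed = if (ind == "Ct")
            sensitivity(named, records, cp[1], decimals) else NA_real_,
          spec_fixed = if (ind == "Ct")
            pct_of_group(named, records, cp[2], "negative", decimals) else
              NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  # Per-location single vs dual sensitivity (fixed Ct cutoffs).
  single <- calls[[anchor]]; dual <- calls[["SDC2/TFPI2"]]
  loc_rows <- list()
  for (case_group in unique(vapply(comparisons, `[`, "", 1))) {
    idx <- match(single$sample_id, records$sample_id)
    in_case <- records$group[idx] == case_group & single$valid
    loc <- as.character(records$location[idx])
    s_pos <- single$call_combined == "positive"
    d_pos <- dual$call_combined == "positive"
    for (l in c(sort(unique(loc[in_case])), "Total")) {
      sel <- in_case & (l == "Total" | loc == l)
      n <- sum(sel)
      if (n == 0) next
      ns <- sum(s_pos[sel]); nd <- sum(d_pos[sel])
      tab <- matrix(c(nd, n - nd, ns, n - ns), nrow = 2, byrow = TRUE)
      loc_rows[[length(loc_rows) + 1]] <- data.frame(
        case_group = case_group, location = l, n = n,
        sens_single = round_half_up(100 * ns / n, decimals),
        sens_dual = round_half_up(100 * nd / n, decimals),
        p_fisher = suppressWarnings(fisher_exact(tab)),
        p_mcnemar = mcnemar_exact(0L, sum(d_pos[sel] & !s_pos[sel])),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(summary = do.call(rbind, summary_rows),
                 by_location = do.call(rbind, loc_rows)),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat("Diagnostic performance summary:\n")
  print(x$summary, row.names = FALSE, digits = 3)
  cat("\nPer-location single vs dual sensitivity:\n")
  print(x$by_location, row.names = FALSE, digits = 3)
  invisible(x)
}
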