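# Pipeline entry points tying the stages together: simulate -> screen ->
# call -> evaluate. Each function is a thin, deterministic composition of
# the module operations, reading and writing plain CSV so runs are
# reproducible and inspectable. inst/cli/dualmeth.R wraps these for the
# shell.

#' Pipeline configuration
#'
#' All thresholds surfaced in one place; defaults are the assay's
#' published operating points (beta 0.2, target Ct 38, ACTB Ct 36).
#'
#' @param beta_threshold Island-level beta threshold.
#' @param ct_cutoff_target,ct_cutoff_actb MSP cutoffs.
#' @param anchor Anchor gene for the screen and single-detection rows.
#' @param decimals Reported-percentage decimals.
#' @param seed Integer seed for any simulation step.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(beta_threshold = 0.2, ct_cutoff_target = 38,
                            ct_cutoff_actb = 36, anchor = "SDC2",
                            decimals = 2, seed = 1L) {
  stopifnot(beta_threshold > 0, beta_threshold < 1)
  structure(list(beta_threshold = beta_threshold,
                 ct_cutoff_target = ct_cutoff_target,
                 ct_cutoff_actb = ct_cutoff_actb,
                 anchor = anchor, decimals = decimals,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file whose top-level keys override the defaults.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals[intersect(names(vals),
                                          names(formals(pipeline_config)))])
}

#' Simulate study-shaped cohorts to disk
#'
#' Writes a beta cohort (matrix, probe annotation, metadata, truth) and a
#' stool MSP cohort (Ct table, metadata, truth) under `out_dir` using
#' [default_cohort_configs()]. Byte-identical outputs for identical
#' seeds.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param configs Optional list with `beta` / `ct` configs overriding the
#'   defaults.
#' @return Named character vector of the files written, invisibly.
#' @export
pipeline_simulate <- function(out_dir, seed = 1L, configs = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- configs %||% default_cohort_configs(seed)
  cfg$beta$seed <- as.integer(seed)
  cfg$ct$seed <- as.integer(seed)
  b <- simulate_beta_cohort(cfg$beta)
  s <- simulate_ct_cohort(cfg$ct)
  paths <- c(beta = file.path(out_dir, "beta_matrix.csv"),
             annotation = file.path(out_dir, "probe_annotation.csv"),
             beta_meta = file.path(out_dir, "beta_metadata.csv"),
             beta_truth = file.path(out_dir, "beta_truth.csv"),
             ct = file.path(out_dir, "ct_table.csv"),
             ct_meta = file.path(out_dir, "ct_metadata.csv"),
             ct_truth = file.path(out_dir, "ct_truth.csv"))
  write_beta_matrix(b$beta, paths[["beta"]])
  utils::write.csv(b$annotation, paths[["annotation"]], row.names = FALSE)
  utils::write.csv(b$samples, paths[["beta_meta"]], row.names = FALSE)
  utils::write.csv(data.frame(sample_id = rownames(b$truth), b$truth),
                   paths[["beta_truth"]], row.names = FALSE)
  write_ct_table(s$ct, paths[["ct"]])
  utils::write.csv(s$samples, paths[["ct_meta"]], row.names = FALSE)
  utils::write.csv(data.frame(sample_id = rownames(s$truth), s$truth),
                   paths[["ct_truth"]], row.names = FALSE)
  message("simulated cohorts with seed ", seed, " -> ", out_dir)
  invisible(paths)
}

#' Run the complement screen on a beta cohort
#'
#' Computes the anchor island level per sample, selects the
#' anchor-hypomethylated subset, ranks every other island by its
#' hypermethylation rate in that subset, and tabulates the top
#' complement's calls by subsite.
#'
#' @param beta_path,annotation_path,metadata_path Input CSVs (layouts of
#'   [read_beta_matrix()], [read_probe_annotation()],
#'   [read_sample_metadata()]).
#' @param out_dir Output directory for `screen_ranking.csv` and
#'   `screen_subsites.csv`.
#' @param config A [pipeline_config()].
#' @return List with `ranking` (the `screen_result`), `hypo_samples`,
#'   and `subsites` (rate table of the top complement), invisibly.
#' @export
pipeline_screen <- function(beta_path, annotation_path, metadata_path,
                            out_dir, config = pipeline_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  mat <- read_beta_matrix(beta_path)
  ann <- read_probe_annotation(annotation_path)
  records <- read_sample_metadata(metadata_path)
  anchor_probes <- ann$probe_id[ann$gene == config$anchor]
  if (length(anchor_probes) == 0)
    stop("anchor gene '", config$anchor, "' not in annotation", call. = FALSE)
  levels_anchor <- island_beta(mat, anchor_probes)
  # the screen runs within the case group: hypomethylated *carcinomas*
  cases <- records$sample_id[records$group == "CRC"]
  hypo <- intersect(select_hypomethylated(levels_anchor,
                                          config$beta_threshold), cases)
  message(length(hypo), " of ", length(intersect(cases, colnames(mat))),
          " case samples anchor-hypomethylated",
          " (beta <= ", config$beta_threshold, ")")
  ranking <- complement_screen(mat, ann[ann$gene != config$anchor, ],
                               hypo, config$beta_threshold)
  top <- ranking$gene[1]
  top_levels <- island_beta(mat, ann$probe_id[ann$gene == top])[hypo]
  subs <- subsite_rate_table(beta_call(top_levels, config$beta_threshold),
                             records, decimals = config$decimals)
  utils::write.csv(ranking, file.path(out_dir, "screen_ranking.csv"),
                   row.names = FALSE)
  utils::write.csv(subs, file.path(out_dir, "screen_subsites.csv"),
                   row.names = FALSE)
  invisible(list(ranking = ranking, hypo_samples = hypo, subsites = subs))
}

#' Call an MSP cohort
#'
#' @param ct_path Ct table CSV ([read_ct_table()] layout).
#' @param out_dir Output directory for `calls.csv`.
#' @param config A [pipeline_config()].
#' @return The call `data.frame` ([call_cohort()]), invisibly.
#' @export
pipeline_call <- function(ct_path, out_dir, config = pipeline_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tab <- read_ct_table(ct_path)
  cc <- call_config(config$ct_cutoff_target, config$ct_cutoff_actb)
  calls <- call_cohort(tab, cc)
  message(nrow(calls), " samples enrolled, ", sum(calls$valid), " valid, ",
          sum(!calls$valid), " excluded (ACTB > ", config$ct_cutoff_actb, ")")
  utils::write.csv(calls, file.path(out_dir, "calls.csv"), row.names = FALSE)
  invisible(calls)
}

#' Evaluate marker performance on an MSP cohort
#'
#' @param ct_path,metadata_path Input CSVs.
#' @param out_dir Output directory for `performance_summary.csv` and
#'   `performance_by_location.csv`.
#' @param config A [pipeline_config()].
#' @return The `performance_report`, invisibly.
#' @export
pipeline_evaluate <- function(ct_path, metadata_path, out_dir,
                              config = pipeline_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tab <- read_ct_table(ct_path)
  records <- read_sample_metadata(metadata_path)
  cc <- call_config(config$ct_cutoff_target, config$ct_cutoff_actb)
  rep <- marker_comparison_report(tab, records, cc, anchor = config$anchor,
                                  decimals = config$decimals)
  utils::write.csv(rep$summary, file.path(out_dir, "performance_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(rep$by_location,
                   file.path(out_dir, "performance_by_location.csv"),
                   row.names = FALSE)
  invisible(rep)
}
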