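# Synthetic beta-matrix and MSP Ct cohorts with the statistical structure
# the analysis assumes: bimodal beta emission around a methylation state,
# subsite-dependent methylation fractions, an explicit anchor-complement
# dependence (the complement is drawn conditionally among anchor-negative
# cases), and group-ordered ACTB template load in stool.

# The 12 probes of the anchor CpG island on the 450k array.
SDC2_PROBES <- c("cg13096260", "cg18719750", "cg24732574", "cg08979737",
                 "cg25070637", "cg14538332", "cg16935295", "cg04261408",
                 "cg14625631", "cg10292139", "cg16673702", "cg07146119")

#' Per-gene simulation parameters
#'
#' @param meth_frac Named numeric vector: probability that a sample of
#'   each diagnostic group is methylated at this gene.
#' @param meth_frac_by_location Optional list, per group, of named
#'   per-location probabilities (with a `default` entry) overriding
#'   `meth_frac`.
#' @param meth_mean,meth_sd,unmeth_mean,unmeth_sd Beta emission
#'   parameters of the methylated / unmethylated peaks (truncated normal
#'   on `[0, 1]`).
#' @param delta_ct_mean,delta_ct_sd Target-minus-ACTB Ct offset for
#'   methylated samples (MSP simulation only).
#' @return List of class `gene_spec`.
#' @export
gene_spec <- function(meth_frac, meth_frac_by_location = NULL,
                      meth_mean = 0.5, meth_sd = 0.15,
                      unmeth_mean = 0.1, unmeth_sd = 0.05,
                      delta_ct_mean = 6, delta_ct_sd = 2) {
  stopifnot(all(meth_frac >= 0 & meth_frac <= 1),
            !is.null(names(meth_frac)),
            all(names(meth_frac) %in% diagnostic_groups()))
  structure(list(meth_frac = meth_frac,
                 meth_frac_by_location = meth_frac_by_location,
                 meth_mean = meth_mean, meth_sd = meth_sd,
                 unmeth_mean = unmeth_mean, unmeth_sd = unmeth_sd,
                 delta_ct_mean = delta_ct_mean, delta_ct_sd = delta_ct_sd),
            class = "gene_spec")
}

meth_prob <- function(spec, group, location) {
  byloc <- spec$meth_frac_by_location[[group]]
  if (!is.null(byloc)) {
    p <- byloc[location]
    p[is.na(p)] <- byloc[["default"]]
    unname(p)
  } else {
    p <- spec$meth_frac[group]
    p[is.na(p)] <- 0
    rep_len(unname(p), length(location))
  }
}

#' Configuration for a synthetic beta-matrix cohort
#'
#' Each sample draws a bowel location, then per gene a latent methylation
#' state (Bernoulli with the group/location probability; the complement
#' gene conditionally on the anchor state for the configured groups),
#' then per probe a beta from the state's truncated-normal emission.
#'
#' @param n_case,n_control,n_adenoma Group sizes.
#' @param genes Named list of [gene_spec()]s.
#' @param probes_per_island Probes simulated per island (default 12, the
#'   anchor island's probe count).
#' @param location_distribution Named probabilities over
#'   [sample_locations()], summing to 1.
#' @param dependence `NULL`, or a list with `anchor`, `complement`,
#'   `groups` (groups in which the dependence acts) and
#'   `p_given_anchor_neg` (named by group or a scalar): the probability
#'   the complement is methylated given the anchor is not.
#' @param seed Integer seed; generation is deterministic given the config.
#' @return List of class `beta_sim_config`.
#' @export
beta_sim_config <- function(n_case, n_control, n_adenoma = 0,
                            genes = default_beta_genes(),
                            probes_per_island = 12,
                            location_distribution = tissue_location_weights(),
                            dependence = list(
                              anchor = "SDC2", complement = "TFPI2",
                              groups = "CRC", p_given_anchor_neg = 0.88),
                            seed = 1L) {
  cfg <- structure(list(n_case = n_case, n_control = n_control,
                        n_adenoma = n_adenoma, genes = genes,
                        probes_per_island = probes_per_island,
                        location_distribution = location_distribution,
                        dependence = dependence, seed = as.integer(seed)),
                   class = "beta_sim_config")
  validate_sim_config(cfg)
  cfg
}

#' @rdname beta_sim_config
#' @export
default_beta_genes <- function() {
  list(
    SDC2 = gene_spec(meth_frac = c(CRC = 1 - 50 / 391, adenoma = 0.85,
                                   normal = 0),
                     meth_mean = 0.492, meth_sd = 0.178,
                     unmeth_mean = 0.067, unmeth_sd = 0.018),
    TFPI2 = gene_spec(meth_frac = c(CRC = 0.85, adenoma = 0.75, normal = 0),
                      meth_mean = 0.558, meth_sd = 0.149,
                      unmeth_mean = 0.161, unmeth_sd = 0.078))
}

#' @rdname beta_sim_config
#' @export
tissue_location_weights <- function() {
  # Subsite composition of the anchor-hypomethylated discovery subset,
  # reused as cohort weights (the study reports no cohort-wide table).
  w <- c(splenic_flexure = 2, sigmoid_colon = 15, rectosigmoid_junction = 11,
         descending_colon = 3, rectum_NOS = 5, colon_NOS = 5,
         ascending_colon = 5, hepatic_flexure = 1, transverse_colon = 1,
         other = 1, unknown = 1)
  w / sum(w)
}

#' Configuration for a synthetic MSP Ct cohort
#'
#' Per sample: a true ACTB Ct from the group's template-load
#' distribution (stool cell load orders CRC < adenoma < normal in Ct);
#' methylated target genes amplify at `ACTB + delta-Ct` (NO_AMP beyond
#' 45 cycles); unmethylated targets are NO_AMP with probability
#' `p_no_amp_unmeth`, else amplify above the positivity cutoff. The
#' reported ACTB Ct carries an extra measurement-noise term
#' (`actb_noise_sd`), which the 2^-ddCt indicator inherits but the raw
#' target Ct does not.
#'
#' @param n_case,n_adenoma,n_control Group sizes.
#' @param genes Named list of [gene_spec()]s (delta-Ct fields used).
#' @param actb Named list per group: `c(mean, sd)` of the true ACTB Ct;
#'   means must order CRC < adenoma < normal.
#' @param actb_noise_sd Measurement noise added to the reported ACTB Ct.
#' @param p_no_amp_unmeth NO_AMP probability for an unmethylated target;
#'   the complement amplifies in `(positivity cutoff, 45]`.
#' @param calibrator_actb,calibrator_delta_ct Positive-control Cts:
#'   ACTB Ct and target-minus-ACTB offset.
#' @param location_distribution,dependence,seed As [beta_sim_config()].
#' @return List of class `ct_sim_config`.
#' @export
ct_sim_config <- function(n_case, n_adenoma, n_control,
                          genes = default_ct_genes(),
                          actb = list(CRC = c(mean = 26, sd = 1.5),
                                      adenoma = c(mean = 28, sd = 1.5),
                                      normal = c(mean = 30, sd = 1.5)),
                          actb_noise_sd = 1,
                          p_no_amp_unmeth = 0.97,
                          calibrator_actb = 28, calibrator_delta_ct = 2,
                          location_distribution = stool_location_weights(),
                          dependence = list(
                            anchor = "SDC2", complement = "TFPI2",
                            groups = c("CRC", "adenoma"),
                            p_given_anchor_neg = c(CRC = 0.553,
                                                   adenoma = 0.253)),
                          seed = 1L) {
  means <- vapply(actb, `[[`, numeric(1), "mean")
  if (!(means[["CRC"]] < means[["adenoma"]] &&
        means[["adenoma"]] < means[["normal"]]))
    stop("ACTB Ct means must order CRC < adenoma < normal", call. = FALSE)
  cfg <- structure(list(n_case = n_case, n_control = n_control,
                        n_adenoma = n_adenoma, genes = genes, actb = actb,
                        actb_noise_sd = actb_noise_sd,
                        p_no_amp_unmeth = p_no_amp_unmeth,
                        calibrator_actb = calibrator_actb,
                        calibrator_delta_ct = calibrator_delta_ct,
                        location_distribution = location_distribution,
                        dependence = dependence, seed = as.integer(seed)),
                   class = "ct_sim_config")
  validate_sim_config(cfg)
  cfg
}

#' @rdname ct_sim_config
#' @export
default_ct_genes <- function() {
  list(
    SDC2 = gene_spec(
      meth_frac = c(CRC = 0.869, adenoma = 0.563, normal = 0.007),
      meth_frac_by_location = list(
        CRC = c(left_colon = 0.837, sigmoid_colon = 0.849, rectum = 0.867,
                default = 0.930),
        adenoma = c(left_colon = 0.485, sigmoid_colon = 0.549,
                    rectum = 0.567, default = 0.629)),
      delta_ct_mean = 6, delta_ct_sd = 2),
    TFPI2 = gene_spec(
      meth_frac = c(CRC = 0.85, adenoma = 0.70, normal = 0.029),
      delta_ct_mean = 6, delta_ct_sd = 2))
}

#' @rdname ct_sim_config
#' @export
stool_location_weights <- function() {
  # Subsite sizes of the stool carcinoma cohort; the residual mass is
  # assigned to the right colon.
  c(left_colon = 49 / 289, sigmoid_colon = 86 / 289, rectum = 98 / 289,
    right_colon = 56 / 289)
}

validate_sim_config <- function(cfg) {
  if (cfg$n_case + cfg$n_control + cfg$n_adenoma <= 0)
    stop("degenerate config: zero samples", call. = FALSE)
  if (cfg$n_case < 0 || cfg$n_control < 0 || cfg$n_adenoma < 0)
    stop("negative group size", call. = FALSE)
  ld <- cfg$location_distribution
  if (is.null(names(ld)) || !all(names(ld) %in% sample_locations()))
    stop("location_distribution must be named by sample_locations()",
         call. = FALSE)
  if (abs(sum(ld) - 1) > 1e-9)
    stop("location_distribution must sum to 1", call. = FALSE)
  if (!all(vapply(cfg$genes, inherits, logical(1), "gene_spec")))
    stop("genes must be gene_spec objects", call. = FALSE)
  dep <- cfg$dependence
  if (!is.null(dep)) {
    stopifnot(dep$anchor %in% names(cfg$genes),
              dep$complement %in% names(cfg$genes),
              all(dep$p_given_anchor_neg >= 0 & dep$p_given_anchor_neg <= 1))
  }
  invisible(cfg)
}

# Truncated-normal draw on [lo, hi] by rejection (peaks sit well inside
# the support, so acceptance is high).
rtrunc <- function(n, mean, sd, lo = 0, hi = 1) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  while (length(bad) > 0) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lo | out[bad] > hi]
  }
  out
}

# Mean of a normal truncated to [lo, hi] (closed form); exposed for the
# Monte-Carlo checks in the test-suite oracles.
#' @rdname gene_spec
#' @param mean,sd,lo,hi Parameters of the truncated normal.
#' @export
truncnorm_mean <- function(mean, sd, lo = 0, hi = 1) {
  a <- (lo - mean) / sd; b <- (hi - mean) / sd
  mean + sd * (stats::dnorm(a) - stats::dnorm(b)) /
    (stats::pnorm(b) - stats::pnorm(a))
}

draw_samples <- function(cfg, prefix) {
  n <- c(CRC = cfg$n_case, adenoma = cfg$n_adenoma, normal = cfg$n_control)
  group <- rep(names(n), times = n)
  ids <- sprintf("%s%04d", prefix, seq_along(group))
  loc <- sample(names(cfg$location_distribution), length(group),
                replace = TRUE, prob = cfg$location_distribution)
  records <- sample_records(ids, group, loc, cohort = prefix)
  # latent methylation states, anchor drawn before the dependent complement
  dep <- cfg$dependence
  gene_names <- names(cfg$genes)
  if (!is.null(dep))
    gene_names <- c(dep$anchor, setdiff(gene_names, dep$anchor))
  truth <- matrix(FALSE, nrow = length(ids), ncol = length(cfg$genes),
                  dimnames = list(ids, names(cfg$genes)))
  for (g in gene_names) {
    p <- numeric(length(loc))
    for (grp in unique(group)) {
      sel <- group == grp
      p[sel] <- meth_prob(cfg$genes[[g]], grp, loc[sel])
    }
    if (!is.null(dep) && g == dep$complement) {
      pg <- dep$p_given_anchor_neg
      for (grp in intersect(dep$groups, unique(group))) {
        cond <- if (is.null(names(pg))) pg else unname(pg[grp])
        sel <- group == grp & !truth[, dep$anchor]
        p[sel] <- cond
      }
    }
    truth[, g] <- stats::runif(length(ids)) < p
  }
  list(records = records, truth = truth, group = group, loc = loc, ids = ids)
}

#' Simulate a beta-matrix cohort
#'
#' @param config A [beta_sim_config()].
#' @return List with `beta` (a [beta_matrix()]), `annotation`
#'   (a [probe_annotation()]; the anchor island carries the canonical 12
#'   450k probe ids), `samples` ([sample_records()]), and `truth`
#'   (logical matrix samples x genes of latent methylation states).
#' @export
simulate_beta_cohort <- function(config) {
  validate_sim_config(config)
  withr::with_seed(config$seed, {
    s <- draw_samples(config, "B")
    ann <- do.call(rbind, lapply(names(config$genes), function(g) {
      probes <- if (g == "SDC2" && config$probes_per_island == 12)
        SDC2_PROBES else sprintf("%s_p%02d", g, seq_len(config$probes_per_island))
      probe_annotation(probes, g, paste0(g, "_island"))
    }))
    vals <- matrix(NA_real_, nrow = nrow(ann), ncol = length(s$ids),
                   dimnames = list(ann$probe_id, s$ids))
    for (g in names(config$genes)) {
      spec <- config$genes[[g]]
      rows <- ann$gene == g
      for (state in c(TRUE, FALSE)) {
        cols <- s$truth[, g] == state
        if (!any(cols)) next
        m <- if (state) spec$meth_mean else spec$unmeth_mean
        sd <- if (state) spec$meth_sd else spec$unmeth_sd
        vals[rows, cols] <- rtrunc(sum(rows) * sum(cols), m, sd)
      }
    }
    list(beta = beta_matrix(vals), annotation = ann,
         samples = s$records, truth = s$truth)
  })
}

#' Simulate an MSP Ct cohort
#'
#' @param config A [ct_sim_config()].
#' @return List with `ct` (a [ct_table()] including the calibrator),
#'   `samples`, and `truth` (logical matrix samples x target genes).
#' @export
simulate_ct_cohort <- function(config) {
  validate_sim_config(config)
  withr::with_seed(config$seed, {
    s <- draw_samples(config, "S")
    n <- length(s$ids)
    actb_true <- numeric(n)
    for (grp in unique(s$group)) {
      sel <- s$group == grp
      a <- config$actb[[grp]]
      actb_true[sel] <- rtrunc(sum(sel), a[["mean"]], a[["sd"]],
                               lo = 0, hi = max_cycles())
    }
    actb_reported <- actb_true + stats::rnorm(n, 0, config$actb_noise_sd)
    actb_reported <- pmin(pmax(actb_reported, 0.01), max_cycles())
    rows <- list(data.frame(sample_id = s$ids, gene = "ACTB",
                            ct = actb_reported, stringsAsFactors = FALSE))
    cutoff <- call_config()$ct_cutoff_target
    for (g in intersect(names(config$genes), target_genes())) {
      meth <- s$truth[, g]
      spec <- config$genes[[g]]
      ct <- rep(NA_real_, n)
      if (any(meth)) {
        tc <- actb_true[meth] +
          stats::rnorm(sum(meth), spec$delta_ct_mean, spec$delta_ct_sd)
        tc[tc <= 0] <- 0.01
        tc[tc > max_cycles()] <- NA  # past run length: NO_AMP
        ct[meth] <- tc
      }
      if (any(!meth)) {
        amp <- stats::runif(sum(!meth)) >= config$p_no_amp_unmeth
        bg <- rep(NA_real_, sum(!meth))
        bg[amp] <- stats::runif(sum(amp), cutoff, max_cycles())
        ct[!meth] <- bg
      }
      rows[[length(rows) + 1]] <- data.frame(sample_id = s$ids, gene = g,
                                             ct = ct, stringsAsFactors = FALSE)
    }
    calibrator <- stats::setNames(
      c(rep(config$calibrator_actb + config$calibrator_delta_ct,
            length(target_genes())), config$calibrator_actb),
      assay_genes())
    tab <- ct_table(do.call(rbind, rows), calibrator = calibrator)
    list(ct = tab, samples = s$records,
         truth = s$truth[, intersect(names(config$genes), target_genes()),
                         drop = FALSE])
  })
}

#' Default study-shaped cohort configurations
#'
#' Convenience configurations matched to the study designs the package
#' emulates: a 391-case / 45-control tissue beta cohort for the
#' discovery screen, and a 289 / 190 / 217 stool MSP cohort. Under the
#' stool defaults the anchor-alone carcinoma sensitivity is ~0.87 and
#' the OR-combined dual sensitivity ~0.94 in expectation (approximate:
#' Ct draws near the cutoff move individual calls).
#'
#' @param seed Integer seed stored in both configs.
#' @return List with elements `beta` ([beta_sim_config()]) and `ct`
#'   ([ct_sim_config()]), plus an `expected` element recording the
#'   approximate design expectations
#'   (`single_sens`, `dual_sens` for carcinoma vs normal).
#' @export
default_cohort_configs <- function(seed = 1L) {
  list(beta = beta_sim_config(n_case = 391, n_control = 45, seed = seed),
       ct = ct_sim_config(n_case = 289, n_adenoma = 190, n_control = 217,
                          seed = seed),
       expected = list(single_sens = 0.87, dual_sens = 0.94))
}
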