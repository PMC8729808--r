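#' @keywords internal
"_PACKAGE"

# Controlled vocabularies ------------------------------------------------

#' Controlled vocabularies for sample annotation
#'
#' Diagnostic groups and bowel-subsite locations used throughout the
#' package. `location_aliases()` returns the default mapping from
#' free-text location strings (as they appear in clinical exports) to the
#' controlled vocabulary; it can be extended via the `aliases` argument of
#' [read_sample_metadata()].
#'
#' @return Character vectors of allowed tokens, or for
#'   `location_aliases()` a named character vector mapping input string ->
#'   canonical location token.
#' @export
diagnostic_groups <- function() c("CRC", "adenoma", "normal")

#' @rdname diagnostic_groups
#' @export
sample_locations <- function() {
  c("left_colon", "right_colon", "sigmoid_colon", "rectum",
    "rectosigmoid_junction", "descending_colon", "ascending_colon",
    "transverse_colon", "splenic_flexure", "hepatic_flexure",
    "colon_NOS", "rectum_NOS", "other", "unknown")
}

#' @rdname diagnostic_groups
#' @export
location_aliases <- function() {
  c("Left colon"                     = "left_colon",
    "Right colon"                    = "right_colon",
    "Sigmoid colon"                  = "sigmoid_colon",
    "Rectal"                         = "rectum",
    "Rectum"                         = "rectum",
    "Rectosigmoid junction"          = "rectosigmoid_junction",
    "Descending colon"               = "descending_colon",
    "Ascending colon"                = "ascending_colon",
    "Transverse colon"               = "transverse_colon",
    "Splenic flexure of the colon"   = "splenic_flexure",
    "Splenic flexure"                = "splenic_flexure",
    "Hepatic flexure of the colon"   = "hepatic_flexure",
    "Hepatic flexure"                = "hepatic_flexure",
    "Colon, NOS"                     = "colon_NOS",
    "Rectum, NOS"                    = "rectum_NOS",
    "Unknown"                        = "unknown")
}

# Genes scored by the MSP assay; ACTB is the reference gene.
#' MSP gene panel
#'
#' @return Character vector of target gene names (`target_genes()`), or all
#'   assayed genes including the reference (`assay_genes()`).
#' @export
target_genes <- function() c("SDC2", "TFPI2")

#' @rdname target_genes
#' @export
assay_genes <- function() c(target_genes(), "ACTB")

# Maximum qPCR cycle number; a reaction that has not crossed threshold by
# this cycle is NO_AMP.
#' @rdname target_genes
#' @export
max_cycles <- function() 45

# BetaMatrix -------------------------------------------------------------

#' Construct a validated beta-value matrix
#'
#' A `beta_matrix` holds probe-level methylation beta values (fraction
#' methylated, in `[0, 1]`) with probes in rows and samples in columns.
#' Missing values (`NA`) are allowed and are excluded from island means
#' downstream.
#'
#' @param values Numeric matrix, probes x samples, with unique non-empty
#'   `rownames` (probe ids) and `colnames` (sample ids).
#' @return An object of class `beta_matrix` (a numeric matrix).
#' @export
beta_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have probe ids as rownames and sample ids as colnames",
         call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate probe_id: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample_id: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "), call. = FALSE)
  bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "beta value outside [0, 1] at probe '%s', sample '%s' (value %g)",
      rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]],
      values[bad[1, 1], bad[1, 2]]), call. = FALSE)
  }
  structure(values, class = c("beta_matrix", class(values)))
}

#' Read a beta-value matrix from delimited text
#'
#' Expects a 450k-export-style layout: first column `probe_id`, one column
#' per sample thereafter. Missing betas may be encoded as empty fields or
#' `NA`.
#'
#' @param path Path to a CSV (default) or TSV file.
#' @param sep Field separator; `","` or `"\t"`. Guessed from the file
#'   extension when `NULL` (`.tsv`/`.txt` -> tab).
#' @return A [beta_matrix()].
#' @export
read_beta_matrix <- function(path, sep = NULL) {
  sep <- sep %||% if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          na.strings = c("", "NA"), stringsAsFactors = FALSE)
  if (ncol(df) < 2)
    stop("malformed header: need a probe_id column plus >= 1 sample column",
         call. = FALSE)
  if (tolower(names(df)[1]) != "probe_id")
    stop("malformed header: first column must be 'probe_id', got '",
         names(df)[1], "'", call. = FALSE)
  probes <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals))
    stop("non-numeric beta values in ", path, call. = FALSE)
  rownames(vals) <- probes
  beta_matrix(vals)
}

#' Write a beta-value matrix to delimited text
#'
#' Inverse of [read_beta_matrix()]: numeric content round-trips exactly at
#' the written precision (15 significant digits).
#'
#' @param x A [beta_matrix()].
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "beta_matrix"))
  df <- data.frame(probe_id = rownames(x),
                   format(unclass(x), digits = 15, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  df[df == "NA"] <- ""
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Probe annotation -------------------------------------------------------

#' Construct / read a probe annotation table
#'
#' Maps array probes to genes and CpG-island grouping keys. Island-level
#' methylation is the unit of marker scoring: the screen averages beta over
#' all probes sharing an `island_id`.
#'
#' @param probe_id,gene,island_id Character vectors of equal length.
#' @return A `data.frame` with columns `probe_id`, `gene`, `island_id`.
#' @export
probe_annotation <- function(probe_id, gene, island_id) {
  probe_id <- as.character(probe_id)
  gene <- rep_len(as.character(gene), length(probe_id))
  island_id <- rep_len(as.character(island_id), length(probe_id))
  if (anyDuplicated(probe_id))
    stop("duplicate probe_id in annotation: ",
         paste(unique(probe_id[duplicated(probe_id)]), collapse = ", "),
         call. = FALSE)
  data.frame(probe_id = probe_id, gene = gene, island_id = island_id,
             stringsAsFactors = FALSE)
}

#' @rdname probe_annotation
#' @param path CSV with columns `probe_id,gene,island_id`.
#' @export
read_probe_annotation <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("probe_id", "gene", "island_id")
  if (!all(need %in% names(df)))
    stop("annotation must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  probe_annotation(df$probe_id, df$gene, df$island_id)
}

# Sample metadata --------------------------------------------------------

#' Read sample metadata
#'
#' Expects CSV columns `sample_id, group, location, cohort`. Group must be
#' one of `r paste(diagnostic_groups(), collapse = ", ")`. Location strings
#' are mapped to the controlled vocabulary through the alias table
#' ([location_aliases()]); canonical tokens pass through unchanged; an
#' unmapped string becomes `"other"` with a warning; empty locations become
#' `"unknown"`.
#'
#' @param path CSV path.
#' @param aliases Named character vector extending/overriding
#'   [location_aliases()].
#' @return `data.frame` with columns `sample_id`, `group` (factor),
#'   `location` (factor over [sample_locations()]), `cohort`.
#' @export
read_sample_metadata <- function(path, aliases = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = character(0))
  need <- c("sample_id", "group", "location", "cohort")
  if (!all(need %in% names(df)))
    stop("metadata must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  sample_records(df$sample_id, df$group, df$location, df$cohort,
                 aliases = aliases)
}

#' @rdname read_sample_metadata
#' @param sample_id,group,location,cohort Vectors of equal length; see
#'   `read_sample_metadata` for the accepted values.
#' @export
sample_records <- function(sample_id, group, location = "unknown",
                           cohort = "cohort", aliases = NULL) {
  n <- length(sample_id)
  sample_id <- as.character(sample_id)
  group <- as.character(group)
  location <- rep_len(as.character(location), n)
  cohort <- rep_len(as.character(cohort), n)
  if (anyDuplicated(sample_id))
    stop("duplicate sample_id: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "),
         call. = FALSE)
  bad_group <- setdiff(unique(group), diagnostic_groups())
  if (length(bad_group) > 0)
    stop("unknown diagnostic group(s): ", paste(bad_group, collapse = ", "),
         "; allowed: ", paste(diagnostic_groups(), collapse = ", "),
         call. = FALSE)
  map <- location_aliases()
  if (!is.null(aliases)) map[names(aliases)] <- aliases
  loc <- ifelse(location %in% sample_locations(), location,
                unname(map[location]))
  loc[!is.na(location) & location == ""] <- "unknown"
  unmapped <- is.na(loc)
  if (any(unmapped)) {
    warning("unmapped location string(s) set to 'other': ",
            paste(unique(location[unmapped]), collapse = "; "),
            call. = FALSE)
    loc[unmapped] <- "other"
  }
  data.frame(sample_id = sample_id,
             group = factor(group, levels = diagnostic_groups()),
             location = factor(loc, levels = sample_locations()),
             cohort = cohort,
             stringsAsFactors = FALSE)
}

# Ct tables --------------------------------------------------------------

# Reserved sample ids flagging control wells in a Ct CSV.
POS_CONTROL_ID <- "POS_CTRL"
NEG_CONTROL_ID <- "NEG_CTRL"

#' Construct a validated MSP Ct table
#'
#' Holds per-sample Ct measurements for the target genes and the ACTB
#' reference, plus the plate controls. `NA` Ct encodes NO_AMP: no
#' amplification within the 45-cycle run. The calibrator (positive
#' control, a fully methylated plasmid mix) must have a finite Ct for
#' every assayed gene because it anchors the 2^-ddCt computation.
#'
#' @param measurements `data.frame` with columns `sample_id`, `gene`
#'   (in [assay_genes()]), `ct` (numeric in `(0, 45]` or `NA` for NO_AMP).
#' @param calibrator Named numeric vector, Ct per gene for the positive
#'   control; finite for all of [assay_genes()].
#' @param negative_control Optional named numeric vector (NA = NO_AMP).
#' @return An object of class `ct_table`.
#' @export
ct_table <- function(measurements, calibrator, negative_control = NULL) {
  need <- c("sample_id", "gene", "ct")
  if (!all(need %in% names(measurements)))
    stop("measurements must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  measurements <- measurements[need]
  measurements$sample_id <- as.character(measurements$sample_id)
  measurements$gene <- as.character(measurements$gene)
  measurements$ct <- as.numeric(measurements$ct)
  bad_gene <- setdiff(unique(measurements$gene), assay_genes())
  if (length(bad_gene) > 0)
    stop("unknown gene(s): ", paste(bad_gene, collapse = ", "), call. = FALSE)
  fin <- !is.na(measurements$ct)
  if (any(fin & (measurements$ct <= 0 | measurements$ct > max_cycles()))) {
    i <- which(fin & (measurements$ct <= 0 | measurements$ct > max_cycles()))[1]
    stop(sprintf("Ct out of range (0, %d] for sample '%s', gene %s: %g",
                 max_cycles(), measurements$sample_id[i],
                 measurements$gene[i], measurements$ct[i]), call. = FALSE)
  }
  key <- paste(measurements$sample_id, measurements$gene)
  if (anyDuplicated(key))
    stop("duplicate (sample_id, gene) measurement: ",
         key[duplicated(key)][1], call. = FALSE)
  missing_cal <- setdiff(assay_genes(), names(calibrator))
  calibrator <- as.numeric(calibrator[assay_genes()])
  names(calibrator) <- assay_genes()
  if (length(missing_cal) > 0 || any(!is.finite(calibrator)))
    stop("calibrator incomplete: need a finite Ct for ",
         paste(assay_genes(), collapse = ", "), call. = FALSE)
  structure(list(measurements = measurements,
                 calibrator = calibrator,
                 negative_control = negative_control),
            class = "ct_table")
}

#' Read an MSP Ct table from CSV
#'
#' Expects columns `sample_id, gene, ct`. The `ct` field is numeric, or
#' one of the tokens `NO_AMP` / `Undetermined` (normalised to NO_AMP).
#' Control wells use the reserved sample ids `POS_CTRL` (calibrator) and
#' `NEG_CTRL`.
#'
#' @param path CSV path.
#' @return A [ct_table()].
#' @export
read_ct_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(ct = "character"))
  need <- c("sample_id", "gene", "ct")
  if (!all(need %in% names(df)))
    stop("Ct table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  ct_chr <- trimws(df$ct)
  no_amp <- ct_chr %in% c("NO_AMP", "Undetermined")
  ct <- suppressWarnings(as.numeric(ct_chr))
  unparsed <- !no_amp & is.na(ct) & ct_chr != ""
  if (any(unparsed))
    stop("unparseable ct value(s): ",
         paste(unique(ct_chr[unparsed]), collapse = ", "), call. = FALSE)
  ct[no_amp] <- NA_real_
  is_pos <- df$sample_id == POS_CONTROL_ID
  is_neg <- df$sample_id == NEG_CONTROL_ID
  calibrator <- stats::setNames(ct[is_pos], df$gene[is_pos])
  negative <- if (any(is_neg)) stats::setNames(ct[is_neg], df$gene[is_neg])
  ct_table(data.frame(sample_id = df$sample_id[!is_pos & !is_neg],
                      gene = df$gene[!is_pos & !is_neg],
                      ct = ct[!is_pos & !is_neg],
                      stringsAsFactors = FALSE),
           calibrator = calibrator, negative_control = negative)
}

#' Write an MSP Ct table to CSV
#'
#' Inverse of [read_ct_table()]; NO_AMP is written as the token `NO_AMP`.
#'
#' @param x A [ct_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(x, path) {
  stopifnot(inherits(x, "ct_table"))
  rows <- x$measurements
  rows <- rbind(rows,
                data.frame(sample_id = POS_CONTROL_ID,
                           gene = names(x$calibrator),
                           ct = as.numeric(x$calibrator),
                           stringsAsFactors = FALSE))
  if (!is.null(x$negative_control))
    rows <- rbind(rows,
                  data.frame(sample_id = NEG_CONTROL_ID,
                             gene = names(x$negative_control),
                             ct = as.numeric(x$negative_control),
                             stringsAsFactors = FALSE))
  rows$ct <- ifelse(is.na(rows$ct), "NO_AMP",
                    format(rows$ct, digits = 15, trim = TRUE,
                           scientific = FALSE))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Internal helpers -------------------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Half-up rounding
#'
#' The rounding convention of the clinical rate tables (R's `round()` is
#' round-half-even). A tiny epsilon guards against values like
#' `0.285 * 1000` landing just below the `.5` boundary in binary.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return `x` rounded half-up.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}
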