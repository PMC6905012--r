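# Input handling: biomarker tables, group assignments, log transform,
# complete-case (biomarker-level) exclusion.

.MISSING_MARKERS <- c("", "na", "nan")

#' Construct a biomarker table
#'
#' The single input currency of the pipeline: a samples x biomarkers matrix
#' of continuous measurements together with a per-sample cohort label and a
#' biomarker -> variable-group assignment. Rosters record the *measured*
#' universe of each variable group, including biomarkers later dropped by
#' the complete-case rule; they are the default denominator universe for
#' network density.
#'
#' @param values Numeric matrix, rows = samples, columns = biomarkers.
#'   Row names are sample ids, column names biomarker names. `NA` marks a
#'   missing measurement.
#' @param cohort Character vector of cohort labels, one per sample.
#' @param group_map Named character vector mapping every biomarker name to
#'   its variable group.
#' @param rosters Optional named list of character vectors giving each
#'   group's measured roster. Defaults to the groups of `group_map`
#'   restricted to the table's biomarkers.
#' @param transform_log Record of an applied log transform
#'   (`list(base=, offset=)`) or `NULL`.
#' @return An object of class `biomarker_table`.
#' @export
biomarker_table <- function(values, cohort, group_map, rosters = NULL,
                            transform_log = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry sample ids (rownames) and biomarker names (colnames)",
         call. = FALSE)
  sample_ids <- rownames(values)
  biomarkers <- colnames(values)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(biomarkers))
    stop("duplicate biomarker name(s): ",
         paste(unique(biomarkers[duplicated(biomarkers)]), collapse = ", "),
         call. = FALSE)
  if (length(cohort) != nrow(values))
    stop("`cohort` must have one label per sample", call. = FALSE)
  unmapped <- setdiff(biomarkers, names(group_map))
  if (length(unmapped))
    stop("biomarker(s) without a variable-group assignment: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  if (is.null(rosters)) {
    gm <- group_map[biomarkers]
    rosters <- split(names(gm), unname(gm))
  }
  overlap <- names(which(table(unlist(rosters)) > 1L))
  if (length(overlap))
    stop("biomarker(s) assigned to more than one group roster: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  structure(
    list(values = values,
         cohort = stats::setNames(as.character(cohort), sample_ids),
         group_map = group_map[names(group_map) %in% unique(unlist(c(rosters, list(biomarkers))))],
         rosters = rosters,
         transform_log = transform_log),
    class = "biomarker_table")
}

#' @export
print.biomarker_table <- function(x, ...) {
  cat(sprintf("biomarker_table: %d samples x %d biomarkers, %d variable group(s)\n",
              nrow(x$values), ncol(x$values), length(x$rosters)))
  cat("cohorts:", paste(sprintf("%s (n=%d)", names(table(x$cohort)),
                                as.integer(table(x$cohort))), collapse = ", "), "\n")
  if (!is.null(x$transform_log))
    cat(sprintf("log-transformed: base %.4g, offset %.4g\n",
                x$transform_log$base, x$transform_log$offset))
  n_miss <- sum(is.na(x$values))
  if (n_miss) cat(sprintf("missing entries: %d\n", n_miss))
  invisible(x)
}

#' Analysis configuration
#'
#' Houses every tunable convention of the pipeline: the hard correlation
#' threshold magnitude (default 0.7), whether the threshold is inclusive,
#' the normalized betweenness cutoff defining hubs (default 0.1, strict
#' "greater than"), the density denominator universe, the betweenness
#' scope, and the t-test variant.
#'
#' @param rho0 Correlation threshold magnitude in (0, 1].
#' @param hub_bc_threshold Normalized betweenness cutoff; a node is a hub
#'   iff its score is strictly greater.
#' @param log_base Base for the log transform (default natural log).
#' @param density_universe `"group_roster"` (measured roster size, the
#'   default) or `"connected_nodes"`.
#' @param bc_scope `"within_group"` (score each group's induced subgraph,
#'   the default) or `"full_network"`.
#' @param ttest_variant `"welch"` (default) or `"pooled"`.
#' @param inclusive_threshold Retain edges with |rho| exactly equal to
#'   `rho0` (default `TRUE`).
#' @param sig_level Two-sided significance level for t-test flags.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(rho0 = 0.7, hub_bc_threshold = 0.1,
                            log_base = exp(1),
                            density_universe = c("group_roster", "connected_nodes"),
                            bc_scope = c("within_group", "full_network"),
                            ttest_variant = c("welch", "pooled"),
                            inclusive_threshold = TRUE,
                            sig_level = 0.05) {
  stopifnot(is.numeric(rho0), length(rho0) == 1L, rho0 > 0, rho0 <= 1,
            is.numeric(hub_bc_threshold), hub_bc_threshold >= 0,
            is.numeric(log_base), log_base > 0, log_base != 1)
  structure(
    list(rho0 = rho0, hub_bc_threshold = hub_bc_threshold,
         log_base = log_base,
         density_universe = match.arg(density_universe),
         bc_scope = match.arg(bc_scope),
         ttest_variant = match.arg(ttest_variant),
         inclusive_threshold = isTRUE(inclusive_threshold),
         sig_level = sig_level),
    class = "analysis_config")
}

#' Read a biomarker -> group assignment file
#'
#' Two delimited columns, `biomarker` and `group`, with a header row.
#'
#' @param path File path.
#' @param sep Field delimiter.
#' @return Named character vector (biomarker -> group).
#' @export
read_group_spec <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L)
    stop("group spec must have two columns: biomarker, group", call. = FALSE)
  stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}

#' Read a delimited biomarker table
#'
#' Expects one header row; the first column holds sample ids, one column
#' (default `"cohort"`) the cohort label, and every remaining column one
#' biomarker. Cells that are empty or read `NA`/`NaN` (case-insensitive),
#' and any cell that does not parse as a number, become missing entries.
#'
#' @param path Path to a delimited text file (UTF-8).
#' @param group_spec Named character vector biomarker -> group, or path to
#'   a two-column spec file in the same dialect.
#' @param cohort_column Name of the cohort label column.
#' @param sep Field delimiter (comma default, tab selectable).
#' @return A validated [biomarker_table].
#' @export
read_biomarker_table <- function(path, group_spec, cohort_column = "cohort",
                                 sep = ",") {
  if (is.character(group_spec) && length(group_spec) == 1L && is.null(names(group_spec)))
    group_spec <- read_group_spec(group_spec, sep = sep)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(raw) < 3L)
    stop("expected at least sample id, cohort and one biomarker column",
         call. = FALSE)
  if (!cohort_column %in% names(raw))
    stop("cohort column '", cohort_column, "' not found", call. = FALSE)
  sample_ids <- raw[[1L]]
  cohort <- raw[[cohort_column]]
  biom_cols <- setdiff(names(raw)[-1L], cohort_column)
  vals <- vapply(raw[biom_cols], function(col) {
    col <- trimws(col)
    col[tolower(col) %in% .MISSING_MARKERS] <- NA_character_
    suppressWarnings(as.numeric(col))
  }, numeric(nrow(raw)))
  vals <- matrix(vals, nrow = nrow(raw),
                 dimnames = list(sample_ids, biom_cols))
  biomarker_table(vals, cohort, group_spec)
}

#' Write a biomarker table as delimited text
#'
#' Round-trips through [read_biomarker_table]: sample id first column,
#' cohort column, then biomarkers. Missing entries are written as `NA`.
#'
#' @param table A [biomarker_table].
#' @param path Output path.
#' @param sep Field delimiter.
#' @param cohort_column Name for the cohort column.
#' @export
write_biomarker_table <- function(table, path, sep = ",",
                                  cohort_column = "cohort") {
  df <- data.frame(sample_id = rownames(table$values),
                   cohort = unname(table$cohort),
                   table$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[2L] <- cohort_column
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Log-transform a biomarker table
#'
#' Element-wise `log(value + offset)` in the given base. Missing entries
#' stay missing; the transform is recorded on the returned table so
#' downstream reports can state the analysed scale.
#'
#' @param table A [biomarker_table].
#' @param base Logarithm base (default natural).
#' @param offset Added before taking logs (default 0).
#' @return The transformed [biomarker_table].
#' @export
log_transform <- function(table, base = exp(1), offset = 0) {
  stopifnot(inherits(table, "biomarker_table"))
  v <- table$values + offset
  bad <- which(!is.na(v) & v <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop("log transform undefined (value + offset <= 0) at sample '",
         rownames(table$values)[bad[1L, 1L]], "', biomarker '",
         colnames(table$values)[bad[1L, 2L]], "'", call. = FALSE)
  }
  table$values <- log(v, base = base)
  table$transform_log <- list(base = base, offset = offset)
  table
}

#' Drop biomarkers with any missing measurement
#'
#' Complete-case analysis at the biomarker (column) level: a biomarker
#' with one or more missing entries is excluded entirely, so every
#' retained biomarker shares the same sample set and the correlation
#' matrix has a single common n. Group rosters keep the dropped names:
#' they remain part of the measured universe used as the default density
#' denominator.
#'
#' @param table A [biomarker_table].
#' @return `list(table = <complete table>, dropped = <character vector>)`.
#' @export
drop_incomplete_biomarkers <- function(table) {
  stopifnot(inherits(table, "biomarker_table"))
  incomplete <- colnames(table$values)[colSums(is.na(table$values)) > 0L]
  if (length(incomplete) == ncol(table$values))
    stop("all biomarkers contain missing data; nothing left to analyse",
         call. = FALSE)
  keep <- setdiff(colnames(table$values), incomplete)
  table$values <- table$values[, keep, drop = FALSE]
  list(table = table, dropped = incomplete)
}
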