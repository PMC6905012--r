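# Pairwise Pearson correlation and the hard threshold rule that defines
# network edges.

#' Pearson product-moment correlation of two vectors
#'
#' Thin wrapper over the textbook coefficient with the pipeline's
#' contracts: vectors of equal length >= 3, and a hard error (not a silent
#' zero) when either vector has zero variance, so degenerate biomarkers
#' never slip into a network unnoticed.
#'
#' @param x,y Numeric vectors of equal length >= 3, no missing values.
#' @return The coefficient, in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 paired observations", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed; run drop_incomplete_biomarkers first", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: Pearson correlation undefined", call. = FALSE)
  stats::cor(x, y)
}

#' Full pairwise correlation matrix of a complete biomarker table
#'
#' Every biomarker against every other biomarker, across all variable
#' groups, on whatever scale the table currently holds (apply
#' [log_transform] first if the analysis scale is logarithmic). The table
#' must be complete; constant columns are a hard error listing the
#' offenders so the caller can decide to drop them.
#'
#' @param table A complete [biomarker_table].
#' @return An object of class `correlation_matrix`: `biomarkers` (ordered
#'   names), `rho` (symmetric matrix, unit diagonal), `n_samples`.
#' @export
correlation_matrix <- function(table) {
  stopifnot(inherits(table, "biomarker_table"))
  v <- table$values
  if (anyNA(v))
    stop("table contains missing entries; run drop_incomplete_biomarkers first",
         call. = FALSE)
  if (nrow(v) < 3L) stop("need at least 3 samples", call. = FALSE)
  sds <- apply(v, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant biomarker column(s): ",
         paste(colnames(v)[sds == 0], collapse = ", "), call. = FALSE)
  rho <- stats::cor(v)
  # cor() is symmetric up to floating error; make it exactly so
  rho <- (rho + t(rho)) / 2
  diag(rho) <- 1
  structure(list(biomarkers = colnames(v), rho = rho, n_samples = nrow(v)),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("correlation_matrix: %d biomarkers, n = %d samples\n",
              length(x$biomarkers), x$n_samples))
  invisible(x)
}

#' Apply the hard correlation threshold to produce the edge list
#'
#' Retains exactly the unordered biomarker pairs whose |rho| reaches the
#' threshold magnitude. The comparison is inclusive (|rho| >= rho0) by
#' default: the study regime this mirrors reports coefficients exactly at
#' the printed threshold as network edges. Signed coefficients are kept at
#' full precision; rounding belongs to report rendering only.
#'
#' @param cm A [correlation_matrix].
#' @param rho0 Threshold magnitude in (0, 1].
#' @param group_map Named character vector biomarker -> group, used to
#'   label each edge `within_group`.
#' @param inclusive If `FALSE`, require |rho| strictly greater than `rho0`.
#' @return A `data.frame` with columns `a`, `b`, `rho`, `group_a`,
#'   `group_b`, `within_group`, ordered lexicographically by (a, b) with
#'   `a < b` inside each pair.
#' @export
threshold_edges <- function(cm, rho0 = 0.7, group_map, inclusive = TRUE) {
  stopifnot(inherits(cm, "correlation_matrix"),
            is.numeric(rho0), rho0 > 0, rho0 <= 1)
  unmapped <- setdiff(cm$biomarkers, names(group_map))
  if (length(unmapped))
    stop("biomarker(s) without group: ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  rho <- cm$rho
  idx <- which(upper.tri(rho) &
                 (if (inclusive) abs(rho) >= rho0 else abs(rho) > rho0),
               arr.ind = TRUE)
  nm <- cm$biomarkers
  a <- nm[idx[, 1L]]
  b <- nm[idx[, 2L]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  edges <- data.frame(
    a = a, b = b,
    rho = rho[idx],
    group_a = unname(group_map[a]),
    group_b = unname(group_map[b]),
    stringsAsFactors = FALSE)
  edges$within_group <- edges$group_a == edges$group_b
  edges <- edges[order(edges$a, edges$b), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Two-sided Fisher-z p-value for a Pearson coefficient
#'
#' Offered as an optional annotation only: the thresholding rule of this
#' pipeline filters on |rho|, never on p-values.
#'
#' @param r Pearson coefficient(s).
#' @param n Sample size (> 3).
#' @return Two-sided p-value(s) under the null rho = 0.
#' @export
fisher_z_pvalue <- function(r, n) {
  stopifnot(n > 3)
  z <- atanh(r) * sqrt(n - 3)
  2 * stats::pnorm(-abs(z))
}

#' Write an edge list as delimited text
#'
#' Columns `a`, `b`, `rho`, `group_a`, `group_b`, `within_group`, in the
#' stable lexicographic (a, b) order produced by [threshold_edges].
#'
#' @param edges Edge-list `data.frame`.
#' @param path Output path.
#' @param sep Field delimiter.
#' @export
write_edge_list <- function(edges, path, sep = ",") {
  edges <- edges[order(edges$a, edges$b), , drop = FALSE]
  utils::write.table(edges, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
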