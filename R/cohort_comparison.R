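# Per-cohort pipeline execution, case-control network comparison, and the
# unpaired t-tests (raw data or published summary statistics).

#' Run the full correlation-network pipeline on one cohort
#'
#' Deterministic composition of the stages: complete-case biomarker
#' exclusion, pairwise Pearson correlation, hard thresholding, network
#' construction, group-level collapse and per-group summaries. A run
#' manifest records the configuration, dropped biomarkers and per-stage
#' counts.
#'
#' @param table A single-cohort [biomarker_table] (values already on the
#'   analysed scale; apply [log_transform] beforehand if needed).
#' @param config An [analysis_config].
#' @return List with `network`, `group_network`, `summaries` (one
#'   `network_summary` per roster group), `edges`, `metrics`
#'   (per-node table) and `manifest`.
#' @export
run_pipeline <- function(table, config = analysis_config()) {
  stopifnot(inherits(table, "biomarker_table"),
            inherits(config, "analysis_config"))
  cc <- drop_incomplete_biomarkers(table)
  cm <- correlation_matrix(cc$table)
  edges <- threshold_edges(cm, rho0 = config$rho0,
                           group_map = cc$table$group_map,
                           inclusive = config$inclusive_threshold)
  net <- build_network(edges, cc$table$group_map)
  net$groups <- sort(unique(c(net$groups, names(table$rosters))))
  gln <- collapse_to_group_level(net)
  summaries <- lapply(names(table$rosters), function(g)
    group_summary(net, g, table$rosters[[g]], config))
  names(summaries) <- names(table$rosters)
  manifest <- list(
    config = unclass(config),
    n_samples = nrow(cc$table$values),
    biomarkers_in = ncol(table$values),
    biomarkers_dropped = cc$dropped,
    biomarkers_analysed = ncol(cc$table$values),
    edges_retained = nrow(edges),
    nodes = nrow(net$nodes))
  list(network = net, group_network = gln, summaries = summaries,
       edges = edges, metrics = node_metrics(net, config),
       manifest = manifest)
}

.edge_keys <- function(edges) {
  if (!nrow(edges)) return(character(0))
  paste(pmin(edges$a, edges$b), pmax(edges$a, edges$b), sep = "--")
}

.connector_keys <- function(gln) {
  if (!nrow(gln$connectors)) return(character(0))
  paste(gln$connectors$group_a, gln$connectors$group_b, sep = "--")
}

#' Compare two cohort networks
#'
#' Runs the pipeline on each cohort and enumerates the differences: total
#' edge counts, edges present in only one cohort, group-pair connectors
#' present in one and absent in the other, and hub overlap.
#'
#' @param tableA,tableB [biomarker_table]s sharing the same biomarker
#'   roster (a roster mismatch is an error listing the symmetric
#'   difference).
#' @param config An [analysis_config].
#' @param labels Length-2 character vector naming the cohorts in the
#'   report.
#' @return An object of class `comparison_report`.
#' @export
compare_cohorts <- function(tableA, tableB, config = analysis_config(),
                            labels = c("A", "B")) {
  mismatch <- c(setdiff(colnames(tableA$values), colnames(tableB$values)),
                setdiff(colnames(tableB$values), colnames(tableA$values)))
  if (length(mismatch))
    stop("biomarker rosters differ between cohorts: ",
         paste(sort(unique(mismatch)), collapse = ", "), call. = FALSE)
  runs <- list(run_pipeline(tableA, config), run_pipeline(tableB, config))
  names(runs) <- labels
  keysA <- .edge_keys(runs[[1L]]$edges)
  keysB <- .edge_keys(runs[[2L]]$edges)
  edges_only_in <- list(
    runs[[1L]]$edges[!(keysA %in% keysB), , drop = FALSE],
    runs[[2L]]$edges[!(keysB %in% keysA), , drop = FALSE])
  names(edges_only_in) <- labels
  connA <- .connector_keys(runs[[1L]]$group_network)
  connB <- .connector_keys(runs[[2L]]$group_network)
  hubsA <- unique(unlist(lapply(runs[[1L]]$summaries, `[[`, "hub_names")))
  hubsB <- unique(unlist(lapply(runs[[2L]]$summaries, `[[`, "hub_names")))
  structure(list(
    labels = labels,
    per_cohort = lapply(runs, function(r)
      list(total_edge_count = nrow(r$edges),
           summaries = r$summaries,
           group_network = r$group_network,
           manifest = r$manifest)),
    runs = runs,
    edges_only_in = edges_only_in,
    connectors_only_in = stats::setNames(
      list(setdiff(connA, connB), setdiff(connB, connA)), labels),
    hub_overlap = list(shared = intersect(hubsA, hubsB),
                       only = stats::setNames(
                         list(setdiff(hubsA, hubsB), setdiff(hubsB, hubsA)),
                         labels))),
    class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  for (i in 1:2)
    cat(sprintf("%s: %d total edge(s), %d connector(s), hubs: %s\n",
                x$labels[i], x$per_cohort[[i]]$total_edge_count,
                nrow(x$per_cohort[[i]]$group_network$connectors),
                paste(unique(unlist(lapply(x$per_cohort[[i]]$summaries,
                                           `[[`, "hub_names"))),
                      collapse = ", ")))
  cat(sprintf("edges only in %s: %d; only in %s: %d\n",
              x$labels[1], nrow(x$edges_only_in[[1L]]),
              x$labels[2], nrow(x$edges_only_in[[2L]])))
  invisible(x)
}

#' Summary statistics of a sample
#'
#' @param x Numeric vector without missing values.
#' @return `list(mean, sd, n)`.
#' @export
summary_stats <- function(x) {
  stopifnot(!anyNA(x), length(x) >= 2L)
  list(mean = mean(x), sd = stats::sd(x), n = length(x))
}

#' Unpaired two-sample t-test from summary statistics
#'
#' Works directly from (mean, sd, n) pairs, so published tables of
#' mean +/- SD can be re-tested without raw data. The Welch
#' (unequal-variance) form with Satterthwaite degrees of freedom is the
#' default; the pooled-variance classic form with df = n_a + n_b - 2 is
#' selectable.
#'
#' @param a,b `list(mean=, sd=, n=)` with sd >= 0 and n >= 2.
#' @param variant `"welch"` (default) or `"pooled"`.
#' @return An object of class `ttest_result`: `t`, `df`, `p` (two-sided),
#'   `variant`.
#' @export
ttest_from_summary <- function(a, b, variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  for (s in list(a, b))
    stopifnot(s$sd >= 0, s$n >= 2)
  if (a$sd == 0 && b$sd == 0) {
    if (a$mean == b$mean)
      return(structure(list(t = 0, df = NA_real_, p = 1, variant = variant),
                       class = "ttest_result"))
    stop("both standard deviations are zero with unequal means: t undefined",
         call. = FALSE)
  }
  if (variant == "welch") {
    va <- a$sd^2 / a$n
    vb <- b$sd^2 / b$n
    t <- (a$mean - b$mean) / sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  } else {
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2)
    t <- (a$mean - b$mean) / sqrt(sp2 * (1 / a$n + 1 / b$n))
    df <- a$n + b$n - 2
  }
  p <- 2 * stats::pt(-abs(t), df = df)
  structure(list(t = t, df = df, p = p, variant = variant),
            class = "ttest_result")
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf("%s t = %.3f, df = %.2f, p = %.4g\n", x$variant, x$t, x$df, x$p))
  invisible(x)
}

#' Per-biomarker unpaired t-tests between two cohorts
#'
#' One test per shared biomarker, on the configured analysis scale: if
#' `log_base` is given and the tables are not yet log-transformed, the
#' transform is applied first. Raw p-values only, flagged at `sig_level`
#' with no multiple-testing correction (the hard-threshold network route
#' is this pipeline's answer to multiplicity, not p-value adjustment).
#'
#' @param tableA,tableB [biomarker_table]s with a shared roster.
#' @param variant `"welch"` or `"pooled"`.
#' @param log_base If non-`NULL` and a table carries no transform record,
#'   log-transform it in this base first.
#' @param sig_level Two-sided significance flag level.
#' @return `data.frame`: biomarker, group, mean_a, sd_a, n_a, mean_b,
#'   sd_b, n_b, t, df, p, significant.
#' @export
ttest_table <- function(tableA, tableB, variant = c("welch", "pooled"),
                        log_base = NULL, sig_level = 0.05) {
  variant <- match.arg(variant)
  shared <- intersect(colnames(tableA$values), colnames(tableB$values))
  if (!length(shared)) stop("no shared biomarkers", call. = FALSE)
  if (!is.null(log_base)) {
    if (is.null(tableA$transform_log)) tableA <- log_transform(tableA, base = log_base)
    if (is.null(tableB$transform_log)) tableB <- log_transform(tableB, base = log_base)
  }
  rows <- lapply(shared, function(bm) {
    xa <- tableA$values[, bm]; xa <- xa[!is.na(xa)]
    xb <- tableB$values[, bm]; xb <- xb[!is.na(xb)]
    if (length(xa) < 2L || length(xb) < 2L)
      stop("fewer than 2 complete observations for biomarker ", bm, call. = FALSE)
    sa <- summary_stats(xa); sb <- summary_stats(xb)
    tt <- ttest_from_summary(sa, sb, variant)
    data.frame(biomarker = bm,
               group = unname(tableA$group_map[bm]),
               mean_a = sa$mean, sd_a = sa$sd, n_a = sa$n,
               mean_b = sb$mean, sd_b = sb$sd, n_b = sb$n,
               t = tt$t, df = tt$df, p = tt$p,
               significant = tt$p < sig_level,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
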