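# Network construction and the graph-theoretic read-outs: degree,
# normalized betweenness centrality, per-group density, hub detection, and
# the group-level collapse.

#' Build a biomarker network from a thresholded edge list
#'
#' Nodes are exactly the endpoints of the supplied edges: a biomarker with
#' no supra-threshold correlation never enters the network, so every node
#' has degree >= 1 by construction. The graph is undirected and simple;
#' duplicate unordered pairs and self-loops are hard errors.
#'
#' @param edges Edge-list `data.frame` as produced by [threshold_edges]
#'   (columns `a`, `b`, `rho` at minimum).
#' @param group_map Named character vector biomarker -> group covering all
#'   endpoints; its full set of group labels is kept as the group registry.
#' @return An object of class `biomarker_network` with `nodes`
#'   (data.frame: biomarker, group), `edges`, and `groups` (registry).
#' @export
build_network <- function(edges, group_map) {
  stopifnot(is.data.frame(edges))
  if (nrow(edges)) {
    stopifnot(all(c("a", "b", "rho") %in% names(edges)))
    if (any(edges$a == edges$b)) stop("self-loop edge", call. = FALSE)
    key <- paste(pmin(edges$a, edges$b), pmax(edges$a, edges$b))
    if (anyDuplicated(key))
      stop("duplicate edge(s): ", paste(unique(key[duplicated(key)]), collapse = "; "),
           call. = FALSE)
    endpoints <- unique(c(edges$a, edges$b))
    unmapped <- setdiff(endpoints, names(group_map))
    if (length(unmapped))
      stop("edge endpoint(s) without group: ", paste(unmapped, collapse = ", "),
           call. = FALSE)
    edges <- edges[order(edges$a, edges$b), , drop = FALSE]
  } else {
    endpoints <- character(0)
    edges <- data.frame(a = character(0), b = character(0), rho = numeric(0),
                        stringsAsFactors = FALSE)
  }
  nodes <- data.frame(biomarker = sort(endpoints),
                      group = unname(group_map[sort(endpoints)]),
                      stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges,
                 groups = sort(unique(unname(group_map)))),
            class = "biomarker_network")
}

#' @export
print.biomarker_network <- function(x, ...) {
  cat(sprintf("biomarker_network: %d nodes, %d edges, groups: %s\n",
              nrow(x$nodes), nrow(x$edges),
              paste(sort(unique(x$nodes$group)), collapse = ", ")))
  invisible(x)
}

#' Convert a biomarker network to an igraph graph
#'
#' Node attributes `group`; edge attribute `rho`.
#'
#' @param net A `biomarker_network`.
#' @return An undirected `igraph` graph.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "biomarker_network"))
  if (nrow(net$nodes) == 0L)
    return(igraph::make_empty_graph(0, directed = FALSE))
  g <- igraph::graph_from_data_frame(
    net$edges[, c("a", "b", "rho"), drop = FALSE],
    directed = FALSE, vertices = net$nodes)
  g
}

#' Induced within-group subnetwork
#'
#' Keeps only the edges internal to one variable group, together with
#' their endpoints. Endpoints whose only edges cross group boundaries drop
#' out (the network invariant "no isolated nodes" is preserved).
#'
#' @param net A `biomarker_network`.
#' @param group A group name from the network's registry.
#' @return A `biomarker_network` restricted to that group.
#' @export
induced_group_subnetwork <- function(net, group) {
  stopifnot(inherits(net, "biomarker_network"))
  if (!group %in% net$groups)
    stop("unknown variable group: ", group, call. = FALSE)
  e <- net$edges
  keep <- if (nrow(e)) e$group_a == group & e$group_b == group else logical(0)
  sub <- e[keep, , drop = FALSE]
  gm <- stats::setNames(net$nodes$group, net$nodes$biomarker)
  out <- build_network(sub, gm)
  out$groups <- net$groups
  out
}

#' Collapse a biomarker network to the group level
#'
#' The meta-network view: variable groups become nodes, and any number of
#' cross-group biomarker edges between two groups is rendered as a single
#' connector (the underlying edge count is retained for reporting).
#' Within-group edge counts are tallied per group.
#'
#' @param net A `biomarker_network`.
#' @return An object of class `group_level_network`: `group_nodes`,
#'   `connectors` (data.frame group_a, group_b, n_edges), and
#'   `within_group_edge_counts` (named integer over the full registry).
#' @export
collapse_to_group_level <- function(net) {
  stopifnot(inherits(net, "biomarker_network"))
  e <- net$edges
  within <- stats::setNames(integer(length(net$groups)), net$groups)
  connectors <- data.frame(group_a = character(0), group_b = character(0),
                           n_edges = integer(0), stringsAsFactors = FALSE)
  if (nrow(e)) {
    w <- e[e$group_a == e$group_b, , drop = FALSE]
    if (nrow(w)) {
      tab <- table(w$group_a)
      within[names(tab)] <- as.integer(tab)
    }
    x <- e[e$group_a != e$group_b, , drop = FALSE]
    if (nrow(x)) {
      ga <- pmin(x$group_a, x$group_b)
      gb <- pmax(x$group_a, x$group_b)
      key <- paste(ga, gb, sep = "\r")
      tab <- table(key)
      parts <- strsplit(names(tab), "\r", fixed = TRUE)
      connectors <- data.frame(
        group_a = vapply(parts, `[[`, "", 1L),
        group_b = vapply(parts, `[[`, "", 2L),
        n_edges = as.integer(tab), stringsAsFactors = FALSE)
      connectors <- connectors[order(connectors$group_a, connectors$group_b), ,
                               drop = FALSE]
      rownames(connectors) <- NULL
    }
  }
  structure(list(group_nodes = sort(unique(net$nodes$group)),
                 connectors = connectors,
                 within_group_edge_counts = within),
            class = "group_level_network")
}

#' @export
print.group_level_network <- function(x, ...) {
  cat(sprintf("group_level_network: %d group(s), %d connector(s)\n",
              length(x$group_nodes), nrow(x$connectors)))
  if (nrow(x$connectors))
    cat(paste(sprintf("  %s -- %s (%d edge%s)", x$connectors$group_a,
                      x$connectors$group_b, x$connectors$n_edges,
                      ifelse(x$connectors$n_edges > 1L, "s", "")),
              collapse = "\n"), "\n")
  invisible(x)
}

#' Node degree
#'
#' Incident-edge count per node; the number of supra-threshold
#' correlations a biomarker has.
#'
#' @param net A `biomarker_network`.
#' @return Named integer vector over the network's nodes.
#' @export
node_degree <- function(net) {
  stopifnot(inherits(net, "biomarker_network"))
  if (nrow(net$nodes) == 0L) return(stats::setNames(integer(0), character(0)))
  d <- igraph::degree(as_igraph(net))
  d[net$nodes$biomarker]
}

#' Normalized betweenness centrality
#'
#' For each node v, the sum over unordered pairs (s, t), s != t != v, of
#' the fraction of shortest s-t paths passing through v; edges are
#' unweighted (|rho| is never used as a distance). The normalized form
#' divides by (n-1)(n-2)/2 where n is the node count of the graph being
#' scored, giving scores in \[0, 1\]; nodes in components of two or fewer
#' nodes score 0.
#'
#' @param net A `biomarker_network`.
#' @param normalized Divide by (n-1)(n-2)/2 (default `TRUE`).
#' @return Named numeric vector over the network's nodes.
#' @export
betweenness_centrality <- function(net, normalized = TRUE) {
  stopifnot(inherits(net, "biomarker_network"))
  n <- nrow(net$nodes)
  if (n == 0L) return(stats::setNames(numeric(0), character(0)))
  bc <- igraph::betweenness(as_igraph(net), directed = FALSE, weights = NA)
  bc <- bc[net$nodes$biomarker]
  if (normalized) {
    denom <- (n - 1) * (n - 2) / 2
    bc <- if (denom > 0) bc / denom else bc * 0
  }
  bc
}

#' Network density over a stated node universe
#'
#' Ratio of existing edges to the edges possible among `universe_size`
#' nodes. The universe is an explicit argument because the convention
#' matters: under the default pipeline configuration it is the measured
#' roster size of a variable group (dropped and unconnected biomarkers
#' included), not merely the connected node count.
#'
#' @param net A `biomarker_network`, or directly a nonnegative edge count.
#' @param universe_size Number of nodes in the denominator universe (>= 2).
#' @return Density in \[0, 1\].
#' @export
network_density <- function(net, universe_size) {
  edge_count <- if (inherits(net, "biomarker_network")) nrow(net$edges)
                else as.numeric(net)
  stopifnot(length(universe_size) == 1L, universe_size >= 2)
  possible <- universe_size * (universe_size - 1) / 2
  if (edge_count > possible)
    stop("edge count exceeds the possible edges of the stated universe",
         call. = FALSE)
  edge_count / possible
}

#' Detect hubs from betweenness scores
#'
#' A hub is a node whose normalized betweenness centrality is strictly
#' greater than the cutoff (default 0.1). Degree is reported alongside in
#' node metrics but plays no part in the criterion.
#'
#' @param bc Named numeric vector of normalized betweenness scores.
#' @param hub_bc_threshold Cutoff (strict "greater than").
#' @return Character vector of hub names, sorted by descending score.
#' @export
detect_hubs <- function(bc, hub_bc_threshold = 0.1) {
  hubs <- bc[bc > hub_bc_threshold]
  names(hubs)[order(-hubs, names(hubs))]
}

#' Per-node metric table
#'
#' Degree, normalized betweenness and hub flag for every node, with
#' betweenness scored on the configured scope: each group's induced
#' subgraph (default) or the full network. Rows are ordered by descending
#' betweenness, then descending degree, then name, so reports are
#' deterministic.
#'
#' @param net A `biomarker_network`.
#' @param config An [analysis_config].
#' @return `data.frame` with columns biomarker, group, degree, bc, is_hub.
#' @export
node_metrics <- function(net, config = analysis_config()) {
  stopifnot(inherits(net, "biomarker_network"))
  deg <- node_degree(net)
  if (config$bc_scope == "full_network") {
    bc <- betweenness_centrality(net)
  } else {
    bc <- stats::setNames(numeric(nrow(net$nodes)), net$nodes$biomarker)
    for (g in unique(net$nodes$group)) {
      sub <- induced_group_subnetwork(net, g)
      if (nrow(sub$nodes)) {
        sbc <- betweenness_centrality(sub)
        bc[names(sbc)] <- sbc
      }
    }
  }
  df <- data.frame(biomarker = net$nodes$biomarker,
                   group = net$nodes$group,
                   degree = as.integer(deg[net$nodes$biomarker]),
                   bc = unname(bc[net$nodes$biomarker]),
                   stringsAsFactors = FALSE)
  df$is_hub <- df$bc > config$hub_bc_threshold
  df <- df[order(-df$bc, -df$degree, df$biomarker), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Summarise one variable group's network properties
#'
#' The per-group row of a network report: within-group edge count, density
#' and betweenness-based hubs. Density uses the group's measured roster
#' size as the denominator universe by default (configurable to the
#' connected-node count); hub betweenness is scored on the configured
#' scope.
#'
#' @param net A `biomarker_network`.
#' @param group A group name.
#' @param roster Character vector: the group's measured roster (used for
#'   the default density universe).
#' @param config An [analysis_config].
#' @return An object of class `network_summary`: group, edge_count,
#'   density, hub_count, hub_names, universe_size.
#' @export
group_summary <- function(net, group, roster, config = analysis_config()) {
  stopifnot(inherits(net, "biomarker_network"))
  if (!group %in% net$groups)
    stop("unknown variable group: ", group, call. = FALSE)
  sub <- induced_group_subnetwork(net, group)
  edge_count <- nrow(sub$edges)
  universe <- switch(config$density_universe,
                     group_roster = length(roster),
                     connected_nodes = nrow(sub$nodes))
  density <- if (universe >= 2) network_density(edge_count, universe) else 0
  scope_net <- if (config$bc_scope == "full_network") net else sub
  group_nodes <- net$nodes$biomarker[net$nodes$group == group]
  bc <- betweenness_centrality(scope_net)
  bc <- bc[names(bc) %in% group_nodes]
  hubs <- detect_hubs(bc, config$hub_bc_threshold)
  structure(list(group = group, edge_count = edge_count, density = density,
                 hub_count = length(hubs), hub_names = hubs,
                 universe_size = universe),
            class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf("%s: %d edge(s), density %.2f, %d hub(s)%s\n",
              x$group, x$edge_count, x$density, x$hub_count,
              if (x$hub_count) paste0(" [", paste(x$hub_names, collapse = ", "), "]")
              else ""))
  invisible(x)
}

#' Write a biomarker network as GraphML
#'
#' Node attributes: group, degree, bc (scoped per `config`), is_hub; edge
#' attribute: rho.
#'
#' @param net A `biomarker_network`.
#' @param path Output path.
#' @param config An [analysis_config] (controls the bc scope recorded).
#' @export
write_graphml <- function(net, path, config = analysis_config()) {
  g <- as_igraph(net)
  if (nrow(net$nodes)) {
    nm <- node_metrics(net, config)
    nm <- nm[match(net$nodes$biomarker, nm$biomarker), ]
    igraph::V(g)$degree <- nm$degree
    igraph::V(g)$bc <- nm$bc
    igraph::V(g)$is_hub <- nm$is_hub
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write per-group network summaries as delimited text
#'
#' Reproduces the classic summary-table schema: network, edge_count,
#' density (2 d.p.), hub_count.
#'
#' @param summaries List of `network_summary` objects.
#' @param path Output path.
#' @param sep Field delimiter.
#' @export
write_group_summaries <- function(summaries, path, sep = ",") {
  df <- data.frame(
    network = vapply(summaries, `[[`, "", "group"),
    edge_count = vapply(summaries, function(s) as.integer(s$edge_count), 1L),
    density = sprintf("%.2f", vapply(summaries, `[[`, 1.0, "density")),
    hub_count = vapply(summaries, function(s) as.integer(s$hub_count), 1L),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Static plot of the group-collapsed network
#'
#' Cosmetic convenience: groups as cluster hulls, node size proportional
#' to degree, cross-group connectivity drawn once per group pair.
#'
#' @param net A `biomarker_network`.
#' @param ... Passed to `plot.igraph`.
#' @export
plot_group_network <- function(net, ...) {
  g <- as_igraph(net)
  if (igraph::vcount(g) == 0L) {
    graphics::plot.new()
    graphics::title("empty network")
    return(invisible(NULL))
  }
  deg <- igraph::degree(g)
  grp <- factor(igraph::V(g)$group)
  igraph::plot.igraph(
    g,
    vertex.size = 5 + 3 * deg,
    vertex.color = grDevices::rainbow(nlevels(grp))[as.integer(grp)],
    mark.groups = split(seq_along(grp), grp),
    edge.width = 1 + abs(igraph::E(g)$rho),
    ...)
  invisible(NULL)
}
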