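edge_df <- function(a, b, rho = 0.8, gm) {
  data.frame(a = a, b = b, rho = rho,
             group_a = unname(gm[a]), group_b = unname(gm[b]),
             within_group = unname(gm[a]) == unname(gm[b]),
             stringsAsFactors = FALSE)
}

test_that("build_network: nodes are exactly the edge endpoints", {
  gm <- c(a = "g", b = "g", c = "g")
  empty <- build_network(data.frame(), gm)
  expect_equal(nrow(empty$nodes), 0L)
  expect_equal(nrow(empty$edges), 0L)

  one <- build_network(edge_df("a", "b", gm = gm), gm)
  expect_setequal(one$nodes$biomarker, c("a", "b"))
  expect_equal(unname(node_degree(one)), c(1L, 1L))

  fix <- obese_immune_network()
  expect_equal(nrow(fix$nodes), 8L)
  expect_equal(nrow(fix$edges), 8L)
  expect_true(all(node_degree(fix) >= 1L))  # no isolated nodes by construction
})

test_that("build_network rejects duplicates, self-loops, unmapped endpoints", {
  gm <- c(a = "g", b = "g")
  dup <- rbind(edge_df("a", "b", gm = gm), edge_df("b", "a", gm = gm))
  expect_error(build_network(dup, gm), "duplicate edge")
  self <- edge_df("a", "a", gm = gm)
  expect_error(build_network(self, gm), "self-loop")
  expect_error(build_network(edge_df("a", "b", gm = gm), c(a = "g")),
               "without group")
})

test_that("induced subnetwork keeps exactly the within-group edges", {
  gm <- c(a = "G", b = "G", c = "G", d = "G", x = "H", y = "H")
  ed <- rbind(edge_df("a", "b", gm = gm), edge_df("b", "c", gm = gm),
              edge_df("c", "d", gm = gm),                      # 3 within G
              edge_df("a", "x", gm = gm), edge_df("d", "y", gm = gm))  # cross
  net <- build_network(ed, gm)
  sub <- induced_group_subnetwork(net, "G")
  expect_equal(nrow(sub$edges), 3L)
  expect_setequal(sub$nodes$biomarker, c("a", "b", "c", "d"))
  # a group connected only across boundaries induces an empty subnetwork
  subH <- induced_group_subnetwork(net, "H")
  expect_equal(nrow(subH$edges), 0L)
  expect_error(induced_group_subnetwork(net, "Z"), "unknown")
  # closure: an all-within network induces itself
  fix <- obese_immune_network()
  again <- induced_group_subnetwork(fix, "immune_cell")
  expect_identical(again$edges, fix$edges)
})

test_that("group-level collapse renders any cross-group bundle as one connector", {
  gm <- c(a = "A", b = "A", p = "B", q = "B", r = "B")
  ed <- rbind(edge_df("a", "p", gm = gm), edge_df("a", "q", gm = gm),
              edge_df("b", "r", gm = gm))
  gln <- collapse_to_group_level(build_network(ed, gm))
  expect_equal(nrow(gln$connectors), 1L)
  expect_equal(gln$connectors$n_edges, 3L)
  expect_equal(unname(gln$within_group_edge_counts), c(0L, 0L))
  # within counts tallied per group
  ed2 <- rbind(ed, edge_df("a", "b", gm = gm))
  gln2 <- collapse_to_group_level(build_network(ed2, gm))
  expect_equal(gln2$within_group_edge_counts[["A"]], 1L)
})

test_that("collapse agrees with a direct reconstruction from the edge list", {
  set.seed(33)
  groups <- c("anthropometric", "metabolic", "immune_cell", "cytokine",
              "microbiome")
  nodes <- sprintf("n%02d", 1:25)
  gm <- stats::setNames(sample(groups, 25, TRUE), nodes)
  for (rep in 1:10) {
    pairs <- t(utils::combn(nodes, 2))
    keep <- sample(nrow(pairs), 40)
    ed <- edge_df(pairs[keep, 1], pairs[keep, 2], gm = gm)
    gln <- collapse_to_group_level(build_network(ed, gm))
    cross <- ed[ed$group_a != ed$group_b, ]
    expected <- unique(paste(pmin(cross$group_a, cross$group_b),
                             pmax(cross$group_a, cross$group_b)))
    expect_setequal(paste(gln$connectors$group_a, gln$connectors$group_b),
                    expected)
    expect_equal(sum(gln$connectors$n_edges), nrow(cross))
    expect_equal(sum(gln$within_group_edge_counts),
                 sum(ed$group_a == ed$group_b))
  }
})

test_that("node degree: star, fixture, degree-sum invariant", {
  gm <- stats::setNames(rep("g", 5), c("c", "l1", "l2", "l3", "l4"))
  star <- build_network(edge_df(rep("c", 4), paste0("l", 1:4), gm = gm), gm)
  d <- node_degree(star)
  expect_equal(d[["c"]], 4L)
  expect_equal(unname(d[paste0("l", 1:4)]), rep(1L, 4))
  fix <- obese_immune_network()
  expect_equal(node_degree(fix)[["Cytotoxic_cells"]], 4L)
  expect_length(node_degree(build_network(data.frame(), gm)), 0L)
  set.seed(5)
  for (rep in 1:10) {
    net <- random_network(sample(4:12, 1), runif(1, 0.2, 0.8))
    expect_equal(sum(node_degree(net)), 2L * nrow(net$edges))
  }
})

test_that("betweenness matches hand-derived small cases", {
  gm <- stats::setNames(rep("g", 4), c("a", "b", "c", "d"))
  path <- build_network(edge_df(c("a", "b"), c("b", "c"), gm = gm), gm)
  expect_equal(betweenness_centrality(path)[["b"]], 1.0)
  expect_equal(betweenness_centrality(path)[["a"]], 0.0)
  # 4-cycle: each opposite pair has two shortest paths -> bc = (1/2)/3
  cyc <- build_network(edge_df(c("a", "b", "c", "d"),
                               c("b", "c", "d", "a"), gm = gm), gm)
  expect_equal(unname(betweenness_centrality(cyc)), rep(1 / 6, 4))
  # components of size <= 2 score zero
  two <- build_network(edge_df("a", "b", gm = gm), gm)
  expect_equal(unname(betweenness_centrality(two)), c(0, 0))
})

test_that("betweenness on the printed immune fixture: raw 12, normalized 12/21", {
  fix <- obese_immune_network()
  raw <- betweenness_centrality(fix, normalized = FALSE)
  oracle <- oracle_betweenness(fix$nodes$biomarker, fix$edges$a, fix$edges$b)
  expect_equal(raw, oracle[names(raw)], tolerance = 1e-12)
  expect_equal(raw[["Treg"]], 12)
  expect_equal(betweenness_centrality(fix)[["Treg"]], 12 / 21)
})

test_that("betweenness equals the brute-force oracle on random graphs", {
  set.seed(99)
  for (rep in 1:40) {
    net <- random_network(sample(4:10, 1), runif(1, 0.1, 0.9))
    if (nrow(net$nodes) == 0L) next
    raw <- betweenness_centrality(net, normalized = FALSE)
    oracle <- oracle_betweenness(net$nodes$biomarker, net$edges$a, net$edges$b)
    expect_equal(raw, oracle[names(raw)], tolerance = 1e-12)
    norm <- betweenness_centrality(net)
    expect_true(all(norm >= 0 & norm <= 1))
  }
})

test_that("network density follows the stated-universe convention", {
  expect_equal(round(network_density(11, 16), 2), 0.09)
  expect_equal(round(network_density(7, 16), 2), 0.06)
  gm <- stats::setNames(rep("g", 4), letters[1:4])
  pairs <- t(utils::combn(letters[1:4], 2))
  complete <- build_network(edge_df(pairs[, 1], pairs[, 2], gm = gm), gm)
  expect_equal(network_density(complete, 4), 1.0)
  expect_error(network_density(3, 1), "universe_size")
  expect_error(network_density(10, 4), "exceeds")
})

test_that("hub rule is strictly greater-than, sorted by descending score", {
  bc <- c(Treg = 0.22, Neutrophils = 0.20, Cytotoxic_cells = 0.15,
          Mast_cells = 0.10, T_cells = 0.04)
  expect_identical(detect_hubs(bc, 0.1),
                   c("Treg", "Neutrophils", "Cytotoxic_cells"))
  expect_length(detect_hubs(c(a = 0, b = 0), 0.1), 0L)
  expect_false("Mast_cells" %in% detect_hubs(bc, 0.1))  # exactly at cutoff
})

test_that("group_summary reproduces the roster-denominator densities", {
  fix <- obese_immune_network()
  roster16 <- c(fix$nodes$biomarker,
                paste0("other", 1:8))  # measured universe of 16 immune cells
  cfg <- analysis_config()
  s <- group_summary(fix, "immune_cell", roster16, cfg)
  expect_equal(s$edge_count, 8L)
  expect_equal(s$universe_size, 16L)
  expect_equal(s$density, 8 / choose(16, 2))
  expect_setequal(s$hub_names, c("Treg", "Neutrophils", "Cytotoxic_cells"))
  # connected-node denominator is the selectable alternative
  cfg2 <- analysis_config(density_universe = "connected_nodes")
  s2 <- group_summary(fix, "immune_cell", roster16, cfg2)
  expect_equal(s2$density, 8 / choose(8, 2))
  # an empty subnetwork summarises to zeros
  gm <- c(a = "G", x = "H", y = "H")
  cross <- build_network(edge_df("a", "x", gm = gm), gm)
  s0 <- group_summary(cross, "G", c("a", "b"), cfg)
  expect_equal(s0$edge_count, 0L)
  expect_equal(s0$density, 0)
  expect_equal(s0$hub_count, 0L)
})

test_that("node_metrics orders deterministically and scopes betweenness", {
  fix <- obese_immune_network()
  nm <- node_metrics(fix, analysis_config())
  expect_identical(nm$biomarker[1], "Treg")
  expect_true(all(diff(nm$bc) <= 0))
  expect_identical(nm$is_hub, nm$bc > 0.1)
  # full-network scope equals within-group scope when one group spans all
  nm2 <- node_metrics(fix, analysis_config(bc_scope = "full_network"))
  expect_equal(nm, nm2)
})

test_that("GraphML and summary writers emit readable artifacts", {
  fix <- obese_immune_network()
  f <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(fix, f)
  g <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::vcount(g), 8)
  expect_equal(igraph::ecount(g), 8)
  expect_true(all(c("group", "degree", "bc", "is_hub") %in%
                    igraph::vertex_attr_names(g)))
  expect_true("rho" %in% igraph::edge_attr_names(g))

  s <- group_summary(fix, "immune_cell", c(fix$nodes$biomarker, paste0("o", 1:8)))
  fcsv <- withr::local_tempfile(fileext = ".csv")
  write_group_summaries(list(s), fcsv)
  back <- utils::read.csv(fcsv, colClasses = "character")
  expect_identical(back$density, "0.07")  # 8/120 at report precision
  expect_identical(back$network, "immune_cell")

  fpng <- withr::local_tempfile(fileext = ".png")
  grDevices::png(fpng); plot_group_network(fix); grDevices::dev.off()
  expect_true(file.size(fpng) > 0)
})
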