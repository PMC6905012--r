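# Independent oracles and in-code fixtures shared across the suite.

# Two-pass textbook Pearson coefficient, independent of stats::cor.
oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Brute-force betweenness: enumerate every shortest path between every
# unordered pair by BFS layered expansion, crediting interior nodes
# fractionally. Returns raw (unnormalized) scores.
oracle_betweenness <- function(nodes, a, b) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (k in seq_along(a)) {
    adj[[a[k]]] <- c(adj[[a[k]]], b[k])
    adj[[b[k]]] <- c(adj[[b[k]]], a[k])
  }
  bc <- stats::setNames(numeric(length(nodes)), nodes)
  bfs_dist <- function(s) {
    dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
    dist[s] <- 0
    q <- s
    while (length(q)) {
      v <- q[1L]; q <- q[-1L]
      for (w in adj[[v]]) if (!is.finite(dist[w])) {
        dist[w] <- dist[v] + 1
        q <- c(q, w)
      }
    }
    dist
  }
  for (i in seq_along(nodes)) {
    s <- nodes[i]
    dist <- bfs_dist(s)
    for (j in seq_along(nodes)) {
      if (j <= i) next
      t <- nodes[j]
      if (!is.finite(dist[t])) next
      # enumerate all shortest s->t paths backwards through BFS layers
      enum <- function(v) {
        if (v == s) return(list(s))
        preds <- adj[[v]][dist[adj[[v]]] == dist[v] - 1]
        out <- list()
        for (p in unique(preds))
          for (pp in enum(p)) out <- c(out, list(c(pp, v)))
        out
      }
      paths <- enum(t)
      interior <- lapply(paths, function(p) p[-c(1L, length(p))])
      for (p in interior)
        for (v in p) bc[v] <- bc[v] + 1 / length(paths)
    }
  }
  bc
}

# The eight published within-immune edges of the disease cohort: the
# canonical small network fixture (8 nodes, 8 edges).
obese_immune_edges <- function() {
  data.frame(
    a = c("Treg", "Treg", "Treg", "Neutrophils", "Neutrophils",
          "Cytotoxic_cells", "Cytotoxic_cells", "Cytotoxic_cells"),
    b = c("Neutrophils", "Cytotoxic_cells", "T_cells", "Macrophages",
          "NK_cells", "Th1_cells", "T_cells", "CD8_T_cells"),
    rho = c(0.73, -0.73, -0.74, 0.80, 0.74, 0.78, 0.77, 0.74),
    stringsAsFactors = FALSE)
}

immune_group_map <- function(extra = character(0)) {
  ed <- obese_immune_edges()
  nm <- unique(c(ed$a, ed$b, extra))
  stats::setNames(rep("immune_cell", length(nm)), nm)
}

obese_immune_network <- function() {
  ed <- obese_immune_edges()
  ed$group_a <- "immune_cell"; ed$group_b <- "immune_cell"
  ed$within_group <- TRUE
  build_network(ed, immune_group_map())
}

# Random Erdos-Renyi network over letter-named nodes, one shared group.
random_network <- function(n, p_edge) {
  nodes <- sprintf("v%02d", seq_len(n))
  pairs <- t(utils::combn(nodes, 2L))
  keep <- stats::runif(nrow(pairs)) < p_edge
  ed <- data.frame(a = pairs[keep, 1L], b = pairs[keep, 2L],
                   rho = stats::runif(sum(keep), 0.7, 1),
                   stringsAsFactors = FALSE)
  gm <- stats::setNames(rep("g", n), nodes)
  build_network(ed, gm)
}

# Small complete two-group table fixture used across io/correlation tests.
toy_table <- function() {
  vals <- cbind(x1 = c(1, 2, 3, 4, 5),
                x2 = c(2, 4, 6, 8, 10),
                y1 = c(5, 3, 4, 1, 2),
                y2 = c(1.2, 0.7, 2.5, 1.9, 0.4))
  rownames(vals) <- paste0("s", 1:5)
  biomarker_table(vals, rep("disease", 5),
                  c(x1 = "metabolic", x2 = "metabolic",
                    y1 = "cytokine", y2 = "cytokine"))
}

# Sample a biomarker table with a given true correlation matrix (Gaussian,
# unit scale) - independent of simulate_cohort's machinery.
sample_gaussian_table <- function(target, n, group_map, cohort = "disease") {
  ch <- chol(target + diag(1e-9, nrow(target)))
  z <- matrix(stats::rnorm(n * nrow(target)), n) %*% ch
  dimnames(z) <- list(sprintf("s%04d", seq_len(n)), colnames(target))
  biomarker_table(z, rep(cohort, n), group_map)
}
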