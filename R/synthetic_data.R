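# Seeded synthetic two-cohort generator: Gaussian copula over a target
# correlation matrix with planted blocks and hubs, lognormal or Gaussian
# marginals, small-n cohorts, optional MCAR missingness.

#' Default variable-group rosters
#'
#' Five groups sized like a typical multi-analyte obesity panel:
#' anthropometric (8), metabolic (12), immune cell abundance (16, the
#' classic immune-profiling cell types), serum cytokines (25) and gut
#' microbial genera (30).
#'
#' @return Named list of character vectors.
#' @export
default_rosters <- function() {
  list(
    anthropometric = c("Age", "BMI", "Waist", "Fat_mass", "Muscle_mass",
                       "Visceral_fat", "WHR", "RMR"),
    metabolic = c("SBP", "DBP", "Triglycerides", "Cholesterol", "HDL", "LDL",
                  "HbA1c", "Glucose", "CRP", "ESR", "HCT", "PLT"),
    immune_cell = c("Mast_cells", "NK_cells", "CD8_T_cells", "DC", "Treg",
                    "CD45", "Macrophages", "T_cells", "Neutrophils",
                    "Cytotoxic_cells", "Th1_cells", "Normal_mucosa",
                    "T_helper_cells", "B_cells", "Th2_cells", "CD4_activated"),
    cytokine = c("IL1b", "IL2", "IL4", "IL5", "IL6", "IL7", "IL8", "IL9",
                 "IL10", "IL12", "IL13", "IL15", "IL17", "TNFa", "IFNg",
                 "VEGF", "PDGF", "GCSF", "GMCSF", "MIP1a", "MIP1b", "IP10",
                 "MCP1", "RANTES", "Eotaxin"),
    microbiome = c("Bacteroides", "Prevotella", "Faecalibacterium", "Blautia",
                   "Holdemania", "Akkermansia", "Anaerostipes",
                   "Flavonifractor", "Escherichia_Shigella", "Roseburia",
                   "Ruminococcus", "Bifidobacterium", "Lactobacillus",
                   "Clostridium", "Dorea", "Coprococcus", "Oscillibacter",
                   "Alistipes", "Parabacteroides", "Dialister", "Veillonella",
                   "Streptococcus", "Collinsella", "Eubacterium",
                   "Butyricicoccus", "Subdoligranulum",
                   "Phascolarctobacterium", "Sutterella", "Desulfovibrio",
                   "Methanobrevibacter"))
}

.default_marginals <- function() {
  # latent (log-scale) location/scale per group; immune-cell values sit on a
  # log2-like abundance-score scale around 2-12 with sd 0.2-0.7
  list(location = c(anthropometric = 4.0, metabolic = 1.5, immune_cell = 7.0,
                    cytokine = 2.5, microbiome = 1.0),
       scale = c(anthropometric = 0.3, metabolic = 0.4, immune_cell = 0.5,
                 cytokine = 0.8, microbiome = 1.0))
}

#' Synthetic-cohort generation recipe
#'
#' The full stated world of a simulation: group rosters, per-cohort sample
#' sizes (defaults 11 disease / 12 control, the small-n regime the
#' pipeline is designed for), planted signed correlations, background
#' correlation shell, marginal family, missing rate and seed.
#'
#' Planted correlations may be given as a plant list (`data.frame` with
#' columns `cohort`, `a`, `b`, `rho`) and/or as an explicit per-cohort
#' target matrix (which wins where both are present). Plants that overlap
#' into chains or hubs should be supplied through an explicit target (see
#' [markov_target]) because a hub center cannot have several
#' highly-correlated but mutually-uncorrelated spokes; positive
#' semidefiniteness forbids it. Whatever the recipe, the matrix actually
#' used is the nearest-correlation repair of the specification, and the
#' ground truth records the repaired entries.
#'
#' @param rosters Named list of group rosters.
#' @param n_per_cohort Named integer vector, cohort -> sample count.
#' @param plants `data.frame(cohort, a, b, rho)` of planted correlations.
#' @param target Optional named list, cohort -> explicit symmetric
#'   unit-diagonal target matrix over all biomarkers.
#' @param hubs Optional named list, cohort -> character vector of planted
#'   hub centers (ground-truth bookkeeping only).
#' @param background_rho_max Background off-diagonal correlations are
#'   drawn i.i.d. uniform in (-background_rho_max, background_rho_max);
#'   default 0.1, a near-zero shell that survives PSD repair essentially
#'   unchanged.
#' @param marginal `"lognormal"` (default; analyse on the log scale) or
#'   `"gaussian"`.
#' @param location,scale Named per-group latent location/scale.
#' @param missing_rate MCAR missing-cell fraction in \[0, 1).
#' @param seed Integer seed; every cohort draw is a pure function of
#'   (seed, cohort).
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(rosters = default_rosters(),
                             n_per_cohort = c(disease = 11L, control = 12L),
                             plants = NULL, target = NULL, hubs = NULL,
                             background_rho_max = 0.1,
                             marginal = c("lognormal", "gaussian"),
                             location = NULL, scale = NULL,
                             missing_rate = 0, seed = 1L) {
  stopifnot(missing_rate >= 0, missing_rate < 1,
            background_rho_max >= 0, background_rho_max < 1,
            all(n_per_cohort >= 2))
  marg <- .default_marginals()
  if (is.null(location)) location <- marg$location[names(rosters)]
  if (is.null(scale)) scale <- marg$scale[names(rosters)]
  location[is.na(location)] <- 0; scale[is.na(scale)] <- 1
  names(location) <- names(scale) <- names(rosters)
  all_bm <- unlist(rosters, use.names = FALSE)
  if (anyDuplicated(all_bm))
    stop("rosters must be disjoint", call. = FALSE)
  if (!is.null(plants)) {
    stopifnot(all(c("cohort", "a", "b", "rho") %in% names(plants)))
    missing_bm <- setdiff(c(plants$a, plants$b), all_bm)
    if (length(missing_bm))
      stop("planted biomarker(s) not in any roster: ",
           paste(missing_bm, collapse = ", "), call. = FALSE)
    stopifnot(all(abs(plants$rho) < 1), all(plants$a != plants$b))
  }
  structure(list(rosters = rosters, n_per_cohort = n_per_cohort,
                 plants = plants, target = target, hubs = hubs,
                 background_rho_max = background_rho_max,
                 marginal = match.arg(marginal),
                 location = location, scale = scale,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Nearest valid correlation matrix by alternating projections
#'
#' Projects alternately onto the positive-semidefinite cone and the
#' unit-diagonal affine set, with Dykstra's correction, giving the nearest
#' (Frobenius) valid correlation matrix. Hand-specified block recipes are
#' frequently indefinite; silent sampling from an invalid target is
#' unacceptable, so every target passes through here. Already-valid input
#' is a fixed point.
#'
#' @param m Symmetric matrix with unit diagonal.
#' @param tol Convergence tolerance on the iterate change and on the
#'   minimum eigenvalue (default 1e-8).
#' @param maxit Maximum iterations (default 200).
#' @return The repaired correlation matrix.
#' @export
nearest_correlation_repair <- function(m, tol = 1e-8, maxit = 200L) {
  if (!is.matrix(m) || nrow(m) != ncol(m) ||
      !isSymmetric(unname(m), tol = 1e-10))
    stop("input must be a symmetric square matrix", call. = FALSE)
  if (max(abs(diag(m) - 1)) > 1e-10)
    stop("input must have unit diagonal", call. = FALSE)
  dn <- dimnames(m)
  y <- unname(m)
  ds <- matrix(0, nrow(y), ncol(y))
  for (it in seq_len(maxit)) {
    r <- y - ds
    e <- eigen(r, symmetric = TRUE)
    x <- e$vectors %*% (pmax(e$values, 0) * t(e$vectors))
    x <- (x + t(x)) / 2
    ds <- x - r
    y_new <- x
    diag(y_new) <- 1
    if (max(abs(y_new - y)) < tol &&
        min(eigen(y_new, symmetric = TRUE, only.values = TRUE)$values) > -tol) {
      y <- y_new
      break
    }
    y <- y_new
  }
  y <- pmin(pmax(y, -1), 1)
  diag(y) <- 1
  dimnames(y) <- dn
  y
}

#' Markov completion of a planted edge skeleton
#'
#' Completes a sparse set of planted signed correlations into a full
#' target matrix by assigning every other pair in the same connected
#' component the signed product of plant weights along a shortest path
#' (the Gaussian Markov / junction-tree extension). For trees and
#' sign-balanced cliques this yields an exactly valid correlation matrix,
#' which is the only way to plant a hub: a center correlated at rho with k
#' spokes forces spoke-spoke correlations near rho^2, so "hub at 0.8,
#' spokes mutually uncorrelated" is not a correlation matrix for k > 1.
#'
#' @param biomarkers Full ordered biomarker vector.
#' @param edges `data.frame(a, b, rho)` of planted signed correlations.
#' @return Symmetric unit-diagonal matrix; unplanted cross-component and
#'   background entries are 0.
#' @export
markov_target <- function(biomarkers, edges) {
  p <- length(biomarkers)
  m <- diag(p)
  dimnames(m) <- list(biomarkers, biomarkers)
  if (is.null(edges) || !nrow(edges)) return(m)
  g <- igraph::graph_from_data_frame(edges[, c("a", "b")], directed = FALSE,
                                     vertices = intersect(biomarkers,
                                                          unique(c(edges$a, edges$b))))
  igraph::E(g)$w <- edges$rho
  comp <- igraph::components(g)
  for (cid in seq_len(comp$no)) {
    vs <- igraph::V(g)$name[comp$membership == cid]
    for (i in seq_along(vs)) {
      paths <- igraph::shortest_paths(g, from = vs[i], to = vs,
                                      output = "epath")
      for (j in seq_along(vs)) {
        if (j == i) next
        m[vs[i], vs[j]] <- prod(igraph::E(g)$w[paths$epath[[j]]])
      }
    }
  }
  (m + t(m)) / 2 -> m
  diag(m) <- 1
  m
}

# Low-rank Gram background correlation block: exactly PSD with small
# off-diagonals (sd ~ shell/2, so the shell bound is a ~4-sigma envelope).
.background_block <- function(m_size, shell, k = 3L) {
  if (m_size < 2L || shell <= 0) return(diag(m_size))
  w <- matrix(stats::rnorm(m_size * k), m_size, k)
  delta <- sqrt(k) / (shell / 2) - k
  s <- tcrossprod(w) + diag(delta, m_size)
  stats::cov2cor(s)
}

.cohort_target <- function(cfg, cohort) {
  biomarkers <- unlist(cfg$rosters, use.names = FALSE)
  p <- length(biomarkers)
  if (!is.null(cfg$target) && !is.null(cfg$target[[cohort]])) {
    m <- cfg$target[[cohort]]
    stopifnot(identical(dim(m), c(p, p)))
    if (is.null(dimnames(m))) dimnames(m) <- list(biomarkers, biomarkers)
    m <- m[biomarkers, biomarkers]
  } else {
    m <- diag(p)
    dimnames(m) <- list(biomarkers, biomarkers)
  }
  # explicit plants override the specified structure
  pl <- cfg$plants
  if (!is.null(pl)) {
    pl <- pl[pl$cohort == cohort, , drop = FALSE]
    for (k in seq_len(nrow(pl)))
      m[pl$a[k], pl$b[k]] <- m[pl$b[k], pl$a[k]] <- pl$rho[k]
  }
  # background shell only among nodes free of planted structure: keeping
  # the structured block and the background block orthogonal makes the
  # whole target exactly block-PSD, so repair does not erode the plants
  if (cfg$background_rho_max > 0) {
    structured <- rowSums(abs(m) > 0) > 1L  # any off-diagonal entry
    free <- which(!structured)
    if (length(free) >= 2L)
      m[free, free] <- .background_block(length(free),
                                         cfg$background_rho_max)
  }
  nearest_correlation_repair(m)
}

.cohort_seed <- function(cfg, cohort) {
  idx <- match(cohort, names(cfg$n_per_cohort))
  (cfg$seed + 7919L * idx) %% .Machine$integer.max
}

#' Simulate one cohort table
#'
#' Draws a multivariate normal with the repaired target correlation,
#' places each group on its latent location/scale, then maps to the
#' configured marginals (lognormal: exponentiate, so the planted Pearson
#' structure is exact on the log scale where the pipeline analyses;
#' Pearson correlations of the raw lognormal values would differ).
#' Missing cells are injected completely at random. Fully reproducible:
#' the draw is a function of (seed, cohort) only.
#'
#' @param cfg A [synthetic_config].
#' @param cohort Cohort name from `cfg$n_per_cohort`.
#' @param n Optional sample-size override (e.g. inflated "test mode").
#' @return `list(table = <biomarker_table>, truth = <ground truth>)`. The
#'   ground truth carries `planted_edges` (with the post-repair rho
#'   actually generated), `planted_hubs`, and the full repaired `target`.
#' @export
simulate_cohort <- function(cfg, cohort, n = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (!cohort %in% names(cfg$n_per_cohort))
    stop("unknown cohort: ", cohort, call. = FALSE)
  if (is.null(n)) n <- cfg$n_per_cohort[[cohort]]
  set.seed(.cohort_seed(cfg, cohort))
  target <- .cohort_target(cfg, cohort)
  biomarkers <- colnames(target)
  p <- length(biomarkers)
  # small ridge guards the Cholesky against the repair's -1e-8 eigen slack
  ch <- chol(target + diag(1e-7, p))
  z <- matrix(stats::rnorm(n * p), n, p) %*% ch
  group_of <- rep(names(cfg$rosters), lengths(cfg$rosters))
  latent <- sweep(sweep(z, 2L, cfg$scale[group_of], `*`), 2L,
                  cfg$location[group_of], `+`)
  vals <- if (cfg$marginal == "lognormal") exp(latent) else latent
  dimnames(vals) <- list(sprintf("%s_%02d", cohort, seq_len(n)), biomarkers)
  if (cfg$missing_rate > 0) {
    miss <- stats::runif(length(vals)) < cfg$missing_rate
    vals[miss] <- NA_real_
  }
  group_map <- stats::setNames(group_of, biomarkers)
  tbl <- biomarker_table(vals, rep(cohort, n), group_map,
                         rosters = cfg$rosters)
  pl <- cfg$plants
  if (!is.null(pl)) pl <- pl[pl$cohort == cohort, , drop = FALSE]
  planted <- if (!is.null(pl) && nrow(pl)) {
    data.frame(a = pmin(pl$a, pl$b), b = pmax(pl$a, pl$b),
               rho_spec = pl$rho,
               rho_true = mapply(function(a, b) target[a, b], pl$a, pl$b),
               stringsAsFactors = FALSE)
  } else {
    data.frame(a = character(0), b = character(0),
               rho_spec = numeric(0), rho_true = numeric(0))
  }
  hubs <- if (!is.null(cfg$hubs) && !is.null(cfg$hubs[[cohort]]))
    cfg$hubs[[cohort]] else character(0)
  list(table = tbl,
       truth = list(cohort = cohort, planted_edges = planted,
                    planted_hubs = hubs, target = target,
                    seed = .cohort_seed(cfg, cohort)))
}

#' Study-emulation plant list
#'
#' The planted signed correlation skeleton of [make_study_emulation],
#' exposed for tests: disease carries the within-immune hub topology
#' (three centers: Treg, neutrophils, cytotoxic cells), cross-group
#' plants for all ten group pairs and one within-group pair per remaining
#' group; control carries disjoint pairs giving eight group-pair
#' connectors — none touching anthropometric or metabolic from the immune
#' side — and no hubs.
#'
#' @param rho_tree Edge weight of the connected immune hub component
#'   (default 0.8: the Markov completion then implies second-neighbour
#'   correlations of 0.64, safely below the 0.7 threshold, which |0.85|
#'   would not be).
#' @param rho_pair Weight of isolated planted pairs (default 0.85).
#' @return `data.frame(cohort, a, b, rho)`.
#' @export
study_emulation_plants <- function(rho_tree = 0.8, rho_pair = 0.85) {
  tree <- data.frame(
    a = c("Treg", "Treg", "Treg", "Neutrophils", "Neutrophils",
          "Cytotoxic_cells", "Cytotoxic_cells", "Cytotoxic_cells",
          "Treg", "Neutrophils", "Neutrophils"),
    b = c("Neutrophils", "Cytotoxic_cells", "T_cells", "Macrophages",
          "NK_cells", "Th1_cells", "T_cells", "CD8_T_cells",
          "MIP1b", "Holdemania", "Blautia"),
    rho = rho_tree * c(1, -1, -1, 1, 1, 1, 1, 1, 1, 1, 1),
    stringsAsFactors = FALSE)
  disease_pairs <- data.frame(
    a = c("Age", "SBP", "BMI", "Fat_mass", "Waist", "CRP", "Glucose", "IL10",
          "BMI", "Cholesterol", "IL4", "Dorea"),
    b = c("Th2_cells", "Mast_cells", "Triglycerides", "IL6", "Bacteroides",
          "TNFa", "Prevotella", "Faecalibacterium",
          "Waist", "LDL", "IL13", "Roseburia"),
    rho = rho_pair * c(-1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1),
    stringsAsFactors = FALSE)
  control_pairs <- data.frame(
    a = c("Th2_cells", "B_cells", "BMI", "Fat_mass", "Waist", "CRP",
          "Glucose", "IL10",
          "Mast_cells", "NK_cells", "DC", "Macrophages", "Th1_cells",
          "Normal_mucosa", "T_cells"),
    b = c("IL4", "Roseburia", "Triglycerides", "IL6", "Bacteroides", "TNFa",
          "Prevotella", "Faecalibacterium",
          "T_helper_cells", "CD8_T_cells", "CD45", "B_cells", "Treg",
          "CD4_activated", "Cytotoxic_cells"),
    rho = rho_pair * c(1, 1, 1, 1, 1, 1, 1, 1, -1, 1, 1, 1, 1, 1, 1),
    stringsAsFactors = FALSE)
  rbind(cbind(cohort = "disease", rbind(tree, disease_pairs)),
        cbind(cohort = "control", control_pairs))
}

#' Generate the two-cohort study emulation
#'
#' A stand-in for the study design the pipeline targets: a small "disease"
#' cohort (n = 11) whose true correlation structure carries three immune
#' hub centers (Treg, neutrophils, cytotoxic cells) and at least one
#' cross-group correlation for every one of the ten group pairs, and a
#' "control" cohort (n = 12) with no hubs and no immune-anthropometric or
#' immune-metabolic connectivity. Connected plant components are completed
#' to exact correlation matrices with [markov_target]; everything else
#' follows [simulate_cohort].
#'
#' @param seed Integer seed.
#' @param n_disease,n_control Cohort sizes (defaults 11 and 12; inflate
#'   for large-n recovery tests).
#' @param missing_rate MCAR missing fraction (default 0).
#' @param background_rho_max Background shell half-width (default 0.1).
#' @return `list(disease = <biomarker_table>, control = <biomarker_table>,
#'   truth = <per-cohort ground truths>, config = <synthetic_config>)`.
#' @export
make_study_emulation <- function(seed = 1L, n_disease = 11L, n_control = 12L,
                                 missing_rate = 0, background_rho_max = 0.1) {
  rosters <- default_rosters()
  biomarkers <- unlist(rosters, use.names = FALSE)
  plants <- study_emulation_plants()
  targets <- lapply(c(disease = "disease", control = "control"), function(co)
    markov_target(biomarkers, plants[plants$cohort == co, , drop = FALSE]))
  cfg <- synthetic_config(
    rosters = rosters,
    n_per_cohort = c(disease = as.integer(n_disease),
                     control = as.integer(n_control)),
    plants = plants, target = targets,
    hubs = list(disease = c("Treg", "Neutrophils", "Cytotoxic_cells"),
                control = character(0)),
    background_rho_max = background_rho_max,
    missing_rate = missing_rate, seed = seed)
  dis <- simulate_cohort(cfg, "disease")
  ctl <- simulate_cohort(cfg, "control")
  list(disease = dis$table, control = ctl$table,
       truth = list(disease = dis$truth, control = ctl$truth),
       config = cfg)
}

#' Write a simulation's ground truth as JSON
#'
#' Planted edges (specified and post-repair rho), planted hubs and seed,
#' for external test harnesses.
#'
#' @param truth Ground-truth list from [simulate_cohort] or the `truth`
#'   element of [make_study_emulation].
#' @param path Output path.
#' @export
write_ground_truth <- function(truth, path) {
  strip <- function(tr) tr[setdiff(names(tr), "target")]
  out <- if (!is.null(truth$planted_edges)) strip(truth) else lapply(truth, strip)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
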