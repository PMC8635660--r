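#' Per-node topological parameters
#'
#' Computes the five node-level parameters used for core-network
#' extraction: degree, betweenness centrality (normalized by
#' \eqn{(n-1)(n-2)/2} for undirected graphs), closeness centrality
#' (computed within each connected component and normalized to \[0, 1\]),
#' local clustering coefficient, and the topological coefficient.
#'
#' The topological coefficient of a node \eqn{v} with degree \eqn{k_v \ge 2}
#' is the mean, over all nodes \eqn{m} sharing at least one neighbour with
#' \eqn{v}, of \eqn{J(v, m) / k_v}, where \eqn{J(v, m)} is the number of
#' shared neighbours plus one if \eqn{m} is adjacent to \eqn{v}. Nodes with
#' fewer than two neighbours get 0, as do isolated nodes for every
#' parameter.
#'
#' @param net A [pharm_network()] or an igraph graph.
#' @return A tibble with columns `node_id`, `degree`, `betweenness`,
#'   `closeness`, `clustering_coefficient`, `topological_coefficient`.
#' @export
node_topology_profiles <- function(net) {
  g <- as_igraph(net)
  n <- igraph::vcount(g)
  if (n == 0) abort("empty graph")
  deg <- igraph::degree(g)

  btw <- igraph::betweenness(g, directed = FALSE)
  denom <- (n - 1) * (n - 2) / 2
  btw <- if (denom > 0) btw / denom else rep(0, n)

  d <- igraph::distances(g)
  finite <- is.finite(d) & d > 0
  clo <- vapply(seq_len(n), function(i) {
    reach <- sum(finite[i, ])
    if (reach == 0) return(0)
    reach / sum(d[i, finite[i, ]])
  }, numeric(1))

  cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  cc[deg < 2] <- 0

  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  shared <- A %*% A
  tc <- vapply(seq_len(n), function(i) {
    if (deg[i] < 2) return(0)
    m <- which(shared[i, ] > 0 & seq_len(n) != i)
    if (length(m) == 0) return(0)
    mean((shared[i, m] + A[i, m]) / deg[i])
  }, numeric(1))

  tibble(node_id = igraph::V(g)$name %||% as.character(seq_len(n)),
         degree = as.integer(unname(deg)),
         betweenness = unname(btw),
         closeness = unname(clo),
         clustering_coefficient = unname(cc),
         topological_coefficient = unname(tc))
}

#' Network-level stability indicators
#'
#' Four whole-network summaries used to quantify how a knockout perturbs
#' the network:
#' \describe{
#'   \item{NC, network centralization}{Freeman-style degree centralization
#'     \eqn{\frac{n}{n-2}\left(\frac{d_{max}}{n-1} - density\right)}, in
#'     \[0, 1\]: 1 for a star, 0 for any regular (e.g. complete) graph.}
#'   \item{CPL, characteristic path length}{Mean shortest-path length over
#'     all unordered connected node pairs; disconnected pairs are excluded
#'     from the average.}
#'   \item{NH, network heterogeneity}{Coefficient of variation of the
#'     degree sequence (population variance); 0 iff all degrees are equal.}
#'   \item{R, robustness}{Fraction of surviving nodes contained in the
#'     largest connected component, \eqn{C / (N - N_r)} where \eqn{C} is
#'     the largest component size, \eqn{N} the original node count and
#'     \eqn{N_r} the number of knocked-out nodes; 1 iff the survivor is
#'     connected.}
#' }
#'
#' @param net A [pharm_network()] or igraph graph (the surviving graph,
#'   for a knockout).
#' @name stability-indicators
NULL

#' @rdname stability-indicators
#' @return `network_centralization()`: NC in \[0, 1\]. Requires n >= 3.
#' @export
network_centralization <- function(net) {
  g <- as_igraph(net)
  n <- igraph::vcount(g)
  if (n < 3) abort("network centralization needs at least 3 nodes")
  deg <- igraph::degree(g)
  density <- 2 * igraph::ecount(g) / (n * (n - 1))
  (n / (n - 2)) * (max(deg) / (n - 1) - density)
}

#' @rdname stability-indicators
#' @return `characteristic_path_length()`: mean shortest-path length over
#'   connected pairs. Requires at least one edge.
#' @export
characteristic_path_length <- function(net) {
  g <- as_igraph(net)
  if (igraph::ecount(g) == 0) abort("characteristic path length needs at least one edge")
  d <- igraph::distances(g)
  vals <- d[upper.tri(d)]
  mean(vals[is.finite(vals)])
}

#' @rdname stability-indicators
#' @return `network_heterogeneity()`: coefficient of variation of the
#'   degree sequence. Requires mean degree > 0.
#' @export
network_heterogeneity <- function(net) {
  g <- as_igraph(net)
  deg <- igraph::degree(g)
  mu <- mean(deg)
  if (mu == 0) abort("network heterogeneity undefined for an all-isolated graph")
  sqrt(mean((deg - mu)^2)) / mu
}

#' @rdname stability-indicators
#' @param n_original Node count of the network before knockout.
#' @param n_removed Number of knocked-out nodes.
#' @return `robustness()`: R in (0, 1], with attributes `C` (largest
#'   component size), `N` and `Nr` so either reading of the formula can be
#'   recomputed.
#' @export
robustness <- function(net, n_original, n_removed = 0) {
  g <- as_igraph(net)
  if (igraph::vcount(g) == 0) abort("robustness undefined for an empty surviving graph")
  if (n_removed >= n_original) abort("n_removed must be smaller than n_original")
  if (igraph::vcount(g) != n_original - n_removed) {
    abort("surviving graph size does not equal n_original - n_removed")
  }
  C <- max(igraph::components(g)$csize)
  r <- C / (n_original - n_removed)
  structure(r, C = C, N = n_original, Nr = n_removed)
}

#' All four stability indicators of one (possibly knocked-out) network
#'
#' @inheritParams robustness
#' @param n_original Original node count; defaults to the graph's own size
#'   (intact network).
#' @return A one-row tibble `nc`, `cpl`, `nh`, `r`, plus the raw
#'   components `largest_component`, `n_original`, `n_removed`.
#' @export
stability_indicators <- function(net, n_original = NULL, n_removed = 0) {
  g <- as_igraph(net)
  n_original <- n_original %||% (igraph::vcount(g) + n_removed)
  rob <- robustness(g, n_original, n_removed)
  tibble(nc = network_centralization(g),
         cpl = characteristic_path_length(g),
         nh = network_heterogeneity(g),
         r = as.numeric(rob),
         largest_component = attr(rob, "C"),
         n_original = n_original,
         n_removed = n_removed)
}

#' Extract the core network by topological-parameter gating
#'
#' Retains the nodes whose gating parameters all strictly exceed the
#' network-wide median of that parameter, and returns the induced
#' subgraph. By default degree, betweenness and closeness gate; the
#' clustering and topological coefficients are computed and reported but
#' do not gate. Both the gating set and the comparison mode are
#' configurable.
#'
#' @param net A [pharm_network()].
#' @param profiles Optional precomputed [node_topology_profiles()]; must
#'   cover all nodes.
#' @param gate_on Character vector of profile columns that gate.
#' @param strict If `TRUE` (default) nodes must strictly exceed each
#'   median; if `FALSE`, `>=` is used.
#' @return A `pharm_network` on the retained nodes, with the gated
#'   profiles in attribute `profiles`.
#' @export
extract_core_network <- function(net, profiles = NULL,
                                 gate_on = c("degree", "betweenness", "closeness"),
                                 strict = TRUE) {
  g <- as_igraph(net)
  profiles <- profiles %||% node_topology_profiles(g)
  if (!setequal(profiles$node_id, igraph::V(g)$name)) {
    abort("`profiles` must cover exactly the network's nodes")
  }
  bad <- setdiff(gate_on, setdiff(names(profiles), "node_id"))
  if (length(bad)) abort(paste0("unknown gating parameter(s): ",
                                paste(bad, collapse = ", ")))
  pass <- rep(TRUE, nrow(profiles))
  for (p in gate_on) {
    med <- median(profiles[[p]])
    pass <- pass & if (strict) profiles[[p]] > med else profiles[[p]] >= med
  }
  if (!any(pass)) {
    abort(paste0("core filter removed every node; relax the thresholds ",
                 "(e.g. strict = FALSE) or gate on fewer parameters"))
  }
  core <- induce_subnetwork(structure(list(graph = g), class = "pharm_network"),
                            profiles$node_id[pass])
  attr(core, "profiles") <- profiles[pass, , drop = FALSE]
  core
}
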