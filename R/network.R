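#' Typed multilayer pharmacology network
#'
#' A `pharm_network` is a simple undirected graph whose nodes carry one of
#' four kinds — `herb`, `compound`, `target`, `pathway` — and whose edges
#' connect herb-compound, compound-target, target-target or target-pathway
#' pairs. Self-loops and duplicate edges are dropped (with a counted
#' warning); isolated nodes are retained and flagged.
#'
#' @param nodes Data frame with columns `id` and `kind`.
#' @param edges Data frame with columns `from` and `to` (node ids).
#'
#' @return An object of class `pharm_network`, a list with an `igraph`
#'   graph (vertex attributes `name`, `kind`; edge attribute `type`).
#' @seealso [build_pharm_network()] for construction from layer-wise edge
#'   tables, [network_nodes()], [network_edges()], [write_graphml()].
#' @export
pharm_network <- function(nodes, edges) {
  stopifnot(is.data.frame(nodes), is.data.frame(edges))
  nodes <- as_tibble(nodes[c("id", "kind")])
  nodes$id <- as.character(nodes$id)
  nodes$kind <- as.character(nodes$kind)
  if (anyDuplicated(nodes$id)) abort("duplicate node ids")
  bad_kind <- setdiff(unique(nodes$kind), c("herb", "compound", "target", "pathway"))
  if (length(bad_kind)) {
    abort(paste0("unknown node kind(s): ", paste(bad_kind, collapse = ", ")))
  }
  edges <- as_tibble(edges[c("from", "to")])
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)

  missing_ep <- setdiff(c(edges$from, edges$to), nodes$id)
  if (length(missing_ep)) {
    abort(paste0("edge endpoint(s) not in node table: ",
                 paste(head(missing_ep, 5), collapse = ", ")))
  }
  loops <- edges$from == edges$to
  if (any(loops)) {
    warn(sprintf("dropping %d self-loop edge(s)", sum(loops)))
    edges <- edges[!loops, , drop = FALSE]
  }
  # canonical unordered form, then dedupe
  lo <- pmin(edges$from, edges$to)
  hi <- pmax(edges$from, edges$to)
  dup <- duplicated(paste0(lo, "\r", hi))
  if (any(dup)) {
    warn(sprintf("dropping %d duplicate edge(s)", sum(dup)))
  }
  edges <- tibble(from = lo[!dup], to = hi[!dup])

  kind_of <- setNames(nodes$kind, nodes$id)
  type <- edge_type(kind_of[edges$from], kind_of[edges$to])
  if (anyNA(type)) {
    i <- which(is.na(type))[1]
    abort(sprintf("edge %s -- %s connects kinds %s and %s, which is not allowed",
                  edges$from[i], edges$to[i],
                  kind_of[[edges$from[i]]], kind_of[[edges$to[i]]]))
  }
  g <- igraph::graph_from_data_frame(
    cbind(edges, type = type), directed = FALSE,
    vertices = nodes[c("id", "kind")]
  )
  structure(list(graph = g), class = "pharm_network")
}

# allowed layer pairs, independent of endpoint order
edge_type <- function(kind_a, kind_b) {
  lo <- pmin(kind_a, kind_b)
  hi <- pmax(kind_a, kind_b)
  key <- paste(lo, hi, sep = "-")
  allowed <- c("compound-herb" = "herb-compound",
               "compound-target" = "compound-target",
               "target-target" = "target-target",
               "pathway-target" = "target-pathway")
  unname(allowed[key])
}

#' Assemble a pharmacology network from layer-wise edge tables
#'
#' Builds a [pharm_network()] from up to four edge tables, one per layer.
#' Node kinds are inferred from the layer each id first appears in; an id
#' may appear in several tables as long as its role is consistent (e.g. a
#' target in both the compound-target and target-target layers).
#'
#' @param herb_compound_edges Data frame, first two columns herb id and
#'   compound id. May be `NULL`.
#' @param compound_target_edges Data frame, first two columns compound id
#'   and target id.
#' @param target_target_edges Data frame, first two columns two target ids.
#'   May be `NULL`.
#' @param pathway_edges Data frame, first two columns target id and pathway
#'   id. May be `NULL`.
#' @param extra_nodes Optional data frame (`id`, `kind`) of nodes to retain
#'   even if isolated.
#'
#' @return A `pharm_network`.
#' @export
build_pharm_network <- function(herb_compound_edges = NULL,
                                compound_target_edges = NULL,
                                target_target_edges = NULL,
                                pathway_edges = NULL,
                                extra_nodes = NULL) {
  layer <- function(df, kind1, kind2) {
    if (is.null(df) || nrow(df) == 0) {
      return(list(nodes = tibble(id = character(), kind = character()),
                  edges = tibble(from = character(), to = character())))
    }
    a <- as.character(df[[1]]); b <- as.character(df[[2]])
    list(nodes = tibble(id = c(a, b), kind = c(rep(kind1, length(a)),
                                               rep(kind2, length(b)))),
         edges = tibble(from = a, to = b))
  }
  parts <- list(
    layer(herb_compound_edges, "herb", "compound"),
    layer(compound_target_edges, "compound", "target"),
    layer(target_target_edges, "target", "target"),
    layer(pathway_edges, "target", "pathway")
  )
  nodes <- bind_rows(lapply(parts, `[[`, "nodes"))
  if (!is.null(extra_nodes)) nodes <- bind_rows(nodes, as_tibble(extra_nodes))
  conflict <- nodes |>
    distinct(.data$id, .data$kind) |>
    count(.data$id) |>
    filter(.data$n > 1)
  if (nrow(conflict)) {
    abort(paste0("node id(s) used with more than one kind: ",
                 paste(head(conflict$id, 5), collapse = ", ")))
  }
  nodes <- distinct(nodes, .data$id, .keep_all = TRUE)
  edges <- bind_rows(lapply(parts, `[[`, "edges"))
  pharm_network(nodes, edges)
}

#' @export
print.pharm_network <- function(x, ...) {
  g <- x$graph
  kinds <- table(igraph::V(g)$kind)
  cat("<pharm_network> ", igraph::vcount(g), " nodes, ",
      igraph::ecount(g), " edges\n", sep = "")
  cat("  ", paste(names(kinds), unname(kinds), sep = ": ", collapse = ", "),
      "\n", sep = "")
  iso <- sum(igraph::degree(g) == 0)
  if (iso > 0) cat("  isolated nodes: ", iso, "\n", sep = "")
  invisible(x)
}

#' Node and edge tables of a pharmacology network
#'
#' @param net A `pharm_network`.
#' @return `network_nodes()`: a tibble `id`, `kind`, `degree`, `isolated`.
#'   `network_edges()`: a tibble `from`, `to`, `type`.
#' @export
network_nodes <- function(net) {
  g <- as_igraph(net)
  tibble(id = igraph::V(g)$name,
         kind = igraph::V(g)$kind,
         degree = unname(igraph::degree(g)),
         isolated = unname(igraph::degree(g) == 0))
}

#' @rdname network_nodes
#' @export
network_edges <- function(net) {
  g <- as_igraph(net)
  el <- igraph::as_edgelist(g)
  tibble(from = el[, 1], to = el[, 2], type = igraph::E(g)$type %||%
           edge_type(igraph::V(g)$kind[match(el[, 1], igraph::V(g)$name)],
                     igraph::V(g)$kind[match(el[, 2], igraph::V(g)$name)]))
}

#' @rdname network_nodes
#' @export
as_igraph <- function(net) {
  if (igraph::is_igraph(net)) return(net)
  if (!inherits(net, "pharm_network")) abort("not a pharm_network")
  net$graph
}

#' Induced subgraph of a pharmacology network
#'
#' @param net A `pharm_network`.
#' @param keep Character vector of node ids to retain.
#' @return A `pharm_network` on the retained nodes.
#' @export
induce_subnetwork <- function(net, keep) {
  g <- as_igraph(net)
  missing <- setdiff(keep, igraph::V(g)$name)
  if (length(missing)) {
    abort(paste0("unknown node id(s): ", paste(head(missing, 5), collapse = ", ")))
  }
  structure(list(graph = igraph::induced_subgraph(g, keep)),
            class = "pharm_network")
}

#' Compound-to-target adjacency of a pharmacology network
#'
#' @param net A `pharm_network`.
#' @return A tibble `compound`, `target`, one row per compound-target edge.
#' @export
compound_target_map <- function(net) {
  e <- network_edges(net)
  n <- network_nodes(net)
  kind_of <- setNames(n$kind, n$id)
  ct <- e[e$type == "compound-target", , drop = FALSE]
  comp_first <- kind_of[ct$from] == "compound"
  tibble(compound = ifelse(comp_first, ct$from, ct$to),
         target = ifelse(comp_first, ct$to, ct$from))
}
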