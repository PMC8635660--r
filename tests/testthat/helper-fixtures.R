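# small deterministic fixtures, built in code

# 2 herbs, 3 compounds, 4 targets; 9 edges
toy_network <- function() {
  build_pharm_network(
    herb_compound_edges = data.frame(
      herb = c("h1", "h1", "h2"),
      compound = c("c1", "c2", "c3")),
    compound_target_edges = data.frame(
      compound = c("c1", "c1", "c2", "c3"),
      target = c("t1", "t2", "t2", "t3")),
    target_target_edges = data.frame(
      from = c("t1", "t2"), to = c("t4", "t4"))
  )
}

# named graph from an adjacency matrix, all nodes typed target
net_from_adj <- function(A) {
  ids <- sprintf("n%02d", seq_len(nrow(A)))
  dimnames(A) <- list(ids, ids)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  igraph::V(g)$kind <- "target"
  g
}

small_synth_config <- function(seed = 1, ...) {
  synth_config(n_herbs = 3, n_compounds = 17, n_targets = 120,
               expr_design = list(n_genes = 300, n_per_group = 8,
                                  n_deg = 30, log2fc = 1.5, sigma = 0.5),
               seed = seed, ...)
}
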