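#' Read a compound catalog
#'
#' Tab-separated, columns `compound_id`, `name`, `herb`, `ob`, `dl`; a
#' compound appearing in several herbs occupies one row per herb.
#'
#' @param path File path.
#' @return A tibble with those columns.
#' @export
read_compound_catalog <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           compound_id = readr::col_character(),
                           name = readr::col_character(),
                           herb = readr::col_character(),
                           ob = readr::col_double(),
                           dl = readr::col_double()))
  need <- c("compound_id", "name", "herb", "ob", "dl")
  if (!all(need %in% names(out))) {
    abort(paste0("catalog must have columns ", paste(need, collapse = ", ")))
  }
  out
}

#' Read a two-column edge table
#'
#' Tab-separated; the first two columns are endpoint ids, an optional
#' third numeric column is an edge score.
#'
#' @param path File path.
#' @return A tibble with the file's columns.
#' @export
read_edge_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  if (ncol(out) < 2L) abort("edge table needs at least two columns")
  out[[1]] <- as.character(out[[1]])
  out[[2]] <- as.character(out[[2]])
  out
}

#' Read a STRING-style scored protein-protein interaction table
#'
#' Tab-separated with columns `protein_a`, `protein_b` and either `score`
#' (already in \[0, 1\]) or `combined_score` (STRING's 0-1000 integer
#' scale, divided by 1000).
#'
#' @param path File path.
#' @return A tibble `protein_a`, `protein_b`, `score` with score in
#'   \[0, 1\].
#' @export
read_string_ppi <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("protein_a", "protein_b") %in% names(out))) {
    abort("PPI table needs columns protein_a, protein_b")
  }
  if ("combined_score" %in% names(out) && !"score" %in% names(out)) {
    out$score <- out$combined_score / 1000
  }
  if (!"score" %in% names(out)) abort("PPI table needs a score or combined_score column")
  if (any(out$score < 0 | out$score > 1, na.rm = TRUE)) {
    abort("PPI scores must lie in [0, 1] after scaling")
  }
  out[c("protein_a", "protein_b", "score")]
}

#' Read a gene list (one symbol per line)
#'
#' @param path File path.
#' @return Character vector of non-empty, trimmed lines.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readr::read_lines(path))
  x[nzchar(x)]
}

#' @rdname read_gene_list
#' @param genes Character vector to write.
#' @export
write_gene_list <- function(genes, path) {
  readr::write_lines(genes, path)
  invisible(path)
}

#' Read an expression matrix
#'
#' Tab-separated, first column `gene`, one numeric column per sample.
#'
#' @param path File path.
#' @return A tibble suitable for [quantile_normalize()] / [two_group_deg()].
#' @export
read_expression_matrix <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  if (names(out)[1] != "gene") names(out)[1] <- "gene"
  out$gene <- as.character(out$gene)
  check_expression(out)
}

#' @rdname read_expression_matrix
#' @param expr Expression tibble to write.
#' @export
write_expression_matrix <- function(expr, path) {
  readr::write_tsv(expr, path)
  invisible(path)
}

#' Read a two-column sample-to-group assignment file
#'
#' @param path File path to a TSV with columns `sample` and `group`.
#' @return Named character vector (names = samples).
#' @export
read_group_assignments <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("sample", "group") %in% names(out))) {
    abort("group file needs columns sample, group")
  }
  setNames(out$group, out$sample)
}

#' Read and write gene-set collections in GMT format
#'
#' Reading goes through `fgsea::gmtPathways()` when available, else a
#' plain parse of the same format (name, description, genes, tab
#' separated).
#'
#' @param path File path.
#' @return `read_gmt()`: named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE)) {
    return(fgsea::gmtPathways(path))
  }
  lines <- strsplit(readr::read_lines(path), "\t", fixed = TRUE)
  lines <- lines[lengths(lines) >= 3]
  setNames(lapply(lines, function(x) x[-(1:2)]),
           vapply(lines, `[[`, character(1), 1))
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Write and read a network in SIF format
#'
#' SIF rows are `nodeA <tab> interaction <tab> nodeB`; the interaction
#' field carries the edge type. Isolated nodes are written as single-field
#' rows, per the format's convention. SIF does not carry node kinds; use
#' [write_graphml()] for a lossless round trip.
#'
#' @param net A [pharm_network()].
#' @param path File path.
#' @export
write_sif <- function(net, path) {
  e <- network_edges(net)
  n <- network_nodes(net)
  lines <- sprintf("%s\t%s\t%s", e$from, e$type, e$to)
  lines <- c(lines, n$id[n$isolated])
  readr::write_lines(lines, path)
  invisible(path)
}

#' @rdname write_sif
#' @return `read_sif()`: a tibble `from`, `type`, `to` (`type` `NA` for
#'   isolated-node rows).
#' @export
read_sif <- function(path) {
  parts <- strsplit(readr::read_lines(path), "\t", fixed = TRUE)
  parts <- parts[lengths(parts) > 0]
  bind_rows(lapply(parts, function(x) {
    if (length(x) == 1L) tibble(from = x, type = NA_character_, to = NA_character_)
    else tibble(from = x[1], type = x[2], to = x[3])
  }))
}

#' Write and read a network as GraphML
#'
#' The `kind` node attribute and `type` edge attribute are preserved, so
#' a `pharm_network` round-trips losslessly.
#'
#' @param net A [pharm_network()].
#' @param path File path.
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @return `read_graphml_network()`: a `pharm_network`.
#' @export
read_graphml_network <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  if (is.null(igraph::vertex_attr(g, "kind"))) {
    abort("GraphML file lacks the `kind` node attribute")
  }
  nodes <- tibble(id = igraph::V(g)$name, kind = igraph::V(g)$kind)
  el <- igraph::as_edgelist(g)
  pharm_network(nodes, tibble(from = el[, 1], to = el[, 2]))
}

#' Write Venn region counts as JSON
#'
#' @param regions Output of [venn_regions()].
#' @param path File path.
#' @export
write_venn_json <- function(regions, path) {
  jsonlite::write_json(setNames(as.list(regions$n), regions$region),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
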