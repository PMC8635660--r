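#' Knock a compound set out of the network
#'
#' Removes the compound node(s) and every target node adjacent to any
#' compound in the set — by default including targets shared with other
#' compounds — and summarises the surviving graph with the four stability
#' indicators. `N` is the original node count and `Nr` the number of
#' removed nodes, so robustness is measured against the surviving node
#' count.
#'
#' @param net A [pharm_network()].
#' @param compounds Character vector of compound node ids (non-empty, all
#'   present in the network).
#' @param target_map Optional compound-target adjacency (tibble with
#'   columns `compound`, `target`); derived from the network's
#'   compound-target edges when `NULL`.
#' @param shared_targets If `TRUE` (default) a knocked-out compound removes
#'   all its adjacent targets even when other compounds also hit them; if
#'   `FALSE`, only targets hit exclusively by the knocked-out set are
#'   removed.
#'
#' @return A `knockout_result`: list with `entity_id` (sorted compound ids
#'   joined by `+`), `removed_nodes`, `indicators` (one-row tibble from
#'   [stability_indicators()], or `NULL` with a `reason` when the surviving
#'   graph is too degenerate to summarise).
#' @export
knockout_entity <- function(net, compounds, target_map = NULL,
                            shared_targets = TRUE) {
  g <- as_igraph(net)
  compounds <- unique(as.character(compounds))
  if (length(compounds) == 0) abort("`compounds` must be non-empty")
  missing <- setdiff(compounds, igraph::V(g)$name)
  if (length(missing)) {
    abort(paste0("compound(s) not in network: ", paste(missing, collapse = ", ")))
  }
  target_map <- target_map %||% compound_target_map(net)
  hit <- unique(target_map$target[target_map$compound %in% compounds])
  if (!shared_targets) {
    others <- unique(target_map$target[!(target_map$compound %in% compounds)])
    hit <- setdiff(hit, others)
  }
  removed <- union(compounds, intersect(hit, igraph::V(g)$name))
  survivor <- igraph::delete_vertices(g, removed)

  ind <- tryCatch(
    stability_indicators(survivor,
                         n_original = igraph::vcount(g),
                         n_removed = length(removed)),
    error = function(e) conditionMessage(e)
  )
  undefined <- is.character(ind)
  structure(list(entity_id = paste(sort(compounds), collapse = "+"),
                 removed_nodes = sort(removed),
                 indicators = if (undefined) NULL else ind,
                 reason = if (undefined) ind else NULL),
            class = "knockout_result")
}

#' @export
print.knockout_result <- function(x, ...) {
  cat("<knockout_result> ", x$entity_id, ": ", length(x$removed_nodes),
      " node(s) removed\n", sep = "")
  if (is.null(x$indicators)) {
    cat("  indicators undefined: ", x$reason, "\n", sep = "")
  } else {
    print(x$indicators)
  }
  invisible(x)
}

#' Indicator matrix over knockout entities
#'
#' Runs [knockout_entity()] for every entity (a compound set) and stacks
#' the four stability indicators into the n-entities-by-4 matrix that
#' feeds entropy weighting. Each indicator column carries an orientation:
#' `positive` means larger values indicate a more destabilizing (hence
#' more important) knockout, `inverse` the opposite. The default —
#' CPL and NH positive, NC and R inverse — makes compounds whose removal
#' fragments the network score high.
#'
#' @param net A [pharm_network()].
#' @param entities List of character vectors of compound ids (>= 2
#'   entities after exclusions).
#' @param orientation Named character vector over `nc`, `cpl`, `nh`, `r`
#'   with values `"positive"` or `"inverse"`.
#' @param mode `"post"` (default): indicators are the surviving network's
#'   values. `"delta"`: surviving value minus the intact network's value.
#' @inheritParams knockout_entity
#'
#' @return An `indicator_matrix`: a tibble `entity_id`, `nc`, `cpl`, `nh`,
#'   `r` with attributes `orientation`, `excluded` (tibble of entities
#'   whose knockout left an unsummarisable graph, with reasons) and
#'   `removed_nodes` (named list).
#' @export
build_indicator_matrix <- function(net, entities, target_map = NULL,
                                   orientation = default_orientation(),
                                   shared_targets = TRUE,
                                   mode = c("post", "delta")) {
  mode <- match.arg(mode)
  check_orientation(orientation)
  if (!is.list(entities) || length(entities) < 2L) {
    abort("need at least two knockout entities")
  }
  target_map <- target_map %||% compound_target_map(net)
  results <- lapply(entities, function(cs) {
    knockout_entity(net, cs, target_map = target_map,
                    shared_targets = shared_targets)
  })
  ok <- !vapply(results, function(r) is.null(r$indicators), logical(1))
  excluded <- tibble(
    entity_id = vapply(results[!ok], `[[`, character(1), "entity_id"),
    reason = vapply(results[!ok], function(r) r$reason %||% "", character(1))
  )
  if (any(!ok)) {
    warn(sprintf("excluding %d entit%s with undefined indicators: %s",
                 sum(!ok), if (sum(!ok) == 1) "y" else "ies",
                 paste(excluded$entity_id, collapse = ", ")))
  }
  results <- results[ok]
  if (length(results) < 2L) abort("fewer than two entities with defined indicators")

  rows <- bind_rows(lapply(results, function(r) {
    bind_cols(tibble(entity_id = r$entity_id),
              r$indicators[, .INDICATORS])
  }))
  if (mode == "delta") {
    base <- stability_indicators(net)
    for (j in .INDICATORS) rows[[j]] <- rows[[j]] - base[[j]]
  }
  structure(rows,
            class = c("indicator_matrix", class(rows)),
            orientation = orientation[.INDICATORS],
            mode = mode,
            excluded = excluded,
            removed_nodes = setNames(lapply(results, `[[`, "removed_nodes"),
                                     vapply(results, `[[`, character(1), "entity_id")))
}

#' Default indicator orientation
#'
#' @return Named character vector mapping each indicator to `"positive"`
#'   or `"inverse"`.
#' @export
default_orientation <- function() .DEFAULT_ORIENTATION

check_orientation <- function(orientation) {
  if (!setequal(names(orientation), .INDICATORS) ||
      !all(orientation %in% c("positive", "inverse"))) {
    abort("`orientation` must map nc, cpl, nh, r to \"positive\" or \"inverse\"")
  }
  invisible(orientation)
}
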