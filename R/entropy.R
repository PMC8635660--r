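#' Min-max normalize an indicator matrix into evaluation values
#'
#' Maps each indicator column onto \[0, 1\]: a `positive` column becomes
#' \eqn{(x - min)/(max - min)}, an `inverse` column \eqn{(max - x)/(max -
#' min)}, so that after normalization a larger evaluation value always
#' means a more destabilizing knockout. A constant column is mapped to all
#' zeros and flagged; downstream its entropy is defined as 1 and its
#' weight as 0 (an uninformative indicator).
#'
#' @param matrix A data frame with an `entity_id` column and numeric
#'   indicator columns (typically an [build_indicator_matrix()] result).
#' @param orientation Named character vector over the indicator columns
#'   (`"positive"`/`"inverse"`); defaults to the matrix's own orientation
#'   attribute, else [default_orientation()].
#'
#' @return A tibble of the same shape with normalized values, attribute
#'   `constant_columns` naming any flagged columns and `orientation`
#'   echoing the orientation used.
#' @export
minmax_normalize <- function(matrix, orientation = NULL) {
  stopifnot(is.data.frame(matrix), "entity_id" %in% names(matrix))
  cols <- setdiff(names(matrix), "entity_id")
  orientation <- orientation %||% attr(matrix, "orientation") %||%
    default_orientation()[cols]
  if (!all(cols %in% names(orientation))) {
    abort("`orientation` must cover every indicator column")
  }
  if (!all(orientation[cols] %in% c("positive", "inverse"))) {
    abort("orientation values must be \"positive\" or \"inverse\"")
  }
  z <- tibble(entity_id = matrix$entity_id)
  constant <- character()
  for (j in cols) {
    x <- as.numeric(matrix[[j]])
    if (any(!is.finite(x))) abort(paste0("non-finite values in column ", j))
    rng <- range(x)
    if (rng[1] == rng[2]) {
      z[[j]] <- rep(0, length(x))
      constant <- c(constant, j)
    } else if (orientation[[j]] == "positive") {
      z[[j]] <- (x - rng[1]) / (rng[2] - rng[1])
    } else {
      z[[j]] <- (rng[2] - x) / (rng[2] - rng[1])
    }
  }
  structure(z, constant_columns = constant, orientation = orientation[cols])
}

#' Entropy weights over indicator columns
#'
#' Implements the entropy-weight method of multi-criteria decision making.
#' From normalized evaluation values \eqn{z_{ij}} over \eqn{n} entities:
#' proportions \eqn{b_{ij} = z_{ij} / \sum_i z_{ij}}, column entropies
#' \eqn{e_j = -k \sum_i b_{ij} \ln b_{ij}} with \eqn{k = 1/\ln(n)} and
#' \eqn{0 \ln 0 := 0}, difference coefficients \eqn{d_j = 1 - e_j}, and
#' weights \eqn{w_j = d_j / \sum_j d_j}. Indicators spread evenly across
#' entities carry maximal entropy and hence zero discriminating power;
#' weight concentrates on the indicators that differ most across
#' knockouts.
#'
#' @param z Normalized evaluation values from [minmax_normalize()] (a data
#'   frame with `entity_id` plus numeric columns in \[0, 1\], n >= 2
#'   rows). Columns flagged constant get \eqn{e_j = 1}, \eqn{w_j = 0}.
#'
#' @return An `entropy_weights` object: list with tibbles `z` and `b`, and
#'   named vectors `e`, `d`, `w` (weights summing to 1).
#' @export
entropy_weights <- function(z) {
  stopifnot(is.data.frame(z), "entity_id" %in% names(z))
  cols <- setdiff(names(z), "entity_id")
  n <- nrow(z)
  if (n < 2L) abort("entropy weighting needs at least two entities")
  constant <- attr(z, "constant_columns") %||% character()
  k <- 1 / log(n)
  b <- tibble(entity_id = z$entity_id)
  e <- d <- setNames(numeric(length(cols)), cols)
  for (j in cols) {
    x <- as.numeric(z[[j]])
    tot <- sum(x)
    if (j %in% constant || tot == 0) {
      b[[j]] <- rep(NA_real_, n)
      e[[j]] <- 1
    } else {
      bj <- x / tot
      b[[j]] <- bj
      terms <- ifelse(bj > 0, bj * log(bj), 0)
      e[[j]] <- -k * sum(terms)
    }
    d[[j]] <- 1 - e[[j]]
  }
  if (sum(d) <= 0) {
    abort("all indicator columns are uninformative (every difference coefficient is 0)")
  }
  w <- d / sum(d)
  structure(list(z = z, b = b, e = e, d = d, w = w,
                 constant_columns = constant),
            class = "entropy_weights")
}

#' @export
print.entropy_weights <- function(x, ...) {
  cat("<entropy_weights> over", nrow(x$z), "entities\n")
  print(round(rbind(entropy = x$e, difference = x$d, weight = x$w), 4))
  invisible(x)
}

#' @method tidy entropy_weights
#' @export
tidy.entropy_weights <- function(x, ...) {
  tibble(indicator = names(x$w), entropy = unname(x$e),
         difference = unname(x$d), weight = unname(x$w),
         constant = names(x$w) %in% x$constant_columns)
}

#' Network contribution scores
#'
#' The contribution score of a knockout entity is the weighted sum of its
#' four evaluation values, with the robustness term's weight doubled:
#' \deqn{score_i = z_{i,nc} w_{nc} + z_{i,cpl} w_{cpl} + z_{i,nh} w_{nh} +
#'   z_{i,r} (2 w_r).}
#' The undoubled score (plain weighted sum) is reported alongside. Scores
#' are computed on the normalized evaluation values by default, which puts
#' the four indicators on a common scale; `raw_values = TRUE` consumes the
#' raw indicator values instead.
#'
#' @param weights An [entropy_weights()] object derived from `matrix`.
#' @param matrix The indicator matrix the weights came from; only needed
#'   when `raw_values = TRUE`.
#' @param raw_values Score raw indicator values instead of normalized
#'   evaluation values.
#' @param double_r Double the robustness weight as in the printed score
#'   formula (default `TRUE`).
#'
#' @return A tibble `entity_id`, `score`, `score_undoubled`.
#' @export
contribution_scores <- function(weights, matrix = NULL, raw_values = FALSE,
                                double_r = TRUE) {
  stopifnot(inherits(weights, "entropy_weights"))
  z <- weights$z
  cols <- setdiff(names(z), "entity_id")
  operand <- if (raw_values) {
    if (is.null(matrix)) abort("`matrix` is required when raw_values = TRUE")
    if (!identical(matrix$entity_id, z$entity_id)) {
      abort("`matrix` rows do not match the weights' entities")
    }
    matrix
  } else z
  w <- weights$w[cols]
  mult <- setNames(rep(1, length(cols)), cols)
  if (double_r && "r" %in% cols) mult[["r"]] <- 2
  vals <- as.matrix(operand[cols])
  tibble(entity_id = z$entity_id,
         score = as.numeric(vals %*% (w * mult)),
         score_undoubled = as.numeric(vals %*% w))
}

#' Enumerate compound combinations
#'
#' All subsets of the given compounds with at least `min_size` members,
#' each exactly once, in deterministic order: by size, then
#' lexicographically within a size. Eight compounds yield the classical
#' \eqn{2^8 - 1 = 255} non-empty combinations.
#'
#' @param compounds Character vector of distinct compound ids.
#' @param min_size Smallest subset size to include (default 1).
#' @return A list of character vectors (each sorted).
#' @export
enumerate_combinations <- function(compounds, min_size = 1) {
  compounds <- as.character(compounds)
  if (anyDuplicated(compounds)) abort("duplicate compound ids")
  p <- length(compounds)
  if (min_size < 1 || min_size > p) abort("`min_size` must lie in [1, length(compounds)]")
  sorted <- sort(compounds)
  out <- list()
  for (k in min_size:p) {
    sets <- combn(sorted, k, simplify = FALSE)
    keys <- vapply(sets, paste, character(1), collapse = "+")
    out <- c(out, sets[order(keys)])
  }
  out
}

#' Select core compounds by per-indicator top-fraction intersection
#'
#' For each indicator column, takes the entities whose evaluation value is
#' in the top `fraction` (ties at the cutoff are all retained), then
#' intersects the four sets — the Venn-style retention of consistently
#' high scorers. If the intersection is empty, falls back (with a
#' warning) to the top \eqn{\lceil fraction \cdot n \rceil} entities by
#' contribution score. `method = "score"` applies the score-median style
#' retention directly.
#'
#' @param matrix An [build_indicator_matrix()] result over single
#'   compounds.
#' @param fraction Retained fraction in (0, 1\]; default 0.5.
#' @param method `"per_indicator"` (default, Venn intersection of
#'   per-indicator top fractions) or `"score"` (top fraction by
#'   contribution score).
#' @inheritParams minmax_normalize
#' @inheritParams contribution_scores
#'
#' @return Character vector of retained entity ids (sorted), with the
#'   per-indicator retained sets in attribute `per_indicator` (for the
#'   default method).
#' @export
select_core_compounds <- function(matrix, fraction = 0.5,
                                  method = c("per_indicator", "score"),
                                  orientation = NULL, double_r = TRUE) {
  method <- match.arg(method)
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    abort("`fraction` must lie in (0, 1]")
  }
  z <- minmax_normalize(matrix, orientation = orientation)
  n <- nrow(z)
  k <- ceiling(fraction * n)
  score_fallback <- function() {
    sc <- contribution_scores(entropy_weights(z), double_r = double_r)
    sc <- arrange(sc, desc(.data$score), .data$entity_id)
    cutoff <- sc$score[k]
    sort(sc$entity_id[sc$score >= cutoff])
  }
  if (method == "score") return(score_fallback())
  cols <- setdiff(names(z), "entity_id")
  per <- lapply(cols, function(j) {
    v <- sort(z[[j]], decreasing = TRUE)
    cutoff <- v[k]
    z$entity_id[z[[j]] >= cutoff]
  })
  names(per) <- cols
  out <- sort(Reduce(intersect, per))
  if (length(out) == 0) {
    warn("per-indicator top-fraction intersection is empty; falling back to contribution-score ranking")
    out <- score_fallback()
  }
  attr(out, "per_indicator") <- per
  out
}

#' Rank all combinations of the core compounds
#'
#' Enumerates every combination of the core compounds with at least
#' `min_size` members, knocks each combination out of the network jointly,
#' builds the combination-level indicator matrix, recomputes entropy
#' weights across the combination rows (combinations are scored on their
#' own scale, not with the single-compound weights), scores them, and
#' returns the ranking. Ties are broken by the lexicographic combination
#' id so the ranking is fully deterministic.
#'
#' @param net A [pharm_network()].
#' @param core_compounds Character vector of at least two compound ids.
#' @param top_k Number of top combinations to report (default 10); the
#'   full ranking is always kept in the returned object.
#' @param min_size Smallest combination size (default 1).
#' @inheritParams build_indicator_matrix
#' @inheritParams contribution_scores
#'
#' @return A `combination_ranking` object: list with `ranking` (tibble
#'   `rank`, `combination`, `size`, `score`, `score_undoubled`, full
#'   length), `top_k`, `weights` (the [entropy_weights()] object),
#'   `orientation`, `excluded` (combinations whose knockout left an
#'   unsummarisable graph), and `indicator_matrix`.
#' @export
rank_combinations <- function(net, core_compounds, target_map = NULL,
                              top_k = 10, min_size = 1,
                              orientation = default_orientation(),
                              shared_targets = TRUE, double_r = TRUE) {
  core_compounds <- as.character(core_compounds)
  if (length(core_compounds) < 2L) abort("need at least two core compounds")
  combos <- enumerate_combinations(core_compounds, min_size = min_size)
  mat <- build_indicator_matrix(net, combos, target_map = target_map,
                                orientation = orientation,
                                shared_targets = shared_targets)
  z <- minmax_normalize(mat)
  w <- entropy_weights(z)
  sc <- contribution_scores(w, matrix = mat, double_r = double_r)
  sc$size <- lengths(strsplit(sc$entity_id, "+", fixed = TRUE))
  ranking <- sc |>
    arrange(desc(.data$score), .data$entity_id) |>
    mutate(rank = row_number()) |>
    select("rank", combination = "entity_id", "size", "score", "score_undoubled")
  structure(list(ranking = ranking,
                 top_k = min(top_k, nrow(ranking)),
                 weights = w,
                 orientation = attr(mat, "orientation"),
                 excluded = attr(mat, "excluded"),
                 indicator_matrix = mat),
            class = "combination_ranking")
}

#' @export
print.combination_ranking <- function(x, ...) {
  cat("<combination_ranking> ", nrow(x$ranking), " combination(s); top ",
      x$top_k, ":\n", sep = "")
  print(head(x$ranking, x$top_k))
  if (nrow(x$excluded) > 0) {
    cat("excluded (undefined indicators):",
        paste(x$excluded$entity_id, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @method tidy combination_ranking
#' @export
tidy.combination_ranking <- function(x, ...) x$ranking

#' @method glance combination_ranking
#' @export
glance.combination_ranking <- function(x, ...) {
  tibble(n_combinations = nrow(x$ranking),
         n_excluded = nrow(x$excluded),
         top_combination = x$ranking$combination[1],
         top_score = x$ranking$score[1],
         w_nc = x$weights$w[["nc"]], w_cpl = x$weights$w[["cpl"]],
         w_nh = x$weights$w[["nh"]], w_r = x$weights$w[["r"]])
}
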