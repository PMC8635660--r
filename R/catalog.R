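#' Screen a compound catalog on oral bioavailability and drug-likeness
#'
#' Applies the standard ADMET pre-filter of network pharmacology: a compound
#' is retained when its oral bioavailability (OB, a percentage) and its
#' drug-likeness (DL, a unitless score) both reach the thresholds. Both
#' comparisons are inclusive (`>=`).
#'
#' @param catalog A data frame with at least columns `compound_id`, `ob`
#'   (percentage in \[0, 100\]) and `dl` (score in \[0, 1\]). Typically read
#'   with [read_compound_catalog()].
#' @param ob_min Minimum oral bioavailability, percent. Default 30.
#' @param dl_min Minimum drug-likeness. Default 0.18.
#'
#' @return A tibble of the retained rows, input order preserved. Rows with
#'   missing, non-finite or negative OB/DL are dropped before filtering and
#'   counted in the `n_invalid` attribute (a warning is raised).
#' @examples
#' catalog <- tibble::tibble(
#'   compound_id = c("c1", "c2", "c3"),
#'   ob = c(30, 29.9, 80), dl = c(0.18, 0.5, 0.1)
#' )
#' filter_compounds_admet(catalog)  # keeps only c1
#' @export
filter_compounds_admet <- function(catalog, ob_min = 30, dl_min = 0.18) {
  stopifnot(is.data.frame(catalog))
  if (!all(c("compound_id", "ob", "dl") %in% names(catalog))) {
    abort("`catalog` needs columns compound_id, ob, dl")
  }
  if (!is.finite(ob_min) || !is.finite(dl_min)) {
    abort("`ob_min` and `dl_min` must be finite")
  }
  catalog <- as_tibble(catalog)
  ob <- suppressWarnings(as.numeric(catalog$ob))
  dl <- suppressWarnings(as.numeric(catalog$dl))
  valid <- is.finite(ob) & is.finite(dl) & ob >= 0 & dl >= 0
  n_invalid <- sum(!valid)
  if (n_invalid > 0) {
    warn(sprintf("dropping %d catalog row(s) with invalid OB/DL", n_invalid))
  }
  out <- catalog[valid & ob >= ob_min & dl >= dl_min, , drop = FALSE]
  attr(out, "n_invalid") <- n_invalid
  out
}

#' Expand a seed target set through scored protein-protein interactions
#'
#' Performs one neighbourhood round over a scored interactome: the result is
#' the seed set plus every protein linked to a seed by an edge whose
#' confidence is strictly above `score_min`. Expansion is deliberately not
#' transitive; on a score-filtered interactome a transitive closure absorbs
#' most of the proteome.
#'
#' @param seed_targets Character vector of gene symbols.
#' @param ppi Data frame with columns `protein_a`, `protein_b`, `score`
#'   (confidence in \[0, 1\]); edges are undirected.
#' @param score_min Confidence threshold; edges with `score > score_min`
#'   (strict) are used. Default 0.850.
#'
#' @return Character vector of gene symbols (upper-cased, trimmed), a
#'   superset of the seeds. Edges with empty symbols are skipped; their count
#'   is attached as attribute `n_skipped` with a warning.
#' @export
expand_targets_ppi <- function(seed_targets, ppi, score_min = 0.850) {
  stopifnot(is.data.frame(ppi))
  if (!all(c("protein_a", "protein_b", "score") %in% names(ppi))) {
    abort("`ppi` needs columns protein_a, protein_b, score")
  }
  if (!is.numeric(score_min) || score_min < 0 || score_min > 1) {
    abort("`score_min` must lie in [0, 1]")
  }
  seeds <- normalize_symbols(seed_targets)
  a <- normalize_symbols(ppi$protein_a)
  b <- normalize_symbols(ppi$protein_b)
  bad <- is.na(a) | is.na(b) | a == "" | b == ""
  if (any(bad)) {
    warn(sprintf("skipping %d PPI edge(s) with empty protein symbols", sum(bad)))
  }
  keep <- !bad & ppi$score > score_min
  a <- a[keep]; b <- b[keep]
  neighbours <- c(b[a %in% seeds], a[b %in% seeds])
  out <- sort(unique(c(seeds, neighbours)))
  attr(out, "n_skipped") <- sum(bad)
  out
}

#' Intersect named gene-symbol sets and tabulate Venn regions
#'
#' Computes the k-way intersection of two or more gene lists after symbol
#' normalization (upper case, whitespace trimmed), as used to pin the
#' formula-syndrome-disease common targets. All Venn region cardinalities
#' are attached for reporting.
#'
#' @param sets A named list of character vectors (at least two).
#'
#' @return Character vector of symbols present in every set, sorted. The
#'   attribute `venn_regions` holds the output of [venn_regions()] on the
#'   same sets.
#' @examples
#' intersect_target_sets(list(a = c("x", "y"), b = c("y", "z")))
#' @export
intersect_target_sets <- function(sets) {
  check_named_sets(sets)
  norm <- lapply(sets, function(s) unique(normalize_symbols(s)))
  out <- sort(Reduce(intersect, norm))
  attr(out, "venn_regions") <- venn_regions(sets)
  out
}

#' Venn region cardinalities for named gene-symbol sets
#'
#' @inheritParams intersect_target_sets
#' @return A tibble with one row per non-empty membership pattern over the
#'   union of the sets: logical columns named after the sets, `region` (a
#'   label like `"a&b"`), and `n`.
#' @export
venn_regions <- function(sets) {
  check_named_sets(sets)
  norm <- lapply(sets, function(s) unique(normalize_symbols(s)))
  universe <- sort(unique(unlist(norm)))
  member <- vapply(norm, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL, names(norm)))
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), length(norm)))
  names(patterns) <- names(norm)
  patterns <- patterns[rowSums(patterns) > 0, , drop = FALSE]
  n <- vapply(seq_len(nrow(patterns)), function(i) {
    want <- unlist(patterns[i, ])
    sum(apply(member, 1L, function(row) all(row == want)))
  }, integer(1))
  region <- vapply(seq_len(nrow(patterns)), function(i) {
    paste(names(norm)[unlist(patterns[i, ])], collapse = "&")
  }, character(1))
  out <- as_tibble(patterns)
  out$region <- region
  out$n <- n
  out
}

normalize_symbols <- function(x) {
  toupper(trimws(as.character(x)))
}

check_named_sets <- function(sets) {
  if (!is.list(sets) || length(sets) < 2L) {
    abort("need a named list of at least two gene-symbol sets")
  }
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    abort("every set must be named")
  }
  invisible(sets)
}
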