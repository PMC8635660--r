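#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) onto a common intensity distribution: each
#' column's sorted values are replaced by the vector of row-wise means of
#' the column-sorted input, with ties averaged. The standard pre-step
#' before two-group differential filtering of array intensities.
#'
#' @param expr A data frame with a `gene` column of unique ids and one
#'   numeric column per sample (linear-scale, non-negative intensities).
#' @return A tibble of the same shape, quantile-normalized. A
#'   single-sample matrix is returned unchanged with a warning.
#' @export
quantile_normalize <- function(expr) {
  expr <- check_expression(expr)
  samples <- setdiff(names(expr), "gene")
  if (length(samples) < 2L) {
    warn("single-sample matrix: quantile normalization is the identity")
    return(expr)
  }
  m <- as.matrix(expr[samples])
  qn <- limma::normalizeQuantiles(m, ties = TRUE)
  out <- as_tibble(as.data.frame(qn))
  names(out) <- samples
  bind_cols(tibble(gene = expr$gene), out)
}

#' Two-group differential-expression filter
#'
#' Per-gene fold change and p value between two sample groups, with the
#' pass rule used for array-based DEG selection: a gene passes when its
#' linear fold change exceeds `fc_min` in either direction (strictly) and
#' its p value is strictly below `p_max`. Fold change is the ratio of
#' group geometric means (log2 arithmetic internally); the p value comes
#' from a two-sided two-sample test on log2 intensities — Welch's by
#' default, Student's behind the `var_equal` flag. Benjamini-Hochberg
#' adjusted p values are reported alongside but do not gate.
#'
#' @inheritParams quantile_normalize
#' @param groups Either a named character vector (names = sample ids) or a
#'   data frame with columns `sample` and `group`; exactly two groups,
#'   each with >= 2 samples. Fold change is group1/group2 in the order
#'   the group labels first appear.
#' @param fc_min Linear fold-change threshold (> 1), strict. Default 1.5.
#' @param p_max P-value threshold, strict. Default 0.05.
#' @param var_equal Use Student's pooled-variance test instead of Welch's.
#' @param pseudo Offset added to all intensities before log2 when any
#'   intensity is zero (recorded in the `pseudo` attribute). Default 1.
#'
#' @return A `deg_table` tibble: `gene`, `fold_change` (linear,
#'   group1/group2), `log2_fc`, `p_value`, `p_adjusted`, `passes`;
#'   attributes `groups` (the two labels, in ratio order), `fc_min`,
#'   `p_max`, `pseudo` (the offset actually applied, or 0).
#' @export
two_group_deg <- function(expr, groups, fc_min = 1.5, p_max = 0.05,
                          var_equal = FALSE, pseudo = 1) {
  expr <- check_expression(expr)
  if (is.data.frame(groups)) groups <- setNames(as.character(groups$group),
                                                as.character(groups$sample))
  samples <- setdiff(names(expr), "gene")
  if (!all(samples %in% names(groups))) abort("every sample needs a group label")
  groups <- groups[samples]
  levels <- unique(unname(groups))
  if (length(levels) != 2L) abort("exactly two groups are required")
  if (any(table(groups) < 2L)) abort("each group needs at least two samples")
  if (!is.numeric(fc_min) || fc_min <= 1) abort("`fc_min` must exceed 1")

  m <- as.matrix(expr[samples])
  applied_pseudo <- 0
  if (any(m <= 0)) {
    applied_pseudo <- pseudo
    inform(sprintf("zero or negative intensities found; adding pseudo-value %g before log2",
                   pseudo))
    m <- m + pseudo
  }
  lm2 <- log2(m)
  g1 <- lm2[, groups == levels[1], drop = FALSE]
  g2 <- lm2[, groups == levels[2], drop = FALSE]
  wt <- row_welch(g1, g2, var_equal = var_equal)
  log2_fc <- rowMeans(g1) - rowMeans(g2)
  fc <- 2^log2_fc
  p_adj <- p.adjust(wt$p, method = "BH")
  out <- tibble(gene = expr$gene,
                fold_change = unname(fc),
                log2_fc = unname(log2_fc),
                p_value = unname(wt$p),
                p_adjusted = unname(p_adj),
                passes = unname((fc > fc_min | fc < 1 / fc_min) & wt$p < p_max))
  structure(out, class = c("deg_table", class(out)),
            groups = levels, fc_min = fc_min, p_max = p_max,
            pseudo = applied_pseudo)
}

#' @method glance deg_table
#' @export
glance.deg_table <- function(x, ...) {
  tibble(n_genes = nrow(x), n_pass = sum(x$passes),
         n_up = sum(x$passes & x$log2_fc > 0),
         n_down = sum(x$passes & x$log2_fc < 0),
         fc_min = attr(x, "fc_min"), p_max = attr(x, "p_max"),
         group1 = attr(x, "groups")[1], group2 = attr(x, "groups")[2])
}

# vectorized two-sided two-sample location test on matrix rows;
# cross-checked against stats::t.test in the test suite
row_welch <- function(g1, g2, var_equal = FALSE) {
  n1 <- ncol(g1); n2 <- ncol(g2)
  m1 <- rowMeans(g1); m2 <- rowMeans(g2)
  v1 <- rowSums((g1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((g2 - m2)^2) / (n2 - 1)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(m1))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- (m1 - m2) / se
  p <- 2 * pt(-abs(t), df)
  # degenerate rows: zero within-group variance
  zero_se <- se == 0
  p[zero_se & m1 == m2] <- 1
  p[zero_se & m1 != m2] <- 0
  list(t = t, df = df, p = p)
}

check_expression <- function(expr) {
  stopifnot(is.data.frame(expr))
  if (!"gene" %in% names(expr)) abort("`expr` needs a `gene` column")
  if (anyDuplicated(expr$gene)) abort("gene ids must be unique")
  samples <- setdiff(names(expr), "gene")
  for (s in samples) {
    if (!is.numeric(expr[[s]])) abort(paste0("sample column ", s, " is not numeric"))
    if (anyNA(expr[[s]])) abort(paste0("missing values in sample ", s))
  }
  as_tibble(expr)
}

#' Over-representation of gene sets by the hypergeometric test
#'
#' For each annotation set, the one-sided hypergeometric tail probability
#' of drawing at least the observed overlap when `length(selected)` genes
#' are drawn from the universe without replacement. A generic
#' over-representation test against user-supplied gene collections (e.g.
#' pathway or ontology sets in GMT form).
#'
#' @param selected Character vector of selected genes; must be a subset of
#'   `universe`.
#' @param annotation Named list of character vectors (gene sets); each set
#'   is intersected with the universe first.
#' @param universe Character vector, the gene universe.
#'
#' @return A tibble `set`, `set_size` (within universe), `overlap`,
#'   `expected`, `p_value`, `p_adjusted` (Benjamini-Hochberg), ordered by
#'   `p_value`.
#' @export
hypergeometric_enrichment <- function(selected, annotation, universe) {
  universe <- unique(normalize_symbols(universe))
  if (length(universe) == 0) abort("empty universe")
  selected <- unique(normalize_symbols(selected))
  if (!all(selected %in% universe)) {
    abort("`selected` must be a subset of `universe`")
  }
  if (!is.list(annotation) || is.null(names(annotation))) {
    abort("`annotation` must be a named list of gene sets")
  }
  N <- length(universe); k <- length(selected)
  rows <- imap(annotation, function(set, name) {
    set <- intersect(unique(normalize_symbols(set)), universe)
    K <- length(set)
    ov <- length(intersect(set, selected))
    p <- if (K == 0) 1 else phyper(ov - 1, K, N - K, k, lower.tail = FALSE)
    tibble(set = name, set_size = K, overlap = ov,
           expected = k * K / N, p_value = p)
  })
  out <- bind_rows(rows)
  out$p_adjusted <- p.adjust(out$p_value, method = "BH")
  arrange(out, .data$p_value, .data$set)
}
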