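#' Validate a pipeline run configuration
#'
#' A run configuration (a YAML file or an R list) names the input files
#' and fixes every threshold of the protocol. Defaults are the standard
#' printed thresholds of the screening protocol: OB >= 30%, DL >= 0.18,
#' PPI score > 0.850, fold change > 1.5 with p < 0.05, top 50% retention,
#' top 10 combinations reported. Unknown keys are rejected; every
#' threshold is range-checked; defaults are filled in and echoed.
#'
#' Recognised keys: input paths (`catalog`, `compound_target`, `ppi`,
#' `disease`, and either `syndrome` or `expression` + `groups`), `out_dir`,
#' thresholds (`ob_min`, `dl_min`, `ppi_score_min`, `fc_min`, `p_max`,
#' `fraction`, `min_size`, `top_k`), `selection_method` (`"per_indicator"`
#' or `"score"`, see [select_core_compounds()]), `orientation`,
#' `shared_targets`, `double_r`, `raw_score_mode`, and `seed`.
#'
#' @param config Path to a YAML file, or a named list.
#' @param check_files Verify that the referenced input files exist
#'   (default `TRUE`).
#'
#' @return A validated `run_config` list with all defaults filled, or an
#'   error listing every violation (key, value, allowed domain).
#' @export
validate_run_config <- function(config, check_files = TRUE) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) abort(paste0("config file not found: ", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("`config` must be a YAML path or a named list")

  defaults <- list(
    catalog = NULL, compound_target = NULL, ppi = NULL,
    disease = NULL, syndrome = NULL, expression = NULL, groups = NULL,
    out_dir = NULL,
    ob_min = 30, dl_min = 0.18, ppi_score_min = 0.850,
    fc_min = 1.5, p_max = 0.05, fraction = 0.5,
    min_size = 1, top_k = 10,
    selection_method = "per_indicator",
    orientation = as.list(default_orientation()),
    shared_targets = TRUE, double_r = TRUE, raw_score_mode = FALSE,
    seed = 1
  )
  unknown <- setdiff(names(config), names(defaults))
  errors <- character()
  if (length(unknown)) {
    errors <- c(errors, paste0("unknown key(s): ", paste(unknown, collapse = ", ")))
  }
  defaulted <- setdiff(names(defaults)[!vapply(defaults, is.null, logical(1))],
                       names(config))
  cfg <- modifyList(defaults, config[setdiff(names(config), unknown)])

  check_range <- function(key, lo, hi, lo_open = FALSE, hi_open = FALSE) {
    v <- cfg[[key]]
    ok <- is.numeric(v) && length(v) == 1L && is.finite(v) &&
      (if (lo_open) v > lo else v >= lo) && (if (hi_open) v < hi else v <= hi)
    if (!ok) {
      errors <<- c(errors, sprintf(
        "%s = %s outside its domain %s%s, %s%s", key,
        paste(v, collapse = ","), if (lo_open) "(" else "[", lo, hi,
        if (hi_open) ")" else "]"))
    }
  }
  check_range("ob_min", 0, 100)
  check_range("dl_min", 0, 1)
  check_range("ppi_score_min", 0, 1)
  check_range("fc_min", 1, Inf, lo_open = TRUE)
  check_range("p_max", 0, 1, lo_open = TRUE)
  check_range("fraction", 0, 1, lo_open = TRUE)
  check_range("min_size", 1, Inf)
  check_range("top_k", 1, Inf)
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L) {
    errors <- c(errors, "seed must be a single integer")
  }
  ori <- unlist(cfg$orientation)
  if (!setequal(names(ori), .INDICATORS) ||
      !all(ori %in% c("positive", "inverse"))) {
    errors <- c(errors, "orientation must map nc, cpl, nh, r to positive/inverse")
  }
  if (!cfg$selection_method %in% c("per_indicator", "score")) {
    errors <- c(errors, "selection_method must be \"per_indicator\" or \"score\"")
  }
  for (flag in c("shared_targets", "double_r", "raw_score_mode")) {
    if (!is.logical(cfg[[flag]]) || length(cfg[[flag]]) != 1L) {
      errors <- c(errors, paste0(flag, " must be TRUE or FALSE"))
    }
  }
  needed <- c("catalog", "compound_target", "ppi", "disease", "out_dir")
  for (key in needed) {
    if (is.null(cfg[[key]])) errors <- c(errors, paste0("missing required key: ", key))
  }
  if (is.null(cfg$syndrome) && (is.null(cfg$expression) || is.null(cfg$groups))) {
    errors <- c(errors,
                "either `syndrome` (a DEG list) or `expression` + `groups` is required")
  }
  if (check_files) {
    for (key in c("catalog", "compound_target", "ppi", "disease",
                  "syndrome", "expression", "groups")) {
      p <- cfg[[key]]
      if (!is.null(p) && !file.exists(p)) {
        errors <- c(errors, paste0(key, " file not found: ", p))
      }
    }
  }
  if (length(errors)) {
    abort(paste0("invalid run configuration:\n",
                 paste0("  - ", errors, collapse = "\n")))
  }
  if (length(defaulted)) {
    inform(paste0("defaults applied for: ", paste(defaulted, collapse = ", ")))
  }
  cfg$orientation <- ori[.INDICATORS]
  structure(cfg, class = "run_config", defaulted = defaulted)
}

#' Run the combination-discovery pipeline end to end
#'
#' Executes, in order: input ingestion; the OB/DL compound screen; the
#' DEG filter on the expression matrix (or a precomputed syndrome DEG
#' list); PPI expansion of the formula targets; the three-way Venn
#' intersection with the disease targets; network assembly on the common
#' targets; core-network extraction by topological gating; single-compound
#' knockouts with core-compound selection; and combination ranking. Every
#' intermediate artifact is written under `out_dir`, together with a JSON
#' run manifest (configuration echo, versions, seed, per-stage row counts
#' and wall time). Identical configurations produce byte-identical ranking
#' reports.
#'
#' @param config A `run_config` from [validate_run_config()], a list, or a
#'   YAML path.
#' @return The manifest, invisibly, as a list; the ranking is also
#'   returned in `$ranking` (a `combination_ranking`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- validate_run_config(config)
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  t0 <- Sys.time()
  stages <- list()
  note <- function(stage, n) stages[[stage]] <<- n

  # 1: ingest
  catalog <- read_compound_catalog(config$catalog)
  ct_edges <- read_edge_tsv(config$compound_target)
  names(ct_edges)[1:2] <- c("compound", "target")
  ppi <- read_string_ppi(config$ppi)
  disease <- read_gene_list(config$disease)

  # 2: ADMET screen
  active <- filter_compounds_admet(catalog, config$ob_min, config$dl_min)
  readr::write_tsv(active, file.path(out, "active_compounds.tsv"))
  if (nrow(active) == 0) abort("stage admet_screen: no compound passed the OB/DL filter")
  note("ingest", length(unique(active$compound_id)))

  # 3: syndrome DEGs
  if (!is.null(config$syndrome)) {
    syndrome <- read_gene_list(config$syndrome)
  } else {
    expr <- read_expression_matrix(config$expression)
    groups <- read_group_assignments(config$groups)
    deg <- two_group_deg(quantile_normalize(expr), groups,
                         fc_min = config$fc_min, p_max = config$p_max)
    readr::write_tsv(deg, file.path(out, "deg_table.tsv"))
    syndrome <- deg$gene[deg$passes]
  }
  write_gene_list(syndrome, file.path(out, "syndrome_degs.txt"))
  if (length(syndrome) == 0) abort("stage deg_filter: no differentially expressed genes")
  note("deg_filter", length(syndrome))

  # 4: formula targets, PPI-expanded
  ct_active <- ct_edges[ct_edges$compound %in% active$compound_id, , drop = FALSE]
  primary <- unique(normalize_symbols(ct_active$target))
  formula_targets <- expand_targets_ppi(primary, ppi,
                                        score_min = config$ppi_score_min)
  write_gene_list(formula_targets, file.path(out, "formula_targets.txt"))

  # 5: Venn intersection
  sets <- list(formula = formula_targets, syndrome = syndrome, disease = disease)
  common <- intersect_target_sets(sets)
  write_venn_json(attr(common, "venn_regions"), file.path(out, "venn.json"))
  write_gene_list(common, file.path(out, "common_targets.txt"))
  if (length(common) == 0) abort("stage venn: empty three-way intersection")
  note("venn", length(common))

  # 6: network assembly on the common targets
  hc <- unique(tibble(herb = active$herb, compound = active$compound_id))
  ct_kept <- ct_active[normalize_symbols(ct_active$target) %in% common, , drop = FALSE]
  ppi_kept <- ppi[ppi$score > config$ppi_score_min &
                    normalize_symbols(ppi$protein_a) %in% common &
                    normalize_symbols(ppi$protein_b) %in% common, , drop = FALSE]
  hc <- hc[hc$compound %in% ct_kept$compound, , drop = FALSE]
  net <- build_pharm_network(
    herb_compound_edges = hc,
    compound_target_edges = ct_kept[c("compound", "target")],
    target_target_edges = ppi_kept[c("protein_a", "protein_b")]
  )
  write_graphml(net, file.path(out, "network.graphml"))
  write_sif(net, file.path(out, "network.sif"))
  note("network_build", nrow(network_nodes(net)))

  # 7: core extraction (relaxed automatically if gating removes the compounds)
  profiles <- node_topology_profiles(net)
  readr::write_tsv(profiles, file.path(out, "topology_profiles.tsv"))
  core <- tryCatch(extract_core_network(net, profiles), error = function(e) NULL)
  n_compounds_in <- function(x) {
    if (is.null(x)) 0L else sum(network_nodes(x)$kind == "compound")
  }
  if (n_compounds_in(core) < 2L) {
    core <- tryCatch(extract_core_network(net, profiles, strict = FALSE),
                     error = function(e) NULL)
  }
  if (n_compounds_in(core) < 2L) {
    warn("topological gating left fewer than two compounds; using the full network as core")
    core <- net
  }
  write_graphml(core, file.path(out, "core_network.graphml"))
  note("core_extraction", nrow(network_nodes(core)))

  # 8: single-compound knockouts and core-compound selection
  core_nodes <- network_nodes(core)
  compounds <- sort(core_nodes$id[core_nodes$kind == "compound"])
  singles <- build_indicator_matrix(core, as.list(compounds),
                                    orientation = config$orientation,
                                    shared_targets = config$shared_targets)
  readr::write_tsv(as_tibble(singles), file.path(out, "single_indicator_matrix.tsv"))
  note("single_knockouts", nrow(singles))
  single_w <- entropy_weights(minmax_normalize(singles))
  single_scores <- contribution_scores(single_w, matrix = singles,
                                       raw_values = config$raw_score_mode,
                                       double_r = config$double_r)
  readr::write_tsv(single_scores, file.path(out, "single_compound_scores.tsv"))
  selected <- select_core_compounds(singles, fraction = config$fraction,
                                    method = config$selection_method,
                                    orientation = config$orientation,
                                    double_r = config$double_r)
  if (length(selected) < 2L) {
    warn("per-indicator intersection retained fewer than two compounds; using score-based retention")
    selected <- select_core_compounds(singles, fraction = config$fraction,
                                      method = "score",
                                      orientation = config$orientation,
                                      double_r = config$double_r)
  }
  write_gene_list(selected, file.path(out, "selected_compounds.txt"))
  if (length(selected) < 2L) abort("stage selection: fewer than two core compounds retained")
  note("compound_selection", length(selected))

  # 9: combination ranking
  ranking <- rank_combinations(core, selected,
                               top_k = config$top_k, min_size = config$min_size,
                               orientation = config$orientation,
                               shared_targets = config$shared_targets,
                               double_r = config$double_r)
  readr::write_tsv(ranking$ranking, file.path(out, "combination_ranking.tsv"))
  jsonlite::write_json(
    list(ranking = head(ranking$ranking, ranking$top_k),
         weights = as.list(ranking$weights$w),
         orientation = as.list(config$orientation),
         double_r = config$double_r,
         excluded = ranking$excluded,
         seed = config$seed),
    file.path(out, "combination_ranking.json"),
    auto_unbox = TRUE, digits = NA)
  note("combination_ranking", nrow(ranking$ranking))

  manifest <- list(
    config = unclass(config),
    package_version = as.character(utils::packageVersion("netcontrib")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    stages = stages,
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  manifest$ranking <- ranking
  invisible(manifest)
}
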