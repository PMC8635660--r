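#' Configuration for the synthetic-data generators
#'
#' One object fixes every stochastic choice of the generators, so that any
#' artifact is a pure function of its configuration. Defaults emulate the
#' magnitudes of an eight-herb formula study: 8 herbs, 170 compounds, 800
#' targets on a scale-free interaction layer; three gene lists (disease,
#' syndrome, formula) with a designed seven-region Venn structure; and a
#' 16-vs-16 blood-transcriptome matrix of 1000 genes with 100 planted
#' differentially expressed genes at |log2 fold change| 1.5 and
#' within-group standard deviation 0.5 on the log2 scale.
#'
#' @param n_herbs,n_compounds,n_targets Layer sizes.
#' @param degree_model `"scale-free"` (preferential attachment) or
#'   `"uniform"` (Erdős–Rényi) for the target-target layer.
#' @param pa_power Preferential-attachment exponent (scale-free model).
#' @param ppi_edges_per_target Edges added per target during attachment
#'   (scale-free) or used to set the expected edge count (uniform).
#' @param targets_per_compound Mean number of targets per (unplanted)
#'   compound.
#' @param n_planted_hubs Number of planted high-impact compounds.
#' @param planted_hub_boost Multiplier (>= 1) on a planted compound's
#'   target degree; planted compounds attach to the highest-degree
#'   targets.
#' @param overlap_design Named integer vector of the seven Venn region
#'   sizes over the sets `disease`, `syndrome`, `formula` (names like
#'   `"disease"`, `"disease&syndrome"`, `"disease&syndrome&formula"`).
#' @param expr_design Named list `n_genes`, `n_per_group`, `n_deg`,
#'   `log2fc`, `sigma` for the expression generator.
#' @param seed Integer seed fixing every stochastic choice.
#'
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_herbs = 8, n_compounds = 170, n_targets = 800,
                         degree_model = c("scale-free", "uniform"),
                         pa_power = 1, ppi_edges_per_target = 2,
                         targets_per_compound = 5,
                         n_planted_hubs = 1, planted_hub_boost = 5,
                         overlap_design = c(
                           "disease" = 700, "syndrome" = 600, "formula" = 400,
                           "disease&syndrome" = 150, "disease&formula" = 120,
                           "syndrome&formula" = 100,
                           "disease&syndrome&formula" = 181),
                         expr_design = list(n_genes = 1000, n_per_group = 16,
                                            n_deg = 100, log2fc = 1.5,
                                            sigma = 0.5),
                         seed = 1) {
  degree_model <- match.arg(degree_model)
  cfg <- list(n_herbs = n_herbs, n_compounds = n_compounds,
              n_targets = n_targets, degree_model = degree_model,
              pa_power = pa_power, ppi_edges_per_target = ppi_edges_per_target,
              targets_per_compound = targets_per_compound,
              n_planted_hubs = n_planted_hubs,
              planted_hub_boost = planted_hub_boost,
              overlap_design = overlap_design,
              expr_design = expr_design, seed = seed)
  counts <- c(n_herbs, n_compounds, n_targets,
              expr_design$n_genes, expr_design$n_per_group)
  if (any(counts < 1)) abort("all counts must be positive")
  if (n_planted_hubs < 0 || n_planted_hubs > n_compounds) {
    abort("`n_planted_hubs` must lie in [0, n_compounds]")
  }
  if (planted_hub_boost < 1) abort("`planted_hub_boost` must be >= 1")
  if (expr_design$n_deg > expr_design$n_genes) {
    abort("`n_deg` cannot exceed `n_genes`")
  }
  if (expr_design$sigma < 0) abort("`sigma` must be non-negative")
  structure(cfg, class = "synth_config")
}

# evaluate code under a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a tripartite herb-compound-target network with planted hubs
#'
#' The target layer is a scale-free (preferential attachment) or uniform
#' random interaction graph. Each unplanted compound attaches to a small
#' random set of targets; planted compounds attach to the targets of
#' highest degree in the target layer, with `planted_hub_boost` times the
#' base target count — their knockout therefore removes network hubs and
#' destabilizes the surviving graph, which is the ground truth the
#' ranking stage should recover. Each compound belongs to one or two
#' herbs.
#'
#' @param config A [synth_config()].
#' @return A list with `network` (a [pharm_network()]), `planted`
#'   (compound ids of the planted hubs), and the three edge tables
#'   `herb_compound`, `compound_target`, `target_target` (the last with a
#'   `score` column in (0.85, 1\] so it can double as a high-confidence
#'   PPI table).
#' @export
synth_pharm_network <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    herbs <- sprintf("H%02d", seq_len(config$n_herbs))
    compounds <- sprintf("C%03d", seq_len(config$n_compounds))
    targets <- sprintf("T%04d", seq_len(config$n_targets))

    g <- if (config$degree_model == "scale-free") {
      igraph::sample_pa(config$n_targets, power = config$pa_power,
                        m = config$ppi_edges_per_target, directed = FALSE)
    } else {
      igraph::sample_gnm(config$n_targets,
                         m = config$ppi_edges_per_target * config$n_targets)
    }
    el <- igraph::as_edgelist(g)
    tt <- tibble(from = targets[as.integer(el[, 1])],
                 to = targets[as.integer(el[, 2])]) |>
      filter(.data$from != .data$to) |>
      distinct()
    tt$score <- round(runif(nrow(tt), 0.851, 1), 3)

    deg <- igraph::degree(g)
    planted <- if (config$n_planted_hubs > 0) {
      sort(sample(compounds, config$n_planted_hubs))
    } else character()
    k_base <- pmax(1, rpois(config$n_compounds, config$targets_per_compound))
    names(k_base) <- compounds
    k_planted <- round(config$planted_hub_boost *
                         pmax(k_base[planted], config$targets_per_compound))
    if (length(k_planted) && max(k_planted) > config$n_targets) {
      abort("planted_hub_boost demands more targets than exist")
    }
    hub_order <- order(deg, decreasing = TRUE)
    ct <- bind_rows(lapply(compounds, function(cmp) {
      if (cmp %in% planted) {
        picked <- targets[hub_order[seq_len(k_planted[[cmp]])]]
      } else {
        picked <- sample(targets, min(k_base[[cmp]], config$n_targets))
      }
      tibble(compound = cmp, target = picked)
    }))

    hc <- bind_rows(lapply(compounds, function(cmp) {
      tibble(herb = sample(herbs, sample(1:2, 1)), compound = cmp)
    }))

    net <- build_pharm_network(herb_compound_edges = hc,
                               compound_target_edges = ct,
                               target_target_edges = tt[c("from", "to")])
    list(network = net, planted = planted,
         herb_compound = hc, compound_target = ct, target_target = tt)
  })
}

#' Generate three gene lists with a designed Venn structure
#'
#' Draws disjoint synthetic gene symbols and assigns them to the seven
#' Venn regions of the `disease`, `syndrome` and `formula` sets exactly as
#' designed, so intersection code can be checked against known region
#' sizes.
#'
#' @param config A [synth_config()]; uses `overlap_design` and `seed`.
#' @return A list `disease`, `syndrome`, `formula` (character vectors) and
#'   `truth` (a tibble `region`, `n` of the designed sizes).
#' @export
synth_gene_lists <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  design <- config$overlap_design
  region_names <- c("disease", "syndrome", "formula",
                    "disease&syndrome", "disease&formula", "syndrome&formula",
                    "disease&syndrome&formula")
  if (!setequal(names(design), region_names)) {
    abort(paste0("`overlap_design` must name exactly the regions: ",
                 paste(region_names, collapse = ", ")))
  }
  if (any(design < 0) || any(design != round(design))) {
    abort("region sizes must be non-negative integers")
  }
  with_seed(config$seed, {
    total <- sum(design)
    symbols <- sprintf("G%05d", sample.int(10 * max(total, 1), total))
    idx <- 0
    member <- list(disease = character(), syndrome = character(),
                   formula = character())
    for (rn in region_names) {
      n <- design[[rn]]
      if (n == 0) next
      sym <- symbols[idx + seq_len(n)]
      idx <- idx + n
      for (set in strsplit(rn, "&", fixed = TRUE)[[1]]) {
        member[[set]] <- c(member[[set]], sym)
      }
    }
    member <- lapply(member, sort)
    member$truth <- tibble(region = region_names,
                           n = as.integer(design[region_names]))
    member
  })
}

#' Generate a two-group expression matrix with planted DEGs
#'
#' Log-normal intensities: per-gene baseline log2 means are drawn from a
#' normal distribution, sample noise is normal on the log2 scale with
#' standard deviation `sigma`, and the first `n_deg` genes are shifted by
#' `log2fc` in group 1 (alternating up/down). With `sigma = 0` every
#' planted gene's fold change is exactly `2^log2fc`.
#'
#' @param config A [synth_config()]; uses `expr_design` and `seed`.
#' @param genes Optional character vector of gene ids to use (length
#'   `n_genes`); generated ids by default.
#' @param deg_genes Optional character vector (subset of `genes`, length
#'   `n_deg`) naming the planted DEGs; the first `n_deg` genes by default.
#' @return A list `expr` (tibble: `gene` plus sample columns), `groups`
#'   (named vector over samples, levels `"g1"`, `"g2"`), `truth` (tibble
#'   `gene`, `direction` for the planted DEGs).
#' @export
synth_expression <- function(config = synth_config(), genes = NULL,
                             deg_genes = NULL) {
  stopifnot(inherits(config, "synth_config"))
  d <- config$expr_design
  genes <- genes %||% sprintf("G%05d", seq_len(d$n_genes))
  if (length(genes) != d$n_genes || anyDuplicated(genes)) {
    abort("`genes` must supply n_genes distinct ids")
  }
  deg_genes <- deg_genes %||% genes[seq_len(d$n_deg)]
  if (length(deg_genes) != d$n_deg || !all(deg_genes %in% genes)) {
    abort("`deg_genes` must be n_deg ids drawn from `genes`")
  }
  with_seed(config$seed, {
    samples <- c(sprintf("s1_%02d", seq_len(d$n_per_group)),
                 sprintf("s2_%02d", seq_len(d$n_per_group)))
    groups <- setNames(rep(c("g1", "g2"), each = d$n_per_group), samples)
    base <- rnorm(d$n_genes, mean = 8, sd = 1.5)
    shift <- numeric(d$n_genes)
    direction <- character(0)
    deg_idx <- match(deg_genes, genes)
    if (d$n_deg > 0) {
      direction <- rep(c("up", "down"), length.out = d$n_deg)
      shift[deg_idx] <- ifelse(direction == "up", d$log2fc, -d$log2fc)
    }
    m <- matrix(0, nrow = d$n_genes, ncol = 2 * d$n_per_group,
                dimnames = list(genes, samples))
    for (j in seq_along(samples)) {
      mu <- base + if (groups[[j]] == "g1") shift else 0
      m[, j] <- 2^(mu + rnorm(d$n_genes, 0, d$sigma))
    }
    expr <- bind_cols(tibble(gene = genes), as_tibble(as.data.frame(m)))
    truth <- tibble(gene = deg_genes, direction = direction)
    list(expr = expr, groups = groups, truth = truth)
  })
}

#' Write a complete synthetic input bundle to disk
#'
#' Emits exactly the file formats the ingest functions read — compound
#' catalog TSV, compound-target and scored PPI edge TSVs, disease gene
#' list, and the expression matrix with its group assignments — so the
#' whole pipeline can run end-to-end from generated files. All layers
#' share one symbol namespace: the expression matrix's genes include
#' every network target (plus filler genes up to `n_genes`), the planted
#' DEGs are drawn preferentially from the targets of the planted
#' compounds and then from random targets, and the disease list covers
#' the planted compounds' targets plus a random half of all targets, so
#' the syndrome-disease-formula intersection is non-degenerate and still
#' contains the planted signal.
#'
#' @param config A [synth_config()]; `expr_design$n_genes` must be at
#'   least `n_targets`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the written paths plus the ground
#'   truth (`planted`, `deg_truth`).
#' @export
write_synth_inputs <- function(config = synth_config(), dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (config$expr_design$n_genes < config$n_targets) {
    abort("`expr_design$n_genes` must be at least `n_targets` for a coherent bundle")
  }
  nw <- synth_pharm_network(config)
  d <- config$expr_design
  targets <- sprintf("T%04d", seq_len(config$n_targets))
  filler <- if (d$n_genes > config$n_targets) {
    sprintf("G%05d", seq_len(d$n_genes - config$n_targets))
  } else character()
  planted_targets <- sort(unique(
    nw$compound_target$target[nw$compound_target$compound %in% nw$planted]))

  aux <- with_seed(config$seed + 1L, {
    pool <- c(intersect(planted_targets, targets),
              sample(setdiff(targets, planted_targets)))
    deg_genes <- pool[seq_len(min(d$n_deg, length(pool)))]
    disease <- sort(unique(c(planted_targets,
                             sample(targets, ceiling(length(targets) / 2)))))
    list(deg_genes = deg_genes, disease = disease)
  })
  ex <- synth_expression(config, genes = c(targets, filler),
                         deg_genes = aux$deg_genes)

  catalog <- with_seed(config$seed + 2L, {
    comp <- unique(nw$herb_compound[c("herb", "compound")])
    tibble(compound_id = comp$compound,
           name = paste0("compound-", comp$compound),
           herb = comp$herb,
           ob = round(runif(nrow(comp), 20, 90), 1),
           dl = round(runif(nrow(comp), 0.1, 0.9), 3))
  })
  # planted compounds must survive the ADMET screen
  catalog$ob[catalog$compound_id %in% nw$planted] <- 60
  catalog$dl[catalog$compound_id %in% nw$planted] <- 0.5

  paths <- list(
    catalog = file.path(dir, "catalog.tsv"),
    compound_target = file.path(dir, "compound_target.tsv"),
    ppi = file.path(dir, "ppi.tsv"),
    disease = file.path(dir, "disease_targets.txt"),
    expression = file.path(dir, "expression.tsv"),
    groups = file.path(dir, "groups.tsv")
  )
  readr::write_tsv(catalog, paths$catalog)
  readr::write_tsv(nw$compound_target, paths$compound_target)
  readr::write_tsv(
    tibble(protein_a = nw$target_target$from,
           protein_b = nw$target_target$to,
           score = nw$target_target$score),
    paths$ppi)
  write_gene_list(aux$disease, paths$disease)
  write_expression_matrix(ex$expr, paths$expression)
  readr::write_tsv(tibble(sample = names(ex$groups), group = unname(ex$groups)),
                   paths$groups)
  invisible(c(paths, list(planted = nw$planted, deg_truth = ex$truth)))
}
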