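test_that("generators are pure functions of their configuration", {
  cfg <- small_synth_config(seed = 101)
  a <- synth_pharm_network(cfg)
  b <- synth_pharm_network(cfg)
  expect_identical(network_edges(a$network), network_edges(b$network))
  expect_identical(a$planted, b$planted)

  ga <- synth_gene_lists(cfg); gb <- synth_gene_lists(cfg)
  expect_identical(ga$disease, gb$disease)

  ea <- synth_expression(cfg); eb <- synth_expression(cfg)
  expect_identical(ea$expr, eb$expr)

  # the generator restores the caller's RNG state
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(synth_pharm_network(cfg)); after <- runif(1)
  expect_identical(before, after)
})

test_that("generated networks satisfy the container invariants", {
  for (seed in c(1, 7)) {
    nw <- synth_pharm_network(small_synth_config(seed = seed))
    nodes <- network_nodes(nw$network)
    edges <- network_edges(nw$network)
    expect_true(all(edges$from %in% nodes$id))
    expect_true(all(edges$to %in% nodes$id))
    expect_false(any(edges$from == edges$to))
    key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
    expect_false(anyDuplicated(key) > 0)
    expect_setequal(unique(nodes$kind), c("herb", "compound", "target"))
  }
})

test_that("planting is controlled by the configuration", {
  none <- synth_pharm_network(small_synth_config(seed = 3, n_planted_hubs = 0))
  expect_length(none$planted, 0L)

  one <- synth_pharm_network(small_synth_config(seed = 3))
  expect_length(one$planted, 1L)
  # the planted compound hits boosted target counts on top-degree targets
  map <- one$compound_target
  planted_deg <- sum(map$compound == one$planted)
  other_deg <- mean(table(map$compound[map$compound != one$planted]))
  expect_gt(planted_deg, 2 * other_deg)
})

test_that("boosted planting destabilizes the network more than unit boost", {
  # paired seeds: knockout robustness drop is larger under boost 5 than boost 1
  delta <- function(boost, seed) {
    nw <- synth_pharm_network(small_synth_config(
      seed = seed, planted_hub_boost = boost))
    intact <- stability_indicators(nw$network)
    res <- knockout_entity(nw$network, nw$planted)
    intact$r - res$indicators$r
  }
  d5 <- vapply(1:8, function(s) delta(5, s), numeric(1))
  d1 <- vapply(1:8, function(s) delta(1, s), numeric(1))
  expect_gt(mean(d5), mean(d1))
})

test_that("gene lists realize the designed Venn regions exactly", {
  cfg <- small_synth_config(seed = 11)
  gl <- synth_gene_lists(cfg)
  sets <- list(disease = gl$disease, syndrome = gl$syndrome,
               formula = gl$formula)
  common <- intersect_target_sets(sets)
  expect_length(common, 181L)
  regions <- attr(common, "venn_regions")
  for (i in seq_len(nrow(gl$truth))) {
    rn <- gl$truth$region[i]
    parts <- sort(strsplit(rn, "&", fixed = TRUE)[[1]])
    match_row <- which(vapply(seq_len(nrow(regions)), function(j) {
      inset <- names(sets)[unlist(regions[j, names(sets)])]
      setequal(sort(inset), parts)
    }, logical(1)))
    expect_equal(regions$n[match_row], gl$truth$n[i])
  }

  # degenerate design: one exclusive region only
  cfg2 <- small_synth_config(seed = 12, overlap_design = c(
    "disease" = 10, "syndrome" = 0, "formula" = 0,
    "disease&syndrome" = 0, "disease&formula" = 0, "syndrome&formula" = 0,
    "disease&syndrome&formula" = 0))
  gl2 <- synth_gene_lists(cfg2)
  expect_length(gl2$disease, 10L)
  expect_length(gl2$syndrome, 0L)
  expect_length(intersect(gl2$disease, gl2$formula), 0L)
})

test_that("random feasible Venn designs are realized per membership tally", {
  for (seed in 1:5) {
    set.seed(seed * 1000)
    design <- setNames(sample(0:40, 7, replace = TRUE),
                       c("disease", "syndrome", "formula",
                         "disease&syndrome", "disease&formula",
                         "syndrome&formula", "disease&syndrome&formula"))
    gl <- synth_gene_lists(small_synth_config(seed = seed,
                                              overlap_design = design))
    tally <- function(in_d, in_s, in_f) {
      u <- unique(c(gl$disease, gl$syndrome, gl$formula))
      sum(vapply(u, function(g) {
        (g %in% gl$disease) == in_d && (g %in% gl$syndrome) == in_s &&
          (g %in% gl$formula) == in_f
      }, logical(1)))
    }
    expect_equal(tally(TRUE, FALSE, FALSE), unname(design["disease"]))
    expect_equal(tally(TRUE, TRUE, FALSE), unname(design["disease&syndrome"]))
    expect_equal(tally(TRUE, TRUE, TRUE),
                 unname(design["disease&syndrome&formula"]))
  }
})

test_that("noise-free expression gives exact planted fold changes", {
  cfg <- synth_config(expr_design = list(n_genes = 50, n_per_group = 3,
                                         n_deg = 10, log2fc = 1, sigma = 0),
                      seed = 21)
  ex <- synth_expression(cfg)
  deg <- suppressWarnings(two_group_deg(ex$expr, ex$groups, fc_min = 1.5))
  planted <- deg$gene %in% ex$truth$gene
  expect_equal(sort(unique(round(deg$fold_change[planted], 10))), c(0.5, 2))
  expect_equal(deg$fold_change[!planted], rep(1, 40))
})

test_that("the null expression generator plants nothing", {
  cfg <- synth_config(expr_design = list(n_genes = 30, n_per_group = 4,
                                         n_deg = 0, log2fc = 2, sigma = 0.3),
                      seed = 22)
  ex <- synth_expression(cfg)
  expect_equal(nrow(ex$truth), 0L)
  expect_error(synth_config(expr_design = list(n_genes = 5, n_per_group = 4,
                                               n_deg = 10, log2fc = 1,
                                               sigma = 0.1)),
               "n_deg")
})

test_that("the written input bundle is readable and coherent", {
  dir <- withr::local_tempdir()
  cfg <- synth_config(n_herbs = 3, n_compounds = 20, n_targets = 150,
                      expr_design = list(n_genes = 200, n_per_group = 4,
                                         n_deg = 40, log2fc = 1.5, sigma = 0.4),
                      seed = 5)
  truth <- write_synth_inputs(cfg, dir)
  catalog <- read_compound_catalog(truth$catalog)
  expect_true(all(truth$planted %in% catalog$compound_id))
  ppi <- read_string_ppi(truth$ppi)
  expect_true(all(ppi$score > 0.85))
  expr <- read_expression_matrix(truth$expression)
  expect_equal(nrow(expr), 200L)
  disease <- read_gene_list(truth$disease)
  # planted DEGs live in the target namespace shared with the disease list
  expect_true(any(truth$deg_truth$gene %in% disease))
})
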