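test_that("ADMET filter keeps boundary compounds and matches a brute-force scan", {
  boundary <- tibble::tibble(compound_id = "c", name = "c", ob = 30, dl = 0.18)
  expect_equal(nrow(filter_compounds_admet(boundary)), 1L)

  empty <- tibble::tibble(compound_id = character(), name = character(),
                          ob = numeric(), dl = numeric())
  expect_equal(nrow(filter_compounds_admet(empty)), 0L)

  set.seed(11)
  catalog <- tibble::tibble(compound_id = sprintf("c%02d", 1:20),
                            name = sprintf("name%02d", 1:20),
                            ob = runif(20, 0, 100), dl = runif(20, 0, 1))
  got <- filter_compounds_admet(catalog, 30, 0.18)
  keep <- logical(20)
  for (i in 1:20) keep[i] <- catalog$ob[i] >= 30 && catalog$dl[i] >= 0.18
  expect_equal(got$compound_id, catalog$compound_id[keep])

  # idempotence
  expect_equal(filter_compounds_admet(got, 30, 0.18)$compound_id,
               got$compound_id)
})

test_that("ADMET filter drops invalid rows with a warning", {
  catalog <- tibble::tibble(compound_id = c("a", "b", "c"),
                            ob = c(50, NA, -3), dl = c(0.5, 0.5, 0.5))
  expect_warning(out <- filter_compounds_admet(catalog), "invalid")
  expect_equal(out$compound_id, "a")
  expect_equal(attr(out, "n_invalid"), 2L)
})

test_that("PPI expansion is one round, strict at the score boundary", {
  ppi <- tibble::tibble(protein_a = "A", protein_b = "B", score = 0.850)
  expect_equal(expand_targets_ppi("A", ppi, 0.850), "A",
               ignore_attr = TRUE)
  ppi$score <- 0.851
  expect_setequal(expand_targets_ppi("A", ppi, 0.850), c("A", "B"))

  empty <- tibble::tibble(protein_a = character(), protein_b = character(),
                          score = numeric())
  expect_equal(expand_targets_ppi(c("X", "Y"), empty, 0.5), c("X", "Y"),
               ignore_attr = TRUE)

  # no transitive closure: A-B (high), B-C (high), seeds {A} -> {A, B} only
  chain <- tibble::tibble(protein_a = c("A", "B"), protein_b = c("B", "C"),
                          score = c(0.9, 0.9))
  expect_setequal(expand_targets_ppi("A", chain, 0.85), c("A", "B"))
})

test_that("PPI expansion equals a brute-force neighbourhood union on random graphs", {
  set.seed(21)
  for (rep in 1:5) {
    ids <- sprintf("P%02d", 1:15)
    pairs <- t(combn(ids, 2))
    take <- runif(nrow(pairs)) < 0.3
    ppi <- tibble::tibble(protein_a = pairs[take, 1],
                          protein_b = pairs[take, 2],
                          score = runif(sum(take)))
    seeds <- sample(ids, 3)
    smin <- 0.5
    got <- expand_targets_ppi(seeds, ppi, smin)
    want <- seeds
    for (k in seq_len(nrow(ppi))) {
      if (ppi$score[k] > smin) {
        if (ppi$protein_a[k] %in% seeds) want <- c(want, ppi$protein_b[k])
        if (ppi$protein_b[k] %in% seeds) want <- c(want, ppi$protein_a[k])
      }
    }
    expect_setequal(got, unique(want))
    # superset of seeds and monotone in score_min
    expect_true(all(seeds %in% got))
    expect_true(length(expand_targets_ppi(seeds, ppi, 0.8)) <= length(got))
  }
})

test_that("set intersection normalizes symbols and reports Venn regions", {
  out <- intersect_target_sets(list(x = c("a", "B", "c"), y = c("b ", "C"),
                                    z = "B"))
  expect_equal(as.character(out), "B")

  disjoint <- intersect_target_sets(list(x = c("A"), y = c("B")))
  expect_length(disjoint, 0)

  expect_error(intersect_target_sets(list(only = "A")), "two")

  set.seed(5)
  universe <- sprintf("G%03d", 1:200)
  sets <- list(a = sample(universe, 50), b = sample(universe, 50),
               c = sample(universe, 50))
  got <- intersect_target_sets(sets)
  want <- universe[universe %in% sets$a & universe %in% sets$b &
                     universe %in% sets$c]
  expect_setequal(got, want)

  # commutative over set order
  expect_equal(as.character(intersect_target_sets(sets[c(3, 1, 2)])),
               as.character(got))

  # region counts sum to the union size
  regions <- venn_regions(sets)
  expect_equal(sum(regions$n), length(unique(unlist(sets))))
  expect_equal(regions$n[regions$region == "a&b&c"], length(want))
})

test_that("network construction validates, deduplicates and types edges", {
  net <- toy_network()
  nodes <- network_nodes(net)
  expect_equal(nrow(nodes), 9L)
  expect_equal(nrow(network_edges(net)), 9L)
  expect_equal(sort(unique(network_edges(net)$type)),
               c("compound-target", "herb-compound", "target-target"))

  # duplicates collapse
  expect_warning(
    dup <- build_pharm_network(
      compound_target_edges = data.frame(compound = c("c1", "c1"),
                                         target = c("t1", "t1"))),
    "duplicate")
  expect_equal(nrow(network_edges(dup)), 1L)

  # self loops dropped with warning
  expect_warning(
    looped <- build_pharm_network(
      target_target_edges = data.frame(from = c("t1", "t1"),
                                       to = c("t2", "t1"))),
    "self-loop")
  expect_equal(nrow(network_edges(looped)), 1L)

  # inconsistent kind use rejected
  expect_error(
    build_pharm_network(
      herb_compound_edges = data.frame(herb = "x", compound = "y"),
      compound_target_edges = data.frame(compound = "x", target = "z")),
    "more than one kind")

  # isolated nodes retained and flagged
  iso <- build_pharm_network(
    compound_target_edges = data.frame(compound = "c1", target = "t1"),
    extra_nodes = data.frame(id = "t9", kind = "target"))
  expect_true(network_nodes(iso)$isolated[network_nodes(iso)$id == "t9"])
})

test_that("random tripartite edge tables round-trip through construction", {
  set.seed(31)
  herbs <- sprintf("h%d", 1:3); comps <- sprintf("c%d", 1:6)
  targs <- sprintf("t%d", 1:10)
  hc <- data.frame(herb = sample(herbs, 10, TRUE),
                   compound = sample(comps, 10, TRUE))
  ct <- data.frame(compound = sample(comps, 20, TRUE),
                   target = sample(targs, 20, TRUE))
  suppressWarnings(net <- build_pharm_network(hc, ct))
  e <- network_edges(net)
  want <- unique(rbind(
    data.frame(a = pmin(hc$herb, hc$compound), b = pmax(hc$herb, hc$compound)),
    data.frame(a = pmin(ct$compound, ct$target), b = pmax(ct$compound, ct$target))
  ))
  got <- data.frame(a = pmin(e$from, e$to), b = pmax(e$from, e$to))
  expect_equal(nrow(got), nrow(want))
  expect_setequal(paste(got$a, got$b), paste(want$a, want$b))
})
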