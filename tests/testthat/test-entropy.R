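test_that("min-max normalization maps positive and inverse columns correctly", {
  m <- tibble::tibble(entity_id = c("a", "b", "c"), x = c(2, 4, 6))
  pos <- minmax_normalize(m, orientation = c(x = "positive"))
  expect_equal(pos$x, c(0, 0.5, 1))
  inv <- minmax_normalize(m, orientation = c(x = "inverse"))
  expect_equal(inv$x, c(1, 0.5, 0))

  const <- tibble::tibble(entity_id = c("a", "b"), x = c(3, 3))
  z <- minmax_normalize(const, orientation = c(x = "positive"))
  expect_equal(z$x, c(0, 0))
  expect_equal(attr(z, "constant_columns"), "x")

  set.seed(61)
  r <- tibble::tibble(entity_id = sprintf("e%02d", 1:17),
                      nc = runif(17), cpl = runif(17, 1, 4),
                      nh = runif(17), r = runif(17))
  z <- minmax_normalize(r)
  ori <- default_orientation()
  for (j in c("nc", "cpl", "nh", "r")) {
    x <- r[[j]]
    want <- if (ori[[j]] == "positive") (x - min(x)) / (max(x) - min(x))
            else (max(x) - x) / (max(x) - min(x))
    expect_equal(z[[j]], want, tolerance = 1e-15)
  }
})

test_that("entropy weights match the direct-summation oracle", {
  set.seed(62)
  for (rep in 1:20) {
    zmat <- matrix(runif(15), nrow = 5, ncol = 3,
                   dimnames = list(NULL, c("i1", "i2", "i3")))
    z <- tibble::as_tibble(as.data.frame(zmat))
    z <- dplyr::bind_cols(tibble::tibble(entity_id = sprintf("e%d", 1:5)), z)
    got <- entropy_weights(z)
    want <- oracle_entropy(zmat)
    expect_equal(unname(got$e), want$e, tolerance = 1e-12)
    expect_equal(unname(got$d), want$d, tolerance = 1e-12)
    expect_equal(unname(got$w), want$w, tolerance = 1e-12)
    expect_equal(sum(got$w), 1, tolerance = 1e-12)
    expect_true(all(got$w >= 0))
    # each defined b column sums to 1
    for (j in c("i1", "i2", "i3")) expect_equal(sum(got$b[[j]]), 1)
  }
})

test_that("degenerate entropy cases follow the conventions", {
  # uniform column: e = 1, zero weight contribution
  z <- tibble::tibble(entity_id = c("a", "b", "c", "d"),
                      flat = rep(0.5, 4), varied = c(0, 0.2, 0.7, 1))
  w <- entropy_weights(z)
  expect_equal(unname(w$e["flat"]), 1, tolerance = 1e-12)
  expect_equal(unname(w$w["flat"]), 0, tolerance = 1e-12)
  expect_equal(unname(w$w["varied"]), 1, tolerance = 1e-12)

  # n = 2 with z = (1, 0): zero entropy, full difference coefficient
  z2 <- tibble::tibble(entity_id = c("a", "b"), only = c(1, 0))
  w2 <- entropy_weights(z2)
  expect_equal(unname(w2$e["only"]), 0)
  expect_equal(unname(w2$d["only"]), 1)

  # all-constant matrix is an error
  zc <- minmax_normalize(tibble::tibble(entity_id = c("a", "b"),
                                        x = c(1, 1), y = c(2, 2)),
                         orientation = c(x = "positive", y = "positive"))
  expect_error(entropy_weights(zc), "uninformative")
})

test_that("higher-entropy columns get strictly lower weight", {
  # same support, one column more concentrated than the other
  z <- tibble::tibble(entity_id = sprintf("e%d", 1:4),
                      peaked = c(1, 0.01, 0.01, 0.01),
                      spread = c(1, 0.8, 0.9, 0.85))
  w <- entropy_weights(z)
  expect_lt(w$e[["peaked"]], w$e[["spread"]])
  expect_gt(w$w[["peaked"]], w$w[["spread"]])
})

test_that("contribution scores are the weighted sums with a doubled robustness term", {
  set.seed(63)
  x <- matrix(runif(68), nrow = 17, ncol = 4,
              dimnames = list(NULL, c("nc", "cpl", "nh", "r")))
  m <- dplyr::bind_cols(tibble::tibble(entity_id = sprintf("e%02d", 1:17)),
                        tibble::as_tibble(as.data.frame(x)))
  z <- minmax_normalize(m)
  w <- entropy_weights(z)
  sc <- contribution_scores(w, matrix = m)
  want <- z$nc * w$w[["nc"]] + z$cpl * w$w[["cpl"]] +
    z$nh * w$w[["nh"]] + z$r * (w$w[["r"]] * 2)
  expect_equal(sc$score, want, tolerance = 1e-12)
  want_plain <- z$nc * w$w[["nc"]] + z$cpl * w$w[["cpl"]] +
    z$nh * w$w[["nh"]] + z$r * w$w[["r"]]
  expect_equal(sc$score_undoubled, want_plain, tolerance = 1e-12)

  # row of all zeros scores 0
  zz <- z; zz[1, -1] <- 0
  sc0 <- contribution_scores(entropy_weights(zz))
  expect_equal(sc0$score[1], 0)

  # ranking stable under row permutation
  perm <- sample(17)
  mp <- m[perm, ]
  scp <- contribution_scores(entropy_weights(minmax_normalize(mp)), matrix = mp)
  expect_equal(scp$score[order(scp$entity_id)], sc$score[order(sc$entity_id)],
               tolerance = 1e-12)
})

test_that("one informative column reduces scoring to that column", {
  z <- tibble::tibble(entity_id = sprintf("e%d", 1:5),
                      flat = rep(0.3, 5), varied = c(0, 0.1, 0.5, 0.9, 1))
  # flag the flat column as constant by construction
  attr(z, "constant_columns") <- "flat"
  z$flat <- 0
  w <- entropy_weights(z)
  sc <- contribution_scores(w)
  expect_equal(order(sc$score), order(z$varied))
  expect_equal(sc$score, z$varied * 1, tolerance = 1e-12)
})

test_that("combination enumeration is complete, unique and ordered", {
  eight <- enumerate_combinations(sprintf("c%d", 1:8))
  expect_length(eight, 255L)
  ids <- vapply(eight, paste, character(1), collapse = "+")
  expect_false(anyDuplicated(ids) > 0)
  expect_true(all(diff(lengths(eight)) >= 0))

  expect_length(enumerate_combinations("only"), 1L)

  three <- enumerate_combinations(c("b", "a", "c"))
  expect_equal(vapply(three, paste, character(1), collapse = "+"),
               c("a", "b", "c", "a+b", "a+c", "b+c", "a+b+c"))

  expect_error(enumerate_combinations(c("a", "a")), "duplicate")
  expect_length(enumerate_combinations(sprintf("c%d", 1:5), min_size = 3), 16L)
})

test_that("core-compound selection intersects per-indicator top fractions", {
  # one entity dominating every column is always selected
  m <- tibble::tibble(entity_id = c("top", "e2", "e3", "e4"),
                      nc = c(0, 0.5, 0.6, 0.7), cpl = c(4, 2, 1, 1.5),
                      nh = c(2, 1, 0.5, 0.2), r = c(0.2, 0.9, 1, 0.8))
  sel <- select_core_compounds(m, fraction = 0.5)
  expect_true("top" %in% sel)

  # identical rankings across columns: top half by that ranking
  v <- seq(16, 1)
  m2 <- tibble::tibble(entity_id = sprintf("e%02d", 1:16),
                       nc = -v, cpl = v, nh = v, r = -v)
  sel2 <- select_core_compounds(m2, fraction = 0.5)
  expect_setequal(sel2, sprintf("e%02d", 1:8))

  # random matrix: equals brute-force per-column sort + intersection
  set.seed(64)
  m3 <- tibble::tibble(entity_id = sprintf("e%02d", 1:17),
                       nc = runif(17), cpl = runif(17), nh = runif(17),
                       r = runif(17))
  sel3 <- select_core_compounds(m3, fraction = 0.5)
  z3 <- minmax_normalize(m3)
  k <- ceiling(0.5 * 17)
  brute <- Reduce(intersect, lapply(c("nc", "cpl", "nh", "r"), function(j) {
    cutoff <- sort(z3[[j]], decreasing = TRUE)[k]
    z3$entity_id[z3[[j]] >= cutoff]
  }))
  expect_setequal(sel3, brute)
})

test_that("empty per-indicator intersection falls back to score ranking", {
  # two columns with exactly opposite rankings and fraction covering half
  m <- tibble::tibble(entity_id = c("a", "b", "c", "d"),
                      up = c(4, 3, 2, 1), down = c(1, 2, 3, 4))
  expect_warning(
    sel <- select_core_compounds(
      m, fraction = 0.5,
      orientation = c(up = "positive", down = "positive")),
    "falling back")
  # the fallback equals the direct score-based retention
  direct <- select_core_compounds(
    m, fraction = 0.5, method = "score",
    orientation = c(up = "positive", down = "positive"))
  expect_setequal(as.character(sel), as.character(direct))
  expect_gte(length(sel), 2L)
})
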