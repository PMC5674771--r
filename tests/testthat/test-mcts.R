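test_that("nodes are born unvisited with an infinite UCB score", {
  nd <- new_search_node()
  expect_equal(nd$v, 0L)
  expect_equal(nd$w, 0)
  expect_equal(nd$z, 0)
  expect_length(nd$children, 0L)
  expect_identical(ucb_score(nd, v_parent = 10L, C = 0.5), Inf)
})

test_that("the UCB score matches hand computation", {
  nd <- new_search_node()
  nd$v <- 1L; nd$w <- 1.0
  expect_equal(ucb_score(nd, v_parent = 2L, C = 0.5),
               1.0 + 0.5 * sqrt(2 * log(2)), tolerance = 1e-10)
  # C = 0: pure exploitation
  nd$v <- 4L; nd$w <- 2.0
  expect_equal(ucb_score(nd, v_parent = 10L, C = 1e-12), 0.5,
               tolerance = 1e-6)
  expect_error(ucb_score(nd, v_parent = 2L, C = 0.5), "inconsistency")
})

test_that("selection follows the largest UCB and prefers unvisited children", {
  root <- new_search_node()
  expect_identical(select_path(root, 0.5), list(root))

  a <- new_search_node(); b <- new_search_node()
  root$children <- list(a, b)
  root$v <- 1L
  a$v <- 1L; a$w <- 0.9      # visited
  # b unvisited: UCB = Inf dominates
  path <- select_path(root, 0.5)
  expect_identical(path[[2]], b)
})

test_that("a two-armed bandit concentrates visits on the better arm", {
  set.seed(17)
  root <- new_search_node()
  good <- new_search_node(); bad <- new_search_node()
  root$children <- list(bad, good)
  for (round in 1:500) {
    path <- select_path(root, 0.5)
    leaf <- path[[length(path)]]
    z <- if (identical(leaf, good)) 0.9 else 0.1
    backpropagate(path, z)
  }
  expect_gt(good$v, 250)
  expect_gt(good$v, bad$v)
})

test_that("expansion arity is four for single sites, six for paired sites", {
  ts <- parse_dotbracket("((....))")
  sites <- target_sites(ts)   # paired sites first, then singles
  set.seed(2)

  leaf <- new_search_node()
  leaf$v <- 1L
  child <- expand_node(leaf, remaining = 1L, sites = sites, beta = 1L)
  expect_length(leaf$children, 6L)
  expect_setequal(vapply(leaf$children, function(nd) nd$event$value,
                         character(1)),
                  c("AU", "UA", "GU", "UG", "CG", "GC"))
  expect_true(any(vapply(leaf$children, identical, logical(1), child)))

  leaf2 <- new_search_node()
  leaf2$v <- 1L
  single_idx <- which(vapply(sites, function(s) s$kind == "single",
                             logical(1)))[1]
  expand_node(leaf2, remaining = single_idx, sites = sites, beta = 1L)
  expect_length(leaf2$children, 4L)
  expect_setequal(vapply(leaf2$children, function(nd) nd$event$value,
                         character(1)),
                  c("A", "C", "G", "U"))
})

test_that("expansion is gated by the visit threshold and the site supply", {
  ts <- parse_dotbracket("((....))")
  sites <- target_sites(ts)
  fresh <- new_search_node()           # v = 0 < beta = 1: skip
  out <- expand_node(fresh, remaining = 1L, sites = sites, beta = 1L)
  expect_identical(out, fresh)
  expect_length(fresh$children, 0L)

  deep <- new_search_node()            # no remaining sites: never expand
  deep$v <- 100L
  out2 <- expand_node(deep, remaining = integer(0), sites = sites, beta = 1L)
  expect_identical(out2, deep)
  expect_length(deep$children, 0L)
})

test_that("backpropagation updates the whole path including the leaf", {
  root <- new_search_node()
  backpropagate(list(root), 1.5)
  expect_equal(root$v, 1L)
  expect_equal(root$w, 1.5)
  expect_equal(root$z, 1.5)
})

test_that("a seeded run keeps the tree internally consistent", {
  ts <- generate_fixture(24, density = 0.25, seed = 41)
  res <- design_rna(ts, params = search_params(seed = 41,
                                               max_iterations = 200))
  audit <- function(node, depth, seen_sites) {
    expect_lte(depth, ts$ell)
    if (!is.na(node$site_index)) {
      expect_false(node$site_index %in% seen_sites)
      seen_sites <- c(seen_sites, node$site_index)
    }
    if (length(node$children) > 0L) {
      vsum <- sum(vapply(node$children, function(nd) nd$v, integer(1)))
      expect_gte(node$v, vsum)
      wsum <- sum(vapply(node$children, function(nd) nd$w, numeric(1)))
      # a node's w is its own playouts' z plus its children's w
      expect_gte(node$w + 1e-9, wsum)
      for (ch in node$children) audit(ch, depth + 1L, seen_sites)
    }
    if (node$v > 0L)
      expect_lte(node$w / node$v, 1 + 1 + 1e-9)  # reward cap 1 + R_GC
  }
  audit(res$tree, 0L, integer(0))
})

test_that("successful designs re-fold to the target for every seed", {
  ts <- parse_dotbracket("((((....))))")
  for (seed in 1:20) {
    res <- design_rna(ts, params = search_params(seed = seed,
                                                 max_iterations = 500))
    expect_true(res$success, info = paste("seed", seed))
    expect_identical(reference_fold(res$sequence)$structure, ts$dotbracket)
    expect_equal(res$reward$d, 0L)
  }
})

test_that("degenerate budgets and tiny targets behave as specified", {
  res0 <- design_rna("((((....))))",
                     params = search_params(seed = 1, max_iterations = 0))
  expect_false(res0$success)
  expect_equal(res0$fold_calls, 0L)
  expect_equal(res0$iterations, 0L)

  res1 <- design_rna(".", params = search_params(seed = 1,
                                                 max_iterations = 10))
  expect_true(res1$success)
  expect_lte(res1$solution_depth, 1L)
})

test_that("pseudoknotted targets are rejected by nested-only backends", {
  expect_error(design_rna("([)]", params = search_params(seed = 1)),
               "nested structures only")
})

test_that("runs are reproducible for a fixed seed and reference backend", {
  ts <- generate_fixture(20, density = 0.25, seed = 9)
  r1 <- design_rna(ts, alpha_star = 0.5,
                   params = search_params(seed = 33, max_iterations = 300))
  r2 <- design_rna(ts, alpha_star = 0.5,
                   params = search_params(seed = 33, max_iterations = 300))
  expect_identical(r1$sequence, r2$sequence)
  expect_identical(r1$iterations, r2$iterations)
  expect_identical(r1$fold_calls, r2$fold_calls)
})

test_that("random-restart local search respects its fold budget and seed", {
  ts <- generate_fixture(40, density = 0.3, seed = 55)
  r1 <- random_restart_design(ts, seed = 8, k = 10, max_fold_calls = 40)
  expect_lte(r1$fold_calls, 40L + 10L)  # final restart may finish
  expect_s3_class(r1, "rna_design")
  r2 <- random_restart_design(ts, seed = 8, k = 10, max_fold_calls = 40)
  expect_identical(r1$sequence, r2$sequence)
  expect_identical(r1$iterations, r2$iterations)
  if (r1$success)
    expect_identical(reference_fold(r1$sequence)$structure, ts$dotbracket)
})

test_that("strict GC mode only accepts designs inside the tolerance window", {
  ts <- parse_dotbracket("((((....))))")
  for (seed in 1:10) {
    res <- design_rna(ts, alpha_star = 0.5, require_gc = TRUE,
                      params = search_params(seed = seed,
                                             max_iterations = 500))
    expect_true(res$success, info = paste("seed", seed))
    expect_lte(abs(res$gc - 0.5), 0.01)
  }
})
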