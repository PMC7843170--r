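test_that("dominance verdicts follow the coordinatewise definition", {
  expect_equal(dominates(c(1, 2), c(2, 2)), c(weak = TRUE, strict = FALSE))
  expect_equal(dominates(c(1, 2), c(2, 1)), c(weak = FALSE, strict = FALSE))
  expect_equal(dominates(c(3, 4), c(3, 4)), c(weak = TRUE, strict = FALSE))
  expect_equal(dominates(c(1, 1), c(2, 2)), c(weak = TRUE, strict = TRUE))
  expect_error(dominates(c(1, 2), c(1, 2, 3)), class = "mlcs_parameter_error")
})

test_that("prune_minima removes strongly dominated points and merges duplicates", {
  ls <- level_set(rbind(c(1, 2), c(2, 3), c(2, 2)), k = 1,
                  symbols = c("A", "B", "C"),
                  parents = list(1L, 1L, 2L))
  out <- prune_minima(ls)
  # (2,3) is strongly dominated by (1,2); (2,2) is weakly but not strongly
  # dominated and must survive: losing it can lose MLCS strings
  expect_equal(out$points, rbind(c(1L, 2L), c(2L, 2L)), ignore_attr = TRUE)

  dup <- level_set(rbind(c(1, 2), c(1, 2)), k = 1, symbols = c("A", "A"),
                   parents = list(2L, 5L))
  merged <- prune_minima(dup)
  expect_equal(nrow(merged$points), 1L)
  expect_equal(merged$parents[[1L]], c(2L, 5L))

  single <- prune_minima(level_set(rbind(c(1, 2)), k = 3, symbols = "A"))
  expect_equal(nrow(single$points), 1L)
})

test_that("prune_minima equals the brute-force dominance oracle", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(2:5, 1L)
    m <- sample(2:15, 1L)
    pts <- matrix(sample.int(20L, m * n, replace = TRUE), m, n)
    pts <- pts[!duplicated(point_keys(pts)), , drop = FALSE]
    got <- prune_minima(level_set(pts, 1L, rep("A", nrow(pts))))$points
    want <- naive_strong_minima(pts)
    expect_equal(got[order(point_keys(got)), , drop = FALSE],
                 want[order(point_keys(want)), , drop = FALSE],
                 ignore_attr = TRUE, label = sprintf("seed %d", seed))
  }
})

test_that("extension upper bound is the suffix-count sum and is admissible", {
  s <- sequence_set(c("AB", "BA"), alphabet = worked_alphabet)
  counts <- build_suffix_counts(s)
  expect_equal(extension_upper_bound(c(0, 0), counts), 2L)
  expect_equal(extension_upper_bound(c(2, 2), counts), 0L)

  aa <- sequence_set(c("AAA", "AAA"), alphabet = "dna")
  expect_equal(extension_upper_bound(c(1, 1), build_suffix_counts(aa)), 2L)

  # admissibility: bound at the source is >= the true MLCS length
  for (seed in 1:15) {
    g <- random_set(seed)
    ub <- extension_upper_bound(rep(0L, g$n), build_suffix_counts(g))
    expect_gte(ub, brute_force_mlcs(g)$length)
  }
})

test_that("expand_level generates pruned successor levels", {
  s <- sequence_set(c("AB", "BA"), alphabet = worked_alphabet)
  tabs <- build_successor_tables(s)
  lvl0 <- level_set(matrix(0L, 1, 2), 0L)
  lvl1 <- expand_level(lvl0, tabs)
  expect_equal(lvl1$k, 1L)
  expect_equal(lvl1$points[order(lvl1$points[, 1]), ],
               rbind(c(1L, 2L), c(2L, 1L)), ignore_attr = TRUE)

  empty <- expand_level(level_set(matrix(integer(), 0, 2), 1L), tabs)
  expect_equal(nrow(empty$points), 0L)

  aa <- sequence_set(c("AA", "AA"), alphabet = "dna")
  t2 <- build_successor_tables(aa)
  lvl2 <- expand_level(level_set(matrix(1L, 1, 2), 1L, "A", list(1L)), t2)
  expect_equal(lvl2$points, rbind(c(2L, 2L)), ignore_attr = TRUE)

  expect_error(expand_level(lvl0, tabs, prune_options("hf")),
               class = "mlcs_config_error")
})

test_that("search terminates with the correct length on canonical cases", {
  g <- run_dominant_point_search(sequence_set(worked_pair,
                                              alphabet = worked_alphabet))
  expect_equal(g$L, 4L)

  ident <- sequence_set(rep("GATTACA", 3), alphabet = "dna")
  gi <- run_dominant_point_search(ident)
  expect_equal(gi$L, 7L)
  expect_true(all(vapply(gi$levels, function(l) nrow(l$points), integer(1)) == 1L))

  gd <- run_dominant_point_search(sequence_set(c("AAA", "CCC"),
                                               alphabet = "dna"))
  expect_equal(gd$L, 0L)
  expect_length(gd$levels, 1L)
})

test_that("every retained level set satisfies the dominant-point conditions", {
  for (seed in 1:12) {
    g0 <- random_set(seed)
    graph <- run_dominant_point_search(g0)
    for (k in seq_len(graph$L)) {
      ls <- graph$levels[[k + 1L]]
      expect_equal(ls$k, k)
      for (j in seq_len(nrow(ls$points))) {
        p <- ls$points[j, ]
        sym <- ls$symbols[[j]]
        # Definition of a match point: all residues equal the symbol
        expect_true(all(vapply(seq_len(g0$n), function(i)
          substring(g0$residues[[i]], p[[i]], p[[i]]) == sym, logical(1))))
        # no same-level point strongly dominates a retained point
        others <- ls$points[-j, , drop = FALSE]
        if (nrow(others))
          expect_false(any(apply(others, 1L, function(q) all(q < p))))
        # monotonicity along every parent edge
        for (par in ls$parents[[j]]) {
          pp <- graph$levels[[k]]$points[par, ]
          expect_true(all(pp < p))
        }
      }
      # no duplicate coordinate vectors at a level
      expect_false(anyDuplicated(point_keys(ls$points)) > 0L)
    }
  }
})

test_that("pf and hf prune modes give identical results", {
  for (seed in 1:25) {
    g0 <- random_set(seed, n = sample(2:4, 1L), len = sample(4:15, 1L))
    rp <- backtrack_enumerate(run_dominant_point_search(g0, prune_options("pf")))
    rh <- backtrack_enumerate(run_dominant_point_search(g0, prune_options("hf")))
    expect_equal(rh$length, rp$length)
    expect_identical(rh$strings, rp$strings)
  }
})

test_that("for pairs the search length equals the pairwise DP length", {
  for (seed in 1:20) {
    set.seed(seed)
    len <- sample(5:60, 2L, replace = TRUE)
    g0 <- generate_random_sequences(2, len, "dna", seed = seed * 13L)
    graph <- run_dominant_point_search(g0)
    expect_equal(graph$L,
                 dp_lcs_length(g0$residues[[1L]], g0$residues[[2L]]),
                 label = sprintf("seed %d", seed))
  }
})

test_that("greedy lower bound is a valid lower bound", {
  for (seed in 1:10) {
    g0 <- random_set(seed)
    lb <- greedy_lower_bound(build_successor_tables(g0))
    graph <- run_dominant_point_search(g0)
    expect_lte(lb, graph$L)
    expect_gte(lb, as.integer(graph$L > 0L))
  }
})

test_that("resource and precondition errors are classed", {
  g0 <- generate_random_sequences(2, 30, "dna", seed = 5)
  err <- tryCatch(run_dominant_point_search(g0, node_budget = 3),
                  error = identity)
  expect_s3_class(err, "mlcs_resource_error")
  expect_match(conditionMessage(err), "level")
  bad <- sequence_set(c("ACGU", "ACGT"), alphabet = "dna")
  expect_error(run_dominant_point_search(bad), class = "mlcs_input_error")
})
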