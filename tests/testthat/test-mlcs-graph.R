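test_that("backtracking enumerates exactly the known string sets", {
  g <- run_dominant_point_search(sequence_set(worked_pair,
                                              alphabet = worked_alphabet))
  rep <- backtrack_enumerate(g)
  expect_equal(rep$length, 4L)
  expect_identical(rep$strings, worked_strings)
  expect_equal(rep$count, 3L)

  ident <- sequence_set(rep("GATTACA", 2), alphabet = "dna")
  ri <- backtrack_enumerate(run_dominant_point_search(ident))
  expect_identical(ri$strings, "GATTACA")
  expect_equal(ri$count, 1L)

  rd <- backtrack_enumerate(run_dominant_point_search(
    sequence_set(c("AAA", "CCC"), alphabet = "dna")))
  expect_equal(rd$length, 0L)
  expect_equal(rd$count, 0L)
  expect_equal(rd$path_count, 0)
})

test_that("every enumerated string verifies and none is extendable", {
  for (seed in 1:12) {
    g0 <- random_set(seed)
    rep <- backtrack_enumerate(run_dominant_point_search(g0))
    expect_true(verify_result(rep, g0)$pass)
    # maximality: the brute-force oracle finds nothing longer
    expect_equal(rep$length, brute_force_mlcs(g0)$length)
  }
})

test_that("verify_result flags non-subsequences and length mismatches", {
  seqs <- sequence_set(worked_pair, alphabet = worked_alphabet)
  good <- result_report("BDAB", 4L)
  expect_true(verify_result(good, seqs)$pass)

  aaa <- sequence_set(c("AAA", "AAA"), alphabet = "dna")
  bad <- result_report("AAAA", 4L)
  v <- verify_result(bad, aaa)
  expect_false(v$pass)
  expect_true(all(v$violations$reason == "not a subsequence"))

  expect_true(verify_result(result_report(character(), 0L), aaa)$pass)
})

test_that("DFS path count agrees with memoized counting and explicit walks", {
  for (seed in 1:12) {
    g0 <- random_set(seed)
    graph <- run_dominant_point_search(g0)
    rep <- backtrack_enumerate(graph)
    expect_equal(rep$path_count, count_paths(graph))
    expect_equal(rep$path_count, naive_count_paths(graph))
    expect_gte(rep$path_count, rep$count)
  }
})

test_that("distinct strings are invariant under traversal order", {
  for (seed in 1:8) {
    g0 <- random_set(seed)
    graph <- run_dominant_point_search(g0)
    ref <- backtrack_enumerate(graph)
    for (s2 in c(3L, 99L)) {
      alt <- backtrack_enumerate(graph, child_order = "random", seed = s2)
      expect_identical(alt$strings, ref$strings)
      expect_equal(alt$path_count, ref$path_count)
    }
  }
})

test_that("malformed graphs raise integrity errors", {
  g0 <- sequence_set(c("ACGT", "AGT"), alphabet = "dna")
  graph <- run_dominant_point_search(g0)

  tampered <- graph
  tampered$levels[[2L]]$parents[[1L]] <- integer()  # unreachable node
  expect_error(backtrack_enumerate(tampered), class = "mlcs_integrity_error")

  gap <- graph
  gap$levels <- gap$levels[-2L]                      # level gap
  expect_error(backtrack_enumerate(gap), class = "mlcs_integrity_error")

  flat <- graph
  flat$levels[[2L]]$points[1L, ] <- c(0L, 0L)        # non-increasing edge
  expect_error(backtrack_enumerate(flat), class = "mlcs_integrity_error")
})

test_that("enumeration respects its path budget", {
  graph <- run_dominant_point_search(sequence_set(worked_pair,
                                                  alphabet = worked_alphabet))
  expect_gt(count_paths(graph), 1)
  expect_error(backtrack_enumerate(graph, enum_budget = 1),
               class = "mlcs_resource_error")
})

test_that("DOT export contains every node and edge", {
  g0 <- sequence_set(c("ACGT", "AGT"), alphabet = "dna")
  graph <- run_dominant_point_search(g0)
  dot <- graph_to_dot(graph)
  expect_equal(dot[[1L]], "digraph mlcs {")
  n_nodes <- sum(vapply(graph$levels, function(l) nrow(l$points), integer(1)))
  n_edges <- sum(lengths(unlist(lapply(graph$levels[-1L], `[[`, "parents"),
                                recursive = FALSE)))
  expect_equal(sum(grepl("label=", dot)), n_nodes)
  expect_equal(sum(grepl("->", dot, fixed = TRUE)), n_edges)
})
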