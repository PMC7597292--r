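test_that("acyclicity test handles the basic cases", {
  expect_true(is_acyclic(rep(list(integer(0)), 4)))
  expect_false(is_acyclic(list(2L, 1L)))
  expect_false(is_acyclic(list(3L, 1L, 2L)))
  expect_true(is_acyclic(list(integer(0), 1L, c(1L, 2L))))
  for (seed in 1:10) {
    dag <- random_dag(8, max_indegree = 3, seed = seed)
    expect_true(is_acyclic(dag))
  }
})

test_that("dynamic programming matches the exhaustive oracle", {
  for (seed in 1:30) {
    n <- 3 + seed %% 3  # 3, 4, 5
    ss <- random_score_set(n, d = 2L, seed = seed)
    dp <- exact_dp(ss)
    bf <- exhaustive_search(ss)
    expect_equal(dp$total_score, bf$total_score, tolerance = 1e-9)
    expect_true(is_acyclic(dp))
    expect_true(is_acyclic(bf))
    # graph_score agrees with the reported totals
    expect_equal(graph_score(ss, dp$parents), dp$total_score)
  }
})

test_that("the worked example's optimum is found and uses only legal CPSs", {
  ss <- example_score_set()
  dp <- exact_dp(ss)
  bf <- exhaustive_search(ss)
  expect_equal(dp$total_score, bf$total_score)
  legal_keys <- lapply(legal_prune(ss)$tables, `[[`, "keys")
  for (i in 1:4) {
    key <- paste(dp$parents[[i]], collapse = ",")
    expect_true(key %in% legal_keys[[i]])
  }
  # pruning to the legal tables does not change the optimum
  expect_equal(exact_dp(legal_prune(ss))$total_score, dp$total_score)
})

test_that("every learned structure keeps at least one root node", {
  for (seed in 1:10) {
    ss <- random_score_set(5, d = 2L, seed = seed)
    for (fit in list(exact_dp(ss), greedy_search(ss),
                     order_local_search(ss, restarts = 2, seed = seed))) {
      expect_true(any(lengths(fit$parents) == 0L))
      expect_true(is_acyclic(fit))
    }
  }
})

test_that("greedy and order-based search never beat the exact optimum", {
  for (seed in 1:20) {
    ss <- random_score_set(4 + seed %% 2, d = 2L, seed = seed + 100)
    opt <- exact_dp(ss)$total_score
    expect_lte(greedy_search(ss)$total_score, opt + 1e-9)
    expect_lte(order_local_search(ss, restarts = 3, seed = seed)$total_score,
               opt + 1e-9)
  }
})

test_that("greedy search takes empty CPSs when they are best", {
  tables <- lapply(1:3, function(i) {
    others <- setdiff(1:3, i)
    list(parents = c(list(integer(0)), as.list(others)),
         scores = c(-1, -5, -6))
  })
  ss <- score_set(c("A", "B", "C"), tables)
  fit <- greedy_search(ss)
  expect_equal(sum(lengths(fit$parents)), 0L)
  expect_equal(fit$total_score, exact_dp(ss)$total_score)
})

test_that("greedy search resolves mutually-best parents by skipping cycles", {
  # both nodes prefer the other as parent; only one can get its wish
  tables <- list(
    list(parents = list(integer(0), 2L), scores = c(-10, -4)),
    list(parents = list(integer(0), 1L), scores = c(-10, -3)))
  ss <- score_set(c("A", "B"), tables)
  fit <- greedy_search(ss)
  # node B has the larger gain (7 vs 6) so it is processed first and wins
  expect_equal(fit$parents[[2]], 1L)
  expect_equal(fit$parents[[1]], integer(0))
  expect_equal(fit$total_score, -13)
})

test_that("order-consistent networks behave as defined", {
  ss <- example_score_set()
  for (seed in 1:5) {
    set.seed(seed)
    ord <- sample(4)
    fit <- order_best_network(ss, ord)
    expect_true(is_acyclic(fit))
    expect_equal(fit$parents[[ord[1]]], integer(0))  # first node is a root
    # each node's parents lie among its predecessors
    for (k in seq_along(ord)) {
      expect_true(all(fit$parents[[ord[k]]] %in% ord[seq_len(k - 1)]))
    }
  }
  expect_error(order_best_network(ss, c(1, 1, 2, 3)), "permutation")
})

test_that("the best order-consistent network attains the exact optimum (n = 4)", {
  for (seed in c(1, 2)) {
    ss <- if (seed == 1) example_score_set() else random_score_set(4, d = 3L, seed = 9)
    best <- max(vapply(all_perms(4), function(ord) {
      order_best_network(ss, ord)$total_score
    }, numeric(1)))
    expect_equal(best, exact_dp(ss)$total_score, tolerance = 1e-9)
  }
})

test_that("order-based local search is deterministic in its seed", {
  ss <- random_score_set(6, d = 2L, seed = 11)
  a <- order_local_search(ss, restarts = 3, seed = 42)
  b <- order_local_search(ss, restarts = 3, seed = 42)
  expect_identical(a$parents, b$parents)
  expect_identical(a$total_score, b$total_score)
})

test_that("zero-iteration local search equals the seeded initial order", {
  ss <- random_score_set(5, d = 2L, seed = 13)
  fit <- order_local_search(ss, restarts = 1, max_iters = 0, seed = 99)
  set.seed(99)
  ord <- sample.int(5)
  expect_equal(fit$total_score, order_best_network(ss, ord)$total_score)
})

test_that("local search reaches the exact optimum on the worked example", {
  ss <- example_score_set()
  fit <- order_local_search(ss, restarts = 10, seed = 1)
  expect_equal(fit$total_score, exact_dp(ss)$total_score)
})

test_that("exact search on pruned tables is monotone in the pruning level", {
  for (seed in 1:5) {
    ss <- legal_prune(random_score_set(5, d = 2L, seed = seed + 50))
    scores <- vapply(c(0, 25, 50, 75, 99), function(p) {
      exact_dp(percent_prune(ss, p))$total_score
    }, numeric(1))
    expect_true(all(diff(scores) <= 1e-9))
  }
})

test_that("search respects size guards", {
  ss <- random_score_set(6, d = 1L, seed = 1)
  expect_error(exhaustive_search(ss), "5 nodes")
  expect_error(exact_dp(ss, max_n = 5), "order_local_search")
})

test_that("order_best_network is invariant to CPS line order in the file", {
  ss <- legal_prune(example_score_set())
  path <- withr::local_tempfile()
  write_scores(ss, path)
  lines <- readLines(path)
  set.seed(3)
  out <- lines[1]
  pos <- 2
  while (pos <= length(lines)) {
    m <- as.integer(strsplit(lines[pos], " ")[[1]][2])
    out <- c(out, lines[pos], sample(lines[pos + seq_len(m)]))
    pos <- pos + m + 1
  }
  path2 <- withr::local_tempfile()
  writeLines(out, path2)
  a <- order_best_network(read_scores(path), c(3, 4, 1, 2))
  b <- order_best_network(read_scores(path2), c(3, 4, 1, 2))
  expect_equal(a$parents, b$parents)
  expect_equal(a$total_score, b$total_score)
})
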