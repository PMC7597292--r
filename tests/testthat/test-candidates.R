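test_that("possible-CPS counts match the closed form at benchmark sizes", {
  expect_equal(count_possible_cps(100, 1)$approx, 10000)
  expect_equal(count_possible_cps(100, 2)$approx, 495100)
  expect_equal(count_possible_cps(100, 3)$approx, 16180000)
  expect_equal(count_possible_cps(4, 3)$approx, 32)
  expect_equal(count_possible_cps(5, 2)$approx, 5 * (1 + 4 + 6))
  # exact arithmetic well beyond double precision
  expect_match(count_possible_cps(200, 100)$value, "^[0-9]{50,}$")
  expect_error(count_possible_cps(4, 4), "\\[0, n - 1\\]")
  expect_error(count_possible_cps(4, -1), "\\[0, n - 1\\]")
})

test_that("enumeration produces every subset up to the in-degree bound", {
  data <- random_dataset(4, N = 50, seed = 3)
  ss <- score_parent_sets(data, max_indegree = 3, legal_only = FALSE)
  expect_equal(n_cps(ss), 32)
  expect_equal(n_cps(ss, per_node = TRUE), rep(8L, 4))
  data5 <- random_dataset(5, N = 50, seed = 4)
  ss5 <- score_parent_sets(data5, max_indegree = 2, legal_only = FALSE)
  expect_equal(n_cps(ss5, per_node = TRUE), rep(11L, 5))  # C(4,0)+C(4,1)+C(4,2)
  ss0 <- score_parent_sets(data, max_indegree = 0)
  expect_equal(n_cps(ss0, per_node = TRUE), rep(1L, 4))
  expect_true(all(vapply(ss0$tables, function(tb) tb$sizes[1L] == 0L, logical(1))))
})

test_that("node tables are sorted by score, then size, then parent indices", {
  for (seed in 1:5) {
    ss <- random_score_set(5, d = 2L, seed = seed)
    for (tb in ss$tables) {
      expect_true(all(diff(tb$scores) <= 0))
      ties <- which(diff(tb$scores) == 0)
      for (t in ties) {
        expect_true(tb$sizes[t] < tb$sizes[t + 1L] ||
                      (tb$sizes[t] == tb$sizes[t + 1L] &&
                         tb$keys[t] < tb$keys[t + 1L]))
      }
    }
  }
})

test_that("legality pruning removes exactly the six dominated sets of the example", {
  ss <- example_score_set()
  lp <- legal_prune(ss)
  expect_equal(n_cps(lp), 26)
  removed <- lapply(1:4, function(i) {
    setdiff(ss$tables[[i]]$keys, lp$tables[[i]]$keys)
  })
  expect_setequal(removed[[1]], c("2,3", "2,4", "2,3,4"))
  expect_setequal(removed[[2]], c("1,3", "1,4", "1,3,4"))
  expect_equal(removed[[3]], character(0))
  expect_equal(removed[[4]], character(0))
})

test_that("legality pruning equals an all-pairs subset-dominance oracle", {
  for (seed in 1:20) {
    ss <- random_score_set(4 + seed %% 2, d = 2L + seed %% 2L, seed = seed)
    lp <- legal_prune(ss)
    for (i in seq_len(ss$n)) {
      tb <- ss$tables[[i]]
      keep <- oracle_legal_keep(tb$parents, tb$scores)
      expect_setequal(lp$tables[[i]]$keys, tb$keys[keep])
    }
  }
})

test_that("strictly improving score tables lose nothing to legality pruning", {
  tables <- lapply(1:3, function(i) {
    others <- setdiff(1:3, i)
    parents <- list(integer(0), others[1], others[2], others)
    list(parents = parents, scores = c(-40, -30, -29, -10))
  })
  ss <- score_set(c("A", "B", "C"), tables)
  expect_equal(n_cps(legal_prune(ss)), n_cps(ss))
})

test_that("percentage pruning keeps the top of each sorted list", {
  ss <- legal_prune(example_score_set())
  expect_equal(percent_prune(ss, 0)$tables, ss$tables)  # identity at p = 0
  # node 3 keeps all 8 entries after legality; its top 4 by printed score
  # survive p = 50, and the empty set is re-appended as the root option
  p50 <- percent_prune(ss, 50)
  expect_equal(p50$tables[[3]]$keys, c("1,2,4", "1,2", "1,4", "2,4", ""))
  # p = 99 on an 8-entry table: ceiling(0.08) = 1 entry plus re-appended empty
  p99 <- percent_prune(ss, 99)
  expect_equal(p99$tables[[3]]$keys, c("1,2,4", ""))
  expect_error(percent_prune(ss, 100), "\\[0, 100\\)")
  expect_error(percent_prune(ss, -1), "\\[0, 100\\)")
})

test_that("percentage pruning is monotone and always retains the empty set", {
  for (seed in 1:5) {
    ss <- legal_prune(random_score_set(5, d = 2L, seed = seed))
    prev <- NULL
    for (p in c(0, 20, 50, 80, 99)) {
      pp <- percent_prune(ss, p)
      for (i in seq_len(ss$n)) {
        expect_gte(length(pp$tables[[i]]$scores), 1L)
        expect_true("" %in% pp$tables[[i]]$keys)
        if (!is.null(prev)) {
          # nesting up to the force-retained empty set
          expect_true(all(setdiff(pp$tables[[i]]$keys, "") %in%
                            prev$tables[[i]]$keys))
        }
      }
      prev <- pp
    }
  }
})

test_that("legal-CPS fraction rises with sample size and falls with in-degree", {
  frac <- function(N, d) {
    mean(vapply(1:3, function(seed) {
      data <- random_dataset(7, N = N, d = 3L, seed = 100 + seed)
      legal_cps_fraction(data, max_indegree = d)
    }, numeric(1)))
  }
  expect_gt(frac(2000, 3), frac(100, 3))
  expect_lt(frac(500, 3), frac(500, 1))
})

test_that("score_set enforces its structural invariants", {
  expect_error(score_set("A", list(list(parents = list(1L), scores = -1))),
               "own parent sets")
  expect_error(score_set(c("A", "B"),
                         list(list(parents = list(2L), scores = -1),
                              list(parents = list(integer(0)), scores = -1))),
               "empty parent set")
  expect_error(score_set(c("A", "B"),
                         list(list(parents = list(integer(0), 2L, 2L), scores = c(-1, -2, -3)),
                              list(parents = list(integer(0)), scores = -1))),
               "duplicate")
})
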