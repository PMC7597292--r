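# DAG search over pre-scored candidate parent sets.
#
# All engines consume a score_set and return a "bnsl" fit. Tie-breaking is
# uniform: higher score, then fewer parents, then lexicographic parent
# indices — realised by the score_set's table sort order, so "first match in
# table order" is always the preferred candidate.

#' Test a parent-set assignment for acyclicity
#'
#' Kahn's algorithm: repeatedly remove nodes whose remaining parent set is
#' empty; the assignment is a DAG iff all nodes can be removed. Every finite
#' DAG necessarily retains at least one root (empty parent set).
#'
#' @param dag a list of parent index vectors, a `bn_dag`, or a [bnsl] fit.
#' @param n number of nodes (inferred from `dag` when omitted).
#' @return `TRUE` iff the directed graph has no cycle.
#' @export
is_acyclic <- function(dag, n = NULL) {
  if (inherits(dag, "bnsl")) dag <- dag$parents
  if (inherits(dag, "bn_dag")) dag <- dag$parents
  if (is.null(n)) n <- length(dag)
  parents <- lapply(dag, as.integer)
  alive <- rep(TRUE, n)
  repeat {
    removable <- which(alive & vapply(seq_len(n), function(i) {
      !any(alive[parents[[i]]])
    }, logical(1)))
    if (!length(removable)) break
    alive[removable] <- FALSE
  }
  !any(alive)
}

topo_order <- function(parents) {
  n <- length(parents)
  alive <- rep(TRUE, n)
  ord <- integer(0)
  repeat {
    removable <- which(alive & vapply(seq_len(n), function(i) {
      !any(alive[parents[[i]]])
    }, logical(1)))
    if (!length(removable)) break
    ord <- c(ord, removable)
    alive[removable] <- FALSE
  }
  if (any(alive)) stop("graph contains a cycle")
  ord
}

count_edges <- function(parents) sum(lengths(parents))

new_bnsl <- function(parents, names, local_scores, total_score, method,
                     score_set = NULL, seed = NA_integer_, restarts = NA_integer_,
                     iterations = NA_integer_) {
  structure(list(parents = parents, names = names,
                 local_scores = local_scores, total_score = total_score,
                 method = method, score_set = score_set, seed = seed,
                 restarts = restarts, iterations = iterations),
            class = "bnsl")
}

assemble_fit <- function(score_set, parents, method, ...) {
  local_scores <- vapply(seq_len(score_set$n), function(i) {
    lookup_score(score_set$tables[[i]], parents[[i]])
  }, numeric(1))
  new_bnsl(parents, score_set$names, local_scores,
           total_score = sum(local_scores), method = method,
           score_set = score_set, ...)
}

#' Exhaustive search over all representable DAGs
#'
#' Enumerates every assignment of one table entry per node, discarding
#' assignments that create a directed cycle, and returns the maximum-score
#' DAG (ties: fewest edges, then lexicographic parent indices). Intended as
#' an independent oracle for the other engines; restricted to `n <= 5`
#' (543 DAGs at n = 4; 29,281 at n = 5).
#'
#' @param score_set a [score_set] with at most 5 variables.
#' @return A [bnsl] fit with `method = "exhaustive"`.
#' @export
exhaustive_search <- function(score_set) {
  stopifnot(inherits(score_set, "score_set"))
  n <- score_set$n
  if (n > 5L) stop("exhaustive search is limited to 5 nodes; use exact_dp")
  tabs <- score_set$tables
  # admissible bound: sum of best per-node scores from node i to n
  best_rest <- rev(cumsum(rev(vapply(tabs, function(tb) tb$scores[1L], numeric(1)))))
  best <- list(score = -Inf, edges = Inf, key = "", parents = NULL)
  assign <- vector("list", n)
  recurse <- function(i, acc) {
    if (i > n) {
      edges <- count_edges(assign)
      key <- paste(vapply(assign, ps_key, character(1)), collapse = ";")
      if (acc > best$score ||
          (acc == best$score && (edges < best$edges ||
                                 (edges == best$edges && key < best$key)))) {
        best <<- list(score = acc, edges = edges, key = key, parents = assign)
      }
      return(invisible())
    }
    if (acc + best_rest[i] < best$score) return(invisible())
    tb <- tabs[[i]]
    for (e in seq_along(tb$scores)) {
      assign[[i]] <<- tb$parents[[e]]
      ok <- is_acyclic(c(assign[seq_len(i)], rep(list(integer(0)), n - i)), n)
      if (ok) recurse(i + 1L, acc + tb$scores[e])
    }
    invisible()
  }
  recurse(1L, 0)
  assemble_fit(score_set, best$parents, "exhaustive")
}

# For node i, map a mask over all n nodes (with bit i absent) to the compact
# mask over the other n-1 nodes. Vectorised over masks.
compact_mask <- function(masks, i, n) {
  low <- bitwAnd(masks, bitwShiftL(1L, i - 1L) - 1L)
  high <- bitwShiftR(masks, i)  # drops bits 0..i-1, i.e. removes bit i-1 region
  bitwOr(low, bitwShiftL(high, i - 1L))
}

#' Exact maximum-score DAG by dynamic programming over variable subsets
#'
#' The Silander–Myllymäki scheme: first the best table entry for every
#' (node, allowed-predecessor subset) pair via a subset-max sweep, then the
#' best sink for every subset of variables. Returns the global optimum over
#' all DAGs whose per-node parent sets occur in the score set. Memory grows
#' as `n * 2^n`; refuse beyond `max_n` and point to [order_local_search()].
#'
#' @param score_set a [score_set].
#' @param max_n hard size limit for the `2^n` tables.
#' @return A [bnsl] fit with `method = "dp"`.
#' @export
exact_dp <- function(score_set, max_n = 20L) {
  stopifnot(inherits(score_set, "score_set"))
  n <- score_set$n
  if (n > max_n)
    stop(sprintf("exact_dp needs 2^%d table entries; for n > %d use order_local_search",
                 n, max_n))
  nmask <- bitwShiftL(1L, n)
  bits <- bitwShiftL(1L, seq_len(n) - 1L)
  # best achievable local score for node i given an allowed predecessor mask
  # (compact, over the other n-1 nodes)
  sub_sz <- bitwShiftL(1L, n - 1L)
  v <- vector("list", n)
  for (i in seq_len(n)) {
    tb <- score_set$tables[[i]]
    vi <- rep(-Inf, sub_sz)
    for (e in rev(seq_along(tb$scores))) {  # reversed: best entry wins ties
      m <- sum(bits[tb$parents[[e]]])
      vi[compact_mask(m, i, n) + 1L] <- tb$scores[e]
    }
    if (n > 1L) {
      sub_masks <- 0:(sub_sz - 1L)
      for (b in bitwShiftL(1L, seq_len(n - 1L) - 1L)) {
        sel <- which(bitwAnd(sub_masks, b) > 0L)
        vi[sel] <- pmax(vi[sel], vi[sel - b])
      }
    }
    v[[i]] <- vi
  }
  cmask <- lapply(seq_len(n), function(i) compact_mask(0:(nmask - 1L), i, n))
  f <- rep(-Inf, nmask)
  f[1L] <- 0
  sink <- integer(nmask)
  for (m in seq_len(nmask - 1L)) {
    members <- which(bitwAnd(m, bits) > 0L)
    rest <- m - bits[members]
    cand <- f[rest + 1L] + vapply(seq_along(members), function(j) {
      i <- members[j]
      v[[i]][cmask[[i]][rest[j] + 1L] + 1L]
    }, numeric(1))
    b <- which.max(cand)
    f[m + 1L] <- cand[b]
    sink[m + 1L] <- members[b]
  }
  # backtrack: peel sinks off the full set, then pick each sink's best entry
  parents <- vector("list", n)
  m <- nmask - 1L
  while (m > 0L) {
    i <- sink[m + 1L]
    rest <- m - bits[i]
    parents[[i]] <- best_entry_within(score_set$tables[[i]], rest, bits)
    m <- rest
  }
  assemble_fit(score_set, parents, "dp")
}

# first (i.e. best, by table sort order) entry whose parents all lie in the
# allowed mask
best_entry_within <- function(tb, allowed, bits) {
  for (e in seq_along(tb$scores)) {
    m <- sum(bits[tb$parents[[e]]])
    if (bitwAnd(m, allowed) == m) return(tb$parents[[e]])
  }
  stop("score table lacks the empty parent set")  # unreachable by invariant
}

#' Greedy constructive DAG search
#'
#' Processes nodes in descending order of potential gain (best CPS score
#' minus empty-set score); each node receives its highest-scoring candidate
#' parent set that keeps the partial graph acyclic, skipping candidates that
#' would close a cycle. The empty set is always available, so the pass
#' always terminates with a valid DAG.
#'
#' @param score_set a [score_set].
#' @return A [bnsl] fit with `method = "greedy"`.
#' @export
greedy_search <- function(score_set) {
  stopifnot(inherits(score_set, "score_set"))
  n <- score_set$n
  gain <- vapply(seq_len(n), function(i) {
    tb <- score_set$tables[[i]]
    tb$scores[1L] - tb$scores[tb$sizes == 0L][1L]
  }, numeric(1))
  parents <- rep(list(integer(0)), n)
  for (i in order(-gain, seq_len(n))) {
    tb <- score_set$tables[[i]]
    for (e in seq_along(tb$scores)) {
      trial <- parents
      trial[[i]] <- tb$parents[[e]]
      if (is_acyclic(trial, n)) {
        parents <- trial
        break
      }
    }
  }
  assemble_fit(score_set, parents, "greedy")
}

#' Best network consistent with a node ordering
#'
#' Given a permutation of the nodes, each node takes its highest-scoring
#' candidate parent set drawn entirely from its predecessors in the order;
#' the result is acyclic by construction and the first node is always a root.
#'
#' @param score_set a [score_set].
#' @param order integer permutation of `1:n`.
#' @return A [bnsl] fit with `method = "order"`.
#' @export
order_best_network <- function(score_set, order) {
  stopifnot(inherits(score_set, "score_set"))
  n <- score_set$n
  order <- as.integer(order)
  if (length(order) != n || !setequal(order, seq_len(n)))
    stop("order must be a permutation of 1:n")
  bits <- bitwShiftL(1L, seq_len(n) - 1L)
  parents <- vector("list", n)
  allowed <- 0L
  for (k in seq_len(n)) {
    i <- order[k]
    parents[[i]] <- best_entry_within(score_set$tables[[i]], allowed, bits)
    allowed <- allowed + bits[i]
  }
  assemble_fit(score_set, parents, "order")
}

#' Order-based local search with random restarts
#'
#' Hill-climbing in the space of node orderings: starting from a seeded
#' random permutation, repeatedly tries adjacent transpositions
#' (first-improvement sweeps), re-scoring only the two affected positions,
#' until a full sweep yields no strict improvement or `max_iters` accepted
#' moves. The best network over all restarts is returned. This is a simple
#' stand-in for large-scale order-based engines (OBS/MINOBS-style) usable
#' when `2^n` dynamic programming is out of reach.
#'
#' @param score_set a [score_set].
#' @param restarts number of random restarts (>= 1).
#' @param max_iters maximum accepted moves per restart; `0` scores the
#'   initial random order only.
#' @param seed integer seed; the only source of randomness.
#' @param time_limit optional wall-clock budget in seconds; the best
#'   result found so far is returned on expiry.
#' @return A [bnsl] fit with `method = "order_ls"`.
#' @export
order_local_search <- function(score_set, restarts = 10L, max_iters = 1000L,
                               seed = 1L, time_limit = NULL) {
  stopifnot(inherits(score_set, "score_set"))
  restarts <- as.integer(restarts)
  if (is.na(restarts) || restarts < 1L) stop("restarts must be >= 1")
  n <- score_set$n
  bits <- bitwShiftL(1L, seq_len(n) - 1L)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  t0 <- proc.time()[["elapsed"]]
  best <- NULL
  total_iters <- 0L
  pick <- function(tb, allowed) {
    for (e in seq_along(tb$scores)) {
      m <- sum(bits[tb$parents[[e]]])
      if (bitwAnd(m, allowed) == m) return(list(p = tb$parents[[e]], s = tb$scores[e]))
    }
  }
  for (r in seq_len(restarts)) {
    ord <- sample.int(n)
    chosen <- vector("list", n)   # per position: list(p, s)
    allowed <- 0L
    for (k in seq_len(n)) {
      chosen[[k]] <- pick(score_set$tables[[ord[k]]], allowed)
      allowed <- allowed + bits[ord[k]]
    }
    total <- sum(vapply(chosen, `[[`, numeric(1), "s"))
    iters <- 0L
    # predecessor mask for each position
    pred <- integer(n)
    acc <- 0L
    for (k in seq_len(n)) { pred[k] <- acc; acc <- acc + bits[ord[k]] }
    while (iters < max_iters) {
      improved <- FALSE
      for (k in seq_len(n - 1L)) {
        a <- ord[k]; b <- ord[k + 1L]
        # after swapping, b sits at k with pred[k]; a sits at k+1 with
        # pred[k] + bit(b)
        nb <- pick(score_set$tables[[b]], pred[k])
        na <- pick(score_set$tables[[a]], pred[k] + bits[b])
        delta <- (na$s + nb$s) - (chosen[[k]]$s + chosen[[k + 1L]]$s)
        if (delta > 0) {
          ord[k] <- b; ord[k + 1L] <- a
          chosen[[k]] <- nb; chosen[[k + 1L]] <- na
          pred[k + 1L] <- pred[k] + bits[b]
          total <- total + delta
          iters <- iters + 1L
          improved <- TRUE
          if (iters >= max_iters) break
        }
      }
      expired <- !is.null(time_limit) &&
        proc.time()[["elapsed"]] - t0 > time_limit
      if (!improved || iters >= max_iters || expired) break
    }
    total_iters <- total_iters + iters
    if (is.null(best) || total > best$total) {
      best <- list(ord = ord, total = total)
    }
    if (!is.null(time_limit) && proc.time()[["elapsed"]] - t0 > time_limit) break
  }
  fit <- order_best_network(score_set, best$ord)
  fit$method <- "order_ls"
  fit$seed <- as.integer(seed)
  fit$restarts <- restarts
  fit$iterations <- total_iters
  fit
}
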