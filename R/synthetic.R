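# Ground-truth generators. Defaults are the package's study conditions:
# binary variables, Dirichlet concentration 0.5 (informative, learnable
# conditional distributions), edge probability 0.5 within a max in-degree.

with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Sample a random DAG
#'
#' Draws a uniform node ordering, then proposes each predecessor edge
#' independently with probability `edge_prob` and truncates each node's
#' parents to its `max_indegree` nearest predecessors in the order. The
#' result is acyclic by construction and deterministic in `seed`.
#'
#' @param n number of nodes.
#' @param max_indegree cap on parents per node, in `[0, n - 1]`.
#' @param edge_prob probability of each candidate predecessor edge.
#' @param seed integer seed.
#' @return An object of class `bn_dag`: list with `parents` (list of integer
#'   vectors) and `names`.
#' @export
random_dag <- function(n, max_indegree = 3L, edge_prob = 0.5, seed = 1L) {
  n <- as.integer(n); d <- as.integer(max_indegree)
  if (is.na(n) || n < 1L) stop("n must be a positive integer")
  if (is.na(d) || d < 0L || d > n - 1L) stop("max_indegree must lie in [0, n - 1]")
  if (!is.numeric(edge_prob) || edge_prob < 0 || edge_prob > 1)
    stop("edge_prob must lie in [0, 1]")
  with_seed(seed, {
    ord <- sample.int(n)
    parents <- rep(list(integer(0)), n)
    for (k in seq_len(n)[-1L]) {
      preds <- ord[seq_len(k - 1L)]
      chosen <- preds[stats::runif(k - 1L) < edge_prob]
      # keep the d most recent predecessors in the sampled order
      if (length(chosen) > d) chosen <- utils::tail(chosen, d)
      parents[[ord[k]]] <- sort(chosen)
    }
    structure(list(parents = parents, names = paste0("V", seq_len(n))),
              class = "bn_dag")
  })
}

#' @export
print.bn_dag <- function(x, ...) {
  cat(sprintf("DAG: %d nodes, %d arcs\n", length(x$parents),
              count_edges(x$parents)))
  invisible(x)
}

#' Attach Dirichlet-sampled conditional probability tables to a DAG
#'
#' Every conditional distribution of each node given one joint parent
#' configuration is drawn from a symmetric Dirichlet with the given
#' concentration. Small concentrations (< 1) give near-deterministic,
#' strongly dependent distributions; large concentrations approach uniform
#' tables (independence). Each row is then floored at `min_prob` per state
#' (and renormalised): without the floor, low concentrations routinely
#' produce effectively constant variables, and a variable that never changes
#' state carries no signal about its neighbours, making the ground-truth
#' structure unidentifiable at any sample size.
#'
#' @param dag a `bn_dag` (see [random_dag()]) or list of parent vectors.
#' @param arities integer vector of per-node state counts (default all 2).
#' @param concentration symmetric Dirichlet parameter (> 0).
#' @param min_prob guaranteed minimum probability per state, in
#'   `[0, 1/max(arities))`; `0` disables the floor.
#' @param seed integer seed.
#' @return An object of class `bn`: list with `dag`, `arities`, `names`, and
#'   `cpts` — per node a `q x r` matrix, row `j` holding the distribution of
#'   the child given parent configuration `j` (mixed-radix order, lowest
#'   parent index least significant).
#' @export
random_cpts <- function(dag, arities = NULL, concentration = 0.5,
                        min_prob = 0.05, seed = 1L) {
  if (inherits(dag, "bn_dag")) {
    parents <- dag$parents
    names <- dag$names
  } else {
    parents <- lapply(dag, as.integer)
    names <- paste0("V", seq_along(parents))
  }
  n <- length(parents)
  if (is.null(arities)) arities <- rep(2L, n)
  arities <- as.integer(arities)
  if (length(arities) != n || any(arities < 2L)) stop("need one arity >= 2 per node")
  if (!is.numeric(concentration) || concentration <= 0)
    stop("concentration must be > 0")
  if (!is.numeric(min_prob) || min_prob < 0 || min_prob >= 1 / max(arities))
    stop("min_prob must lie in [0, 1/max(arities))")
  with_seed(seed, {
    cpts <- lapply(seq_len(n), function(i) {
      q <- prod(arities[parents[[i]]])
      r <- arities[i]
      g <- matrix(stats::rgamma(q * r, shape = concentration), nrow = q)
      p <- g / rowSums(g)
      (1 - r * min_prob) * p + min_prob
    })
    structure(list(dag = structure(list(parents = parents, names = names),
                                   class = "bn_dag"),
                   cpts = cpts, arities = arities, names = names),
              class = "bn")
  })
}

#' @export
print.bn <- function(x, ...) {
  cat(sprintf("Ground-truth Bayesian network: %d nodes, %d arcs\n",
              length(x$names), count_edges(x$dag$parents)))
  cat("  arities:", paste0(x$names, "=", x$arities, collapse = ", "), "\n")
  invisible(x)
}

#' Draw multinomial samples from a Bayesian network by ancestral sampling
#'
#' Nodes are sampled in a topological order of the DAG; each node's state is
#' drawn from its conditional distribution given the already-sampled parent
#' configuration. Deterministic in `seed`.
#'
#' @param bn a `bn` object from [random_cpts()].
#' @param N number of observations (>= 1).
#' @param seed integer seed.
#' @return A [bn_data] object.
#' @export
forward_sample <- function(bn, N, seed = 1L) {
  stopifnot(inherits(bn, "bn"))
  N <- as.integer(N)
  if (is.na(N) || N < 1L) stop("N must be a positive integer")
  n <- length(bn$names)
  with_seed(seed, {
    x <- matrix(0L, nrow = N, ncol = n)
    for (i in topo_order(bn$dag$parents)) {
      ps <- bn$dag$parents[[i]]
      r <- bn$arities[i]
      j <- integer(N)
      radix <- 1L
      for (p in ps) {
        j <- j + x[, p] * radix
        radix <- radix * bn$arities[p]
      }
      for (jj in unique(j)) {
        rows <- which(j == jj)
        x[rows, i] <- sample.int(r, length(rows), replace = TRUE,
                                 prob = bn$cpts[[i]][jj + 1L, ]) - 1L
      }
    }
    bn_data(x, names = bn$names, arities = bn$arities)
  })
}

#' @export
simulate.bn <- function(object, nsim = 1000L, seed = 1L, ...) {
  forward_sample(object, N = nsim, seed = seed)
}

#' Worked four-node example of BDeu-scored candidate parent sets
#'
#' A fixed [score_set] over four binary-style nodes named "1".."4" with all
#' 32 candidate parent sets up to in-degree 3 and their local BDeu scores
#' (one decimal place). It is a useful didactic and testing fixture: exactly
#' six of the 32 sets are score-dominated by one of their subsets — for node
#' 1 the sets \{2,3\}, \{2,4\} and \{2,3,4\}, and for node 2 the sets
#' \{1,3\}, \{1,4\} and \{1,3,4\} — so [legal_prune()] leaves 26 legal CPSs,
#' and the optimal DAG uses only legal sets.
#'
#' @return A [score_set] with 32 entries.
#' @examples
#' ss <- example_score_set()
#' n_cps(ss)                  # 32
#' n_cps(legal_prune(ss))     # 26
#' @export
example_score_set <- function() {
  entry <- function(score, ...) list(score = score, parents = c(...))
  tabs <- list(
    list(  # node 1
      entry(-2288.7), entry(-2274.6, 2), entry(-2196.2, 3), entry(-2240.7, 4),
      entry(-2252.8, 2, 3), entry(-2256.1, 2, 4), entry(-2171.3, 3, 4),
      entry(-2173.5, 2, 3, 4)),
    list(  # node 2
      entry(-2003.7), entry(-1989.6, 1), entry(-1900.7, 3), entry(-1915.1, 4),
      entry(-1903.8, 1, 3), entry(-1918.3, 1, 4), entry(-1849.2, 3, 4),
      entry(-1851.4, 1, 3, 4)),
    list(  # node 3
      entry(-2891.5), entry(-2799.0, 1), entry(-2788.5, 2), entry(-2811.3, 4),
      entry(-2714.5, 1, 2), entry(-2741.9, 1, 4), entry(-2745.5, 2, 4),
      entry(-2692.6, 1, 2, 4)),
    list(  # node 4
      entry(-1951.6), entry(-1903.6, 1), entry(-1862.9, 2), entry(-1871.4, 3),
      entry(-1829.5, 1, 2), entry(-1846.5, 1, 3), entry(-1819.9, 2, 3),
      entry(-1807.6, 1, 2, 3)))
  tables <- lapply(tabs, function(tb) {
    list(parents = lapply(tb, function(e) as.integer(e$parents)),
         scores = vapply(tb, `[[`, numeric(1), "score"))
  })
  score_set(as.character(1:4), tables, max_indegree = 3L)
}
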