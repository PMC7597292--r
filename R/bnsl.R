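#' Learn a Bayesian network structure from discrete data or scores
#'
#' The fitting front end of the package. Given discrete data, it enumerates
#' and BDeu-scores candidate parent sets up to `max_indegree`, applies the
#' subset-score legality rule, optionally prunes the bottom `percent` of each
#' node's sorted legal list, and then searches the remaining score tables for
#' a maximum-score DAG. Given a ready-made [score_set] (e.g. read from a
#' GOBNILP/Jaakkola file with [read_scores()]), the scoring stage is skipped.
#'
#' @param x a [bn_data] object, a matrix/data frame of 0-based integer codes,
#'   or a [score_set].
#' @param method search engine: `"dp"` (exact dynamic programming, up to
#'   ~20 nodes), `"greedy"` (constructive pass), `"order"` (order-based local
#'   search with restarts), or `"exhaustive"` (testing oracle, n <= 5).
#' @param max_indegree maximum number of parents per node (scoring stage).
#' @param ess BDeu equivalent sample size.
#' @param percent percentage of each node's sorted legal CPS list to prune
#'   before the search, in `[0, 100)`.
#' @param legal_only apply legality pruning after enumeration.
#' @param restarts,max_iters,seed,time_limit passed to
#'   [order_local_search()] when `method = "order"`.
#' @return An object of class `bnsl`: the learned parent sets, per-node local
#'   scores, the total BDeu score, the search method used, and the score set
#'   searched. Methods: `print`, `summary`, `coef` (per-node local scores),
#'   `as.matrix` (adjacency matrix) and `plot` (needs \pkg{igraph}).
#' @examples
#' ss <- example_score_set()
#' fit <- bnsl(ss, method = "dp")
#' fit
#' coef(fit)
#' @export
bnsl <- function(x, method = c("dp", "greedy", "order", "exhaustive"),
                 max_indegree = 3L, ess = 1, percent = 0, legal_only = TRUE,
                 restarts = 10L, max_iters = 1000L, seed = 1L,
                 time_limit = NULL) {
  method <- match.arg(method)
  if (inherits(x, "score_set")) {
    ss <- x
  } else {
    if (!inherits(x, "bn_data")) x <- bn_data(x)
    ss <- score_parent_sets(x, max_indegree = max_indegree, ess = ess,
                            legal_only = legal_only)
  }
  if (percent > 0) ss <- percent_prune(ss, percent)
  fit <- switch(method,
    dp = exact_dp(ss),
    greedy = greedy_search(ss),
    order = order_local_search(ss, restarts = restarts,
                               max_iters = max_iters, seed = seed,
                               time_limit = time_limit),
    exhaustive = exhaustive_search(ss))
  fit$call <- match.call()
  fit
}

#' @export
print.bnsl <- function(x, ...) {
  cat(sprintf("Bayesian network structure (%s search)\n", x$method))
  cat(sprintf("  nodes: %d   arcs: %d   total BDeu score: %.4f\n",
              length(x$names), count_edges(x$parents), x$total_score))
  arcs <- unlist(lapply(seq_along(x$parents), function(i) {
    if (length(x$parents[[i]]))
      paste0(x$names[x$parents[[i]]], " -> ", x$names[i])
  }))
  if (length(arcs)) {
    cat("  arcs:", paste(arcs, collapse = ", "), "\n")
  } else {
    cat("  arcs: none (empty graph)\n")
  }
  invisible(x)
}

#' @export
summary.bnsl <- function(object, ...) {
  df <- data.frame(
    node = object$names,
    parents = vapply(object$parents, function(p) {
      if (length(p)) paste(object$names[p], collapse = ",") else "{}"
    }, character(1)),
    in_degree = lengths(object$parents),
    local_score = object$local_scores,
    stringsAsFactors = FALSE)
  structure(list(table = df, total_score = object$total_score,
                 method = object$method), class = "summary.bnsl")
}

#' @export
print.summary.bnsl <- function(x, ...) {
  cat(sprintf("Learned structure (%s search), total BDeu score %.4f\n",
              x$method, x$total_score))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
coef.bnsl <- function(object, ...) {
  stats::setNames(object$local_scores, object$names)
}

#' Adjacency matrix of a learned structure
#'
#' @param x a [bnsl] fit.
#' @param ... unused.
#' @return A 0/1 matrix `A` with `A[u, v] = 1` iff there is an arc `u -> v`.
#' @export
as.matrix.bnsl <- function(x, ...) {
  n <- length(x$names)
  a <- matrix(0L, n, n, dimnames = list(x$names, x$names))
  for (i in seq_len(n)) a[x$parents[[i]], i] <- 1L
  a
}

#' @export
plot.bnsl <- function(x, ...) {
  if (!requireNamespace("igraph", quietly = TRUE))
    stop("plotting needs the 'igraph' package")
  g <- igraph::graph_from_adjacency_matrix(as.matrix(x), mode = "directed")
  plot(g, ...)
  invisible(x)
}
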