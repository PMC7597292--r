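#' Exact structure count
#'
#' Wraps an exact (arbitrary-precision) integer count of graph structures,
#' keeping both the exact decimal string and a double approximation.
#'
#' @param value internal bignum or a single non-negative number.
#' @param n the node count the value refers to.
#' @return An object of class `structure_count` with elements `n`,
#'   `value` (exact decimal string) and `approx` (double).
#' @export
structure_count <- function(value, n) {
  if (is.numeric(value) && length(value) == 1L) value <- bi(value)
  structure(list(n = as.integer(n), value = bi_str(value),
                 approx = bi_num(value)), class = "structure_count")
}

#' @export
print.structure_count <- function(x, ...) {
  cat(sprintf("%s (~%.3g) structures for n = %d\n", x$value, x$approx, x$n))
  invisible(x)
}

#' @export
as.numeric.structure_count <- function(x, ...) x$approx

#' @export
format.structure_count <- function(x, ...) x$value

#' Number of labeled DAGs on n nodes
#'
#' Robinson's recurrence for the number of labeled directed acyclic graphs,
#' \deqn{a(m) = \sum_{i=1}^{m} (-1)^{i+1} \binom{m}{i} 2^{i(m-i)} a(m-i)},
#' \eqn{a(0) = 1}, evaluated in exact integer arithmetic. The super-
#' exponential growth of this count is what makes exhaustive structure search
#' infeasible: for 10 nodes it is already about 4.2e18.
#'
#' @param n number of nodes (>= 0).
#' @return A [structure_count].
#' @export
dag_count <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 0L) stop("n must be a non-negative integer")
  a <- vector("list", n + 1L)
  a[[1L]] <- bi(1)
  for (m in seq_len(n)) {
    row <- bi_pascal_row(m)
    pos <- bi(0); neg <- bi(0)
    for (i in seq_len(m)) {
      term <- bi_mul(bi_mul(row[[i + 1L]], bi_pow2(i * (m - i))), a[[m - i + 1L]])
      if (i %% 2L == 1L) pos <- bi_add(pos, term) else neg <- bi_add(neg, term)
    }
    a[[m + 1L]] <- bi_sub(pos, neg)
  }
  structure_count(a[[n + 1L]], n = n)
}

#' Number of structures consistent with the node orderings
#'
#' Order-based search reduces the space to the DAGs consistent with a node
#' ordering: each of the \eqn{n(n-1)/2} ordered pairs may or may not carry an
#' arc, giving \eqn{2^{n(n-1)/2}} structures — about 3.5e13 for 10 nodes,
#' against 4.2e18 unrestricted DAGs.
#'
#' @param n number of nodes (>= 0).
#' @return A [structure_count].
#' @export
order_structure_count <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 0L) stop("n must be a non-negative integer")
  structure_count(bi_pow2(n * (n - 1L) / 2L), n = n)
}

#' Relative score discrepancy between a baseline and a pruned search
#'
#' \deqn{\Delta = (S^* - S)/S^*} where `s_star` is the BDeu score of the
#' baseline (unpruned) graph and `s` the score of the graph learned after
#' pruning. With negative log scores and `s <= s_star`, `delta <= 0`; a
#' pruned result that is worse than the baseline therefore reports a
#' negative discrepancy (conventionally printed in per mille).
#'
#' @param s_star baseline score (non-zero).
#' @param s score of the pruned-search graph.
#' @return The raw ratio; multiply by 1000 for per-mille reporting (see
#'   [format_permille()]).
#' @export
delta_discrepancy <- function(s_star, s) {
  if (!is.numeric(s_star) || length(s_star) != 1L || s_star == 0)
    stop("the baseline score s_star must be a single non-zero number")
  (s_star - s) / s_star
}

#' Format a discrepancy in per mille
#'
#' @param delta raw ratio from [delta_discrepancy()].
#' @param digits decimal places.
#' @return Character, e.g. `"-6.70 permille"` style `"-6.70‰"`.
#' @export
format_permille <- function(delta, digits = 2L) {
  sprintf("%.*f‰", digits, 1000 * delta + 0)  # + 0 normalises IEEE -0
}

#' Sweep pruning levels and measure the accuracy trade-off
#'
#' Runs the full pipeline at each CPS pruning level: the legal score tables
#' are percentage-pruned at level `p`, the requested search engine learns a
#' DAG, and the loss relative to the unpruned baseline (level 0, always
#' included, learned with the same engine and seed) is reported as the
#' discrepancy \eqn{\Delta = (S^* - S)/S^*}.
#'
#' @param x a [bn_data] object or a [score_set]. Data is scored with
#'   `max_indegree`/`ess` and legality-pruned first; a score set is assumed
#'   legal already.
#' @param levels pruning percentages in `[0, 100)`.
#' @param method search engine, as in [bnsl()].
#' @param seed seed for stochastic engines.
#' @param restarts restarts for `method = "order"`.
#' @param max_indegree,ess scoring parameters used when `x` is data.
#' @param time_limit optional per-level search budget in seconds.
#' @return A data frame with one row per level: `level`, `cps_graph` (CPS
#'   count over all nodes after pruning), `cps_per_node`, `score` (S),
#'   `baseline` (S*), `delta` (raw ratio), `delta_permille` and `time_secs`
#'   (informational).
#' @export
pruning_curve <- function(x, levels = c(0, 30, 60, 90),
                          method = c("dp", "greedy", "order"), seed = 1L,
                          restarts = 10L, max_indegree = 3L, ess = 1,
                          time_limit = NULL) {
  method <- match.arg(method)
  if (inherits(x, "score_set")) {
    ss <- x
  } else {
    if (!inherits(x, "bn_data")) x <- bn_data(x)
    ss <- score_parent_sets(x, max_indegree = max_indegree, ess = ess,
                            legal_only = TRUE)
  }
  levels <- sort(unique(c(0, as.numeric(levels))))
  if (any(levels < 0 | levels >= 100)) stop("levels must lie in [0, 100)")
  run <- function(p) {
    pruned <- if (p > 0) percent_prune(ss, p) else ss
    t0 <- proc.time()[["elapsed"]]
    fit <- switch(method,
      dp = exact_dp(pruned),
      greedy = greedy_search(pruned),
      order = order_local_search(pruned, restarts = restarts, seed = seed,
                                 time_limit = time_limit))
    list(cps = n_cps(pruned), per_node = mean(n_cps(pruned, per_node = TRUE)),
         score = fit$total_score,
         time = proc.time()[["elapsed"]] - t0)
  }
  rows <- lapply(levels, run)
  s_star <- rows[[1L]]$score
  out <- data.frame(
    level = levels,
    cps_graph = vapply(rows, `[[`, numeric(1), "cps"),
    cps_per_node = vapply(rows, `[[`, numeric(1), "per_node"),
    score = vapply(rows, `[[`, numeric(1), "score"),
    baseline = s_star,
    delta = vapply(rows, function(r) delta_discrepancy(s_star, r$score), numeric(1)),
    time_secs = vapply(rows, `[[`, numeric(1), "time"))
  out$delta_permille <- 1000 * out$delta
  class(out) <- c("pruning_curve", "data.frame")
  out
}

#' Write a pruning curve as TSV
#'
#' @param curve a data frame from [pruning_curve()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_curve_tsv <- function(curve, path) {
  df <- data.frame(level = curve$level, cps_graph = curve$cps_graph,
                   cps_per_node = curve$cps_per_node, S = curve$score,
                   S_star = curve$baseline,
                   delta_permille = sprintf("%.2f", curve$delta_permille),
                   time_secs = curve$time_secs)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
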