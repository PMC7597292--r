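#' Contingency counts for a child and a parent set
#'
#' Tallies the joint counts N_jk of the child's states (k) against the joint
#' parent configurations (j). Configurations are indexed in mixed radix with
#' the lowest parent index as the least-significant digit, and `q` counts all
#' product-of-arity configurations, observed or not.
#'
#' @param data a [bn_data] object.
#' @param child child variable index (1-based).
#' @param parents integer vector of parent indices; may be empty.
#' @return A list with `child`, `parents` (sorted), `q` (number of parent
#'   configurations), `r` (child arity) and `counts`, a `q x r` integer
#'   matrix of N_jk.
#' @export
contingency_counts <- function(data, child, parents = integer(0)) {
  stopifnot(inherits(data, "bn_data"))
  child <- as.integer(child)
  parents <- sort(as.integer(parents))
  if (length(child) != 1L || is.na(child) || child < 1L || child > data$n)
    stop("invalid child index")
  if (length(parents) && (anyNA(parents) || any(parents < 1L) || any(parents > data$n)))
    stop("invalid parent index")
  if (child %in% parents) stop("child must not be among its parents")
  if (anyDuplicated(parents)) stop("duplicate parent index")
  r <- data$arities[child]
  q <- if (length(parents)) prod(as.numeric(data$arities[parents])) else 1
  if (q * r > 5e7) stop("parent configuration space too large to tabulate")
  q <- as.integer(q)
  j <- integer(data$N)
  radix <- 1L
  for (p in parents) {
    j <- j + data$x[, p] * radix
    radix <- radix * data$arities[p]
  }
  cnt <- tabulate(j * r + data$x[, child] + 1L, nbins = q * r)
  counts <- matrix(cnt, nrow = q, ncol = r, byrow = TRUE)
  list(child = child, parents = parents, q = q, r = r, counts = counts)
}

#' BDeu local score of a child given a parent set
#'
#' Log marginal likelihood of the child's column under symmetric Dirichlet
#' priors with total equivalent sample size `ess` spread uniformly over the
#' `q * r` parameter cells:
#' \deqn{\sum_j [\ln\Gamma(\alpha/q) - \ln\Gamma(\alpha/q + N_{j})] +
#'       \sum_{j,k} [\ln\Gamma(\alpha/(qr) + N_{jk}) - \ln\Gamma(\alpha/(qr))]}
#' Natural-log scale; always finite and non-positive.
#'
#' @inheritParams contingency_counts
#' @param ess equivalent sample size \eqn{\alpha > 0} of the Dirichlet prior.
#' @return The local score, a single non-positive number.
#' @examples
#' d <- bn_data(matrix(c(0L, 1L), ncol = 1), names = "A")
#' bdeu_local_score(d, 1)  # log((1/2) * (1/4)) = log(1/8)
#' @export
bdeu_local_score <- function(data, child, parents = integer(0), ess = 1) {
  if (!is.numeric(ess) || length(ess) != 1L || ess <= 0) stop("ess must be > 0")
  ct <- contingency_counts(data, child, parents)
  aq <- ess / ct$q
  aqr <- ess / (ct$q * ct$r)
  nj <- rowSums(ct$counts)
  obs <- which(nj > 0L)
  sum(lgamma(aq) - lgamma(aq + nj[obs])) +
    sum(lgamma(aqr + ct$counts[obs, , drop = FALSE]) - lgamma(aqr))
}

#' Total (decomposable) score of a DAG under a score set
#'
#' The graph score is the sum over nodes of the local score of the node's
#' assigned parent set; every (node, parent set) pair must be present in
#' `score_set`.
#'
#' @param score_set a [score_set] object.
#' @param dag a DAG given as a list of parent index vectors, one per node
#'   (as returned by [random_dag()] or found in a [bnsl] fit).
#' @return The total score, a single number.
#' @export
graph_score <- function(score_set, dag) {
  stopifnot(inherits(score_set, "score_set"))
  parents <- dag_parents(dag, score_set$n)
  total <- 0
  for (i in seq_len(score_set$n)) {
    s <- lookup_score(score_set$tables[[i]], parents[[i]])
    if (is.na(s))
      stop(sprintf("no score for node '%s' with parent set {%s}",
                   score_set$names[i],
                   paste(score_set$names[parents[[i]]], collapse = ",")))
    total <- total + s
  }
  total
}

# normalise the accepted DAG representations to a plain list of sorted
# integer parent vectors
dag_parents <- function(dag, n) {
  if (inherits(dag, "bnsl")) dag <- dag$parents
  if (inherits(dag, "bn_dag")) dag <- dag$parents
  if (!is.list(dag) || length(dag) != n)
    stop(sprintf("dag must be a list of %d parent sets", n))
  lapply(dag, function(p) sort(as.integer(p)))
}

ps_key <- function(parents) paste(sort(as.integer(parents)), collapse = ",")

lookup_score <- function(table, parents) {
  k <- ps_key(parents)
  i <- match(k, table$keys)
  if (is.na(i)) NA_real_ else table$scores[i]
}
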