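# Independent oracles and fixture builders used across the suite. These are
# deliberately naive (row loops, all-pairs subset comparisons, exhaustive
# enumeration) so they share no code path with the implementation.

# brute-force N_jk tally by looping over rows
oracle_counts <- function(data, child, parents) {
  parents <- sort(parents)
  q <- if (length(parents)) prod(data$arities[parents]) else 1L
  r <- data$arities[child]
  counts <- matrix(0L, q, r)
  for (row in seq_len(data$N)) {
    j <- 0L
    radix <- 1L
    for (p in parents) {
      j <- j + data$x[row, p] * radix
      radix <- radix * data$arities[p]
    }
    k <- data$x[row, child]
    counts[j + 1L, k + 1L] <- counts[j + 1L, k + 1L] + 1L
  }
  counts
}

# all-pairs subset-dominance check on one node table
oracle_legal_keep <- function(parents, scores) {
  m <- length(parents)
  keep <- rep(TRUE, m)
  for (a in seq_len(m)) {
    for (b in seq_len(m)) {
      if (a == b) next
      pa <- parents[[a]]; pb <- parents[[b]]
      if (length(pb) < length(pa) && all(pb %in% pa) && scores[b] >= scores[a]) {
        keep[a] <- FALSE
      }
    }
  }
  keep
}

# count labeled DAGs on n nodes by depth-first enumeration of per-node
# parent subsets with incremental cycle pruning
oracle_dag_count <- function(n) {
  all_subsets <- list(integer(0))
  for (k in seq_len(n)) all_subsets <- c(all_subsets,
    lapply(seq_len(ncol(utils::combn(n, k))), function(j) utils::combn(n, k)[, j]))
  subsets_for <- lapply(seq_len(n), function(i)
    Filter(function(s) !(i %in% s), all_subsets))
  count <- 0L
  assign <- vector("list", n)
  acyclic_prefix <- function(k) {
    parents <- c(assign[seq_len(k)], rep(list(integer(0)), n - k))
    bnprune::is_acyclic(parents, n)
  }
  recurse <- function(i) {
    if (i > n) {
      count <<- count + 1L
      return(invisible())
    }
    for (s in subsets_for[[i]]) {
      assign[[i]] <<- s
      if (acyclic_prefix(i)) recurse(i + 1L)
    }
    invisible()
  }
  recurse(1L)
  count
}

# random score set with direct (not data-derived) scores; all subsets up to
# size d are present so legality pruning is well defined
random_score_set <- function(n, d = 2L, seed = 1L) {
  set.seed(seed)
  tables <- lapply(seq_len(n), function(i) {
    others <- setdiff(seq_len(n), i)
    parents <- list(integer(0))
    for (k in seq_len(min(d, n - 1L))) {
      cm <- utils::combn(others, k)
      parents <- c(parents, lapply(seq_len(ncol(cm)), function(j) cm[, j]))
    }
    # anchored near -100 with size-dependent jitter so some supersets win
    # and others lose against their subsets
    scores <- -100 - stats::runif(length(parents), 0, 10) +
      2 * lengths(parents) * stats::rbinom(length(parents), 1, 0.5)
    list(parents = parents, scores = scores)
  })
  bnprune::score_set(paste0("X", seq_len(n)), tables,
                     max_indegree = min(d, n - 1L))
}

# small synthetic dataset from a seeded ground truth
random_dataset <- function(n, N, d = 2L, seed = 1L, arity = 2L,
                           concentration = 0.5) {
  dag <- bnprune::random_dag(n, max_indegree = min(d, n - 1L),
                             edge_prob = 0.6, seed = seed)
  bn <- bnprune::random_cpts(dag, arities = rep(arity, n),
                             concentration = concentration, seed = seed + 1000L)
  bnprune::forward_sample(bn, N = N, seed = seed + 2000L)
}

# skeleton + v-structures; two DAGs are Markov equivalent iff both match
cpdag_signature <- function(parents) {
  n <- length(parents)
  skel <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (p in parents[[i]]) {
      skel[i, p] <- TRUE
      skel[p, i] <- TRUE
    }
  }
  vstruct <- character(0)
  for (i in seq_len(n)) {
    ps <- parents[[i]]
    if (length(ps) >= 2L) {
      for (ab in combn_pairs(ps)) {
        if (!skel[ab[1L], ab[2L]]) {
          vstruct <- c(vstruct, paste(ab[1L], ab[2L], i, sep = "-"))
        }
      }
    }
  }
  list(skeleton = skel, vstructures = sort(vstruct))
}

combn_pairs <- function(v) {
  m <- utils::combn(sort(v), 2L)
  lapply(seq_len(ncol(m)), function(j) m[, j])
}

markov_equivalent <- function(parents_a, parents_b) {
  a <- cpdag_signature(parents_a)
  b <- cpdag_signature(parents_b)
  identical(a$skeleton, b$skeleton) && identical(a$vstructures, b$vstructures)
}

# all permutations of 1:n (n small)
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

# weakest arc of a ground truth: min over arcs of the maximum total-variation
# distance between the child's conditional rows that differ only in that
# parent's state. Computed from the true CPTs alone (no data involved); a
# truth whose weakest arc is near 0 is unidentifiable at any sample size.
min_edge_strength <- function(bn) {
  strength <- function(child, parent) {
    ps <- bn$dag$parents[[child]]
    cpt <- bn$cpts[[child]]
    k <- match(parent, ps)
    ar <- bn$arities[ps]
    radix_k <- if (k > 1) prod(ar[seq_len(k - 1)]) else 1
    best <- 0
    for (j in 0:(nrow(cpt) - 1)) {
      digits <- integer(length(ps)); m <- j
      for (t in seq_along(ps)) { digits[t] <- m %% ar[t]; m <- m %/% ar[t] }
      if (digits[k] == 0) {
        for (s in seq_len(ar[k] - 1)) {
          tv <- 0.5 * sum(abs(cpt[j + 1, ] - cpt[j + s * radix_k + 1, ]))
          best <- max(best, tv)
        }
      }
    }
    best
  }
  vals <- unlist(lapply(seq_along(bn$names), function(i) {
    vapply(bn$dag$parents[[i]], function(p) strength(i, p), numeric(1))
  }))
  if (length(vals)) min(vals) else Inf
}
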