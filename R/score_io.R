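#' Read a GOBNILP/Jaakkola local-score file
#'
#' The `.jkl` dialect: the first non-blank line holds the number of
#' variables `n`; then, for each variable, a header line `name m` followed
#' by `m` lines `score k parent1 ... parentk`. Parent fields may be variable
#' names or 0-based indices; indices are assumed when every parent token in
#' the file is an integer that matches no variable name. Tables are re-sorted
#' to descending score order regardless of file order.
#'
#' @param path path to the score file.
#' @return A [score_set].
#' @seealso [write_scores()]
#' @export
read_scores <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  tok <- strsplit(trimws(lines[keep]), "[ \t]+")
  lineno <- keep  # original line numbers for error messages
  if (!length(tok)) stop("empty score file")
  n <- suppressWarnings(as.integer(tok[[1L]][1L]))
  if (is.na(n) || n < 1L) stop(sprintf("line %d: expected the variable count", lineno[1L]))
  pos <- 2L
  names <- character(n)
  raw <- vector("list", n)
  for (i in seq_len(n)) {
    if (pos > length(tok)) stop("unexpected end of file: fewer variable blocks than declared")
    hd <- tok[[pos]]
    if (length(hd) != 2L)
      stop(sprintf("line %d: expected 'name count' header", lineno[pos]))
    names[i] <- hd[1L]
    m <- suppressWarnings(as.integer(hd[2L]))
    if (is.na(m) || m < 1L)
      stop(sprintf("line %d: bad CPS count '%s'", lineno[pos], hd[2L]))
    pos <- pos + 1L
    entries <- vector("list", m)
    for (e in seq_len(m)) {
      if (pos > length(tok)) stop("unexpected end of file inside a variable block")
      ln <- tok[[pos]]
      s <- suppressWarnings(as.numeric(ln[1L]))
      k <- suppressWarnings(as.integer(ln[2L]))
      if (length(ln) < 2L || is.na(s) || is.na(k) || length(ln) != 2L + k)
        stop(sprintf("line %d: malformed score line", lineno[pos]))
      entries[[e]] <- list(score = s, parents = ln[-(1:2)], line = lineno[pos])
      pos <- pos + 1L
    }
    raw[[i]] <- entries
  }
  if (anyDuplicated(names)) stop("duplicate variable names in score file")
  # decide whether parent tokens are names or 0-based indices
  ptok <- unlist(lapply(raw, function(es) unlist(lapply(es, `[[`, "parents"))))
  by_index <- length(ptok) > 0 &&
    all(grepl("^[0-9]+$", ptok)) && !any(ptok %in% names)
  tables <- lapply(raw, function(es) {
    parents <- lapply(es, function(en) {
      p <- en$parents
      if (length(p) == 0L) return(integer(0))
      if (by_index) {
        idx <- as.integer(p) + 1L
      } else {
        idx <- match(p, names)
      }
      if (anyNA(idx) || any(idx < 1L) || any(idx > length(names)))
        stop(sprintf("line %d: unknown parent '%s'", en$line,
                     paste(p[is.na(idx) | idx < 1L | idx > length(names)][1L])))
      idx
    })
    list(parents = parents, scores = vapply(es, `[[`, numeric(1), "score"))
  })
  score_set(names, tables)
}

#' Write a score set in the GOBNILP/Jaakkola dialect
#'
#' Entries are written in sorted table order, parents by variable name, with
#' fixed decimal precision (round-trips are exact to that precision).
#'
#' @param score_set a [score_set].
#' @param path output file path.
#' @param digits decimal places used for scores.
#' @return `path`, invisibly.
#' @export
write_scores <- function(score_set, path, digits = 6L) {
  stopifnot(inherits(score_set, "score_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(score_set$n), con)
  for (i in seq_len(score_set$n)) {
    tb <- score_set$tables[[i]]
    writeLines(paste(score_set$names[i], length(tb$scores)), con)
    for (e in seq_along(tb$scores)) {
      p <- score_set$names[tb$parents[[e]]]
      writeLines(paste(c(sprintf("%.*f", digits, tb$scores[e]),
                         length(p), p), collapse = " "), con)
    }
  }
  invisible(path)
}

#' Write a learned network as a JSON document
#'
#' Emits `{"nodes": [{"name", "parents", "local_score"}, ...],
#' "total_score": ...}` for a fitted [bnsl] object.
#'
#' @param fit a [bnsl] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network_json <- function(fit, path) {
  stopifnot(inherits(fit, "bnsl"))
  nodes <- lapply(seq_along(fit$names), function(i) {
    list(name = fit$names[i],
         parents = as.list(fit$names[fit$parents[[i]]]),
         local_score = fit$local_scores[i])
  })
  doc <- list(nodes = nodes, total_score = fit$total_score,
              method = fit$method)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a learned network from its JSON document
#'
#' @param path path to a file written by [write_network_json()].
#' @return A [bnsl] object (without an attached score set).
#' @export
read_network_json <- function(path) {
  doc <- jsonlite::read_json(path)
  names <- vapply(doc$nodes, `[[`, character(1), "name")
  parents <- lapply(doc$nodes, function(nd) {
    match(unlist(nd$parents), names)
  })
  parents <- lapply(parents, function(p) sort(as.integer(if (is.null(p)) integer(0) else p)))
  local_scores <- vapply(doc$nodes, `[[`, numeric(1), "local_score")
  new_bnsl(parents, names, local_scores, total_score = doc$total_score,
           method = if (is.null(doc$method)) "unknown" else doc$method)
}

#' Export a DAG in Graphviz DOT format
#'
#' @param fit a [bnsl] object or a list of parent index vectors.
#' @param path output file path.
#' @param names variable names (taken from `fit` when available).
#' @return `path`, invisibly.
#' @export
write_network_dot <- function(fit, path, names = NULL) {
  if (inherits(fit, "bnsl")) {
    names <- fit$names
    parents <- fit$parents
  } else {
    parents <- fit
    if (is.null(names)) names <- paste0("V", seq_along(parents))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("digraph bn {", con)
  for (nm in names) writeLines(sprintf("  \"%s\";", nm), con)
  for (i in seq_along(parents)) {
    for (p in parents[[i]]) {
      writeLines(sprintf("  \"%s\" -> \"%s\";", names[p], names[i]), con)
    }
  }
  writeLines("}", con)
  invisible(path)
}
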