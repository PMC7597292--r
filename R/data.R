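#' Discrete dataset for structure learning
#'
#' Bundles an N x n matrix of integer observations with variable names and
#' arities (number of states per variable). Values for variable `i` are
#' 0-based codes in `[0, arities[i])`. This is the observational input to
#' BDeu scoring and to [bnsl()].
#'
#' @param x integer matrix or data frame, one row per observation, one column
#'   per variable; values are 0-based state codes.
#' @param names character vector of unique variable names; defaults to the
#'   column names of `x` or `V1..Vn`.
#' @param arities integer vector of per-variable state counts (each >= 2).
#'   When `NULL`, arity is inferred as `max(observed value) + 1`, floored
#'   at 2.
#' @return An object of class `bn_data`: a list with elements `names`,
#'   `arities`, `x` (integer matrix), `n` (variables) and `N` (observations).
#' @examples
#' d <- bn_data(matrix(c(0L, 1L, 1L, 0L), nrow = 2), names = c("A", "B"))
#' d$arities
#' @export
bn_data <- function(x, names = NULL, arities = NULL) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(as.integer(x), ncol = 1L)
  storage.mode(x) <- "integer"
  if (nrow(x) < 1L) stop("dataset must contain at least one observation")
  if (anyNA(x)) stop("dataset contains missing values")
  n <- ncol(x)
  if (is.null(names)) names <- colnames(x)
  if (is.null(names)) names <- paste0("V", seq_len(n))
  names <- as.character(names)
  if (length(names) != n) stop("length(names) must equal ncol(x)")
  if (anyDuplicated(names)) stop("variable names must be unique")
  if (any(x < 0L)) stop("values must be non-negative integer state codes")
  if (is.null(arities)) {
    arities <- pmax(apply(x, 2L, max) + 1L, 2L)
  }
  arities <- as.integer(arities)
  if (length(arities) != n) stop("length(arities) must equal ncol(x)")
  if (any(arities < 2L)) stop("every arity must be at least 2")
  bad <- which(apply(x, 2L, max) >= arities)
  if (length(bad)) {
    stop(sprintf("values of variable '%s' exceed its arity %d",
                 names[bad[1L]], arities[bad[1L]]))
  }
  dimnames(x) <- list(NULL, names)
  structure(list(names = names, arities = arities, x = x,
                 n = n, N = nrow(x)),
            class = "bn_data")
}

#' @export
print.bn_data <- function(x, ...) {
  cat(sprintf("Discrete dataset: %d observations of %d variables\n", x$N, x$n))
  cat("  arities:", paste0(x$names, "=", x$arities, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.bn_data <- function(x) c(x$N, x$n)

#' Read a whitespace-delimited discrete data file
#'
#' The format is the plain-text table used by GOBNILP-style tools: the first
#' row holds variable names, an optional second row holds integer arities,
#' and every remaining row holds one observation of 0-based integer codes.
#' The second row is taken to be an arity row when all its tokens are
#' integers >= 2 and at least one data row follows; otherwise it is treated
#' as data and arities are inferred as `max + 1` (floored at 2). A file
#' without an arity row whose first observation happens to contain only
#' values >= 2 is therefore ambiguous; [write_bn_data()] always writes the
#' explicit arity row, so round trips are unaffected.
#'
#' @param path path to the data file.
#' @return A [bn_data] object.
#' @seealso [write_bn_data()]
#' @export
read_bn_data <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("data file needs a name row and at least one data row")
  tok <- strsplit(trimws(lines), "[ \t]+")
  names <- tok[[1L]]
  n <- length(names)
  parse_row <- function(i) {
    row <- tok[[i]]
    if (length(row) != n)
      stop(sprintf("line %d: expected %d fields, found %d", i, n, length(row)))
    v <- suppressWarnings(as.integer(row))
    if (anyNA(v) || any(v != as.numeric(row)))
      stop(sprintf("line %d: non-integer value", i))
    v
  }
  second <- parse_row_or_null(tok[[2L]], n)
  body_start <- 2L
  arities <- NULL
  if (!is.null(second) && length(lines) >= 3L && all(second >= 2L)) {
    arities <- second
    body_start <- 3L
  }
  rows <- vapply(seq.int(body_start, length(lines)), parse_row, integer(n))
  rows <- if (is.matrix(rows)) t(rows) else matrix(rows, ncol = n)
  if (any(rows < 0L)) {
    i <- which(apply(rows < 0L, 1L, any))[1L]
    stop(sprintf("line %d: negative value", body_start + i - 1L))
  }
  if (!is.null(arities)) {
    for (j in seq_len(n)) {
      bad <- which(rows[, j] >= arities[j])
      if (length(bad))
        stop(sprintf("line %d: value %d out of range for variable '%s' (arity %d)",
                     body_start + bad[1L] - 1L, rows[bad[1L], j], names[j], arities[j]))
    }
  }
  bn_data(rows, names = names, arities = arities)
}

# integer row of the right width, or NULL if it cannot be one
parse_row_or_null <- function(row, n) {
  if (length(row) != n) return(NULL)
  v <- suppressWarnings(as.integer(row))
  if (anyNA(v)) return(NULL)
  v
}

#' Write a discrete dataset to a whitespace-delimited file
#'
#' Inverse of [read_bn_data()]; always writes the explicit arity row.
#'
#' @param data a [bn_data] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bn_data <- function(data, path) {
  stopifnot(inherits(data, "bn_data"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(data$names, collapse = " "), con)
  writeLines(paste(data$arities, collapse = " "), con)
  writeLines(apply(data$x, 1L, paste, collapse = " "), con)
  invisible(path)
}
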