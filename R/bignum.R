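# Minimal arbitrary-precision non-negative integers, stored little-endian in
# base 1e4. Only what the exact structure-count formulas need: add, subtract
# (a >= b), multiply, compare, powers of two, Pascal-row binomials.

BI_BASE <- 10000L

bi <- function(x) {
  stopifnot(is.numeric(x), length(x) == 1L, x >= 0, x == floor(x), x < 2^53)
  if (x == 0) return(0L)
  d <- integer(0)
  while (x > 0) {
    d <- c(d, as.integer(x %% BI_BASE))
    x <- floor(x / BI_BASE)
  }
  d
}

bi_trim <- function(a) {
  n <- length(a)
  while (n > 1L && a[n] == 0L) n <- n - 1L
  a[seq_len(n)]
}

bi_add <- function(a, b) {
  n <- max(length(a), length(b))
  a <- c(a, integer(n - length(a)))
  b <- c(b, integer(n - length(b)))
  s <- a + b
  carry <- 0L
  for (i in seq_len(n)) {
    s[i] <- s[i] + carry
    carry <- s[i] %/% BI_BASE
    s[i] <- s[i] %% BI_BASE
  }
  if (carry > 0L) s <- c(s, carry)
  s
}

# requires a >= b
bi_sub <- function(a, b) {
  stopifnot(bi_cmp(a, b) >= 0L)
  n <- length(a)
  b <- c(b, integer(n - length(b)))
  d <- a - b
  for (i in seq_len(n)) {
    if (d[i] < 0L) {
      d[i] <- d[i] + BI_BASE
      d[i + 1L] <- d[i + 1L] - 1L
    }
  }
  bi_trim(d)
}

bi_cmp <- function(a, b) {
  a <- bi_trim(a); b <- bi_trim(b)
  if (length(a) != length(b)) return(if (length(a) > length(b)) 1L else -1L)
  for (i in rev(seq_along(a))) {
    if (a[i] != b[i]) return(if (a[i] > b[i]) 1L else -1L)
  }
  0L
}

bi_mul <- function(a, b) {
  if (bi_is_zero(a) || bi_is_zero(b)) return(0L)
  # accumulate in doubles: digit products < 1e8, row sums stay far below 2^53
  acc <- numeric(length(a) + length(b))
  for (i in seq_along(a)) {
    if (a[i] == 0L) next
    idx <- (i - 1L) + seq_along(b)
    acc[idx] <- acc[idx] + as.numeric(a[i]) * as.numeric(b)
  }
  out <- integer(length(acc) + 2L)
  carry <- 0
  for (i in seq_along(acc)) {
    v <- acc[i] + carry
    carry <- floor(v / BI_BASE)
    out[i] <- as.integer(v - carry * BI_BASE)
  }
  i <- length(acc)
  while (carry > 0) {
    i <- i + 1L
    out[i] <- as.integer(carry %% BI_BASE)
    carry <- floor(carry / BI_BASE)
  }
  bi_trim(out[seq_len(max(i, 1L))])
}

bi_is_zero <- function(a) length(bi_trim(a)) == 1L && bi_trim(a)[1] == 0L

bi_pow2 <- function(k) {
  stopifnot(k >= 0)
  out <- bi(1)
  while (k >= 13) {  # 2^13 = 8192 < base^2, keeps chunks cheap
    out <- bi_mul(out, bi(8192))
    k <- k - 13
  }
  if (k > 0) out <- bi_mul(out, bi(2^k))
  out
}

bi_str <- function(a) {
  a <- bi_trim(a)
  hi <- as.character(a[length(a)])
  lo <- sprintf("%04d", rev(a[-length(a)]))
  paste0(hi, paste(lo, collapse = ""))
}

bi_num <- function(a) {
  a <- bi_trim(a)
  sum(as.numeric(a) * BI_BASE^(seq_along(a) - 1L))
}

# row n of Pascal's triangle, entries C(n, 0..n), computed by additions only
bi_pascal_row <- function(n) {
  row <- list(bi(1))
  if (n == 0L) return(row)
  for (m in seq_len(n)) {
    new <- vector("list", m + 1L)
    new[[1L]] <- bi(1)
    new[[m + 1L]] <- bi(1)
    if (m > 1L) {
      for (j in 2:m) new[[j]] <- bi_add(row[[j - 1L]], row[[j]])
    }
    row <- new
  }
  row
}
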