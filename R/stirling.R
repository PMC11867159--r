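# Unsigned Stirling numbers of the first kind, c(n, k): the number of
# permutations of n elements with exactly k cycles.  They drive the exact
# depth laws of random leaves in reduced and evolutionary trees.
#
# The recurrence c(n,k) = c(n-1,k-1) + (n-1) c(n-1,k) needs only addition and
# multiplication by a small scalar, so exact rows are kept as little-endian
# digit matrices in base 1e7 (one column per k); no external big-integer
# library is required.  Rows are cached per session.

.stirling_cache <- new.env(parent = emptyenv())

.BIGBASE <- 1e7

.big_normalize <- function(D) {
  # D: digits x cols matrix of non-negative integer-valued doubles
  while (any(D >= .BIGBASE)) {
    carry <- floor(D / .BIGBASE)
    D <- D - carry * .BIGBASE
    if (any(carry[nrow(carry), ] > 0))
      D <- rbind(D, 0)
    carry <- rbind(0, carry)[seq_len(nrow(D)), , drop = FALSE]
    D <- D + carry
  }
  D
}

.big_to_character <- function(D) {
  apply(D, 2, function(col) {
    top <- max(c(1, which(col != 0)))
    s <- paste0(sprintf("%.0f", col[top]),
                paste(sprintf("%07.0f", rev(col[seq_len(top - 1)])),
                      collapse = ""))
    s
  })
}

.big_to_double <- function(D) {
  # exact when the value is < 2^53, best double approximation otherwise
  drop(.BIGBASE^(seq_len(nrow(D)) - 1) %*% D)
}

.stirling_row_big <- function(n) {
  key <- sprintf("row%d", n)
  if (!is.null(.stirling_cache[[key]])) return(.stirling_cache[[key]])
  # start from the highest cached row below n
  cached <- ls(.stirling_cache, pattern = "^row")
  have <- if (length(cached)) as.integer(sub("row", "", cached)) else integer(0)
  have <- have[have < n]
  if (length(have)) {
    m <- max(have)
    D <- .stirling_cache[[sprintf("row%d", m)]]
  } else {
    m <- 0L
    D <- matrix(1, 1, 1) # c(0,0) = 1
  }
  while (m < n) {
    m <- m + 1L
    shifted <- cbind(0, D)              # c(m-1, k-1)
    scaled <- cbind((m - 1) * D, 0)     # (m-1) c(m-1, k)
    D <- .big_normalize(shifted + scaled)
  }
  .stirling_cache[[key]] <- D
  D
}

#' Unsigned Stirling numbers of the first kind
#'
#' `stirling_first_kind(n, k)` is the number of permutations of `n` elements
#' with exactly `k` cycles, computed exactly by the recurrence
#' `c(n,k) = c(n-1,k-1) + (n-1) c(n-1,k)` using internal big-integer rows.
#' These numbers give the exact depth distributions of a random leaf in
#' reduced and evolutionary trees under neutral models.
#'
#' @param n non-negative integer, at most 500.
#' @param k non-negative integer (values with `k > n` return 0 by convention).
#' @param exact if `TRUE` (default) return the exact value: a double when it is
#'   below 2^53, otherwise a decimal character string. If `FALSE`, always
#'   return the closest double.
#' @return A double, or a character string for values at or above 2^53 when
#'   `exact = TRUE`.
#' @examples
#' stirling_first_kind(4, 2) # 11
#' stirling_first_kind(3, 2) # 3
#' @export
stirling_first_kind <- function(n, k, exact = TRUE) {
  if (length(n) != 1 || length(k) != 1 || n < 0 || k < 0)
    stop("n and k must be single non-negative integers")
  if (n > 500) stop("exact Stirling numbers supported for n <= 500; ",
                    "use log_stirling_row() beyond")
  if (k > n) return(0)
  D <- .stirling_row_big(as.integer(n))[, k + 1, drop = FALSE]
  val <- .big_to_double(D)
  if (val < 2^53 || !exact) val else .big_to_character(D)
}

#' @rdname stirling_first_kind
#' @description `stirling_row(n)` returns the whole exact row `c(n, 0..n)`
#'   as doubles (exact while below 2^53).
#' @export
stirling_row <- function(n) {
  if (n < 0 || n > 500) stop("n must be in 0..500")
  .big_to_double(.stirling_row_big(as.integer(n)))
}

#' @rdname stirling_first_kind
#' @description `log_stirling_row(n)` returns `log c(n, 0..n)` (natural log,
#'   `-Inf` for the zero entry `c(n, 0)`, `n >= 1`), computed by the same
#'   recurrence in log space; usable for large `n` where exact integers
#'   overflow doubles.
#' @export
log_stirling_row <- function(n) {
  n <- as.integer(n)
  if (n < 0) stop("n must be non-negative")
  key <- sprintf("log%d", n)
  if (!is.null(.stirling_cache[[key]])) return(.stirling_cache[[key]])
  lr <- 0 # log c(0, 0)
  if (n >= 1) {
    for (m in seq_len(n)) {
      a <- c(-Inf, lr)                      # log c(m-1, k-1)
      b <- c(log(m - 1) + lr, -Inf)         # log((m-1) c(m-1, k))
      hi <- pmax(a, b)
      lr <- hi + log1p(exp(pmin(a, b) - hi))
      lr[is.nan(lr)] <- -Inf
    }
  }
  .stirling_cache[[key]] <- lr
  lr
}
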