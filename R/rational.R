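#' Exact rational numbers on IEEE doubles
#'
#' A minimal exact rational type used for the small-n probability computations
#' (shape probabilities, depth laws, Shapley weights). Numerator and
#' denominator are stored as doubles and kept reduced; arithmetic is exact as
#' long as intermediate integers stay below 2^53, which comfortably covers the
#' exact regime (leaf counts up to about 12-18) where worked-example
#' probabilities such as 1/6, 1/90 or 2/3 must be reproduced bit-exactly.
#' Operations stop with an error rather than silently losing precision.
#'
#' @param num integer-valued numerator(s).
#' @param den integer-valued denominator(s), non-zero.
#' @return An object of class `"rational"` (list with `num` and `den`
#'   vectors, reduced, denominator positive).
#' @examples
#' r <- rational(2, 12)
#' format(r) # "1/6"
#' as.numeric(rational_add(rational(1, 3), rational(1, 2)))
#' @export
rational <- function(num, den = 1) {
  stopifnot(is.numeric(num), is.numeric(den), all(den != 0))
  n <- cbind(as.numeric(num), as.numeric(den)) # recycle
  num <- n[, 1]; den <- n[, 2]
  if (any(num != round(num)) || any(den != round(den)))
    stop("rational() requires integer-valued numerator and denominator")
  .rat_check(num); .rat_check(den)
  sgn <- ifelse(den < 0, -1, 1)
  num <- num * sgn; den <- den * sgn
  g <- .gcd(abs(num), den)
  g[g == 0] <- 1
  structure(list(num = num / g, den = den / g), class = "rational")
}

.rat_check <- function(x) {
  if (any(abs(x) >= 2^53))
    stop("exact rational arithmetic overflow (value >= 2^53)")
  invisible(x)
}

.gcd <- function(a, b) {
  # vectorized Euclid on non-negative integer-valued doubles
  while (any(b > 0)) {
    t <- b
    b <- ifelse(b > 0, a %% b, 0)
    a <- ifelse(t > 0, t, a)
  }
  a
}

#' @rdname rational
#' @param x,y rationals (or numbers coercible via `rational()`).
#' @export
rational_add <- function(x, y) {
  x <- as_rational(x); y <- as_rational(y)
  g <- .gcd(x$den, y$den) # add over the lcm to delay overflow
  dy <- y$den / g; dx <- x$den / g
  .rat_check(x$num * dy); .rat_check(y$num * dx); .rat_check(x$den * dy)
  .rat_check(x$num * dy + y$num * dx)
  rational(x$num * dy + y$num * dx, x$den * dy)
}

#' @rdname rational
#' @export
rational_mul <- function(x, y) {
  x <- as_rational(x); y <- as_rational(y)
  # cross-reduce first to delay overflow
  g1 <- .gcd(abs(x$num), y$den); g1[g1 == 0] <- 1
  g2 <- .gcd(abs(y$num), x$den); g2[g2 == 0] <- 1
  .rat_check((x$num / g1) * (y$num / g2))
  rational((x$num / g1) * (y$num / g2), (x$den / g2) * (y$den / g1))
}

#' @rdname rational
#' @export
rational_div <- function(x, y) {
  y <- as_rational(y)
  if (any(y$num == 0)) stop("division by zero rational")
  rational_mul(x, structure(list(num = y$den * sign(y$num), den = abs(y$num)),
                            class = "rational"))
}

#' @rdname rational
#' @export
as_rational <- function(x) {
  if (inherits(x, "rational")) x else rational(x, 1)
}

#' @rdname rational
#' @export
rational_sum <- function(x) {
  out <- rational(0)
  for (i in seq_along(x$num))
    out <- rational_add(out, rational(x$num[i], x$den[i]))
  out
}

#' @export
as.double.rational <- function(x, ...) x$num / x$den

#' @export
format.rational <- function(x, ...) {
  ifelse(x$den == 1, sprintf("%.0f", x$num),
         sprintf("%.0f/%.0f", x$num, x$den))
}

#' @export
print.rational <- function(x, ...) {
  cat(format(x), sep = " ")
  cat("\n")
  invisible(x)
}

#' @export
`==.rational` <- function(e1, e2) {
  e1 <- as_rational(e1); e2 <- as_rational(e2)
  e1$num == e2$num & e1$den == e2$den
}
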