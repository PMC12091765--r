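# Exact rationals with big-integer numerators and factored denominators.
#
# A value is list(s, num, dp, de): sign in {-1, 0, 1}, |numerator| as a bigint
# limb vector, and the denominator as parallel vectors of primes (dp) and
# positive exponents (de). The denominator is always a product of small primes
# because divisions only ever come from integral-average operators dividing by
# monomial exponents; numerators, by contrast, can exceed 2^53 (running common
# denominators of the augmented index on the larger drugs reach ~1e36), which
# is why the numerator is a bignum. Canonical form: numerator coprime to every
# denominator prime, so equality is structural.

factor_num <- function(n) {
  stopifnot(n >= 1, n == floor(n), n < 2^53)
  p <- integer(0); e <- integer(0)
  d <- 2
  while (d * d <= n) {
    if (n %% d == 0) {
      k <- 0L
      while (n %% d == 0) { n <- n / d; k <- k + 1L }
      p <- c(p, as.integer(d)); e <- c(e, k)
    }
    d <- d + if (d == 2) 1 else 2
  }
  if (n > 1) { p <- c(p, as.integer(n)); e <- c(e, 1L) }
  list(p = p, e = e)
}

bi_mul_prime_pow <- function(a, p, e) {
  while (e > 0L) {
    chunk <- min(e, max(1L, floor(52 * log(2) / log(p))))
    a <- bi_mul_num(a, p^chunk)
    e <- e - chunk
  }
  a
}

# floor(a / p^e); sequential flooring composes correctly for the final floor
bi_div_prime_pow <- function(a, p, e) {
  while (e > 0L) {
    chunk <- min(e, max(1L, floor(log(9e8) / log(p))))
    a <- bi_divmod_num(a, p^chunk)$q
    e <- e - chunk
  }
  a
}

#' Exact rational arithmetic
#'
#' A small exact-rational layer used for all index and polynomial
#' coefficients: values are big-integer numerators over denominators kept as
#' products of small primes, so arithmetic is exact at any magnitude and
#' equality is structural. \code{xr_from_int} and \code{xr_frac} construct
#' values; \code{xr_add}, \code{xr_sub}, \code{xr_mul}, \code{xr_div_int},
#' \code{xr_scale_int} and \code{xr_pow} combine them; \code{xr_eq} tests
#' exact equality; \code{xr_to_num} converts to double and
#' \code{xr_round_num} / \code{xr_format} round half-up at a fixed number of
#' decimals, exactly.
#'
#' @param n,d integer numerator and denominator (magnitude below 2^53).
#' @param a,b \code{xrat} values.
#' @param k an integer (scale, divide or exponentiate by).
#' @param digits number of decimals for rounding/formatting.
#' @return An \code{xrat}, except \code{xr_eq} (logical), \code{xr_to_num}
#'   and \code{xr_round_num} (numeric), and \code{xr_format} (character).
#' @name exact-rationals
NULL

#' @rdname exact-rationals
#' @export
xr_zero <- function() structure(list(s = 0L, num = bi_zero(),
                                     dp = integer(0), de = integer(0)),
                                class = "xrat")

# cancel numerator against denominator primes and normalise zero
xr_canon <- function(s, num, dp, de) {
  if (bi_is_zero(num)) return(xr_zero())
  keep <- logical(length(dp))
  for (k in seq_along(dp)) {
    while (de[k] > 0L) {
      dm <- bi_divmod_num(num, dp[k])
      if (dm$r != 0) break
      num <- dm$q
      de[k] <- de[k] - 1L
    }
    keep[k] <- de[k] > 0L
  }
  ord <- order(dp[keep])
  structure(list(s = as.integer(s), num = num,
                 dp = dp[keep][ord], de = de[keep][ord]),
            class = "xrat")
}

#' @rdname exact-rationals
#' @export
xr_from_int <- function(n) {
  stopifnot(length(n) == 1L, n == floor(n), abs(n) < 2^53)
  if (n == 0) return(xr_zero())
  structure(list(s = if (n > 0) 1L else -1L, num = bi_from_num(abs(n)),
                 dp = integer(0), de = integer(0)), class = "xrat")
}

# n / d for plain integers, |n| < 2^53, 0 < d < 2^53
#' @rdname exact-rationals
#' @export
xr_frac <- function(n, d) xr_div_int(xr_from_int(n), d)

#' @rdname exact-rationals
#' @export
xr_is_zero <- function(a) a$s == 0L

#' @rdname exact-rationals
#' @export
xr_neg <- function(a) {
  a$s <- -a$s
  a
}

.xr_den_union <- function(a, b) {
  dp <- sort(unique(c(a$dp, b$dp)))
  ea <- integer(length(dp)); eb <- integer(length(dp))
  ea[match(a$dp, dp)] <- a$de
  eb[match(b$dp, dp)] <- b$de
  list(dp = dp, emax = pmax(ea, eb), ea = ea, eb = eb)
}

#' @rdname exact-rationals
#' @export
xr_add <- function(a, b) {
  if (xr_is_zero(a)) return(b)
  if (xr_is_zero(b)) return(a)
  u <- .xr_den_union(a, b)
  na <- a$num; nb <- b$num
  for (k in seq_along(u$dp)) {
    if (u$emax[k] > u$ea[k]) na <- bi_mul_prime_pow(na, u$dp[k], u$emax[k] - u$ea[k])
    if (u$emax[k] > u$eb[k]) nb <- bi_mul_prime_pow(nb, u$dp[k], u$emax[k] - u$eb[k])
  }
  if (a$s == b$s) {
    xr_canon(a$s, bi_add(na, nb), u$dp, u$emax)
  } else {
    cmp <- bi_cmp(na, nb)
    if (cmp == 0L) return(xr_zero())
    if (cmp > 0L) xr_canon(a$s, bi_sub(na, nb), u$dp, u$emax)
    else          xr_canon(b$s, bi_sub(nb, na), u$dp, u$emax)
  }
}

#' @rdname exact-rationals
#' @export
xr_sub <- function(a, b) xr_add(a, xr_neg(b))

#' @rdname exact-rationals
#' @export
xr_mul <- function(a, b) {
  if (xr_is_zero(a) || xr_is_zero(b)) return(xr_zero())
  dp <- sort(unique(c(a$dp, b$dp)))
  de <- integer(length(dp))
  de[match(a$dp, dp)] <- de[match(a$dp, dp)] + a$de
  de[match(b$dp, dp)] <- de[match(b$dp, dp)] + b$de
  xr_canon(a$s * b$s, bi_mul(a$num, b$num), dp, de)
}

# multiply by a plain integer (|k| < 2^53)
#' @rdname exact-rationals
#' @export
xr_scale_int <- function(a, k) xr_mul(a, xr_from_int(k))

# divide by a plain non-zero integer
#' @rdname exact-rationals
#' @export
xr_div_int <- function(a, k) {
  stopifnot(k != 0, k == floor(k), abs(k) < 2^53)
  if (xr_is_zero(a)) return(a)
  f <- factor_num(abs(k))
  dp <- sort(unique(c(a$dp, f$p)))
  de <- integer(length(dp))
  de[match(a$dp, dp)] <- a$de
  de[match(f$p, dp)] <- de[match(f$p, dp)] + f$e
  xr_canon(a$s * sign(k), a$num, dp, de)
}

#' @rdname exact-rationals
#' @export
xr_pow <- function(a, k) {
  stopifnot(k >= 0, k == floor(k))
  out <- xr_from_int(1)
  while (k > 0) {
    out <- xr_mul(out, a)
    k <- k - 1
  }
  out
}

#' @rdname exact-rationals
#' @export
xr_eq <- function(a, b) {
  a$s == b$s && bi_cmp(a$num, b$num) == 0L &&
    identical(as.integer(a$dp), as.integer(b$dp)) &&
    identical(as.integer(a$de), as.integer(b$de))
}

xr_is_int <- function(a) length(a$dp) == 0L

#' @rdname exact-rationals
#' @export
xr_to_num <- function(a) {
  if (xr_is_zero(a)) return(0)
  x <- a$s * bi_to_num(a$num)
  for (k in seq_along(a$dp)) x <- x / a$dp[k]^a$de[k]
  x
}

# exact half-up (away from zero) rounding to `digits` decimals, as a double
#' @rdname exact-rationals
#' @export
xr_round_num <- function(a, digits = 4L) {
  as.numeric(xr_format(a, digits))
}

# exact half-up decimal rendering
#' @rdname exact-rationals
#' @export
xr_format <- function(a, digits = 4L) {
  stopifnot(digits >= 0L)
  if (xr_is_zero(a)) {
    return(if (digits > 0L) paste0("0.", strrep("0", digits)) else "0")
  }
  scaled <- bi_mul_prime_pow(bi_mul_prime_pow(a$num, 2L, digits + 1L),
                             5L, digits + 1L)
  for (k in seq_along(a$dp)) scaled <- bi_div_prime_pow(scaled, a$dp[k], a$de[k])
  last <- bi_divmod_num(scaled, 10)
  q <- last$q
  if (last$r >= 5) q <- bi_add(q, bi_from_num(1))
  s <- bi_to_str(q)
  if (digits > 0L) {
    if (nchar(s) <= digits) s <- paste0(strrep("0", digits + 1L - nchar(s)), s)
    s <- paste0(substr(s, 1L, nchar(s) - digits), ".",
                substr(s, nchar(s) - digits + 1L, nchar(s)))
  }
  paste0(if (a$s < 0L) "-" else "", s)
}

#' @export
print.xrat <- function(x, ...) {
  if (xr_is_zero(x)) {
    cat("0\n")
  } else {
    den <- prod(as.numeric(x$dp)^x$de)
    cat(if (x$s < 0) "-" else "", bi_to_str(x$num),
        if (den != 1) paste0("/", format(den, scientific = FALSE)) else "",
        "\n", sep = "")
  }
  invisible(x)
}
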