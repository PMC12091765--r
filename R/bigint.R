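# Minimal non-negative big-integer arithmetic on base-1e7 limb vectors.
# Limbs are numeric, little-endian, each in [0, 1e7); the empty vector is zero.
# Intermediates never exceed 2^53, so plain doubles are exact throughout.

BI_BASE <- 1e7

bi_zero <- function() numeric(0)

bi_is_zero <- function(a) length(a) == 0L

bi_strip <- function(a) {
  n <- length(a)
  while (n > 0L && a[n] == 0) n <- n - 1L
  a[seq_len(n)]
}

# carry-propagate a limb vector whose entries may be >= BI_BASE (but < 2^53)
bi_norm <- function(a) {
  repeat {
    carry <- floor(a / BI_BASE)
    if (all(carry == 0)) break
    a <- a - carry * BI_BASE
    a <- c(a, 0) + c(0, carry)
  }
  bi_strip(a)
}

bi_from_num <- function(x) {
  stopifnot(is.numeric(x), length(x) == 1L, x >= 0, x == floor(x), x < 2^53)
  limbs <- numeric(0)
  while (x > 0) {
    limbs <- c(limbs, x %% BI_BASE)
    x <- floor(x / BI_BASE)
  }
  limbs
}

bi_to_num <- function(a) {
  if (bi_is_zero(a)) return(0)
  sum(a * BI_BASE^(seq_along(a) - 1))
}

bi_to_str <- function(a) {
  if (bi_is_zero(a)) return("0")
  n <- length(a)
  head <- format(a[n], scientific = FALSE)
  rest <- if (n > 1L) sprintf("%07d", rev(a[-n])) else character(0)
  paste0(head, paste(rest, collapse = ""))
}

bi_cmp <- function(a, b) {
  if (length(a) != length(b)) return(sign(length(a) - length(b)))
  if (length(a) == 0L) return(0L)
  for (k in rev(seq_along(a))) {
    if (a[k] != b[k]) return(if (a[k] > b[k]) 1L else -1L)
  }
  0L
}

bi_add <- function(a, b) {
  n <- max(length(a), length(b))
  bi_norm(c(a, numeric(n - length(a))) + c(b, numeric(n - length(b))))
}

# a - b, requires a >= b
bi_sub <- function(a, b) {
  stopifnot(bi_cmp(a, b) >= 0L)
  n <- length(a)
  b <- c(b, numeric(n - length(b)))
  out <- numeric(n)
  borrow <- 0
  for (k in seq_len(n)) {
    d <- a[k] - b[k] - borrow
    if (d < 0) {
      d <- d + BI_BASE
      borrow <- 1
    } else borrow <- 0
    out[k] <- d
  }
  bi_strip(out)
}

# multiply by a plain non-negative double; chunked so limb products stay exact
bi_mul_num <- function(a, m) {
  stopifnot(m >= 0, m == floor(m), m < 2^53)
  if (m == 0 || bi_is_zero(a)) return(bi_zero())
  out <- bi_zero()
  shift <- 0L
  while (m > 0) {
    digit <- m %% BI_BASE
    m <- floor(m / BI_BASE)
    if (digit > 0) {
      part <- bi_norm(c(numeric(shift), a * digit))
      out <- bi_add(out, part)
    }
    shift <- shift + 1L
  }
  out
}

bi_mul <- function(a, b) {
  if (bi_is_zero(a) || bi_is_zero(b)) return(bi_zero())
  out <- bi_zero()
  for (k in seq_along(b)) {
    if (b[k] == 0) next
    out <- bi_add(out, bi_norm(c(numeric(k - 1L), a * b[k])))
  }
  out
}

# quotient and remainder for a small divisor d (d < 2^26 keeps r*BASE exact;
# all divisors used in the package are primes or prime powers below 1e7)
bi_divmod_num <- function(a, d) {
  stopifnot(d > 0, d == floor(d), d < 9e8)
  if (bi_is_zero(a)) return(list(q = bi_zero(), r = 0))
  q <- numeric(length(a))
  r <- 0
  for (k in rev(seq_along(a))) {
    t <- r * BI_BASE + a[k]
    q[k] <- floor(t / d)
    r <- t - q[k] * d
  }
  list(q = bi_strip(q), r = r)
}
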