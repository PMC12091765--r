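# Sparse bivariate Laurent polynomials with exact rational coefficients, and
# the operator calculus used to derive topological indices from the NEC
# polynomial: the degree operators d_x, d_y (x d/dx, y d/dy), the
# integral-average operators S_x, S_y (divide each coefficient by the
# exponent in that variable), the exponent shift Psi_k (multiply by x^k,
# k possibly negative) and the diagonalisation J (substitute y = x).

#' Construct a sparse bivariate polynomial
#'
#' Builds an exact-coefficient polynomial \eqn{\sum c_{ij} x^i y^j}. Exponents
#' are integers and may be negative (Laurent monomials arise from the shift
#' operator); coefficients may be given as integer-valued numerics or as a
#' list of exact rationals. Terms with equal exponent pairs are merged and
#' zero coefficients dropped.
#'
#' @param ex,ey integer exponent vectors for the two variables.
#' @param coef numeric vector of integer coefficients, or a list of exact
#'   rational coefficients of the same length.
#' @return An object of class \code{bvpoly}.
#' @export
bvpoly <- function(ex = integer(0), ey = integer(0), coef = numeric(0)) {
  stopifnot(length(ex) == length(ey), length(ex) == length(coef))
  stopifnot(all(ex == floor(ex)), all(ey == floor(ey)))
  if (!is.list(coef)) coef <- lapply(coef, xr_from_int)
  bp_canon(as.integer(ex), as.integer(ey), coef)
}

bp_canon <- function(ex, ey, coef) {
  if (length(ex)) {
    key <- paste(ex, ey)
    if (anyDuplicated(key)) {
      idx <- split(seq_along(key), key)
      ex2 <- integer(0); ey2 <- integer(0); c2 <- list()
      for (ii in idx) {
        ex2 <- c(ex2, ex[ii[1L]]); ey2 <- c(ey2, ey[ii[1L]])
        c2 <- c(c2, list(Reduce(xr_add, coef[ii])))
      }
      ex <- ex2; ey <- ey2; coef <- c2
    }
    keep <- !vapply(coef, xr_is_zero, logical(1))
    ex <- ex[keep]; ey <- ey[keep]; coef <- coef[keep]
    ord <- order(ex, ey)
    ex <- ex[ord]; ey <- ey[ord]; coef <- coef[ord]
  }
  structure(list(ex = ex, ey = ey, coef = coef), class = "bvpoly")
}

bp_is_zero <- function(p) length(p$ex) == 0L

bp_n_terms <- function(p) length(p$ex)

bp_add <- function(p, q) {
  bp_canon(c(p$ex, q$ex), c(p$ey, q$ey), c(p$coef, q$coef))
}

bp_scale <- function(p, k) {
  bp_canon(p$ex, p$ey, lapply(p$coef, xr_scale_int, k = k))
}

bp_equal <- function(p, q) {
  length(p$ex) == length(q$ex) &&
    identical(p$ex, q$ex) && identical(p$ey, q$ey) &&
    all(mapply(xr_eq, p$coef, q$coef))
}

#' Degree operators
#'
#' \code{op_dx} maps each monomial \eqn{c x^i y^j} to \eqn{c\,i\, x^i y^j}
#' (that is, \eqn{x\,\partial/\partial x}); \code{op_dy} acts on the second
#' exponent.
#'
#' @param p a \code{bvpoly}.
#' @return A \code{bvpoly}.
#' @export
op_dx <- function(p) {
  bp_canon(p$ex, p$ey, mapply(function(cf, i) xr_scale_int(cf, i),
                              p$coef, p$ex, SIMPLIFY = FALSE))
}

#' @rdname op_dx
#' @export
op_dy <- function(p) {
  bp_canon(p$ex, p$ey, mapply(function(cf, j) xr_scale_int(cf, j),
                              p$coef, p$ey, SIMPLIFY = FALSE))
}

#' Integral-average operators
#'
#' \code{op_sx} maps \eqn{c x^i y^j} to \eqn{(c/i) x^i y^j}, the monomial
#' action of \eqn{\int_0^x h(t, y)/t \, dt}; \code{op_sy} acts on the second
#' variable. A monomial with zero exponent in the integrated variable has no
#' finite image and raises an error.
#'
#' @param p a \code{bvpoly}.
#' @return A \code{bvpoly}.
#' @export
op_sx <- function(p) {
  if (any(p$ex == 0L)) {
    stop("op_sx undefined: monomial with zero x-exponent", call. = FALSE)
  }
  bp_canon(p$ex, p$ey, mapply(function(cf, i) xr_div_int(cf, i),
                              p$coef, p$ex, SIMPLIFY = FALSE))
}

#' @rdname op_sx
#' @export
op_sy <- function(p) {
  if (any(p$ey == 0L)) {
    stop("op_sy undefined: monomial with zero y-exponent", call. = FALSE)
  }
  bp_canon(p$ex, p$ey, mapply(function(cf, j) xr_div_int(cf, j),
                              p$coef, p$ey, SIMPLIFY = FALSE))
}

#' Diagonalisation operator
#'
#' \code{op_j} substitutes \eqn{y = x}: each monomial \eqn{c x^i y^j} becomes
#' \eqn{c x^{i+j}}, and coefficients of colliding exponents are summed
#' exactly.
#'
#' @param p a \code{bvpoly}.
#' @return A univariate \code{bvpoly} (all y-exponents zero).
#' @export
op_j <- function(p) {
  bp_canon(p$ex + p$ey, rep(0L, length(p$ex)), p$coef)
}

#' Exponent-shift operator
#'
#' Multiplies by \eqn{x^k}: every first-variable exponent is shifted by
#' \code{k}, which may be negative (producing Laurent monomials).
#'
#' @param p a \code{bvpoly}.
#' @param k integer shift.
#' @return A \code{bvpoly}.
#' @export
op_psi <- function(p, k) {
  stopifnot(length(k) == 1L, k == floor(k))
  bp_canon(p$ex + as.integer(k), p$ey, p$coef)
}

#' Evaluate a polynomial at (1, 1)
#'
#' Returns the exact coefficient sum, the final step of every operator-route
#' index derivation.
#'
#' @param p a \code{bvpoly}.
#' @return An exact rational (class \code{xrat}).
#' @export
bp_eval_one <- function(p) {
  if (bp_is_zero(p)) return(xr_zero())
  Reduce(xr_add, p$coef)
}

#' @export
print.bvpoly <- function(x, ...) {
  if (bp_is_zero(x)) {
    cat("<bvpoly> 0\n")
    return(invisible(x))
  }
  mono <- function(cf, i, j) {
    cs <- if (xr_is_int(cf) && bi_cmp(cf$num, bi_from_num(1)) == 0L) {
      if (cf$s < 0) "-" else ""
    } else {
      paste0(if (cf$s < 0) "-" else "", bi_to_str(cf$num),
             if (length(cf$dp)) paste0("/", format(prod(as.numeric(cf$dp)^cf$de),
                                                   scientific = FALSE)) else "")
    }
    xs <- if (i == 0L) "" else if (i == 1L) "x" else sprintf("x^%d", i)
    ys <- if (j == 0L) "" else if (j == 1L) "y" else sprintf("y^%d", j)
    body <- paste0(xs, ys)
    if (body == "") body <- if (cs %in% c("", "-")) "1" else ""
    paste0(cs, body)
  }
  terms <- mapply(mono, x$coef, x$ex, x$ey)
  cat("<bvpoly> ", paste(terms, collapse = " + "), "\n", sep = "")
  invisible(x)
}

#' Read and write polynomials as TSV
#'
#' Serialises one monomial per row with columns \code{exp_x}, \code{exp_y},
#' \code{coefficient}. Coefficients are written as decimal integers or
#' \code{num/den} fractions and parsed back exactly.
#'
#' @param p a \code{bvpoly}.
#' @param path file path.
#' @return \code{read_bvpoly_tsv} returns a \code{bvpoly};
#'   \code{write_bvpoly_tsv} returns \code{path} invisibly.
#' @export
write_bvpoly_tsv <- function(p, path) {
  fmt <- vapply(p$coef, function(cf) {
    den <- if (length(cf$dp)) format(prod(as.numeric(cf$dp)^cf$de),
                                     scientific = FALSE) else ""
    paste0(if (cf$s < 0) "-" else "", bi_to_str(cf$num),
           if (nzchar(den)) paste0("/", den) else "")
  }, character(1))
  utils::write.table(
    data.frame(exp_x = p$ex, exp_y = p$ey, coefficient = fmt),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bvpoly_tsv
#' @export
read_bvpoly_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("integer", "integer", "character"))
  coef <- lapply(df$coefficient, function(s) {
    parts <- strsplit(s, "/", fixed = TRUE)[[1]]
    num <- as.numeric(parts[1])
    if (length(parts) == 2L) xr_frac(num, as.numeric(parts[2])) else xr_from_int(num)
  })
  bp_canon(df$exp_x, df$exp_y, coef)
}
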