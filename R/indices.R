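# The eight neighborhood-eccentricity indices. Each index has two exact
# computation routes that must agree monomial-for-monomial as rationals:
#
#   direct    - sum over edge classes (i, j) of m_ij * f(i, j)
#   operators - an operator composition applied to the NEC polynomial,
#               evaluated at (1, 1)
#
# index      f(i, j)                 operator route
# NE1        i + j                   (d_x + d_y)
# NE2        i * j                   d_x d_y
# NFE        i^2 + j^2               d_x^2 + d_y^2
# NRE        i j (i + j)             d_x d_y (d_x + d_y)
# NSDdegE    i/j + j/i               d_x S_y + S_x d_y
# NISIE      i j / (i + j)           S_x J d_x d_y
# NHE        2 / (i + j)             2 S_x J
# NAE        (i j / (i + j - 2))^3   S_x^3 Psi_-2 J d_x^3 d_y^3

INDEX_NAMES <- c("NE1", "NE2", "NFE", "NRE", "NSDdegE", "NISIE", "NHE", "NAE")

# printed decimal places per index (integers for the first four)
INDEX_DIGITS <- c(NE1 = 0L, NE2 = 0L, NFE = 0L, NRE = 0L,
                  NSDdegE = 3L, NISIE = 4L, NHE = 4L, NAE = 3L)

.index_term <- function(which, i, j) {
  switch(which,
    NE1 = xr_from_int(i + j),
    NE2 = xr_from_int(i * j),
    NFE = xr_from_int(i^2 + j^2),
    NRE = xr_from_int(i * j * (i + j)),
    NSDdegE = xr_add(xr_frac(i, j), xr_frac(j, i)),
    NISIE = xr_frac(i * j, i + j),
    NHE = xr_frac(2, i + j),
    NAE = {
      if (i + j == 2) {
        stop("NAE undefined: edge class with i + j = 2", call. = FALSE)
      }
      xr_pow(xr_frac(i * j, i + j - 2), 3L)
    },
    stop("unknown index: ", which, call. = FALSE))
}

#' Direct edge-sum route for one index
#'
#' Computes \eqn{\sum_{(i,j)} m_{ij} f(i, j)} in exact rational arithmetic,
#' with \eqn{f} the defining edge term of the requested index (see the table
#' in the package vignette).
#'
#' @param p an \code{edge_partition}.
#' @param which index name, one of \code{INDEX_NAMES}.
#' @return An exact rational (\code{xrat}).
#' @export
index_direct <- function(p, which = INDEX_NAMES) {
  which <- match.arg(which)
  stopifnot(inherits(p, "edge_partition"))
  acc <- xr_zero()
  for (k in seq_len(nrow(p))) {
    acc <- xr_add(acc, xr_scale_int(.index_term(which, p$i[k], p$j[k]), p$m[k]))
  }
  acc
}

#' Operator-calculus route for one index
#'
#' Applies the index's operator composition to the NEC polynomial and
#' evaluates at (1, 1). All steps are exact.
#'
#' @param nec a \code{bvpoly}, the NEC polynomial of a graph.
#' @param which index name.
#' @return An exact rational (\code{xrat}).
#' @export
index_via_operators <- function(nec, which = INDEX_NAMES) {
  which <- match.arg(which)
  stopifnot(inherits(nec, "bvpoly"))
  p <- switch(which,
    NE1 = bp_add(op_dx(nec), op_dy(nec)),
    NE2 = op_dx(op_dy(nec)),
    NFE = bp_add(op_dx(op_dx(nec)), op_dy(op_dy(nec))),
    NRE = {
      s <- bp_add(op_dx(nec), op_dy(nec))
      op_dx(op_dy(s))
    },
    NSDdegE = bp_add(op_dx(op_sy(nec)), op_sx(op_dy(nec))),
    NISIE = op_sx(op_j(op_dx(op_dy(nec)))),
    NHE = bp_scale(op_sx(op_j(nec)), 2),
    NAE = {
      q <- op_psi(op_j(op_dx(op_dx(op_dx(op_dy(op_dy(op_dy(nec))))))), -2L)
      if (any(q$ex == 0L)) {
        stop("NAE undefined: edge class with i + j = 2", call. = FALSE)
      }
      op_sx(op_sx(op_sx(q)))
    })
  bp_eval_one(p)
}

#' Compute all eight indices for a graph or partition
#'
#' Runs the full pipeline (eccentricities, neighborhood eccentricities, edge
#' partition) and evaluates every index by both the direct edge-sum and the
#' operator route, stopping if the two exact results ever disagree.
#'
#' @param g a \code{molgraph}, or an \code{edge_partition} directly.
#' @param exact return the exact rationals instead of doubles.
#' @return A named numeric vector of the eight index values (or a named list
#'   of \code{xrat} when \code{exact = TRUE}).
#' @export
compute_all_indices <- function(g, exact = FALSE) {
  p <- if (inherits(g, "edge_partition")) g else edge_partition(g)
  nec <- nec_polynomial(p)
  vals <- lapply(INDEX_NAMES, function(w) {
    a <- index_direct(p, w)
    b <- index_via_operators(nec, w)
    if (!xr_eq(a, b)) {
      stop("internal consistency failure: direct and operator routes disagree for ",
           w, call. = FALSE)
    }
    a
  })
  names(vals) <- INDEX_NAMES
  if (exact) return(vals)
  vapply(vals, xr_to_num, numeric(1))
}

#' Index table for a set of graphs or partitions
#'
#' One row per input, eight index columns, values rounded half-up at the
#' reporting precision used throughout (integers for NE1, NE2, NFE, NRE;
#' 3 decimals for NSDdegE and NAE; 4 for NISIE and NHE).
#'
#' @param inputs named list of \code{molgraph} or \code{edge_partition}
#'   objects.
#' @return A data frame with row names the input names.
#' @export
index_table <- function(inputs) {
  stopifnot(is.list(inputs), !is.null(names(inputs)))
  rows <- lapply(inputs, function(x) {
    ex <- compute_all_indices(x, exact = TRUE)
    vapply(INDEX_NAMES, function(w) xr_round_num(ex[[w]], INDEX_DIGITS[[w]]),
           numeric(1))
  })
  df <- as.data.frame(do.call(rbind, rows))
  names(df) <- INDEX_NAMES
  df
}

#' Write an index table as TSV
#'
#' @param tab a data frame from \code{index_table}.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
write_index_table <- function(tab, path) {
  utils::write.table(cbind(graph = rownames(tab), tab), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
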