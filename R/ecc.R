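# Distances, eccentricities, neighborhood eccentricities, the edge partition
# by endpoint labels, and the EC/NEC generating polynomials.
#
# For a connected graph, the eccentricity of a vertex is its maximum graph
# distance to any vertex; the neighborhood eccentricity mu(u) is the sum of
# the eccentricities of the neighbors of u. Edges are then partitioned by the
# unordered pair of endpoint mu values, and the NEC polynomial is the
# generating polynomial of that partition: the coefficient of x^i y^j counts
# the edges whose endpoints carry labels (i, j).

#' All-pairs shortest-path distances
#'
#' Breadth-first distances between every vertex pair of a connected molecular
#' graph.
#'
#' @param g a \code{molgraph}.
#' @return An integer distance matrix with vertex labels as dimnames;
#'   symmetric, zero diagonal.
#' @export
all_pairs_distances <- function(g) {
  d <- igraph::distances(as_igraph(g), algorithm = "unweighted")
  if (any(!is.finite(d))) stop("graph is disconnected", call. = FALSE)
  storage.mode(d) <- "integer"
  d[g$vertices, g$vertices, drop = FALSE]
}

#' Vertex eccentricities
#'
#' @param g a \code{molgraph}.
#' @return Named integer vector: for each vertex the maximum distance to any
#'   other vertex.
#' @export
eccentricities <- function(g) {
  d <- all_pairs_distances(g)
  apply(d, 1L, max)
}

#' Neighborhood eccentricities
#'
#' For each vertex \code{u}, the sum of the eccentricities of the vertices
#' adjacent to \code{u}.
#'
#' @param g a \code{molgraph}.
#' @return Named integer vector of \eqn{\mu} values.
#' @export
neighborhood_eccentricities <- function(g) {
  eps <- eccentricities(g)
  mu <- stats::setNames(integer(length(g$vertices)), g$vertices)
  for (k in seq_len(nrow(g$edges))) {
    a <- g$edges[k, 1]; b <- g$edges[k, 2]
    mu[a] <- mu[a] + eps[b]
    mu[b] <- mu[b] + eps[a]
  }
  mu
}

#' Build an edge partition table
#'
#' @param i,j positive integer endpoint labels (need not be ordered).
#' @param m positive integer multiplicities.
#' @return A data frame of class \code{edge_partition} with columns \code{i},
#'   \code{j} (normalised so \code{i <= j}) and \code{m}; duplicate keys are
#'   merged.
#' @export
edge_partition_table <- function(i, j, m = rep(1L, length(i))) {
  stopifnot(length(i) == length(j), length(i) == length(m),
            all(i >= 1), all(j >= 1), all(m >= 1),
            all(i == floor(i)), all(j == floor(j)), all(m == floor(m)))
  if (length(i) == 0L) {
    out <- data.frame(i = integer(0), j = integer(0), m = integer(0))
    class(out) <- c("edge_partition", "data.frame")
    return(out)
  }
  lo <- as.integer(pmin(i, j)); hi <- as.integer(pmax(i, j))
  agg <- stats::aggregate(list(m = as.integer(m)), list(i = lo, j = hi), sum)
  agg <- agg[order(agg$i, agg$j), , drop = FALSE]
  rownames(agg) <- NULL
  class(agg) <- c("edge_partition", "data.frame")
  agg
}

partition_size <- function(p) sum(p$m)

#' Edge partition by neighborhood eccentricity
#'
#' Groups the edges of \code{g} by the unordered pair of endpoint
#' \eqn{\mu} values.
#'
#' @param g a \code{molgraph}.
#' @return An \code{edge_partition} whose multiplicities sum to the edge
#'   count of \code{g}.
#' @export
edge_partition <- function(g) {
  mu <- neighborhood_eccentricities(g)
  edge_partition_table(mu[g$edges[, 1]], mu[g$edges[, 2]])
}

#' NEC and EC polynomials
#'
#' \code{nec_polynomial} turns an edge partition (by neighborhood
#' eccentricity, or a \code{molgraph} which is partitioned first) into its
#' generating polynomial \eqn{\sum_{i \le j} m_{ij} x^i y^j}.
#' \code{ec_polynomial} is the same construction with plain vertex
#' eccentricities in place of \eqn{\mu}. For both, evaluation at (1, 1)
#' returns the edge count.
#'
#' @param p an \code{edge_partition} or a \code{molgraph}.
#' @return A \code{bvpoly}.
#' @export
nec_polynomial <- function(p) {
  if (inherits(p, "molgraph")) p <- edge_partition(p)
  stopifnot(inherits(p, "edge_partition"))
  bvpoly(p$i, p$j, p$m)
}

#' @rdname nec_polynomial
#' @param g a \code{molgraph}.
#' @export
ec_polynomial <- function(g) {
  eps <- eccentricities(g)
  p <- edge_partition_table(eps[g$edges[, 1]], eps[g$edges[, 2]])
  bvpoly(p$i, p$j, p$m)
}

#' Read and write edge partitions as TSV
#'
#' Columns \code{i}, \code{j}, \code{multiplicity}.
#'
#' @param p an \code{edge_partition}.
#' @param path file path.
#' @return \code{read_partition_tsv} returns an \code{edge_partition};
#'   \code{write_partition_tsv} returns \code{path} invisibly.
#' @export
write_partition_tsv <- function(p, path) {
  utils::write.table(data.frame(i = p$i, j = p$j, multiplicity = p$m),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_partition_tsv
#' @export
read_partition_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  edge_partition_table(df$i, df$j, df$multiplicity)
}
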