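# Molecular graphs: simple connected undirected graphs on opaque vertex
# labels, the hydrogen-depleted heavy-atom skeletons of the drugs. Bond order
# and element identity are deliberately ignored; every covalent bond between
# heavy atoms is one edge.

#' Construct a molecular graph
#'
#' @param edges two-column character matrix (or data frame) of vertex label
#'   pairs, one bond per row.
#' @param vertices optional character vector of vertex labels; defaults to the
#'   labels appearing in \code{edges}. Extra isolated vertices are rejected
#'   because the graph must be connected.
#' @return An object of class \code{molgraph} with components \code{vertices}
#'   (character) and \code{edges} (two-column character matrix).
#' @details Self-loops and duplicate edges (compared as unordered pairs) are
#'   format errors; a disconnected vertex set is a validation error that names
#'   the components.
#' @export
molgraph <- function(edges, vertices = NULL) {
  edges <- as.matrix(edges)
  if (length(edges) == 0L) stop("molgraph needs at least one edge", call. = FALSE)
  if (ncol(edges) != 2L) stop("edges must have two columns", call. = FALSE)
  storage.mode(edges) <- "character"
  if (any(edges[, 1] == edges[, 2])) {
    stop("self-loop: ", paste(unique(edges[edges[, 1] == edges[, 2], 1]),
                              collapse = ", "), call. = FALSE)
  }
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  if (anyDuplicated(key)) {
    stop("duplicate edge: ", paste(unique(key[duplicated(key)]), collapse = "; "),
         call. = FALSE)
  }
  seen <- unique(as.vector(t(edges)))
  if (is.null(vertices)) {
    vertices <- seen
  } else {
    vertices <- as.character(vertices)
    if (anyDuplicated(vertices)) stop("duplicate vertex labels", call. = FALSE)
    if (!all(seen %in% vertices)) {
      stop("edge endpoint not declared as vertex: ",
           paste(setdiff(seen, vertices), collapse = ", "), call. = FALSE)
    }
  }
  g <- structure(list(vertices = vertices, edges = edges), class = "molgraph")
  ig <- as_igraph(g)
  if (!igraph::is_connected(ig)) {
    comps <- igraph::components(ig)
    parts <- split(names(comps$membership), comps$membership)
    stop("graph is disconnected; components: ",
         paste(vapply(parts, function(p) paste0("{", paste(p, collapse = ","), "}"),
                      character(1)), collapse = " "), call. = FALSE)
  }
  g
}

as_igraph <- function(g) {
  igraph::graph_from_data_frame(
    data.frame(from = g$edges[, 1], to = g$edges[, 2]),
    directed = FALSE,
    vertices = data.frame(name = g$vertices))
}

#' @export
print.molgraph <- function(x, ...) {
  cat(sprintf("<molgraph> %d vertices, %d edges\n",
              length(x$vertices), nrow(x$edges)))
  invisible(x)
}

n_vertices <- function(g) length(g$vertices)
n_edges <- function(g) nrow(g$edges)

#' Read a molecular graph from an edge-list file
#'
#' One edge per line, two whitespace-separated vertex labels; blank lines and
#' \code{#} comments are ignored. The vertex set is the union of the endpoint
#' labels.
#'
#' @param path file path, or a character vector of lines via \code{text}.
#' @param text optional character vector of lines, used instead of \code{path}.
#' @return A validated \code{molgraph}.
#' @export
read_edge_list <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else {
    if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
    readLines(path, warn = FALSE)
  }
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("edge list is empty", call. = FALSE)
  toks <- strsplit(lines, "[[:space:]]+")
  bad <- lengths(toks) != 2L
  if (any(bad)) {
    stop("malformed edge line (need exactly two labels): ",
         paste(shQuote(lines[bad]), collapse = ", "), call. = FALSE)
  }
  molgraph(do.call(rbind, toks))
}

#' Write a molecular graph as an edge list
#'
#' @param g a \code{molgraph}.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
write_edge_list <- function(g, path) {
  writeLines(paste(g$edges[, 1], g$edges[, 2]), path)
  invisible(path)
}

#' Random connected graph generator
#'
#' Draws a uniformly labelled random tree on \code{n} vertices and adds
#' \code{extra} further non-parallel edges, so the result is simple and
#' connected by construction. Used for property-style checks of the
#' index machinery on graphs that are not molecular.
#'
#' @param n number of vertices (\eqn{\ge 2}).
#' @param extra number of extra edges beyond the spanning tree; capped at the
#'   number of available vertex pairs.
#' @return A \code{molgraph} with vertex labels \code{v1 ... vn}.
#' @export
random_connected_graph <- function(n, extra = 0L) {
  stopifnot(n >= 2)
  labs <- paste0("v", seq_len(n))
  edges <- cbind(labs[1], labs[2])
  if (n > 2) {
    parent <- vapply(3:n, function(k) sample.int(k - 1L, 1L), integer(1))
    edges <- rbind(edges, cbind(labs[parent], labs[3:n]))
  }
  if (extra > 0L && n > 2) {
    all_pairs <- t(combn(labs, 2))
    key <- paste(pmin(all_pairs[, 1], all_pairs[, 2]),
                 pmax(all_pairs[, 1], all_pairs[, 2]))
    used <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    avail <- which(!(key %in% used))
    take <- avail[sample.int(length(avail), min(extra, length(avail)))]
    edges <- rbind(edges, all_pairs[take, , drop = FALSE])
  }
  molgraph(edges)
}

#' Read the heavy-atom skeleton from a MOL/SDF connection table
#'
#' Convenience importer: reads the first molecule of a V2000 MOL/SDF file via
#' ChemmineR, drops hydrogen atoms and bonds to them, and returns the
#' heavy-atom graph with labels \code{<element><index>}.
#'
#' @param path path to a MOL or SDF file.
#' @return A \code{molgraph}.
#' @export
read_mol <- function(path) {
  if (!requireNamespace("ChemmineR", quietly = TRUE)) {
    stop("read_mol requires the ChemmineR package", call. = FALSE)
  }
  sdf <- ChemmineR::read.SDFset(path)[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elem <- sub("_.*$", "", rownames(ab))
  heavy <- elem != "H"
  labs <- paste0(elem, seq_along(elem))
  keep <- heavy[bb[, 1]] & heavy[bb[, 2]]
  molgraph(cbind(labs[bb[keep, 1]], labs[bb[keep, 2]]),
           vertices = labs[heavy])
}
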