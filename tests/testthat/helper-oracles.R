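# independent oracles and tiny graph builders used across tests

# Floyd-Warshall all-pairs distances; deliberately independent of the
# BFS-based implementation under test
fw_distances <- function(g) {
  v <- g$vertices
  n <- length(v)
  d <- matrix(Inf, n, n, dimnames = list(v, v))
  diag(d) <- 0
  for (k in seq_len(nrow(g$edges))) {
    a <- g$edges[k, 1]; b <- g$edges[k, 2]
    d[a, b] <- 1; d[b, a] <- 1
  }
  for (k in v) d <- pmin(d, outer(d[, k], d[k, ], `+`))
  d
}

path_graph <- function(n) {
  labs <- letters[seq_len(n)]
  molgraph(cbind(labs[-n], labs[-1]))
}

cycle_graph <- function(n) {
  labs <- paste0("c", seq_len(n))
  molgraph(cbind(labs, labs[c(2:n, 1)]))
}

# degree of every vertex
vertex_degrees <- function(g) {
  tab <- table(as.vector(g$edges))
  stats::setNames(as.integer(tab), names(tab))[g$vertices]
}

xr_expect_equal <- function(a, b) expect_true(xr_eq(a, b))
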