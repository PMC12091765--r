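# distances, eccentricities, neighborhood eccentricities, partitions and the
# generating polynomials

test_that("distances satisfy metric axioms and match a Floyd-Warshall oracle", {
  p3 <- path_graph(3)
  d <- all_pairs_distances(p3)
  expect_identical(d["a", "c"], 2L)
  expect_identical(d["a", "b"], 1L)
  set.seed(101)
  for (rep in 1:15) {
    g <- random_connected_graph(sample(3:10, 1), extra = sample(0:3, 1))
    d <- all_pairs_distances(g)
    expect_identical(d, t(d))
    expect_true(all(diag(d) == 0L))
    fw <- fw_distances(g)
    expect_equal(unname(d[rownames(fw), colnames(fw)]), unname(fw),
                 ignore_attr = TRUE)
    # edges are exactly the distance-1 pairs
    e1 <- sum(d == 1L) / 2
    expect_identical(as.integer(e1), necindex:::n_edges(g))
  }
})

test_that("eccentricities obey radius/diameter and adjacency bounds", {
  expect_identical(eccentricities(path_graph(3)),
                   c(a = 2L, b = 1L, c = 2L))
  expect_true(all(eccentricities(cycle_graph(4)) == 2L))
  set.seed(55)
  for (rep in 1:15) {
    g <- random_connected_graph(sample(3:12, 1), extra = sample(0:4, 1))
    eps <- eccentricities(g)
    expect_lte(max(eps), 2L * min(eps))           # diameter <= 2 radius
    for (k in seq_len(necindex:::n_edges(g))) {   # adjacent eccentricities
      expect_lte(abs(eps[g$edges[k, 1]] - eps[g$edges[k, 2]]), 1L)
    }
    # equals the column maxima of the independent oracle
    fw <- fw_distances(g)
    expect_equal(unname(eps[rownames(fw)]), unname(apply(fw, 1, max)))
  }
})

test_that("neighborhood eccentricity is the sum of neighbor eccentricities", {
  expect_identical(neighborhood_eccentricities(path_graph(3)),
                   c(a = 1L, b = 4L, c = 1L))
  expect_identical(neighborhood_eccentricities(path_graph(4)),
                   c(a = 2L, b = 5L, c = 5L, d = 2L))
  expect_true(all(neighborhood_eccentricities(cycle_graph(4)) == 4L))
  # degree bounds on random graphs
  set.seed(77)
  for (rep in 1:10) {
    g <- random_connected_graph(sample(4:12, 1), extra = sample(0:4, 1))
    eps <- eccentricities(g)
    mu <- neighborhood_eccentricities(g)
    deg <- vertex_degrees(g)
    expect_true(all(mu >= deg * min(eps)))
    expect_true(all(mu <= deg * max(eps)))
  }
})

test_that("edge partitions are normalised and sum to the edge count", {
  p4 <- edge_partition(path_graph(4))
  expect_identical(as.data.frame(p4),
                   data.frame(i = c(2L, 5L), j = c(5L, 5L), m = c(2L, 1L)))
  c4 <- edge_partition(cycle_graph(4))
  expect_identical(as.data.frame(c4),
                   data.frame(i = 4L, j = 4L, m = 4L))
  set.seed(13)
  for (rep in 1:10) {
    g <- random_connected_graph(sample(3:12, 1), extra = sample(0:4, 1))
    expect_identical(sum(edge_partition(g)$m), necindex:::n_edges(g))
  }
  # cycles are vertex-transitive: single class at (2*ecc, 2*ecc)
  for (n in c(5, 8)) {
    p <- edge_partition(cycle_graph(n))
    expect_identical(nrow(p), 1L)
    expect_identical(p$i, p$j)
  }
})

test_that("reconstructed drug graphs reproduce their printed partitions exactly", {
  fx <- drug_fixtures()
  for (d in c("arbidol", "chloroquine", "hydroxychloroquine", "thalidomide")) {
    expect_identical(as.data.frame(edge_partition(fx[[d]]$graph)),
                     as.data.frame(fx[[d]]$partition),
                     label = d)
  }
})

test_that("NEC and EC polynomials encode the partitions", {
  p <- edge_partition_table(c(2, 5), c(5, 5), c(2, 1))
  nec <- nec_polynomial(p)
  expect_identical(nec$ex, c(2L, 5L))
  expect_identical(nec$ey, c(5L, 5L))
  expect_true(xr_eq(bp_eval_one(nec), xr_from_int(3)))
  # zero polynomial from an empty partition
  expect_true(necindex:::bp_is_zero(
    nec_polynomial(edge_partition_table(integer(0), integer(0), integer(0)))))
  # thalidomide: 12 monomials, coefficient sum 21
  th <- nec_polynomial(drug_fixtures()$thalidomide$partition)
  expect_identical(necindex:::bp_n_terms(th), 12L)
  expect_true(xr_eq(bp_eval_one(th), xr_from_int(21)))
  # EC polynomial: P3 -> 2xy^2, C4 -> 4x^2y^2
  ec3 <- ec_polynomial(path_graph(3))
  expect_identical(ec3$ex, 1L); expect_identical(ec3$ey, 2L)
  expect_true(xr_eq(ec3$coef[[1]], xr_from_int(2)))
  ec4 <- ec_polynomial(cycle_graph(4))
  expect_identical(ec4$ex, 2L); expect_identical(ec4$ey, 2L)
  expect_true(xr_eq(ec4$coef[[1]], xr_from_int(4)))
  # EC coefficient sum equals edge count on a fixture graph
  g <- drug_fixtures()$arbidol$graph
  expect_true(xr_eq(bp_eval_one(ec_polynomial(g)), xr_from_int(31)))
})

test_that("partition TSV serialization round-trips", {
  p <- edge_partition(path_graph(5))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_partition_tsv(p, path)
  expect_identical(as.data.frame(read_partition_tsv(path)), as.data.frame(p))
})
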