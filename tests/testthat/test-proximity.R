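path4 <- as_interactome(rbind(c("A", "B"), c("B", "C"), c("C", "D")))

test_that("drug-disease closest distance matches hand examples", {
  expect_equal(as.numeric(
    closest_distance_drug_disease(path4, c("A", "B"), c("A", "B"))), 0)
  expect_equal(as.numeric(
    closest_distance_drug_disease(path4, "A", c("C", "D"))), 2.5)
  expect_error(closest_distance_drug_disease(path4, character(0), "A"), "empty")
  # disease protein that is itself a target contributes 0
  expect_equal(as.numeric(
    closest_distance_drug_disease(path4, "B", c("B", "D"))), 1)
})

test_that("closest drug-disease distance equals the exhaustive double loop", {
  set.seed(13)
  fx <- random_graph_fixture(30, 0.12)
  for (i in 1:25) {
    X <- random_subset(fx$nodes); Y <- random_subset(fx$nodes)
    want <- finite_mean_oracle(
      vapply(Y, function(y) min(fx$d[X, y]), numeric(1)))
    expect_equal(as.numeric(closest_distance_drug_disease(fx$ia, X, Y)), want)
  }
})

test_that("unreachable disease proteins are skipped and counted", {
  two <- as_interactome(rbind(c("A", "B"), c("X", "Y")))
  v <- closest_distance_drug_disease(two, "A", c("B", "X"))
  expect_equal(as.numeric(v), 1)
  expect_equal(attr(v, "n_skipped"), 1L)
  all_un <- closest_distance_drug_disease(two, "A", c("X", "Y"))
  expect_true(is.na(all_un))
})

test_that("separation matches hand values and identity contracts", {
  # A = B: <d_AB> = 0, s = -<d_AA> <= 0
  s <- separation(path4, c("A", "B"), c("A", "B"))
  expect_equal(s$mean_d_ab, 0)
  expect_equal(s$s_ab, -s$mean_d_aa)
  expect_lte(s$s_ab, 0)
  # distinct singletons: s = d(a, b)
  s2 <- separation(path4, "A", "D")
  expect_equal(s2$s_ab, 3)
  # symmetry
  sAB <- separation(path4, c("A", "C"), c("B", "D"))
  sBA <- separation(path4, c("B", "D"), c("A", "C"))
  expect_equal(sAB$s_ab, sBA$s_ab)
})

test_that("all pairwise measures collapse correctly for singletons", {
  for (nodes in list(c("A", "D"), c("B", "C"))) {
    a <- nodes[1]; b <- nodes[2]
    d <- igraph::distances(path4$graph, a, b)[1, 1]
    expect_equal(as.numeric(distance_closest(path4, a, b)), d)
    expect_equal(as.numeric(distance_shortest(path4, a, b)), d)
    expect_equal(as.numeric(distance_centre(path4, a, b)), d)
    expect_equal(as.numeric(distance_kernel(path4, a, b)), d + 1)
  }
  # identical singleton sets: kernel = 1 (d = 0), others 0
  expect_equal(as.numeric(distance_kernel(path4, "B", "B")), 1)
  expect_equal(as.numeric(distance_closest(path4, "B", "B")), 0)
})

test_that("shortest measure averages all cross pairs", {
  # A1, A2 equidistant (d = 2) from b
  star <- as_interactome(rbind(c("A1", "m"), c("A2", "m"), c("m", "b")))
  expect_equal(as.numeric(distance_shortest(star, c("A1", "A2"), "b")), 2)
})

test_that("centre measure picks the topological centre and averages ties", {
  tri <- as_interactome(rbind(c("A", "B"), c("B", "C")))
  expect_equal(netcombo:::set_centre(tri, c("A", "B", "C")), "B")
  # two tied centres on a 4-path
  expect_setequal(netcombo:::set_centre(path4, c("A", "B", "C", "D")),
                  c("B", "C"))
})

test_that("every measure equals its brute-force oracle on random graphs", {
  set.seed(29)
  for (i in 1:60) {
    fx <- random_graph_fixture(sample(5:12, 1), runif(1, 0.2, 0.5))
    A <- random_subset(fx$nodes); B <- random_subset(fx$nodes)
    expect_equal(as.numeric(distance_closest(fx$ia, A, B)),
                 oracle_closest(fx$d, A, B), tolerance = 1e-12)
    expect_equal(as.numeric(distance_shortest(fx$ia, A, B)),
                 oracle_shortest(fx$d, A, B), tolerance = 1e-12)
    expect_equal(as.numeric(distance_kernel(fx$ia, A, B)),
                 oracle_kernel(fx$d, A, B), tolerance = 1e-12)
    expect_equal(as.numeric(distance_centre(fx$ia, A, B)),
                 oracle_centre(fx$d, A, B), tolerance = 1e-12)
    expect_equal(separation(fx$ia, A, B)$s_ab,
                 oracle_separation(fx$d, A, B), tolerance = 1e-12)
  }
})

test_that("pairwise measures are symmetric on random fixtures", {
  set.seed(31)
  fx <- random_graph_fixture(20, 0.2)
  for (i in 1:40) {
    A <- random_subset(fx$nodes); B <- random_subset(fx$nodes)
    for (f in list(distance_closest, distance_shortest, distance_kernel,
                   distance_centre)) {
      expect_equal(as.numeric(f(fx$ia, A, B)), as.numeric(f(fx$ia, B, A)))
    }
    expect_equal(separation(fx$ia, A, B)$s_ab, separation(fx$ia, B, A)$s_ab)
  }
})

test_that("proximity z-score is reproducible and flags zero-sigma", {
  set.seed(17)
  fx <- random_graph_fixture(40, 0.15)
  b <- build_degree_bins(fx$ia, 10)
  X <- sample(fx$nodes, 4); Y <- sample(fx$nodes, 8)
  r1 <- proximity_z(fx$ia, b, X, Y, n_random = 50, seed = 5)
  r2 <- proximity_z(fx$ia, b, X, Y, n_random = 50, seed = 5)
  expect_identical(r1$mu, r2$mu)
  expect_identical(r1$sigma, r2$sigma)
  expect_identical(r1$z, r2$z)
  expect_error(proximity_z(fx$ia, b, X, Y, n_random = 1), "n_random")

  # complete graph with Y = all nodes: every randomization reproduces the same
  # sets up to relabeling -> constant reference distance -> sigma 0 sentinel
  k5 <- as_interactome(t(utils::combn(sprintf("k%d", 1:5), 2)))
  bk <- build_degree_bins(k5, 1)
  r <- proximity_z(k5, bk, "k1", sprintf("k%d", 1:5), n_random = 10, seed = 1)
  expect_true(is.na(r$z))
  expect_match(r$note, "zero")
})

test_that("planted drugs recover the expected z sign", {
  fx <- generate_planted_fixture(small_fixture_spec(seed = 3))
  b <- build_degree_bins(fx$interactome, 50)
  inside <- proximity_z(fx$interactome, b, fx$drug_targets$targets$DA,
                        fx$disease_genes, n_random = 100, seed = 2)
  outside <- proximity_z(fx$interactome, b, fx$drug_targets$targets$DH,
                         fx$disease_genes, n_random = 100, seed = 2)
  expect_lt(inside$z, 0)
  expect_gt(outside$z, 0)
})

test_that("separation_matrix returns one row per known pair and reports exclusions", {
  ia <- as_interactome(rbind(c("t1", "t2"), c("t2", "t3"), c("t3", "t4")))
  m <- structure(list(targets = list(d1 = c("t1", "t2"), d2 = c("t3", "t4"),
                                     d3 = c("t2", "t3")),
                      provenance = NULL, log = list()),
                 class = "drug_target_map")
  tab <- separation_matrix(ia, m)
  expect_equal(nrow(tab), 3)
  expect_named(tab, c("drug_a", "drug_b", "s_ab", "d_aa", "d_bb", "d_ab",
                      "n_skipped"))
  for (i in seq_len(nrow(tab))) {
    expect_equal(tab$s_ab[i],
                 separation(ia, m$targets[[tab$drug_a[i]]],
                            m$targets[[tab$drug_b[i]]])$s_ab)
  }
  pairs <- data.frame(drug_a = c("d1", "d1"), drug_b = c("d2", "dX"))
  tab2 <- separation_matrix(ia, m, pairs)
  expect_equal(nrow(tab2), 1)
  expect_equal(attr(tab2, "exclusions")$drug_b, "dX")
})
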