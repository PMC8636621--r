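drift_ensemble <- function(disp_a, disp_b, base = c(0, 0, 0, 40, 0, 0)) {
  top <- bead_structure("A", c(1, 5), x = c(base[1], base[4]))
  T <- nrow(disp_a)
  xyz <- matrix(rep(base, each = T), T)
  xyz[, 1:3] <- xyz[, 1:3] + disp_a
  xyz[, 4:6] <- xyz[, 4:6] + disp_b
  new_ensemble(top, xyz, state = "s")
}

test_that("identical displacement series give c = 1 and weight 0", {
  set.seed(1)
  d <- matrix(rnorm(60, sd = 0.5), 20)
  e <- drift_ensemble(d, d)
  cc <- cross_correlation(e, fit = FALSE)
  expect_equal(cc$c[1, 2], 1.0, tolerance = 1e-12)
  expect_equal(-log(abs(cc$c[1, 2])), 0)
})

test_that("opposite displacement series give c = -1, |c| = 1, weight 0", {
  set.seed(2)
  d <- matrix(rnorm(60, sd = 0.5), 20)
  e <- drift_ensemble(d, -d)
  cc <- cross_correlation(e, fit = FALSE)
  expect_equal(cc$c[1, 2], -1.0, tolerance = 1e-12)
})

test_that("independent orthogonal fluctuations decorrelate as 3/sqrt(T)", {
  set.seed(3)
  T <- 1e4
  da <- cbind(rnorm(T, sd = 0.5), 0, 0)
  db <- cbind(0, rnorm(T, sd = 0.5), 0)
  e <- drift_ensemble(da, db)
  cc <- cross_correlation(e, fit = FALSE)
  expect_lt(abs(cc$c[1, 2]), 0.05)
})

test_that("cross-correlation agrees with an independent implementation", {
  gen <- generate_planted_ensembles(planted_config(n_frames = 100, seed = 9))
  e <- gen$ensembles$apo
  cc <- cross_correlation(e, fit = FALSE)
  # bio3d::dccm on the node-atom coordinates, no fitting
  ca <- which(e$topology$atom$elety == "CA")
  cols <- as.numeric(t(outer(3 * (ca - 1), 1:3, "+")))
  ref <- suppressWarnings(bio3d::dccm(e$xyz[, cols]))
  expect_equal(unname(cc$c), unname(ref[, ]), tolerance = 1e-8)
})

test_that("zero-fluctuation residues yield zeroed correlations with warning", {
  top <- bead_structure("A", c(1, 5), x = c(0, 40))
  T <- 20
  xyz <- matrix(rep(c(0, 0, 0, 40, 0, 0), each = T), T)
  set.seed(4)
  xyz[, 1:3] <- xyz[, 1:3] + matrix(rnorm(3 * T, sd = 0.3), T)
  e <- new_ensemble(top, xyz)
  expect_warning(cc <- cross_correlation(e, fit = FALSE), "zero fluctuation")
  expect_equal(cc$c[1, 2], 0)
  expect_equal(cc$c[2, 2], 0)
})

test_that("network edges require both persistence and nonzero correlation", {
  labs <- c("A:1", "A:5")
  p <- matrix(c(0, 0.8, 0.8, 0), 2, dimnames = list(labs, labs))
  map <- structure(list(state = "s", residues = NULL, p = p, cutoff = 4.5,
                        nframes = 10), class = "ContactMap")
  cmat <- matrix(c(1, exp(-1), exp(-1), 1), 2, dimnames = list(labs, labs))
  corr <- structure(list(c = cmat), class = "CorrelationMatrix")
  g <- build_dynamic_network(map, corr)
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::E(g)$weight, 1.0)
  # |c| = 1 gives weight 0
  corr$c[1, 2] <- corr$c[2, 1] <- 1
  expect_equal(igraph::E(g <- build_dynamic_network(map, corr))$weight, 0)
  # p below the 75% persistence threshold: no edge
  map$p[1, 2] <- map$p[2, 1] <- 0.70
  expect_equal(igraph::ecount(build_dynamic_network(map, corr)), 0)
  # c = 0: edge omitted (infinite weight)
  map$p[1, 2] <- map$p[2, 1] <- 0.9
  corr$c[1, 2] <- corr$c[2, 1] <- 0
  expect_equal(igraph::ecount(build_dynamic_network(map, corr)), 0)
})

test_that("weights decrease monotonically in |c|", {
  w <- function(c) -log(abs(c))
  cs <- seq(0.05, 1, by = 0.05)
  expect_true(all(diff(w(cs)) < 0))
})

test_that("edge betweenness matches hand counts on a path graph", {
  g <- generate_toy_graph(edges = data.frame(from = c("a", "b"),
                                             to = c("b", "c"), weight = 1))
  eb <- edge_betweenness_scores(g)
  expect_equal(sort(eb$betweenness), c(2, 2))  # each edge carries 2 of 3 pairs
})

test_that("symmetric graphs spread betweenness evenly; components are isolated", {
  g4 <- generate_toy_graph(edges = data.frame(from = c("a", "b", "c", "d"),
                                              to = c("b", "c", "d", "a"),
                                              weight = 1))
  eb <- edge_betweenness_scores(g4)
  expect_true(all(abs(eb$betweenness - eb$betweenness[1]) < 1e-12))
  # two components: no cross-component pair contributes
  g2 <- generate_toy_graph(edges = data.frame(from = c("a", "c"),
                                              to = c("b", "d"), weight = 1))
  expect_equal(edge_betweenness_scores(g2)$betweenness, c(1, 1))
})

test_that("betweenness agrees with brute-force path enumeration", {
  for (sd in 1:10) {
    g <- generate_toy_graph(n = sample(5:9, 1), p = 0.4, seed = sd)
    got <- edge_betweenness_scores(g)$betweenness
    want <- oracle_edge_betweenness(g)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("a rigid ensemble degenerates to an empty network, not a crash", {
  top <- bead_structure("A", c(1, 3), x = c(0, 3))
  e <- static_ensemble(top, T = 10)
  map <- compute_contact_map(e)
  expect_warning(cc <- cross_correlation(e, fit = FALSE), "zero fluctuation")
  g <- build_dynamic_network(map, cc)
  expect_equal(igraph::ecount(g), 0)
})
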