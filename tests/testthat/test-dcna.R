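fake_map <- function(p, state = "s", nframes = 100) {
  structure(list(state = state, residues = NULL, p = p, cutoff = 4.5,
                 nframes = nframes), class = "ContactMap")
}

rand_maps <- function(n, states, seed) {
  set.seed(seed)
  labs <- sprintf("A:%d", seq_len(n))
  lapply(stats::setNames(states, states), function(st) {
    p <- matrix(0, n, n, dimnames = list(labs, labs))
    ut <- upper.tri(p)
    vals <- round(stats::runif(sum(ut)), 2)
    p[ut] <- vals
    p <- p + t(p)
    fake_map(p, st)
  })
}

test_that("consensus requires the threshold in every state", {
  labs <- c("A:1", "A:3")
  mk <- function(v) {
    p <- matrix(c(0, v, v, 0), 2, dimnames = list(labs, labs))
    fake_map(p)
  }
  g <- build_consensus_network(list(mk(0.95), mk(0.92), mk(0.91)))
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::E(g)$weight, 1.0)
  expect_equal(igraph::ecount(
    build_consensus_network(list(mk(0.95), mk(0.95), mk(0.80)))), 0)
  # boundary: >= is inclusive
  expect_equal(igraph::ecount(
    build_consensus_network(list(mk(0.90), mk(0.90)))), 1)
  # threshold 0: intersection of nonzero-contact sets
  expect_equal(igraph::ecount(
    build_consensus_network(list(mk(0.2), mk(0.0)), threshold = 0)), 0)
  expect_equal(igraph::ecount(
    build_consensus_network(list(mk(0.2), mk(0.1)), threshold = 0)), 1)
})

test_that("girvan-newman separates two cliques joined by a bridge", {
  g <- barbell_graph()
  part <- girvan_newman_partition(g)
  expect_equal(part$K, 2)
  expect_equal(part$modularity, 12 / 13 - 1 / 2, tolerance = 1e-12)
  expect_equal(length(unique(part$membership[letters[1:4]])), 1)
  expect_equal(length(unique(part$membership[letters[5:8]])), 1)
  # exhaustive search confirms the clique split is the optimum
  orc <- oracle_best_partition(g)
  expect_equal(orc$modularity, part$modularity, tolerance = 1e-12)
  expect_equal(orc$K, 2)
})

test_that("a single clique is never split", {
  ed <- NULL
  for (i in 1:4) for (j in (i + 1):5)
    ed <- rbind(ed, data.frame(from = letters[i], to = letters[j], weight = 1))
  g <- generate_toy_graph(edges = ed)
  part <- girvan_newman_partition(g)
  expect_equal(part$K, 1)
  # oracle: every split lowers modularity below the single community's 0
  orc <- oracle_best_partition(g)
  expect_equal(orc$K, 1)
  expect_equal(orc$modularity, 0)
})

test_that("disconnected components are communities at minimum granularity", {
  ed <- data.frame(from = c("a", "c", "e"), to = c("b", "d", "f"), weight = 1)
  g <- generate_toy_graph(edges = ed)
  part <- girvan_newman_partition(g)
  expect_gte(part$K, 3)
  m <- part$membership
  expect_true(all(c(m["a"] == m["b"] || part$K > 3,
                    m["a"] != m["c"], m["c"] != m["e"], m["a"] != m["e"])))
})

test_that("edgeless networks partition into singletons with a warning", {
  g <- igraph::make_empty_graph(3, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = c("x", "y", "z"))
  expect_warning(part <- girvan_newman_partition(g), "edgeless")
  expect_equal(part$K, 3)
  expect_equal(part$modularity, 0)
})

test_that("modularity matches the closed form and igraph", {
  g <- barbell_graph()
  memb <- c(rep(1, 4), rep(2, 4))[match(igraph::V(g)$name, letters[1:8])]
  expect_equal(modularity_q(g, memb), 12 / 13 - 1 / 2, tolerance = 1e-12)
  expect_equal(modularity_q(g, rep(1, 8)), 0)
  singletons <- seq_len(8)
  expect_lt(modularity_q(g, singletons), 0)
  gi <- g; class(gi) <- "igraph"
  expect_equal(modularity_q(g, memb),
               igraph::modularity(gi, memb,
                                  weights = rep(1, igraph::ecount(gi))),
               tolerance = 1e-12)
  for (sd in 1:5) {
    gg <- generate_toy_graph(n = 7, p = 0.4, seed = sd)
    mm <- sample(1:3, 7, replace = TRUE)
    gi2 <- gg; class(gi2) <- "igraph"
    expect_equal(modularity_q(gg, mm),
                 igraph::modularity(gi2, mm,
                                    weights = rep(1, igraph::ecount(gi2))),
                 tolerance = 1e-12)
  }
})

test_that("difference maps subtract probabilities and antisymmetrize", {
  maps <- rand_maps(5, c("apo", "ATP"), seed = 1)
  d <- difference_map(maps$ATP, maps$apo)
  expect_equal(d["A:1", "A:2"],
               maps$ATP$p["A:1", "A:2"] - maps$apo$p["A:1", "A:2"])
  expect_identical(unclass(d), t(unclass(d)))
  d_rev <- difference_map(maps$apo, maps$ATP)
  expect_equal(unclass(d), -unclass(d_rev), ignore_attr = TRUE)
  expect_true(all(d >= -1 & d <= 1))
  expect_true(all(difference_map(maps$apo, maps$apo) == 0))
})

test_that("community deltas sum residue differences across community pairs", {
  labs <- sprintf("A:%d", 1:4)
  d <- matrix(0, 4, 4, dimnames = list(labs, labs))
  d[1, 3] <- d[3, 1] <- 0.5
  d[1, 4] <- d[4, 1] <- -0.2
  d[2, 3] <- d[3, 2] <- 0.1
  part <- structure(list(membership = stats::setNames(c(1, 1, 2, 2), labs),
                         K = 2), class = "Partition")
  dp <- community_delta(d, part)
  expect_equal(dp["C1", "C2"], 0.4)
  expect_equal(dp["C2", "C1"], 0.4)
  expect_true(is.na(dp["C1", "C1"]))
  expect_true(all(community_delta(d * 0, part) == 0, na.rm = TRUE))
})

test_that("hydrolysis-cycle deltas telescope to zero", {
  maps <- rand_maps(8, c("apo", "ATP", "ADP"), seed = 7)
  part <- structure(list(
    membership = stats::setNames(rep(1:2, each = 4), rownames(maps$apo$p)),
    K = 2), class = "Partition")
  deltas <- hydrolysis_cycle_deltas(maps, part)
  expect_named(deltas, c("apo->ATP", "ATP->ADP", "ADP->apo"))
  total <- Reduce(`+`, deltas)
  expect_lt(max(abs(total), na.rm = TRUE), 1e-12)
  # degenerate transition: equal maps give a zero delta and mutual negatives
  maps$ATP <- fake_map(maps$apo$p, "ATP")
  deltas2 <- hydrolysis_cycle_deltas(maps, part)
  expect_true(all(deltas2[["apo->ATP"]] == 0, na.rm = TRUE))
  expect_equal(unclass(deltas2[["ATP->ADP"]]),
               -unclass(deltas2[["ADP->apo"]]), ignore_attr = TRUE)
  expect_error(hydrolysis_cycle_deltas(maps[1:2], part), "missing state")
})

test_that("planted block networks are recovered exactly", {
  ok <- 0
  for (sd in 1:20) {
    set.seed(sd)
    pm <- matrix(0.05, 3, 3); diag(pm) <- 0.9
    g <- igraph::sample_sbm(30, pref.matrix = pm, block.sizes = rep(10, 3))
    igraph::V(g)$name <- sprintf("n%02d", 1:30)
    part <- girvan_newman_partition(g)
    tab <- table(part$membership, rep(1:3, each = 10))
    if (part$K == 3 && all(colSums(tab > 0) == 1) && all(rowSums(tab > 0) == 1))
      ok <- ok + 1
  }
  expect_gte(ok, 19)
})

test_that("partition and delta outputs serialize", {
  gen <- generate_planted_ensembles(planted_config(n_frames = 50, seed = 4))
  maps <- lapply(gen$ensembles, compute_contact_map)
  cons <- build_consensus_network(maps)
  part <- girvan_newman_partition(cons)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_partition(part, maps[[1]], f)
  expect_true(file.exists(f) && file.exists(paste0(f, ".json")))
  js <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(js$K, part$K)
  deltas <- hydrolysis_cycle_deltas(maps, part)
  fd <- withr::local_tempfile(fileext = ".tsv")
  write_delta(deltas[[1]], fd)
  expect_gt(nrow(utils::read.table(fd, header = TRUE, sep = "\t")), 0)
})
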