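triangle_graph <- function() {
  generate_toy_graph(edges = data.frame(from = c("s", "a", "s"),
                                        to = c("a", "t", "t"),
                                        weight = c(1, 1, 3)))
}

test_that("the optimal path minimizes total weight", {
  g <- triangle_graph()
  p <- optimal_path(g, "s", "t")
  expect_equal(p$nodes, c("s", "a", "t"))
  expect_equal(p$weight, 2)
})

test_that("disconnected endpoints give a no-path result, not an error", {
  g <- generate_toy_graph(edges = data.frame(from = c("a", "c"),
                                             to = c("b", "d"), weight = 1))
  expect_null(optimal_path(g, "a", "d"))
  expect_error(soan_suboptimal_paths(g, "a", "d"), "no path")
})

test_that("zero-weight ties break to the lexicographically smallest path", {
  ed <- data.frame(from = c("s", "s", "b", "c"), to = c("b", "c", "t", "t"),
                   weight = 0)
  g <- generate_toy_graph(edges = ed)
  p <- optimal_path(g, "s", "t")
  expect_equal(p$nodes, c("s", "b", "t"))
  expect_equal(p$weight, 0)
})

test_that("suboptimal enumeration equals exhaustive enumeration when the
           reduction keeps the whole graph", {
  ed <- data.frame(from = c("s", "s", "a", "a", "b", "c"),
                   to   = c("a", "b", "b", "t", "c", "t"),
                   weight = c(1, 2.5, 0.7, 2, 0.6, 0.9))
  g <- generate_toy_graph(edges = ed)
  ps <- soan_suboptimal_paths(g, "s", "t", k = 100, hop_radius = 10)
  orc <- oracle_simple_paths(g, "s", "t")
  expect_same_paths(ps$paths, orc)
  # k truncates the same list
  ps3 <- soan_suboptimal_paths(g, "s", "t", k = 3, hop_radius = 10)
  expect_same_paths(ps3$paths, orc[1:3])
  # k = 1 returns exactly the optimal path
  ps1 <- soan_suboptimal_paths(g, "s", "t", k = 1, hop_radius = 10)
  expect_equal(length(ps1$paths), 1)
  expect_equal(ps1$paths[[1]]$nodes, optimal_path(g, "s", "t")$nodes)
})

test_that("weights are nondecreasing along every path set", {
  for (sd in 1:5) {
    g <- generate_toy_graph(n = 8, p = 0.4, seed = sd)
    vn <- igraph::V(g)$name
    ps <- soan_suboptimal_paths(g, vn[1], vn[8], k = 50, hop_radius = 10)
    w <- vapply(ps$paths, function(p) p$weight, numeric(1))
    expect_true(all(diff(w) >= -1e-12))
    expect_equal(ps$paths[[1]]$weight, optimal_path(g, vn[1], vn[8])$weight)
  }
})

test_that("the hop-radius reduction prunes distant detours (documented artifact)", {
  # optimal path is the direct edge s-t; a suboptimal detour runs through
  # v3, which lies 3 hops from both endpoints and is pruned at radius 2
  ed <- data.frame(
    from = c("s", "s", "v1", "v2", "v3", "v4", "v5"),
    to   = c("t", "v1", "v2", "v3", "v4", "v5", "t"),
    weight = c(1.0, rep(0.3, 6)))
  g <- generate_toy_graph(edges = ed)
  orc <- oracle_simple_paths(g, "s", "t")
  expect_equal(length(orc), 2)
  expect_equal(orc[[1]]$nodes, c("s", "t"))
  ps2 <- soan_suboptimal_paths(g, "s", "t", k = 10, hop_radius = 2)
  ps3 <- soan_suboptimal_paths(g, "s", "t", k = 10, hop_radius = 3)
  expect_equal(length(ps2$paths), 1)  # detour pruned with the default radius
  expect_same_paths(ps3$paths, orc)   # a radius covering the graph keeps it
})

test_that("removing an edge off every returned path leaves the set unchanged", {
  ed <- data.frame(from = c("s", "a", "s", "u"), to = c("a", "t", "t", "t"),
                   weight = c(1, 1, 3, 50))
  g <- generate_toy_graph(edges = ed)
  ps <- soan_suboptimal_paths(g, "s", "t", k = 2, hop_radius = 1)
  g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c("u", "t")))
  ps2 <- soan_suboptimal_paths(g2, "s", "t", k = 2, hop_radius = 1)
  expect_same_paths(ps$paths, ps2$paths)
})

test_that("path composition counts nodes and scores query sets", {
  g <- triangle_graph()
  ps <- soan_suboptimal_paths(g, "s", "t", k = 10, hop_radius = 10)
  pc <- path_composition(ps)
  expect_equal(unname(pc$frequency[c("s", "t")]), c(2, 2))
  expect_equal(unname(pc$frequency["a"]), 1)
  # node on no path counts off-path
  expect_warning(
    pc2 <- path_composition(ps, query = c("a", "zz"), network = g),
    "absent")
  expect_equal(pc2$on_path_fraction, 0.5)
  # endpoints lie on every path
  pc3 <- path_composition(ps, query = c("s", "t"))
  expect_equal(pc3$on_path_fraction, 1.0)
})

test_that("path sets serialize as ranked TSV", {
  g <- triangle_graph()
  ps <- soan_suboptimal_paths(g, "s", "t", k = 10, hop_radius = 10)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_pathset(ps, f)
  df <- utils::read.table(f, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  expect_equal(df$rank, seq_along(ps$paths))
  expect_equal(df$nodes[1], "s,a,t")
})
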