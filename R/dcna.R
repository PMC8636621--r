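# Difference contact network analysis across functional states.
#
# 1. A consensus network keeps the contacts that are stable in every state
#    (p >= threshold in all contact maps; edges unweighted).
# 2. The consensus network is divided into dynamic communities with the
#    unweighted Girvan-Newman algorithm, stopping when the modularity gain
#    between successive partitions falls below a tolerance.
# 3. Per state transition, residue-level contact-probability differences
#    are aggregated over community pairs into the net change matrix
#    dP[A,B] = sum of (p_to - p_from) over residue pairs i in A, j in B.

#' Consensus network across functional states
#'
#' Default ("intersection") rule: an edge exists iff the contact probability
#' is >= threshold in every state — contacts persistent across all
#' functional states. The alternative "subtraction" rule keeps contacts
#' with p >= threshold in the first (reference) state whose probability
#' changes by at most 1 - threshold in every other state.
#'
#' @param maps list of \code{ContactMap}s (>= 2) over identical residues
#' @param threshold consensus probability threshold (inclusive)
#' @param mode "intersection" or "subtraction"
#' @return an igraph graph (class \code{ConsensusNetwork} prepended), all
#'   edge weights 1.0; isolated residues are retained as vertices
#' @export
build_consensus_network <- function(maps, threshold = 0.90,
                                    mode = c("intersection", "subtraction")) {
  mode <- match.arg(mode)
  if (length(maps) < 2) stop("need contact maps for at least 2 states")
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  labs <- rownames(maps[[1]]$p)
  for (m in maps[-1])
    if (!identical(rownames(m$p), labs))
      stop("contact maps cover different residue lists")
  keep <- if (mode == "intersection") {
    Reduce(`&`, lapply(maps, function(m) m$p >= threshold))
  } else {
    ref <- maps[[1]]$p
    ok <- ref >= threshold
    for (m in maps[-1]) ok <- ok & (abs(ref - m$p) <= 1 - threshold)
    ok
  }
  if (threshold == 0)  # limit case: intersection of nonzero-contact sets
    keep <- keep & Reduce(`&`, lapply(maps, function(m) m$p > 0))
  sel <- which(keep & upper.tri(keep), arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = length(labs), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = labs)
  if (nrow(sel))
    g <- igraph::add_edges(g, t(cbind(sel[, 1], sel[, 2])), weight = 1.0)
  g$threshold <- threshold
  g$states <- vapply(maps, function(m) m$state, character(1))
  g$mode <- mode
  class(g) <- c("ConsensusNetwork", class(g))
  g
}

#' Newman modularity of a partition
#'
#' Q = sum_c [ e_c/m - (d_c/2m)^2 ], with m the edge count, e_c the
#' intra-community edge count and d_c the total degree of community c.
#' Defined as 0 for an edgeless graph.
#'
#' @param graph an igraph graph (treated as unweighted)
#' @param membership community id per vertex (vector, vertex order)
#' @return modularity Q
#' @export
modularity_q <- function(graph, membership) {
  m <- igraph::ecount(graph)
  if (length(membership) != igraph::vcount(graph))
    stop("membership must cover all vertices")
  if (m == 0) return(0)
  ends <- igraph::ends(graph, igraph::E(graph), names = FALSE)
  memb <- as.integer(factor(membership))
  intra <- memb[ends[, 1]] == memb[ends[, 2]]
  nc <- max(memb)
  e_c <- vapply(seq_len(nc), function(c) sum(intra & memb[ends[, 1]] == c),
                numeric(1))
  deg <- igraph::degree(graph)
  d_c <- vapply(seq_len(nc), function(c) sum(deg[memb == c]), numeric(1))
  sum(e_c / m - (d_c / (2 * m))^2)
}

# lexicographically smallest (from, to) among maximal-betweenness edges
.max_betweenness_edge <- function(g) {
  eb <- igraph::edge_betweenness(g, directed = FALSE, weights = NA)
  top <- which(eb >= max(eb) - 1e-9)
  ends <- igraph::ends(g, igraph::E(g)[top])
  a <- pmin(ends[, 1], ends[, 2]); b <- pmax(ends[, 1], ends[, 2])
  top[order(a, b)][1]
}

#' Girvan-Newman community detection with modularity convergence
#'
#' Repeatedly removes the edge of maximal (unweighted) edge betweenness,
#' recomputed exactly after every removal; ties broken towards the
#' lexicographically smallest endpoint pair. Each time the component
#' structure changes, the induced partition is accepted and its modularity
#' evaluated; division stops when the modularity change between successive
#' accepted partitions drops below \code{modularity_tol}. The returned
#' partition is the best-modularity partition on the trace. With
#' \code{modularity_tol = -Inf} the full dendrogram is explored.
#'
#' @param network an igraph graph (consensus network); edge weights ignored
#' @param modularity_tol convergence tolerance on the modularity change
#' @return object of class \code{Partition}: \code{membership} (named),
#'   \code{K}, \code{modularity}, \code{trace} (Q of every accepted
#'   partition, starting with the input components)
#' @export
girvan_newman_partition <- function(network, modularity_tol = 0.001) {
  g0 <- network
  class(g0) <- "igraph"
  n <- igraph::vcount(g0)
  if (n == 0) stop("empty network")
  labs <- igraph::V(g0)$name %||% as.character(seq_len(n))
  if (igraph::ecount(g0) == 0) {
    warning("edgeless network: every node is its own community")
    memb <- stats::setNames(seq_len(n), labs)
    return(structure(list(membership = memb, K = n, modularity = 0,
                          trace = 0), class = "Partition"))
  }
  comp <- igraph::components(g0)$membership
  best <- list(memb = comp, q = modularity_q(g0, comp))
  trace <- best$q
  trace_membership <- list(stats::setNames(as.integer(comp), labs))
  prev_q <- best$q
  ncomp <- max(comp)
  g <- g0
  while (igraph::ecount(g) > 0) {
    g <- igraph::delete_edges(g, .max_betweenness_edge(g))
    cm <- igraph::components(g)$membership
    if (max(cm) == ncomp) next
    ncomp <- max(cm)
    q <- modularity_q(g0, cm)
    trace <- c(trace, q)
    trace_membership[[length(trace_membership) + 1]] <-
      stats::setNames(as.integer(cm), labs)
    if (q > best$q) best <- list(memb = cm, q = q)
    if (q - prev_q < modularity_tol) break
    prev_q <- q
  }
  memb <- stats::setNames(as.integer(factor(best$memb,
                                            levels = unique(best$memb))), labs)
  structure(list(membership = memb, K = max(memb), modularity = best$q,
                 trace = trace, trace_membership = trace_membership),
            class = "Partition")
}

#' @export
print.Partition <- function(x, ...) {
  cat(sprintf("Partition: %d communities over %d nodes, modularity Q = %.4f (%d accepted splits)\n",
              x$K, length(x$membership), x$modularity, length(x$trace) - 1))
  invisible(x)
}

#' Residue-level contact-probability difference map
#'
#' d_ij = p_ij(to) - p_ij(from); symmetric, in [-1, 1]; antisymmetric under
#' swapping the transition direction.
#'
#' @param map_to,map_from \code{ContactMap}s over identical residues
#' @return matrix with dimnames = residue labels and attribute
#'   \code{transition}
#' @export
difference_map <- function(map_to, map_from) {
  if (!identical(rownames(map_to$p), rownames(map_from$p)))
    stop("contact maps cover different residue lists")
  d <- map_to$p - map_from$p
  attr(d, "transition") <- paste0(map_from$state, "->", map_to$state)
  d
}

#' Community-pair net contact change
#'
#' dP[A,B] = sum of d_ij over residues i in A, j in B for A != B (each
#' unordered residue pair counted once); the diagonal is not reported (NA).
#'
#' @param diff residue difference matrix from \code{\link{difference_map}}
#' @param partition a \code{Partition} over the same residues
#' @return K x K matrix (communities in id order), diagonal NA, with
#'   attribute \code{transition} carried over
#' @export
community_delta <- function(diff, partition) {
  memb <- partition$membership
  if (length(memb) != nrow(diff))
    stop("partition does not cover the difference matrix residues")
  if (!is.null(names(memb)) && !is.null(rownames(diff)) &&
      !identical(names(memb), rownames(diff)))
    memb <- memb[rownames(diff)]
  K <- partition$K
  M <- matrix(0, nrow(diff), K)
  M[cbind(seq_along(memb), memb)] <- 1
  dp <- t(M) %*% diff %*% M
  diag(dp) <- NA
  dimnames(dp) <- list(paste0("C", seq_len(K)), paste0("C", seq_len(K)))
  attr(dp, "transition") <- attr(diff, "transition")
  dp
}

#' Community contact changes over the ATP-hydrolysis cycle
#'
#' Computes the three transition difference matrices apo->ATP, ATP->ADP and
#' ADP->apo and aggregates each over the community partition. By
#' construction the three dP matrices telescope to zero.
#'
#' @param maps named list of \code{ContactMap}s; names must include the
#'   three state labels in cycle order (default c("apo", "ATP", "ADP"))
#' @param partition a \code{Partition} from the consensus network
#' @param cycle state labels in cycle order
#' @return named list of three dP matrices ("apo->ATP", "ATP->ADP",
#'   "ADP->apo")
#' @export
hydrolysis_cycle_deltas <- function(maps, partition,
                                    cycle = c("apo", "ATP", "ADP")) {
  miss <- setdiff(cycle, names(maps))
  if (length(miss)) stop("missing state(s): ", paste(miss, collapse = ", "))
  out <- list()
  for (k in seq_along(cycle)) {
    from <- cycle[k]; to <- cycle[if (k == length(cycle)) 1 else k + 1]
    d <- difference_map(maps[[to]], maps[[from]])
    out[[paste0(from, "->", to)]] <- community_delta(d, partition)
  }
  out
}

#' Write a partition as TSV plus a JSON summary
#' @param partition a \code{Partition}
#' @param map the \code{ContactMap} (or consensus network residue table)
#'   providing chain/resno per node
#' @param path TSV output path; the JSON summary goes to
#'   \code{paste0(path, ".json")}
#' @export
write_partition <- function(partition, map, path) {
  df <- data.frame(chain = map$residues$chain, resid = map$residues$resno,
                   community = as.integer(partition$membership))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(K = partition$K, Q = partition$modularity,
                            trace = partition$trace),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a community-pair delta matrix as TSV
#' @param dp matrix from \code{\link{community_delta}}
#' @param path output path
#' @export
write_delta <- function(dp, path) {
  ut <- which(upper.tri(dp), arr.ind = TRUE)
  df <- data.frame(community_a = rownames(dp)[ut[, 1]],
                   community_b = colnames(dp)[ut[, 2]],
                   delta_p = dp[ut])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# transition=%s", attr(dp, "transition") %||% ""), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
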