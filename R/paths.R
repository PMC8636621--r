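# Optimal and suboptimal path enumeration on correlation-weighted networks.
#
# The optimal path is the minimum-total-weight simple path (nonnegative
# weights); ties are broken towards the lexicographically smallest node
# sequence. Suboptimal paths follow the SOAN scheme: the graph is reduced
# to nodes within a hop radius of the optimal path, and the k lowest-weight
# simple paths are enumerated inside the reduced graph with a deviation
# (Yen-style) algorithm, returned sorted by weight then lexicographically.

.path_weight <- function(g, nodes) {
  if (length(nodes) < 2) return(0)
  eids <- igraph::get_edge_ids(g, rbind(nodes[-length(nodes)], nodes[-1]))
  if (any(eids == 0)) return(NA_real_)
  sum(igraph::E(g)$weight[eids])
}

# locale-independent lexicographic key for a node sequence: "\r" sorts
# below every printable byte, so byte order on the key equals elementwise
# comparison of the node names (radix ordering avoids locale collation)
.path_key <- function(nodes) paste(nodes, collapse = "\r")

# Shortest path with deterministic lexicographic tie-break. Distances come
# from Dijkstra (igraph); the path is reconstructed greedily, always taking
# the smallest-named neighbour that still lies on a shortest route, with
# backtracking to stay simple when zero-weight edges are present.
shortest_path_lex <- function(g, source, target, eps = 1e-12) {
  if (source == target) stop("source and target must differ")
  vn <- igraph::V(g)$name
  if (!(source %in% vn) || !(target %in% vn))
    stop("source/target not in network")
  w <- igraph::E(g)$weight
  dt <- as.numeric(igraph::distances(g, v = target, weights = w))
  names(dt) <- vn
  total <- dt[[source]]
  if (!is.finite(total)) return(NULL)
  tol <- eps * max(1, total)
  adj <- igraph::adjacent_vertices(g, igraph::V(g))
  names(adj) <- vn

  path <- character(0)
  found <- FALSE
  visit <- function(node, acc) {
    path[length(path) + 1] <<- node
    if (node == target) { found <<- TRUE; return() }
    nb <- adj[[node]]$name
    nb <- setdiff(nb, path)
    if (length(nb)) {
      eids <- igraph::get_edge_ids(g, rbind(rep(node, length(nb)), nb))
      ew <- w[eids]
      ok <- which(acc + ew + dt[nb] <= total + tol)
      for (i in ok[order(nb[ok], method = "radix")]) {
        visit(nb[i], acc + ew[i])
        if (found) return()
      }
    }
    path <<- path[-length(path)]
  }
  visit(source, 0)
  if (!found) return(NULL)
  list(nodes = path, weight = total)
}

#' Minimum-weight path between two residues
#'
#' @param network an igraph graph with nonnegative edge weights
#' @param source,target vertex names (residue labels)
#' @return list with \code{nodes} and \code{weight}, or NULL when source
#'   and target are disconnected
#' @export
optimal_path <- function(network, source, target) {
  g <- network
  class(g) <- "igraph"
  if (is.null(igraph::E(g)$weight))
    g <- igraph::set_edge_attr(g, "weight", value = rep(1, igraph::ecount(g)))
  if (any(igraph::E(g)$weight < 0)) stop("negative edge weights")
  shortest_path_lex(g, source, target)
}

# Yen-style deviation enumeration of the k lowest-weight simple paths.
# Candidates at the k-th weight boundary are exhausted before truncation so
# the returned list is the unique (weight, lexicographic) ordering.
yen_k_paths <- function(g, source, target, k, eps = 1e-12) {
  first <- shortest_path_lex(g, source, target, eps)
  if (is.null(first)) return(list())
  A <- list(first)
  B <- list()
  seen <- .path_key(first$nodes)  # keys ever in A or B, never regenerated
  repeat {
    prev <- A[[length(A)]]$nodes
    for (i in seq_len(length(prev) - 1)) {
      spur <- prev[i]
      root <- prev[seq_len(i)]
      g2 <- g
      # remove edges used by already-accepted paths sharing this root
      for (p in A) {
        pn <- p$nodes
        if (length(pn) > i && identical(pn[seq_len(i)], root)) {
          eid <- igraph::get_edge_ids(g2, c(pn[i], pn[i + 1]))
          if (length(eid) && eid != 0) g2 <- igraph::delete_edges(g2, eid)
        }
      }
      if (i > 1) g2 <- igraph::delete_vertices(g2, root[seq_len(i - 1)])
      sp <- tryCatch(shortest_path_lex(g2, spur, target, eps),
                     error = function(e) NULL)
      if (is.null(sp)) next
      cand_nodes <- c(root[-length(root)], sp$nodes)
      key <- .path_key(cand_nodes)
      if (key %in% seen) next
      if (any(duplicated(cand_nodes))) next
      wgt <- .path_weight(g, cand_nodes)
      B[[length(B) + 1]] <- list(nodes = cand_nodes, weight = wgt)
      seen <- c(seen, key)
    }
    if (!length(B)) break
    ws <- vapply(B, function(p) p$weight, numeric(1))
    # pop minimum weight; among ties the lexicographically smallest
    cand <- which(ws <= min(ws) + eps * max(1, min(ws)))
    keys <- vapply(B[cand], function(p) .path_key(p$nodes), character(1))
    pick <- cand[order(keys, method = "radix")[1]]
    nxt <- B[[pick]]
    B <- B[-pick]
    kth_w <- if (length(A) >= k) A[[k]]$weight else Inf
    if (length(A) >= k && nxt$weight > kth_w + eps * max(1, kth_w)) break
    A[[length(A) + 1]] <- nxt
  }
  # resolve ordering (and the tie boundary) exactly
  ord <- order(vapply(A, function(p) p$weight, numeric(1)))
  A <- A[ord]
  i <- 1
  while (i < length(A)) {
    j <- i
    while (j < length(A) &&
           A[[j + 1]]$weight <= A[[i]]$weight + eps * max(1, A[[i]]$weight))
      j <- j + 1
    if (j > i) {
      blk <- A[i:j]
      blk <- blk[order(vapply(blk, function(p) .path_key(p$nodes),
                              character(1)), method = "radix")]
      A[i:j] <- blk
    }
    i <- j + 1
  }
  A[seq_len(min(k, length(A)))]
}

#' SOAN suboptimal path enumeration
#'
#' Computes the optimal path, reduces the network to all nodes within
#' \code{hop_radius} hops (unweighted) of any optimal-path node, and
#' enumerates the \code{k} lowest-weight simple paths from source to target
#' inside the reduced graph.
#'
#' @param network an igraph graph with nonnegative edge weights
#' @param source,target vertex names
#' @param k number of paths (optimal + suboptimal)
#' @param hop_radius reduction radius in hops around the optimal path
#' @return object of class \code{PathSet}: source, target, list of paths
#'   (nodes, weight) sorted by nondecreasing weight then lexicographically,
#'   reduction parameters and the retained node set
#' @export
soan_suboptimal_paths <- function(network, source, target, k = 5000,
                                  hop_radius = 2) {
  g <- network
  class(g) <- "igraph"
  if (is.null(igraph::E(g)$weight))
    g <- igraph::set_edge_attr(g, "weight", value = rep(1, igraph::ecount(g)))
  if (any(igraph::E(g)$weight < 0)) stop("negative edge weights")
  opt <- shortest_path_lex(g, source, target)
  if (is.null(opt)) stop("no path between ", source, " and ", target)
  hops <- igraph::distances(g, v = opt$nodes, weights = NA)
  keep <- colnames(hops)[apply(hops, 2, min) <= hop_radius]
  red <- igraph::induced_subgraph(g, keep)
  paths <- yen_k_paths(red, source, target, k)
  structure(list(source = source, target = target, paths = paths,
                 k = k, hop_radius = hop_radius, nodes = keep),
            class = "PathSet")
}

#' @export
print.PathSet <- function(x, ...) {
  cat(sprintf("PathSet %s -> %s: %d path(s), weights [%g, %g], hop radius %d\n",
              x$source, x$target, length(x$paths),
              if (length(x$paths)) x$paths[[1]]$weight else NA,
              if (length(x$paths)) x$paths[[length(x$paths)]]$weight else NA,
              x$hop_radius))
  invisible(x)
}

#' Path-composition statistics
#'
#' Per-node count of paths containing the node, and for a query residue
#' set the fraction of query nodes lying on at least one path. With
#' \code{include_neighbors = TRUE} a query node also counts as on-path when
#' any of its network neighbours is on a path.
#'
#' @param paths a \code{PathSet}
#' @param query character vector of node names (e.g. mutation positions)
#' @param include_neighbors extend on-path membership to 1-hop neighbours
#' @param network required when \code{include_neighbors = TRUE}
#' @return list with \code{frequency} (named counts over all path nodes)
#'   and \code{on_path_fraction}
#' @export
path_composition <- function(paths, query = character(0),
                             include_neighbors = FALSE, network = NULL) {
  if (!length(paths$paths)) stop("empty path set")
  freq <- table(unlist(lapply(paths$paths, function(p) unique(p$nodes))))
  freq <- stats::setNames(as.integer(freq), names(freq))
  on_path_frac <- NA_real_
  if (length(query)) {
    onset <- names(freq)
    if (include_neighbors) {
      if (is.null(network)) stop("include_neighbors needs the network")
      g <- network
      class(g) <- "igraph"
      nb <- unique(unlist(lapply(igraph::adjacent_vertices(g, onset),
                                 function(v) v$name)))
      onset <- union(onset, nb)
    }
    known <- query
    if (!is.null(network)) {
      g <- network
      class(g) <- "igraph"
      absent <- setdiff(query, igraph::V(g)$name)
      if (length(absent))
        warning("query node(s) absent from network (counted off-path): ",
                paste(absent, collapse = ", "))
    }
    on_path_frac <- mean(known %in% onset)
  }
  list(frequency = freq, on_path_fraction = on_path_frac)
}

#' Write a path set as TSV (rank, weight, node sequence)
#' @param paths a \code{PathSet}
#' @param path output file
#' @export
write_pathset <- function(paths, path) {
  df <- data.frame(rank = seq_along(paths$paths),
                   weight = vapply(paths$paths, function(p) p$weight,
                                   numeric(1)),
                   nodes = vapply(paths$paths, function(p)
                     paste(p$nodes, collapse = ","), character(1)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
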