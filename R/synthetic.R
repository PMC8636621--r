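# Planted-community pseudo-ensembles and toy graphs with ground truth.
# Designated intra-community contacts link residues at sequence distance
# 2-4, a band dense enough that the planted communities are the
# modularity optimum of the consensus network.
#
# Each residue is a body atom (the network node, carrying the planted
# correlated displacement) plus one dedicated probe atom per designated
# contact pair. Per frame, a designated pair's probes sit either 2.8 A
# apart (in contact at the 4.5 A cutoff) or 10 A apart, by an independent
# Bernoulli draw with the planted probability, so measured contact
# probabilities are exact binomial samples of the planted values. Body
# atoms and foreign probes are kept clear of the cutoff by layout
# construction (verified, with deterministic re-jitter on collision), so
# only the designated probes decide contacts.
#
# Displacements: d_i(t) = sqrt(rho) s_k(i)(t) + sqrt(1 - rho) e_i(t) with
# community-shared Gaussian s_k and independent e_i (per-coordinate sd
# sigma), giving intra-community correlation rho and inter-community 0 on
# the raw coordinates; generated frames carry no rigid-body drift.

#' Planted ensemble configuration
#'
#' @param n_communities number of planted communities K
#' @param residues_per_community residues per community
#' @param states functional-state labels
#' @param p_intra contact probability of designated intra-community pairs
#'   (all non-sequence-adjacent pairs within a community), every state
#' @param inter_prob named list over community pairs ("1-2", "1-3", ...);
#'   each entry a numeric vector of per-state contact probabilities for the
#'   designated toggling pairs. Defaults to a cyclic gain/loss pattern over
#'   three states emulating an ATP-hydrolysis cycle.
#' @param n_inter_pairs designated toggling residue pairs per community pair
#' @param n_bridge_pairs stable inter-community pairs per community pair
#'   (contact probability \code{bridge_prob} in every state); these give
#'   the consensus network its inter-community edges
#' @param bridge_prob probability for bridge pairs
#' @param rho shared-motion correlation strength in [0, 1]
#' @param sigma per-coordinate displacement noise (Angstrom)
#' @param n_frames frames per state (>= 2)
#' @param seed random seed
#' @export
planted_config <- function(n_communities = 3, residues_per_community = 10,
                           states = c("apo", "ATP", "ADP"),
                           p_intra = 0.95, inter_prob = NULL,
                           n_inter_pairs = 3, n_bridge_pairs = 1,
                           bridge_prob = 0.98, rho = 0.8, sigma = 0.4,
                           n_frames = 1000, seed = 1) {
  K <- n_communities
  S <- length(states)
  if (is.null(inter_prob)) {
    pairs <- utils::combn(K, 2)
    inter_prob <- list()
    base <- c(0.10, 0.85, 0.45)
    for (q in seq_len(ncol(pairs))) {
      v <- base[((seq_len(S) - 1 + (q - 1)) %% 3) + 1]
      inter_prob[[paste(pairs[, q], collapse = "-")]] <- v
    }
  }
  cfg <- list(n_communities = K, residues_per_community = residues_per_community,
              states = states, p_intra = p_intra, inter_prob = inter_prob,
              n_inter_pairs = n_inter_pairs, n_bridge_pairs = n_bridge_pairs,
              bridge_prob = bridge_prob, rho = rho, sigma = sigma,
              n_frames = n_frames, seed = seed)
  probs <- c(p_intra, bridge_prob, unlist(inter_prob))
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (n_frames < 2) stop("need at least 2 frames")
  if (K < 1) stop("need at least 1 community")
  if (rho < 0 || rho > 1) stop("rho must be in [0, 1]")
  for (nm in names(inter_prob))
    if (length(inter_prob[[nm]]) != S)
      stop("inter_prob entries must have one probability per state")
  if (n_inter_pairs + n_bridge_pairs > residues_per_community)
    stop("not enough residues per community for the designated inter pairs")
  cfg
}

# body-atom layout: community centres on a regular polygon (midpoints of
# centre pairs stay clear of other communities), residues on a 12 A grid
# inside each community
.planted_layout <- function(K, m) {
  radius <- max(80, 30 * K)
  ang <- 2 * pi * (seq_len(K) - 1) / max(K, 1)
  centres <- cbind(radius * cos(ang), radius * sin(ang), 0)
  if (K == 1) centres <- matrix(0, 1, 3)
  gdim <- ceiling(m^(1 / 3))
  idx <- seq_len(m) - 1
  local <- cbind(idx %% gdim, (idx %/% gdim) %% gdim, idx %/% gdim^2) * 12
  bodies <- NULL
  for (k in seq_len(K)) bodies <- rbind(bodies, sweep(local, 2, centres[k, ], "+"))
  list(bodies = bodies, centres = centres)
}

# deterministic contact-site placement: intra-pair sites on an 18 A grid
# "shelf" below their community, inter/bridge sites on a perpendicular
# line above the midpoint of the two community centres; probe reach is
# +/- 5 A about a site, so foreign atoms stay >= 8 A apart by construction
.planted_sites <- function(pairs, comm, centres, jitter = NULL, z_top = 34) {
  np <- nrow(pairs)
  sites <- matrix(0, np, 3)
  spacing <- 18
  for (k in seq_len(max(comm))) {
    rows <- which(pairs$type == "intra" & comm[pairs$i] == k)
    if (!length(rows)) next
    gw <- ceiling(sqrt(length(rows)))
    t <- seq_along(rows) - 1
    sites[rows, ] <- cbind(
      centres[k, 1] + ((t %% gw) - (gw - 1) / 2) * spacing,
      centres[k, 2] + ((t %/% gw) - (gw - 1) / 2) * spacing,
      -22)
  }
  inter_rows <- which(pairs$type %in% c("inter", "bridge"))
  if (length(inter_rows)) {
    key <- paste(comm[pairs$i[inter_rows]], comm[pairs$j[inter_rows]])
    for (kk in unique(key)) {
      rows <- inter_rows[key == kk]
      k1 <- comm[pairs$i[rows[1]]]; k2 <- comm[pairs$j[rows[1]]]
      mid <- (centres[k1, ] + centres[k2, ]) / 2
      u <- centres[k2, ] - centres[k1, ]
      v <- c(-u[2], u[1], 0)
      v <- v / sqrt(sum(v^2))
      t <- seq_along(rows) - (length(rows) + 1) / 2
      sites[rows, ] <- cbind(mid[1] + t * spacing * v[1],
                             mid[2] + t * spacing * v[2],
                             z_top)
    }
  }
  if (!is.null(jitter)) sites <- sites + jitter
  sites
}

#' Generate multi-state planted ensembles with ground truth
#'
#' @param config from \code{\link{planted_config}}
#' @return list with \code{ensembles} (named list of \code{Ensemble}s, one
#'   per state) and \code{truth}: \code{membership} (named, community id
#'   per residue), \code{p_planted} (N x N x S array of planted contact
#'   probabilities), \code{delta_planted} (list over cycle transitions of
#'   planted community-pair dP matrices), \code{pairs} (designated-pair
#'   table), \code{rho}
#' @export
generate_planted_ensembles <- function(config = planted_config()) {
  set.seed(config$seed)
  K <- config$n_communities; m <- config$residues_per_community
  N <- K * m; S <- length(config$states); T <- config$n_frames
  comm <- rep(seq_len(K), each = m)
  chain <- LETTERS[comm]
  resno <- rep(seq_len(m), K)
  layout <- .planted_layout(K, m)
  bodies <- layout$bodies

  # designated pair table: one row per pair, per-state probabilities.
  # Intra-community contacts connect residues at sequence distance 2 and 3
  # (distance-1 pairs are covalent neighbours, excluded from contact maps),
  # giving each community a connected band of designated contacts.
  pairs <- NULL
  for (k in seq_len(K)) {
    idx <- which(comm == k)
    for (a in seq_len(m)) for (b in seq_len(m))
      if ((b - a) %in% c(2, 3, 4))
        pairs <- rbind(pairs, data.frame(i = idx[a], j = idx[b],
                                         type = "intra",
                                         t(rep(config$p_intra, S))))
  }
  cpairs <- if (K >= 2) utils::combn(K, 2) else matrix(nrow = 2, ncol = 0)
  for (q in seq_len(ncol(cpairs))) {
    k1 <- cpairs[1, q]; k2 <- cpairs[2, q]
    key <- paste(k1, k2, sep = "-")
    pv <- config$inter_prob[[key]]
    if (is.null(pv)) pv <- rep(0, S)
    for (r in seq_len(config$n_inter_pairs))
      pairs <- rbind(pairs, data.frame(i = which(comm == k1)[r],
                                       j = which(comm == k2)[r],
                                       type = "inter", t(pv)))
    for (r in seq_len(config$n_bridge_pairs))
      pairs <- rbind(pairs, data.frame(i = rev(which(comm == k1))[r],
                                       j = rev(which(comm == k2))[r],
                                       type = "bridge",
                                       t(rep(config$bridge_prob, S))))
  }
  names(pairs)[4:(3 + S)] <- config$states
  np <- nrow(pairs)

  # deterministic contact sites, verified: for every residue pair, atoms
  # other than the pair's own probes must stay clear of the cutoff in both
  # probe states (small re-jitter as fallback for degenerate layouts)
  in_sep <- 1.4; out_sep <- 5.0; clearance <- 4.5 + 2.5
  uvec <- (bodies[pairs$j, ] - bodies[pairs$i, ])
  uvec <- uvec / sqrt(rowSums(uvec^2))
  ok_layout <- FALSE
  for (attempt in 1:50) {
    jit <- if (attempt == 1) NULL else
      matrix(stats::runif(3 * np, -0.5, 0.5), np, 3)
    sites <- .planted_sites(pairs, comm, layout$centres, jit,
                            z_top = 12 * (ceiling(m^(1 / 3)) - 1) + 22)
    # atom cloud: bodies, then probe positions (in and out, both ends)
    cloud <- rbind(bodies,
                   sites - in_sep * uvec, sites + in_sep * uvec,
                   sites - out_sep * uvec, sites + out_sep * uvec)
    owner <- c(seq_len(N), pairs$i, pairs$j, pairs$i, pairs$j)
    pair_of <- c(rep(NA, N), rep(seq_len(np), 4))
    d2 <- as.matrix(stats::dist(cloud))^2
    bad <- FALSE
    pk <- paste(pmin(pairs$i, pairs$j), pmax(pairs$i, pairs$j))
    for (a in seq_len(nrow(cloud) - 1)) {
      ra <- owner[a]
      close_b <- which(d2[a, ] < clearance^2)
      close_b <- close_b[close_b > a]
      for (b in close_b) {
        rb <- owner[b]
        if (ra == rb) next
        same_pair <- !is.na(pair_of[a]) && !is.na(pair_of[b]) &&
          pair_of[a] == pair_of[b]
        if (same_pair) next
        # atoms of a designated pair other than its own probes must not
        # approach the cutoff; any other residue pair must stay clear too
        bad <- TRUE
        break
      }
      if (bad) break
    }
    if (!bad) { ok_layout <- TRUE; break }
  }
  if (!ok_layout)
    stop("geometric infeasibility: could not place designated contact ",
         "sites without collisions; reduce pair counts or community size")

  # topology: per residue, a body CA followed by its probes (one per
  # designated pair the residue takes part in; sign = which end of the
  # pair axis the probe sits on)
  probe <- data.frame(owner = c(pairs$i, pairs$j),
                      pair = rep(seq_len(np), 2),
                      sign = rep(c(-1, 1), each = np))
  probe <- probe[order(probe$owner, probe$pair), , drop = FALSE]
  atom_owner <- c(seq_len(N), probe$owner)
  atom_is_probe <- c(rep(FALSE, N), rep(TRUE, nrow(probe)))
  atom_pair <- c(rep(NA_integer_, N), probe$pair)
  atom_sign <- c(rep(0, N), probe$sign)
  ord <- order(atom_owner, atom_is_probe, atom_pair)
  atom_owner <- atom_owner[ord]; atom_is_probe <- atom_is_probe[ord]
  atom_pair <- atom_pair[ord]; atom_sign <- atom_sign[ord]
  n_atoms <- length(atom_owner)
  elety <- character(n_atoms)
  elety[!atom_is_probe] <- "CA"
  for (i in seq_len(N)) {
    w <- which(atom_owner == i & atom_is_probe)
    if (length(w)) elety[w] <- sprintf("C%02d", seq_along(w))
  }
  base_in <- base_out <- matrix(0, n_atoms, 3)
  base_in[!atom_is_probe, ] <- bodies
  base_out[!atom_is_probe, ] <- bodies
  pw <- which(atom_is_probe)
  base_in[pw, ] <- sites[atom_pair[pw], ] +
    atom_sign[pw] * in_sep * uvec[atom_pair[pw], ]
  base_out[pw, ] <- sites[atom_pair[pw], ] +
    atom_sign[pw] * out_sep * uvec[atom_pair[pw], ]
  res_sorted <- atom_owner
  atom <- data.frame(chain = chain[res_sorted], resno = resno[res_sorted],
                     insert = "", resname = "ALA", elety = elety,
                     element = "C",
                     x = base_in[, 1], y = base_in[, 2], z = base_in[, 3],
                     occ = 1, b = 0, stringsAsFactors = FALSE)
  top <- new_structure(atom)
  labs <- residue_labels(top)

  sq_rho <- sqrt(config$rho); sq_eps <- sqrt(1 - config$rho)
  ensembles <- list()
  for (s in seq_len(S)) {
    draws <- matrix(stats::runif(np * T) < rep(pairs[[3 + s]], T), np, T)
    s_comm <- array(stats::rnorm(T * K * 3, sd = config$sigma), c(T, K, 3))
    eps <- array(stats::rnorm(T * N * 3, sd = config$sigma), c(T, N, 3))
    disp <- array(0, c(T, N, 3))
    for (d in 1:3)
      disp[, , d] <- sq_rho * s_comm[, comm, d] + sq_eps * eps[, , d]
    xyz <- matrix(0, T, 3 * n_atoms)
    for (a in seq_len(n_atoms)) {
      res <- res_sorted[a]
      if (!atom_is_probe[a]) {
        base <- matrix(base_in[a, ], T, 3, byrow = TRUE)
      } else {
        inflag <- draws[atom_pair[a], ]
        base <- ifelse(matrix(inflag, T, 3),
                       matrix(base_in[a, ], T, 3, byrow = TRUE),
                       matrix(base_out[a, ], T, 3, byrow = TRUE))
      }
      xyz[, (3 * a - 2):(3 * a)] <- base + disp[, res, ]
    }
    ensembles[[config$states[s]]] <- new_ensemble(top, xyz,
                                                  state = config$states[s])
  }

  # ground truth
  p_planted <- array(0, c(N, N, S), dimnames = list(labs, labs, config$states))
  for (s in seq_len(S)) {
    pm <- matrix(0, N, N)
    pm[cbind(pairs$i, pairs$j)] <- pairs[[3 + s]]
    pm[cbind(pairs$j, pairs$i)] <- pairs[[3 + s]]
    p_planted[, , s] <- pm
  }
  delta_planted <- list()
  for (s in seq_len(S)) {
    s2 <- if (s == S) 1 else s + 1
    dp <- matrix(0, K, K, dimnames = list(paste0("C", 1:K), paste0("C", 1:K)))
    dvals <- pairs[[3 + s2]] - pairs[[3 + s]]
    cross <- comm[pairs$i] != comm[pairs$j]
    for (r in which(cross)) {
      ka <- comm[pairs$i[r]]; kb <- comm[pairs$j[r]]
      dp[ka, kb] <- dp[ka, kb] + dvals[r]
      dp[kb, ka] <- dp[kb, ka] + dvals[r]
    }
    diag(dp) <- NA
    delta_planted[[paste0(config$states[s], "->", config$states[s2])]] <- dp
  }
  truth <- list(membership = stats::setNames(comm, labs),
                p_planted = p_planted, delta_planted = delta_planted,
                pairs = pairs, rho = config$rho)
  list(ensembles = ensembles, truth = truth)
}

#' Toy weighted graph with brute-force oracles
#'
#' Either builds the graph from an explicit edge table or draws a connected
#' Erdos-Renyi graph with uniform random weights. Oracle helpers
#' (\code{\link{oracle_simple_paths}}, \code{\link{oracle_best_partition}},
#' \code{\link{oracle_edge_betweenness}}) give exhaustive references for
#' small graphs.
#'
#' @param edges optional data.frame (from, to, weight)
#' @param n,p Erdos-Renyi parameters when \code{edges} is NULL
#' @param weight_range uniform range for random edge weights
#' @param seed random seed (random mode)
#' @return an igraph graph with named vertices and a \code{weight} edge
#'   attribute
#' @export
generate_toy_graph <- function(edges = NULL, n = 8, p = 0.35,
                               weight_range = c(0.5, 1.5), seed = 1) {
  if (!is.null(edges)) {
    if (any(edges$weight < 0)) stop("negative edge weights not allowed")
    g <- igraph::graph_from_data_frame(edges, directed = FALSE)
    igraph::E(g)$weight <- edges$weight
    return(g)
  }
  set.seed(seed)
  names <- sprintf("%s", letters[seq_len(n)])
  repeat {
    adj <- which(upper.tri(matrix(0, n, n)) &
                   matrix(stats::runif(n * n) < p, n, n), arr.ind = TRUE)
    if (!nrow(adj)) next
    g <- igraph::make_empty_graph(n = n, directed = FALSE)
    g <- igraph::set_vertex_attr(g, "name", value = names)
    g <- igraph::add_edges(g, t(adj),
                           weight = stats::runif(nrow(adj), weight_range[1],
                                                 weight_range[2]))
    if (igraph::is_connected(g)) return(g)
  }
}

#' Exhaustive simple-path enumeration (oracle)
#'
#' All simple paths between two vertices by depth-first search, sorted by
#' total weight then lexicographically. Intended as a brute-force reference
#' for small graphs (guarded at 12 vertices).
#'
#' @param graph igraph graph with a weight edge attribute
#' @param source,target vertex names
#' @return list of (nodes, weight), as in a \code{PathSet}
#' @export
oracle_simple_paths <- function(graph, source, target) {
  g <- graph
  class(g) <- "igraph"
  if (igraph::vcount(g) > 12) stop("oracle limited to 12 vertices")
  w <- igraph::E(g)$weight %||% rep(1, igraph::ecount(g))
  adj <- igraph::adjacent_vertices(g, igraph::V(g))
  names(adj) <- igraph::V(g)$name
  out <- list()
  path <- character(0)
  dfs <- function(v, acc) {
    path[length(path) + 1] <<- v
    if (v == target) {
      out[[length(out) + 1]] <<- list(nodes = path, weight = acc)
    } else {
      for (u in setdiff(adj[[v]]$name, path)) {
        eid <- igraph::get_edge_ids(g, c(v, u))
        dfs(u, acc + w[eid])
      }
    }
    path <<- path[-length(path)]
  }
  dfs(source, 0)
  ws <- vapply_num(out, function(p) p$weight)
  keys <- vapply(out, function(p) .path_key(p$nodes), character(1))
  ord <- order(ws, keys, method = "radix")
  # group float-equal weights, lex order within groups
  out <- out[ord]
  ws <- ws[ord]
  i <- 1
  while (i < length(out)) {
    j <- i
    while (j < length(out) && ws[j + 1] <= ws[i] + 1e-12 * max(1, ws[i]))
      j <- j + 1
    if (j > i) {
      blk <- out[i:j]
      blk <- blk[order(vapply(blk, function(p) .path_key(p$nodes),
                              character(1)), method = "radix")]
      out[i:j] <- blk
    }
    i <- j + 1
  }
  out
}

# all set partitions of n elements as a Bell(n) x n matrix of restricted
# growth strings, built breadth-first and fully vectorized
.all_partitions <- function(n) {
  P <- matrix(1L, 1, 1)
  mx <- 1L
  for (k in seq_len(n)[-1]) {
    reps <- mx + 1L
    idx <- rep(seq_along(mx), reps)
    newv <- unlist(lapply(mx, function(m) seq_len(m + 1L)))
    P <- cbind(P[idx, , drop = FALSE], newv, deparse.level = 0)
    mx <- pmax(mx[idx], newv)
  }
  P
}

#' Exhaustive best-modularity partition (oracle)
#'
#' Enumerates every set partition of the vertices (guarded at 10 vertices),
#' optionally restricted to partitions whose communities induce connected
#' subgraphs (those reachable by divisive edge removal), and returns the
#' maximum-modularity partition.
#'
#' @param graph igraph graph (treated as unweighted)
#' @param connected_only restrict to connected communities
#' @return list with \code{membership} (named), \code{K}, \code{modularity}
#' @export
oracle_best_partition <- function(graph, connected_only = FALSE) {
  g <- graph
  class(g) <- "igraph"
  n <- igraph::vcount(g)
  if (n > 10) stop("oracle limited to 10 vertices")
  m <- igraph::ecount(g)
  ends <- igraph::ends(g, igraph::E(g), names = FALSE)
  deg <- igraph::degree(g)
  adj <- lapply(igraph::adjacent_vertices(g, igraph::V(g)), as.integer)
  connected_ok <- function(memb) {
    for (c in unique(memb)) {
      vs <- which(memb == c)
      if (length(vs) == 1) next
      seen <- vs[1]; front <- vs[1]
      while (length(front)) {
        nxt <- setdiff(intersect(unlist(adj[front]), vs), seen)
        seen <- c(seen, nxt); front <- nxt
      }
      if (length(seen) < length(vs)) return(FALSE)
    }
    TRUE
  }
  P <- .all_partitions(n)
  if (m == 0) {
    memb <- stats::setNames(rep(1L, n), igraph::V(g)$name)
    return(list(membership = memb, K = 1L, modularity = 0))
  }
  # vectorized Q over every partition: intra-edge fraction minus the
  # degree-based expectation
  intra_frac <- rowSums(P[, ends[, 1], drop = FALSE] ==
                          P[, ends[, 2], drop = FALSE]) / m
  dsq <- numeric(nrow(P))
  for (c in seq_len(n)) {
    d_c <- (P == c) %*% deg
    dsq <- dsq + (d_c / (2 * m))^2
  }
  q_all <- intra_frac - dsq
  ord <- order(q_all, decreasing = TRUE)
  pick <- ord[1]
  if (connected_only)
    for (r in ord) if (connected_ok(P[r, ])) { pick <- r; break }
  memb <- stats::setNames(as.integer(P[pick, ]), igraph::V(g)$name)
  list(membership = memb, K = max(memb), modularity = q_all[pick])
}

#' Brute-force edge betweenness (oracle)
#'
#' Enumerates all simple paths per vertex pair, keeps the minimum-weight
#' ones, and credits each edge fractionally. Guarded at 12 vertices.
#'
#' @param graph igraph graph; weight attribute used if present
#' @return numeric vector of betweenness per edge (edge order of the graph)
#' @export
oracle_edge_betweenness <- function(graph) {
  g <- graph
  class(g) <- "igraph"
  n <- igraph::vcount(g)
  if (n > 12) stop("oracle limited to 12 vertices")
  vn <- igraph::V(g)$name
  out <- numeric(igraph::ecount(g))
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    paths <- oracle_simple_paths(g, vn[a], vn[b])
    if (!length(paths)) next
    wmin <- paths[[1]]$weight
    short <- Filter(function(p) p$weight <= wmin + 1e-12 * max(1, wmin), paths)
    for (p in short) {
      eids <- igraph::get_edge_ids(g, rbind(p$nodes[-length(p$nodes)],
                                            p$nodes[-1]))
      out[eids] <- out[eids] + 1 / length(short)
    }
  }
  out
}
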