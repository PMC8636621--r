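# Correlation-weighted dynamic networks.
#
# Node positions are Calpha for amino acids and P for nucleotides (falling
# back to the residue heavy-atom centroid when the named atom is absent, or
# always when node_atom = "centroid"). Cross-correlation of positional
# fluctuations weights the persistent-contact edges as w = -ln|c|.

node_atom_coords <- function(ensemble, scope, node_atom = c("calpha", "centroid")) {
  node_atom <- match.arg(node_atom)
  top <- ensemble$topology
  nres <- length(scope)
  T <- ensemble$nframes
  out <- array(NA_real_, c(T, nres, 3))
  for (k in seq_len(nres)) {
    i <- scope[k]
    rows <- which(top$atom$resix == i & top$atom$element != "H")
    if (node_atom == "calpha") {
      want <- if (top$residues$polymer[i] == "nucleic") "P" else "CA"
      hit <- rows[toupper(top$atom$elety[rows]) == want]
      if (length(hit)) rows <- hit[1]
    }
    cols <- xyz_cols(rows)
    if (length(rows) == 1) {
      out[, k, ] <- ensemble$xyz[, cols, drop = FALSE]
    } else {
      xk <- ensemble$xyz[, cols, drop = FALSE]
      out[, k, 1] <- rowMeans(xk[, seq(1, ncol(xk), 3), drop = FALSE])
      out[, k, 2] <- rowMeans(xk[, seq(2, ncol(xk), 3), drop = FALSE])
      out[, k, 3] <- rowMeans(xk[, seq(3, ncol(xk), 3), drop = FALSE])
    }
  }
  out
}

# least-squares superposition of every frame onto the ensemble mean,
# iterated (fit -> new mean -> fit) to remove rigid-body drift
superpose_nodes <- function(coords, iterations = 2) {
  T <- dim(coords)[1]
  n <- dim(coords)[2]
  for (it in seq_len(iterations)) {
    mref <- apply(coords, c(2, 3), mean)
    for (t in seq_len(T)) {
      x <- matrix(coords[t, , ], n, 3)
      if (n < 3) {
        # rotation underdetermined: remove translation only
        coords[t, , ] <- sweep(x, 2, colMeans(x) - colMeans(mref))
      } else {
        k <- kabsch(x, mref)
        coords[t, , ] <- sweep(x, 2, k$center_x) %*% k$R +
          matrix(k$center_y, n, 3, byrow = TRUE)
      }
    }
  }
  coords
}

#' Cross-correlation matrix of residue positional fluctuations
#'
#' c_ij = <dr_i . dr_j> / (<|dr_i|^2>^1/2 <|dr_j|^2>^1/2), with dr the
#' node-atom deviation from its time average. Frames are least-squares
#' superposed onto the ensemble mean (iterated twice) before the averages
#' unless \code{fit = FALSE} (appropriate for ensembles known to carry no
#' rigid-body drift).
#'
#' @param ensemble an \code{Ensemble} with at least two frames
#' @param node_atom "calpha" (Calpha / nucleic P) or "centroid"
#' @param residue_scope selection (default: all polymer residues)
#' @param fit superpose frames before computing fluctuations
#' @return object of class \code{CorrelationMatrix}: residue table and
#'   symmetric matrix \code{c} with unit diagonal (zero-fluctuation
#'   residues get zero off-diagonal entries, with a warning)
#' @export
cross_correlation <- function(ensemble, node_atom = c("calpha", "centroid"),
                              residue_scope = NULL, fit = TRUE) {
  if (ensemble$nframes < 2) stop("cross-correlation needs at least 2 frames")
  top <- ensemble$topology
  scope <- if (is.null(residue_scope))
    which(top$residues$polymer != "other")
  else select_residues(top, residue_scope)
  coords <- node_atom_coords(ensemble, scope, node_atom)
  if (fit) coords <- superpose_nodes(coords)
  T <- dim(coords)[1]; n <- dim(coords)[2]
  dx <- coords[, , 1] - matrix(colMeans(coords[, , 1]), T, n, byrow = TRUE)
  dy <- coords[, , 2] - matrix(colMeans(coords[, , 2]), T, n, byrow = TRUE)
  dz <- coords[, , 3] - matrix(colMeans(coords[, , 3]), T, n, byrow = TRUE)
  cov <- (crossprod(dx) + crossprod(dy) + crossprod(dz)) / T
  v <- diag(cov)
  zero <- v <= .Machine$double.eps
  if (any(zero))
    warning(sum(zero), " residue(s) with zero fluctuation; their ",
            "correlations are undefined and set to 0")
  denom <- sqrt(v); denom[zero] <- 1
  cmat <- cov / tcrossprod(denom)
  cmat[zero, ] <- 0; cmat[, zero] <- 0
  diag(cmat)[!zero] <- 1
  labs <- residue_labels(top, scope)
  dimnames(cmat) <- list(labs, labs)
  structure(list(scope = scope, residues = top$residues[scope, , drop = FALSE],
                 c = cmat, node_atom = match.arg(node_atom), fitted = fit),
            class = "CorrelationMatrix")
}

#' Build the correlation-weighted dynamic network
#'
#' Edges connect residue pairs whose contact probability strictly exceeds
#' the persistence threshold (default 0.75) and whose correlation is
#' nonzero; weights are w = -ln|c| (clamped at 0 for |c| >= 1). A pair with
#' c = 0 carries no communication in this metric and is omitted.
#'
#' @param map a \code{ContactMap}
#' @param corr a \code{CorrelationMatrix} over the same residues
#' @param persistence fraction in [0, 1]
#' @return an igraph graph (class \code{WeightedNetwork} prepended) with
#'   vertex names = residue labels and edge attribute \code{weight}
#' @export
build_dynamic_network <- function(map, corr, persistence = 0.75) {
  if (!identical(rownames(map$p), rownames(corr$c)))
    stop("contact map and correlation matrix cover different residues")
  sel <- which(upper.tri(map$p) & map$p > persistence & corr$c != 0,
               arr.ind = TRUE)
  labs <- rownames(map$p)
  g <- igraph::make_empty_graph(n = length(labs), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = labs)
  if (nrow(sel)) {
    w <- pmax(0, -log(pmin(1, abs(corr$c[sel]))))
    g <- igraph::add_edges(g, t(cbind(sel[, 1], sel[, 2])), weight = w)
  }
  g$persistence <- persistence
  g$state <- map$state
  class(g) <- c("WeightedNetwork", class(g))
  g
}

#' Edge betweenness of a weighted network
#'
#' Count (unnormalized) of weighted shortest paths over all vertex pairs
#' traversing each edge, ties split fractionally.
#'
#' @param network an igraph graph; edge weights used if present
#' @return data.frame with columns from, to, betweenness
#' @export
edge_betweenness_scores <- function(network) {
  if (igraph::vcount(network) == 0) stop("empty network")
  w <- igraph::E(network)$weight
  b <- igraph::edge_betweenness(network, directed = FALSE, weights = w)
  ends <- igraph::ends(network, igraph::E(network))
  data.frame(from = ends[, 1], to = ends[, 2], betweenness = b,
             stringsAsFactors = FALSE)
}

#' Export a network as edge-list TSV (and optionally GraphML)
#' @param network an igraph graph
#' @param path output TSV path
#' @param graphml optional GraphML output path
#' @export
write_network <- function(network, path, graphml = NULL) {
  ends <- igraph::ends(network, igraph::E(network))
  df <- data.frame(from = ends[, 1], to = ends[, 2],
                   weight = igraph::E(network)$weight %||%
                     rep(1, igraph::ecount(network)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(graphml)) {
    g2 <- network
    class(g2) <- "igraph"
    igraph::write_graph(g2, graphml, format = "graphml")
  }
  invisible(path)
}
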