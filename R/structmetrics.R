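# Structural metrics: Shrake-Rupley solvent-accessible surface area,
# buried surface area with sub-group decomposition, ensemble-derived
# B-factors, and rigid-body rotation angles between conformers.

# Bondi van der Waals radii (Angstrom)
.vdw_radii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90,
                MG = 1.73, ZN = 1.39, FE = 2.00, MN = 2.00, `NA` = 2.27,
                K = 2.75, CA = 2.31)

atom_radii <- function(element, default_radius = 2.0) {
  r <- .vdw_radii[toupper(element)]
  if (anyNA(r)) {
    warning("unknown element(s) ",
            paste(unique(element[is.na(r)]), collapse = ", "),
            "; using default vdW radius ", default_radius, " A")
    r[is.na(r)] <- default_radius
  }
  unname(r)
}

# per-atom Shrake-Rupley areas for a coordinate/radius set
shrake_rupley <- function(co, radii, probe, n_points) {
  pts <- sphere_points(n_points)
  m <- nrow(co)
  rr <- radii + probe
  area <- numeric(m)
  for (a in seq_len(m)) {
    # neighbours whose expanded spheres can clip this atom's test sphere
    d2 <- (co[, 1] - co[a, 1])^2 + (co[, 2] - co[a, 2])^2 +
      (co[, 3] - co[a, 3])^2
    nb <- which(d2 < (rr[a] + rr)^2 & seq_len(m) != a)
    p <- pts * rr[a]
    p <- sweep(p, 2, co[a, ], "+")
    acc <- rep(TRUE, n_points)
    for (b in nb) {
      inside <- (p[, 1] - co[b, 1])^2 + (p[, 2] - co[b, 2])^2 +
        (p[, 3] - co[b, 3])^2 < rr[b]^2
      acc <- acc & !inside
      if (!any(acc)) break
    }
    area[a] <- 4 * pi * rr[a]^2 * sum(acc) / n_points
  }
  area
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' For each atom, the fraction of \code{n_points} quasi-uniform test points
#' on the probe-expanded sphere not buried inside any neighbour's expanded
#' sphere, times the expanded-sphere area. Hydrogens are excluded by
#' default (heavy-atom SASA); van der Waals radii follow the Bondi set.
#'
#' @param structure a \code{Structure}
#' @param probe probe radius in Angstrom
#' @param n_points test points per atom
#' @param keep_hydrogens include hydrogens in the calculation
#' @param atom_subset optional integer vector of atom rows to include
#' @return object of class \code{AreaReport}: per-atom and per-residue
#'   areas (A^2), total, probe and point count
#' @export
sasa <- function(structure, probe = 1.4, n_points = 960,
                 keep_hydrogens = FALSE, atom_subset = NULL) {
  a <- structure$atom
  rows <- atom_subset %||% seq_len(nrow(a))
  if (!keep_hydrogens) rows <- rows[a$element[rows] != "H"]
  if (!length(rows)) stop("no atoms selected for SASA")
  co <- as.matrix(a[rows, c("x", "y", "z")])
  radii <- atom_radii(a$element[rows])
  area <- shrake_rupley(co, radii, probe, n_points)
  resix <- a$resix[rows]
  per_res <- tapply(area, resix, sum)
  res_area <- stats::setNames(as.numeric(per_res),
                              residue_labels(structure,
                                             as.integer(names(per_res))))
  structure(list(atom_rows = rows, atom_area = area, residue_area = res_area,
                 total = sum(area), probe = probe, n_points = n_points),
            class = "AreaReport")
}

#' @export
print.AreaReport <- function(x, ...) {
  cat(sprintf("AreaReport: total SASA %.1f A^2 over %d atoms (probe %.2f A, %d points)\n",
              x$total, length(x$atom_rows), x$probe, x$n_points))
  invisible(x)
}

#' Buried surface area between two residue groups
#'
#' BSA = SASA(A alone) + SASA(B alone) - SASA(A and B together), reported
#' unhalved (total area buried on both sides); \code{halved = TRUE} divides
#' by two. Optional sub-groups of A are decomposed with the same formula
#' restricted to the sub-group's atoms (BSA(s, B)), with their percentage
#' of the pair total.
#'
#' @param structure a \code{Structure}
#' @param group_a,group_b disjoint selections (expression or indices)
#' @param subgroups_a optional named list of selections, each a subset of A
#' @param halved report per-side (halved) burial
#' @param probe,n_points as in \code{\link{sasa}}
#' @return list with \code{bsa}, \code{sasa_a}, \code{sasa_b},
#'   \code{sasa_ab} and \code{subgroups} (data.frame: name, bsa, percent)
#' @export
buried_surface_area <- function(structure, group_a, group_b,
                                subgroups_a = NULL, halved = FALSE,
                                probe = 1.4, n_points = 960) {
  ra <- select_residues(structure, group_a)
  rb <- select_residues(structure, group_b)
  if (!length(ra) || !length(rb)) stop("empty group selection")
  if (length(intersect(ra, rb))) stop("groups A and B overlap")
  atoms_of <- function(res) which(structure$atom$resix %in% res)
  s_of <- function(rows) sasa(structure, probe, n_points,
                              atom_subset = rows)$total
  aa <- atoms_of(ra); ab <- atoms_of(rb)
  sa <- s_of(aa); sb <- s_of(ab); sab <- s_of(c(aa, ab))
  bsa <- sa + sb - sab
  if (halved) bsa <- bsa / 2
  sub <- NULL
  if (!is.null(subgroups_a)) {
    rows <- lapply(subgroups_a, function(s) {
      rs <- select_residues(structure, s)
      if (length(setdiff(rs, ra)))
        stop("subgroup not contained in group A")
      atoms_of(rs)
    })
    vals <- vapply_num(rows, function(as_) {
      v <- s_of(as_) + sb - s_of(c(as_, ab))
      if (halved) v / 2 else v
    })
    sub <- data.frame(name = names(subgroups_a) %||%
                        paste0("sub", seq_along(subgroups_a)),
                      bsa = vals, percent = 100 * vals / bsa,
                      stringsAsFactors = FALSE)
  }
  list(bsa = bsa, sasa_a = sa, sasa_b = sb, sasa_ab = sab,
       halved = halved, subgroups = sub)
}

#' Ensemble-derived B-factors
#'
#' B_i = (8 pi^2 / 3) <|dr_i|^2>, the mean-square fluctuation of the
#' residue node atom (Calpha / nucleic P) about its ensemble mean after
#' least-squares superposition.
#'
#' @param ensemble an \code{Ensemble} with at least two frames
#' @param node_atom "calpha" or "centroid"
#' @param residue_scope selection (default all polymer residues)
#' @param fit superpose frames first (see \code{\link{cross_correlation}})
#' @return named numeric vector of B-factors (A^2) per residue
#' @export
computed_bfactors <- function(ensemble, node_atom = c("calpha", "centroid"),
                              residue_scope = NULL, fit = TRUE) {
  if (ensemble$nframes < 2)
    stop("B-factors are undefined for a single frame")
  top <- ensemble$topology
  scope <- if (is.null(residue_scope))
    which(top$residues$polymer != "other")
  else select_residues(top, residue_scope)
  coords <- node_atom_coords(ensemble, scope, node_atom)
  if (fit) coords <- superpose_nodes(coords)
  T <- dim(coords)[1]; n <- dim(coords)[2]
  msf <- numeric(n)
  for (d in 1:3) {
    x <- coords[, , d]
    msf <- msf + colMeans(sweep(x, 2, colMeans(x))^2)
  }
  stats::setNames((8 * pi^2 / 3) * msf, residue_labels(top, scope))
}

#' Rigid-body rotation of a substructure between two conformers
#'
#' Superposes \code{frame_b} onto \code{frame_a} using the \code{align_on}
#' selection, then extracts the optimal rotation carrying the
#' \code{duplex} atoms of a onto those of b; returns the rotation angle
#' (degrees) and axis.
#'
#' @param frame_a,frame_b \code{Structure}s with identical residue content
#' @param align_on selection used for the global superposition
#' @param duplex selection whose residual rotation is measured
#' @return list with \code{angle} (degrees) and \code{axis} (unit vector)
#' @export
duplex_rotation_angle <- function(frame_a, frame_b, align_on, duplex) {
  co <- function(s, res) {
    rows <- which(s$atom$resix %in% res & s$atom$element != "H")
    as.matrix(s$atom[rows, c("x", "y", "z")])
  }
  res_al_a <- select_residues(frame_a, align_on)
  res_al_b <- select_residues(frame_b, align_on)
  res_du_a <- select_residues(frame_a, duplex)
  res_du_b <- select_residues(frame_b, duplex)
  if (!identical(res_al_a, res_al_b) || !identical(res_du_a, res_du_b))
    stop("selections resolve differently in the two frames")
  xa <- co(frame_a, res_al_a); xb <- co(frame_b, res_al_b)
  if (nrow(xa) < 3) stop("need at least 3 atoms to superpose")
  fit <- kabsch(xb, xa)
  da <- co(frame_a, res_du_a)
  db <- co(frame_b, res_du_b)
  if (nrow(da) < 3) stop("need at least 3 duplex atoms")
  db_fit <- sweep(sweep(db, 2, fit$center_x) %*% fit$R, 2, fit$center_y, "+")
  rot <- kabsch(da, db_fit)
  if (abs(det(rot$R) - 1) > 1e-6 ||
      qr(sweep(da, 2, colMeans(da)))$rank < 2)
    stop("degenerate (collinear) duplex geometry")
  list(angle = rotation_angle(rot$R), axis = rotation_axis(rot$R))
}
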