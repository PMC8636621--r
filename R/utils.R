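`%||%` <- function(a, b) if (is.null(a)) b else a

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares rotation (and translation) carrying one coordinate set onto
#' another. Used for trajectory fitting, rotation-angle extraction and
#' B-factor computation.
#'
#' @param x,y numeric matrices (n x 3); \code{x} is rotated onto \code{y}.
#' @return list with \code{R} (3x3 rotation, proper), \code{center_x},
#'   \code{center_y} and \code{rmsd}. The transform is
#'   \code{(x - center_x) \%*\% R + center_y}.
#' @keywords internal
kabsch <- function(x, y) {
  stopifnot(is.matrix(x), is.matrix(y), ncol(x) == 3, ncol(y) == 3,
            nrow(x) == nrow(y), nrow(x) >= 3)
  cx <- colMeans(x); cy <- colMeans(y)
  xc <- sweep(x, 2, cx); yc <- sweep(y, 2, cy)
  s <- svd(crossprod(xc, yc))
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- xc %*% rot
  list(R = rot, center_x = cx, center_y = cy,
       rmsd = sqrt(mean(rowSums((fitted - yc)^2))))
}

#' Rotation angle of a 3x3 rotation matrix, in degrees
#' @keywords internal
rotation_angle <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  acos(min(1, max(-1, ct))) * 180 / pi
}

#' Rotation axis (unit vector) of a 3x3 rotation matrix
#' @keywords internal
rotation_axis <- function(R) {
  e <- eigen(R)
  i <- which.min(abs(Re(e$values) - 1))
  ax <- Re(e$vectors[, i])
  ax / sqrt(sum(ax^2))
}

#' Deterministic quasi-uniform points on the unit sphere (Fibonacci lattice)
#' @keywords internal
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Frames-by-3M coordinate matrix -> list utilities
#' @keywords internal
xyz_cols <- function(atom_idx) {
  c(rbind(3 * (atom_idx - 1) + 1, 3 * (atom_idx - 1) + 2, 3 * atom_idx))
}

vapply_num <- function(x, f, ...) vapply(x, f, numeric(1), ...)
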