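# Density maps: minimal MRC/CCP4 (mode 2) I/O, model-to-density simulation
# and map-to-model cross-correlation.

.atomic_number <- c(H = 1, C = 6, N = 7, O = 8, P = 15, S = 16, F = 9,
                    CL = 17, BR = 35, I = 53, SE = 34, MG = 12, ZN = 30,
                    FE = 26, MN = 25, `NA` = 11, K = 19, CA = 20)

#' Construct a DensityMap
#'
#' @param grid 3-D numeric array of density values
#' @param voxel voxel edge lengths in Angstrom (length 1 or 3)
#' @param origin Cartesian coordinates (Angstrom) of the first voxel centre
#' @param resolution declared map resolution in Angstrom (optional)
#' @export
new_density_map <- function(grid, voxel, origin = c(0, 0, 0),
                            resolution = NA_real_) {
  if (length(dim(grid)) != 3 || any(dim(grid) < 1))
    stop("grid must be a 3-D array")
  voxel <- rep(as.numeric(voxel), length.out = 3)
  if (any(voxel <= 0)) stop("voxel size must be positive")
  structure(list(grid = grid, voxel = voxel, origin = as.numeric(origin),
                 resolution = resolution), class = "DensityMap")
}

#' @export
print.DensityMap <- function(x, ...) {
  cat(sprintf("DensityMap: %s grid, voxel %.3f x %.3f x %.3f A, origin (%.1f, %.1f, %.1f)\n",
              paste(dim(x$grid), collapse = " x "), x$voxel[1], x$voxel[2],
              x$voxel[3], x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Read / write CCP4-MRC density maps (mode 2, float32)
#'
#' Handles the MAPC/MAPR/MAPS axis permutation and derives the origin from
#' ORIGIN fields when set, else from NxSTART times the voxel size.
#'
#' @param path file path
#' @return a \code{DensityMap}
#' @export
read_ccp4_map <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 1024)
  if (length(hdr) < 1024) stop("truncated MRC header in ", path)
  word_int <- function(i) readBin(hdr[(4 * (i - 1) + 1):(4 * i)], "integer",
                                  1, size = 4, endian = "little")
  word_num <- function(i) readBin(hdr[(4 * (i - 1) + 1):(4 * i)], "numeric",
                                  1, size = 4, endian = "little")
  nc <- word_int(1); nr <- word_int(2); ns <- word_int(3)
  mode <- word_int(4)
  if (mode != 2) stop("unsupported MRC mode ", mode, " (only mode 2, float32)")
  nstart <- c(word_int(5), word_int(6), word_int(7))
  mxyz <- c(word_int(8), word_int(9), word_int(10))
  cell <- vapply_num(11:13, word_num)
  mapcrs <- c(word_int(17), word_int(18), word_int(19))
  nsymbt <- word_int(24)
  origin_field <- vapply_num(50:52, word_num)
  if (nsymbt > 0) readBin(con, "raw", nsymbt)
  vals <- readBin(con, "numeric", nc * nr * ns, size = 4, endian = "little")
  if (length(vals) < nc * nr * ns) stop("truncated MRC data block in ", path)
  arr <- array(vals, dim = c(nc, nr, ns))
  voxel <- cell / pmax(1, mxyz)
  # permute from file (col,row,sec) storage to (x,y,z)
  perm <- order(mapcrs)
  arr <- aperm(arr, perm)
  origin <- if (any(origin_field != 0)) origin_field
            else nstart[perm] * voxel
  new_density_map(arr, voxel, origin)
}

#' @rdname read_ccp4_map
#' @param map a \code{DensityMap}
#' @export
write_ccp4_map <- function(map, path) {
  dm <- dim(map$grid)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(c(dm, 2, round(map$origin / map$voxel), dm)), con,
           size = 4, endian = "little")
  writeBin(as.numeric(c(dm * map$voxel, 90, 90, 90)), con, size = 4,
           endian = "little")
  writeBin(as.integer(c(1, 2, 3)), con, size = 4, endian = "little")
  writeBin(as.numeric(c(min(map$grid), max(map$grid), mean(map$grid))), con,
           size = 4, endian = "little")
  writeBin(as.integer(c(1, 0)), con, size = 4, endian = "little")  # ispg, nsymbt
  writeBin(raw(25 * 4), con)  # extra
  writeBin(as.numeric(map$origin), con, size = 4, endian = "little")  # words 50-52
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), con)  # little-endian stamp
  writeBin(as.numeric(stats::sd(map$grid)), con, size = 4, endian = "little")
  writeBin(as.integer(0), con, size = 4, endian = "little")  # nlabl
  writeBin(raw(800), con)
  writeBin(as.numeric(map$grid), con, size = 4, endian = "little")
  invisible(path)
}

#' Simulate a density map from an atomic model
#'
#' Sum of atom-centred isotropic Gaussians with sigma = \code{kernel_frac}
#' times the resolution and amplitude proportional to atomic number,
#' evaluated on a given grid or on a padded bounding-box grid.
#'
#' @param structure a \code{Structure}
#' @param resolution target resolution (Angstrom)
#' @param voxel voxel size when building a new grid
#' @param pad bounding-box padding (Angstrom)
#' @param on_grid optional \code{DensityMap} whose grid to reuse
#' @param kernel_frac Gaussian sigma as a fraction of the resolution
#' @return a \code{DensityMap}
#' @export
simulate_density <- function(structure, resolution, voxel = 1, pad = 5,
                             on_grid = NULL, kernel_frac = 0.225) {
  a <- structure$atom
  co <- as.matrix(a[, c("x", "y", "z")])
  zn <- .atomic_number[toupper(a$element)]
  zn[is.na(zn)] <- 6
  sigma <- kernel_frac * resolution
  if (is.null(on_grid)) {
    lo <- apply(co, 2, min) - pad
    hi <- apply(co, 2, max) + pad
    voxel <- rep(voxel, length.out = 3)
    dm <- pmax(2L, as.integer(ceiling((hi - lo) / voxel)) + 1L)
    origin <- lo
  } else {
    dm <- dim(on_grid$grid)
    voxel <- on_grid$voxel
    origin <- on_grid$origin
  }
  ax <- lapply(1:3, function(d) origin[d] + (seq_len(dm[d]) - 1) * voxel[d])
  lo_g <- vapply_num(ax, min); hi_g <- vapply_num(ax, max)
  if (any(apply(co, 2, min) < lo_g - 3 * sigma - 5) ||
      any(apply(co, 2, max) > hi_g + 3 * sigma + 5))
    stop("model lies outside the map grid")
  grid <- array(0, dm)
  reach <- 4 * sigma
  for (k in seq_len(nrow(co))) {
    rng <- lapply(1:3, function(d) {
      which(ax[[d]] >= co[k, d] - reach & ax[[d]] <= co[k, d] + reach)
    })
    if (!all(lengths(rng))) next
    gx <- exp(-(ax[[1]][rng[[1]]] - co[k, 1])^2 / (2 * sigma^2))
    gy <- exp(-(ax[[2]][rng[[2]]] - co[k, 2])^2 / (2 * sigma^2))
    gz <- exp(-(ax[[3]][rng[[3]]] - co[k, 3])^2 / (2 * sigma^2))
    grid[rng[[1]], rng[[2]], rng[[3]]] <-
      grid[rng[[1]], rng[[2]], rng[[3]]] +
      zn[k] * outer(outer(gx, gy), gz)
  }
  new_density_map(grid, voxel, origin, resolution)
}

#' Map-to-model cross-correlation coefficient
#'
#' Simulates a density from the model on the experimental map's grid and
#' returns the Pearson correlation between simulated and experimental
#' values over the simulated envelope (voxels where the simulated density
#' exceeds \code{envelope_frac} of its maximum), or over all voxels about
#' the mean with \code{domain = "about-mean"}.
#'
#' @param structure a \code{Structure}
#' @param map a \code{DensityMap}
#' @param resolution resolution for the simulation kernel (defaults to the
#'   map's declared resolution)
#' @param domain "envelope" or "about-mean"
#' @param envelope_frac envelope threshold as a fraction of the simulated
#'   maximum
#' @param kernel_frac Gaussian sigma as a fraction of the resolution
#' @return CCC in [-1, 1]
#' @export
map_model_ccc <- function(structure, map, resolution = NULL,
                          domain = c("envelope", "about-mean"),
                          envelope_frac = 0.01, kernel_frac = 0.225) {
  domain <- match.arg(domain)
  resolution <- resolution %||% map$resolution
  if (is.na(resolution)) stop("resolution required")
  sim <- simulate_density(structure, resolution, on_grid = map,
                          kernel_frac = kernel_frac)
  s <- as.numeric(sim$grid); e <- as.numeric(map$grid)
  if (domain == "envelope") {
    sel <- s > envelope_frac * max(s)
    s <- s[sel]; e <- e[sel]
  }
  if (stats::sd(s) == 0 || stats::sd(e) == 0) return(0)
  stats::cor(s, e)
}
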