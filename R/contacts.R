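# Residue-residue contact probabilities over an ensemble.
#
# A contact is a residue pair with at least one heavy-atom pair within the
# distance cutoff (default 4.5 A, inclusive). Contact probability is the
# fraction of frames in which the pair is in contact. Sequence-adjacent
# pairs within a chain are excluded (covalent neighbours are trivially in
# contact); the exclusion window is configurable.

#' Is a residue pair in contact in a single frame?
#'
#' @param frame M x 3 coordinate matrix congruent with \code{structure}
#' @param structure the \code{Structure} describing the atoms
#' @param i,j residue indices (rows of \code{structure$residues})
#' @param cutoff heavy-atom distance cutoff in Angstrom (inclusive)
#' @return TRUE iff the minimum heavy-atom distance between the residues
#'   is <= cutoff
#' @export
residue_contact_frame <- function(frame, structure, i, j, cutoff = 4.5) {
  if (i == j) stop("i and j must differ")
  heavy <- structure$atom$element != "H"
  ai <- which(structure$atom$resix == i & heavy)
  aj <- which(structure$atom$resix == j & heavy)
  if (!length(ai) || !length(aj))
    stop("residue without heavy atoms: ",
         residue_labels(structure, c(i, j)[c(!length(ai), !length(aj))][1]))
  d2 <- outer(seq_along(ai), seq_along(aj), function(a, b)
    (frame[ai[a], 1] - frame[aj[b], 1])^2 +
    (frame[ai[a], 2] - frame[aj[b], 2])^2 +
    (frame[ai[a], 3] - frame[aj[b], 3])^2)
  min(d2) <= cutoff^2
}

#' Contact-probability map of an ensemble
#'
#' For every residue pair in scope, the fraction of frames in which any
#' heavy-atom pair is within \code{cutoff}. Pairs of sequence-adjacent
#' residues in the same chain (|resno difference| <= \code{exclude_within})
#' are recorded as 0.
#'
#' Implementation detail: per-atom bounding boxes over all frames prune the
#' atom pairs that can never meet the cutoff, so cost scales with the number
#' of near-contact atom pairs rather than with all pairs in every frame.
#'
#' @param ensemble an \code{Ensemble}
#' @param cutoff contact cutoff in Angstrom (inclusive)
#' @param residue_scope selection expression / indices (default: all polymer
#'   residues; ions and ligands excluded)
#' @param exclude_within same-chain resno separation treated as bonded
#' @return object of class \code{ContactMap}: state label, scope residue
#'   table, symmetric probability matrix \code{p}, cutoff, frame count
#' @export
compute_contact_map <- function(ensemble, cutoff = 4.5, residue_scope = NULL,
                                exclude_within = 1) {
  top <- ensemble$topology
  scope <- if (is.null(residue_scope))
    which(top$residues$polymer != "other")
  else select_residues(top, residue_scope)
  if (!length(scope)) stop("empty residue scope")
  nres <- length(scope)
  res_of <- match(top$atom$resix, scope)  # NA = out of scope
  heavy <- top$atom$element != "H" & !is.na(res_of)
  aidx <- which(heavy)
  if (!length(aidx)) stop("no heavy atoms in scope")
  m <- length(aidx)
  T <- ensemble$nframes

  xyzc <- ensemble$xyz[, xyz_cols(aidx), drop = FALSE]
  xs <- xyzc[, seq(1, 3 * m, by = 3), drop = FALSE]
  ys <- xyzc[, seq(2, 3 * m, by = 3), drop = FALSE]
  zs <- xyzc[, seq(3, 3 * m, by = 3), drop = FALSE]
  lo <- rbind(apply(xs, 2, min), apply(ys, 2, min), apply(zs, 2, min))
  hi <- rbind(apply(xs, 2, max), apply(ys, 2, max), apply(zs, 2, max))

  # residue pair exclusion mask (same chain, close in sequence)
  rtab <- top$residues[scope, , drop = FALSE]
  excl_pair <- function(ri, rj)
    rtab$chain[ri] == rtab$chain[rj] &
      abs(rtab$resno[ri] - rtab$resno[rj]) <= exclude_within

  # candidate atom pairs by bounding-box separation
  gap <- function(k) pmax(outer(lo[k, ], hi[k, ], "-"),
                          t(outer(lo[k, ], hi[k, ], "-")), 0)
  boxd2 <- gap(1)^2 + gap(2)^2 + gap(3)^2
  ra <- res_of[aidx]
  same_res <- outer(ra, ra, "==")
  cand <- which(boxd2 <= cutoff^2 & !same_res & upper.tri(boxd2),
                arr.ind = TRUE)

  counts <- matrix(0L, nres, nres)
  if (nrow(cand)) {
    pr_i <- ra[cand[, 1]]; pr_j <- ra[cand[, 2]]
    keep <- !excl_pair(pr_i, pr_j)
    cand <- cand[keep, , drop = FALSE]
    pr_i <- pr_i[keep]; pr_j <- pr_j[keep]
    if (nrow(cand)) {
      pair_key <- paste(pmin(pr_i, pr_j), pmax(pr_i, pr_j))
      for (k in unique(pair_key)) {
        rows <- which(pair_key == k)
        incontact <- rep(FALSE, T)
        for (r in rows) {
          a <- cand[r, 1]; b <- cand[r, 2]
          d2 <- (xs[, a] - xs[, b])^2 + (ys[, a] - ys[, b])^2 +
            (zs[, a] - zs[, b])^2
          incontact <- incontact | (d2 <= cutoff^2)
          if (all(incontact)) break
        }
        ri <- pr_i[rows[1]]; rj <- pr_j[rows[1]]
        counts[ri, rj] <- counts[rj, ri] <- sum(incontact)
      }
    }
  }
  p <- counts / T
  dimnames(p) <- list(residue_labels(top, scope), residue_labels(top, scope))
  structure(list(state = ensemble$state, scope = scope, residues = rtab,
                 p = p, cutoff = cutoff, nframes = T,
                 exclude_within = exclude_within),
            class = "ContactMap")
}

#' @export
print.ContactMap <- function(x, ...) {
  nz <- sum(x$p[upper.tri(x$p)] > 0)
  cat(sprintf(
    "ContactMap '%s': %d residues, %d contacting pairs, cutoff %.2f A, %d frames\n",
    x$state, nrow(x$residues), nz, x$cutoff, x$nframes))
  invisible(x)
}

#' Persistent contacts of a contact map
#'
#' Pairs whose contact probability strictly exceeds \code{threshold}
#' (default 0.5: contacts present in more than half of the frames), sorted
#' by decreasing probability, then by residue indices.
#'
#' @param map a \code{ContactMap}
#' @param threshold persistence fraction in [0, 1]
#' @return data.frame with columns i, j (scope-relative indices), res_i,
#'   res_j (labels), p
#' @export
persistent_contacts <- function(map, threshold = 0.5) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  ut <- which(upper.tri(map$p) & map$p > threshold, arr.ind = TRUE)
  lab <- rownames(map$p)
  out <- data.frame(i = ut[, 1], j = ut[, 2],
                    res_i = lab[ut[, 1]], res_j = lab[ut[, 2]],
                    p = map$p[ut], stringsAsFactors = FALSE)
  out <- out[order(-out$p, out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write / read a contact map as TSV
#'
#' Columns: chain_a, resid_a, chain_b, resid_b, probability (upper-triangle
#' nonzero entries). Metadata (state, cutoff, frames) goes in '#' header
#' lines so the file round-trips.
#' @param map a \code{ContactMap}
#' @param path file path
#' @export
write_contact_map <- function(map, path) {
  ut <- which(upper.tri(map$p) & map$p > 0, arr.ind = TRUE)
  df <- data.frame(chain_a = map$residues$chain[ut[, 1]],
                   resid_a = map$residues$resno[ut[, 1]],
                   chain_b = map$residues$chain[ut[, 2]],
                   resid_b = map$residues$resno[ut[, 2]],
                   probability = map$p[ut])
  df <- df[order(ut[, 1], ut[, 2]), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# state=%s", map$state),
               sprintf("# cutoff=%g", map$cutoff),
               sprintf("# frames=%d", map$nframes),
               sprintf("# residues=%s",
                       paste(rownames(map$p), collapse = ","))), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_contact_map
#' @export
read_contact_map <- function(path) {
  hdr <- readLines(path, n = 10)
  hdr <- hdr[startsWith(hdr, "#")]
  getv <- function(k) sub(paste0("^# ", k, "="), "",
                          hdr[startsWith(hdr, paste0("# ", k, "="))][1])
  labs <- strsplit(getv("residues"), ",")[[1]]
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "integer", "character",
                                         "integer", "numeric"))
  n <- length(labs)
  p <- matrix(0, n, n, dimnames = list(labs, labs))
  la <- paste0(df$chain_a, ":", df$resid_a)
  lb <- paste0(df$chain_b, ":", df$resid_b)
  ia <- match(la, labs); ib <- match(lb, labs)
  if (anyNA(ia) || anyNA(ib)) stop("contact map TSV refers to unknown residues")
  p[cbind(ia, ib)] <- df$probability
  p[cbind(ib, ia)] <- df$probability
  parts <- do.call(rbind, strsplit(labs, ":", fixed = TRUE))
  residues <- data.frame(chain = parts[, 1],
                         resno = as.integer(gsub("[A-Za-z]+$", "", parts[, 2])),
                         insert = gsub("^-?[0-9]+", "", parts[, 2]),
                         resname = NA_character_, polymer = NA_character_,
                         stringsAsFactors = FALSE)
  structure(list(state = getv("state"), scope = seq_len(n),
                 residues = residues, p = p,
                 cutoff = as.numeric(getv("cutoff")),
                 nframes = as.integer(getv("frames")), exclude_within = NA),
            class = "ContactMap")
}
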