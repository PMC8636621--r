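# Chemical classification of residue-residue contacts.
#
# Geometric criteria (documented defaults, config-overridable):
#   salt bridge : basic side-chain N (Lys NZ; Arg NE/NH1/NH2; His ND1/NE2)
#                 to acidic side-chain O (Asp OD1/OD2; Glu OE1/OE2; terminal
#                 OXT) or nucleic phosphate O (OP1/OP2/O1P/O2P), d <= 4.0 A
#   hydrogen bond: donor heavy atom to acceptor heavy atom, d <= 3.5 A;
#                 when the donor carries a resolved hydrogen the
#                 donor-H...acceptor angle must be >= 120 degrees,
#                 otherwise the heavy-atom distance alone decides
#   hydrophobic : apolar carbon to apolar carbon, d <= 4.5 A, side-chain
#                 atoms only
# Per frame a contact may satisfy several criteria; the most specific wins
# (salt bridge > hydrogen bond > hydrophobic). The reported class is the one
# with the highest persistence fraction; "other" if none exceeds the
# persistence threshold.

.basic_n <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                 HIS = c("ND1", "NE2"), HSP = c("ND1", "NE2"),
                 HIP = c("ND1", "NE2"))
.acidic_o <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
.phosphate_o <- c("OP1", "OP2", "O1P", "O2P")

.donor_atoms <- list(
  ARG = c("NE", "NH1", "NH2"), ASN = "ND2", GLN = "NE2",
  HIS = c("ND1", "NE2"), LYS = "NZ", SER = "OG", THR = "OG1",
  TYR = "OH", TRP = "NE1", CYS = "SG")
.acceptor_atoms <- list(
  ASN = "OD1", GLN = "OE1", ASP = c("OD1", "OD2"),
  GLU = c("OE1", "OE2"), HIS = c("ND1", "NE2"), SER = "OG", THR = "OG1",
  TYR = "OH", MET = "SD")
.nuc_donor <- c("O2'", "N1", "N2", "N3", "N4", "N6")
.nuc_acceptor <- c("O2", "O4", "O6", "N1", "N3", "N7",
                   "O2'", "O3'", "O4'", "O5'", "OP1", "OP2", "O1P", "O2P")
# carbons covalently bonded to N/O are not apolar
.polar_carbons <- list(ARG = "CZ", ASN = "CG", ASP = "CG", GLN = "CD",
                       GLU = "CD", HIS = c("CG", "CD2", "CE1"),
                       TYR = "CZ", TRP = c("CD1", "CE2"))

#' Contact classification criteria
#'
#' @param salt_bridge,hbond,hydrophobic distance cutoffs in Angstrom
#' @param hbond_angle minimum donor-H...acceptor angle (degrees), applied
#'   only when hydrogens are present
#' @param persistence fraction of frames a class criterion must hold for
#'   the contact to be assigned that class rather than "other"
#' @export
contact_class_criteria <- function(salt_bridge = 4.0, hbond = 3.5,
                                   hydrophobic = 4.5, hbond_angle = 120,
                                   persistence = 0.5) {
  list(salt_bridge = salt_bridge, hbond = hbond, hydrophobic = hydrophobic,
       hbond_angle = hbond_angle, persistence = persistence)
}

res_atom_roles <- function(structure, i) {
  rows <- which(structure$atom$resix == i)
  a <- structure$atom[rows, , drop = FALSE]
  resname <- toupper(structure$residues$resname[i])
  pol <- structure$residues$polymer[i]
  nm <- toupper(a$elety)
  standard <- pol %in% c("protein", "nucleic") &&
    (resname %in% names(c(.donor_atoms, .acceptor_atoms, .basic_n,
                          .acidic_o, .polar_carbons)) ||
       resname %in% .AA3 || resname %in% .NUC)
  if (pol == "protein") {
    basic <- nm %in% (.basic_n[[resname]] %||% character(0))
    acidic <- nm %in% c(.acidic_o[[resname]] %||% character(0), "OXT")
    donor <- nm == "N" | nm %in% (.donor_atoms[[resname]] %||% character(0))
    acceptor <- nm %in% c("O", "OXT") |
      nm %in% (.acceptor_atoms[[resname]] %||% character(0))
    apolar <- a$element == "C" & !(nm %in% c("C", "CA")) &
      !(nm %in% (.polar_carbons[[resname]] %||% character(0)))
  } else if (pol == "nucleic") {
    basic <- rep(FALSE, nrow(a))
    acidic <- nm %in% .phosphate_o
    donor <- nm %in% .nuc_donor
    acceptor <- nm %in% .nuc_acceptor
    apolar <- a$element == "C" & !grepl("'", nm, fixed = TRUE)
  } else {
    # generic typing for nonstandard residues
    basic <- a$element == "N"
    acidic <- a$element == "O"
    donor <- a$element %in% c("N", "O")
    acceptor <- a$element %in% c("N", "O")
    apolar <- a$element == "C"
    standard <- FALSE
  }
  list(rows = rows, names = nm, element = a$element, basic = basic,
       acidic = acidic, donor = donor, acceptor = acceptor, apolar = apolar,
       standard = standard)
}

#' Classify a residue-residue contact chemically
#'
#' Evaluates the salt-bridge, hydrogen-bond and hydrophobic criteria in
#' every frame and reports per-class persistence fractions plus the winning
#' class (most specific criterion on ties).
#'
#' @param ensemble an \code{Ensemble}
#' @param i,j residue indices
#' @param criteria see \code{\link{contact_class_criteria}}
#' @return list with \code{class} and \code{persistence} (named vector for
#'   salt-bridge / hydrogen-bond / hydrophobic)
#' @export
classify_contact <- function(ensemble, i, j,
                             criteria = contact_class_criteria()) {
  top <- ensemble$topology
  ri <- res_atom_roles(top, i)
  rj <- res_atom_roles(top, j)
  if (!ri$standard || !rj$standard)
    warning("nonstandard residue in pair ",
            paste(residue_labels(top, c(i, j)), collapse = " - "),
            "; using generic donor/acceptor/apolar atom typing")
  T <- ensemble$nframes
  sb <- hb <- hp <- logical(T)

  pair_min_d2 <- function(co, rows_a, rows_b) {
    if (!length(rows_a) || !length(rows_b)) return(Inf)
    min(outer(rows_a, rows_b, function(a, b)
      (co[a, 1] - co[b, 1])^2 + (co[a, 2] - co[b, 2])^2 +
        (co[a, 3] - co[b, 3])^2))
  }
  hb_ok <- function(co, don, acc, don_roles) {
    # donor heavy -> acceptor distance; angle check if donor has hydrogens
    for (d in don) for (a in acc) {
      d2 <- sum((co[d, ] - co[a, ])^2)
      if (d2 > criteria$hbond^2) next
      hs <- don_roles$rows[don_roles$element == "H"]
      if (length(hs)) {
        hd <- hs[rowSums(sweep(co[hs, , drop = FALSE], 2, co[d, ])^2) <= 1.25^2]
        if (length(hd)) {
          ok <- FALSE
          for (h in hd) {
            v1 <- co[d, ] - co[h, ]; v2 <- co[a, ] - co[h, ]
            ang <- acos(min(1, max(-1, sum(v1 * v2) /
                                     sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
            if (ang >= criteria$hbond_angle) { ok <- TRUE; break }
          }
          if (!ok) next
        }
      }
      return(TRUE)
    }
    FALSE
  }

  for (t in seq_len(T)) {
    co <- get_frame(ensemble, t)
    sb[t] <-
      pair_min_d2(co, ri$rows[ri$basic], rj$rows[rj$acidic]) <= criteria$salt_bridge^2 ||
      pair_min_d2(co, rj$rows[rj$basic], ri$rows[ri$acidic]) <= criteria$salt_bridge^2
    hb[t] <- hb_ok(co, ri$rows[ri$donor], rj$rows[rj$acceptor], ri) ||
      hb_ok(co, rj$rows[rj$donor], ri$rows[ri$acceptor], rj)
    hp[t] <- pair_min_d2(co, ri$rows[ri$apolar], rj$rows[rj$apolar]) <=
      criteria$hydrophobic^2
  }
  pers <- c(`salt-bridge` = mean(sb), `hydrogen-bond` = mean(hb),
            hydrophobic = mean(hp))
  cls <- if (max(pers) > criteria$persistence)
    names(pers)[which.max(pers)]  # which.max keeps precedence order on ties
  else "other"
  list(class = cls, persistence = pers)
}
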