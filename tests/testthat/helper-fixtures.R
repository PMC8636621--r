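# Fixtures built in code: tiny structures, hand-written PDB/mmCIF text,
# a minimal DCD writer, and reference graphs.

mk_structure <- function(...) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  if (is.null(df$insert)) df$insert <- ""
  if (is.null(df$occ)) df$occ <- 1
  if (is.null(df$b)) df$b <- 0
  new_structure(df)
}

# one-bead-per-residue helper
bead_structure <- function(chain, resno, x, y = 0, z = 0, resname = "ALA",
                           elety = "CA", element = "C") {
  mk_structure(chain = chain, resno = resno, insert = "", resname = resname,
               elety = elety, element = element, x = x, y = y, z = z)
}

# three-residue protein fixture with side-chain atoms for classification:
# A:1 LYS (NZ), A:2 GLU (OE1), A:3 SER (OG)
classify_fixture <- function(d_nz_oe1 = 3.2, d_og = 30) {
  mk_structure(
    chain = "A",
    resno = c(1, 1, 1, 2, 2, 2, 3, 3, 3),
    resname = c("LYS", "LYS", "LYS", "GLU", "GLU", "GLU", "SER", "SER", "SER"),
    elety = c("N", "CA", "NZ", "N", "CA", "OE1", "N", "CA", "OG"),
    element = c("N", "C", "N", "N", "C", "O", "N", "C", "O"),
    x = c(-8, -7, 0, 10, 11, d_nz_oe1, d_og, d_og + 1, d_og + 2),
    y = 0, z = 0)
}

# static ensemble: repeat a structure's coordinates over T frames
static_ensemble <- function(structure, T = 5, state = "apo") {
  co <- as.numeric(t(as.matrix(structure$atom[, c("x", "y", "z")])))
  new_ensemble(structure, matrix(rep(co, each = T), nrow = T), state = state)
}

# hand-written three-residue PDB text (two chains, one nucleic residue)
fixture_pdb_lines <- function() {
  c("ATOM      1  N   ALA A 320      11.104   6.134  -6.504  1.00 10.00           N",
    "ATOM      2  CA  ALA A 320      11.639   6.071  -5.147  1.00 10.00           C",
    "ATOM      3  CA  GLY A 321      14.500   7.100  -4.000  1.00 11.00           C",
    "ATOM      4  P    DA B   5       2.000   3.000   4.000  1.00 12.00           P",
    "END")
}

# the same fixture rendered as mmCIF
fixture_cif_lines <- function() {
  c("data_fixture",
    "#",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_entity_id",
    "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 N N . ALA A 1 1 ? 11.104 6.134 -6.504 1.00 10.00 ? 320 ALA A N 1",
    "ATOM 2 C CA . ALA A 1 1 ? 11.639 6.071 -5.147 1.00 10.00 ? 320 ALA A CA 1",
    "ATOM 3 C CA . GLY A 1 2 ? 14.500 7.100 -4.000 1.00 11.00 ? 321 GLY A CA 1",
    "ATOM 4 P P . DA B 2 1 ? 2.000 3.000 4.000 1.00 12.00 ? 5 DA B P 1",
    "#")
}

# PDB with two altlocs for one side chain (A occ 0.6, B occ 0.4)
fixture_altloc_lines <- function() {
  c("ATOM      1  N   SER A  10       0.000   0.000   0.000  1.00 10.00           N",
    "ATOM      2  CA  SER A  10       1.400   0.000   0.000  1.00 10.00           C",
    "ATOM      3  OG ASER A  10       2.000   1.000   0.000  0.60 10.00           O",
    "ATOM      4  OG BSER A  10       2.000  -1.000   0.000  0.40 10.00           O",
    "END")
}

# minimal X-PLOR style DCD (no unit cell), readable by bio3d::read.dcd
write_minimal_dcd <- function(xyz, path) {
  T <- nrow(xyz); natom <- ncol(xyz) / 3
  con <- file(path, "wb")
  on.exit(close(con))
  rec <- function(writer) {
    # Fortran record: length marker, payload, length marker
    tmp <- raw(0)
    tcon <- rawConnection(tmp, "wb")
    writer(tcon)
    payload <- rawConnectionValue(tcon)
    close(tcon)
    writeBin(length(payload), con, size = 4, endian = "little")
    writeBin(payload, con)
    writeBin(length(payload), con, size = 4, endian = "little")
  }
  rec(function(c2) {
    writeBin(charToRaw("CORD"), c2)
    icntrl <- integer(20)
    icntrl[1] <- T
    writeBin(icntrl, c2, size = 4, endian = "little")
  })
  rec(function(c2) {
    writeBin(1L, c2, size = 4, endian = "little")
    title <- sprintf("%-80s", "synthetic fixture")
    writeBin(charToRaw(title), c2)
  })
  rec(function(c2) writeBin(as.integer(natom), c2, size = 4,
                            endian = "little"))
  for (t in seq_len(T)) {
    co <- matrix(xyz[t, ], ncol = 3, byrow = TRUE)
    for (d in 1:3)
      rec(function(c2) writeBin(as.numeric(co[, d]), c2, size = 4,
                                endian = "little"))
  }
  invisible(path)
}

# barbell(4,4): two 4-cliques joined by one bridge, unit weights
barbell_graph <- function() {
  ed <- NULL
  for (cl in list(letters[1:4], letters[5:8]))
    for (i in 1:3) for (j in (i + 1):4)
      ed <- rbind(ed, data.frame(from = cl[i], to = cl[j], weight = 1))
  ed <- rbind(ed, data.frame(from = "d", to = "e", weight = 1))
  generate_toy_graph(edges = ed)
}

expect_same_paths <- function(got, want) {
  expect_equal(length(got), length(want))
  for (i in seq_along(got)) {
    expect_identical(got[[i]]$nodes, want[[i]]$nodes)
    expect_equal(got[[i]]$weight, want[[i]]$weight, tolerance = 1e-9)
  }
}
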