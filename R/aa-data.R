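# Static amino-acid knowledge: codes, masses, radii, pharmacophore lookup and
# idealized side-chain internal coordinates used for mutant modelling.

#' @keywords internal
aa_three_to_one_tbl <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

#' @keywords internal
aa_one_to_three_tbl <- stats::setNames(names(aa_three_to_one_tbl),
                                       unname(aa_three_to_one_tbl))

# modified / non-standard residues mapped to their parent amino acid
nonstandard_aa_map <- c(
  MSE = "MET", SEC = "CYS", SEP = "SER", TPO = "THR", PTR = "TYR",
  CSO = "CYS", HYP = "PRO", MLY = "LYS", PCA = "GLU", CME = "CYS"
)

# average residue masses in unified atomic mass units (Da)
aa_residue_mass <- c(
  A = 71.079,  R = 156.188, N = 114.104, D = 115.089, C = 103.144,
  Q = 128.131, E = 129.116, G = 57.052,  H = 137.141, I = 113.160,
  L = 113.160, K = 128.174, M = 131.198, F = 147.177, P = 97.117,
  S = 87.078,  T = 101.105, W = 186.213, Y = 163.176, V = 99.133
)

# van der Waals radii (Angstrom) by element, used by the SASA machinery
element_vdw_radius <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20,
                        P = 1.80)

#' @keywords internal
default_vdw_radius <- 1.70

#' Infer element from a PDB atom name
#' @keywords internal
element_from_atom_name <- function(name) {
  first <- substr(gsub("[0-9 ']", "", toupper(name)), 1, 1)
  ifelse(first %in% c("C", "N", "O", "S", "P", "H"), first, "C")
}

pharmacophore_classes <- c("hydrophobic", "positive", "negative",
                           "acceptor", "donor", "aromatic", "sulfur",
                           "neutral")

# Backbone heavy atoms share the same classes in every residue type:
# amide nitrogen donates, carbonyl oxygen accepts, C-alpha is apolar carbon
# and the carbonyl carbon is polarized but neither donor nor acceptor.
.backbone_pharma <- list(N = "donor", CA = "hydrophobic", C = "neutral",
                         O = "acceptor", OXT = "acceptor")

# Side-chain atom classes. Formal charges are counted once per charged group
# (carboxylate carbon, guanidinium carbon, ammonium nitrogen) so that class
# deltas between residues track net charge changes.
.sidechain_pharma <- list(
  ALA = list(CB = "hydrophobic"),
  ARG = list(CB = "hydrophobic", CG = "hydrophobic", CD = "neutral",
             NE = "donor", CZ = "positive", NH1 = "donor", NH2 = "donor"),
  ASN = list(CB = "hydrophobic", CG = "neutral", OD1 = "acceptor",
             ND2 = "donor"),
  ASP = list(CB = "hydrophobic", CG = "negative", OD1 = "acceptor",
             OD2 = "acceptor"),
  CYS = list(CB = "hydrophobic", SG = "sulfur"),
  GLN = list(CB = "hydrophobic", CG = "hydrophobic", CD = "neutral",
             OE1 = "acceptor", NE2 = "donor"),
  GLU = list(CB = "hydrophobic", CG = "hydrophobic", CD = "negative",
             OE1 = "acceptor", OE2 = "acceptor"),
  GLY = list(),
  HIS = list(CB = "hydrophobic", CG = "aromatic",
             ND1 = c("acceptor", "aromatic"), CD2 = c("aromatic"),
             CE1 = c("aromatic"), NE2 = c("donor", "aromatic")),
  ILE = list(CB = "hydrophobic", CG1 = "hydrophobic", CG2 = "hydrophobic",
             CD1 = "hydrophobic"),
  LEU = list(CB = "hydrophobic", CG = "hydrophobic", CD1 = "hydrophobic",
             CD2 = "hydrophobic"),
  LYS = list(CB = "hydrophobic", CG = "hydrophobic", CD = "hydrophobic",
             CE = "neutral", NZ = c("positive", "donor")),
  MET = list(CB = "hydrophobic", CG = "hydrophobic", SD = "sulfur",
             CE = "hydrophobic"),
  PHE = list(CB = "hydrophobic",
             CG = c("aromatic", "hydrophobic"), CD1 = c("aromatic", "hydrophobic"),
             CD2 = c("aromatic", "hydrophobic"), CE1 = c("aromatic", "hydrophobic"),
             CE2 = c("aromatic", "hydrophobic"), CZ = c("aromatic", "hydrophobic")),
  PRO = list(CB = "hydrophobic", CG = "hydrophobic", CD = "hydrophobic"),
  SER = list(CB = "neutral", OG = c("donor", "acceptor")),
  THR = list(CB = "neutral", OG1 = c("donor", "acceptor"),
             CG2 = "hydrophobic"),
  TRP = list(CB = "hydrophobic", CG = "aromatic",
             CD1 = "aromatic", CD2 = c("aromatic", "hydrophobic"),
             NE1 = c("donor", "aromatic"), CE2 = "aromatic",
             CE3 = c("aromatic", "hydrophobic"), CZ2 = c("aromatic", "hydrophobic"),
             CZ3 = c("aromatic", "hydrophobic"), CH2 = c("aromatic", "hydrophobic")),
  TYR = list(CB = "hydrophobic",
             CG = c("aromatic", "hydrophobic"), CD1 = c("aromatic", "hydrophobic"),
             CD2 = c("aromatic", "hydrophobic"), CE1 = c("aromatic", "hydrophobic"),
             CE2 = c("aromatic", "hydrophobic"), CZ = c("aromatic", "hydrophobic"),
             OH = c("donor", "acceptor")),
  VAL = list(CB = "hydrophobic", CG1 = "hydrophobic", CG2 = "hydrophobic")
)

#' Pharmacophore classes for one atom of one residue type
#'
#' Atoms absent from the lookup map to `"neutral"`.
#' @keywords internal
pharma_lookup <- function(resname, atom) {
  resname <- toupper(resname)
  if (resname %in% names(nonstandard_aa_map)) resname <- nonstandard_aa_map[[resname]]
  cls <- .backbone_pharma[[atom]]
  if (is.null(cls) && resname %in% names(.sidechain_pharma)) {
    cls <- .sidechain_pharma[[resname]][[atom]]
  }
  if (is.null(cls)) cls <- "neutral"
  cls
}

#' Per-class side-chain atom counts for one amino acid (1-letter code)
#'
#' Counts every class borne by every side-chain heavy atom (an atom with two
#' classes contributes to both). Used for mutation pharmacophore deltas.
#' @keywords internal
sidechain_class_counts <- function(aa1) {
  res3 <- aa_one_to_three_tbl[[aa1]]
  counts <- stats::setNames(rep(0L, length(pharmacophore_classes)),
                            pharmacophore_classes)
  for (cls in unlist(.sidechain_pharma[[res3]])) {
    counts[cls] <- counts[cls] + 1L
  }
  counts
}

# Idealized side-chain internal coordinates (Z-matrix rows). Each atom is
# placed from three previously-known atoms: bond to a3, angle a2-a3-atom,
# dihedral a1-a2-a3-atom (degrees). The single most common rotamer is used;
# no minimization. CB is placed the same way for every non-Gly residue.
.zrow <- function(atom, a1, a2, a3, bond, angle, dihedral) {
  list(atom = atom, a1 = a1, a2 = a2, a3 = a3,
       bond = bond, angle = angle, dihedral = dihedral)
}

.cb_row <- .zrow("CB", "C", "N", "CA", 1.530, 110.5, -122.6)

sidechain_zmat <- list(
  GLY = list(),
  ALA = list(.cb_row),
  SER = list(.cb_row, .zrow("OG", "N", "CA", "CB", 1.417, 110.8, -65)),
  CYS = list(.cb_row, .zrow("SG", "N", "CA", "CB", 1.808, 114.4, -65)),
  THR = list(.cb_row,
             .zrow("OG1", "N", "CA", "CB", 1.433, 109.6, -60),
             .zrow("CG2", "N", "CA", "CB", 1.521, 110.5, 60)),
  VAL = list(.cb_row,
             .zrow("CG1", "N", "CA", "CB", 1.527, 110.5, 175),
             .zrow("CG2", "N", "CA", "CB", 1.527, 110.5, -65)),
  LEU = list(.cb_row,
             .zrow("CG", "N", "CA", "CB", 1.530, 116.3, -65),
             .zrow("CD1", "CA", "CB", "CG", 1.521, 110.7, 65),
             .zrow("CD2", "CA", "CB", "CG", 1.521, 110.7, -175)),
  ILE = list(.cb_row,
             .zrow("CG1", "N", "CA", "CB", 1.530, 110.4, -60),
             .zrow("CG2", "N", "CA", "CB", 1.521, 110.5, 60),
             .zrow("CD1", "CA", "CB", "CG1", 1.513, 113.8, 170)),
  PRO = list(.cb_row,
             .zrow("CG", "N", "CA", "CB", 1.495, 104.5, 30),
             .zrow("CD", "CA", "CB", "CG", 1.507, 105.5, -35)),
  MET = list(.cb_row,
             .zrow("CG", "N", "CA", "CB", 1.520, 114.1, -65),
             .zrow("SD", "CA", "CB", "CG", 1.803, 112.7, 180),
             .zrow("CE", "CB", "CG", "SD", 1.791, 100.9, 180)),
  PHE = list(.cb_row,
             .zrow("CG", "N", "CA", "CB", 1.502, 113.8, -65),
             .zrow("CD1", "CA", "CB", "CG", 1.384, 120.8, -90),
             .zrow("CD2", "CA", "CB", "CG", 1.384, 120.8, 90),
             .zrow("CE1", "CB", "CG", "CD1", 1.382, 120.1, 180),
             .zrow("CE2", "CB", "CG", "CD2", 1.382, 120.1, 180),
             .zrow("CZ", "CG", "CD1", "CE1", 1.382, 120.0, 0)),
  TYR = list(.cb_row,
             .zrow("CG", "N", "CA", "CB", 1.512, 113.9, -65),
             .zrow("CD1", "CA", "CB", "CG", 1.389, 120.8, -90),
             .zrow("CD2", "CA", "CB", "CG", 1.389, 120.8, 90),
             .zrow("CE1", "CB", "CG", "CD1", 1.382, 121.2, 180),
             .zrow("CE2", "CB", "CG", "CD2", 1.382, 121.2, 180),
             .zrow("CZ", "CG", "CD1", "CE1", 1.378, 119.6, 0),
             .zrow("OH", "CD1", "CE1", "CZ", 1.376, 119.9, 180)),
  TRP = list(.cb_row,
             .zrow("CG", "N", "CA", "CB", 1.498, 113.6, -65),
             .zrow("CD1", "CA", "CB", "CG", 1.365, 126.9, -90),
             .zrow("CD2", "CA", "CB", "CG", 1.433, 126.6, 90),
             .zrow("NE1", "CB", "CG", "CD1", 1.374, 110.2, 180),
             .zrow("CE2", "CB", "CG", "CD2", 1.409, 107.2, 180),
             .zrow("CE3", "CB", "CG", "CD2", 1.398, 133.9, 0),
             .zrow("CZ2", "CG", "CD2", "CE2", 1.394, 122.4, 180),
             .zrow("CZ3", "CG", "CD2", "CE3", 1.391, 118.6, 180),
             .zrow("CH2", "CD2", "CE2", "CZ2", 1.368, 117.5, 0)),
  ASP = list(.cb_row,
             .zrow("CG", "N", "CA", "CB", 1.516, 112.6, -65),
             .zrow("OD1", "CA", "CB", "CG", 1.249, 118.4, -15),
             .zrow("OD2", "CA", "CB", "CG", 1.249, 118.4, 165)),
  ASN = list(.cb_row,
             .zrow("CG", "N", "CA", "CB", 1.516, 112.6, -65),
             .zrow("OD1", "CA", "CB", "CG", 1.231, 120.8, -60),
             .zrow("ND2", "CA", "CB", "CG", 1.328, 116.4, 120)),
  GLU = list(.cb_row,
             .zrow("CG", "N", "CA", "CB", 1.520, 114.1, -65),
             .zrow("CD", "CA", "CB", "CG", 1.516, 112.6, 180),
             .zrow("OE1", "CB", "CG", "CD", 1.249, 118.4, -15),
             .zrow("OE2", "CB", "CG", "CD", 1.249, 118.4, 165)),
  GLN = list(.cb_row,
             .zrow("CG", "N", "CA", "CB", 1.520, 114.1, -65),
             .zrow("CD", "CA", "CB", "CG", 1.516, 112.6, 180),
             .zrow("OE1", "CB", "CG", "CD", 1.231, 120.8, -60),
             .zrow("NE2", "CB", "CG", "CD", 1.328, 116.4, 120)),
  LYS = list(.cb_row,
             .zrow("CG", "N", "CA", "CB", 1.520, 114.1, -65),
             .zrow("CD", "CA", "CB", "CG", 1.520, 111.3, 180),
             .zrow("CE", "CB", "CG", "CD", 1.520, 111.3, 180),
             .zrow("NZ", "CG", "CD", "CE", 1.489, 111.9, 180)),
  ARG = list(.cb_row,
             .zrow("CG", "N", "CA", "CB", 1.520, 114.1, -65),
             .zrow("CD", "CA", "CB", "CG", 1.520, 111.3, 180),
             .zrow("NE", "CB", "CG", "CD", 1.461, 112.0, 180),
             .zrow("CZ", "CG", "CD", "NE", 1.329, 124.2, 180),
             .zrow("NH1", "CD", "NE", "CZ", 1.326, 120.0, 0),
             .zrow("NH2", "CD", "NE", "CZ", 1.326, 120.0, 180)),
  HIS = list(.cb_row,
             .zrow("CG", "N", "CA", "CB", 1.497, 113.8, -65),
             .zrow("ND1", "CA", "CB", "CG", 1.378, 122.7, -70),
             .zrow("CD2", "CA", "CB", "CG", 1.356, 131.1, 110),
             .zrow("CE1", "CB", "CG", "ND1", 1.321, 109.3, 180),
             .zrow("NE2", "CB", "CG", "CD2", 1.374, 107.2, 180))
)

#' Standard 1-letter amino-acid codes
#' @return Character vector of the 20 standard 1-letter codes.
#' @export
standard_aa_codes <- function() unname(aa_three_to_one_tbl)

#' Convert 3-letter residue names to 1-letter codes
#'
#' Non-standard residues with a known parent amino acid (e.g. MSE) map to the
#' parent's code; unknown names map to `NA`.
#' @param resname Character vector of 3-letter residue names.
#' @return Character vector of 1-letter codes (NA when unmappable).
#' @export
aa_three_to_one <- function(resname) {
  resname <- toupper(resname)
  mapped <- ifelse(resname %in% names(nonstandard_aa_map),
                   nonstandard_aa_map[resname], resname)
  out <- unname(aa_three_to_one_tbl[mapped])
  out
}

#' Convert 1-letter amino-acid codes to 3-letter names
#' @param aa1 Character vector of 1-letter codes.
#' @return Character vector of 3-letter residue names.
#' @export
aa_one_to_three <- function(aa1) {
  unname(aa_one_to_three_tbl[toupper(aa1)])
}
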