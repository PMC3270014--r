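#' Atom-type vocabulary for the protein-DNA pair potential
#'
#' The potential distinguishes every heavy atom of the 20 standard amino
#' acids (167 protein types) and every heavy atom of the four standard
#' deoxyribonucleotides including the sugar-phosphate backbone (82 DNA
#' types).  A type is the pair `residue.atom`, e.g. `"ARG.NH1"` or
#' `"DG.N7"`.  Terminal `OXT` and the 5'-terminal `OP3` are outside the
#' vocabulary; atoms that do not map to a type (solvent, ligands, modified
#' residues) are skipped by the counting machinery.
#'
#' @name atom-types
#' @keywords internal
NULL

# Heavy-atom names per standard amino acid (PDB v3 nomenclature, no OXT).
.protein_atom_table <- list(
  ALA = c("N", "CA", "C", "O", "CB"),
  ARG = c("N", "CA", "C", "O", "CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  ASN = c("N", "CA", "C", "O", "CB", "CG", "OD1", "ND2"),
  ASP = c("N", "CA", "C", "O", "CB", "CG", "OD1", "OD2"),
  CYS = c("N", "CA", "C", "O", "CB", "SG"),
  GLN = c("N", "CA", "C", "O", "CB", "CG", "CD", "OE1", "NE2"),
  GLU = c("N", "CA", "C", "O", "CB", "CG", "CD", "OE1", "OE2"),
  GLY = c("N", "CA", "C", "O"),
  HIS = c("N", "CA", "C", "O", "CB", "CG", "ND1", "CD2", "CE1", "NE2"),
  ILE = c("N", "CA", "C", "O", "CB", "CG1", "CG2", "CD1"),
  LEU = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2"),
  LYS = c("N", "CA", "C", "O", "CB", "CG", "CD", "CE", "NZ"),
  MET = c("N", "CA", "C", "O", "CB", "CG", "SD", "CE"),
  PHE = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PRO = c("N", "CA", "C", "O", "CB", "CG", "CD"),
  SER = c("N", "CA", "C", "O", "CB", "OG"),
  THR = c("N", "CA", "C", "O", "CB", "OG1", "CG2"),
  TRP = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "NE1", "CE2",
          "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "CE1", "CE2",
          "CZ", "OH"),
  VAL = c("N", "CA", "C", "O", "CB", "CG1", "CG2")
)

.dna_backbone_atoms <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'",
                         "C3'", "O3'", "C2'", "C1'")

.dna_base_atom_table <- list(
  DA = c("N9", "C8", "N7", "C5", "C6", "N6", "N1", "C2", "N3", "C4"),
  DC = c("N1", "C2", "O2", "N3", "C4", "N4", "C5", "C6"),
  DG = c("N9", "C8", "N7", "C5", "C6", "O6", "N1", "C2", "N2", "N3", "C4"),
  DT = c("N1", "C2", "O2", "N3", "C4", "O4", "C5", "C7", "C6")
)

.dna_atom_table <- lapply(.dna_base_atom_table,
                          function(b) c(.dna_backbone_atoms, b))

#' Enumerate the protein or DNA atom-type vocabulary
#'
#' @param kind `"protein"` (167 types) or `"dna"` (82 types).
#' @return Character vector of `residue.atom` labels in a fixed order.
#' @examples
#' length(atom_type_vocabulary("protein"))  # 167
#' length(atom_type_vocabulary("dna"))      # 82
#' @export
atom_type_vocabulary <- function(kind = c("protein", "dna")) {
  kind <- match.arg(kind)
  tab <- if (kind == "protein") .protein_atom_table else .dna_atom_table
  unlist(lapply(names(tab), function(res) paste(res, tab[[res]], sep = ".")),
         use.names = FALSE)
}

# Legacy atom-name spellings mapped to PDB v3.
.atom_name_aliases <- c(
  "O1P" = "OP1", "O2P" = "OP2", "O3P" = "OP3",
  "C5M" = "C7",   # thymine methyl
  "O1'" = "O4'"
)

# Legacy single-letter deoxyribonucleotide codes.
.dna_residue_aliases <- c("A" = "DA", "C" = "DC", "G" = "DG", "T" = "DT",
                          "ADE" = "DA", "CYT" = "DC", "GUA" = "DG",
                          "THY" = "DT")

#' Normalize residue and atom nomenclature
#'
#' Converts legacy PDB spellings to current conventions: `*` primes to `'`,
#' `O1P`/`O2P` to `OP1`/`OP2`, thymine `C5M` to `C7`, and single-letter DNA
#' residue codes (`A`, `C`, `G`, `T`) to `DA`/`DC`/`DG`/`DT`.
#'
#' @param residue_name,atom_name character vectors of equal length.
#' @return List with normalized `residue_name` and `atom_name`.
#' @export
normalize_nomenclature <- function(residue_name, atom_name) {
  atom_name <- gsub("*", "'", trimws(atom_name), fixed = TRUE)
  hit <- atom_name %in% names(.atom_name_aliases)
  atom_name[hit] <- .atom_name_aliases[atom_name[hit]]
  residue_name <- trimws(residue_name)
  hit <- residue_name %in% names(.dna_residue_aliases)
  residue_name[hit] <- .dna_residue_aliases[residue_name[hit]]
  list(residue_name = residue_name, atom_name = atom_name)
}

#' Assign knowledge-base atom types
#'
#' Maps `(residue_name, atom_name)` pairs onto the 167-protein / 82-DNA type
#' vocabulary after nomenclature normalization.  Atoms outside the
#' vocabulary (water, ions, OXT, modified residues, terminal phosphate
#' oxygens) get `NA`.
#'
#' @param residue_name,atom_name character vectors (recycled to equal
#'   length).
#' @return Character vector of type labels (`"RES.ATOM"`) or `NA`.
#' @examples
#' assign_type("ARG", "NH1")   # "ARG.NH1"
#' assign_type("DG", "N7")     # "DG.N7"
#' assign_type("HOH", "O")     # NA
#' @export
assign_type <- function(residue_name, atom_name) {
  nm <- normalize_nomenclature(residue_name, atom_name)
  lab <- paste(nm$residue_name, nm$atom_name, sep = ".")
  vocab <- c(atom_type_vocabulary("protein"), atom_type_vocabulary("dna"))
  lab[!(lab %in% vocab)] <- NA_character_
  lab
}

# Residue kind helpers -------------------------------------------------------

.standard_dna_residues <- c("DA", "DC", "DG", "DT")

is_dna_residue <- function(residue_name) {
  normalize_nomenclature(residue_name, "")$residue_name %in%
    .standard_dna_residues
}

is_protein_residue <- function(residue_name) {
  trimws(residue_name) %in% names(.protein_atom_table)
}

#' Watson-Crick complement of a base or DNA residue code
#'
#' @param base character vector of single letters (`A`,`C`,`G`,`T`) or
#'   residue codes (`DA`,`DC`,`DG`,`DT`).
#' @return Complements in the same encoding.
#' @export
wc_complement <- function(base) {
  res <- base %in% .standard_dna_residues
  out <- base
  out[res] <- paste0("D", chartr("ACGT", "TGCA", substring(base[res], 2)))
  out[!res] <- chartr("ACGT", "TGCA", base[!res])
  out
}

is_purine_residue <- function(residue_name) residue_name %in% c("DA", "DG")

# Glycosidic frame atom names used for base substitution: C1' plus the
# glycosidic nitrogen and the adjacent ring anchor (isosteric between
# purines and pyrimidines).
glycosidic_frame_atoms <- function(residue_name) {
  if (is_purine_residue(residue_name)) c("C1'", "N9", "C4")
  else c("C1'", "N1", "C2")
}
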