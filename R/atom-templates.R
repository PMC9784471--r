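#' @keywords internal
"_PACKAGE"

# Heavy-atom templates for the twenty standard amino acids.
#
# Typing is a pure function of (res_name, atom_name):
#   * backbone N is a donor (except proline), backbone O and OXT are acceptors;
#   * sidechain donors/acceptors follow standard amino-acid chemistry;
#   * an "apolar carbon" is a carbon with no covalent bond to N or O in the
#     residue template (CA and C are therefore never apolar; TYR CZ is bonded
#     to OH and is excluded from the ring carbons).
# Sulfur (CYS SG, MET SD) is treated as weakly donor/acceptor-capable; this is
# switchable off through `contact_params(include_sulfur = FALSE)`.

.SIDECHAIN <- list(
  ALA = list(apolar = "CB"),
  ARG = list(apolar = c("CB", "CG"), polarC = c("CD", "CZ"),
             donor = c("NE", "NH1", "NH2")),
  ASN = list(apolar = "CB", polarC = "CG", donor = "ND2", acceptor = "OD1"),
  ASP = list(apolar = "CB", polarC = "CG", acceptor = c("OD1", "OD2")),
  CYS = list(apolar = "CB", sulfur = "SG"),
  GLN = list(apolar = c("CB", "CG"), polarC = "CD", donor = "NE2",
             acceptor = "OE1"),
  GLU = list(apolar = c("CB", "CG"), polarC = "CD",
             acceptor = c("OE1", "OE2")),
  GLY = list(),
  HIS = list(apolar = "CB", polarC = c("CG", "CD2", "CE1"),
             donor = c("ND1", "NE2"), acceptor = c("ND1", "NE2")),
  ILE = list(apolar = c("CB", "CG1", "CG2", "CD1")),
  LEU = list(apolar = c("CB", "CG", "CD1", "CD2")),
  LYS = list(apolar = c("CB", "CG", "CD"), polarC = "CE", donor = "NZ"),
  MET = list(apolar = c("CB", "CG", "CE"), sulfur = "SD"),
  PHE = list(apolar = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  PRO = list(apolar = c("CB", "CG"), polarC = "CD"),
  SER = list(polarC = "CB", donor = "OG", acceptor = "OG"),
  THR = list(apolar = "CG2", polarC = "CB", donor = "OG1", acceptor = "OG1"),
  TRP = list(apolar = c("CB", "CG", "CD2", "CE3", "CZ2", "CZ3", "CH2"),
             polarC = c("CD1", "CE2"), donor = "NE1"),
  TYR = list(apolar = c("CB", "CG", "CD1", "CD2", "CE1", "CE2"), polarC = "CZ",
             donor = "OH", acceptor = "OH"),
  VAL = list(apolar = c("CB", "CG1", "CG2"))
)

.AA3to1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)
.AA1to3 <- stats::setNames(names(.AA3to1), unname(.AA3to1))

.element_of <- function(atom_name) {
  # PDB convention: first character of a standard amino-acid heavy-atom name
  substr(atom_name, 1L, 1L)
}

.build_template_table <- function() {
  rows <- lapply(names(.SIDECHAIN), function(res) {
    sc <- .SIDECHAIN[[res]]
    atoms <- c("N", "CA", "C", "O",
               sc$apolar, sc$polarC,
               setdiff(unique(c(sc$donor, sc$acceptor)), "SG"),
               sc$sulfur)
    atoms <- unique(atoms)
    data.frame(
      res_name  = res,
      atom_name = atoms,
      element   = vapply(atoms, .element_of, character(1)),
      is_donor  = atoms %in% c(if (res != "PRO") "N", sc$donor),
      is_acceptor = atoms %in% c("O", sc$acceptor),
      is_sulfur = atoms %in% sc$sulfur,
      is_apolar = atoms %in% sc$apolar,
      is_backbone = atoms %in% c("N", "CA", "C", "O"),
      row.names = NULL
    )
  })
  do.call(rbind, rows)
}

.TEMPLATES <- .build_template_table()

#' Heavy-atom typing template for the standard amino acids
#'
#' Returns the per-(residue, atom) classification used to decide which atom
#' pairs can form hydrogen bonds (donor/acceptor-capable atoms) and which can
#' form hydrophobic contacts (apolar carbons, i.e. carbons not covalently
#' bonded to nitrogen or oxygen in the residue template).
#'
#' @return A data frame with columns `res_name`, `atom_name`, `element`,
#'   `is_donor`, `is_acceptor`, `is_sulfur`, `is_apolar`, `is_backbone`.
#'   `OXT` is not listed; it is typed as a backbone acceptor when encountered.
#' @examples
#' tpl <- atom_templates()
#' subset(tpl, res_name == "TYR" & atom_name == "OH")
#' @export
atom_templates <- function() .TEMPLATES

#' Convert three-letter residue codes to one-letter codes
#'
#' Unknown or non-standard residue names map to `"X"`.
#'
#' @param res_names character vector of three-letter codes (e.g. `"TYR"`).
#' @return character vector of one-letter codes.
#' @examples
#' aa3_to_1(c("VAL", "GLN", "ILE", "MSE"))
#' @export
aa3_to_1 <- function(res_names) {
  out <- unname(.AA3to1[toupper(res_names)])
  out[is.na(out)] <- "X"
  out
}

#' Convert one-letter residue codes to three-letter codes
#'
#' @param aa character vector of one-letter codes.
#' @return character vector of three-letter codes; unknown letters give `"UNK"`.
#' @export
aa1_to_3 <- function(aa) {
  out <- unname(.AA1to3[toupper(aa)])
  out[is.na(out)] <- "UNK"
  out
}

#' Canonical human tau 2N4R sequence
#'
#' The 441-residue 2N4R isoform of human microtubule-associated protein tau
#' (UniProt P10636-8), packaged as the numbering template for all construct
#' design and motif scanning. Residue 1 is the initiator methionine; the
#' PHF6* (VQIINK) motif spans 275-280 and the PHF6 (VQIVYK) motif 306-311.
#'
#' @return A single character string of length 441.
#' @examples
#' substr(tau_2N4R_sequence(), 306, 311)  # "VQIVYK"
#' @export
tau_2N4R_sequence <- function() {
  path <- system.file("extdata", "tau_2N4R_P10636-8.fasta", package = "taucore",
                      mustWork = TRUE)
  seqs <- Biostrings::readAAStringSet(path)
  as.character(seqs[[1]])
}
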