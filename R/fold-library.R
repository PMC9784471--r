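# Synthetic stand-in protomers for the eight tauopathy fibril folds.
#
# These are NOT the deposited cryo-EM coordinates: they are schematic
# fixtures built with make_contact_fixture() that encode two documented
# properties of each fold -- (a) the approximate modeled residue range of
# one protomer chain in 2N4R author numbering, which determines whether the
# VQIINK and VQIVYK hexamers are ordered (and hence the single/dual-core
# strain class), and (b) the published residue-pair interactions lost when
# the VYK or INK motif suffix is truncated, planted at plausible
# hydrogen-bond / hydrophobic distances. They let the classification and
# truncation-loss machinery run offline; they carry no information about
# the real backbone geometry of the folds.

# removed-suffix neighbour pairs per fold; a = suffix residue, b = neighbour
.FOLD_PAIRS <- list(
  AD = list(
    list(seq_id_a = 310, atom_a = "OH",  seq_id_b = 374, atom_b = "NE2", distance = 3.1, type = "hbond"),
    list(seq_id_a = 310, atom_a = "CE1", seq_id_b = 376, atom_b = "CD1", distance = 4.2, type = "hydrophobic")),
  CTE = list(
    list(seq_id_a = 310, atom_a = "OH",  seq_id_b = 374, atom_b = "NE2", distance = 3.2, type = "hbond"),
    list(seq_id_a = 310, atom_a = "CE1", seq_id_b = 376, atom_b = "CD1", distance = 4.4, type = "hydrophobic")),
  PiD = list(
    list(seq_id_a = 310, atom_a = "CE1", seq_id_b = 337, atom_b = "CG1", distance = 4.0, type = "hydrophobic")),
  CBD = list(
    list(seq_id_a = 309, atom_a = "CG1", seq_id_b = 297, atom_b = "CD1", distance = 4.3, type = "hydrophobic"),
    list(seq_id_a = 310, atom_a = "CE1", seq_id_b = 337, atom_b = "CG1", distance = 4.1, type = "hydrophobic"),
    list(seq_id_a = 311, atom_a = "CD",  seq_id_b = 297, atom_b = "CG2", distance = 4.6, type = "hydrophobic"),
    list(seq_id_a = 311, atom_a = "NZ",  seq_id_b = 295, atom_b = "OD1", distance = 2.9, type = "hbond"),
    list(seq_id_a = 279, atom_a = "CB",  seq_id_b = 376, atom_b = "CD1", distance = 4.5, type = "hydrophobic")),
  AGD = list(
    list(seq_id_a = 309, atom_a = "CG1", seq_id_b = 297, atom_b = "CD1", distance = 4.2, type = "hydrophobic"),
    list(seq_id_a = 310, atom_a = "CE1", seq_id_b = 337, atom_b = "CG1", distance = 4.0, type = "hydrophobic"),
    list(seq_id_a = 311, atom_a = "NZ",  seq_id_b = 295, atom_b = "OD1", distance = 3.0, type = "hbond")),
  PSP = list(
    list(seq_id_a = 309, atom_a = "CG1", seq_id_b = 350, atom_b = "CG1", distance = 4.2, type = "hydrophobic"),
    list(seq_id_a = 309, atom_a = "CG2", seq_id_b = 348, atom_b = "CB",  distance = 4.6, type = "hydrophobic"),
    list(seq_id_a = 310, atom_a = "CD1", seq_id_b = 301, atom_b = "CG",  distance = 4.3, type = "hydrophobic"),
    list(seq_id_a = 310, atom_a = "OH",  seq_id_b = 299, atom_b = "NE2", distance = 3.2, type = "hbond"),
    list(seq_id_a = 311, atom_a = "NZ",  seq_id_b = 348, atom_b = "OD1", distance = 2.8, type = "hbond")),
  GGT = list(
    list(seq_id_a = 309, atom_a = "CG1", seq_id_b = 296, atom_b = "CB",  distance = 4.5, type = "hydrophobic"),
    list(seq_id_a = 309, atom_a = "CG2", seq_id_b = 297, atom_b = "CD1", distance = 4.3, type = "hydrophobic"),
    list(seq_id_a = 310, atom_a = "OH",  seq_id_b = 348, atom_b = "OD1", distance = 2.9, type = "hbond"),
    list(seq_id_a = 310, atom_a = "CE1", seq_id_b = 354, atom_b = "CD1", distance = 4.2, type = "hydrophobic"),
    list(seq_id_a = 311, atom_a = "NZ",  seq_id_b = 348, atom_b = "OD2", distance = 3.0, type = "hbond")),
  GPT = list(
    list(seq_id_a = 309, atom_a = "CG1", seq_id_b = 350, atom_b = "CG1", distance = 4.2, type = "hydrophobic"),
    list(seq_id_a = 310, atom_a = "CE1", seq_id_b = 297, atom_b = "CD1", distance = 4.1, type = "hydrophobic"),
    list(seq_id_a = 310, atom_a = "OH",  seq_id_b = 295, atom_b = "OD1", distance = 3.1, type = "hbond"),
    list(seq_id_a = 311, atom_a = "CD",  seq_id_b = 350, atom_b = "CG2", distance = 4.6, type = "hydrophobic"),
    list(seq_id_a = 311, atom_a = "NZ",  seq_id_b = 348, atom_b = "OD1", distance = 2.9, type = "hbond")))

# approximate modeled extents of one protomer chain, 2N4R numbering; the
# Pick fold is 3R tau, so R2 (275-305) is physically absent and the author
# numbering jumps from 274 to 306
.FOLD_RANGES <- list(
  AD  = list(entry = "5O3L", disease = "Alzheimer's disease",            segs = list(306:378)),
  CTE = list(entry = "6NWP", disease = "chronic traumatic encephalopathy", segs = list(305:379)),
  PiD = list(entry = "6GX5", disease = "Pick's disease",                 segs = list(254:274, 306:378)),
  CBD = list(entry = "6TJO", disease = "corticobasal degeneration",      segs = list(274:380)),
  AGD = list(entry = "7P6D", disease = "argyrophilic grain disease",     segs = list(273:380)),
  PSP = list(entry = "7P65", disease = "progressive supranuclear palsy", segs = list(272:381)),
  GGT = list(entry = "7P66", disease = "globular glial tauopathy",       segs = list(272:379)),
  GPT = list(entry = "7P6A", disease = "GGT-PSP-tau",                    segs = list(272:379)))

#' Names of the synthetic fold stand-ins
#'
#' @return Character vector of the eight fold labels.
#' @export
fold_names <- function() names(.FOLD_RANGES)

#' Fold metadata table
#'
#' @return Data frame with one row per fold: `fold`, `pdb_entry` (the
#'   deposition the stand-in emulates), `disease`.
#' @export
fold_info <- function() {
  data.frame(fold = names(.FOLD_RANGES),
             pdb_entry = vapply(.FOLD_RANGES, `[[`, character(1), "entry"),
             disease = vapply(.FOLD_RANGES, `[[`, character(1), "disease"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Synthetic stand-in protomer for a tauopathy fold
#'
#' Builds a schematic single-chain structure whose modeled residue range
#' matches the published extent of the named fold (so motif scanning and
#' strain classification behave as for the deposition) and whose only
#' contacts are the published VYK/INK truncation-loss residue pairs,
#' planted at fixed hydrogen-bond or hydrophobic distances. Synthetic: not
#' the deposited coordinates.
#'
#' @param fold one of [fold_names()].
#' @param seed integer jitter seed.
#' @return A `tau_structure` (chain `"A"`).
#' @examples
#' p <- select_protomer(synthetic_fold_protomer("AD"))
#' classify_fold(scan_motifs(extract_sequence(p)))
#' @export
synthetic_fold_protomer <- function(fold = fold_names(), seed = 1L) {
  fold <- match.arg(fold)
  info <- .FOLD_RANGES[[fold]]
  tau <- tau_2N4R_sequence()
  ids <- unlist(info$segs)
  residues <- data.frame(
    chain_id = "A", seq_id = ids,
    res_name = aa1_to_3(strsplit(substring(tau, 1), "")[[1]][ids]),
    stringsAsFactors = FALSE)
  spec <- contact_fixture_spec(residues, planted_pairs = .FOLD_PAIRS[[fold]])
  fx <- make_contact_fixture(spec, seed = seed)
  fx$source <- paste0("synthetic:fold:", fold, " (models PDB ", info$entry, ")")
  fx
}

#' The published truncation-loss pairs a fold stand-in plants
#'
#' @param fold one of [fold_names()].
#' @return Data frame of the planted pairs (`seq_id_a` is the motif-suffix
#'   residue, `seq_id_b` the spatial neighbour) with the planted atom names,
#'   distances and bond types.
#' @export
fold_planted_pairs <- function(fold = fold_names()) {
  fold <- match.arg(fold)
  do.call(rbind, lapply(.FOLD_PAIRS[[fold]], function(p)
    data.frame(seq_id_a = p$seq_id_a, atom_a = p$atom_a,
               seq_id_b = p$seq_id_b, atom_b = p$atom_b,
               distance = p$distance, bond_type = p$type,
               stringsAsFactors = FALSE)))
}
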