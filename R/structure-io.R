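# Structure input/output and protomer selection.
#
# PDB parsing is delegated to bio3d; mmCIF (atom_site loop) is parsed with a
# minimal reader since no installed R package handles mmCIF. Both routes feed
# the same atom table so downstream contact analysis is format-independent.

.WATER <- c("HOH", "WAT", "DOD", "H2O")

.new_structure <- function(atoms, source = NA_character_) {
  rownames(atoms) <- NULL
  if (is.null(atoms$is_standard))
    atoms$is_standard <- atoms$res_name %in% names(.SIDECHAIN)
  structure(list(atoms = atoms, source = source), class = "tau_structure")
}

#' Read a fibril structure from a PDB or mmCIF file
#'
#' Parses the full atom hierarchy of the first model. Water molecules are
#' excluded; other heteroatoms and non-standard residues are retained and
#' flagged via the `is_standard` column.
#'
#' @param path path to a structure file.
#' @param format `"pdb"`, `"mmcif"`, or `"auto"` (decide from the file
#'   extension: `.cif`/`.mmcif` is mmCIF, anything else PDB).
#' @return A `tau_structure` object: a list with an `atoms` data frame
#'   (columns `record`, `chain`, `seq_id`, `icode`, `res_name`, `atom_name`,
#'   `element`, `altloc`, `x`, `y`, `z`, `occupancy`, `is_standard`) and the
#'   source path.
#' @seealso [select_protomer()], [write_structure_pdb()]
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  atoms <- if (format == "pdb") .read_pdb_atoms(path) else .read_mmcif_atoms(path)
  atoms <- atoms[!(atoms$res_name %in% .WATER), , drop = FALSE]
  if (nrow(atoms) == 0L) stop("no atoms: '", path, "' contains no coordinates")
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("parse error: non-finite coordinates in ", path)
  atoms$is_standard <- atoms$res_name %in% names(.SIDECHAIN)
  .new_structure(atoms, source = path)
}

.read_pdb_atoms <- function(path) {
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
    error = function(e) stop("parse error reading PDB '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  a <- pdb$atom
  data.frame(
    record    = a$type,
    chain     = ifelse(is.na(a$chain), "", a$chain),
    seq_id    = as.integer(a$resno),
    icode     = ifelse(is.na(a$insert), "", a$insert),
    res_name  = toupper(a$resid),
    atom_name = toupper(a$elety),
    element   = toupper(ifelse(is.na(a$elesy), substr(a$elety, 1, 1), a$elesy)),
    altloc    = ifelse(is.na(a$alt), "", a$alt),
    x = a$x, y = a$y, z = a$z,
    occupancy = ifelse(is.na(a$o), 1, a$o),
    stringsAsFactors = FALSE
  )
}

# Minimal mmCIF reader: extracts the atom_site loop of the first model.
.read_mmcif_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  li <- which(trimws(lines) == "loop_")
  for (i in li) {
    j <- i + 1L
    tags <- character(0)
    while (j <= length(lines) && startsWith(trimws(lines[j]), "_")) {
      tags <- c(tags, trimws(lines[j])); j <- j + 1L
    }
    if (length(tags) && all(startsWith(tags, "_atom_site."))) {
      k <- j
      while (k <= length(lines)) {
        ln <- trimws(lines[k])
        if (ln == "" || startsWith(ln, "#") || startsWith(ln, "_") ||
            startsWith(ln, "loop_") || startsWith(ln, "data_")) break
        k <- k + 1L
      }
      body <- lines[j:(k - 1L)]
      vals <- scan(text = paste(body, collapse = "\n"), what = "character",
                   quiet = TRUE)
      if (length(vals) %% length(tags) != 0L)
        stop("parse error: mmCIF atom_site loop in '", path,
             "' has a ragged row (", length(vals), " tokens for ",
             length(tags), " tags)")
      m <- matrix(vals, ncol = length(tags), byrow = TRUE)
      colnames(m) <- sub("^_atom_site\\.", "", tags)
      return(.atoms_from_cif_matrix(m, path))
    }
  }
  stop("parse error: no atom_site loop found in '", path, "'")
}

.cif_col <- function(m, primary, fallback = NULL, default = NA_character_) {
  if (primary %in% colnames(m)) return(m[, primary])
  if (!is.null(fallback) && fallback %in% colnames(m)) return(m[, fallback])
  rep(default, nrow(m))
}

.atoms_from_cif_matrix <- function(m, path) {
  blank <- function(v) ifelse(v %in% c(".", "?"), "", v)
  model <- .cif_col(m, "pdbx_PDB_model_num", default = "1")
  keep <- model == model[1]
  m <- m[keep, , drop = FALSE]
  seq_raw <- blank(.cif_col(m, "auth_seq_id", "label_seq_id"))
  data.frame(
    record    = .cif_col(m, "group_PDB", default = "ATOM"),
    chain     = blank(.cif_col(m, "auth_asym_id", "label_asym_id")),
    seq_id    = as.integer(seq_raw),
    icode     = blank(.cif_col(m, "pdbx_PDB_ins_code")),
    res_name  = toupper(blank(.cif_col(m, "auth_comp_id", "label_comp_id"))),
    atom_name = toupper(blank(.cif_col(m, "auth_atom_id", "label_atom_id"))),
    element   = toupper(blank(.cif_col(m, "type_symbol"))),
    altloc    = blank(.cif_col(m, "label_alt_id")),
    x = as.numeric(.cif_col(m, "Cartn_x")),
    y = as.numeric(.cif_col(m, "Cartn_y")),
    z = as.numeric(.cif_col(m, "Cartn_z")),
    occupancy = suppressWarnings(as.numeric(blank(.cif_col(m, "occupancy",
                                                           default = "1")))),
    stringsAsFactors = FALSE
  )
}

#' Write a structure as a PDB file
#'
#' Emits standard fixed-width ATOM records (author chain, residue numbering,
#' three-decimal coordinates), one model, terminated by `END`.
#'
#' @param x a `tau_structure` or `tau_protomer`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(x, path) {
  a <- .atoms_of(x)
  aname <- ifelse(nchar(a$atom_name) >= 4, substr(a$atom_name, 1, 4),
                  sprintf(" %-3s", a$atom_name))
  lines <- sprintf(
    "ATOM  %5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)) %% 100000L, aname, a$altloc, a$res_name,
    substr(paste0(a$chain, " "), 1, 1), a$seq_id, substr(paste0(a$icode, " "), 1, 1),
    a$x, a$y, a$z, a$occupancy, 0, a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write a structure as a minimal mmCIF file
#'
#' Emits a single `atom_site` loop carrying the same atom inventory as
#' [write_structure_pdb()]; useful for cross-format round-trip checks.
#'
#' @inheritParams write_structure_pdb
#' @return `path`, invisibly.
#' @export
write_structure_cif <- function(x, path) {
  a <- .atoms_of(x)
  dot <- function(v) ifelse(v == "" | is.na(v), ".", v)
  header <- c("data_taucore", "#", "loop_",
              paste0("_atom_site.", c("group_PDB", "id", "type_symbol",
                                      "auth_atom_id", "label_alt_id",
                                      "auth_comp_id", "auth_asym_id",
                                      "auth_seq_id", "pdbx_PDB_ins_code",
                                      "Cartn_x", "Cartn_y", "Cartn_z",
                                      "occupancy", "pdbx_PDB_model_num")))
  rows <- sprintf("%s %d %s %s %s %s %s %d %s %.3f %.3f %.3f %.2f 1",
                  "ATOM", seq_len(nrow(a)), dot(a$element), dot(a$atom_name),
                  dot(a$altloc), dot(a$res_name), dot(a$chain), a$seq_id,
                  dot(a$icode), a$x, a$y, a$z, a$occupancy)
  writeLines(c(header, rows, "#"), path)
  invisible(path)
}

.atoms_of <- function(x) {
  if (inherits(x, "tau_structure") || inherits(x, "tau_protomer")) return(x$atoms)
  stop("expected a tau_structure or tau_protomer")
}

#' @export
print.tau_structure <- function(x, ...) {
  a <- x$atoms
  cat("tau_structure:", nrow(a), "atoms,",
      length(unique(a$chain)), "chain(s) [",
      paste(unique(a$chain), collapse = " "), "]\n")
  invisible(x)
}

#' Select a single protomer (one chain, one conformer) for contact analysis
#'
#' Reduces a structure to the analysis unit of intra-molecular contact
#' mapping: one chain of one model, the `'A'`/blank alternate location only,
#' hydrogens removed, and every atom typed for hydrogen-bond and hydrophobic
#' contact classification via the fixed per-residue templates (see
#' [atom_templates()]).
#'
#' @param structure a `tau_structure`.
#' @param chain chain identifier; default is the first chain containing
#'   standard amino-acid residues (the first polymer chain in file order).
#' @return A `tau_protomer`: list with a typed `atoms` data frame (adds
#'   `is_donor`, `is_acceptor`, `is_sulfur`, `is_apolar`, `is_backbone`,
#'   `typed`), the chain id, and the source path.
#' @export
select_protomer <- function(structure, chain = NULL) {
  a <- .atoms_of(structure)
  polymer_chains <- unique(a$chain[a$is_standard])
  if (is.null(chain)) {
    if (!length(polymer_chains)) stop("no polymer chain found")
    chain <- polymer_chains[1]
  } else if (!chain %in% a$chain) {
    stop("chain '", chain, "' not found; available chains: ",
         paste(unique(a$chain), collapse = ", "))
  }
  a <- a[a$chain == chain, , drop = FALSE]
  a <- a[a$altloc %in% c("", "A"), , drop = FALSE]
  a <- a[!(a$element %in% c("H", "D")), , drop = FALSE]
  nonstd <- !a$is_standard
  if (any(nonstd)) {
    warning(sum(nonstd), " atoms in non-standard residues (",
            paste(unique(a$res_name[nonstd]), collapse = ", "),
            ") dropped from protomer")
    a <- a[!nonstd, , drop = FALSE]
  }
  if (nrow(a) == 0L) stop("protomer is empty after filtering")
  key <- paste(a$res_name, a$atom_name)
  tkey <- paste(.TEMPLATES$res_name, .TEMPLATES$atom_name)
  idx <- match(key, tkey)
  for (col in c("is_donor", "is_acceptor", "is_sulfur", "is_apolar",
                "is_backbone")) {
    a[[col]] <- ifelse(is.na(idx), FALSE, .TEMPLATES[[col]][idx])
  }
  a$typed <- !is.na(idx)
  oxt <- a$atom_name == "OXT"
  a$is_acceptor[oxt] <- TRUE
  a$is_backbone[oxt] <- TRUE
  a$typed[oxt] <- TRUE
  a <- a[order(a$seq_id, a$icode), , drop = FALSE]
  rownames(a) <- NULL
  structure(list(atoms = a, chain = chain, source = structure$source),
            class = "tau_protomer")
}

#' @export
print.tau_protomer <- function(x, ...) {
  a <- x$atoms
  cat("tau_protomer: chain", x$chain, "-", nrow(a), "atoms,",
      length(unique(a$seq_id)), "residues (",
      min(a$seq_id), "-", max(a$seq_id), ")\n")
  invisible(x)
}

#' Extract the modeled one-letter sequence of a protomer
#'
#' Reads the resolved residues in ascending author numbering and records
#' where the numbering jumps (unmodeled stretches in the deposition, or a
#' physically absent segment such as R2 in 3R tau).
#'
#' @param protomer a `tau_protomer`.
#' @return A `modeled_sequence`: list with `sequence` (one-letter string,
#'   unknown residues as `X`), `seq_ids` (parallel author numbering, strictly
#'   increasing) and `gap_after` (logical, `TRUE` where the numbering jumps
#'   between position i and i+1).
#' @examples
#' fx <- make_contact_fixture(contact_fixture_spec(
#'   residues = data.frame(chain_id = "A", seq_id = 306:311,
#'                         res_name = aa1_to_3(strsplit("VQIVYK", "")[[1]]))))
#' extract_sequence(select_protomer(fx))$sequence
#' @export
extract_sequence <- function(protomer) {
  a <- .atoms_of(protomer)
  res <- unique(a[, c("seq_id", "icode", "res_name")])
  res <- res[order(res$seq_id, res$icode), , drop = FALSE]
  if (anyDuplicated(res$seq_id))
    stop("duplicate author seq_ids with insertion codes are not supported")
  n <- nrow(res)
  structure(list(
    sequence = paste(aa3_to_1(res$res_name), collapse = ""),
    seq_ids  = res$seq_id,
    gap_after = if (n > 1) c(diff(res$seq_id) > 1L, FALSE) else logical(n)
  ), class = "modeled_sequence")
}

#' @export
print.modeled_sequence <- function(x, ...) {
  cat("modeled_sequence:", nchar(x$sequence), "residues, ids",
      min(x$seq_ids), "-", max(x$seq_ids),
      if (any(x$gap_after)) paste0("(", sum(x$gap_after), " gap(s))") else
        "(contiguous)", "\n")
  invisible(x)
}
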