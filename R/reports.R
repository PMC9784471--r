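# Report assembly: strain classification over structure sets, the full
# construct catalogue, and reproducible fixture emission. Every report
# embeds the contact cutoffs actually used.

.provenance <- function(params) {
  sprintf("hbond_max=%.2f A; hydrophobic_max=%.2f A; min_seq_separation=%d; backbone_backbone=%s; sulfur=%s",
          params$hbond_max, params$hydrophobic_max, params$min_seq_separation,
          params$include_backbone_backbone, params$include_sulfur)
}

#' Classify a set of fibril structures into nucleation-core strain classes
#'
#' For each input: selects a protomer, scans the modeled sequence for the
#' nucleation hexamers, assigns the single/dual-core strain class, computes
#' the truncation-loss report for every fully resolved hexamer, and ranks
#' the cores by lost-interaction count. Parse failures on individual files
#' are reported as warnings and the run continues.
#'
#' @param inputs a character vector of structure file paths (PDB/mmCIF), or
#'   a named list of `tau_structure` objects.
#' @param params a [contact_params()] object.
#' @param chain optional chain id forwarded to [select_protomer()].
#' @return A `classification_report`: list with `summary` (data frame, one
#'   row per input: `id`, `label`, `cores_present`, `phf6_resolved`,
#'   `n_pairs_PHF6`, `n_pairs_PHF6s`, `primary_core`, `ranking_tied`),
#'   `losses` (per-input named list of `loss_report`s keyed by motif),
#'   `params`, and `provenance` (the cutoffs used, as text).
#' @export
run_classify <- function(inputs, params = contact_params(), chain = NULL) {
  if (is.character(inputs)) {
    if (!length(inputs)) stop("usage error: at least one structure input required")
    nm <- if (!is.null(names(inputs))) names(inputs) else
      tools::file_path_sans_ext(basename(inputs))
    structures <- stats::setNames(vector("list", length(inputs)), nm)
    for (i in seq_along(inputs)) {
      structures[[i]] <- tryCatch(read_structure(inputs[i]), error = function(e) {
        warning("skipping '", inputs[i], "': ", conditionMessage(e))
        NULL
      })
    }
    structures <- Filter(Negate(is.null), structures)
  } else {
    if (!length(inputs)) stop("usage error: at least one structure input required")
    structures <- inputs
    if (is.null(names(structures)))
      names(structures) <- paste0("structure_", seq_along(structures))
  }
  rows <- list(); losses <- list()
  for (id in names(structures)) {
    prot <- select_protomer(structures[[id]], chain = chain)
    hits <- scan_motifs(extract_sequence(prot))
    cls <- classify_fold(hits)
    reps <- list()
    for (core in cls$cores_present) {
      hit <- hits[hits$motif == core & hits$fully_resolved, , drop = FALSE][1, ]
      reps[[core]] <- truncation_loss(prot, hit, params)
    }
    losses[[id]] <- reps
    npairs <- function(core) if (core %in% names(reps))
      nrow(reps[[core]]$pairs) else NA_integer_
    ranking <- if (length(reps)) rank_cores(reps) else NULL
    rows[[id]] <- data.frame(
      id = id, label = cls$label,
      cores_present = paste(cls$cores_present, collapse = "+"),
      phf6_resolved = "PHF6" %in% cls$cores_present,
      n_pairs_PHF6 = npairs("PHF6"), n_pairs_PHF6s = npairs("PHF6*"),
      primary_core = if (is.null(ranking)) NA_character_ else ranking$motif[1],
      ranking_tied = if (is.null(ranking)) NA else any(ranking$tied),
      stringsAsFactors = FALSE)
  }
  structure(list(summary = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 losses = losses, params = params,
                 provenance = .provenance(params)),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("classification_report (", x$provenance, ")\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Write a classification report to CSV and JSON
#'
#' The CSV starts with a comment line recording the cutoffs used; the JSON
#' carries the summary, the per-fold lost-pair tables and the parameters.
#'
#' @param report a `classification_report`.
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_classification <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "classification.csv")
  con <- file(csv, "w")
  writeLines(paste("#", report$provenance), con)
  utils::write.csv(report$summary, con, row.names = FALSE)
  close(con)
  js <- file.path(dir, "classification.json")
  jsonlite::write_json(list(
    provenance = report$provenance, params = unclass(report$params),
    summary = report$summary,
    losses = lapply(report$losses, function(reps)
      lapply(reps, function(r) list(motif = r$motif,
                                    removed_seq_ids = r$removed_seq_ids,
                                    pairs = r$pairs)))),
    js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(csv, js))
}

#' Emit the full construct catalogue
#'
#' Combines the six isoforms, the N- and C-terminal truncation series and
#' the three hexamer-extension constructs into one table with lengths,
#' predicted and observed amyloidogenicity. A `note` column flags the
#' N-series rows, whose default cut points are not asserted to reproduce
#' the observed outcomes (the original endpoints are not recoverable from
#' the domain map alone).
#'
#' @param map a [tau_domain_map()].
#' @param template the 2N4R template sequence.
#' @return Construct table with 22 rows (6 isoforms + 8 N + 5 C + 3
#'   extensions) and a `series` column.
#' @export
run_constructs <- function(map = tau_domain_map(),
                           template = tau_2N4R_sequence()) {
  iso <- build_isoforms(map, template);              iso$series <- "isoform"
  nser <- build_truncation_series(map, template, "n_terminal")
  nser$series <- "N"
  cser <- build_truncation_series(map, template, "c_terminal")
  cser$series <- "C"
  ext <- build_extension_constructs(map, template);  ext$series <- "extension"
  out <- rbind(iso, nser, cser, ext)
  out$note <- ifelse(out$series == "N",
                     "default N-series endpoints approximate; prediction not asserted against observed outcome",
                     "")
  rownames(out) <- NULL
  out
}

#' Write the construct catalogue as TSV and FASTA
#'
#' @param constructs a construct table from [run_constructs()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_constructs <- function(constructs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, "constructs.tsv")
  cols <- c("name", "series", "parent", "length", "predicted_amyloidogenic",
            "observed_amyloidogenic", "note")
  utils::write.table(constructs[, cols], tsv, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  fa <- file.path(dir, "constructs.fasta")
  write_construct_fasta(constructs, fa)
  invisible(c(tsv, fa))
}

#' Emit reproducible fixtures, curves and their ground truth
#'
#' Writes, under `dir`: a planted-contact fixture (PDB), a two-layer mini
#' fibril (PDB), one aggregating and one flat simulated ThT curve (CSV),
#' and a `truth.json` recording the planted contacts and simulation
#' parameters so downstream checks can compare engine output against known
#' ground truth. Byte-identical for identical seeds.
#'
#' @param dir output directory (created if missing).
#' @param seed integer seed controlling every random draw.
#' @return Invisibly, the paths written.
#' @export
run_simulate <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spec <- contact_fixture_spec(
    residues = data.frame(chain_id = "A", seq_id = c(10L, 20L, 30L, 40L),
                          res_name = c("TYR", "HIS", "VAL", "LEU")),
    planted_pairs = list(
      list(seq_id_a = 10, atom_a = "OH", seq_id_b = 20, atom_b = "NE2",
           distance = 3.2, type = "hbond"),
      list(seq_id_a = 30, atom_a = "CG1", seq_id_b = 40, atom_b = "CD1",
           distance = 4.9, type = "hydrophobic")))
  fx <- make_contact_fixture(spec, seed = seed)
  p_fx <- file.path(dir, "fixture.pdb")
  write_structure_pdb(fx, p_fx)
  fib <- make_minifibril(minifibril_spec(spec, n_layers = 2L), seed = seed)
  p_fib <- file.path(dir, "minifibril.pdb")
  write_structure_pdb(fib, p_fib)
  pos <- simulate_tht(tht_sim_params(seed = seed), name = "aggregating")
  neg <- simulate_tht(tht_sim_params(aggregating = FALSE, seed = seed + 1L),
                      name = "flat")
  p_pos <- file.path(dir, "tht_aggregating.csv")
  p_neg <- file.path(dir, "tht_flat.csv")
  write_tht_csv(pos, p_pos); write_tht_csv(neg, p_neg)
  truth <- list(
    seed = seed,
    planted_pairs = lapply(spec$planted_pairs, function(p)
      p[c("seq_id_a", "atom_a", "seq_id_b", "atom_b", "distance", "type")]),
    decoy_min_distance = spec$decoy_min_distance,
    minifibril = list(n_layers = 2L, rise_per_layer = 4.7),
    tht = list(aggregating = unclass(attr(pos, "params")),
               flat = unclass(attr(neg, "params"))))
  p_truth <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, p_truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(p_fx, p_fib, p_pos, p_neg, p_truth))
}
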