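# Nucleation-motif scanning and single/dual-core strain classification.

#' The tau nucleation motifs
#'
#' PHF6 (`VQIVYK`, the start of repeat R3) and PHF6* (`VQIINK`, the start of
#' repeat R2) are the hexameric aggregation nucleation cores of tau; `VQI` is
#' their three-residue consensus. `suffix_len` gives the number of C-terminal
#' motif residues removed in the truncation-loss analysis (the `VYK` / `INK`
#' suffix).
#'
#' @return Data frame with columns `name`, `sequence`, `suffix_len`.
#' @export
tau_motifs <- function() {
  data.frame(name = c("PHF6", "PHF6*", "VQI"),
             sequence = c("VQIVYK", "VQIINK", "VQI"),
             suffix_len = c(3L, 3L, 0L),
             stringsAsFactors = FALSE)
}

.as_modeled_sequence <- function(seq) {
  if (inherits(seq, "modeled_sequence")) return(seq)
  if (is.character(seq) && length(seq) == 1L) {
    n <- nchar(seq)
    return(structure(list(sequence = toupper(seq), seq_ids = seq_len(n),
                          gap_after = rep(FALSE, n)),
                     class = "modeled_sequence"))
  }
  stop("expected a modeled_sequence or a single character string")
}

#' Scan a modeled sequence for nucleation motifs
#'
#' Reports every occurrence of each motif in the concatenated one-letter
#' string of resolved residues, including overlapping occurrences (`VQI` is
#' a prefix of both hexamers). An occurrence whose residues span a numbering
#' gap is reported but marked not fully resolved.
#'
#' @param seq a `modeled_sequence` (see [extract_sequence()]) or a plain
#'   character string (numbered 1..n).
#' @param motifs a motif table as returned by [tau_motifs()].
#' @return Data frame of hits: `motif`, `start_seq_id`, `end_seq_id`
#'   (author numbering of the first and last matched residue) and
#'   `fully_resolved` (`TRUE` iff all motif residues are present
#'   consecutively in the model).
#' @examples
#' scan_motifs(tau_2N4R_sequence())
#' @export
scan_motifs <- function(seq, motifs = tau_motifs()) {
  ms <- .as_modeled_sequence(seq)
  s <- ms$sequence
  hits <- list()
  for (m in seq_len(nrow(motifs))) {
    pat <- toupper(motifs$sequence[m])
    w <- nchar(pat)
    if (w == 0L || w > nchar(s)) next
    starts <- which(vapply(seq_len(nchar(s) - w + 1L),
                           function(i) substr(s, i, i + w - 1L) == pat,
                           logical(1)))
    for (i in starts) {
      ids <- ms$seq_ids[i:(i + w - 1L)]
      hits[[length(hits) + 1L]] <- data.frame(
        motif = motifs$name[m],
        start_seq_id = ids[1], end_seq_id = ids[w],
        fully_resolved = (ids[w] - ids[1] + 1L) == w,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) {
    return(data.frame(motif = character(0), start_seq_id = integer(0),
                      end_seq_id = integer(0), fully_resolved = logical(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$motif, out$start_seq_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify a fold by its resolved nucleation cores
#'
#' A fold with both hexamers ordered in the model is a dual-core strain;
#' with exactly one, a single-core strain (in all tauopathy structures
#' determined so far that core is PHF6/VQIVYK); with neither, no core.
#' Only fully resolved hexamer occurrences count: an unresolved VQIINK is
#' exactly what distinguishes the single-core AD/CTE/Pick folds.
#'
#' @param hits a hit table from [scan_motifs()] computed on one protomer.
#' @return A `strain_class`: list with `label` (`"single_core"`,
#'   `"dual_core"` or `"no_core"`) and `cores_present` (character vector of
#'   resolved hexamer motif names).
#' @export
classify_fold <- function(hits) {
  cores <- sort(unique(hits$motif[hits$fully_resolved &
                                  hits$motif %in% c("PHF6", "PHF6*")]))
  label <- switch(as.character(length(cores)),
                  "0" = "no_core", "1" = "single_core", "2" = "dual_core")
  structure(list(label = label, cores_present = cores),
            class = "strain_class")
}

#' @export
print.strain_class <- function(x, ...) {
  cat("strain_class:", x$label,
      if (length(x$cores_present))
        paste0("(", paste(x$cores_present, collapse = " + "), ")") else "",
      "\n")
  invisible(x)
}

#' Residue-pair interactions lost by truncating a motif suffix
#'
#' Computes the interactions that disappear when the last `suffix_len`
#' residues of a nucleation hexamer (the `VYK` of VQIVYK or `INK` of VQIINK)
#' are removed: all residue-pair interactions of the protomer involving a
#' removed residue, excluding pairs internal to the motif itself.
#'
#' @param protomer a typed `tau_protomer`.
#' @param hit one row of a [scan_motifs()] hit table (must be fully
#'   resolved on this protomer).
#' @param params a [contact_params()] object.
#' @param motifs motif table supplying `suffix_len` per motif name.
#' @return A `loss_report`: list with `motif`, `removed_seq_ids`, and
#'   `pairs` (a residue-pair interaction table sorted by residue number).
#' @export
truncation_loss <- function(protomer, hit, params = contact_params(),
                            motifs = tau_motifs()) {
  if (is.data.frame(hit)) {
    stopifnot(nrow(hit) == 1L)
    hit <- as.list(hit)
  }
  if (!isTRUE(hit$fully_resolved))
    stop("motif hit is not fully resolved on this protomer")
  suffix_len <- motifs$suffix_len[match(hit$motif, motifs$name)]
  if (is.na(suffix_len) || suffix_len < 1L)
    stop("motif '", hit$motif, "' has no truncation suffix defined")
  removed <- (hit$end_seq_id - suffix_len + 1L):hit$end_seq_id
  motif_range <- hit$start_seq_id:hit$end_seq_id
  pairs <- aggregate_residue_pairs(find_contacts(protomer, params))
  touches <- pairs$seq_id_a %in% removed | pairs$seq_id_b %in% removed
  internal <- pairs$seq_id_a %in% motif_range & pairs$seq_id_b %in% motif_range
  lost <- pairs[touches & !internal, , drop = FALSE]
  lost <- lost[order(lost$seq_id_a, lost$seq_id_b), , drop = FALSE]
  rownames(lost) <- NULL
  structure(list(motif = hit$motif, removed_seq_ids = removed, pairs = lost),
            class = "loss_report")
}

#' @export
print.loss_report <- function(x, ...) {
  cat("loss_report:", x$motif, "suffix", paste(range(x$removed_seq_ids),
                                               collapse = "-"),
      "->", nrow(x$pairs), "lost residue-pair interaction(s)\n")
  if (nrow(x$pairs)) print(x$pairs)
  invisible(x)
}

#' Rank nucleation cores by lost-interaction count
#'
#' Orders cores by the total number of residue-pair interactions in their
#' truncation-loss reports, descending; the top core is the primary
#' nucleation core. Ties are broken alphabetically by motif name and
#' flagged.
#'
#' @param reports list of `loss_report` objects (one per core).
#' @return Data frame with columns `motif`, `n_pairs`, `rank`, `role`
#'   (`"primary"` / `"secondary"`), `tied`.
#' @export
rank_cores <- function(reports) {
  if (!length(reports)) stop("at least one loss report required")
  df <- data.frame(
    motif = vapply(reports, `[[`, character(1), "motif"),
    n_pairs = vapply(reports, function(r) nrow(r$pairs), integer(1)),
    stringsAsFactors = FALSE)
  df <- df[order(-df$n_pairs, df$motif), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  df$role <- ifelse(df$rank == 1L, "primary", "secondary")
  df$tied <- duplicated(df$n_pairs) | duplicated(df$n_pairs, fromLast = TRUE)
  rownames(df) <- NULL
  df
}
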