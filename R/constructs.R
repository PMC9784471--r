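# Tau isoform and truncation/extension construct design.
#
# All constructs are defined as sets of retained closed intervals on the
# 2N4R numbering (1-based), optionally followed by an appended motif.
# Purification tags are never part of the designed sequence: tags are
# plumbing, not motif logic.

#' Domain-boundary map of tau 2N4R
#'
#' Named, contiguous, non-overlapping 1-based closed intervals covering the
#' full 441-residue 2N4R template. Defaults follow the standard numbering:
#' the N-terminal inserts N1/N2, the proline-rich domain, the four
#' microtubule-binding repeats R1-R4 (R2 starting with VQIINK at 275, R3
#' with VQIVYK at 306), and the C-terminal tail. All boundaries can be
#' overridden, or loaded from JSON with [read_domain_map()].
#'
#' @param boundaries named list of `c(start, end)` integer pairs.
#' @param template_length total template length (default 441).
#' @return A validated `tau_domain_map`.
#' @export
tau_domain_map <- function(boundaries = list(
                             N_head = c(1, 44), N1_insert = c(45, 73),
                             N2_insert = c(74, 102), mid = c(103, 150),
                             proline_rich = c(151, 243), R1 = c(244, 274),
                             R2 = c(275, 305), R3 = c(306, 336),
                             R4 = c(337, 368), C_tail = c(369, 441)),
                           template_length = 441L) {
  need <- c("N1_insert", "N2_insert", "R1", "R2", "R3", "R4")
  if (!all(need %in% names(boundaries)))
    stop("domain map must name at least: ", paste(need, collapse = ", "))
  iv <- do.call(rbind, boundaries)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  if (iv[1, 1] != 1L || iv[nrow(iv), 2] != template_length ||
      any(iv[-1, 1] != iv[-nrow(iv), 2] + 1L))
    stop("domain intervals must be contiguous, non-overlapping and cover 1..",
         template_length)
  structure(list(boundaries = lapply(boundaries, as.integer),
                 template_length = as.integer(template_length)),
            class = "tau_domain_map")
}

#' Read a domain map from a JSON boundary configuration
#'
#' @param path JSON file mapping domain names to `[start, end]` pairs, with
#'   an optional `template_length` entry.
#' @return A `tau_domain_map`.
#' @export
read_domain_map <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  len <- if (!is.null(cfg$template_length)) cfg$template_length else 441L
  cfg$template_length <- NULL
  tau_domain_map(boundaries = lapply(cfg, as.integer), template_length = len)
}

.check_template <- function(map, template) {
  if (nchar(template) != map$template_length)
    stop("template length ", nchar(template), " does not match domain map (",
         map$template_length, ")")
  r2 <- map$boundaries$R2; r3 <- map$boundaries$R3
  if (substr(template, r2[1], r2[1] + 5) != "VQIINK")
    stop("R2 must begin with VQIINK at ", r2[1])
  if (substr(template, r3[1], r3[1] + 5) != "VQIVYK")
    stop("R3 must begin with VQIVYK at ", r3[1])
  invisible(TRUE)
}

.construct_row <- function(name, parent, intervals, template,
                           appended_motif = "", observed = NA) {
  iv <- matrix(as.integer(intervals), ncol = 2, byrow = TRUE)
  if (any(iv[, 1] > iv[, 2]) || any(iv < 1) || any(iv > nchar(template)))
    stop("invalid interval for construct ", name)
  seq <- paste0(paste(vapply(seq_len(nrow(iv)),
                             function(i) substr(template, iv[i, 1], iv[i, 2]),
                             character(1)), collapse = ""), appended_motif)
  expected <- sum(iv[, 2] - iv[, 1] + 1L) + nchar(appended_motif)
  stopifnot(nchar(seq) == expected)   # length conservation by construction
  data.frame(name = name, parent = parent,
             intervals = I(list(iv)), appended_motif = appended_motif,
             sequence = seq, length = nchar(seq),
             predicted_amyloidogenic = predict_amyloidogenic(seq),
             observed_amyloidogenic = observed,
             stringsAsFactors = FALSE)
}

#' Build the six human tau isoforms from the domain map
#'
#' Generates all combinations of 0/1/2 N-terminal inserts (dropping N1+N2,
#' N2 only, or neither) and 3R/4R repeats (dropping R2 or not). The 2N4R
#' isoform reproduces the template exactly.
#'
#' @param map a [tau_domain_map()].
#' @param template the 2N4R template sequence (default the packaged
#'   canonical sequence).
#' @return Construct table with 6 rows (columns as in
#'   [build_truncation_series()]); all six isoforms retain VQIVYK and are
#'   predicted amyloidogenic, 3R isoforms lack VQIINK.
#' @export
build_isoforms <- function(map = tau_domain_map(),
                           template = tau_2N4R_sequence()) {
  .check_template(map, template)
  b <- map$boundaries
  len <- map$template_length
  drop_iv <- function(drops) {
    # retained intervals = template minus the dropped domains
    keep <- rep(TRUE, len)
    for (d in drops) keep[b[[d]][1]:b[[d]][2]] <- FALSE
    r <- rle(keep)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    as.vector(t(cbind(starts[r$values], ends[r$values])))
  }
  n_opts <- list(`2N` = character(0), `1N` = "N2_insert",
                 `0N` = c("N1_insert", "N2_insert"))
  r_opts <- list(`4R` = character(0), `3R` = "R2")
  rows <- list()
  for (ni in names(n_opts)) for (ri in names(r_opts)) {
    nm <- paste0(ni, ri)
    rows[[nm]] <- .construct_row(nm, "2N4R",
                                 drop_iv(c(n_opts[[ni]], r_opts[[ri]])),
                                 template, observed = TRUE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Default truncation-series cut points
#'
#' One cut per named domain boundary of the default map: the N-terminal
#' series starts each construct at successive domain starts, the C-terminal
#' series ends each construct at successive domain ends (working inward).
#'
#' @param direction `"n_terminal"` or `"c_terminal"`.
#' @return Integer vector of cut points on 2N4R numbering.
#' @export
default_cuts <- function(direction = c("n_terminal", "c_terminal")) {
  direction <- match.arg(direction)
  if (direction == "n_terminal") c(45L, 74L, 103L, 151L, 244L, 275L, 306L, 337L)
  else c(368L, 336L, 305L, 274L, 243L)
}

#' Build a systematic truncation series
#'
#' N-terminal series: construct k retains `[cut_k, template_length]`
#' (progressively deleting from the N-terminus, names N1, N2, ...).
#' C-terminal series: construct k retains `[1, cut_k]` (names C1, C2, ...).
#'
#' @param map a [tau_domain_map()].
#' @param template the 2N4R template sequence.
#' @param direction `"n_terminal"` or `"c_terminal"`.
#' @param cuts ordered cut points; must be strictly monotone (increasing for
#'   the N-series, decreasing for the C-series) and within the template.
#' @return Construct table, one row per cut. `observed_amyloidogenic`
#'   carries the reported aggregation outcome for the default series
#'   (N1-N6 and C1-C3 positive, N7/N8 and C4/C5 negative); note that for
#'   the N-series the default domain-boundary cut points are not asserted
#'   to reproduce those outcomes (the exact construct endpoints of the
#'   original series are not recoverable; see the package vignette).
#' @export
build_truncation_series <- function(map = tau_domain_map(),
                                    template = tau_2N4R_sequence(),
                                    direction = c("n_terminal", "c_terminal"),
                                    cuts = default_cuts(direction)) {
  direction <- match.arg(direction)
  .check_template(map, template)
  cuts <- as.integer(cuts)
  if (direction == "n_terminal") {
    if (any(diff(cuts) <= 0)) stop("n_terminal cuts must be strictly increasing")
  } else if (any(diff(cuts) >= 0)) stop("c_terminal cuts must be strictly decreasing")
  if (any(cuts < 1L | cuts > map$template_length))
    stop("cuts must lie within the template")
  prefix <- if (direction == "n_terminal") "N" else "C"
  default_obs <- list(
    n_terminal = c(rep(TRUE, 6), FALSE, FALSE),
    c_terminal = c(TRUE, TRUE, TRUE, FALSE, FALSE))
  obs <- if (identical(cuts, default_cuts(direction)))
    default_obs[[direction]] else rep(NA, length(cuts))
  rows <- lapply(seq_along(cuts), function(k) {
    iv <- if (direction == "n_terminal") c(cuts[k], map$template_length)
          else c(1L, cuts[k])
    .construct_row(paste0(prefix, k), "2N4R", iv, template, observed = obs[k])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build the hexamer-extension constructs C6, C7, C8
#'
#' All three use the non-amyloidogenic C4 carrier (residues 1 to the end of
#' R1): C6 appends VQIINK (in the 2N4R parent, VQIINK of R2 directly joins
#' R1), C8 appends the trimeric consensus VQI, and C7 is built on the 2N3R
#' parent, where VQIVYK of R3 directly joins R1, truncated right after the
#' hexamer so it ends ...VQIVYK.
#'
#' @param map a [tau_domain_map()].
#' @param template the 2N4R template sequence (the 2N3R parent is derived
#'   from it by dropping R2).
#' @return Construct table with rows C6, C7, C8 (observed aggregation
#'   outcomes: C6 and C7 positive, C8 negative).
#' @export
build_extension_constructs <- function(map = tau_domain_map(),
                                       template = tau_2N4R_sequence()) {
  .check_template(map, template)
  r1_end <- map$boundaries$R1[2]
  r3 <- map$boundaries$R3
  rbind(
    .construct_row("C6", "2N4R", c(1L, r1_end), template,
                   appended_motif = "VQIINK", observed = TRUE),
    .construct_row("C7", "2N3R", c(1L, r1_end, r3[1], r3[1] + 5L), template,
                   observed = TRUE),
    .construct_row("C8", "2N4R", c(1L, r1_end), template,
                   appended_motif = "VQI", observed = FALSE))
}

#' Intact-hexamer amyloidogenicity rule
#'
#' A tau-derived sequence is predicted amyloidogenic iff it contains an
#' intact nucleation hexamer -- VQIVYK or VQIINK -- as a contiguous
#' substring. The trimeric consensus VQI alone does not qualify.
#'
#' @param seq a character sequence, or a construct table row with a
#'   `sequence` column.
#' @return Logical vector.
#' @examples
#' predict_amyloidogenic("AAVQIVYKAA")  # TRUE
#' predict_amyloidogenic("AAVQIAA")     # FALSE
#' @export
predict_amyloidogenic <- function(seq) {
  if (is.data.frame(seq)) seq <- seq$sequence
  grepl("VQIVYK", seq, fixed = TRUE) | grepl("VQIINK", seq, fixed = TRUE)
}

#' Write constructs to FASTA
#'
#' Standard 60-column FASTA; each header carries the construct name, length
#' and predicted amyloidogenicity flag.
#'
#' @param constructs a construct table (rows from the `build_*` functions).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_construct_fasta <- function(constructs, path) {
  if (anyDuplicated(constructs$name))
    stop("duplicate construct names: ",
         paste(unique(constructs$name[duplicated(constructs$name)]),
               collapse = ", "))
  if (nrow(constructs) == 0L) {
    warning("writing empty FASTA: no constructs supplied")
    file.create(path)
    return(invisible(path))
  }
  aas <- Biostrings::AAStringSet(constructs$sequence)
  names(aas) <- sprintf("%s length=%d amyloidogenic=%s", constructs$name,
                        constructs$length,
                        ifelse(constructs$predicted_amyloidogenic, "yes", "no"))
  Biostrings::writeXStringSet(aas, path, width = 60L)
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return Named character vector of sequences (names are the first word of
#'   each header).
#' @export
read_fasta_sequences <- function(path) {
  aas <- Biostrings::readAAStringSet(path)
  out <- as.character(aas)
  names(out) <- vapply(strsplit(names(aas), "\\s+"), `[[`, character(1), 1)
  out
}
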