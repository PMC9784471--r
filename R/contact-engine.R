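# Intra-protomer contact enumeration under heavy-atom distance criteria.
#
# A hydrogen bond is any donor-capable/acceptor-capable atom pair within
# hbond_max; a hydrophobic contact is any apolar-carbon pair within
# hydrophobic_max. Distances are Euclidean on heavy atoms; ties at exactly
# the cutoff are included. A polar pair inside both cutoffs is reported once,
# as a hydrogen bond (atom classes are disjoint, so a pair can never satisfy
# both definitions).

#' Contact-detection parameters
#'
#' @param hbond_max maximum hydrogen-bond length, in Angstrom (default 3.3).
#' @param hydrophobic_max maximum hydrophobic-interaction distance, in
#'   Angstrom (default 5.0).
#' @param min_seq_separation minimum residue-number separation `|i - j|` for
#'   a pair to be reported (default 3). With the default, trivial i+/-1 and
#'   i+/-2 proximities that follow from chain connectivity are suppressed;
#'   set to 0 for a full audit.
#' @param include_backbone_backbone report contacts where both atoms are
#'   backbone atoms (default `FALSE`; cross-beta backbone ladders are
#'   ubiquitous and uninformative for sidechain packing analysis).
#' @param include_sulfur treat CYS SG / MET SD as weakly donor- and
#'   acceptor-capable (default `TRUE`).
#' @return A `contact_params` list.
#' @export
contact_params <- function(hbond_max = 3.3, hydrophobic_max = 5.0,
                           min_seq_separation = 3L,
                           include_backbone_backbone = FALSE,
                           include_sulfur = TRUE) {
  stopifnot(hbond_max > 0, hbond_max <= hydrophobic_max,
            min_seq_separation >= 0)
  structure(list(hbond_max = hbond_max, hydrophobic_max = hydrophobic_max,
                 min_seq_separation = as.integer(min_seq_separation),
                 include_backbone_backbone = isTRUE(include_backbone_backbone),
                 include_sulfur = isTRUE(include_sulfur)),
            class = "contact_params")
}

.empty_contacts <- function() {
  data.frame(chain = character(0), seq_id_a = integer(0),
             res_name_a = character(0), atom_a = character(0),
             seq_id_b = integer(0), res_name_b = character(0),
             atom_b = character(0), distance = numeric(0),
             bond_type = character(0), stringsAsFactors = FALSE)
}

# Classify candidate atom pairs (index vectors i, j into the atom table) and
# return canonical contact rows. Shared by the cell-list and brute-force paths.
.classify_pairs <- function(a, i, j, params) {
  if (!length(i)) return(.empty_contacts())
  keep <- abs(a$seq_id[i] - a$seq_id[j]) >= params$min_seq_separation &
    a$seq_id[i] != a$seq_id[j]
  if (!params$include_backbone_backbone)
    keep <- keep & !(a$is_backbone[i] & a$is_backbone[j])
  i <- i[keep]; j <- j[keep]
  if (!length(i)) return(.empty_contacts())
  d <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 + (a$z[i] - a$z[j])^2)
  don <- a$is_donor | (params$include_sulfur & a$is_sulfur)
  acc <- a$is_acceptor | (params$include_sulfur & a$is_sulfur)
  hb <- ((don[i] & acc[j]) | (don[j] & acc[i])) & d <= params$hbond_max
  hp <- a$is_apolar[i] & a$is_apolar[j] & d <= params$hydrophobic_max
  sel <- hb | hp
  if (!any(sel)) return(.empty_contacts())
  i <- i[sel]; j <- j[sel]; d <- d[sel]
  type <- ifelse(hb[sel], "hbond", "hydrophobic")
  # canonical order: seq_id_a < seq_id_b
  swap <- a$seq_id[i] > a$seq_id[j]
  tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
  out <- data.frame(
    chain = a$chain[i],
    seq_id_a = a$seq_id[i], res_name_a = a$res_name[i], atom_a = a$atom_name[i],
    seq_id_b = a$seq_id[j], res_name_b = a$res_name[j], atom_b = a$atom_name[j],
    distance = d, bond_type = type, stringsAsFactors = FALSE)
  out <- out[order(out$seq_id_a, out$seq_id_b, out$atom_a, out$atom_b), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

.check_typed <- function(a) {
  if (any(!a$typed))
    stop("configuration error: ", sum(!a$typed), " untyped atom(s), e.g. ",
         paste(utils::head(unique(paste(a$res_name[!a$typed],
                                        a$atom_name[!a$typed])), 5),
               collapse = ", "),
         "; extend the typing templates or remove these atoms")
}

#' Enumerate intra-protomer atomic contacts
#'
#' Finds all hydrogen-bond and hydrophobic contacts within one protomer
#' using a cell-list spatial index (cells of edge `hydrophobic_max`; only the
#' 27 neighbouring cells of each atom are searched). Results are identical to
#' the exhaustive all-pairs scan of [brute_force_contacts()].
#'
#' @param protomer a typed `tau_protomer` from [select_protomer()].
#' @param params a [contact_params()] object.
#' @return A data frame of atomic contacts, one row per atom pair, with
#'   columns `chain`, `seq_id_a`, `res_name_a`, `atom_a`, `seq_id_b`,
#'   `res_name_b`, `atom_b`, `distance`, `bond_type`; ordered by residue then
#'   atom, with `seq_id_a < seq_id_b`.
#' @export
find_contacts <- function(protomer, params = contact_params()) {
  a <- .atoms_of(protomer)
  .check_typed(a)
  n <- nrow(a)
  if (n < 2L) return(.empty_contacts())
  L <- params$hydrophobic_max
  cx <- floor(a$x / L); cy <- floor(a$y / L); cz <- floor(a$z / L)
  # collapse 3D cell coordinates to a single integer key
  ox <- cx - min(cx); oy <- cy - min(cy); oz <- cz - min(cz)
  nx <- max(ox) + 1; ny <- max(oy) + 1
  key <- ox + nx * (oy + ny * oz)
  cells <- split(seq_len(n), key)
  keys <- as.numeric(names(cells))
  keypos <- stats::setNames(seq_along(cells), names(cells))
  # 13 forward offsets + self avoid double counting across cells
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[offs$dz > 0 | (offs$dz == 0 & (offs$dy > 0 |
          (offs$dy == 0 & offs$dx > 0))), , drop = FALSE]
  ii <- integer(0); jj <- integer(0)
  for (c_idx in seq_along(cells)) {
    members <- cells[[c_idx]]
    if (length(members) > 1L) {
      pr <- utils::combn(members, 2L)
      ii <- c(ii, pr[1, ]); jj <- c(jj, pr[2, ])
    }
    k <- keys[c_idx]
    kz <- k %/% (nx * ny); rem <- k %% (nx * ny)
    ky <- rem %/% nx; kx <- rem %% nx
    for (o in seq_len(nrow(offs))) {
      nk <- (kx + offs$dx[o]) + nx * ((ky + offs$dy[o]) + ny * (kz + offs$dz[o]))
      # guard against wrap-around at the grid faces
      if (kx + offs$dx[o] < 0 || kx + offs$dx[o] >= nx) next
      if (ky + offs$dy[o] < 0 || ky + offs$dy[o] >= ny) next
      pos <- keypos[as.character(nk)]
      if (is.na(pos)) next
      other <- cells[[pos]]
      ii <- c(ii, rep(members, each = length(other)))
      jj <- c(jj, rep(other, times = length(members)))
    }
  }
  .classify_pairs(a, ii, jj, params)
}

#' Exhaustive all-pairs contact oracle
#'
#' Computes the same contact set as [find_contacts()] by checking every atom
#' pair with a full distance matrix. Quadratic in atom count; intended as the
#' independent reference for validating the spatial-indexed engine.
#'
#' @inheritParams find_contacts
#' @return Same as [find_contacts()].
#' @export
brute_force_contacts <- function(protomer, params = contact_params()) {
  a <- .atoms_of(protomer)
  .check_typed(a)
  n <- nrow(a)
  if (n < 2L) return(.empty_contacts())
  pr <- utils::combn(seq_len(n), 2L)
  .classify_pairs(a, pr[1, ], pr[2, ], params)
}

#' Aggregate atomic contacts to residue-pair interactions
#'
#' @param contacts a contact data frame from [find_contacts()].
#' @return A data frame with one row per unordered residue pair: `seq_id_a`,
#'   `res_name_a`, `seq_id_b`, `res_name_b`, `n_hbond`, `n_hydrophobic`,
#'   `min_distance`, `dominant_type` (`"hbond"` whenever at least one
#'   hydrogen bond is present, else `"hydrophobic"`).
#' @export
aggregate_residue_pairs <- function(contacts) {
  if (nrow(contacts) == 0L) {
    return(data.frame(seq_id_a = integer(0), res_name_a = character(0),
                      seq_id_b = integer(0), res_name_b = character(0),
                      n_hbond = integer(0), n_hydrophobic = integer(0),
                      min_distance = numeric(0), dominant_type = character(0),
                      stringsAsFactors = FALSE))
  }
  key <- paste(contacts$seq_id_a, contacts$seq_id_b)
  grp <- split(seq_len(nrow(contacts)), key)
  rows <- lapply(grp, function(idx) {
    cc <- contacts[idx, , drop = FALSE]
    nh <- sum(cc$bond_type == "hbond")
    data.frame(seq_id_a = cc$seq_id_a[1], res_name_a = cc$res_name_a[1],
               seq_id_b = cc$seq_id_b[1], res_name_b = cc$res_name_b[1],
               n_hbond = nh, n_hydrophobic = sum(cc$bond_type == "hydrophobic"),
               min_distance = min(cc$distance),
               dominant_type = if (nh >= 1) "hbond" else "hydrophobic",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$seq_id_a, out$seq_id_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Residue-pair interactions touching a set of residues
#'
#' Filters a residue-pair table to rows where either residue belongs to the
#' query set, and names the partner outside the set as the spatial
#' neighbour (`NA` when both members are inside the set).
#'
#' @param pairs a residue-pair table from [aggregate_residue_pairs()].
#' @param seq_ids integer vector of query residue numbers.
#' @return The filtered table with extra columns `neighbour_seq_id` and
#'   `neighbour_res_name`.
#' @export
neighbors_of <- function(pairs, seq_ids) {
  in_a <- pairs$seq_id_a %in% seq_ids
  in_b <- pairs$seq_id_b %in% seq_ids
  out <- pairs[in_a | in_b, , drop = FALSE]
  ia <- in_a[in_a | in_b]; ib <- in_b[in_a | in_b]
  out$neighbour_seq_id <- ifelse(ia & ib, NA_integer_,
                                 ifelse(ia, out$seq_id_b, out$seq_id_a))
  out$neighbour_res_name <- ifelse(ia & ib, NA_character_,
                                   ifelse(ia, out$res_name_b, out$res_name_a))
  rownames(out) <- NULL
  out
}
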