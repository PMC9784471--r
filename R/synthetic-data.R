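# Synthetic fixtures with exactly known ground truth.
#
# Residues are laid out on a coarse 1D grid with per-residue jitter; planted
# atom pairs are then positioned analytically on a parallel "planting row",
# one lattice site per pair. With grid spacing 2*(decoy_min + d_max) every
# non-planted inter-residue atom pair is guaranteed farther than
# decoy_min_distance, so the contact engine must recover exactly the planted
# pairs that fall inside its cutoffs -- no optimisation, no accidental decoys.
# Construction is verified a posteriori by an all-pairs distance check and
# aborts if the requested geometry is unsatisfiable.

#' Specification of a planted-contact fixture
#'
#' @param residues data frame with columns `chain_id`, `seq_id`, `res_name`
#'   (3-letter codes); `(chain_id, seq_id)` must be unique. All residues of a
#'   fixture must share one chain id.
#' @param planted_pairs list of planted atom pairs; each element is a list
#'   `list(seq_id_a, atom_a, seq_id_b, atom_b, distance, type)` with `type`
#'   one of `"hbond"`, `"hydrophobic"`, `"none"`. Hydrogen-bond pairs must
#'   use donor/acceptor-capable atom names, hydrophobic pairs apolar carbons,
#'   and `"none"` pairs must request a distance beyond both default cutoffs.
#'   Any atom may appear in at most one planted pair.
#' @param decoy_min_distance minimum separation, in Angstrom, guaranteed
#'   between all non-planted inter-residue atom pairs (default 8).
#' @return A validated `contact_fixture_spec`.
#' @export
contact_fixture_spec <- function(residues, planted_pairs = list(),
                                 decoy_min_distance = 8) {
  stopifnot(is.data.frame(residues),
            all(c("chain_id", "seq_id", "res_name") %in% names(residues)),
            decoy_min_distance > 0)
  residues$res_name <- toupper(residues$res_name)
  if (anyDuplicated(residues[, c("chain_id", "seq_id")]))
    stop("duplicate (chain_id, seq_id) in residues")
  if (length(unique(residues$chain_id)) != 1L)
    stop("all fixture residues must share one chain_id")
  if (!all(residues$res_name %in% names(.SIDECHAIN)))
    stop("unknown residue name(s): ",
         paste(setdiff(residues$res_name, names(.SIDECHAIN)), collapse = ", "))
  used_atoms <- character(0)
  for (p in planted_pairs) {
    p <- .normalize_pair(p)
    if (p$distance <= 0) stop("planted distance must be > 0")
    for (side in list(c(p$seq_id_a, p$atom_a), c(p$seq_id_b, p$atom_b))) {
      sid <- as.integer(side[1]); at <- side[2]
      row <- residues[residues$seq_id == sid, , drop = FALSE]
      if (nrow(row) == 0L) stop("planted pair references absent residue ", sid)
      tpl <- .TEMPLATES[.TEMPLATES$res_name == row$res_name &
                        .TEMPLATES$atom_name == at, , drop = FALSE]
      if (nrow(tpl) == 0L)
        stop("atom ", at, " not in template for ", row$res_name, " ", sid)
      tag <- paste(sid, at)
      if (tag %in% used_atoms)
        stop("infeasible geometry: atom ", tag,
             " appears in more than one planted pair")
      used_atoms <- c(used_atoms, tag)
    }
    cap <- .pair_capability(residues, p)
    if (p$type == "hbond" && !cap$hbond)
      stop("planted hbond pair (", p$seq_id_a, " ", p$atom_a, ", ", p$seq_id_b,
           " ", p$atom_b, ") is not donor/acceptor-capable")
    if (p$type == "hydrophobic" && !cap$hydrophobic)
      stop("planted hydrophobic pair must use apolar carbons")
    if (p$type == "none" && p$distance <= 5.0)
      stop("'none' pairs must be beyond both default cutoffs (> 5.0)")
  }
  structure(list(residues = residues,
                 planted_pairs = lapply(planted_pairs, .normalize_pair),
                 decoy_min_distance = decoy_min_distance),
            class = "contact_fixture_spec")
}

.normalize_pair <- function(p) {
  stopifnot(all(c("seq_id_a", "atom_a", "seq_id_b", "atom_b", "distance",
                  "type") %in% names(p)))
  p$seq_id_a <- as.integer(p$seq_id_a); p$seq_id_b <- as.integer(p$seq_id_b)
  p$atom_a <- toupper(p$atom_a); p$atom_b <- toupper(p$atom_b)
  p$type <- match.arg(p$type, c("hbond", "hydrophobic", "none"))
  p
}

.atom_flags <- function(residues, seq_id, atom) {
  res <- residues$res_name[residues$seq_id == seq_id]
  .TEMPLATES[.TEMPLATES$res_name == res & .TEMPLATES$atom_name == atom, ]
}

.pair_capability <- function(residues, p) {
  fa <- .atom_flags(residues, p$seq_id_a, p$atom_a)
  fb <- .atom_flags(residues, p$seq_id_b, p$atom_b)
  don <- function(f) f$is_donor | f$is_sulfur
  acc <- function(f) f$is_acceptor | f$is_sulfur
  list(hbond = (don(fa) && acc(fb)) || (don(fb) && acc(fa)),
       hydrophobic = fa$is_apolar && fb$is_apolar)
}

#' Build a structure with planted contacts at exactly known distances
#'
#' Realises a [contact_fixture_spec()] as coordinates: every planted atom
#' pair sits at its requested distance (to machine precision, far below the
#' 1e-6 Angstrom contract) and every other inter-residue atom pair is
#' farther than `decoy_min_distance`. Deterministic for a fixed seed.
#'
#' @param spec a `contact_fixture_spec`.
#' @param seed integer seed for the per-residue jitter.
#' @return A `tau_structure` containing the full heavy-atom template of
#'   every residue.
#' @export
make_contact_fixture <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "contact_fixture_spec"))
  res <- spec$residues[order(spec$residues$seq_id), , drop = FALSE]
  n <- nrow(res)
  dmax <- max(c(5, vapply(spec$planted_pairs, `[[`, numeric(1), "distance")))
  s <- 2 * (spec$decoy_min_distance + dmax)
  rows <- vector("list", n)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  for (i in seq_len(n)) {
    tpl <- .TEMPLATES[.TEMPLATES$res_name == res$res_name[i], , drop = FALSE]
    jit <- stats::runif(3, -0.2, 0.2)                     # per-residue jitter
    k <- seq_len(nrow(tpl)) - 1L
    rows[[i]] <- data.frame(
      record = "ATOM", chain = res$chain_id[i], seq_id = res$seq_id[i],
      icode = "", res_name = res$res_name[i], atom_name = tpl$atom_name,
      element = tpl$element, altloc = "",
      x = i * s + jit[1], y = 0.5 * k + jit[2], z = jit[3],
      occupancy = 1, stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, rows)
  # analytic placement of planted pairs on the planting row (y = -s)
  for (k in seq_along(spec$planted_pairs)) {
    p <- spec$planted_pairs[[k]]
    mid <- c(k * s, -s, 0)
    ia <- which(atoms$seq_id == p$seq_id_a & atoms$atom_name == p$atom_a)
    ib <- which(atoms$seq_id == p$seq_id_b & atoms$atom_name == p$atom_b)
    atoms[ia, c("x", "y", "z")] <- mid - c(p$distance / 2, 0, 0)
    atoms[ib, c("x", "y", "z")] <- mid + c(p$distance / 2, 0, 0)
  }
  fx <- .new_structure(atoms, source = "synthetic:contact_fixture")
  .verify_fixture(fx, spec)
  fx
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

.verify_fixture <- function(fx, spec) {
  a <- fx$atoms
  tag <- paste(a$seq_id, a$atom_name)
  planted_idx <- matrix(0L, nrow = 0, ncol = 2)
  for (p in spec$planted_pairs) {
    ia <- which(tag == paste(p$seq_id_a, p$atom_a))
    ib <- which(tag == paste(p$seq_id_b, p$atom_b))
    d <- sqrt(sum((unlist(a[ia, c("x", "y", "z")]) -
                   unlist(a[ib, c("x", "y", "z")]))^2))
    if (abs(d - p$distance) > 1e-6)
      stop("infeasible geometry: planted pair off by ", abs(d - p$distance))
    planted_idx <- rbind(planted_idx, c(ia, ib))
  }
  xyz <- as.matrix(a[, c("x", "y", "z")])
  dm <- as.matrix(stats::dist(xyz))
  unplanted <- outer(a$seq_id, a$seq_id, "!=")   # inter-residue pairs only
  for (r in seq_len(nrow(planted_idx))) {
    unplanted[planted_idx[r, 1], planted_idx[r, 2]] <- FALSE
    unplanted[planted_idx[r, 2], planted_idx[r, 1]] <- FALSE
  }
  if (any(dm[unplanted] <= spec$decoy_min_distance))
    stop("infeasible geometry: a non-planted inter-residue pair fell inside ",
         "decoy_min_distance")
  invisible(TRUE)
}

#' Specification of a mini fibril stack
#'
#' @param protomer a [contact_fixture_spec()] describing one layer.
#' @param n_layers number of stacked protomer copies (>= 1).
#' @param rise_per_layer axial rise between consecutive layers, in Angstrom.
#'   Default 4.7, the canonical cross-beta stacking spacing.
#' @return A `minifibril_spec`.
#' @export
minifibril_spec <- function(protomer, n_layers = 1L, rise_per_layer = 4.7) {
  stopifnot(inherits(protomer, "contact_fixture_spec"))
  if (n_layers < 1L) stop("n_layers must be >= 1")
  if (rise_per_layer <= 0) stop("rise_per_layer must be > 0")
  structure(list(protomer = protomer, n_layers = as.integer(n_layers),
                 rise_per_layer = rise_per_layer), class = "minifibril_spec")
}

#' Build a mini fibril by stacking translated protomer copies
#'
#' Each layer is an exact copy of the protomer fixture translated along z by
#' multiples of the rise and assigned its own chain id (`A`, `B`, ...), so
#' equivalent atoms of adjacent chains are exactly one rise apart and the
#' intra-chain contact set is identical in every layer.
#'
#' @param spec a [minifibril_spec()].
#' @param seed integer seed, forwarded to [make_contact_fixture()].
#' @return A `tau_structure` with `n_layers` chains.
#' @export
make_minifibril <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "minifibril_spec"))
  if (spec$n_layers > 26L) stop("at most 26 layers supported")
  base <- make_contact_fixture(spec$protomer, seed = seed)
  layers <- lapply(seq_len(spec$n_layers), function(l) {
    a <- base$atoms
    a$chain <- LETTERS[l]
    a$z <- a$z + (l - 1L) * spec$rise_per_layer
    a
  })
  out <- .new_structure(do.call(rbind, layers), source = "synthetic:minifibril")
  out$atoms$is_standard <- TRUE
  out
}

#' Parameters for a simulated thioflavin-T aggregation curve
#'
#' @param amplitude plateau fluorescence gain, arbitrary units.
#' @param baseline starting fluorescence, arbitrary units.
#' @param t50 half-maximal time, hours.
#' @param rate_k logistic growth rate, 1/hour.
#' @param noise_sd standard deviation of additive Gaussian noise, a.u.
#' @param duration total observation time, hours (plate-reader runs of this
#'   kind typically plateau within 40-80 h).
#' @param n_points number of equally spaced time points (>= 10).
#' @param aggregating if `FALSE` the sigmoidal term is omitted and the curve
#'   is flat baseline plus noise.
#' @param seed integer seed for the noise.
#' @return A `tht_sim_params` list.
#' @export
tht_sim_params <- function(amplitude = 100, baseline = 10, t50 = 20,
                           rate_k = 0.5, noise_sd = 2, duration = 80,
                           n_points = 200L, aggregating = TRUE, seed = 1L) {
  stopifnot(duration > 0, n_points >= 10, noise_sd >= 0)
  structure(list(amplitude = amplitude, baseline = baseline, t50 = t50,
                 rate_k = rate_k, noise_sd = noise_sd, duration = duration,
                 n_points = as.integer(n_points),
                 aggregating = isTRUE(aggregating), seed = as.integer(seed)),
            class = "tht_sim_params")
}

#' Simulate a thioflavin-T fluorescence time series
#'
#' Aggregating curves follow a logistic
#' `baseline + amplitude / (1 + exp(-rate_k * (t - t50)))` plus Gaussian
#' noise; non-aggregating curves are flat baseline plus noise. Reproducible
#' under the seed carried in `params`.
#'
#' @param params a [tht_sim_params()] object.
#' @param name optional construct name stored as metadata.
#' @return A `tht_curve`: data frame with columns `time_h` and
#'   `fluorescence_au`, with the simulation parameters attached as the
#'   `"params"` attribute.
#' @export
simulate_tht <- function(params = tht_sim_params(), name = NA_character_) {
  stopifnot(inherits(params, "tht_sim_params"))
  t <- seq(0, params$duration, length.out = params$n_points)
  mu <- if (params$aggregating) {
    params$baseline + params$amplitude / (1 + exp(-params$rate_k * (t - params$t50)))
  } else rep(params$baseline, length(t))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(params$seed)
  y <- mu + stats::rnorm(length(t), 0, params$noise_sd)
  out <- data.frame(time_h = t, fluorescence_au = y)
  attr(out, "params") <- params
  attr(out, "name") <- name
  class(out) <- c("tht_curve", "data.frame")
  out
}
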