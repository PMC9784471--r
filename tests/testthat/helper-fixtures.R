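# Shared fixture builders for the test suite.

tpl <- atom_templates()
SC_DONORS <- tpl[tpl$is_donor & !tpl$is_backbone, c("res_name", "atom_name")]
SC_ACCEPTORS <- tpl[tpl$is_acceptor & !tpl$is_backbone, c("res_name", "atom_name")]
APOLARS <- tpl[tpl$is_apolar, c("res_name", "atom_name")]

# A deterministic random planted-contact fixture spec. Planted pairs use
# sidechain donor/acceptor atoms (so the backbone-backbone exclusion never
# interferes) and distances straddling the cutoffs, making the expected
# contact set exactly derivable from the spec.
random_fixture_spec <- function(n_residues, seed, max_pairs = 8L) {
  set.seed(seed)
  seq_ids <- cumsum(sample(1:4, n_residues, replace = TRUE)) + 100L
  res_names <- sample(unique(tpl$res_name), n_residues, replace = TRUE)
  residues <- data.frame(chain_id = "A", seq_id = seq_ids,
                         res_name = res_names, stringsAsFactors = FALSE)
  pairs <- list()
  used <- character(0)
  n_pairs <- sample(0:max_pairs, 1)
  tries <- 0
  while (length(pairs) < n_pairs && tries < 200) {
    tries <- tries + 1
    type <- sample(c("hbond", "hydrophobic", "none"), 1)
    i <- sample(n_residues, 1); j <- sample(n_residues, 1)
    if (abs(seq_ids[i] - seq_ids[j]) < 3) next
    pool_a <- switch(type,
      hbond = SC_DONORS, hydrophobic = APOLARS, none = APOLARS)
    pool_b <- switch(type,
      hbond = SC_ACCEPTORS, hydrophobic = APOLARS, none = APOLARS)
    ca <- pool_a$atom_name[pool_a$res_name == res_names[i]]
    cb <- pool_b$atom_name[pool_b$res_name == res_names[j]]
    if (length(ca)) ca <- ca[!paste(seq_ids[i], ca) %in% used]
    if (length(cb)) cb <- cb[!paste(seq_ids[j], cb) %in% used]
    if (!length(ca) || !length(cb)) next
    atom_a <- sample(ca, 1); atom_b <- sample(cb, 1)
    d <- switch(type,
      hbond = runif(1, 2.6, 3.6),
      hydrophobic = runif(1, 3.5, 5.6),
      none = runif(1, 5.5, 7.9))
    pairs[[length(pairs) + 1L]] <- list(
      seq_id_a = seq_ids[i], atom_a = atom_a,
      seq_id_b = seq_ids[j], atom_b = atom_b, distance = d, type = type)
    used <- c(used, paste(seq_ids[i], atom_a), paste(seq_ids[j], atom_b))
  }
  contact_fixture_spec(residues, planted_pairs = pairs)
}

# Expected contact set of a random fixture: planted pairs within their
# type's cutoff, in the engine's canonical residue order.
expected_planted_contacts <- function(spec, params = contact_params()) {
  keep <- Filter(function(p)
    (p$type == "hbond" && p$distance <= params$hbond_max) ||
    (p$type == "hydrophobic" && p$distance <= params$hydrophobic_max),
    spec$planted_pairs)
  if (!length(keep)) return(NULL)
  df <- do.call(rbind, lapply(keep, function(p) {
    if (p$seq_id_a > p$seq_id_b) {
      tmp <- p
      p$seq_id_a <- tmp$seq_id_b; p$atom_a <- tmp$atom_b
      p$seq_id_b <- tmp$seq_id_a; p$atom_b <- tmp$atom_a
    }
    data.frame(seq_id_a = p$seq_id_a, atom_a = p$atom_a,
               seq_id_b = p$seq_id_b, atom_b = p$atom_b,
               distance = p$distance, bond_type = p$type,
               stringsAsFactors = FALSE)
  }))
  df[order(df$seq_id_a, df$seq_id_b, df$atom_a, df$atom_b), , drop = FALSE]
}

# Small named fixture used across files: TYR-HIS polar pair + VAL-LEU
# apolar pair at configurable distances.
two_pair_spec <- function(d_polar = 3.2, d_apolar = 4.9) {
  contact_fixture_spec(
    residues = data.frame(chain_id = "A", seq_id = c(10L, 20L, 30L, 40L),
                          res_name = c("TYR", "HIS", "VAL", "LEU")),
    planted_pairs = list(
      list(seq_id_a = 10, atom_a = "OH", seq_id_b = 20, atom_b = "NE2",
           distance = d_polar, type = if (d_polar <= 5) "hbond" else "none"),
      list(seq_id_a = 30, atom_a = "CG1", seq_id_b = 40, atom_b = "CD1",
           distance = d_apolar,
           type = if (d_apolar <= 5) "hydrophobic" else "none")))
}
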