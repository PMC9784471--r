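test_that("distance cutoffs gate hydrogen-bond and hydrophobic classification", {
  # polar pair at 3.2 A: one hbond; apolar at 4.9: one hydrophobic
  p <- select_protomer(make_contact_fixture(two_pair_spec(3.2, 4.9)))
  ct <- find_contacts(p)
  expect_equal(nrow(ct), 2L)
  hb <- ct[ct$bond_type == "hbond", ]
  expect_equal(c(hb$seq_id_a, hb$seq_id_b), c(10L, 20L))
  expect_equal(hb$distance, 3.2)

  # polar pair at 3.4 A is not an hbond and never becomes hydrophobic
  ct2 <- find_contacts(select_protomer(make_contact_fixture(two_pair_spec(3.4, 4.9))))
  expect_equal(nrow(ct2), 1L)
  expect_equal(ct2$bond_type, "hydrophobic")

  # apolar pair at 5.1 A: no contact at default cutoffs
  ct3 <- find_contacts(select_protomer(make_contact_fixture(two_pair_spec(3.4, 5.1))))
  expect_equal(nrow(ct3), 0L)

  # ties at exactly the cutoff are included
  ct4 <- find_contacts(select_protomer(make_contact_fixture(two_pair_spec(3.3, 5.0))))
  expect_equal(nrow(ct4), 2L)
})

test_that("spatial-indexed engine equals the brute-force oracle on random fixtures", {
  for (seed in 1:12) {
    n <- sample(10:120, 1)
    spec <- random_fixture_spec(n, seed = seed)
    p <- select_protomer(make_contact_fixture(spec, seed = seed))
    fast <- find_contacts(p)
    slow <- brute_force_contacts(p)
    expect_identical(fast, slow)
    # and both equal the expected planted set
    exp <- expected_planted_contacts(spec)
    if (is.null(exp)) {
      expect_equal(nrow(fast), 0L)
    } else {
      expect_equal(fast[, c("seq_id_a", "atom_a", "seq_id_b", "atom_b",
                            "bond_type")],
                   exp[, c("seq_id_a", "atom_a", "seq_id_b", "atom_b",
                           "bond_type")],
                   ignore_attr = TRUE)
      expect_equal(fast$distance, exp$distance, tolerance = 1e-9)
    }
  }
})

test_that("results are invariant under atom-order permutation", {
  spec <- random_fixture_spec(40, seed = 77)
  p <- select_protomer(make_contact_fixture(spec, seed = 77))
  shuffled <- p
  set.seed(1)
  shuffled$atoms <- shuffled$atoms[sample(nrow(shuffled$atoms)), ]
  expect_identical(find_contacts(p), find_contacts(shuffled))
})

test_that("tighter cutoffs yield a subset; looser settings a superset", {
  spec <- random_fixture_spec(60, seed = 5)
  p <- select_protomer(make_contact_fixture(spec, seed = 5))
  loose <- find_contacts(p, contact_params(3.3, 5.0))
  tight <- find_contacts(p, contact_params(3.0, 4.5))
  key <- function(d) paste(d$seq_id_a, d$atom_a, d$seq_id_b, d$atom_b)
  expect_true(all(key(tight) %in% key(loose)))

  full <- find_contacts(p, contact_params(min_seq_separation = 0,
                                          include_backbone_backbone = TRUE))
  expect_true(all(key(loose) %in% key(full)))
})

test_that("sequence-separation and backbone-backbone exclusions apply", {
  res <- data.frame(chain_id = "A", seq_id = c(100L, 101L, 120L, 121L),
                    res_name = c("SER", "THR", "ALA", "GLY"))
  spec <- contact_fixture_spec(res, planted_pairs = list(
    list(seq_id_a = 100, atom_a = "OG", seq_id_b = 101, atom_b = "OG1",
         distance = 3.0, type = "hbond"),       # |dseq| = 1: suppressed
    list(seq_id_a = 120, atom_a = "N", seq_id_b = 121, atom_b = "O",
         distance = 3.0, type = "hbond")))      # backbone-backbone, adjacent
  p <- select_protomer(make_contact_fixture(spec))
  expect_equal(nrow(find_contacts(p)), 0L)
  audit <- find_contacts(p, contact_params(min_seq_separation = 0,
                                           include_backbone_backbone = TRUE))
  expect_equal(nrow(audit), 2L)
  # separation alone readmits the sidechain pair but not the backbone pair
  sep0 <- find_contacts(p, contact_params(min_seq_separation = 0))
  expect_equal(nrow(sep0), 1L)
  expect_equal(sep0$atom_a, "OG")
})

test_that("sulfur atoms are hbond-capable only when enabled", {
  res <- data.frame(chain_id = "A", seq_id = c(1L, 10L),
                    res_name = c("CYS", "SER"))
  spec <- contact_fixture_spec(res, planted_pairs = list(
    list(seq_id_a = 1, atom_a = "SG", seq_id_b = 10, atom_b = "OG",
         distance = 3.1, type = "hbond")))
  p <- select_protomer(make_contact_fixture(spec))
  expect_equal(nrow(find_contacts(p)), 1L)
  expect_equal(nrow(find_contacts(p, contact_params(include_sulfur = FALSE))), 0L)
})

test_that("residue-pair aggregation counts, minima and dominance", {
  expect_equal(nrow(aggregate_residue_pairs(
    find_contacts(select_protomer(make_contact_fixture(contact_fixture_spec(
      data.frame(chain_id = "A", seq_id = 1L, res_name = "GLY"))))))), 0L)

  # three atomic contacts between residues 310 and 337, mixed types
  res <- data.frame(chain_id = "A", seq_id = c(310L, 337L),
                    res_name = c("TYR", "GLN"))
  spec <- contact_fixture_spec(res, planted_pairs = list(
    list(seq_id_a = 310, atom_a = "CE1", seq_id_b = 337, atom_b = "CB",
         distance = 4.5, type = "hydrophobic"),
    list(seq_id_a = 310, atom_a = "CE2", seq_id_b = 337, atom_b = "CG",
         distance = 4.0, type = "hydrophobic"),
    list(seq_id_a = 310, atom_a = "OH", seq_id_b = 337, atom_b = "OE1",
         distance = 3.0, type = "hbond")))
  pairs <- aggregate_residue_pairs(find_contacts(select_protomer(
    make_contact_fixture(spec))))
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$n_hbond, 1L)
  expect_equal(pairs$n_hydrophobic, 2L)
  expect_equal(pairs$min_distance, 3.0)
  expect_equal(pairs$dominant_type, "hbond")
})

test_that("neighbour queries name the partner outside the query set", {
  p <- select_protomer(synthetic_fold_protomer("AD"))
  pairs <- aggregate_residue_pairs(find_contacts(p))
  nb <- neighbors_of(pairs, 310)
  expect_setequal(nb$neighbour_seq_id, c(374L, 376L))
  expect_setequal(nb$neighbour_res_name, c("HIS", "LEU"))
  expect_equal(nrow(neighbors_of(pairs, 9999)), 0L)
})
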