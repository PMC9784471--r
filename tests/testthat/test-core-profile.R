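test_that("motif scan locates the nucleation cores on the canonical sequence", {
  hits <- scan_motifs(tau_2N4R_sequence())
  phf6 <- hits[hits$motif == "PHF6", ]
  phf6s <- hits[hits$motif == "PHF6*", ]
  vqi <- hits[hits$motif == "VQI", ]
  expect_equal(c(phf6$start_seq_id, phf6$end_seq_id), c(306L, 311L))
  expect_equal(c(phf6s$start_seq_id, phf6s$end_seq_id), c(275L, 280L))
  expect_equal(sort(vqi$start_seq_id), c(275L, 306L))
  expect_true(all(hits$fully_resolved))
})

test_that("overlapping occurrences and gap-spanning hits are handled", {
  # VQI is reported as a prefix of a hexamer hit at the same position
  hits <- scan_motifs("AAVQIVYKAA")
  expect_equal(hits$motif[hits$start_seq_id == 3], c("PHF6", "VQI"))

  # hexamer spanning a numbering gap is reported but not fully resolved
  ms <- structure(list(sequence = "VQIVYK",
                       seq_ids = c(306L, 307L, 308L, 320L, 321L, 322L),
                       gap_after = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE)),
                  class = "modeled_sequence")
  h <- scan_motifs(ms)
  expect_false(h$fully_resolved[h$motif == "PHF6"])
})

test_that("strain classification follows resolved core membership", {
  expect_equal(classify_fold(scan_motifs("VQIVYK"))$label, "single_core")
  both <- classify_fold(scan_motifs(paste0("VQIINK", strrep("G", 10), "VQIVYK")))
  expect_equal(both$label, "dual_core")
  expect_setequal(both$cores_present, c("PHF6", "PHF6*"))
  expect_equal(classify_fold(scan_motifs("GGGGGG"))$label, "no_core")
  # unresolved hexamer does not count as a core
  ms <- structure(list(sequence = "VQIVYK",
                       seq_ids = c(1L, 2L, 3L, 10L, 11L, 12L),
                       gap_after = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE)),
                  class = "modeled_sequence")
  expect_equal(classify_fold(scan_motifs(ms))$label, "no_core")
})

test_that("classification is independent of motif-list order", {
  seq <- tau_2N4R_sequence()
  m <- tau_motifs()
  a <- classify_fold(scan_motifs(seq, m))
  b <- classify_fold(scan_motifs(seq, m[rev(seq_len(nrow(m))), ]))
  expect_identical(a, b)
})

test_that("3R-derived sequences contain no VQIINK", {
  iso <- build_isoforms()
  for (nm in c("2N3R", "1N3R", "0N3R")) {
    hits <- scan_motifs(iso$sequence[iso$name == nm])
    expect_false("PHF6*" %in% hits$motif)
    expect_true("PHF6" %in% hits$motif)
  }
})

test_that("truncation-loss reports cover exactly the suffix-residue pairs", {
  p <- select_protomer(synthetic_fold_protomer("AGD"))
  hits <- scan_motifs(extract_sequence(p))
  hit <- hits[hits$motif == "PHF6" & hits$fully_resolved, ][1, ]
  lr <- truncation_loss(p, hit)
  expect_equal(lr$removed_seq_ids, 309:311)
  got <- sort(paste(lr$pairs$seq_id_a, lr$pairs$seq_id_b))
  expect_equal(got, sort(c("297 309", "310 337", "295 311")))
  # every listed pair involves a removed residue, and the report is a
  # subset of the full residue-pair table
  expect_true(all(lr$pairs$seq_id_a %in% 309:311 |
                    lr$pairs$seq_id_b %in% 309:311))
  full <- aggregate_residue_pairs(find_contacts(p))
  expect_true(all(paste(lr$pairs$seq_id_a, lr$pairs$seq_id_b) %in%
                    paste(full$seq_id_a, full$seq_id_b)))

  # unresolved hit is rejected
  bad <- hit; bad$fully_resolved <- FALSE
  expect_error(truncation_loss(p, bad), "not fully resolved")
})

test_that("intra-motif contacts are excluded from loss reports", {
  res <- data.frame(chain_id = "A",
                    seq_id = c(306:311, 350L),
                    res_name = c(aa1_to_3(strsplit("VQIVYK", "")[[1]]), "LEU"))
  spec <- contact_fixture_spec(res, planted_pairs = list(
    list(seq_id_a = 306, atom_a = "CG1", seq_id_b = 310, atom_b = "CE1",
         distance = 4.0, type = "hydrophobic"),   # internal to the motif
    list(seq_id_a = 310, atom_a = "CE2", seq_id_b = 350, atom_b = "CD1",
         distance = 4.2, type = "hydrophobic")))
  p <- select_protomer(make_contact_fixture(spec))
  hit <- scan_motifs(extract_sequence(p))
  hit <- hit[hit$motif == "PHF6", ]
  lr <- truncation_loss(p, hit)
  expect_equal(nrow(lr$pairs), 1L)
  expect_equal(lr$pairs$seq_id_b, 350L)
})

test_that("zero-contact suffixes give empty reports and ranking breaks ties", {
  res <- data.frame(chain_id = "A", seq_id = 306:311,
                    res_name = aa1_to_3(strsplit("VQIVYK", "")[[1]]))
  p <- select_protomer(make_contact_fixture(contact_fixture_spec(res)))
  hit <- scan_motifs(extract_sequence(p))
  lr <- truncation_loss(p, hit[hit$motif == "PHF6", ])
  expect_equal(nrow(lr$pairs), 0L)

  r1 <- list(motif = "PHF6", pairs = data.frame(x = 1:3),
             removed_seq_ids = 309:311)
  r2 <- list(motif = "PHF6*", pairs = data.frame(x = 1),
             removed_seq_ids = 278:280)
  rk <- rank_cores(list(r1, r2))
  expect_equal(rk$motif, c("PHF6", "PHF6*"))
  expect_equal(rk$role, c("primary", "secondary"))
  expect_false(any(rk$tied))

  tie <- rank_cores(list(r1, list(motif = "PHF6*",
                                  pairs = data.frame(x = 1:3),
                                  removed_seq_ids = 278:280)))
  expect_true(all(tie$tied))
  expect_equal(tie$motif[1], "PHF6")   # alphabetical tie-break

  single <- rank_cores(list(r2))
  expect_equal(single$role, "primary")
  expect_error(rank_cores(list()), "at least one")
})
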