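test_that("the six isoforms have canonical lengths and motif content", {
  iso <- build_isoforms()
  expect_equal(nrow(iso), 6L)
  expect_equal(stats::setNames(iso$length, iso$name),
               c(`2N4R` = 441L, `2N3R` = 410L, `1N4R` = 412L, `1N3R` = 381L,
                 `0N4R` = 383L, `0N3R` = 352L))
  expect_equal(iso$sequence[iso$name == "2N4R"], tau_2N4R_sequence())
  expect_true(all(grepl("VQIVYK", iso$sequence, fixed = TRUE)))
  has_phf6s <- grepl("VQIINK", iso$sequence, fixed = TRUE)
  expect_equal(has_phf6s, grepl("4R", iso$name))
  expect_true(all(iso$predicted_amyloidogenic))
})

test_that("removing inserts and R2 commutes and brackets the length lattice", {
  iso <- build_isoforms()
  len <- stats::setNames(iso$length, iso$name)
  expect_equal(unname(len["2N4R"] - len["0N4R"]), unname(len["2N3R"] - len["0N3R"]))
  expect_equal(unname(len["2N4R"] - len["2N3R"]), unname(len["0N4R"] - len["0N3R"]))
  expect_equal(unname(which.min(len)), match("0N3R", names(len)))
  expect_equal(unname(which.max(len)), match("2N4R", names(len)))
})

test_that("truncation series have the documented counts and retained spans", {
  nser <- build_truncation_series(direction = "n_terminal")
  cser <- build_truncation_series(direction = "c_terminal")
  expect_equal(nrow(nser), 8L)
  expect_equal(nrow(cser), 5L)
  tau <- tau_2N4R_sequence()
  expect_equal(nser$sequence[1], substr(tau, 45, 441))
  expect_equal(cser$sequence[4], substr(tau, 1, 274))
  # single cut at 1 returns the full template
  full <- build_truncation_series(direction = "n_terminal", cuts = 1L)
  expect_equal(full$sequence, tau)
  expect_error(build_truncation_series(direction = "n_terminal",
                                       cuts = c(50L, 40L)), "increasing")
  expect_error(build_truncation_series(direction = "c_terminal",
                                       cuts = c(100L, 500L)), "decreasing")
})

test_that("length conservation holds on every construct record", {
  tab <- run_constructs()
  expect_equal(nrow(tab), 22L)
  for (i in seq_len(nrow(tab))) {
    iv <- tab$intervals[[i]]
    expect_equal(tab$length[i],
                 sum(iv[, 2] - iv[, 1] + 1L) + nchar(tab$appended_motif[i]))
    expect_equal(nchar(tab$sequence[i]), tab$length[i])
  }
})

test_that("extension constructs terminate in their appended hexamers", {
  ext <- build_extension_constructs()
  c6 <- ext[ext$name == "C6", ]; c7 <- ext[ext$name == "C7", ]
  c8 <- ext[ext$name == "C8", ]
  tail_n <- function(s, n) substr(s, nchar(s) - n + 1, nchar(s))
  expect_equal(tail_n(c6$sequence, 6), "VQIINK")
  expect_equal(tail_n(c7$sequence, 6), "VQIVYK")
  expect_equal(tail_n(c8$sequence, 3), "VQI")
  expect_equal(c6$length, c8$length + 3L)
  expect_equal(c7$parent, "2N3R")
  expect_false(grepl("VQIVYK", c8$sequence, fixed = TRUE) ||
                 grepl("VQIINK", c8$sequence, fixed = TRUE))
  # C7 joins R1 directly to the R3 hexamer
  tau <- tau_2N4R_sequence()
  expect_equal(c7$sequence, paste0(substr(tau, 1, 274), "VQIVYK"))
})

test_that("the amyloidogenicity rule matches the encoded assay outcomes", {
  tab <- run_constructs()
  asserted <- tab$series %in% c("C", "extension", "isoform")
  expect_true(all(tab$predicted_amyloidogenic[asserted] ==
                    tab$observed_amyloidogenic[asserted]))
  cpos <- tab$name %in% c("C1", "C2", "C3", "C6", "C7")
  cneg <- tab$name %in% c("C4", "C5", "C8")
  expect_true(all(tab$predicted_amyloidogenic[cpos]))
  expect_false(any(tab$predicted_amyloidogenic[cneg]))
})

test_that("rule and motif scan agree on every construct", {
  tab <- run_constructs()
  for (i in seq_len(nrow(tab))) {
    hits <- scan_motifs(tab$sequence[i])
    has_hexamer <- any(hits$motif %in% c("PHF6", "PHF6*") & hits$fully_resolved)
    expect_equal(tab$predicted_amyloidogenic[i], has_hexamer)
  }
})

test_that("domain maps validate coverage and motif anchoring", {
  expect_error(tau_domain_map(boundaries = list(
    N_head = c(1, 44), N1_insert = c(45, 73), N2_insert = c(74, 102),
    mid = c(103, 150), proline_rich = c(151, 243), R1 = c(244, 274),
    R2 = c(276, 305), R3 = c(306, 336), R4 = c(337, 368),
    C_tail = c(369, 441))), "contiguous")
  shifted <- tau_domain_map(boundaries = list(
    N_head = c(1, 44), N1_insert = c(45, 73), N2_insert = c(74, 102),
    mid = c(103, 150), proline_rich = c(151, 244), R1 = c(245, 274),
    R2 = c(275, 305), R3 = c(306, 336), R4 = c(337, 368),
    C_tail = c(369, 441)))
  expect_s3_class(shifted, "tau_domain_map")
  expect_error(build_isoforms(template = "SHORT"), "length")

  json <- system.file("extdata", "tau_domains_2N4R.json", package = "taucore")
  map <- read_domain_map(json)
  expect_equal(map$boundaries$R3, c(306L, 336L))
  expect_identical(build_isoforms(map)$sequence, build_isoforms()$sequence)
})

test_that("FASTA output round-trips and rejects duplicate names", {
  tab <- run_constructs()
  f <- withr::local_tempfile(fileext = ".fasta")
  write_construct_fasta(tab, f)
  back <- read_fasta_sequences(f)
  expect_equal(length(back), 22L)
  expect_equal(unname(back[match(tab$name, names(back))]), tab$sequence)
  expect_error(write_construct_fasta(rbind(tab, tab[1, ]), f), "duplicate")
  expect_warning(write_construct_fasta(tab[0, ], f), "empty")
})
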