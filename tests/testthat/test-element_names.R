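test_that("conserved-sequence names encode classes and taxa", {
  expect_identical(cs_name("Acar", 1000, 600, 100, c("S", "M", "B")),
                   "Acar1000l1SMB")
  expect_identical(cs_name("Acar", 1, 99, 95, "S"), "Acar1s1S")
  expect_identical(cs_name("Acar", 7, 250, 90, "M"), "Acar7m2M")
  expect_identical(cs_name("Acar", 2, 100, 89, "G"), "Acar2m3G")
  expect_identical(cs_name("Acar", 3, 500, 85, "S"), "Acar3l3S")
  # taxa serialize in canonical S,M,B,G order whatever the input order
  expect_identical(cs_name("Acar", 4, 50, 96, c("B", "S", "M")),
                   "Acar4s1SMB")
  # fractional percents round half-up before classing
  expect_identical(cs_name("Acar", 5, 50, 94.5, "S"), "Acar5s1S")
  expect_identical(cs_name("Acar", 5, 50, 94.4, "S"), "Acar5s2S")
  expect_identical(cs_name("Acar", 5, 50, 84.5, "S"), "Acar5s3S")
  expect_error(cs_name("Acar", 2, 50, 80, "S"),
               class = "agnc_out_of_class_error")
  expect_error(cs_name("Acar", 2, 50, 90, character()),
               class = "agnc_domain_error")
  expect_error(cs_name("acar", 2, 50, 90, "S"),
               class = "agnc_code_format_error")
})

test_that("CS parsing recovers fields and reports class intervals", {
  p <- cs_parse("Acar1000l1SMB")
  expect_identical(p$species_code, "Acar")
  expect_identical(p$index, 1000L)
  expect_identical(p$length_class, "l")
  expect_identical(p$length_range, c(500, Inf))
  expect_identical(p$conservation_class, 1L)
  expect_identical(p$conservation_range, c(95, 100))
  expect_identical(p$taxa, c("S", "M", "B"))
  expect_identical(cs_parse("Acar1s1S")$length_range, c(1, 99))
  expect_error(cs_parse("Acar1x1S"), class = "agnc_grammar_error")
  expect_error(cs_parse("Acar1s4S"), class = "agnc_grammar_error")
  expect_error(cs_parse("Acar1s1MS"), class = "agnc_grammar_error")  # order
  expect_error(cs_parse("Bcar1s1S"), class = "agnc_grammar_error")
})

test_that("cs_parse recovers everything cs_name encodes", {
  set.seed(5)
  taxa_pool <- c("S", "M", "B", "G")
  for (i in 1:100) {
    len <- sample(1:1200, 1)
    pct <- round(runif(1, 85, 100), 1)
    taxa <- sample(taxa_pool, sample(1:4, 1))
    idx <- sample(1:99999, 1)
    nm <- cs_name("Asag", idx, len, pct, taxa)
    p <- cs_parse(nm)
    expect_identical(p$species_code, "Asag")
    expect_identical(p$index, idx)
    expect_identical(sort(p$taxa), sort(taxa))
    expect_true(len >= p$length_range[1] && len <= p$length_range[2])
    rounded <- floor(pct + 0.5)
    expect_true(rounded >= p$conservation_range[1] &&
                  rounded <= p$conservation_range[2])
  }
})

test_that("STR names are three underscore-separated fields", {
  expect_identical(str_name("Acar", 8), "Acar_str_8")
  expect_identical(str_name("Acar", 1), "Acar_str_1")
  expect_identical(str_name("Asag", 3), "Asag_str_3")
  expect_error(str_name("Acar", 0), class = "agnc_domain_error")
  expect_error(str_name("ACAR", 1), class = "agnc_code_format_error")
  p <- str_parse("Acar_str_8")
  expect_identical(p, list(species_code = "Acar", index = 8L))
  expect_error(str_parse("Acar_str_"), class = "agnc_grammar_error")
  expect_error(str_parse("Acar_str_08"), class = "agnc_grammar_error")
})

test_that("TE names round-trip through the grammar", {
  expect_identical(te_name("Helitron", 1, "Acar"), "Helitron-1_Acar")
  expect_identical(te_name("Helitron", 1, "Acar", nonautonomous_id = 1),
                   "Helitron-1N1_Acar")
  expect_identical(te_name("hAT", 1, "Acar", horizontal = TRUE),
                   "hAT-HT1_Acar")
  p <- te_parse("hobo-1_Acar")
  expect_identical(p$lineage, "hobo")
  expect_identical(p$family_id, 1L)
  expect_false(p$horizontal)
  expect_true(is.na(p$nonautonomous_id))
  p <- te_parse("Helitron-1N1_Acar")
  expect_identical(p$nonautonomous_id, 1L)
  p <- te_parse("hAT-HT1_Acar")
  expect_true(p$horizontal)
  expect_error(te_parse("hAT_1_Acar"), class = "agnc_grammar_error")
  expect_error(te_parse("hAT-1_acar"), class = "agnc_grammar_error")
  expect_error(te_name("heli-tron", 1, "Acar"),
               class = "agnc_grammar_error")

  set.seed(3)
  for (i in 1:100) {
    args <- list(lineage = sample(c("Helitron", "hobo", "hAT", "Charlie",
                                    "restless", "L1"), 1),
                 family_id = sample(1:50, 1),
                 species_code = sample(c("Acar", "Asag", "Agra"), 1),
                 nonautonomous_id = if (runif(1) < 0.5) sample(1:9, 1)
                                    else NULL,
                 horizontal = runif(1) < 0.5)
    nm <- do.call(te_name, args)
    p <- te_parse(nm)
    expect_identical(p$lineage, args$lineage)
    expect_identical(p$family_id, as.integer(args$family_id))
    expect_identical(p$horizontal, args$horizontal)
    expect_identical(p$species_code, args$species_code)
    if (is.null(args$nonautonomous_id)) {
      expect_true(is.na(p$nonautonomous_id))
    } else {
      expect_identical(p$nonautonomous_id,
                       as.integer(args$nonautonomous_id))
    }
    # reserialize: identity on valid names
    expect_identical(do.call(te_name, list(
      lineage = p$lineage, family_id = p$family_id,
      species_code = p$species_code,
      nonautonomous_id = if (is.na(p$nonautonomous_id)) NULL
                         else p$nonautonomous_id,
      horizontal = p$horizontal)), nm)
  }
})

test_that("the STR scanner reproduces its worked examples", {
  out <- scan_strs("ACACACAC", min_unit = 2, max_unit = 2, min_copies = 3)
  expect_identical(nrow(out), 1L)
  expect_identical(out$unit, "AC")
  expect_identical(out$copies, 4L)
  expect_identical(c(out$start, out$end), c(0L, 8L))

  expect_identical(nrow(scan_strs("ACGT")), 0L)

  out <- scan_strs("AAAATTTTTT", min_copies = 3)
  expect_identical(out$unit, c("A", "T"))
  expect_identical(out$copies, c(4L, 6L))
  expect_identical(out$start, c(0L, 4L))  # leftmost-first indexing

  # unit reported as lexicographically minimal rotation
  out <- scan_strs("GTAGTAGTA", min_copies = 3)
  expect_identical(out$unit, "AGT")

  expect_error(scan_strs("ACGU"), class = "agnc_sequence_error")
  expect_error(scan_strs("ACGT", min_copies = 1), class = "agnc_domain_error")
})

test_that("the scanner matches the exhaustive enumerator on random sequences", {
  set.seed(17)
  for (i in 1:20) {
    n <- sample(50:500, 1)
    s <- random_dna(n)
    # salt in some genuine repeats so non-trivial cases occur
    if (i %% 2 == 0) {
      unit <- random_dna(sample(1:4, 1))
      rep_seq <- strrep(unit, sample(3:8, 1))
      pos <- sample(1:(n - nchar(rep_seq)), 1)
      s <- paste0(substr(s, 1, pos), rep_seq,
                  substr(s, pos + nchar(rep_seq) + 1, n))
    }
    got <- scan_strs(s, min_copies = 3)
    want <- oracle_scan(s, min_copies = 3)
    expect_identical(nrow(got), nrow(want), info = paste("case", i))
    if (nrow(want)) {
      expect_identical(got$start, as.integer(want$start - 1L))
      expect_identical(got$end, as.integer(want$start - 1L + want$len))
      expect_identical(got$copies, as.integer(want$copies))
      expect_identical(got$unit_length, as.integer(want$u))
    }
  }
})

test_that("the STR registry names loci in scan order and persists", {
  seqs <- c(scaf1 = "AAAAACGTGCGTACACACACTT", scaf2 = "TTTGGGGGGA")
  reg <- str_registry(seqs, species_code = "Acar", min_copies = 4)
  expect_identical(reg$name, paste0("Acar_str_", seq_len(nrow(reg))))
  expect_true(all(diff(vapply(reg$name, function(n) str_parse(n)$index,
                              integer(1))) == 1L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_str_registry(reg, path)
  expect_identical(read_str_registry(path), reg)

  # FASTA input path
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">scaf1 descr", "AAAAACGTGCGT", "ACACACACTT",
               ">scaf2", "TTTGGGGGGA"), fa)
  reg_fa <- str_registry(fa, species_code = "Acar", min_copies = 4)
  expect_identical(reg_fa, reg)
})
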