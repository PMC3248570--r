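test_that("fixture generators are seed-deterministic", {
  expect_identical(make_species_fixture(10, 0.5, 7),
                   make_species_fixture(10, 0.5, 7))
  expect_false(identical(make_species_fixture(10, 0.5, 7),
                         make_species_fixture(10, 0.5, 8)))
  c1 <- make_synteny_fixture(3, 4, 8, 11)
  c2 <- make_synteny_fixture(3, 4, 8, 11)
  expect_identical(c1, c2)
  # the generators must not disturb the session RNG stream
  set.seed(1); a <- runif(1)
  set.seed(1); invisible(make_species_fixture(5, 0, 3)); b <- runif(1)
  expect_identical(a, b)
})

test_that("species fixtures force resolvable collisions", {
  fix <- make_species_fixture(10, 0, 7)
  expect_identical(nrow(fix), 10L)
  reg <- assign_codes(fix$epithet, fix$precedence_rank)
  # with no collisions every code is the default first-three-letters form
  expect_identical(reg$code,
                   paste0("A", substr(fix$epithet, 1, 2),
                          substr(fix$epithet, 3, 3)))
  fix2 <- make_species_fixture(200, 0.3, 1)
  reg2 <- assign_codes(fix2$epithet, fix2$precedence_rank)
  expect_identical(anyDuplicated(reg2$code), 0L)
  expect_identical(nrow(reg2), 200L)
  # collision pressure is real: some names had to fall back
  prefixes <- substr(fix2$epithet, 1, 3)
  expect_gt(sum(duplicated(prefixes)), 0)
})

test_that("synteny fixtures hit their requested counts exactly", {
  set.seed(31)
  for (i in 1:40) {
    fl <- sample(2:10, 1)
    up <- sample(0:fl, 1)
    down <- sample(0:fl, 1)
    ctx <- make_synteny_fixture(up, down, fl, seed = i)
    expect_identical(ecc_synteny_fields(ctx),
                     c(up = as.integer(up), down = as.integer(down)),
                     info = sprintf("case %d (%d,%d,%d)", i, up, down, fl))
    # and the oracle agrees with the counter on the same context
    expect_identical(
      unname(ecc_synteny_fields(ctx)),
      c(oracle_flank(ctx$upstream_genes, ctx$ortholog_map,
                     ctx$reference_rank),
        oracle_flank(ctx$downstream_genes, ctx$ortholog_map,
                     ctx$reference_rank)))
  }
  expect_identical(unname(ecc_synteny_fields(
    make_synteny_fixture(0, 0, 5, 1))), c(0L, 0L))
})

test_that("the pipeline assembles the worked single-gene code", {
  genes <- data.frame(gene_id = "gene2", protein_metric = 80,
                      nucleotide_metric = 55, expression_code = "TS")
  evidence <- data.frame(transcript_id = "gene2", est = TRUE,
                         protein = FALSE, prediction = TRUE, cdna = FALSE)
  orthologs <- data.frame(gene_id = "gene2", copies_query = 1,
                          copies_reference = 1)
  presence <- data.frame(gene_id = "gene2", mammals = TRUE, birds = TRUE,
                         non_avian_reptiles = TRUE, amphibians = TRUE,
                         teleosts = TRUE, non_vertebrate_chordates = TRUE)
  contexts <- list(gene2 = make_synteny_fixture(3, 4, 8, 11))
  out <- ecc_pipeline(genes, evidence, orthologs, presence, contexts)
  expect_identical(out$ecc, "gene2:chordates:80,55:1-1:5:3,4:TS")
  expect_identical(nrow(attr(out, "excluded")), 0L)
})

test_that("the pipeline reports missing genes instead of dropping them", {
  genes <- data.frame(gene_id = c("g1", "g2"), protein_metric = 70,
                      nucleotide_metric = 60)
  evidence <- data.frame(transcript_id = "g1", est = TRUE, protein = TRUE,
                         prediction = FALSE, cdna = FALSE)
  orthologs <- data.frame(gene_id = c("g1", "g2"), copies_query = 1,
                          copies_reference = 2)
  presence <- data.frame(gene_id = c("g1", "g2"), mammals = TRUE,
                         birds = FALSE, non_avian_reptiles = FALSE,
                         amphibians = FALSE, teleosts = FALSE,
                         non_vertebrate_chordates = FALSE)
  syn <- data.frame(gene_id = c("g1", "g2"), synteny_up = 2,
                    synteny_down = 0)
  expect_warning(out <- ecc_pipeline(genes, evidence, orthologs, presence,
                                     syn),
                 "excluded")
  expect_identical(out$gene_id, "g1")
  expect_identical(out$ecc, "g1:amniotes:70,60:1-n:3:2,0:ND")
  ex <- attr(out, "excluded")
  expect_identical(ex$gene_id, "g2")
  expect_match(ex$reason, "evidence")
})

test_that("pipeline output round-trips for a synthetic gene set", {
  set.seed(77)
  n <- 100L
  ids <- paste0("g", seq_len(n))
  genes <- data.frame(gene_id = ids,
                      protein_metric = round(runif(n, 30, 100), 1),
                      nucleotide_metric = round(runif(n, 30, 100), 1),
                      expression_code = sample(c("TS", "CE", "ND"), n,
                                               replace = TRUE))
  evidence <- data.frame(transcript_id = ids,
                         est = runif(n) < 0.5, protein = runif(n) < 0.5,
                         prediction = runif(n) < 0.5,
                         cdna = runif(n) < 0.5)
  orthologs <- data.frame(gene_id = ids,
                          copies_query = sample(1:3, n, replace = TRUE),
                          copies_reference = sample(1:3, n, replace = TRUE))
  taxa <- c("mammals", "birds", "non_avian_reptiles", "amphibians",
            "teleosts", "non_vertebrate_chordates")
  presence <- data.frame(gene_id = ids)
  for (tx in taxa) presence[[tx]] <- runif(n) < 0.8
  # guarantee at least one hit per gene so no gene lacks a span
  presence$teleosts[rowSums(presence[taxa]) == 0] <- TRUE
  syn <- data.frame(gene_id = ids,
                    synteny_up = sample(0:6, n, replace = TRUE),
                    synteny_down = sample(0:6, n, replace = TRUE))
  out <- ecc_pipeline(genes, evidence, orthologs, presence, syn)
  expect_identical(nrow(out), n)
  for (i in seq_len(n)) {
    rec <- ecc_parse(out$ecc[i])
    expect_identical(rec$gene_id, out$gene_id[i])
    expect_identical(ecc_serialize(rec), out$ecc[i])
  }
})

test_that("batch ECC table building matches record-level serialization", {
  tab <- data.frame(gene_id = c("gene2", "gx"),
                    taxonomic_span = c("chordates", "amniotes"),
                    protein_metric = c(80, 70.5),
                    nucleotide_metric = c(55, 66),
                    copies_query = c(1, 2),
                    copies_reference = c(1, 3),
                    evidence_score = c(5, 12),
                    synteny_up = c(3, 0), synteny_down = c(4, 1),
                    expression_code = c("TS", "ND"))
  out <- ecc_build_table(tab)
  expect_identical(out[1], "gene2:chordates:80,55:1-1:5:3,4:TS")
  expect_identical(out[2], "gx:amniotes:70.5,66:n-n:12:0,1:ND")
})

test_that("configuration validates and loads from YAML", {
  cfg <- agnc_config()
  expect_s3_class(cfg, "agnc_config")
  expect_identical(cfg$synteny_max_gap, 0L)
  expect_error(agnc_config(synteny_max_gap = -1),
               class = "agnc_config_error")
  expect_error(agnc_config(str_min_copies = 1),
               class = "agnc_config_error")
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("synteny_max_gap: 2", "output_format: json",
               "expression_codes: [TS, CE, ND, XX]"), path)
  cfg2 <- load_config(path)
  expect_identical(cfg2$synteny_max_gap, 2L)
  expect_identical(cfg2$output_format, "json")
  expect_true("XX" %in% cfg2$expression_codes)
  writeLines("not_a_real_key: 1", path)
  expect_error(load_config(path), class = "agnc_config_error")
})

test_that("the CLI dispatcher runs the main subcommands", {
  expect_output(st <- agnc_main(c("species", "validate", "Asag")),
                "sagrei")
  expect_identical(st, 0L)
  expect_output(st <- agnc_main(c("species", "validate", "asag")))
  expect_identical(st, 1L)
  expect_output(st <- agnc_main(c("species", "code", "Anolis sagrei",
                                  "gracilipes")), "Asag")
  expect_identical(st, 0L)
  expect_output(agnc_main(c("gene", "derive", "GENE2")), "gene2")
  expect_output(agnc_main(c("gene", "dup", "gene2", "-n", "2")), "gene2b")
  expect_output(agnc_main(c("ecc", "parse",
                            "gene2:chordates:80,55:1-1:5:3,4:TS")),
                "chordates")
  expect_output(agnc_main(c("cs", "name", "Acar", "1000", "600", "100",
                            "SMB")), "Acar1000l1SMB")
  expect_output(agnc_main(c("te", "parse", "Helitron-1N1_Acar")),
                "Helitron")
  expect_output(agnc_main(c("--format", "json", "species", "validate",
                            "Asag")), '"ok": true')
  # malformed input exits 2 with a message on stderr, no R error
  expect_message(st <- agnc_main(c("bogus")), "agnc:")
  expect_identical(st, 2L)
  expect_message(st <- agnc_main(c("te", "parse", "nope")), "agnc:")
  expect_identical(st, 2L)
})

test_that("CLI score and ecc build run over TSV files", {
  dir <- withr::local_tempdir()
  ev <- file.path(dir, "ev.tsv")
  write.table(data.frame(transcript_id = c("t1", "t2"), est = c(1, 0),
                         protein = c(0, 0), prediction = c(1, 0),
                         cdna = c(0, 1)),
              ev, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_output(st <- agnc_main(c("score", ev)), "t1\t5")
  expect_identical(st, 0L)
  tab <- file.path(dir, "ecc.tsv")
  write.table(data.frame(gene_id = "gene2", taxonomic_span = "chordates",
                         protein_metric = 80, nucleotide_metric = 55,
                         copies_query = 1, copies_reference = 1,
                         evidence_score = 5, synteny_up = 3,
                         synteny_down = 4, expression_code = "TS"),
              tab, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_output(st <- agnc_main(c("ecc", "build", tab)),
                "gene2:chordates:80,55:1-1:5:3,4:TS", fixed = TRUE)
  expect_identical(st, 0L)
})
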