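test_that("12-column tabular hits parse with database and identity stamped", {
  p <- write_tsv_lines(c(
    hit_row("GL000001", "XP_1", 85.2, 1e-20),
    hit_row("GL000002", "XP_2", 60.0, 1e-8)
  ))
  hits <- read_homology_hits(p, "refseq", "amino_acid")
  expect_equal(nrow(hits), 2)
  expect_equal(hits$evalue[2], 1e-8)
  expect_equal(hits$pct_identity[1], 85.2)
  expect_true(all(hits$database == "refseq"))
  expect_true(all(hits$identity_kind == "amino_acid"))

  # reversed query coordinates are normalised
  p3 <- write_tsv_lines(hit_row("GL1", "S", 90, 1e-9, qstart = 200, qend = 50))
  h3 <- read_homology_hits(p3, "nr")
  expect_lte(h3$align_start, h3$align_end)

  expect_equal(nrow(read_homology_hits(write_tsv_lines(character()), "nr")), 0)
  bad <- write_tsv_lines(c(hit_row("A", "B", 90, 1e-9), "A\tB\t90"))
  expect_error(read_homology_hits(bad, "nr"), "line 2",
               class = "ylink_parse_error")
})

test_that("per-database thresholds drop weak hits and are idempotent", {
  hits <- dplyr::bind_rows(
    make_hits("S1", "nr", evalue = 1e-5),              # fails e <= 1e-6
    make_hits("S2", "refseq", evalue = 1e-20),         # kept
    make_hits("S3", "rpro_transcripts", pct_identity = 99.5, evalue = 1e-9),
    make_hits("S4", "rpro_transcripts", pct_identity = 100, evalue = 1e-9),
    make_hits("S5", "rpro_geneid", pct_identity = 100, evalue = 1e-7)
  )
  kept <- filter_homology_hits(hits)
  expect_setequal(kept$scaffold_id, c("S2", "S4"))
  expect_identical(filter_homology_hits(kept), kept)

  odd <- make_hits("S9", "mystery_db")
  expect_error(filter_homology_hits(odd), class = "ylink_config_error")
})

test_that("bacterial/TE contaminant flagging uses a strict identity cutoff", {
  hits <- dplyr::bind_rows(
    make_hits("BACT96", "bacterial", pct_identity = 96),
    make_hits("BACT95", "bacterial", pct_identity = 95.0),
    make_hits("TE100", "te", pct_identity = 100),
    make_hits("GENE", "refseq", pct_identity = 100) # never a contaminant
  )
  expect_setequal(flag_contaminants(hits, 95), c("BACT96", "TE100"))
  # genome-level screen: exact 100% identity flags, below does not
  expect_setequal(flag_contaminants(hits, 100, inclusive = TRUE),
                  c("TE100"))
})

test_that("evidence tiers rank hit quality with transcript support separate", {
  cons <- tibble::tibble(
    subject_id = c("KNOWN1", "CONSHYP1", "UNCONS1"),
    label = c("known", "conserved_hypothetical", "unconserved_hypothetical")
  )
  hits <- dplyr::bind_rows(
    make_hits("T1", "refseq", subject_id = "KNOWN1"),
    make_hits("T1", "rpro_transcripts"),
    make_hits("T2", "rpro_geneid_trash"),
    make_hits("T3", "nr", subject_id = "CONSHYP1"),
    make_hits("T4", "refseq", subject_id = "UNCONS1"),
    make_hits("T4", "rpro_geneid"),
    make_hits("T5", "rpro_transcripts")
  )
  rec <- assign_evidence_tiers(hits, cons)
  tier <- setNames(rec$tier, rec$scaffold_id)
  expect_equal(tier[["T1"]], 1L)
  expect_equal(tier[["T2"]], 5L)
  expect_equal(tier[["T3"]], 2L)
  expect_equal(tier[["T4"]], 3L) # annotated gene (3) beats unconserved (4)
  expect_true(is.na(tier[["T5"]])) # transcript only: no tier-bearing hit
  expect_true(rec$has_transcript[rec$scaffold_id == "T1"])
  expect_true(rec$has_transcript[rec$scaffold_id == "T5"])
  expect_false(rec$has_transcript[rec$scaffold_id == "T2"])

  # a RefSeq/NR subject missing from the conservation map is a metadata error
  expect_error(
    assign_evidence_tiers(make_hits("Z", "refseq", subject_id = "NOPE"), cons),
    class = "ylink_metadata_error"
  )
  expect_equal(nrow(assign_evidence_tiers(empty <- make_hits(character(),
    character()), cons)), 0)
})

test_that("tier assignment is a pure per-scaffold function", {
  cons <- tibble::tibble(subject_id = "K", label = "known")
  hits <- dplyr::bind_rows(
    make_hits("B", "rpro_geneid"),
    make_hits("A", "refseq", subject_id = "K"),
    make_hits("A", "rpro_transcripts")
  )
  rec1 <- assign_evidence_tiers(hits, cons)
  rec2 <- assign_evidence_tiers(hits[c(3, 1, 2), ], cons)
  expect_equal(rec1, rec2)
  # each scaffold's record matches running it alone
  solo <- assign_evidence_tiers(hits[hits$scaffold_id == "A", ], cons)
  expect_equal(rec1[rec1$scaffold_id == "A", ], solo)
})

test_that("testable selection needs three databases, transcripts sort first", {
  cons <- tibble::tibble(subject_id = "K", label = "known")
  hits <- dplyr::bind_rows(
    make_hits("SEL", "nr", subject_id = "K"),
    make_hits("SEL", "rpro_transcripts"),
    make_hits("SEL", "rpro_geneid"),
    make_hits("SEL2", "nr", subject_id = "K"),
    make_hits("SEL2", "rpro_geneid"),
    make_hits("SEL2", "rpro_geneid_trash"),
    make_hits("ONEDB", "nr", subject_id = "K"),
    # bacterial support must not count toward the three databases
    make_hits("ONEDB", "bacterial"),
    make_hits("ONEDB", "te")
  )
  rec <- select_testable(assign_evidence_tiers(hits, cons))
  sel <- setNames(rec$selected_for_testing, rec$scaffold_id)
  expect_true(sel[["SEL"]])
  expect_true(sel[["SEL2"]])
  expect_false(sel[["ONEDB"]])
  expect_equal(rec$scaffold_id[1], "SEL") # transcript-bearing first

  # counting oracle: qualifying-scaffold totals equal brute-force recounts
  filtered <- filter_homology_hits(hits)
  gene_dbs <- setdiff(unique(filtered$database), c("bacterial", "te"))
  brute_n <- length(unique(filtered$scaffold_id[filtered$database %in% gene_dbs]))
  expect_equal(nrow(rec), brute_n)
  for (db in gene_dbs) {
    brute <- sort(unique(filtered$scaffold_id[filtered$database == db]))
    via_rec <- sort(rec$scaffold_id[vapply(rec$databases_hit,
                                           function(d) db %in% d, logical(1))])
    expect_equal(via_rec, brute)
  }
})

test_that("evidence tables serialise database sets readably", {
  cons <- tibble::tibble(subject_id = "K", label = "known")
  rec <- select_testable(assign_evidence_tiers(dplyr::bind_rows(
    make_hits("S", "refseq", subject_id = "K"),
    make_hits("S", "rpro_transcripts")
  ), cons))
  p <- tempfile(fileext = ".tsv")
  write_evidence_table(rec, p)
  back <- readr::read_tsv(p, show_col_types = FALSE)
  expect_equal(back$databases_hit, "refseq;rpro_transcripts")
})
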