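test_that("read maps parse with optional headers and report row counts", {
  p <- write_tsv_lines(c("#scaffold_id\tread_id",
                         "SC1\tNAAX1", "SC1\tNADD1", "SC2\tNAAX2"))
  rm <- read_read_map(p)
  expect_equal(nrow(rm), 3)
  expect_equal(attr(rm, "n_rows"), 3)
  expect_named(rm, c("scaffold_id", "read_id"))

  # header is optional
  p2 <- write_tsv_lines(c("SC1\tNAAX1", "SC2\tNADD1"))
  expect_equal(nrow(read_read_map(p2)), 2)

  # empty file -> empty stream, 0 rows
  p3 <- write_tsv_lines(character())
  rm3 <- read_read_map(p3)
  expect_equal(nrow(rm3), 0)
  expect_equal(attr(rm3, "n_rows"), 0)
})

test_that("malformed read-map rows are parse errors naming the line", {
  p <- write_tsv_lines(c("SC1\tNAAX1", "SC2", "SC3\tNAAX3"))
  expect_error(read_read_map(p), "line 2", class = "ylink_parse_error")
  p2 <- write_tsv_lines(c("#scaffold_id\tread_id", "SC1\tNAAX1\textra"))
  expect_error(read_read_map(p2), "line 2", class = "ylink_parse_error")
})

test_that("scaffold lengths load from TSV and FASTA identically", {
  tsv <- write_tsv_lines(c("scaffold_id\tlength_bp", "SC1\t500", "SC2\t1200"))
  lt <- read_scaffold_lengths(tsv)
  expect_equal(lt$length_bp, c(500L, 1200L))

  seqs <- c(SC1 = paste(rep("ACGT", 125), collapse = ""),
            SC2 = paste(rep("AC", 600), collapse = ""))
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">SC1 desc", seqs[["SC1"]], ">SC2", seqs[["SC2"]]), fa)
  lf <- read_scaffold_lengths(fa)
  expect_equal(lf, lt) # same ids, lengths nchar-derived
})

test_that("per-scaffold counts match the worked example and handle zeros", {
  cat <- rhodnius_catalog()
  rm <- tibble::tibble(scaffold_id = "S",
                       read_id = c("NAAX1", "NAAX2", "NADD1"))
  lens <- tibble::tibble(scaffold_id = c("S", "EMPTY"),
                         length_bp = c(100L, 500L))
  cts <- count_scaffold_reads(rm, cat, lens)
  s <- cts[cts$scaffold_id == "S", ]
  expect_equal(s$n_total, 3L)
  expect_equal(s$n_male, 2L)
  expect_equal(s$n_female, 1L)
  expect_equal(s$male_fraction, 2 / 3)

  e <- cts[cts$scaffold_id == "EMPTY", ]
  expect_equal(e$n_total, 0L)
  expect_equal(e$length_bp, 500L)
  expect_true(is.na(e$male_fraction))
})

test_that("duplicate placements collapse; multi-placed reads count per scaffold", {
  cat <- rhodnius_catalog()
  rm <- tibble::tibble(
    scaffold_id = c("S1", "S1", "S2"),
    read_id = c("NAAX1", "NAAX1", "NAAX1") # dup on S1, also placed on S2
  )
  cts <- count_scaffold_reads(rm, cat)
  expect_equal(cts$n_total, c(1L, 1L))
  expect_equal(sum(cts$n_male), 2L) # once per scaffold
})

test_that("unknown prefixes error by default but can be skipped with a count", {
  cat <- rhodnius_catalog()
  rm <- tibble::tibble(scaffold_id = c("S", "S"),
                       read_id = c("NAAX1", "XYZ9"))
  expect_error(count_scaffold_reads(rm, cat), class = "ylink_unknown_library")
  cts <- count_scaffold_reads(rm, cat, on_unknown = "skip")
  expect_equal(cts$n_total, 1L)
  expect_equal(attr(cts, "n_unknown_skipped"), 1L)
})

test_that("counts agree with a brute-force tally and are permutation-invariant", {
  rm <- random_read_map(100, 20, p_male = 0.6, seed = 11)
  cat <- rhodnius_catalog()
  cts <- count_scaffold_reads(rm, cat)
  oracle <- oracle_counts(rm, paper_catalog_df())
  expect_equal(cts$scaffold_id, oracle$scaffold_id)
  expect_equal(cts$n_total, oracle$n_total)
  expect_equal(cts$n_male, oracle$n_male)
  expect_equal(cts$n_female, oracle$n_female)

  # conservation: summed male counts equal male-prefixed rows in the input
  n_male_rows <- sum(startsWith(rm$read_id, "NAAX") |
                     startsWith(rm$read_id, "GFL7EVZ"))
  expect_equal(sum(cts$n_male), n_male_rows)

  # shuffling input rows changes nothing
  shuffled <- rm[withr::with_seed(1, sample.int(nrow(rm))), ]
  expect_equal(count_scaffold_reads(shuffled, cat), cts,
               ignore_attr = "n_unknown_skipped")
})

test_that("the six-column count table round-trips and formats percentages", {
  cat <- rhodnius_catalog()
  rm <- random_read_map(20, 15, seed = 3)
  lens <- tibble::tibble(scaffold_id = c(unique(rm$scaffold_id), "NONE"),
                         length_bp = 1000L)
  cts <- count_scaffold_reads(rm, cat, lens)
  path <- tempfile(fileext = ".tsv")
  write_count_table(cts, path)

  hdr <- readLines(path, n = 1)
  expect_identical(hdr, "scaffold_id\tlength_bp\tn_total\tn_male\tn_female\tpct_male")

  back <- read_count_table(path)
  expect_equal(back$n_total, cts$n_total)
  expect_equal(back$n_male, cts$n_male)
  expect_equal(back$n_female, cts$n_female)
  expect_equal(back$length_bp, cts$length_bp)
  expect_equal(back$male_fraction, cts$male_fraction)

  # a 61%-male control scaffold prints as "61.0"; zero-read scaffolds as NA
  ctrl <- tibble::tibble(scaffold_id = c("GL563091like", "Z"),
                         length_bp = c(100L, 50L), n_total = c(100L, 0L),
                         n_male = c(61L, 0L), n_female = c(39L, 0L),
                         male_fraction = c(0.61, NA))
  p2 <- tempfile(fileext = ".tsv")
  write_count_table(ctrl, p2)
  rows <- readLines(p2)[-1]
  expect_match(rows[1], "\t61\\.0$")
  expect_match(rows[2], "\tNA$")
})
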