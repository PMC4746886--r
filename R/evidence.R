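#' Homology databases recognised by the triage stage
#'
#' `homology_databases()` lists every database label the evidence functions
#' accept; `gene_evidence_databases()` lists the subset that counts as gene
#' evidence (the bacterial and transposable-element databases are contaminant
#' screens and never count toward candidate support).
#'
#' @return Character vector of database labels.
#' @export
homology_databases <- function() {
  c("refseq", "nr", "bacterial", "te",
    "rpro_transcripts", "rpro_geneid", "rpro_geneid_trash")
}

#' @rdname homology_databases
#' @export
gene_evidence_databases <- function() {
  setdiff(homology_databases(), c("bacterial", "te"))
}

#' Read 12-column tabular homology-search results
#'
#' Parses the standard tab-separated output of sequence-similarity searches
#' (query, subject, percent identity, alignment length, mismatches, gap
#' opens, query start/end, subject start/end, e-value, bit score), stamping
#' each hit with its source database and whether the identity is nucleotide
#' or amino-acid level. A row with the wrong column count is a parse error
#' reported with its line number. Query coordinates are normalised so
#' `align_start <= align_end`.
#'
#' @param path Path to the tabular hits file (no header).
#' @param database One of [homology_databases()].
#' @param identity_kind `"amino_acid"` or `"nucleotide"`.
#' @return A tibble of hits: `scaffold_id`, `database`, `subject_id`,
#'   `pct_identity`, `evalue`, `bitscore`, `align_start`, `align_end`,
#'   `identity_kind`.
#' @export
read_homology_hits <- function(path, database,
                               identity_kind = c("amino_acid", "nucleotide")) {
  identity_kind <- match.arg(identity_kind)
  database <- match.arg(database, homology_databases())
  if (!file.exists(path)) abort(sprintf("Hits file not found: %s", path))

  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) return(empty_hits())

  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12)) {
    bad <- which(nf != 12)[1]
    abort(sprintf(
      "Malformed homology row at line %d: expected 12 tab-separated columns, found %d.",
      lineno[bad], nf[bad]
    ), class = "ylink_parse_error")
  }
  col <- function(i) vapply(fields, `[[`, character(1), i)
  qs <- as.integer(col(7))
  qe <- as.integer(col(8))
  out <- tibble(
    scaffold_id = col(1),
    database = database,
    subject_id = col(2),
    pct_identity = as.numeric(col(3)),
    evalue = as.numeric(col(11)),
    bitscore = as.numeric(col(12)),
    align_start = pmin(qs, qe),
    align_end = pmax(qs, qe),
    identity_kind = identity_kind
  )
  if (any(is.na(out$pct_identity)) || any(is.na(out$evalue)) ||
      any(is.na(out$align_start))) {
    abort("Non-numeric identity, e-value or coordinate field in hits file.",
      class = "ylink_parse_error")
  }
  if (any(out$evalue < 0) || any(out$pct_identity < 0 | out$pct_identity > 100)) {
    abort("Identity must be in [0, 100] and e-value >= 0.")
  }
  out
}

empty_hits <- function() {
  tibble(
    scaffold_id = character(), database = character(),
    subject_id = character(), pct_identity = numeric(),
    evalue = numeric(), bitscore = numeric(),
    align_start = integer(), align_end = integer(),
    identity_kind = character()
  )
}

#' Per-database significance thresholds
#'
#' Defaults mirror the search parameters used to screen candidate scaffolds:
#' protein searches (RefSeq, NR, bacterial proteins) and the transposable-
#' element search at e-value <= 1e-6; searches against the species' own
#' transcripts and annotated genes at e-value <= 1e-8 **and** 100% identity
#' (a same-genome match must be exact). `min_identity = NA` disables the
#' identity requirement for a database.
#'
#' @return Tibble with columns `database`, `max_evalue`, `min_identity`.
#' @export
evidence_thresholds <- function() {
  tibble(
    database = homology_databases(),
    max_evalue = c(1e-6, 1e-6, 1e-6, 1e-6, 1e-8, 1e-8, 1e-8),
    min_identity = c(NA, NA, NA, NA, 100, 100, 100)
  )
}

#' Filter homology hits by per-database thresholds
#'
#' Removes hits failing their database's e-value or identity threshold.
#' Idempotent: filtering twice equals filtering once.
#'
#' @param hits Tibble from [read_homology_hits()] (rows from several
#'   databases may be bound together).
#' @param thresholds Tibble like [evidence_thresholds()]; every database
#'   present in `hits` must appear, or a config error is raised.
#' @return The filtered hits tibble.
#' @export
filter_homology_hits <- function(hits, thresholds = evidence_thresholds()) {
  stopifnot(is.data.frame(hits),
            all(c("database", "pct_identity", "evalue") %in% names(hits)))
  missing_db <- setdiff(unique(hits$database), thresholds$database)
  if (length(missing_db) > 0) {
    abort(sprintf("No thresholds configured for database(s): %s",
                  paste(missing_db, collapse = ", ")),
      class = "ylink_config_error")
  }
  hits %>%
    left_join(thresholds, by = "database") %>%
    filter(.data$evalue <= .data$max_evalue,
           is.na(.data$min_identity) | .data$pct_identity >= .data$min_identity) %>%
    select(-"max_evalue", -"min_identity")
}

#' Flag scaffolds as bacterial / transposable-element contaminants
#'
#' A scaffold is flagged when it has at least one hit against the bacterial
#' or TE database with identity strictly above `identity_cutoff`. The
#' candidate-level screen uses 95; the genome-level bacterial screen uses
#' hits at exactly 100% identity (`identity_cutoff = 100` with
#' `inclusive = TRUE`).
#'
#' @param hits Hits tibble (typically unfiltered, so weak but near-identical
#'   matches still flag).
#' @param identity_cutoff Percent identity above which a hit flags its
#'   scaffold (default 95).
#' @param inclusive If `TRUE`, hits at exactly `identity_cutoff` also flag
#'   (needed for a 100%-identity screen, where "above" cannot apply).
#' @return Sorted character vector of flagged scaffold ids.
#' @export
flag_contaminants <- function(hits, identity_cutoff = 95, inclusive = FALSE) {
  stopifnot(identity_cutoff >= 0, identity_cutoff <= 100)
  screen <- filter(hits, .data$database %in% c("bacterial", "te"))
  hit <- if (inclusive) {
    screen$pct_identity >= identity_cutoff
  } else {
    screen$pct_identity > identity_cutoff
  }
  sort(unique(screen$scaffold_id[hit]))
}

tier_of_hit <- function(database, conservation_label) {
  case_when(
    database %in% c("refseq", "nr") & conservation_label == "known" ~ 1L,
    database %in% c("refseq", "nr") & conservation_label == "conserved_hypothetical" ~ 2L,
    database == "rpro_geneid" ~ 3L,
    database %in% c("refseq", "nr") & conservation_label == "unconserved_hypothetical" ~ 4L,
    database == "rpro_geneid_trash" ~ 5L,
    TRUE ~ NA_integer_
  )
}

#' Assign the five-tier evidence ranking to candidate scaffolds
#'
#' Transcript support is the strongest evidence that a candidate scaffold
#' carries a real gene and is tracked separately (`has_transcript`). The
#' remaining evidence is ranked: (1) a conserved known gene from RefSeq or
#' NR; (2) a conserved hypothetical gene; (3) an annotated gene of the
#' species; (4) an unconserved hypothetical gene; (5) a discarded annotation
#' (GeneID trash). A scaffold's tier is the best (lowest) rank among its
#' hits; scaffolds with only transcript evidence, or none, get tier `NA`.
#'
#' Conservation status (`known`, `conserved_hypothetical`,
#' `unconserved_hypothetical`) is an input annotation of the subject
#' sequences, supplied as metadata — it is not inferred from hit
#' descriptions. A RefSeq/NR hit whose subject is missing from the map is a
#' metadata error.
#'
#' @param hits Filtered, non-contaminant hits tibble
#'   (see [filter_homology_hits()]).
#' @param conservation Tibble with columns `subject_id`, `label`.
#' @return Evidence tibble: one row per scaffold with `scaffold_id`,
#'   `databases_hit` (list-column over [gene_evidence_databases()]),
#'   `n_databases`, `has_transcript`, `tier`.
#' @export
assign_evidence_tiers <- function(hits, conservation = NULL) {
  stopifnot(is.data.frame(hits))
  hits <- filter(hits, .data$database %in% gene_evidence_databases())
  if (nrow(hits) == 0) {
    return(tibble(scaffold_id = character(), databases_hit = list(),
                  n_databases = integer(), has_transcript = logical(),
                  tier = integer()))
  }

  needs_label <- hits$database %in% c("refseq", "nr")
  label <- rep(NA_character_, nrow(hits))
  if (any(needs_label)) {
    if (is.null(conservation)) {
      abort("RefSeq/NR hits present but no conservation map supplied.",
        class = "ylink_metadata_error")
    }
    stopifnot(all(c("subject_id", "label") %in% names(conservation)))
    idx <- match(hits$subject_id, conservation$subject_id)
    label <- conservation$label[idx]
    unmapped <- needs_label & is.na(label)
    if (any(unmapped)) {
      abort(sprintf(
        "Conservation label missing for RefSeq/NR subject(s): %s",
        paste(utils::head(unique(hits$subject_id[unmapped]), 3), collapse = ", ")
      ), class = "ylink_metadata_error")
    }
  }

  hits %>%
    mutate(hit_tier = tier_of_hit(.data$database, label)) %>%
    group_by(.data$scaffold_id) %>%
    summarise(
      databases_hit = list(sort(unique(.data$database))),
      n_databases = length(unique(.data$database)),
      has_transcript = any(.data$database == "rpro_transcripts"),
      tier = if (all(is.na(.data$hit_tier))) NA_integer_
             else min(.data$hit_tier, na.rm = TRUE),
      .groups = "drop"
    ) %>%
    arrange(.data$scaffold_id)
}

#' Select candidates for linkage testing
#'
#' Candidates supported by at least `min_databases` distinct gene-evidence
#' databases are selected; the output is ordered for bench work — transcript-
#' backed candidates first, then by evidence tier, breadth of database
#' support, and scaffold id.
#'
#' @param records Evidence tibble from [assign_evidence_tiers()].
#' @param min_databases Minimum number of distinct databases (default 3).
#' @return `records` with a `selected_for_testing` column, sorted.
#' @export
select_testable <- function(records, min_databases = 3L) {
  stopifnot(min_databases >= 1)
  records %>%
    mutate(selected_for_testing = .data$n_databases >= min_databases) %>%
    arrange(desc(.data$has_transcript), .data$tier, desc(.data$n_databases),
            .data$scaffold_id)
}

#' Write the evidence table as TSV
#'
#' `databases_hit` is serialised as a semicolon-separated list.
#'
#' @param records Evidence tibble (from [assign_evidence_tiers()] or
#'   [select_testable()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_evidence_table <- function(records, path) {
  out <- records %>%
    mutate(databases_hit = purrr::map_chr(.data$databases_hit,
                                          paste, collapse = ";"))
  readr::write_tsv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}
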