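#' Read a read-to-scaffold assignment table
#'
#' The read map is the assembly's read-tracking record flattened to two
#' tab-separated columns: `scaffold_id` then `read_id`, one row per read
#' placement. An optional header line (`scaffold_id<TAB>read_id`, with or
#' without a leading `#`) is recognised and skipped. Any other row with a
#' column count other than two is a parse error reported with its line
#' number.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `scaffold_id` and `read_id` and an
#'   `n_rows` attribute recording the number of data rows parsed.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("#scaffold_id\tread_id", "SC1\tNAAX1", "SC1\tNADD1"), tf)
#' read_read_map(tf)
#' @export
read_read_map <- function(path) {
  if (!file.exists(path)) abort(sprintf("Read map file not found: %s", path))
  lines <- readLines(path)
  lineno <- seq_along(lines)

  # drop an optional header
  if (length(lines) > 0) {
    hdr <- sub("^#", "", lines[1])
    if (identical(strsplit(hdr, "\t", fixed = TRUE)[[1]][1:2],
                  c("scaffold_id", "read_id"))) {
      lines <- lines[-1]
      lineno <- lineno[-1]
    }
  }
  keep <- nzchar(lines)
  lines <- lines[keep]
  lineno <- lineno[keep]

  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 2)) {
    bad <- which(nf != 2)[1]
    abort(sprintf(
      "Malformed read-map row at line %d: expected 2 tab-separated columns, found %d.",
      lineno[bad], nf[bad]
    ), class = "ylink_parse_error")
  }

  out <- tibble(
    scaffold_id = vapply(fields, `[[`, character(1), 1),
    read_id = vapply(fields, `[[`, character(1), 2)
  )
  if (any(!nzchar(out$scaffold_id)) || any(!nzchar(out$read_id))) {
    bad <- which(!nzchar(out$scaffold_id) | !nzchar(out$read_id))[1]
    abort(sprintf("Empty field in read-map row at line %d.", lineno[bad]),
      class = "ylink_parse_error")
  }
  attr(out, "n_rows") <- nrow(out)
  out
}

#' Read scaffold lengths from a FASTA file or a two-column TSV
#'
#' FASTA input (detected from a leading `>`) is measured with
#' [Biostrings::fasta.seqlengths()]; TSV input must have columns
#' `scaffold_id` and `length_bp` (header optional).
#'
#' @param path Path to the FASTA or TSV file.
#' @return A tibble with columns `scaffold_id` and `length_bp`.
#' @export
read_scaffold_lengths <- function(path) {
  if (!file.exists(path)) abort(sprintf("Lengths file not found: %s", path))
  first <- readLines(path, n = 1)
  if (length(first) == 1 && startsWith(first, ">")) {
    len <- Biostrings::fasta.seqlengths(path)
    # FASTA ids are the first whitespace-delimited token of the header
    ids <- sub("\\s.*$", "", names(len))
    return(tibble(scaffold_id = ids, length_bp = as.integer(unname(len))))
  }
  has_header <- grepl("^#?scaffold_id\t", first)
  df <- readr::read_tsv(path,
    col_names = c("scaffold_id", "length_bp"),
    col_types = readr::cols(scaffold_id = readr::col_character(),
                            length_bp = readr::col_double()),
    skip = if (has_header) 1L else 0L,
    comment = "", progress = FALSE
  )
  if (any(is.na(df$length_bp)) || any(df$length_bp < 0)) {
    abort("Scaffold lengths must be non-negative numbers.")
  }
  mutate(df, length_bp = as.integer(.data$length_bp))
}

#' Count male and female reads per scaffold
#'
#' The core tally of the separate-libraries method: each read placement is
#' resolved to a sex through the library catalog and accumulated per
#' scaffold. A read placed on several scaffolds counts once on each (the
#' assembler's view); duplicate placements of one read on one scaffold are
#' collapsed. Scaffolds present in `lengths` but absent from the read map are
#' reported with zero reads; scaffolds in the read map but missing from
#' `lengths` get `length_bp = 0` with a warning.
#'
#' @param read_map Tibble with columns `scaffold_id`, `read_id` (from
#'   [read_read_map()] or built in code).
#' @param catalog A [library_catalog()].
#' @param lengths Optional tibble with columns `scaffold_id`, `length_bp`.
#' @param on_unknown `"error"` (default) aborts on a read matching no library
#'   prefix; `"skip"` drops such reads and records how many in the
#'   `n_unknown_skipped` attribute.
#'
#' @return A tibble with one row per scaffold: `scaffold_id`, `length_bp`,
#'   `n_total`, `n_male`, `n_female`, `male_fraction` (`NA` when
#'   `n_total = 0`), sorted by `scaffold_id`.
#' @examples
#' rm <- tibble::tibble(
#'   scaffold_id = c("S", "S", "S"),
#'   read_id = c("NAAX1", "NAAX2", "NADD1")
#' )
#' count_scaffold_reads(rm, rhodnius_catalog())
#' @export
count_scaffold_reads <- function(read_map, catalog, lengths = NULL,
                                 on_unknown = c("error", "skip")) {
  on_unknown <- match.arg(on_unknown)
  stopifnot(is.data.frame(read_map),
            all(c("scaffold_id", "read_id") %in% names(read_map)))

  read_map <- distinct(as_tibble(read_map), .data$scaffold_id, .data$read_id)
  sex <- sex_of_read(read_map$read_id, catalog,
    unknown = if (on_unknown == "skip") "na" else "error")
  n_unknown <- sum(is.na(sex))
  read_map <- read_map[!is.na(sex), ]
  sex <- sex[!is.na(sex)]

  counts <- read_map %>%
    mutate(sex = sex) %>%
    group_by(.data$scaffold_id) %>%
    summarise(
      n_total = n(),
      n_male = sum(.data$sex == "male"),
      n_female = sum(.data$sex == "female"),
      .groups = "drop"
    )

  if (!is.null(lengths)) {
    stopifnot(all(c("scaffold_id", "length_bp") %in% names(lengths)))
    lengths <- distinct(as_tibble(lengths), .data$scaffold_id, .keep_all = TRUE)
    missing_len <- setdiff(counts$scaffold_id, lengths$scaffold_id)
    if (length(missing_len) > 0) {
      warn(sprintf(
        "%d scaffold(s) in the read map have no length record (length_bp set to 0), e.g. %s",
        length(missing_len), paste(utils::head(missing_len, 3), collapse = ", ")
      ))
    }
    counts <- lengths %>%
      select("scaffold_id", "length_bp") %>%
      dplyr::full_join(counts, by = "scaffold_id") %>%
      mutate(across(c("length_bp", "n_total", "n_male", "n_female"),
                    ~ dplyr::coalesce(.x, 0)))
  } else {
    counts <- mutate(counts, length_bp = 0L, .after = "scaffold_id")
  }

  counts %>%
    mutate(
      length_bp = as.integer(.data$length_bp),
      n_total = as.integer(.data$n_total),
      n_male = as.integer(.data$n_male),
      n_female = as.integer(.data$n_female),
      male_fraction = if_else(.data$n_total > 0,
                              .data$n_male / .data$n_total, NA_real_)
    ) %>%
    arrange(.data$scaffold_id) %>%
    structure(n_unknown_skipped = n_unknown)
}

#' Write / read the six-column per-scaffold count table
#'
#' The table has the columns `scaffold_id`, `length_bp`, `n_total`, `n_male`,
#' `n_female`, `pct_male` — scaffold identifier, scaffold size, reads
#' incorporated in the scaffold, reads from male libraries, reads from female
#' libraries, and the percentage of male reads. `pct_male` is formatted to
#' one decimal; scaffolds with no reads get `NA`. Integer fields round-trip
#' bit-exactly through [read_count_table()], which also rebuilds
#' `male_fraction` from the integer counts.
#'
#' @param counts Tibble from [count_scaffold_reads()].
#' @param path Output (or input) TSV path.
#' @return `write_count_table()` returns `path` invisibly;
#'   `read_count_table()` returns a counts tibble.
#' @export
write_count_table <- function(counts, path) {
  stopifnot(all(c("scaffold_id", "length_bp", "n_total", "n_male", "n_female")
                %in% names(counts)))
  out <- counts %>%
    mutate(pct_male = if_else(.data$n_total > 0,
      sprintf("%.1f", 100 * .data$n_male / .data$n_total), NA_character_)) %>%
    select("scaffold_id", "length_bp", "n_total", "n_male", "n_female", "pct_male")
  readr::write_tsv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("Count table not found: %s", path))
  df <- readr::read_tsv(path, col_types = readr::cols(
    scaffold_id = readr::col_character(),
    length_bp = readr::col_integer(),
    n_total = readr::col_integer(),
    n_male = readr::col_integer(),
    n_female = readr::col_integer(),
    pct_male = readr::col_double()
  ), na = "NA", progress = FALSE)
  df %>%
    mutate(male_fraction = if_else(.data$n_total > 0,
                                   .data$n_male / .data$n_total, NA_real_)) %>%
    select(-"pct_male")
}
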