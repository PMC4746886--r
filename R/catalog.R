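#' Build a library catalog mapping read-name prefixes to sex
#'
#' In a sex-separated sequencing design every read carries the name of the
#' library it came from as a prefix of its read id, so the sex of origin of
#' each read can be recovered from its name alone. A library catalog records
#' that mapping.
#'
#' Prefixes must be unambiguous: no catalog prefix may be a prefix of another
#' catalog prefix, so each read id matches at most one entry. The catalog must
#' name at least one male and one female library. Matching is case-sensitive.
#'
#' @param entries Data frame with columns `prefix` (character) and `sex`
#'   (`"male"` or `"female"`), one row per library.
#' @param match_mode `"prefix"` (default) matches a read id that starts with a
#'   catalog prefix; `"exact"` requires the read id to equal the prefix.
#'
#' @return A tibble of class `ylink_catalog` with columns `prefix` and `sex`
#'   and a `match_mode` attribute.
#'
#' @examples
#' cat <- library_catalog(
#'   data.frame(prefix = c("MAL", "FEM"), sex = c("male", "female"))
#' )
#' sex_of_read(c("MAL001", "FEM042"), cat)
#' @seealso [rhodnius_catalog()] for the catalog used in the *Rhodnius
#'   prolixus* genome project.
#' @export
library_catalog <- function(entries, match_mode = c("prefix", "exact")) {
  match_mode <- match.arg(match_mode)
  if (!is.data.frame(entries) || !all(c("prefix", "sex") %in% names(entries))) {
    abort("`entries` must be a data frame with columns `prefix` and `sex`.")
  }
  entries <- as_tibble(entries)[, c("prefix", "sex")]
  entries$prefix <- as.character(entries$prefix)
  entries$sex <- as.character(entries$sex)

  if (nrow(entries) == 0) abort("Catalog must have at least one entry.")
  if (any(is.na(entries$prefix)) || any(!nzchar(entries$prefix))) {
    abort("Catalog prefixes must be non-empty strings.")
  }
  if (!all(entries$sex %in% c("male", "female"))) {
    abort("Catalog `sex` values must be \"male\" or \"female\".")
  }
  if (anyDuplicated(entries$prefix)) {
    abort("Catalog prefixes must be unique.")
  }
  # unambiguous matching: no prefix may be a prefix of another
  for (p in entries$prefix) {
    others <- setdiff(entries$prefix, p)
    if (any(startsWith(others, p))) {
      abort(sprintf(
        "Catalog prefix \"%s\" is a prefix of another entry; matching would be ambiguous.", p
      ))
    }
  }
  if (!all(c("male", "female") %in% entries$sex)) {
    abort("Catalog must contain at least one male and one female library.")
  }

  structure(entries,
    match_mode = match_mode,
    class = c("ylink_catalog", class(entries))
  )
}

#' The sequencing-library catalog of the *Rhodnius prolixus* genome project
#'
#' Male DNA was sequenced in libraries NAAX (Sanger) and GFL7EVZ (454 Roche);
#' female DNA in libraries NADD, NADK and NADN (Sanger only). Every read in
#' the assembly carries one of these prefixes.
#'
#' @return A [library_catalog()] with the five library prefixes.
#' @examples
#' rhodnius_catalog()
#' @export
rhodnius_catalog <- function() {
  library_catalog(tibble(
    prefix = c("NAAX", "GFL7EVZ", "NADD", "NADK", "NADN"),
    sex = c("male", "male", "female", "female", "female")
  ))
}

#' Resolve the sex of origin of reads from their names
#'
#' @param read_id Character vector of read ids.
#' @param catalog A [library_catalog()].
#' @param unknown What to do with a read whose name matches no catalog prefix:
#'   `"error"` (default) aborts naming the offending reads; `"na"` returns
#'   `NA` for them so callers can count and drop.
#'
#' @return Character vector (`"male"`/`"female"`, possibly `NA`) parallel to
#'   `read_id`.
#' @examples
#' sex_of_read("NAAX00012345", rhodnius_catalog())
#' sex_of_read("NADK9", rhodnius_catalog())
#' @export
sex_of_read <- function(read_id, catalog, unknown = c("error", "na")) {
  unknown <- match.arg(unknown)
  stopifnot(inherits(catalog, "ylink_catalog"))
  read_id <- as.character(read_id)
  mode <- attr(catalog, "match_mode")

  sex <- rep(NA_character_, length(read_id))
  for (i in seq_len(nrow(catalog))) {
    hit <- if (identical(mode, "exact")) {
      read_id == catalog$prefix[i]
    } else {
      startsWith(read_id, catalog$prefix[i])
    }
    sex[hit] <- catalog$sex[i]
  }

  if (unknown == "error" && anyNA(sex)) {
    bad <- unique(read_id[is.na(sex)])
    abort(sprintf(
      "%d read id(s) match no library prefix (e.g. %s). Use `unknown = \"na\"` or fix the catalog.",
      length(bad), paste(utils::head(bad, 3), collapse = ", ")
    ), class = "ylink_unknown_library")
  }
  sex
}
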