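# Shared fixtures and independent oracles. The tally oracle deliberately
# avoids the package's dplyr pipeline: base-R loops over a unique()d table.

paper_catalog_df <- function() {
  data.frame(
    prefix = c("NAAX", "GFL7EVZ", "NADD", "NADK", "NADN"),
    sex = c("male", "male", "female", "female", "female")
  )
}

# brute-force per-scaffold tally straight from the rows
oracle_counts <- function(read_map, catalog_df) {
  rm <- unique(read_map[, c("scaffold_id", "read_id")])
  sex <- rep(NA_character_, nrow(rm))
  for (i in seq_len(nrow(catalog_df))) {
    sex[startsWith(rm$read_id, catalog_df$prefix[i])] <- catalog_df$sex[i]
  }
  stopifnot(!anyNA(sex))
  ids <- sort(unique(rm$scaffold_id))
  out <- data.frame(scaffold_id = ids, n_total = 0L, n_male = 0L, n_female = 0L)
  for (j in seq_along(ids)) {
    s <- sex[rm$scaffold_id == ids[j]]
    out$n_total[j] <- length(s)
    out$n_male[j] <- sum(s == "male")
    out$n_female[j] <- sum(s == "female")
  }
  out
}

random_read_map <- function(n_scaffolds, reads_each, p_male = 0.5, seed = 42) {
  withr::with_seed(seed, {
    scaffold <- rep(sprintf("SC%03d", seq_len(n_scaffolds)), each = reads_each)
    male <- stats::runif(length(scaffold)) < p_male
    prefix <- ifelse(male, sample(c("NAAX", "GFL7EVZ"), length(scaffold), TRUE),
                     sample(c("NADD", "NADK", "NADN"), length(scaffold), TRUE))
    data.frame(scaffold_id = scaffold,
               read_id = paste0(prefix, seq_along(scaffold)))
  })
}

write_tsv_lines <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

# one 12-column tabular homology row
hit_row <- function(query, subject, pct_id, evalue,
                    qstart = 1L, qend = 100L) {
  paste(query, subject, pct_id, 100, 0, 0, qstart, qend, 1, 100,
        format(evalue, scientific = TRUE), 200, sep = "\t")
}

make_hits <- function(scaffold_id, database, pct_identity = 99,
                      evalue = 1e-20, subject_id = "SUBJ1") {
  tibble::tibble(
    scaffold_id = scaffold_id, database = database, subject_id = subject_id,
    pct_identity = pct_identity, evalue = evalue, bitscore = 200,
    align_start = 1L, align_end = 100L, identity_kind = "amino_acid"
  )
}
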