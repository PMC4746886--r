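#' Classify scaffolds by chromosomal linkage
#'
#' Applies the separate-libraries decision rule to a per-scaffold count
#' table. Each scaffold receives exactly one call, in priority order:
#'
#' * `excluded_contaminant` — the scaffold is on the contaminant list
#'   (bacterial / transposable-element screen, see [flag_contaminants()]);
#' * `no_reads` — no reads were assigned;
#' * `excluded_low_reads` — fewer than `min_reads` total reads, where the
#'   all-male false-positive chance would exceed the tolerated bound;
#' * `Y_candidate` — every read is male; the per-scaffold false-positive
#'   probability p^n is attached as `fp_probability`;
#' * `X_band` — male fraction within `x_band_halfwidth` of the X expectation
#'   r/(r+2); a flag, not a confident call, since autosomal sampling noise
#'   overlaps this band heavily;
#' * `autosome_like` — everything else.
#'
#' The default `min_reads = 11` retains scaffolds with more than 10 reads,
#' the published filter; the model-derived threshold
#' [min_read_threshold()]`(p, alpha)` is recorded in the result's
#' configuration and a message notes any disagreement between the two.
#'
#' @param counts Tibble from [count_scaffold_reads()] (or
#'   [read_count_table()]).
#' @param stats Optional one-row tibble from [global_male_fraction()] /
#'   [global_read_stats()]; computed from `counts` when omitted.
#' @param contaminants Character vector of scaffold ids to exclude as
#'   contaminants.
#' @param alpha Per-scaffold false-positive bound (default 1/200).
#' @param min_reads Scaffolds with `n_total < min_reads` are excluded
#'   (default 11, i.e. scaffolds with 10 reads or less are dropped).
#' @param x_band_halfwidth Half-width of the X-candidate male-fraction band
#'   around r/(r+2) (default 0.05).
#' @param quiet Suppress the threshold-disagreement message.
#'
#' @return A tibble of class `ylink_calls` with columns `scaffold_id`,
#'   `call`, `length_bp`, `n_total`, `n_male`, `male_fraction`,
#'   `fp_probability` (defined only for `Y_candidate` rows), carrying the
#'   read statistics and configuration as attributes. Works with [tidy()],
#'   [glance()], [autoplot()] and [summarize_candidates()].
#' @examples
#' counts <- tibble::tibble(
#'   scaffold_id = c("S1", "S2", "S3"),
#'   length_bp = c(5000L, 800L, 12000L),
#'   n_total = c(15L, 10L, 100L),
#'   n_male = c(15L, 10L, 61L),
#'   n_female = c(0L, 0L, 39L),
#'   male_fraction = c(1, 1, 0.61)
#' )
#' classify_scaffolds(counts, stats = global_read_stats(585, 415))
#' @export
classify_scaffolds <- function(counts, stats = NULL, contaminants = character(),
                               alpha = 1 / 200, min_reads = 11L,
                               x_band_halfwidth = 0.05, quiet = FALSE) {
  stopifnot(alpha > 0, alpha < 1, min_reads >= 1, x_band_halfwidth >= 0)
  if (is.null(stats)) stats <- global_male_fraction(counts)
  p <- stats$p_male
  r <- stats$r_rate_ratio
  x_expect <- expected_male_fraction("X", r)

  model_min_reads <- min_read_threshold(p, alpha)
  if (!quiet && model_min_reads != min_reads) {
    inform(sprintf(
      "min_reads = %d differs from the model-derived threshold %d (smallest n with p^n <= alpha; p = %.4f, alpha = %.4g).",
      min_reads, model_min_reads, p, alpha
    ))
  }

  calls <- counts %>%
    mutate(
      call = case_when(
        .data$scaffold_id %in% contaminants ~ "excluded_contaminant",
        .data$n_total == 0L ~ "no_reads",
        .data$n_total < min_reads ~ "excluded_low_reads",
        .data$n_male == .data$n_total ~ "Y_candidate",
        abs(.data$male_fraction - x_expect) <= x_band_halfwidth ~ "X_band",
        TRUE ~ "autosome_like"
      ),
      fp_probability = if_else(.data$call == "Y_candidate",
                               p^.data$n_total, NA_real_)
    ) %>%
    select("scaffold_id", "call", "length_bp", "n_total", "n_male",
           "male_fraction", "fp_probability")

  structure(calls,
    stats = stats,
    config = list(alpha = alpha, min_reads = as.integer(min_reads),
                  x_band_halfwidth = x_band_halfwidth,
                  model_min_reads = model_min_reads,
                  x_expected_male_fraction = x_expect),
    class = c("ylink_calls", class(calls))
  )
}

retained_calls <- c("Y_candidate", "X_band", "autosome_like")

#' Summarise candidate calls
#'
#' Builds the per-percent histogram of scaffold counts and of summed
#' scaffold lengths over retained scaffolds, plus headline totals: number of
#' Y candidates, their summed length, the retained assembly size and the
#' Y-candidate share of it, and the expected number of false positives
#' (the sum of p^n over retained scaffolds — what the per-scaffold binomial
#' model predicts would be all-male by chance).
#'
#' Percent bins are the floor of the male percentage; the 100 bin is reserved
#' for scaffolds whose reads are exactly all male, so a 99.6%-male scaffold
#' never rounds into the Y bin.
#'
#' @param calls A `ylink_calls` tibble from [classify_scaffolds()].
#' @param counts Optional counts tibble supplying `length_bp` when `calls`
#'   lacks it.
#' @return A list of class `ylink_summary`: `histogram` (tibble `pct_male`,
#'   `n_scaffolds`, `total_bp`) and `totals` (one-row tibble).
#' @export
summarize_candidates <- function(calls, counts = NULL) {
  stopifnot(inherits(calls, "ylink_calls"))
  stats <- attr(calls, "stats")
  cfg <- attr(calls, "config")
  if (!is.null(counts)) {
    calls <- calls %>%
      select(-"length_bp") %>%
      left_join(select(counts, "scaffold_id", "length_bp"), by = "scaffold_id")
  }

  retained <- filter(calls, .data$call %in% retained_calls)
  hist <- retained %>%
    mutate(pct_male = if_else(.data$n_male == .data$n_total, 100,
                              floor(100 * .data$male_fraction))) %>%
    group_by(.data$pct_male) %>%
    summarise(n_scaffolds = n(),
              total_bp = sum(as.numeric(.data$length_bp)), .groups = "drop") %>%
    arrange(.data$pct_male)

  y <- filter(retained, .data$call == "Y_candidate")
  totals <- tibble(
    n_scaffolds = nrow(calls),
    n_retained = nrow(retained),
    n_excluded_low_reads = sum(calls$call == "excluded_low_reads"),
    n_excluded_contaminant = sum(calls$call == "excluded_contaminant"),
    n_no_reads = sum(calls$call == "no_reads"),
    n_y_candidates = nrow(y),
    y_candidate_bp = sum(as.numeric(y$length_bp)),
    retained_bp = sum(as.numeric(retained$length_bp)),
    pct_genome_y = genome_fraction(sum(as.numeric(y$length_bp)),
                                   max(sum(as.numeric(retained$length_bp)), 1)),
    expected_false_positives = sum(stats$p_male^retained$n_total),
    p_male = stats$p_male,
    alpha = cfg$alpha,
    min_reads = cfg$min_reads,
    model_min_reads = cfg$model_min_reads
  )

  structure(list(histogram = hist, totals = totals), class = "ylink_summary")
}

#' @export
print.ylink_summary <- function(x, ...) {
  t <- x$totals
  cat(sprintf(
    paste0("Separate-libraries scan: %d scaffolds, %d retained ",
           "(min_reads = %d)\n  p_male = %.4f; %d Y candidates spanning ",
           "%s bp (%.1f%% of retained assembly)\n  expected false positives: %.2f\n"),
    t$n_scaffolds, t$n_retained, t$min_reads, t$p_male, t$n_y_candidates,
    format(t$y_candidate_bp, big.mark = ","), t$pct_genome_y,
    t$expected_false_positives
  ))
  invisible(x)
}

#' Percentage of the genome covered by candidate scaffolds
#'
#' @param candidate_bp Summed candidate length in bp.
#' @param genome_bp Genome (or retained-assembly) size in bp; must be > 0.
#' @return `100 * candidate_bp / genome_bp`, rounded to one decimal.
#' @examples
#' genome_fraction(1.6e6, 700e6) # 0.2
#' @export
genome_fraction <- function(candidate_bp, genome_bp) {
  stopifnot(candidate_bp >= 0)
  if (any(genome_bp <= 0)) abort("`genome_bp` must be positive.")
  round(100 * candidate_bp / genome_bp, 1)
}
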