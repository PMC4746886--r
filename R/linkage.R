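#' Genome-wide male-read statistics
#'
#' `global_read_stats()` builds the statistics from raw totals;
#' `global_male_fraction()` computes them from a per-scaffold count table.
#' `p_male` is the genome-wide proportion of male reads (p). Because the
#' genome is overwhelmingly autosomal, p also estimates the per-chromosome-
#' copy male:female sampling-rate ratio as r = p / (1 - p): an autosome has
#' two copies in each sex, so its reads split male:female as r : 1.
#'
#' `restrict_band` optionally restricts estimation to scaffolds whose male
#' fraction lies in a central band, approximating an autosome-only estimate
#' (sex-linked scaffolds sit near the extremes). The default uses every
#' retained read, which is appropriate when Y and X content is a negligible
#' share of the read total.
#'
#' @param counts Tibble from [count_scaffold_reads()].
#' @param restrict_band Optional length-2 numeric: keep only scaffolds with
#'   `male_fraction` inside `[restrict_band[1], restrict_band[2]]` when
#'   summing reads.
#' @param total_male,total_female Non-negative read totals.
#' @return One-row tibble with `total_male`, `total_female`, `p_male`,
#'   `r_rate_ratio`.
#' @examples
#' global_read_stats(4227964, 2993635) # p_male ~ 0.585
#' @export
global_male_fraction <- function(counts, restrict_band = NULL) {
  stopifnot(all(c("n_male", "n_female") %in% names(counts)))
  if (!is.null(restrict_band)) {
    stopifnot(length(restrict_band) == 2, restrict_band[1] <= restrict_band[2])
    counts <- filter(counts, !is.na(.data$male_fraction),
      .data$male_fraction >= restrict_band[1],
      .data$male_fraction <= restrict_band[2])
  }
  global_read_stats(sum(counts$n_male), sum(counts$n_female))
}

#' @rdname global_male_fraction
#' @export
global_read_stats <- function(total_male, total_female) {
  stopifnot(length(total_male) == 1, length(total_female) == 1,
            total_male >= 0, total_female >= 0)
  total <- total_male + total_female
  if (total == 0) {
    abort("Cannot compute male-read statistics from zero reads.",
      class = "ylink_undefined_stats")
  }
  p <- total_male / total
  tibble(
    total_male = total_male,
    total_female = total_female,
    p_male = p,
    r_rate_ratio = p / (1 - p)
  )
}

#' False-positive probability for an all-male scaffold
#'
#' An autosome-like scaffold assembled from n reads is all-male by chance
#' with probability p^n, where p is the genome-wide male-read proportion:
#' each of its reads is independently male with probability p. This is the
#' per-scaffold probability that a scaffold with no female copies of its
#' sequence *appears* Y-linked purely through sampling.
#'
#' @param n_reads Integer vector, each >= 1.
#' @param p_male Male-read proportion in (0, 1].
#' @return `p_male ^ n_reads`, vectorised over `n_reads`.
#' @examples
#' fp_probability(9, 0.585)  # ~0.008, above a 1/200 bound
#' fp_probability(11, 0.585) # below 1/200
#' @export
fp_probability <- function(n_reads, p_male) {
  if (any(n_reads < 1) || any(n_reads != floor(n_reads))) {
    abort("`n_reads` must be integers >= 1.")
  }
  stopifnot(length(p_male) == 1, p_male > 0, p_male <= 1)
  p_male^n_reads
}

#' Minimum read count for a target false-positive bound
#'
#' The smallest integer n with `p_male^n <= alpha`: scaffolds assembled from
#' at least this many reads have a per-scaffold chance of at most `alpha` of
#' being all-male by accident. Closed form n = ceil(log alpha / log p),
#' corrected for floating-point edge cases so that the defining inequality
#' `p^n <= alpha < p^(n-1)` holds exactly.
#'
#' @param p_male Male-read proportion in (0, 1).
#' @param alpha False-positive bound in (0, 1).
#' @return Integer n (vectorised over `p_male`/`alpha` recycled).
#' @examples
#' min_read_threshold(0.585, 1 / 200) # 10
#' @export
min_read_threshold <- function(p_male, alpha) {
  stopifnot(all(p_male > 0), all(p_male < 1), all(alpha > 0), all(alpha < 1))
  one <- function(p, a) {
    n <- max(1L, as.integer(ceiling(log(a) / log(p) - 1e-9)))
    while (p^n > a) n <- n + 1L
    while (n > 1L && p^(n - 1L) <= a) n <- n - 1L
    n
  }
  as.integer(mapply(one, p_male, alpha))
}

#' Expected male-read fraction by chromosome class
#'
#' Copy numbers per diploid individual are (male, female) = (2, 2) for
#' autosomes, (1, 2) for the X and (1, 0) for the Y. With a per-copy
#' male:female sampling-rate ratio r, a scaffold of class c with copies
#' (m_c, f_c) accumulates male reads in expectation r * m_c and female reads
#' f_c (in rate units), giving expected male fractions r/(r+1) for autosomes,
#' r/(r+2) for the X and 1 for the Y. At equal per-sex effort (r = 1) these
#' are 1/2, 1/3 (i.e. two thirds female reads) and 1.
#'
#' @param chrom_class Character vector over `"A"`, `"X"`, `"Y"`.
#' @param r_rate_ratio Per-copy male:female sampling-rate ratio, > 0.
#' @return Numeric vector of expected male fractions.
#' @examples
#' expected_male_fraction(c("A", "X", "Y"), 1)
#' @export
expected_male_fraction <- function(chrom_class, r_rate_ratio) {
  stopifnot(all(chrom_class %in% c("A", "X", "Y")), r_rate_ratio > 0)
  r <- r_rate_ratio
  unname(c(A = r / (r + 1), X = r / (r + 2), Y = 1)[chrom_class])
}
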