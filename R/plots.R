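#' Plot the male-read-fraction spectrum of a scan
#'
#' The diagnostic view of a separate-libraries scan: a histogram of
#' scaffolds by integer percent of male reads over retained scaffolds.
#' Autosomal scaffolds pile up around the genome-wide male fraction, the X
#' band sits lower, and Y candidates form the isolated spike at 100%.
#'
#' @param object A `ylink_calls` tibble from [classify_scaffolds()].
#' @param y `"scaffolds"` (number of scaffolds per percent bin) or `"bp"`
#'   (summed scaffold length per bin).
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' sim <- simulate_counts(synthetic_genome_spec(n_autosomal = 200,
#'   n_x = 20, n_y = 10, seed = 2))
#' autoplot(classify_scaffolds(sim$counts, quiet = TRUE))
#' @method autoplot ylink_calls
#' @export
autoplot.ylink_calls <- function(object, y = c("scaffolds", "bp"), ...) {
  y <- match.arg(y)
  hist <- summarize_candidates(object)$histogram
  yvar <- if (y == "scaffolds") "n_scaffolds" else "total_bp"
  ylab <- if (y == "scaffolds") "Scaffolds" else "Summed scaffold length (bp)"
  x_expect <- attr(object, "config")$x_expected_male_fraction

  ggplot2::ggplot(hist, ggplot2::aes(x = .data$pct_male, y = .data[[yvar]])) +
    ggplot2::geom_col(width = 0.9, fill = "grey35") +
    ggplot2::geom_vline(xintercept = 100 * x_expect, linetype = "dashed",
                        colour = "steelblue") +
    ggplot2::labs(
      x = "Male reads (%)", y = ylab,
      title = "Scaffolds by percentage of male reads",
      subtitle = "Spike at 100% = Y-linkage candidates; dashed line = X expectation"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the false-positive probability against read count
#'
#' Shows p^n, the chance that an autosome-like scaffold with n reads is
#' all-male by accident, with the tolerated bound and the resulting minimum
#' read threshold marked.
#'
#' @param p_male Genome-wide male-read proportion.
#' @param alpha False-positive bound to mark (default 1/200).
#' @param max_reads Largest read count to show.
#' @return A ggplot object.
#' @examples
#' plot_fp_curve(0.585)
#' @export
plot_fp_curve <- function(p_male, alpha = 1 / 200, max_reads = 25L) {
  n <- seq_len(max_reads)
  df <- tibble(n_reads = n, fp = fp_probability(n, p_male))
  thr <- min_read_threshold(p_male, alpha)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_reads, y = .data$fp)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = alpha, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::geom_vline(xintercept = thr, linetype = "dotted") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "Reads in scaffold (n)",
      y = "P(all reads male | autosome-like)",
      title = sprintf("False-positive probability p^n at p = %.3f", p_male),
      subtitle = sprintf("Bound %.4g met from n = %d reads", alpha, thr)
    ) +
    ggplot2::theme_minimal()
}
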