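#' Tidy and glance methods for linkage-call tables
#'
#' `tidy()` returns the calls as a plain tibble (attributes dropped);
#' `glance()` returns the one-row headline summary — scaffold and candidate
#' totals, candidate bp and genome share, the genome-wide male fraction and
#' the thresholds in force.
#'
#' @param x A `ylink_calls` object from [classify_scaffolds()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy ylink_calls
#' @examples
#' counts <- simulate_counts(synthetic_genome_spec(n_autosomal = 100,
#'   n_x = 5, n_y = 5, seed = 3))$counts
#' fit <- classify_scaffolds(counts, quiet = TRUE)
#' glance(fit)
#' @export
tidy.ylink_calls <- function(x, ...) {
  out <- as_tibble(x)
  attr(out, "stats") <- NULL
  attr(out, "config") <- NULL
  class(out) <- setdiff(class(out), "ylink_calls")
  out
}

#' @rdname tidy.ylink_calls
#' @method glance ylink_calls
#' @export
glance.ylink_calls <- function(x, ...) {
  summarize_candidates(x)$totals
}

#' @export
print.ylink_calls <- function(x, ...) {
  stats <- attr(x, "stats")
  cfg <- attr(x, "config")
  cat(sprintf(
    "<ylink_calls> %d scaffolds; p_male = %.4f; min_reads = %d; alpha = %.4g\n",
    nrow(x), stats$p_male, cfg$min_reads, cfg$alpha
  ))
  y <- x
  class(y) <- setdiff(class(y), "ylink_calls")
  print(y, ...)
  invisible(x)
}
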