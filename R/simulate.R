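#' Specify a synthetic sex-separated sequencing experiment
#'
#' The simulator emulates the statistical structure the separate-libraries
#' method relies on: scaffolds of chromosomal classes A / X / Y with copy
#' numbers (male, female) = (2, 2) / (1, 2) / (1, 0), read totals drawn
#' Poisson with mean proportional to scaffold length, depth and class copy
#' weight, and the male/female split drawn binomially with the class's
#' expected male fraction under a per-copy male:female sampling-rate ratio
#' r = effort / (1 - effort).
#'
#' Copy weights are normalised so `reads_per_bp` is the expected depth of an
#' autosomal scaffold: w_c = (m_c r + f_c) / (2r + 2) for class copies
#' (m_c, f_c), giving w_A = 1, w_X = (r + 2)/(2r + 2), w_Y = r/(2r + 2).
#'
#' Cross-sex contamination (mis-binned reads, e.g. barcode hopping or sample
#' mix-ups) is modelled as independent label flips: each read's recorded sex
#' is flipped with probability `contamination_rate`. Assembly chimerism is
#' not modelled.
#'
#' @param n_autosomal,n_x,n_y Scaffold counts per class (at least one
#'   scaffold overall).
#' @param length_range Min/max scaffold length in bp; lengths are drawn
#'   log-uniformly to mimic the heavy small-scaffold skew of draft
#'   assemblies.
#' @param reads_per_bp Expected reads per base for an autosomal scaffold
#'   (default 0.01, the regime of a ~7 million-read, 700 Mb Sanger/454
#'   assembly).
#' @param effort_male_fraction Share of total sequencing effort from the male
#'   library, in (0, 1); default 0.585, the realized share in the genome
#'   project this method was built for.
#' @param contamination_rate Probability a read's sex label is flipped, in
#'   \[0, 1).
#' @param fixed_n_total Optional integer: force every scaffold's read total
#'   to this value instead of drawing it Poisson (used for calibration at a
#'   fixed read count).
#' @param seed Integer seed; identical specs give byte-identical output.
#' @return A list of class `ylink_sim_spec`.
#' @export
synthetic_genome_spec <- function(n_autosomal = 1000L, n_x = 60L, n_y = 40L,
                                  length_range = c(1e3, 1e5),
                                  reads_per_bp = 0.01,
                                  effort_male_fraction = 0.585,
                                  contamination_rate = 0,
                                  fixed_n_total = NULL,
                                  seed = 1L) {
  stopifnot(
    n_autosomal >= 0, n_x >= 0, n_y >= 0, n_autosomal + n_x + n_y >= 1,
    length(length_range) == 2, length_range[1] > 0,
    length_range[1] <= length_range[2],
    reads_per_bp > 0,
    effort_male_fraction > 0, effort_male_fraction < 1,
    contamination_rate >= 0, contamination_rate < 1,
    is.null(fixed_n_total) || fixed_n_total >= 0
  )
  structure(list(
    n_autosomal = as.integer(n_autosomal), n_x = as.integer(n_x),
    n_y = as.integer(n_y), length_range = as.numeric(length_range),
    reads_per_bp = reads_per_bp,
    effort_male_fraction = effort_male_fraction,
    contamination_rate = contamination_rate,
    fixed_n_total = if (is.null(fixed_n_total)) NULL else as.integer(fixed_n_total),
    seed = as.integer(seed)
  ), class = "ylink_sim_spec")
}

sim_class_params <- function(r) {
  tibble(
    true_class = c("A", "X", "Y"),
    copies_male = c(2, 1, 1),
    copies_female = c(2, 2, 0),
    q_male = expected_male_fraction(c("A", "X", "Y"), r),
    copy_weight = (c(2, 1, 1) * r + c(2, 2, 0)) / (2 * r + 2)
  )
}

#' Simulate per-scaffold read counts with known chromosomal truth
#'
#' @param spec A [synthetic_genome_spec()].
#' @return A list with `counts` (a tibble in [count_scaffold_reads()] form)
#'   and `truth` (tibble `scaffold_id`, `true_class`, `length_bp`, `n_total`,
#'   `n_male` — the drawn values, after any contamination flips, so the
#'   emitted read map reproduces them exactly).
#' @examples
#' sim <- simulate_counts(synthetic_genome_spec(n_autosomal = 50, seed = 7))
#' head(sim$counts)
#' @export
simulate_counts <- function(spec) {
  stopifnot(inherits(spec, "ylink_sim_spec"))
  e <- spec$effort_male_fraction
  r <- e / (1 - e)
  params <- sim_class_params(r)

  cls <- rep(c("A", "X", "Y"), times = c(spec$n_autosomal, spec$n_x, spec$n_y))
  n <- length(cls)
  i <- match(cls, params$true_class)

  withr::with_seed(spec$seed, {
    length_bp <- as.integer(round(exp(runif(
      n, log(spec$length_range[1]), log(spec$length_range[2])
    ))))
    lambda <- length_bp * spec$reads_per_bp * params$copy_weight[i]
    n_total <- if (is.null(spec$fixed_n_total)) {
      rpois(n, lambda)
    } else {
      rep(spec$fixed_n_total, n)
    }
    n_male_true <- rbinom(n, n_total, params$q_male[i])
    eps <- spec$contamination_rate
    n_male <- if (eps > 0) {
      rbinom(n, n_male_true, 1 - eps) + rbinom(n, n_total - n_male_true, eps)
    } else {
      n_male_true
    }
  })

  truth <- tibble(
    scaffold_id = sprintf("SC%06d", seq_len(n)),
    true_class = cls,
    length_bp = length_bp,
    n_total = as.integer(n_total),
    n_male = as.integer(n_male)
  )
  counts <- truth %>%
    select(-"true_class") %>%
    mutate(
      n_female = .data$n_total - .data$n_male,
      male_fraction = if_else(.data$n_total > 0,
                              .data$n_male / .data$n_total, NA_real_)
    ) %>%
    select("scaffold_id", "length_bp", "n_total", "n_male", "n_female",
           "male_fraction")
  list(counts = counts, truth = truth)
}

#' Emit a read map realising simulated truth counts
#'
#' Writes a two-column read-map TSV whose rows, run back through
#' [read_read_map()] and [count_scaffold_reads()], reproduce each truth
#' record's `(n_total, n_male)` exactly. Read names are a catalog prefix of
#' the appropriate sex plus a unique numeric suffix; rows are written in
#' shuffled order so downstream code cannot rely on grouping.
#'
#' @param truth Truth tibble from [simulate_counts()].
#' @param catalog A [library_catalog()].
#' @param path Output TSV path.
#' @param seed Integer seed for prefix choice and row shuffling.
#' @return `path`, invisibly.
#' @export
emit_read_map <- function(truth, catalog, path, seed = 1L) {
  stopifnot(inherits(catalog, "ylink_catalog"),
            all(c("scaffold_id", "n_total", "n_male") %in% names(truth)))
  male_pre <- catalog$prefix[catalog$sex == "male"]
  female_pre <- catalog$prefix[catalog$sex == "female"]

  n_male <- truth$n_male
  n_female <- truth$n_total - n_male
  scaffold <- c(
    rep(truth$scaffold_id, times = n_male),
    rep(truth$scaffold_id, times = n_female)
  )
  sex_is_male <- rep(c(TRUE, FALSE), times = c(sum(n_male), sum(n_female)))
  total <- length(scaffold)

  withr::with_seed(as.integer(seed), {
    prefix <- character(total)
    prefix[sex_is_male] <- sample(male_pre, sum(sex_is_male), replace = TRUE)
    prefix[!sex_is_male] <- sample(female_pre, sum(!sex_is_male), replace = TRUE)
    ord <- sample.int(total)
  })
  read_id <- paste0(prefix, sprintf("%09d", seq_len(total)))

  out <- tibble(scaffold_id = scaffold[ord], read_id = read_id[ord])
  readr::write_lines("#scaffold_id\tread_id", path)
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE,
                   append = TRUE)
  invisible(path)
}

#' Score recovery of simulated truth by the classifier
#'
#' Quantifies how well the separate-libraries decision rule recovers known
#' chromosomal classes: sensitivity for true Y scaffolds and false-positive
#' rates among retained autosomal and X scaffolds, alongside the analytic
#' expectation (the mean of p^n over retained non-Y scaffolds).
#'
#' @param calls A `ylink_calls` tibble from [classify_scaffolds()].
#' @param truth Truth tibble from [simulate_counts()]; every scaffold in
#'   `calls` must appear.
#' @return One-row tibble: `sensitivity_y`, `fp_rate_autosomal`, `fp_rate_x`
#'   (each `NA` when its denominator is empty), `expected_fp_rate`,
#'   `n_excluded_low_reads`, `n_retained`.
#' @export
score_recovery <- function(calls, truth) {
  stopifnot(inherits(calls, "ylink_calls"),
            all(c("scaffold_id", "true_class") %in% names(truth)))
  missing <- setdiff(calls$scaffold_id, truth$scaffold_id)
  if (length(missing) > 0) {
    abort(sprintf("Scaffold(s) in calls missing from truth: %s",
                  paste(utils::head(missing, 3), collapse = ", ")),
      class = "ylink_alignment_error")
  }
  p <- attr(calls, "stats")$p_male
  joined <- left_join(as_tibble(calls),
                      select(truth, "scaffold_id", "true_class"),
                      by = "scaffold_id") %>%
    mutate(retained = .data$call %in% retained_calls,
           called_y = .data$call == "Y_candidate")

  rate <- function(df) if (nrow(df) == 0) NA_real_ else mean(df$called_y)
  ret <- filter(joined, .data$retained)
  non_y_ret <- filter(ret, .data$true_class != "Y")

  tibble(
    sensitivity_y = rate(filter(ret, .data$true_class == "Y")),
    fp_rate_autosomal = rate(filter(ret, .data$true_class == "A")),
    fp_rate_x = rate(filter(ret, .data$true_class == "X")),
    expected_fp_rate = if (nrow(non_y_ret) == 0) NA_real_
                       else mean(p^non_y_ret$n_total),
    n_excluded_low_reads = sum(joined$call == "excluded_low_reads"),
    n_retained = nrow(ret)
  )
}
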