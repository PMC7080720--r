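#' Run one simulated detection trial
#'
#' One iteration of the Monte-Carlo validation loop: excise a random
#' vector segment and insert it into the genome, simulate test reads from the
#' edited genome and contrast reads from the unmodified genome at the same
#' coverage, profile every vector position with the one-sided G-test, and
#' judge detection against the known truth. Detection and false-positive
#' counts are reported under both the raw and the Williams-corrected G
#' statistic, computed from the same counts.
#'
#' @param genome Host genome (base string).
#' @param vector_seq Vector sequence (base string).
#' @param insert_length Insert length L in nt.
#' @param k Word length (must be <= L, otherwise the combination is
#'   undefined in the method).
#' @param coverage Mean sequencing depth for both samples.
#' @param read_length,fragment_mean,fragment_sd,error_rate See
#'   [simulate_read_pairs()].
#' @param alpha Significance level.
#' @param circular Vector topology.
#' @param seed Optional integer seed applied locally; record it to reproduce
#'   the trial exactly.
#' @return A one-row tibble with the truth, the totals and the outcome.
#' @export
run_detection_trial <- function(genome, vector_seq, insert_length, k, coverage,
                                read_length = 100, fragment_mean = 500,
                                fragment_sd = 50, error_rate = 0.003,
                                alpha = 0.01, circular = TRUE, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  g <- as_sequence(genome, "genome")
  v <- as_sequence(vector_seq, "vector")
  if (k > insert_length) {
    stop("k (", k, ") exceeds insert length (", insert_length,
         ") - combination undefined in the method", call. = FALSE)
  }
  ins <- insert_segment(g, v, insert_length, circular = circular)
  np <- function(glen) as.integer(round(coverage * glen / (2 * read_length)))
  test <- cpp_simulate_count(ins$genome, v, as.integer(k), circular,
                             np(nchar(ins$genome)), as.integer(read_length),
                             fragment_mean, fragment_sd, error_rate)
  ctr <- cpp_simulate_count(g, v, as.integer(k), circular,
                            np(nchar(g)), as.integer(read_length),
                            fragment_mean, fragment_sd, error_rate)
  a <- test$counts
  b <- ctr$counts
  n1 <- test$total
  n2 <- ctr$total
  thr <- g_critical(alpha)
  nz <- which(a > 0 | b > 0)
  sig <- sig_w <- integer(0)
  if (length(nz) > 0) {
    G <- g_statistic(a[nz], b[nz], n1, n2)
    Gw <- g_statistic(a[nz], b[nz], n1, n2, correction = "williams")
    excess <- a[nz] / n1 > b[nz] / n2
    sig <- nz[G >= thr & excess]
    sig_w <- nz[Gw >= thr & excess]
  }
  tr <- ins$truth
  elig <- eligible_region(tr$vector_start, tr$vector_end, k, nchar(v))
  tibble(
    vector_start = tr$vector_start, vector_end = tr$vector_end,
    insert_length = insert_length, genome_position = tr$genome_position,
    k = k, coverage = coverage,
    total_test = n1, total_contrast = n2,
    max_eligible_count = if (length(elig)) max(a[elig]) else 0L,
    n_significant = length(sig),
    detected = any(sig %in% elig),
    false_positives = sum(!sig %in% elig),
    detected_williams = any(sig_w %in% elig),
    false_positives_williams = sum(!sig_w %in% elig),
    seed = seed %||% NA_integer_
  )
}

# Shared campaign driver over a cell grid. Per-trial seeds are
# base_seed + (cell_index - 1) * iterations + iteration, so any single trial
# is independently reproducible from the summary row.
run_campaign <- function(cells, genome, vector_seq, iterations, base_seed,
                         read_length, fragment_mean, fragment_sd, error_rate,
                         alpha, circular, progress = FALSE) {
  trials <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, ]
    if (cell$k > cell$insert_length) next  # undefined cell
    rows <- vector("list", iterations)
    for (it in seq_len(iterations)) {
      rows[[it]] <- run_detection_trial(
        genome, vector_seq, cell$insert_length, cell$k, cell$coverage,
        read_length = read_length, fragment_mean = fragment_mean,
        fragment_sd = fragment_sd, error_rate = error_rate, alpha = alpha,
        circular = circular,
        seed = base_seed + (ci - 1L) * iterations + it
      )
    }
    trials[[ci]] <- dplyr::bind_rows(rows)
    if (progress) {
      message(sprintf("cell %d/%d (L=%d, k=%d, %gx): done",
                      ci, nrow(cells), cell$insert_length, cell$k,
                      cell$coverage))
    }
  }
  trials <- dplyr::bind_rows(trials)
  summary <- cells |>
    dplyr::mutate(cell = dplyr::row_number()) |>
    dplyr::left_join(
      trials |>
        dplyr::group_by(.data$insert_length, .data$k, .data$coverage) |>
        dplyr::summarise(
          iterations = dplyr::n(),
          successes = sum(.data$detected),
          accuracy = 100 * mean(.data$detected),
          successes_williams = sum(.data$detected_williams),
          accuracy_williams = 100 * mean(.data$detected_williams),
          fp_mean = mean(.data$false_positives),
          fp_sd = stats::sd(.data$false_positives),
          fp_mean_williams = mean(.data$false_positives_williams),
          .groups = "drop"
        ),
      by = c("insert_length", "k", "coverage")
    ) |>
    dplyr::mutate(undefined = .data$k > .data$insert_length)
  list(trials = trials, summary = summary)
}

#' Detection-power campaign over insert lengths and word lengths
#'
#' For every (insert length, k) cell at a fixed coverage, runs `iterations`
#' independent trials ([run_detection_trial()]) and tabulates successes and
#' false positives. Cells with k greater than the insert length are reported
#' as undefined rather than run: no fully-internal window exists there.
#'
#' @param vector_seq Vector sequence (base string or [read_fasta()] row).
#' @param insert_lengths,k_values Grid of insert lengths and word lengths.
#' @param coverage Sequencing depth for all cells.
#' @param genome Host genome string; if `NULL`, a random genome of
#'   `genome_length` nt is generated from `base_seed`.
#' @param genome_length Length of the synthetic genome (default 100 kb).
#' @param iterations Trials per cell (default 1000).
#' @param base_seed Campaign seed; per-trial seeds derive from it.
#' @param read_length,fragment_mean,fragment_sd,error_rate,alpha,circular
#'   Passed to [run_detection_trial()].
#' @param progress Emit a message per completed cell.
#' @return An object of class `kmer_experiment`: list with `trials` (one row
#'   per trial) and `summary` (one row per cell).
#' @export
run_power_experiment <- function(vector_seq, insert_lengths = c(15, 20, 30, 50),
                                 k_values = c(10, 15, 20, 25, 30),
                                 coverage = 50, genome = NULL,
                                 genome_length = 1e5, iterations = 1000,
                                 base_seed = 1, read_length = 100,
                                 fragment_mean = 500, fragment_sd = 50,
                                 error_rate = 0.003, alpha = 0.01,
                                 circular = TRUE, progress = FALSE) {
  v <- as_sequence(vector_seq, "vector")
  if (is.null(genome)) genome <- random_genome(genome_length, seed = base_seed)
  cells <- tidyr::expand_grid(insert_length = insert_lengths, k = k_values,
                              coverage = coverage)
  res <- run_campaign(cells, genome, v, iterations, base_seed, read_length,
                      fragment_mean, fragment_sd, error_rate, alpha, circular,
                      progress)
  structure(c(res, list(kind = "power", base_seed = base_seed)),
            class = "kmer_experiment")
}

#' Detection accuracy as a function of sequencing depth
#'
#' Runs `iterations` trials at each coverage for a fixed insert length and k
#' (defaults: the 20-nt insert / 20-mer screening configuration) and reports
#' the detection accuracy and false-positive statistics per coverage.
#'
#' @param coverages Depths to examine (default 10x-50x).
#' @param insert_length,k Fixed insert and word length.
#' @inheritParams run_power_experiment
#' @return A `kmer_experiment` (see [run_power_experiment()]).
#' @export
run_coverage_sweep <- function(vector_seq, coverages = c(10, 20, 30, 40, 50),
                               insert_length = 20, k = 20, genome = NULL,
                               genome_length = 1e5, iterations = 1000,
                               base_seed = 1, read_length = 100,
                               fragment_mean = 500, fragment_sd = 50,
                               error_rate = 0.003, alpha = 0.01,
                               circular = TRUE, progress = FALSE) {
  v <- as_sequence(vector_seq, "vector")
  if (is.null(genome)) genome <- random_genome(genome_length, seed = base_seed)
  cells <- tibble(insert_length = insert_length, k = k, coverage = coverages)
  res <- run_campaign(cells, genome, v, iterations, base_seed, read_length,
                      fragment_mean, fragment_sd, error_rate, alpha, circular,
                      progress)
  structure(c(res, list(kind = "coverage_sweep", base_seed = base_seed)),
            class = "kmer_experiment")
}

#' @export
print.kmer_experiment <- function(x, ...) {
  cat("<kmer_experiment>", x$kind, "| seed", x$base_seed, "\n")
  print(x$summary, n = Inf)
  invisible(x)
}

#' @rdname run_power_experiment
#' @param x A `kmer_experiment`.
#' @param ... Unused.
#' @export
tidy.kmer_experiment <- function(x, ...) x$summary

#' Plot detection accuracy against coverage
#'
#' @param object A `kmer_experiment` from [run_coverage_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kmer_experiment <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$coverage, y = .data$accuracy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "mean sequencing depth (x)",
                  y = "detection accuracy (%)") +
    ggplot2::theme_minimal()
}

#' Expected number of null (false) hits over a vector
#'
#' With a per-position significance level alpha and no multiplicity
#' correction, random data are expected to produce about
#' `vector_length * alpha` significant positions — e.g. about 66 for a
#' 6,646-bp vector at the 1% level.
#'
#' @param vector_length Number of tested vector positions.
#' @param alpha Significance level in (0, 1), or 0 for none.
#' @return Expected false-hit count.
#' @export
expected_null_hits <- function(vector_length, alpha = 0.01) {
  if (alpha < 0 || alpha >= 1) stop("alpha must lie in [0, 1)", call. = FALSE)
  vector_length * alpha
}

#' Probability that a base is never sequenced under Poisson sampling
#'
#' The Poisson zero-class exp(-coverage): with coverage over 100 this is
#' below 1e-43, so under ideal random sampling a genome of ordinary size is
#' fully covered. Real libraries are biased, so this is a lower bound on
#' practice.
#'
#' @param coverage Mean depth (>= 0).
#' @return The non-coverage probability.
#' @export
poisson_uncovered_probability <- function(coverage) {
  if (any(coverage < 0)) stop("coverage must be >= 0", call. = FALSE)
  exp(-coverage)
}
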