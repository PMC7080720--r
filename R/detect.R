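#' Per-position detection profile of a vector against test and contrast reads
#'
#' The core screening operation: both read sets are decomposed into k-mers on
#' both strands and counted against the same vector index, and each vector
#' position's matching count is compared between the two samples with a
#' one-sided G-test of independence (matching vs all other k-mers x test vs
#' contrast). The marginals `n1`, `n2` are each sample's global total k-mer
#' count, identical for every position.
#'
#' @param test_reads,contrast_reads Read-pair tibbles (columns `r1`, `r2`) or
#'   character vectors of reads; the contrast is a wild-type sample carrying
#'   no vector-derived DNA.
#' @param vector_seq Vector sequence (string or [read_fasta()] row).
#' @param k Word length.
#' @param circular Vector topology; default taken from the tibble, else
#'   circular.
#' @param alpha Per-position significance level (no multiplicity correction
#'   is applied; the expected number of null hits is `n_positions * alpha`).
#' @param correction G-statistic correction, see [g_statistic()].
#' @return An object of class `detection_profile`; see [tidy.detection_profile()].
#' @export
detect_profile <- function(test_reads, contrast_reads, vector_seq, k,
                           circular = NULL, alpha = 0.01,
                           correction = c("none", "williams")) {
  correction <- match.arg(correction)
  idx <- kmer_index(vector_seq, k, circular)
  ct <- count_kmer_positions(test_reads, idx)
  cc <- count_kmer_positions(contrast_reads, idx)
  n1 <- attr(ct, "total_kmers")
  n2 <- attr(cc, "total_kmers")
  if (n1 == 0 || n2 == 0) {
    stop("empty sample: no k-mers could be extracted (reads shorter than k?)",
         call. = FALSE)
  }
  tab <- test_positions(ct$position, ct$count, cc$count, n1, n2,
                        alpha = alpha, correction = correction)
  tab <- dplyr::mutate(tab, pattern = idx$pattern_at, .after = "position")
  structure(
    list(table = tab, k = idx$k, vector_length = idx$vector_length,
         circular = idx$circular, alpha = alpha,
         g_threshold = g_critical(alpha), correction = correction,
         total_test = n1, total_contrast = n2),
    class = "detection_profile"
  )
}

#' @export
print.detection_profile <- function(x, ...) {
  ns <- sum(x$table$significant)
  cat("<detection_profile> k =", x$k, "|", x$vector_length, "bp",
      if (x$circular) "circular" else "linear", "vector\n")
  cat("  total k-mers: test", format(x$total_test, big.mark = ","),
      "| contrast", format(x$total_contrast, big.mark = ","), "\n")
  cat("  significant positions at alpha =", x$alpha,
      paste0("(G >= ", round(x$g_threshold, 3),
             if (x$correction == "williams") ", Williams-corrected" else "",
             "):"), ns, "\n")
  invisible(x)
}

#' @rdname detect_profile
#' @param x A `detection_profile`.
#' @param ... Unused.
#' @export
tidy.detection_profile <- function(x, ...) x$table

#' @rdname detect_profile
#' @export
glance.detection_profile <- function(x, ...) {
  tibble(
    k = x$k, vector_length = x$vector_length, circular = x$circular,
    alpha = x$alpha, g_threshold = x$g_threshold, correction = x$correction,
    total_test = x$total_test, total_contrast = x$total_contrast,
    n_positions = nrow(x$table), n_significant = sum(x$table$significant)
  )
}

#' Vector positions at which a true insert can produce matches
#'
#' Only k-mer windows lying fully inside the inserted segment's source
#' interval physically exist in the edited genome; windows spanning an
#' insert/genome junction cannot match the vector. Intervals wrapping a
#' circular vector's origin are given on the extended coordinate
#' (`vector_end` may exceed the vector length) and positions are normalized
#' back to 1..L.
#'
#' @param vector_start,vector_end 1-based inclusive source interval of the
#'   insert on the vector.
#' @param k Word length; must not exceed the insert length (a k longer than
#'   the insert can never produce a fully-internal window, so the
#'   combination is undefined).
#' @param vector_length Vector length, required to normalize wrapped
#'   intervals; may be omitted for non-wrapped intervals.
#' @return Sorted integer vector of eligible positions.
#' @export
eligible_region <- function(vector_start, vector_end, k, vector_length = NULL) {
  L <- vector_end - vector_start + 1
  if (L < 1) stop("invalid insert interval", call. = FALSE)
  if (k > L) {
    stop("k (", k, ") exceeds insert length (", L,
         ") - combination undefined in the method", call. = FALSE)
  }
  p <- vector_start:(vector_end - k + 1)
  if (!is.null(vector_length)) p <- ((p - 1L) %% as.integer(vector_length)) + 1L
  sort(unique(p))
}

#' Detection judgement against a known insert
#'
#' An insert is "detected" when at least one significant position falls in
#' its eligible region; significant positions outside that region are false
#' positives.
#'
#' @param profile A [detect_profile()] result, or a tibble with columns
#'   `position` and `significant`.
#' @param vector_start,vector_end The insert's source interval (see
#'   [eligible_region()]).
#' @param k Word length; defaults to the profile's k.
#' @return A one-row tibble: `detected`, `false_positives`, `n_significant`,
#'   `n_eligible`.
#' @export
judge_detection <- function(profile, vector_start, vector_end, k = NULL) {
  if (inherits(profile, "detection_profile")) {
    k <- k %||% profile$k
    L <- profile$vector_length
    tab <- profile$table
  } else {
    if (is.null(k)) stop("k must be supplied with a bare table", call. = FALSE)
    L <- max(profile$position)
    tab <- profile
  }
  elig <- eligible_region(vector_start, vector_end, k, L)
  sig <- tab$position[tab$significant]
  tibble(
    detected = any(sig %in% elig),
    false_positives = sum(!sig %in% elig),
    n_significant = length(sig),
    n_eligible = length(elig)
  )
}

#' Write a detection profile as TSV
#'
#' One row per vector position with counts, totals, G and the significance
#' flag (0/1) — the report format consumed by downstream/regulatory review.
#'
#' @param profile A `detection_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  stopifnot(inherits(profile, "detection_profile"))
  out <- profile$table |>
    dplyr::transmute(
      position = .data$position,
      vector_kmer = .data$pattern,
      count_test = .data$count_test,
      count_contrast = .data$count_contrast,
      total_test = .data$total_test,
      total_contrast = .data$total_contrast,
      G = .data$G,
      direction = .data$direction,
      significant = as.integer(.data$significant)
    )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Plot a detection profile
#'
#' Per-position matching k-mer counts in the test sample and the G statistic,
#' with the significance threshold drawn as a horizontal line and significant
#' positions highlighted — the standard count/G profile view.
#'
#' @param object A `detection_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.detection_profile <- function(object, ...) {
  tab <- object$table |>
    tidyr::pivot_longer(c("count_test", "G"), names_to = "panel",
                        values_to = "value") |>
    dplyr::mutate(panel = factor(.data$panel, c("count_test", "G"),
                                 c("count", "G-statistic")))
  thr <- tibble(panel = factor("G-statistic", c("count", "G-statistic")),
                yintercept = object$g_threshold)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$position, y = .data$value)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$significant), width = 1,
                      show.legend = FALSE) +
    ggplot2::geom_hline(data = thr,
                        ggplot2::aes(yintercept = .data$yintercept),
                        colour = "red", linewidth = 0.3) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey30", `TRUE` = "red")) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$panel), scales = "free_y") +
    ggplot2::labs(x = "vector position (nt)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang %||%
NULL
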