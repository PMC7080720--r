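#' Generate a random genome sequence
#'
#' I.i.d. uniform bases over A/C/G/T — a composition-free stand-in for a host
#' genome at desk scale. Reproducible from R's RNG; pass `seed` or call
#' `set.seed()` beforehand.
#'
#' @param length Genome length in nt.
#' @param seed Optional integer seed applied locally.
#' @return A base string of the requested length.
#' @export
random_genome <- function(length, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  if (length < 1) stop("length must be >= 1", call. = FALSE)
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
}

#' Insert a random vector segment into a genome
#'
#' A segment of the requested length is excised from a uniformly random
#' position on the (circular) vector and inserted at a uniformly random
#' genome position — the edited-genome model used throughout the simulation
#' campaigns. Source intervals wrapping the circular origin are reported on
#' the extended coordinate (`vector_end` may exceed the vector length).
#'
#' @param genome Host genome (string or [read_fasta()] row).
#' @param vector_seq Vector sequence (string or [read_fasta()] row).
#' @param insert_length Segment length L (1 <= L <= vector length).
#' @param circular Vector topology (default circular).
#' @param seed Optional integer seed applied locally.
#' @return A list with `genome` (the modified sequence) and `truth`, a
#'   one-row tibble with `vector_start`, `vector_end`, `genome_position`
#'   (1-based position of the first inserted base in the modified genome).
#' @export
insert_segment <- function(genome, vector_seq, insert_length, circular = TRUE,
                           seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  g <- as_sequence(genome, "genome")
  v <- as_sequence(vector_seq, "vector")
  L <- as.integer(insert_length)
  vlen <- nchar(v)
  if (L < 1 || L > vlen) {
    stop("insert length must lie in 1..vector length (", vlen, ")",
         call. = FALSE)
  }
  if (circular) {
    start <- sample.int(vlen, 1)
  } else {
    start <- sample.int(vlen - L + 1, 1)
  }
  end <- start + L - 1L
  ext <- if (end > vlen) paste0(v, substr(v, 1, end - vlen)) else v
  segment <- substr(ext, start, end)
  pos <- sample.int(nchar(g) + 1L, 1)  # insert before base `pos`
  modified <- paste0(substr(g, 1, pos - 1L), segment,
                     substr(g, pos, nchar(g)))
  list(
    genome = modified,
    truth = tibble(vector_start = start, vector_end = end,
                   insert_length = L, genome_position = pos)
  )
}

#' Simulate paired-end reads with substitution errors
#'
#' Fragments start uniformly on the forward strand with lengths drawn from
#' round(Normal(`fragment_mean`, `fragment_sd`)), clipped to
#' `[read_length, space remaining]`. R1 is the first `read_length` bases of
#' the fragment and R2 the reverse complement of the last `read_length`
#' (FR orientation; detection is strand-symmetric, so the convention is
#' inert). Each base is substituted with probability `error_rate` to a
#' uniformly chosen different base; template `N` bases are never altered.
#' The number of pairs is `round(coverage * genome_length / (2 * read_length))`.
#'
#' @param genome Template genome (string or [read_fasta()] row).
#' @param coverage Mean sequencing depth (total read nt / genome nt).
#' @param read_length Read length in nt (default 100).
#' @param fragment_mean,fragment_sd Fragment-length distribution (default
#'   500 +/- 50 nt).
#' @param error_rate Per-base substitution probability (default 0.003, the
#'   HiSeq-like rate).
#' @param n_pairs Override the pair count directly (ignores `coverage`).
#' @param seed Optional integer seed applied locally.
#' @return A read-pair tibble (`pair_id`, `r1`, `r2`).
#' @export
simulate_read_pairs <- function(genome, coverage = NULL, read_length = 100,
                                fragment_mean = 500, fragment_sd = 50,
                                error_rate = 0.003, n_pairs = NULL,
                                seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  g <- as_sequence(genome, "genome")
  glen <- nchar(g)
  if (glen < fragment_mean) {
    stop("genome (", glen, " nt) is shorter than the mean fragment length (",
         fragment_mean, " nt)", call. = FALSE)
  }
  if (is.null(n_pairs)) {
    if (is.null(coverage) || coverage <= 0) {
      stop("coverage must be > 0 (or supply n_pairs)", call. = FALSE)
    }
    n_pairs <- round(coverage * glen / (2 * read_length))
  }
  n_pairs <- as.integer(n_pairs)
  if (n_pairs < 1) stop("requested read count is zero", call. = FALSE)
  res <- cpp_simulate_pairs(g, n_pairs, as.integer(read_length),
                            fragment_mean, fragment_sd, error_rate)
  tibble(pair_id = sprintf("pair_%d", seq_len(n_pairs)),
         r1 = res$r1, r2 = res$r2)
}
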