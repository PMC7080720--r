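#' k-mer pattern census against the theoretical total
#'
#' Counts the distinct k-mer patterns over all windows of the supplied
#' sequences and their reverse complements (so the pattern set is closed
#' under reverse complement) and relates the count to the theoretical total
#' 4^k. A fraction near 1 means k is saturated — too short for any segment
#' of that length to be distinguishable from the host background.
#'
#' @param seqs Sequences: character vector or a tibble with a `seq` column
#'   (e.g. from [read_fasta()]).
#' @param k Word length(s); vectorized.
#' @return A tibble with one row per k: `k`, `distinct`, `theoretical`
#'   (4^k), `fraction`.
#' @export
pattern_census <- function(seqs, k) {
  if (is.data.frame(seqs)) seqs <- seqs$seq
  stopifnot(is.character(seqs), all(k >= 1))
  purrr::map_dfr(as.integer(k), function(kk) {
    d <- cpp_distinct_count(seqs, kk)
    tibble(k = kk, distinct = d, theoretical = 4^kk, fraction = d / 4^kk)
  })
}

#' Shared k-mer patterns between a genome and a vector
#'
#' Intersects the (reverse-complement-closed) k-mer pattern sets of a genome
#' and a vector, reporting each shared pattern with its occurrence positions
#' in both sequences, plus the expectation under a uniform-random null:
#' `n_genome * n_vector / 4^k`, where the two factors are the observed
#' distinct-pattern counts of each side. Complementary patterns count
#' separately (a single two-strand genomic locus hitting the vector
#' contributes two shared patterns unless palindromic).
#'
#' @param genome_seqs Genome sequences (character vector or `seq`-column
#'   tibble).
#' @param vector_seq Vector sequence (string or [read_fasta()] row).
#' @param k Word length (<= 31).
#' @param circular Vector topology (default circular).
#' @return A list of class `shared_patterns`: `k`, `observed`, `expected`,
#'   `n_genome`, `n_vector`, `genome_occ` and `vector_occ` occurrence
#'   tibbles.
#' @export
shared_patterns <- function(genome_seqs, vector_seq, k, circular = TRUE) {
  if (is.data.frame(genome_seqs)) genome_seqs <- genome_seqs$seq
  v <- as_sequence(vector_seq, "vector")
  if (k > nchar(v)) stop("k exceeds vector length", call. = FALSE)
  res <- cpp_shared_patterns(genome_seqs, v, as.integer(k), circular)
  n_g <- cpp_distinct_count(genome_seqs, as.integer(k))
  structure(
    list(
      k = as.integer(k),
      observed = res$observed,
      expected = n_g * res$n_vector_distinct / 4^k,
      n_genome = n_g,
      n_vector = res$n_vector_distinct,
      genome_occ = as_tibble(res$genome_occ),
      vector_occ = as_tibble(res$vector_occ)
    ),
    class = "shared_patterns"
  )
}

#' @export
print.shared_patterns <- function(x, ...) {
  cat("<shared_patterns> k =", x$k, "\n")
  cat("  distinct patterns: genome", format(x$n_genome, big.mark = ","),
      "| vector", format(x$n_vector, big.mark = ","), "\n")
  cat("  shared: observed", x$observed, "| expected",
      format(x$expected, digits = 4), "\n")
  invisible(x)
}

#' @rdname shared_patterns
#' @param x A `shared_patterns` object.
#' @param ... Unused.
#' @export
glance.shared_patterns <- function(x, ...) {
  tibble(k = x$k, observed = x$observed, expected = x$expected,
         n_genome = x$n_genome, n_vector = x$n_vector)
}
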