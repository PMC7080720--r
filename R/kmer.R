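#' Build the vector k-mer position index
#'
#' Records, for every k-mer pattern of the vector, the 1-based left-end
#' positions at which it occurs on the forward strand. For a circular vector
#' the first k-1 bases are appended past the end before windowing, so that
#' k-mers spanning the origin are captured and every position 1..L carries a
#' window; a linear vector yields positions 1..L-k+1. Windows containing `N`
#' are skipped.
#'
#' @param vector_seq Vector sequence: a base string or a one-row tibble from
#'   [read_fasta()] (whose `topology` column then supplies the default for
#'   `circular`).
#' @param k Word length in nucleotides (1 <= k <= vector length).
#' @param circular Is the vector a circular molecule? Default `TRUE`, the
#'   usual case for a plasmid; overridden by the tibble's topology if present.
#' @return An object of class `kmer_index`.
#' @export
kmer_index <- function(vector_seq, k, circular = NULL) {
  if (is.data.frame(vector_seq) && is.null(circular) &&
      "topology" %in% names(vector_seq)) {
    circular <- identical(vector_seq$topology[[1]], "circular")
  }
  if (is.null(circular)) circular <- TRUE
  seq <- as_sequence(vector_seq, "vector sequence")
  seq <- normalize_bases(seq, what = "vector sequence")
  L <- nchar(seq)
  k <- as.integer(k)
  if (is.na(k) || k < 1) stop("k must be a positive integer", call. = FALSE)
  if (k > L) {
    stop("k (", k, ") exceeds vector length (", L, ")", call. = FALSE)
  }
  structure(
    list(k = k, vector_length = L, circular = circular, seq = seq,
         pattern_at = cpp_position_patterns(seq, k, circular)),
    class = "kmer_index"
  )
}

#' @export
print.kmer_index <- function(x, ...) {
  cat("<kmer_index> k =", x$k, "|", x$vector_length, "bp",
      if (x$circular) "circular" else "linear", "vector |",
      length(x$pattern_at), "indexed positions\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a k-mer index into a position/pattern tibble
#'
#' @param x A `kmer_index`.
#' @param ... Unused.
#' @return A tibble with columns `position`, `pattern` (`NA` for N-containing
#'   windows).
#' @export
tidy.kmer_index <- function(x, ...) {
  tibble(position = seq_along(x$pattern_at), pattern = x$pattern_at)
}

#' Extract the k-mers of a read (both strands)
#'
#' Yields every window of the read and every window of its reverse
#' complement, dropping windows that contain `N`. No canonicalization is
#' applied, so a palindromic k-mer legitimately appears from both strands.
#'
#' @param read A base string.
#' @param k Word length.
#' @return Character vector of k-mers (possibly with duplicates); empty when
#'   the read is shorter than k.
#' @export
read_kmers <- function(read, k) {
  read <- normalize_bases(as_sequence(read, "read"), what = "read")
  n <- nchar(read)
  if (n < k) return(character(0))
  windows <- function(s) {
    w <- substring(s, 1:(n - k + 1), k:n)
    w[!grepl("N", w, fixed = TRUE)]
  }
  c(windows(read), windows(reverse_complement(read)))
}

# Flatten read input (tibble of pairs, or character vector) to a character
# vector of individual reads.
as_read_vector <- function(reads, what = "reads") {
  if (is.data.frame(reads)) {
    if (!all(c("r1", "r2") %in% names(reads))) {
      stop(what, ": expected columns r1 and r2", call. = FALSE)
    }
    reads <- c(reads$r1, reads$r2)
  }
  if (!is.character(reads)) stop(what, " must be character", call. = FALSE)
  if (length(reads) == 0) stop("empty sample: no reads in ", what, call. = FALSE)
  reads
}

#' Count matching k-mers per vector position for a read set
#'
#' Every N-free k-mer from both strands of every read is looked up in the
#' vector index; a hit increments the count of every vector position carrying
#' that pattern. `total_kmers` accumulates all extracted k-mers, matched or
#' not — the "all other k-mers" marginal of the downstream 2x2 test.
#'
#' @param reads A read-pair tibble (columns `r1`, `r2`) or a character vector
#'   of reads.
#' @param index A [kmer_index()].
#' @return A tibble with columns `position`, `count`, carrying attributes
#'   `total_kmers` and `k`.
#' @export
count_kmer_positions <- function(reads, index) {
  stopifnot(inherits(index, "kmer_index"))
  reads <- as_read_vector(reads)
  res <- cpp_count_positions(reads, index$seq, index$k, index$circular)
  out <- tibble(position = seq_along(res$counts), count = res$counts)
  attr(out, "total_kmers") <- res$total
  attr(out, "k") <- index$k
  out
}
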