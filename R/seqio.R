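#' @useDynLib kmerscreen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
#' @import dplyr
#' @importFrom tibble tibble as_tibble
NULL

IUPAC_AMBIG <- "RYSWKMBDHVryswkmbdhv"

# Normalize a base string: upcase, and either reject ambiguity codes other
# than N (strict) or collapse them to N (lenient). Anything outside the IUPAC
# alphabet is always an error.
normalize_bases <- function(x, strict = TRUE, what = "sequence") {
  x <- toupper(x)
  bad <- unique(unlist(strsplit(gsub("[ACGTNRYSWKMBDHV]", "", x), "")))
  if (length(bad) > 0) {
    stop(what, " contains non-IUPAC characters: ",
         paste(sQuote(bad), collapse = ", "), call. = FALSE)
  }
  has_ambig <- grepl("[RYSWKMBDHV]", x)
  if (any(has_ambig)) {
    if (strict) {
      amb <- unique(unlist(strsplit(gsub("[ACGTN]", "", x[has_ambig]), "")))
      stop(what, " contains ambiguity codes other than N (strict mode): ",
           paste(sQuote(amb), collapse = ", "),
           "; use strict = FALSE to map them to N", call. = FALSE)
    }
    x <- gsub("[RYSWKMBDHV]", "N", x)
  }
  x
}

# Accept either a bare base string or a sequence tibble (as returned by
# read_fasta); returns a single character string.
as_sequence <- function(x, what = "sequence") {
  if (is.data.frame(x)) {
    if (!"seq" %in% names(x) || nrow(x) < 1) {
      stop(what, ": expected a data frame with a 'seq' column", call. = FALSE)
    }
    if (nrow(x) > 1) {
      stop(what, ": expected a single sequence, got ", nrow(x), call. = FALSE)
    }
    x <- x$seq[[1]]
  }
  if (!is.character(x) || length(x) != 1 || is.na(x) || nchar(x) < 1) {
    stop(what, ": expected a non-empty base string", call. = FALSE)
  }
  x
}

#' Read a FASTA file into a sequence tibble
#'
#' Each record becomes one row with its identifier, upper-cased base string
#' and a topology flag. Topology is never inferred from the file: a circular
#' molecule (e.g. a plasmid vector) must be declared by the caller.
#'
#' @param path Path to a FASTA file (optionally gzip-compressed).
#' @param topology `"linear"` (default) or `"circular"`, applied to every
#'   record in the file.
#' @param strict If `TRUE` (default), IUPAC ambiguity codes other than `N`
#'   are an error; if `FALSE` they are mapped to `N`. k-mer identity must be
#'   unambiguous, so there is no third option.
#' @return A tibble with columns `id`, `seq`, `topology`.
#' @export
read_fasta <- function(path, topology = c("linear", "circular"), strict = TRUE) {
  topology <- match.arg(topology)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ss <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(ss) == 0) stop("no records in FASTA file ", path, call. = FALSE)
  if (any(Biostrings::width(ss) == 0)) {
    stop("empty record in FASTA file ", path, " (record ",
         which(Biostrings::width(ss) == 0)[1], ")", call. = FALSE)
  }
  tibble(
    id = sub("\\s.*$", "", names(ss)),
    seq = unname(normalize_bases(as.character(ss), strict = strict,
                                 what = paste0("FASTA record in ", path))),
    topology = topology
  )
}

#' Write a sequence tibble to FASTA
#'
#' @param seqs Tibble with columns `id` and `seq` (as from [read_fasta()]),
#'   or a named character vector.
#' @param path Output path.
#' @param width Line-wrap width of the canonical form.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  if (is.character(seqs)) {
    seqs <- tibble(id = names(seqs) %||% paste0("seq", seq_along(seqs)),
                   seq = unname(seqs))
  }
  ss <- Biostrings::BStringSet(seqs$seq)
  names(ss) <- seqs$id
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read paired FASTQ files into a read-pair tibble
#'
#' Mates are paired by file order, not by name parsing. Quality strings are
#' parsed and discarded: the detection method uses sequence only and assumes
#' reads were already quality-trimmed upstream.
#'
#' @param path_r1,path_r2 FASTQ files for the two mates (optionally gzipped).
#' @param strict See [read_fasta()].
#' @return A tibble with columns `pair_id`, `r1`, `r2`.
#' @export
read_fastq_pairs <- function(path_r1, path_r2, strict = TRUE) {
  for (p in c(path_r1, path_r2)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  rd <- function(p) tryCatch(
    Biostrings::readBStringSet(p, format = "fastq"),
    error = function(e) stop("malformed FASTQ in ", p, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  s1 <- rd(path_r1)
  s2 <- rd(path_r2)
  if (length(s1) != length(s2)) {
    stop("read-pair files have mismatched record counts: ",
         length(s1), " vs ", length(s2), call. = FALSE)
  }
  tibble(
    pair_id = sub("\\s.*$", "", names(s1)),
    r1 = unname(normalize_bases(as.character(s1), strict = strict,
                                what = "FASTQ read")),
    r2 = unname(normalize_bases(as.character(s2), strict = strict,
                                what = "FASTQ read"))
  )
}

#' Write a read-pair tibble to a pair of FASTQ files
#'
#' Constant placeholder qualities are written ('I'); the method is
#' quality-agnostic.
#'
#' @param pairs Tibble with columns `pair_id`, `r1`, `r2`.
#' @param path_r1,path_r2 Output paths.
#' @return The two paths, invisibly.
#' @export
write_fastq_pairs <- function(pairs, path_r1, path_r2) {
  wr <- function(seqs, ids, path) {
    con <- file(path, "w")
    on.exit(close(con))
    q <- vapply(nchar(seqs), function(n) strrep("I", n), character(1))
    writeLines(paste0("@", ids, "\n", seqs, "\n+\n", q), con)
  }
  wr(pairs$r1, pairs$pair_id, path_r1)
  wr(pairs$r2, pairs$pair_id, path_r2)
  invisible(c(path_r1, path_r2))
}

#' Reverse complement of base strings
#'
#' Vectorized; `N` maps to `N`.
#'
#' @param x Character vector of base strings over `{A,C,G,T,N}`.
#' @return Character vector of the same length.
#' @export
reverse_complement <- function(x) {
  x <- normalize_bases(x, strict = TRUE, what = "reverse_complement input")
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
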