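# Independent oracles used across the suite. These deliberately avoid the
# package's own counting/statistics code paths.

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Reverse complement by table lookup, independent of Biostrings.
oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# Brute-force per-position counting: extract every N-free window from every
# read strand, then string-compare against every vector position's window.
oracle_count <- function(reads, vec, k, circular) {
  ext <- if (circular && k > 1) paste0(vec, substr(vec, 1, k - 1)) else vec
  npos <- if (circular) nchar(vec) else nchar(vec) - k + 1
  pat <- substring(ext, 1:npos, k:(npos + k - 1))
  win <- unlist(lapply(reads, function(r) {
    both <- c(r, oracle_revcomp(r))
    unlist(lapply(both, function(s) {
      n <- nchar(s)
      if (n < k) return(character(0))
      w <- substring(s, 1:(n - k + 1), k:n)
      w[!grepl("N", w, fixed = TRUE)]
    }))
  }))
  counts <- vapply(pat, function(p) {
    if (grepl("N", p, fixed = TRUE)) 0L else sum(win == p)
  }, integer(1))
  list(counts = unname(counts), total = length(win))
}

# Likelihood-ratio oracle: 2 x (two free binomials vs pooled binomial).
oracle_g <- function(a, b, n1, n2) {
  ll <- function(x, n, p) {
    if (p == 0 || p == 1) {
      if ((p == 0 && x > 0) || (p == 1 && x < n)) return(-Inf)
      return(0)
    }
    x * log(p) + (n - x) * log(1 - p)
  }
  p1 <- a / n1
  p2 <- b / n2
  pp <- (a + b) / (n1 + n2)
  2 * (ll(a, n1, p1) + ll(b, n2, p2) - ll(a, n1, pp) - ll(b, n2, pp))
}

make_pairs <- function(reads1, reads2 = NULL) {
  if (is.null(reads2)) reads2 <- vapply(reads1, oracle_revcomp, character(1))
  tibble::tibble(pair_id = paste0("p", seq_along(reads1)),
                 r1 = reads1, r2 = unname(reads2))
}
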