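test_that("vector index enumerates circular and linear windows by hand", {
  circ <- kmer_index("ACGT", 3, circular = TRUE)
  expect_equal(tidy(circ),
               tibble::tibble(position = 1:4,
                              pattern = c("ACG", "CGT", "GTA", "TAC")))

  lin <- kmer_index("ACGT", 3, circular = FALSE)
  expect_equal(tidy(lin)$pattern, c("ACG", "CGT"))

  expect_error(kmer_index("ACGT", 5, circular = FALSE), "exceeds vector length")
})

test_that("a circular plasmid-sized vector indexes one position per base", {
  set.seed(21)
  v <- random_seq(6646)
  idx <- kmer_index(v, 20, circular = TRUE)
  tab <- tidy(idx)
  expect_equal(nrow(tab), 6646)
  expect_false(anyNA(tab$pattern))
  # N windows are dropped from the index but positions stay addressable
  vn <- paste0("NN", substr(v, 3, 200))
  idxn <- kmer_index(vn, 5, circular = FALSE)
  expect_true(all(is.na(tidy(idxn)$pattern[1:2])))
})

test_that("read k-mer extraction covers both strands and skips N windows", {
  expect_equal(sort(read_kmers("ACGTT", 4)),
               sort(c("ACGT", "CGTT", "AACG", "ACGT")))
  expect_equal(sum(read_kmers("ACGTT", 4) == "ACGT"), 2)  # palindrome, twice
  expect_equal(read_kmers("ACNGT", 3), character(0))
  expect_equal(read_kmers("ACG", 10), character(0))
})

test_that("counting matches the brute-force string-scan oracle", {
  set.seed(31)
  for (case in 1:100) {
    k <- sample(3:12, 1)
    circular <- sample(c(TRUE, FALSE), 1)
    vlen <- sample(k:150, 1)
    alpha <- if (case %% 4 == 0) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
    vec <- random_seq(vlen, alphabet = c("A", "C", "G", "T"))
    reads <- replicate(sample(3:12, 1), random_seq(sample(2:50, 1), alpha))
    # seed some reads with true vector substrings so matches actually occur
    if (vlen >= k + 5) {
      s <- sample(vlen - k - 4, 1)
      reads <- c(reads, substr(vec, s, s + k + 4))
    }
    idx <- kmer_index(vec, k, circular = circular)
    got <- count_kmer_positions(reads, idx)
    want <- oracle_count(reads, vec, k, circular)
    expect_equal(got$count, want$counts)
    expect_equal(attr(got, "total_kmers"), want$total)
  }
})

test_that("rotating a circular vector cyclically shifts the count profile", {
  set.seed(41)
  for (case in 1:8) {
    vec <- random_seq(200)
    k <- sample(4:15, 1)
    reads <- c(replicate(10, random_seq(60)),
               substr(vec, 50, 120),  # guaranteed signal
               substr(paste0(vec, vec), 190, 230))  # spans the origin
    r <- sample(199, 1)
    rot <- paste0(substr(vec, r + 1, 200), substr(vec, 1, r))
    c0 <- count_kmer_positions(reads, kmer_index(vec, k, circular = TRUE))
    c1 <- count_kmer_positions(reads, kmer_index(rot, k, circular = TRUE))
    # position p on the rotated vector is position p + r (mod 200) on the original
    shifted <- c0$count[((seq_len(200) + r - 1L) %% 200L) + 1L]
    expect_equal(c1$count, shifted)
    expect_equal(attr(c1, "total_kmers"), attr(c0, "total_kmers"))
  }
})

test_that("counts and totals are invariant under reverse-complementing the reads", {
  set.seed(51)
  vec <- random_seq(300)
  reads <- c(replicate(15, random_seq(80)), substr(vec, 101, 180))
  idx <- kmer_index(vec, 9, circular = TRUE)
  fwd <- count_kmer_positions(reads, idx)
  rc <- count_kmer_positions(vapply(reads, oracle_revcomp, character(1)), idx)
  expect_equal(rc$count, fwd$count)
  expect_equal(attr(rc, "total_kmers"), attr(fwd, "total_kmers"))
})

test_that("reads tiling a repeat-free linear vector cover every indexed position", {
  set.seed(61)
  vec <- random_seq(300)
  k <- 12
  expect_equal(length(unique(tidy(kmer_index(vec, k, FALSE))$pattern)),
               300 - k + 1)  # repeat-free premise
  starts <- seq(1, 241, by = 30)
  reads <- substring(vec, starts, starts + 59)
  counts <- count_kmer_positions(reads, kmer_index(vec, k, circular = FALSE))
  expect_true(all(counts$count >= 1))
})

test_that("reads disjoint from the vector yield zero counts but nonzero totals", {
  reads <- c(strrep("A", 50), strrep("AC", 25))
  counts <- count_kmer_positions(reads, kmer_index(strrep("G", 60), 10, FALSE))
  expect_true(all(counts$count == 0))
  expect_gt(attr(counts, "total_kmers"), 0)
})
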