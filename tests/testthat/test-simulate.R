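test_that("random genomes have the right length, composition and determinism", {
  g <- random_genome(1000, seed = 5)
  expect_equal(nchar(g), 1000)
  expect_equal(random_genome(1000, seed = 5), g)
  counts <- table(strsplit(g, "")[[1]])
  expect_true(all(names(counts) %in% c("A", "C", "G", "T")))
  # each base count within 5 sd of 250 (binomial sd ~ 13.7)
  expect_true(all(abs(counts - 250) < 5 * sqrt(1000 * 0.25 * 0.75)))
})

test_that("segment insertion preserves content and records the truth", {
  set.seed(15)
  g <- random_genome(5000)
  v <- random_genome(400)
  ins <- insert_segment(g, v, 20)
  expect_equal(nchar(ins$genome), 5020)
  tr <- ins$truth
  expect_equal(tr$vector_end - tr$vector_start + 1, 20)
  ext <- paste0(v, substr(v, 1, 30))
  expect_equal(substr(ins$genome, tr$genome_position, tr$genome_position + 19),
               substr(ext, tr$vector_start, tr$vector_end))
  # removing the insert restores the original genome
  restored <- paste0(substr(ins$genome, 1, tr$genome_position - 1),
                     substr(ins$genome, tr$genome_position + 20, 5020))
  expect_equal(restored, g)
  # reproducible from a seed, including wrapped source intervals
  a <- insert_segment(g, v, 50, seed = 99)
  b <- insert_segment(g, v, 50, seed = 99)
  expect_equal(a, b)
  wrapped <- NULL
  for (s in 1:200) {
    cand <- insert_segment(g, v, 50, seed = s)
    if (cand$truth$vector_end > 400) { wrapped <- cand; break }
  }
  expect_false(is.null(wrapped))
  expect_equal(substr(wrapped$genome, wrapped$truth$genome_position,
                      wrapped$truth$genome_position + 49),
               substr(ext, wrapped$truth$vector_start,
                      wrapped$truth$vector_end))
})

test_that("pair counts follow the coverage arithmetic and realized depth is exact", {
  set.seed(25)
  g <- random_genome(100000)
  pairs <- simulate_read_pairs(g, coverage = 10)
  expect_equal(nrow(pairs), 5000)
  expect_true(all(nchar(pairs$r1) == 100))
  expect_true(all(nchar(pairs$r2) == 100))
  realized <- sum(nchar(pairs$r1) + nchar(pairs$r2)) / 100000
  expect_lt(abs(realized - 10) / 10, 0.01)
})

test_that("error-free reads are exact substrings of the genome or its complement", {
  set.seed(35)
  g <- random_genome(2000)
  pairs <- simulate_read_pairs(g, coverage = 5, error_rate = 0)
  grc <- oracle_revcomp(g)
  for (r in c(pairs$r1, pairs$r2)) {
    expect_true(grepl(r, g, fixed = TRUE) || grepl(r, grc, fixed = TRUE))
  }
})

test_that("the substitution rate lands in the calibrated band", {
  set.seed(45)
  # homopolymer template: every substituted base is directly observable
  g <- strrep("A", 2000)
  pairs <- simulate_read_pairs(g, n_pairs = 10000, error_rate = 0.003)
  mis <- sum(vapply(pairs$r1, function(r) sum(strsplit(r, "")[[1]] != "A"),
                    numeric(1))) +
         sum(vapply(pairs$r2, function(r) sum(strsplit(r, "")[[1]] != "T"),
                    numeric(1)))
  rate <- mis / (2e6)
  expect_gte(rate, 0.0028)
  expect_lte(rate, 0.0032)
})

test_that("read starts are uniform across the genome", {
  set.seed(55)
  g <- random_genome(100000)
  pairs <- simulate_read_pairs(g, n_pairs = 50000, error_rate = 0)
  kmers <- substring(g, 1:(100000 - 19), 20:100000)
  starts <- match(substr(pairs$r1, 1, 20), kmers)
  expect_false(anyNA(starts))
  bins <- cut(starts, breaks = seq(1, 100000 - 99, length.out = 101),
              include.lowest = TRUE)
  p <- suppressWarnings(stats::chisq.test(table(bins))$p.value)
  expect_gt(p, 0.001)
})

test_that("the fused simulate-and-count path equals the staged pipeline", {
  g <- random_genome(5000, seed = 65)
  v <- random_genome(500, seed = 66)
  idx <- kmer_index(v, 11, circular = TRUE)
  set.seed(77)
  pairs <- simulate_read_pairs(g, coverage = 5)
  staged <- count_kmer_positions(pairs, idx)
  set.seed(77)
  fused <- kmerscreen:::cpp_simulate_count(g, v, 11L, TRUE, 125L, 100L,
                                           500, 50, 0.003)
  expect_equal(fused$counts, staged$count)
  expect_equal(fused$total, attr(staged, "total_kmers"))
})

test_that("degenerate simulator inputs are rejected", {
  expect_error(simulate_read_pairs(random_genome(100, seed = 1), coverage = 5),
               "shorter than the mean fragment")
  expect_error(simulate_read_pairs(random_genome(1000, seed = 1)),
               "coverage")
})
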