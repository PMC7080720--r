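test_that("identical test and contrast read sets yield no significant positions", {
  set.seed(101)
  vec <- random_seq(600)
  reads <- make_pairs(replicate(30, random_seq(100)))
  prof <- detect_profile(reads, reads, vec, k = 15)
  expect_equal(nrow(prof$table), 600)
  expect_true(all(prof$table$G == 0))
  expect_equal(sum(prof$table$significant), 0)
})

test_that("vector-derived reads against an unrelated contrast light up every position", {
  set.seed(111)
  vec <- random_seq(1000)
  # flank the vector so fragment sampling covers its ends evenly
  template <- paste0(random_seq(300), vec, random_seq(300))
  test <- simulate_read_pairs(template, coverage = 50, error_rate = 0)
  contrast <- simulate_read_pairs(random_seq(10000), coverage = 10,
                                  error_rate = 0)
  prof <- detect_profile(test, contrast, vec, k = 20, circular = FALSE)
  expect_equal(nrow(prof$table), 1000 - 20 + 1)
  expect_true(all(prof$table$significant))
  expect_true(all(prof$table$direction == "test_excess"))
})

test_that("eligible region keeps fully-internal windows only, with circular wrap", {
  expect_equal(eligible_region(100, 119, 20), 100)            # L = k: one window
  expect_equal(eligible_region(5577, 5676, 50), 5577:5627)
  expect_error(eligible_region(100, 119, 25), "undefined")
  # interval wrapping a 6,646-bp circular origin, given on extended coordinates
  expect_equal(eligible_region(6640, 6659, 20, vector_length = 6646), 6640)
  expect_equal(eligible_region(6640, 6659, 10, vector_length = 6646),
               sort(c(6640:6646, 1:4)))
})

test_that("detection judgement is set membership against the eligible region", {
  tab <- tibble::tibble(position = 1:6646, significant = FALSE)
  tab$significant[c(12, 5600)] <- TRUE
  v <- judge_detection(tab, 5577, 5676, k = 50)
  expect_true(v$detected)
  expect_equal(v$false_positives, 1)

  tab$significant[] <- FALSE
  v0 <- judge_detection(tab, 5577, 5676, k = 50)
  expect_false(v0$detected)
  expect_equal(v0$false_positives, 0)
})

test_that("a simulated insert is recovered exactly when junction bases mismatch", {
  set.seed(121)
  vec <- random_seq(6646)
  genome <- random_seq(20000)
  src <- c(5577, 5676)
  segment <- substr(vec, src[1], src[2])
  before <- substr(vec, src[1] - 1, src[1] - 1)
  after <- substr(vec, src[2] + 1, src[2] + 1)
  pos <- 10000
  while (substr(genome, pos - 1, pos - 1) == before ||
         substr(genome, pos, pos) == after) pos <- pos + 1
  edited <- paste0(substr(genome, 1, pos - 1), segment,
                   substr(genome, pos, 20000))
  test <- simulate_read_pairs(edited, coverage = 50)
  contrast <- simulate_read_pairs(genome, coverage = 50)
  prof <- detect_profile(test, contrast, vec, k = 50)
  expect_equal(prof$table$position[prof$table$significant],
               eligible_region(src[1], src[2], 50))
  verdict <- judge_detection(prof, src[1], src[2])
  expect_true(verdict$detected)
  expect_equal(verdict$false_positives, 0)
})

test_that("without an insert, independent read sets from one genome give no hits at k = 20", {
  set.seed(131)
  vec <- random_seq(6646)
  genome <- random_seq(50000)
  expect_equal(shared_patterns(genome, vec, 20)$observed, 0)  # premise
  test <- simulate_read_pairs(genome, coverage = 10)
  contrast <- simulate_read_pairs(genome, coverage = 10)
  prof <- detect_profile(test, contrast, vec, k = 20)
  expect_equal(sum(prof$table$significant), 0)
})

test_that("null significant fraction at a saturating k stays below alpha", {
  set.seed(141)
  vec <- random_seq(6646)
  genome <- random_seq(100000)
  frac <- replicate(3, {
    test <- simulate_read_pairs(genome, coverage = 10)
    contrast <- simulate_read_pairs(genome, coverage = 10)
    prof <- detect_profile(test, contrast, vec, k = 10)
    mean(prof$table$significant)
  })
  expect_lte(mean(frac), 0.01)
})

test_that("profiles serialize to the TSV report and plot", {
  set.seed(151)
  vec <- random_seq(400)
  reads <- make_pairs(replicate(10, random_seq(100)))
  prof <- detect_profile(reads, reads, vec, k = 12)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_profile_tsv(prof, f)
  tab <- readr::read_tsv(f, show_col_types = FALSE)
  expect_equal(names(tab),
               c("position", "vector_kmer", "count_test", "count_contrast",
                 "total_test", "total_contrast", "G", "direction",
                 "significant"))
  expect_equal(nrow(tab), 400)
  expect_true(all(tab$significant %in% 0:1))
  expect_s3_class(ggplot2::autoplot(prof), "ggplot")
  g <- glance(prof)
  expect_equal(g$n_positions, 400)
  expect_equal(g$n_significant, 0)
})

test_that("empty read sets are rejected", {
  expect_error(detect_profile(character(0), "ACGTACGTAC", "ACGTACGT", k = 4),
               "empty sample")
})
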