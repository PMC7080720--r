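#' G-test of independence on a 2x2 matching-vs-other k-mer table
#'
#' Computes the likelihood-ratio statistic G = 2 * sum O * ln(O/E) over the
#' four cells of the table `[[a, n1-a], [b, n2-b]]`, with expectations from
#' the marginals (a test of independence with both margins free — the Model
#' II sampling design of Sokal & Rohlf). Zero cells contribute 0 (the
#' 0*ln(0) = 0 limit). The default is the raw statistic; Williams' correction
#' (G divided by q = 1 + (n/r1 + n/r2 - 1)(n/c1 + n/c2 - 1) / (6n)) is
#' available for sensitivity analysis.
#'
#' All arguments are vectorized and recycled.
#'
#' @param a,b Matching k-mer counts in the test and contrast samples.
#' @param n1,n2 Total extracted k-mer counts of the two samples (must be > 0).
#' @param correction `"none"` (default) or `"williams"`.
#' @return Numeric vector of G values (df = 1).
#' @export
g_statistic <- function(a, b, n1, n2, correction = c("none", "williams")) {
  correction <- match.arg(correction)
  m <- vctrs_recycle(as.numeric(a), as.numeric(b), as.numeric(n1),
                     as.numeric(n2))
  a <- m[[1]]; b <- m[[2]]; n1 <- m[[3]]; n2 <- m[[4]]
  if (any(n1 <= 0) || any(n2 <= 0)) stop("empty sample: n1 and n2 must be > 0",
                                         call. = FALSE)
  if (any(a < 0) || any(b < 0) || any(a > n1) || any(b > n2)) {
    stop("counts must satisfy 0 <= a <= n1 and 0 <= b <= n2", call. = FALSE)
  }
  N <- n1 + n2
  c1 <- a + b
  c2 <- N - c1
  O <- cbind(a, n1 - a, b, n2 - b)
  E <- cbind(n1 * c1 / N, n1 * c2 / N, n2 * c1 / N, n2 * c2 / N)
  term <- O * log(O / E)
  term[O == 0] <- 0
  G <- 2 * rowSums(term)
  G[G < 0] <- 0  # guard against roundoff on near-homogeneous tables
  if (correction == "williams") {
    q <- 1 + ((N / n1 + N / n2 - 1) * (N / c1 + N / c2 - 1)) / (6 * N)
    q[c1 == 0 | c2 == 0] <- 1  # degenerate margin: G is 0 there anyway
    G <- G / q
  }
  unname(G)
}

vctrs_recycle <- function(...) {
  xs <- list(...)
  n <- max(vapply(xs, length, integer(1)))
  lapply(xs, rep_len, length.out = n)
}

#' Critical G value at a given significance level
#'
#' The 1-alpha quantile of the chi-square distribution with 1 degree of
#' freedom; at the 1% level this is 6.6349 (conventionally printed 6.634).
#'
#' @param alpha Significance level in (0, 1).
#' @return The critical value.
#' @export
g_critical <- function(alpha = 0.01) {
  if (!is.numeric(alpha) || any(alpha <= 0) || any(alpha >= 1)) {
    stop("alpha must lie strictly between 0 and 1", call. = FALSE)
  }
  stats::qchisq(1 - alpha, df = 1)
}

#' Per-position significance calls (one-sided adoption)
#'
#' Applies the G-test to each position's 2x2 table and flags a position
#' significant only when G meets the critical value *and* the test sample
#' shows the excess (a/n1 > b/n2): a significant deficit in the test sample
#' is never adopted as a detection. Ties at exactly the threshold count as
#' significant.
#'
#' @param position Vector positions (for bookkeeping; any vector).
#' @param a,b,n1,n2 As in [g_statistic()].
#' @param alpha Significance level.
#' @param correction Passed to [g_statistic()].
#' @return A tibble with columns `position`, `count_test`, `count_contrast`,
#'   `total_test`, `total_contrast`, `G`, `direction`, `significant`.
#' @export
test_positions <- function(position, a, b, n1, n2, alpha = 0.01,
                           correction = c("none", "williams")) {
  correction <- match.arg(correction)
  G <- g_statistic(a, b, n1, n2, correction = correction)
  thr <- g_critical(alpha)
  p1 <- a / n1
  p2 <- b / n2
  direction <- dplyr::case_when(
    p1 > p2 ~ "test_excess",
    p1 < p2 ~ "contrast_excess",
    TRUE ~ "none"
  )
  tibble(
    position = position,
    count_test = a, count_contrast = b,
    total_test = n1, total_contrast = n2,
    G = G,
    direction = direction,
    significant = G >= thr & direction == "test_excess"
  )
}
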