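---
title: "Screening resequencing data for foreign vector DNA with exact k-mers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening resequencing data for foreign vector DNA with exact k-mers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Genome-edited crops are often produced with the help of a plasmid vector
that is meant to be absent from the final product. Regulators therefore need
a way to demonstrate, from whole-genome resequencing data alone, that no
fragment of the vector — even one a few tens of nucleotides long — remains
in the host genome. Read mapping pipelines are ill-suited to this question:
different aligners give different answers, and a reference genome of the
edited individual is never available. Exact k-mer matching against the known
vector sequence sidesteps both problems: the search is unambiguous,
deterministic, and needs no reference genome.

`kmerscreen` implements this screening method end to end: a per-position
k-mer counting engine over a (circular) vector, a one-sided G-test of each
position against a wild-type contrast sample, a detection judgement for a
known or suspected insert, a paired-end read simulator, Monte-Carlo power
campaigns, and k-mer pattern census utilities that quantify when k is long
enough to be informative.

## The statistic

Every read in each sample is decomposed into all of its k-mers on both
strands. Each k-mer is looked up in an index of the vector that maps every
k-mer pattern to its 1-based left-end positions on the vector's forward
strand; because the vector is typically a circular plasmid, the first k-1
bases are appended past the end before indexing, so positions spanning the
origin exist and every one of the L vector positions carries a window.
Windows containing `N` are skipped on both sides. No canonicalization is
applied: a palindromic k-mer is genuinely seen from both strands of a read
and counts twice. This convention is deterministic and symmetric; choosing
the alternative (count once) would shift every palindromic position's count
by a factor 2 in both samples and leave the test essentially unchanged.

For each vector position the matching count is compared between the test
sample and a wild-type contrast through the 2x2 table

|              | matching k-mers | all other k-mers |
|--------------|-----------------|------------------|
| test         | $a$             | $n_1 - a$        |
| contrast     | $b$             | $n_2 - b$        |

where $n_1, n_2$ are the samples' total extracted k-mer counts (identical
for every position). The statistic is the likelihood-ratio (G) test of
independence,

$$G = 2 \sum_{\text{cells}} O \ln(O/E), \qquad df = 1,$$

with expectations from the marginals and the $0\ln 0 = 0$ convention; both
margins are free (the Model II sampling design in Sokal & Rohlf's
terminology). A position is *adopted* only when $G$ meets the critical value
**and** the excess is in the test sample ($a/n_1 > b/n_2$): a deficit of
vector k-mers can never be evidence of an insert. At the default
$\alpha = 0.01$ the critical value is $\chi^2_{1,0.99} = 6.6349$. No
multiplicity correction is applied; instead the expected number of null
hits, `vector_length * alpha` (about 66 for a 6,646-bp plasmid at 1%), is
reported and interpreted directly.

An insert whose source interval on the vector is $[s, e]$ can only generate
true matches at positions $s \dots e-k+1$ — the windows lying fully inside
the segment, since junction-spanning windows do not exist in the vector.
The insert is judged *detected* when at least one position of this eligible
region is significant; significant positions elsewhere are false positives.
When $k$ exceeds the insert length no eligible window exists and the
combination is undefined (the campaign tables mark such cells rather than
run them).

## Raw versus Williams-corrected G

Whether a small-sample correction is applied to G materially changes one
number only: detection accuracy at marginal depth. With $b = 0$ and large
totals, $G \to 2a\ln 2$, so raw G crosses 6.6349 at $a \ge 5$ matching
k-mers while the Williams-corrected statistic ($G/q$ with
$q = 1 + (n/r_1 + n/r_2 - 1)(n/c_1 + n/c_2 - 1)/(6n)$) requires $a \ge 6$.
At 10x depth the expected number of error-free read windows fully covering a
20-nt insert is about $10 \times 81/100 \times 0.997^{20} \approx 7.6$, so
the two thresholds predict detection probabilities of roughly
$P(\mathrm{Pois}(7.6) \ge 5) \approx 0.88$ and
$P(\mathrm{Pois}(7.6) \ge 6) \approx 0.77$. Our simulations reproduce both
numbers (85–86% raw, 76–78% corrected at 10x; identical above 30x). The
package defaults to the raw statistic — the published critical value 6.634
is the uncorrected quantile — and every campaign reports both conventions
side by side, so the sensitivity is always visible. At the recommended 30x
or deeper the choice is immaterial.

## The simulator

`simulate_read_pairs()` emulates a HiSeq-like paired-end run:

* 100-nt reads from fragments of length $\mathrm{round}(N(500, 50))$,
  fragment starts uniform on the forward strand, R1/R2 in FR orientation
  (R2 is the reverse complement of the fragment's last 100 nt);
* uniform substitution errors at 0.3% per base (drawn as a per-read binomial
  count with uniform positions and a uniform choice among the three
  alternative bases — indistinguishable from per-base Bernoulli at this
  rate), no indels, template `N` bases left untouched;
* pair count `round(coverage * genome_length / (2 * read_length))`, making
  the realized depth exact up to rounding;
* fragments shorter than a read are clipped up to the read length — a
  negligible event at 500 +/- 50.

Substitution-only errors and even fragment sampling are idealizations:
real libraries have GC bias, duplicates, adapter chimeras and locally
uneven coverage, and real wild-type samples can carry contaminating DNA
from library preparation kits. Passing simulations therefore bound the
method's *statistical* behaviour (power, false-positive calibration), not
every failure mode of production data; the Poisson zero-class probability
`poisson_uncovered_probability()` makes the same point analytically — ideal
random sampling at 100x leaves no base unsequenced (probability $< 10^{-43}$),
yet real 140x data sets still show thousands of zero-depth positions.

`insert_segment()` models the edited genome: a segment of chosen length is
excised from a uniformly random (circular) vector position and inserted at
a uniformly random genome position. One insert per genome per iteration is
simulated; source intervals wrapping the plasmid origin are kept on the
extended coordinate and normalized when the eligible region is computed.

## Campaign design and problem sizes

`run_power_experiment()` (grid over insert length and k) and
`run_coverage_sweep()` (grid over depth) run 1,000 iterations per cell by
default, with a fresh, independently simulated contrast read set per
iteration at the same depth as the test set — the symmetric choice when the
contrast depth is not otherwise specified. Per-trial seeds are
`base_seed + (cell_index - 1) * iterations + iteration`, so any single
trial can be reproduced in isolation; the per-trial table is returned
alongside the summary and every summary quantity is recomputable from it.
The false-positive spread is reported as the sample standard deviation
(n − 1 denominator).

The default campaign genome is a 100-kb i.i.d. random sequence rather than
a full plant genome. True-positive power is locus-local — it depends on read
sampling over the insert and only weakly (through $\ln$ of the totals) on
library size — so detection accuracies transfer from a 373-Mb genome to a
100-kb one essentially unchanged; this keeps a 1,000-iteration sweep in the
minutes range on one CPU. What does *not* transfer is the small-k
false-positive background: at k = 10 or 15 the count of significant
positions depends on how often each vector k-mer occurs in the real host
genome, i.e. on host composition. Those cells are reproduced only when a
real genome is supplied, and the package documents them as
genome-dependent. A random genome needs roughly 10 Mb before every 10-mer
pattern is present (coupon-collector arithmetic: $2G$ strand windows over
$4^{10}$ patterns leave $\approx 4^{10} e^{-2G/4^{10}}$ missing), so the
saturation demonstrations use a 12-Mb sequence, and the
small-k-drowns-the-signal demonstration uses a 2-Mb genome where each
10-mer occurs a handful of times.

One empirical subtlety the campaigns surface: false positives at k >= 20 on
a random genome are *not* zero. Whenever a genome base flanking the
insertion point happens to equal the adjacent vector base (probability 1/4
per side), the run of matching windows extends one or more positions beyond
the eligible region, and those junction positions carry full counts. This
is a property of the detection geometry, not noise; it produces a mean of
roughly 0.6–0.8 false positives per iteration at L = 20, k = 20 — below
one, and concentrated immediately adjacent to the true interval, where a
reviewer would naturally read them as part of the same signal.

## Pattern census

`pattern_census()` counts distinct k-mers (both strands, so the set is
closed under reverse complement) against the theoretical total $4^k$, and
`shared_patterns()` intersects a genome's and a vector's pattern sets,
reporting every shared pattern with its positions and strands on both
sides, next to the uniform-null expectation $n_g n_v / 4^k$ (each of the
vector's $n_v$ distinct patterns is present in the genome's set with
probability $n_g/4^k$ under a uniform null; hypergeometric refinements
differ negligibly at these scales). Complementary patterns count
separately — a convention forced by the fact that a single two-strand
genomic locus shared with the vector is naturally described as two shared
patterns. For k <= 13 the census uses a dense $4^k$ presence table; larger
k uses hashed sets, and genome-wide distinct counts at k = 20 on gigabase
genomes are a large-memory operation best run on the vector-restricted
shared-pattern path instead.

## Numerical and degenerate-input choices

* `a = b = 0` (position untouched in both samples): G = 0, never
  significant — untouched vector positions stay silent.
* Ties at exactly the critical value count as significant (`>=`).
* Tiny negative G from floating-point cancellation on near-homogeneous
  tables is clamped to 0.
* Counts and totals are handled in double precision throughout (totals of
  deep libraries overflow 32-bit integers).
* Reads shorter than k contribute nothing and are not an error; an entirely
  empty read set is.
* Ambiguity codes other than N are rejected by default (k-mer identity must
  be unambiguous); a lenient mode maps them to N. Circularity is always an
  explicit declaration, never inferred.

## Limitations

* Exact matching only: a single substitution inside a k-mer destroys the
  match, which is precisely why power falls at shallow depth; there is no
  mismatch-tolerant mode, by design.
* The contrast sample is assumed vector-free; kit contamination or cisgenic
  (host-derived) vector regions produce legitimate signal in both samples
  and must be interpreted, or masked, by the analyst.
* The simulator does not model GC bias, duplicates, indels, or structural
  variation beyond the single insert.
* Small-k false-positive levels are host-composition-dependent and cannot
  be predicted from synthetic genomes.
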