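---
title: "Binding clusters and co-binding statistics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binding clusters and co-binding statistics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfclust)
```

## The procedure

`tfclust` analyses the joint placement of binding sites of several
transcription factors (TFs) along a genome. Its input is one simplified BED
file of ChIP-seq peaks per TF and a table of chromosome lengths; its output
is a partition of all sites into *binding clusters*, statistics of the
cluster-size distribution against a random-placement null, and a pairwise
co-binding analysis (co-occurrence counts, row correlations, hierarchically
ordered heatmaps).

### Sites

Each peak is reduced to a single coordinate. When the input carries a summit
column (a numeric fourth BED field, enabled with `summit_col = TRUE`) the
site is `start + offset`; otherwise it is the interval midpoint,
`floor((start + end) / 2)`. The midpoint fallback is deterministic and
unbiased for roughly symmetric peaks; for strongly skewed peak shapes a real
summit column is preferable. Coordinates are 0-based throughout: BED input
is 0-based half-open, and GFF3 `##sequence-region` pragmas (1-based
inclusive) are converted to lengths only. Strand is ignored — nothing in the
analysis depends on it. Exact duplicate records are retained with a message
(deduplication is an option); duplicates usually indicate an upstream
problem but dropping them silently would hide it.

### Chaining

All sites of all TFs are pooled and sorted by (chromosome, position, TF
label). Walking left to right, the open cluster extends to the next site
while two conditions hold:

* **gap rule** — the distance to the previous site is strictly less than
  `gap` (default 200 nt). "Strictly" is a deliberate reading of the rule
  "closer than 200 nt": two summits exactly 200 nt apart split.
* **span cap** — the distance from the cluster's first site is at most
  `span_cap` (default 500 nt). The cap bounds cluster width at roughly a
  promoter's extent, the range over which DNA-bound proteins can physically
  interact; it can be disabled (`span_cap = NULL`).

Any violation closes the cluster; the next site opens a new one. Sites at
equal positions always co-cluster (distance 0) and are ordered by TF label,
which makes the whole procedure deterministic. Every site belongs to exactly
one cluster, and singletons are emitted like any other cluster.

The cap needs a tie-break that the gap rule alone does not: when a chain of
gap-compatible sites grows wider than the cap, *something* must split, and
the split point is not canonically defined. We use greedy left-to-right
closure — close when the next site would exceed `start + span_cap` — because
it is single-pass, deterministic given the sorted pool, and independent of
input file order. Other conventions (e.g. balanced splitting) would move a
handful of boundary sites in wide chains; at the default parameters such
chains are rare.

Cluster size is reported under two metrics: `distinct_tfs` (how many
different factors co-occupy the locus — the headline metric) and
`total_sites`. They coincide unless one TF contributes several sites to a
cluster; we retain all member sites rather than collapsing per-TF
duplicates, and expose both counts.

### Size statistics and the null model

`size_histogram()` counts clusters per size; `fit_tail()` fits the log
counts by least squares, against `log k` (power law) or `k` (exponential),
using only sizes at or above `k_min` with nonzero counts and requiring at
least three usable points. Least squares on log counts mirrors how such
histograms are read on a semi-log/log-log plot and keeps the two competing
models directly comparable through `r_squared`; maximum-likelihood power-law
estimation would be the natural upgrade but is deliberately out of scope
here.

`simulate_null()` answers "could this histogram arise by chance?". Each
replicate repositions every TF's sites uniformly at random — integer
positions, chromosomes weighted by length, per-TF counts preserved,
collisions allowed (no self-avoidance: independent placement is the
baseline actually being claimed when a cluster is called non-random) — and
re-runs the identical chaining. Reported per size `k`: the null mean and
standard deviation of the count, and, when an observed histogram is given,
the empirical exceedance probability both of the per-size count and of the
upper-tail count (clusters of size ≥ `k`). The tail version is the one to
use for statements like "clusters of ≥ 4 TFs exceed chance". Probabilities
use the `(r + 1) / (reps + 1)` correction so a finite simulation never
reports zero. In the low-density limit the expected number of cross-TF
pairs within the gap approaches `2 g n_A n_B / L`, which the test suite
verifies at `n_A = n_B = 50`, `L = 10^6`, `g = 200` over 2000 replicates.

`tf_occurrence()` reports, per TF, the fraction of clusters containing at
least one of its sites. The denominator is a genuine choice: by default only
clusters with ≥ 2 member sites count (occurrence then measures participation
in co-binding, keeping singletons in would mostly measure each TF's share of
the site pool), with `include_singletons = TRUE` as the alternative. An
empty denominator yields `NA` with a warning, never an error.

### Co-binding

`pairwise_cooccurrence()` counts, for every TF pair (i, j), *all* site pairs
on the same chromosome within `window` nt (default 200, matching the gap).
Counting all cross pairs — rather than "sites with at least one partner" —
is the only convention under which the matrix is exactly symmetric in
integer arithmetic. The diagonal holds each TF's site count; it is
interpretable and is dropped before correlating anyway. The implementation
is a sorted sweep (binary search per site), checked in the tests against a
quadratic double loop.

`correlation_matrix()` computes the Pearson correlation of matrix rows —
two TFs are associated when they co-occur with the *same other factors* at
similar rates. By default the entries at positions i and j are removed from
both row vectors first (`drop_self_indices`), preventing the large diagonal
from inflating every correlation; this requires ≥ 3 TFs. Zero-variance
vectors (typically a TF whose co-occurrence row is all zeros) give `NA`
cells, not an exception. Values are reported on the full `[-1, 1]` scale;
co-occurrence counts are non-negative and in practice correlations land in
`[0, 1]`, but nothing in the definition guarantees that. Spearman rank
correlation is available via `method = "spearman"`.

`hierarchical_order()` clusters TFs agglomeratively on `d = 1 - r` (average
linkage by default). Labels are pre-sorted and every merge is oriented by
alphabetical rank, so tied distances — common in small integer matrices —
resolve deterministically. `NA` correlations enter as distance 1 with a
warning. `render_heatmap()` writes the ordered matrix as an SVG generated
directly by the package: white→red for positive values, white→blue for
negative, grey for `NA`, optional block outlines. Direct generation keeps
the output byte-identical across runs for identical input, which the
pipeline's determinism guarantee relies on; it is a rendering choice, not a
plotting framework.

### The pipeline

`run_all()` (and the `exec/tfclust` CLI) executes the whole flow from a YAML
config: clusters (BED6-style, name = joined TF labels, score = distinct-TF
count), both size histograms, occurrence, both tail fits, the null model,
co-occurrence and correlation matrices, the heatmap, and a parameter log.
Every output is first written with a `.partial` suffix and renamed on
success. With a fixed config and seed all numeric outputs are
byte-identical across reruns.

## The synthetic generator

`generate_sitesets()` builds test landscapes from a `synthesis_spec`:
uniform background sites per TF plus planted *hubs* — loci where each member
TF places one site at `center + U[-jitter, +jitter]`. The generator's role
is to make every downstream claim checkable against a known truth:

* a hub with `jitter < gap / 2` chains into a single cluster (consecutive
  jittered sites are ≤ 2·jitter < gap apart, and the span ≤ 2·jitter stays
  under the cap);
* hub jitter is uniform, not Gaussian, precisely so this recovery guarantee
  is provable rather than probabilistic;
* jittered sites are clamped at chromosome edges (not rejected), keeping
  per-TF counts exact;
* background draws within `hub_guard` (default 500 nt) of a hub center are
  resampled, so hubs sit in otherwise-unoccupied loci and recovery does not
  depend on the luck of the seed. The guard removes a vanishing fraction of
  the genome (a few kb out of tens of Mb) and leaves background statistics
  unaffected at the densities used.

`hub_fixture_spec()` fixes the standard study conditions: a 3 × 10 Mb
genome, twelve TFs with 100 background sites each (site density
4 × 10⁻⁵ per nt, a realistic genome-scale peak density), ten hubs of 5–10
members drawn from a ten-TF pool, 50 nt jitter, centers ≥ 1 Mb apart, and
two TFs that never join hubs so the heatmap has structure to find. What the
generator does *not* emulate: read-level signal and peak-calling noise,
sequence composition and motif content, nucleosome positioning, chromatin
domains, or correlated (non-uniform) background binding such as open-
chromatin bias. Passing tests therefore demonstrate the correctness of the
machinery — chaining, counting, null calibration, block recovery — not that
real genomes are uniform outside hubs; on real data the uniform null is a
lower bound on clustering expected by confounders.

`generate_powerlaw_sizes()` draws sizes from `P(k) ∝ k^-alpha` truncated at
`k_max`, with the normalization computed by direct summation. The fit-
recovery exercise uses `alpha = 2.5`, `n = 5000`, `k_max = 12`: the support
is chosen so the expected count in the rarest bin stays around 8, where
least squares on log counts is stable (repeated draws recover the exponent
within 10% with `r² > 0.95`); on wider supports the near-empty tail bins
make the log-scale fit erratic.

## Numerical choices and degenerate inputs

* Distance comparisons are `< gap` (strict) and `<= span_cap` / `<= window`
  (inclusive); all are integer-exact.
* Empty inputs are values, not errors: an empty site pool gives an empty
  cluster set, an empty cluster list an empty histogram and an empty BED
  file (header comment only).
* `fit_tail()` with fewer than three usable sizes, negative `gap`, a cap
  below the gap, duplicate TF labels, or a mislabelled matrix are contract
  errors and fail loudly with the offending value named.
* Matrix TSVs round-trip integers exactly and floats to six decimals;
  cluster BED output is sorted by (chromosome, start).
* Monte-Carlo sizes in the shipped tests: 200 random oracle instances per
  equivalence check, 2000 replicates for the analytic pair-rate limit,
  199 replicates for the exceedance tests — chosen so the full suite stays
  fast while keeping Monte-Carlo error far from every asserted margin.

## Known limitations

* The greedy span-cap split is a convention; a different convention moves
  boundary sites in chains wider than the cap.
* Least-squares log-log fitting is biased for heavy tails compared with
  discrete MLE; slopes should be read as descriptive.
* The uniform null ignores chromatin context; observed exceedances on real
  data conflate co-binding with shared accessibility.
* Occurrence and correlation are unweighted by site quality; no
  significance test is attached to individual correlations.
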