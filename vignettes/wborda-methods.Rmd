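---
title: "Dimension-combination similarity search for multivariate time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dimension-combination similarity search for multivariate time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wborda)
```

## The problem

A multivariate time series (MTS) is an $m \times n$ matrix $X$: $m$ time
points observed simultaneously on $n$ channels — an EEG recording across
electrodes, a glove of motion sensors, a battery of force/torque gauges.
Similarity search over such items (find the $k$ nearest neighbours of a
query, over whole items or over sliding windows of a long recording) is the
primitive behind retrieval, motif discovery and 1-NN classification.

Two families of measures exist. *Overall matching* treats the item as one
object, typically comparing PCA eigenspaces. *Match-by-dimension* breaks the
MTS into univariate series, searches each separately with any univariate
measure, and aggregates the per-dimension results. `wborda` implements the
second family with a rank-aggregation twist: the per-dimension hit lists are
combined by **weighted BORDA voting**, which uses both the *rank order* and
the *actual distance gaps* between hits, weighted by how much variance each
dimension carries.

## The pipeline

`knn_search()` chains four stages, each exposed as ordinary functions.

**1. PCA reduction** (`fit_pca`, `choose_num_components`,
`project_components`). Channels are correlated, so the search runs on
principal-component (PC) series instead of raw channels. PCA is performed on
the *covariance* matrix of each item; the projection uses mean-centred data
so the variance of the $i$-th PC series equals the $i$-th eigenvalue
$\lambda_i$. The retained count $p$ is the smallest number of leading
components that keeps strictly more than a `threshold` (default 0.9) of
total variance *in every item*. The threshold is a tunable fraction, not a
constant of the method: collections whose variance concentrates in few
components (small $p$) are the method's favourable regime, because
candidate alignment across many PC dimensions becomes fragile as $p$ grows.

Two conventions are fixed for determinism: eigenvector columns are
sign-flipped so their largest-magnitude entry is positive (DTW distances are
sign-sensitive, and linear-algebra backends disagree on signs), and tied
eigenvalues keep their original order.

**2. Per-dimension constrained DTW kNN** (`dtw_distance`,
`knn_whole_matching`, `knn_subsequence`). Each PC dimension is searched as a
univariate series under dynamic time warping with squared local cost,
symmetric steps, and a Sakoe–Chiba warping window. The window is expressed
as `band_fraction` (default 0.05) of the longer series length and converted
to a band width $w = \max(1, \lceil 0.05\,L \rceil)$; a band of width $w$
admits alignment offsets $|i-j| \le w-1$, so width 1 is the diagonal and
reduces exactly to the Euclidean distance on equal lengths. (Stating the
feasibility condition as $|{\rm len}(a)-{\rm len}(b)| \le w-1$ keeps that
limit exact; when whole items of genuinely different lengths are compared
the band is widened minimally to admit a path.) Each dimension returns
$k' \ge k$ neighbours (`kprime`, default $2k$); in subsequence matching, a
greedy `exclusion_zone` (default half the query length $l$) prevents
returning $k'$ shifted copies of one event, and windows overlapping the
query's own position are skipped — the query is its own 0-distance match
$s_0$ and never a result.

**3. Truncation** (`group_matches`, `delete_isolated`, `align_groups`,
`reorder_candidates`). Per-dimension hits rarely start at identical times.
They are grouped as connected components of the relation "same source and
window overlap strictly greater than $l/2$"; groups covering fewer than half
the dimensions ($2\,|g| < p$) are isolated noise and deleted; each surviving
group is aligned to one candidate multivariate sequence starting at the mean
member start (rounded half up), with per-dimension distances reused from the
stored hits where available (`recompute_all = FALSE`) and computed fresh via
DTW for the missing dimensions; finally candidates are reordered per
dimension. For whole matching, windows either coincide or are disjoint, so
groups reduce to item identity and alignment is the identity. A group whose
aligned window would run past the series end is dropped, not clamped; the
choice is arbitrary but a clamped window would no longer have length $l$.

**4. Voting** (`s_wborda_rank`, `s_borda_rank`). Classical BORDA scoring
awards position points only, which discards the *size* of similarity gaps: in
a four-round race with orders $r_1r_2r_3r_4$, $r_2r_1r_4r_3$, $r_4r_3r_1r_2$,
$r_3r_4r_2r_1$, all four runners tie at 10 points no matter how far apart
they finished. The weighted voting score of neighbour $s_i$ in dimension $j$
is instead

$$\mathrm{vs}_i \;=\; w_j\Bigl(1 + k'\bigl(1 - d_i/d_{k'}\bigr)\Bigr),$$

linear in the distance ratio: $d_i = 0$ earns $w_j(1+k')$ (the query's own
anchor) and $d_i = d_{k'}$ earns $w_j$. The score depends on distances only
through $d_i/d_{k'}$, so per-dimension rescaling cannot shift a dimension's
influence — that is the job of the weights. A candidate's weighted BORDA
score sums its votes over the $p$ dimensions; the top $k$ are the result.
Two interpretation points are fixed here: the formula is applied for all
$i = 1..k'$ (its endpoints reproduce the stated anchors), and after
truncation the $d_{k'}$ anchor is re-based to the largest surviving
candidate distance per dimension, since truncation changes the candidate
count.

The baseline `measure = "borda"` ranks the same candidates with positional
points per dimension (a list of $i$ hits awards $i, i-1, \ldots, 1$) after
eliminating candidates voted for by fewer than half the dimensions; the
"same time period" identity of votes across dimensions is resolved by the
same truncation grouping, which the elimination rule mirrors.

**Weights** (`compute_weights`). $w_i = f(V_i) / \sum_j f(V_j)$, where
$V_i$ collects the $i$-th eigenvalue across items and $f$ aggregates by
`min`, `mean` (default) or `max`. With `normalize = TRUE` (default for whole
matching) each item's eigenvalue vector is first divided by its own sum, so
items of different overall energy contribute comparably; for subsequence
matching $V_i$ is the long series' single eigenvalue and the strategy is
immaterial. Normalisation uses the full eigenvalue vector even when only
$p < n$ components are weighted.

## Evaluation protocol

`cross_validate()` estimates the 1-NN classification error: stratified
$k$-fold assignment (default 10 folds, 10 repeats) from a recorded seed,
each test item classified by the label of its top-ranked neighbour in the
training folds, errors reported per fold in percent and averaged per repeat
then overall. `scan_components()` walks $p$ upward from the retention floor
and stops the first time the error rises above the best seen (the full
evaluated table is kept so alternative stopping readings can be audited).
`wilcoxon_signed_rank()` compares two measures' paired per-dataset errors;
the variant is pinned — zeros dropped, average ranks, normal approximation
*without* continuity correction — because that is the standard large-sample
form of the test and the one whose p-values the package's tests freeze
(e.g. five same-signed pairs give $W^+=15$, $z \approx 2.023$,
$p \approx 0.043$). Stratification and deterministic 1-NN tie-breaking
(smaller distance, then earlier start, then id) are implementation choices
the protocol leaves open; both are fixed by config and recorded in every
report.

## What the synthetic generator emulates

`generate_labeled_mts()` draws, per class, `latent_rank` smooth template
waveforms (seeded sinusoid mixtures, unit sd); an item adds unit-sd smooth
latent variation, applies one random smooth time-warp of up to 5% of the
length (matching the DTW band, so elastic alignment is genuinely needed),
mixes latents into `n` channels through a single loading matrix shared by
the whole collection, and adds white noise. `separation` scales the
templates in units of the within-class latent sd: at 0 the classes are
statistically exchangeable (1-NN error $\approx (1 - 1/\#classes) \cdot
100\%$), at 10 they are far apart (error 0). The shared loading matrix is
deliberate: class-specific loadings would leak class identity through the
eigenvector geometry even at zero separation, breaking the null condition.
`generate_long_with_motifs()` plants noisy copies of a smooth multivariate
motif at non-overlapping seeded positions in unit-variance white noise and
returns the clean motif as the query.

What the generator does *not* emulate: heavy-tailed or nonstationary noise,
missing samples, channel counts in the hundreds, classes that differ only in
loading geometry, or background autocorrelation in the long series. Passing
tests on these data show the pipeline recovers planted structure under its
own assumptions — low effective rank, smooth signals, modest warping — not
that it wins on any particular real corpus; on real collections whose
variance spreads over many components the method is expected to degrade.

## Numerical choices and degenerate inputs

- DTW: squared local cost, symmetric steps, square root of accumulated
  cost; these match the most common formulation so external DTW
  implementations can serve as oracles. The band-width convention is the one
  that makes width 1 equal Euclidean distance (above).
- Distance ties everywhere break deterministically: smaller distance, then
  earlier start, then lexicographic id / group order.
- Eigenvalues are clipped at 0 (covariance roundoff can produce $-10^{-17}$);
  an all-constant item is a degenerate-input error, as are NaNs anywhere.
- `weighted_voting_score` with $d_{k'} = 0$ (every candidate coincides with
  the query) returns the query anchor $w_j(1+k')$ for all of them.
- Mean starts are rounded half up (`floor(x + 0.5)`); R's banker's rounding
  would make group alignment depend on parity.
- If truncation deletes every group (disjoint per-dimension lists under a
  small $k'$), `knn_search` doubles $k'$ (capped at the corpus size) and
  retries with a warning rather than returning an empty result mid-protocol.
- CSV output prints 17 significant digits, so datasets round-trip
  bit-exactly through `write_mts_dataset()` / `read_mts_dataset()`.

## Problem sizes used by the packaged checks

The packaged tests and `scripts/acceptance.R` run at desk scale, chosen so
the full suite completes in well under a minute on one core: labelled
collections of 3 classes × 20 items (m = 60, n = 6, latent rank 2) for the
classification checks, 600-point long series with three planted 50-point
motifs across five seeds for subsequence search, brute-force DTW path
enumeration up to length 6, and exhaustive voting oracles up to 10
candidates. Larger corpora are a matter of compute, not of code paths: the
sliding-window DTW scan is $O(M\,l\,w)$ per dimension and the whole-matching
search $O(N\,m\,w)$ per dimension.

## Known limitations

- The truncation heuristic assumes hits for a true multivariate event are
  near-aligned across dimensions; events visible in fewer than half the
  dimensions are discarded by design.
- Reused member distances after alignment are cheap but slightly stale when
  the aligned start differs from a member's own start; `recompute_all = TRUE`
  trades compute for exactness.
- No lower-bounding or indexing: every window/item is scanned. Fine at
  $M \sim 10^4$; beyond that, envelope pruning would be the first addition.
- The variance-retention rule couples $p$ across all items; one noisy item
  can force a large $p$ for the whole collection.
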