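---
title: "Auditing a panel of hexapeptide amyloid classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing a panel of hexapeptide amyloid classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amylaudit)
```

## The problem

Experimentally confirmed amyloidogenic hexapeptides are scarce (on the
order of two hundred), so machine-learning classifiers of amyloid "hot
spots" are sometimes trained on datasets extended by windowing whole
proteins into hexapeptides and labelling every window by the parent
protein's amyloid status. Such a construction can go wrong in two ways
that have nothing to do with amyloid propensity:

* **composition bias** — a small experimental set folded into the positive
  class can dominate its position-specific residue statistics (a single
  motif such as STVIIE leaves a visible fingerprint), giving learners an
  incidental pattern to latch onto;
* **behavioural isolation** — a classifier trained on such labels can
  disagree systematically with every independent method in the field while
  still scoring well against its own (equally biased) test split.

`amylaudit` implements both audits as a reusable pipeline: a composition
audit of the training set itself, and a clustering audit of the
classifier's decisions against a panel of established predictors.

## Composition audit

For a fixed-length peptide set, `position_frequencies()` tabulates the
residue counts per position, and `background_ratio()` scores each
(residue, position) cell by

$$r(a, p) = \frac{f_{\text{set}}(a, p)}{f_{\text{bg}}(a)},$$

the dataset frequency relative to a *position-independent* background
distribution (the shipped default is a frozen snapshot of global
UniProtKB/Swiss-Prot residue frequencies; supply your own via
`read_background()`). Ratios above 1 flag over-represented residues;
cells with zero counts report exactly 0. The background is global rather
than positional because the question is representativeness of the protein
world, not positional conservation. `format_ratio_table()` lays the
result out residues-by-positions at one decimal, the conventional report
shape.

`information_content()` computes per-position sequence-logo heights in
bits, $R_p = \log_2 20 - H_p$, with $H_p$ the Shannon entropy of the
position's frequencies and an optional small-sample correction
$e_n = 19/(2 n \ln 2)$. The correction is off by default: the audit's
typical $n$ is in the thousands, where $e_n < 0.01$ bits. Both the
frequency matrix and the information-scaled stack heights are returned,
so either scaling of a logo can be drawn.

`dataset_overlap()` measures leakage: the number of *distinct* peptide
strings shared between a query and a reference set. The reported fraction
divides by the query's raw size (duplicates included), because that is
the convention under which a contribution of 66 peptides to a set of 1226
reads as 5.4%; a distinct-string denominator is available via
`denominator = "distinct"`.

## Clustering the panel

The decisions of $k$ methods over $n$ peptides form an $n \times k$
binary matrix. For a pair of methods with contingency counts
$a = n_{11}$, $b = n_{10}$, $c = n_{01}$, $d = n_{00}$, three
similarities are provided, all counting negative matches ($d$) as
agreement — two methods that both call a peptide non-amyloid agree just
as much as two that both call it amyloid:

* Sokal–Michener: $s = (a+d)/(a+b+c+d)$
* Rogers–Tanimoto: $s = (a+d)/(a+2(b+c)+d)$
* Sokal–Sneath: $s = ad/\sqrt{(a+b)(a+c)(b+d)(c+d)}$

Several Sokal–Sneath variants exist in the literature; the one above (the
geometric-mean form over the four marginals) is the variant this package
ships, and the measure registry is written so further coefficients can be
added. Its degenerate cases are resolved explicitly: $b = c = 0$ means
identical decision vectors, so the similarity is 1 even when a marginal
factor vanishes (all-positive or all-negative vectors); otherwise a zero
marginal yields 0. These choices preserve "identical ⇒ similarity 1"
across all three measures.

Dissimilarity is taken as $1 - s$ rather than $\sqrt{1-s}$: it is the
simplest monotone transform, and both the rank-based validity index below
and most linkages depend only on the ordering of distances.

`gamma_scan()` then varies **measure × algorithm × number of clusters
u**. The algorithm suite comprises seven agglomerative linkages (single,
complete, average, McQuitty/WPGMA, Ward, centroid, median) computed by
`stats::hclust`, divisive clustering (`cluster::diana`) and k-medoids
(`cluster::pam`, entering the scan at each `u` directly rather than
through a dendrogram). Ward is implemented as Ward.D2. Equal-distance
merge ties are resolved by `hclust`'s deterministic rule, so dendrograms
are bit-reproducible for a given matrix. PAM's BUILD+SWAP is
deterministic on a fixed dissimilarity matrix; its `seed` argument exists
only for interface uniformity. Centroid and median linkage can produce
height inversions; the other linkages are monotone.

Each cell of the scan is scored by the **Baker–Hubert Gamma**: with
$s^+$ the number of (within-cluster, between-cluster) distance pairs in
which the between distance is strictly larger, and $s^-$ the number in
which it is strictly smaller,

$$G(u) = \frac{s^+ - s^-}{s^+ + s^-}.$$

Ties ($b = w$) count in neither term, following the Goodman–Kruskal
convention — they are common for binary-data distances, where many pairs
share the same value. $G = 1$ means every within-cluster pair is closer
than every between-cluster pair; the $u$ maximising $G$ is taken as the
number of clusters. A partition of all singletons, or a single cluster,
has no valid comparisons and is rejected; a scan cell where all
comparisons tie reports `NA`. By default the scan runs $u$ from 2 to
$\min(8, k-1)$. When several cells attain the maximum, all are reported.

## Stability validation

`consensus_matrix()` implements resampled consensus clustering: `B` times,
a fraction `rate` of the resampling unit is drawn without replacement, the
distance matrix is rebuilt, and the clustering is repeated; $M(i,j)$ is
the co-clustering frequency of methods $i, j$ among the resamples where
both were evaluable. The defaults `B = 100`, `rate = 0.8` follow the
standard consensus-clustering convention. The resampling unit defaults to
*items*: the clustered objects are a dozen methods, far too few to
subsample informatively, while the thousands of peptides give the
bootstrap its meaning; method resampling is nevertheless implemented
(resamples retaining fewer than `u` methods are skipped and logged).
Resample $r$ uses seed `seed + r`, making runs reproducible and
individual resamples independently recomputable.

`merge_consensus()` averages the per-algorithm matrices element-wise
(unweighted) into a merged consensus matrix; `cluster_from_consensus()`
treats $1 - M$ as a distance matrix and partitions it (average linkage by
default). The stability suite used throughout the package's examples is
agglomerative-average, k-medoids, agglomerative-complete,
agglomerative-Ward and divisive. k-medoids stands where a k-means step
would traditionally appear, because centroid means are undefined for
binary-data dissimilarities — PAM is the natural medoid-based analogue on
a precomputed distance matrix.

`consensus_robustness()` reports, for each method, the **membership
robustness**: its mean consensus connectivity to the other members of its
cluster; and per cluster the mean over within-cluster pairs. A singleton
cluster needs a convention. Its *cluster* robustness is 1 (a one-member
cluster is trivially self-consistent). Its *membership* robustness,
however, is defined as the method's mean consensus connectivity to the
whole remaining panel: membership robustness exists to expose outliers,
and awarding an isolated method the maximum score would invert the
statistic's meaning exactly in the case the audit cares about — a method
so unlike the rest of the panel that every algorithm leaves it alone.
Singletons are flagged in the report so both readings remain visible.
Because the question of whether robustness box plots should aggregate
per-algorithm or merged values is open in practice, both the
per-algorithm matrices and the merged matrix are plain first-class
objects and either can be fed to `consensus_robustness()`.

## Unanimous voting

`unanimous_vote()` audits a focal method against the ensemble of all
others: items where every base method votes 0 (or 1) form the unanimous
negative (positive) sets, and the report gives the fraction of each on
which the focal method concurs. Percentages are rounded half-up for
display; full-precision fractions are always retained. An empty
unanimity class reports `NA`, never a fake 0%. The calibration anchor is
that a focal method flipping fair coins scores ≈50% on any unanimity
set — an observed agreement near 50% therefore means "unrelated to the
panel consensus", which is the interpretive yardstick for this audit.

## What the synthetic module emulates

`simulate_peptides()` draws negatives i.i.d. per position from the
background and positives likewise, except that a fraction `q` of
positives carries a planted motif — either verbatim (`replace`, emulating
an experimental set folded into the positives; the default, with
`q = 0.054` and motif STVIIE at the audit's canonical scale
$n_+ = n_- = 1226$) or diffusely (`per-position`, each motif position
independently with probability `bias`, emulating enrichment without
duplication).

`simulate_classifications()` plants the panel structure the clustering
audit is designed to detect: 2452 items; two method blocks (five
FoldAmyloid-like variants, six Waltz-like variants plus a consensus
method) whose members report a shared latent Bernoulli($\pi$) call
flipped independently with probability $\varepsilon$; and one outlier
method answering an independent coin. Defaults: $\pi = 0.2$ (amyloid
calls are the minority for real panels), $\varepsilon = 0.05$ (a small
disagreement rate within a family of variants), outlier rate 0.5 (a pure
coin flip, the reference point for the voting calibration).

What the generator does **not** emulate: any physico-chemical model of
aggregation, correlations between the two blocks beyond chance agreement
of their latent calls, method-specific error structure (flips are
homogeneous across items), or the real predictors' decision rules.
Passing the planted-structure tests therefore shows that the pipeline
recovers this kind of structure when present — not that any particular
real tool is or is not an outlier; for that, users supply the real
decision matrix.

## Problem sizes and numerical notes

The package's tests and the acceptance script run the full pipeline at
the canonical audit scale — 2452 items, 12 methods, $B = 100$ resamples
per algorithm, 1226 peptides per composition set — which completes in a
few seconds; unit tests use smaller planted instances (hundreds of items,
6–7 methods) where the same structure is recoverable by hand or by
brute-force oracles. Gamma is validated against exhaustive pair
enumeration at $n \le 7$ objects, k-medoids against exhaustive partition
enumeration at $n = 4$.

One geometry subtlety is worth knowing: Sokal–Sneath weights the four
marginal products, so when positive calls are a minority (latent rate
$\pi = 0.2$) two independent block signals can sit marginally *farther*
apart under it than a coin-flip outlier sits from a block. A
gamma-optimal two-way split under Sokal–Sneath may then group the outlier
with one block even though Sokal–Michener and Rogers–Tanimoto always
isolate it. Conclusions about outlier status are therefore best read
across measures, which is exactly what the scan reports.

Known limitations: Gamma is undefined (and reported `NA`) when every
within/between comparison ties, which can occur for tiny panels of
identical methods; centroid/median dendrogram inversions make their cut
heights non-interpretable (cuts by count `u` remain well defined);
consensus entries under method resampling can be `NA` for pairs never
jointly retained — `cluster_from_consensus()` refuses such matrices
rather than guessing.
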