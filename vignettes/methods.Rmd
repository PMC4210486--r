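---
title: "Detecting atypical genes in virus families: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting atypical genes in virus families: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atypicalr)
```

## The problem and the model

Genes that entered a viral genome by recent horizontal transfer tend to carry
the compositional signature of their source genome rather than of their new
host. Because viruses lack universal marker genes and deep, reliable
phylogenies, composition is often the only usable evidence. `atypicalr`
frames the task as unsupervised novelty detection *within a virus family*:
all genes of the family are represented as compositional feature vectors, and
a one-class \(\nu\)-SVM with a Gaussian kernel
\(k(x, y) = \exp(-\gamma \lVert x - y \rVert^2)\) learns a boundary enclosing
the bulk of the family. No labels are needed, which matters because no gold
standard of viral HGT events exists.

The one-class SVM separates the data from the origin in feature space with a
maximal-margin hyperplane; \(\nu \in (0, 1]\) bounds the fraction of points
expected to fall outside the boundary. We deliberately do not use the binary
in/out decision. Instead each gene is scored by the *signed distance* of its
feature vector to the decision boundary — negative outside, positive inside —
and genes are enumerated in ascending order of this distance. The head of the
list holds the most atypical genes, which are the HGT candidates. The exact
boundary position is of minor importance for a ranking, which is what makes
the otherwise hard unsupervised parameter-selection problem tractable
(cross-validation is unavailable without labels).

Ties in signed distance are broken by dataset ingest order, so results are
deterministic and reruns are byte-identical.

## Feature sets

Nine signatures are computed from the coding sequence alone
(`feature_specs()`):

| name                   | dimension | description |
|------------------------|-----------|-------------|
| `mono` … `tetra`       | 4, 16, 64, 256 | overlapping k-mer word frequencies, k = 1..4, lexicographic order |
| `codon_usage`          | 64        | frame-0 codon frequencies (stop codons included as ordinary entries) |
| `relative_codon_usage` | 64        | codon frequencies normalized within each synonymous family of the standard genetic code |
| `amino_acid`           | 20        | translated amino-acid frequencies, stops excluded, alphabetical one-letter order |
| `position_nt`          | 12        | base frequencies at each of the three codon positions (each triplet of four sums to 1) |
| `gc_content`           | 1         | proportion of G+C among ACGT characters |

k-mers above 4 are not offered: short viral genes cannot support the
statistics of higher-dimensional word spaces. Counting decisions worth
stating explicitly:

* k-mer windows are *overlapping*; windows or codons containing a non-ACGT
  character (IUPAC ambiguity codes are accepted on input) are skipped, never
  imputed, so real records with `N`s do not fabricate counts;
* the reading frame is frame 0 of the supplied CDS; a trailing partial codon
  is dropped with a warning;
* a synonymous family never observed in a gene receives a uniform
  `1/|family|` in `relative_codon_usage` instead of 0/0, keeping rows
  comparable (the imputation count is recorded on the feature table);
* translation uses the standard genetic code by default; the NCBI table id
  is exposed (`genetic_code`) for completeness;
* sequences are taken on the given (coding) strand with no reverse-complement
  canonicalization — single-stranded viruses genuinely differ between
  strands, and that asymmetry is informative.

Before entering the SVM, every feature matrix is standardized column-wise to
zero mean and unit variance using the *population* standard deviation, a
choice made so independent implementations agree bit-for-bit;
zero-variance columns become all-zero. GC content is never given to the SVM:
it serves as the one-dimensional baseline, ranking genes by absolute
deviation from the family's median GC.

An experimental option (`gc_regression = TRUE`, CLI flag
`--experimental-gc-regression`) residualizes each feature column on GC
content before standardization. It is excluded from the default feature sets
and from all benchmarks: exploratory use only.

## Parameter selection by ranking stability

With no labels, parameters are chosen where the *ranking* is robust: a
stable result is not necessarily correct, but an unstable one is untrustworthy.
`stability_sweep()` walks \(\nu\) over 1,000 equidistant values
0.001, 0.002, …, 1.000 and \(\gamma\) over
\(10^{-6}, 10^{-5}, 10^{-4}, 10^{-3}, 0.01, 0.1, 1, 10, 100\) and the
rule-of-thumb \((2D)^{-1}\) (D = feature dimension). The stability at
\(\nu_i\) is the Spearman correlation of its ranking with the rankings at
\(\nu_{i-1}\) and \(\nu_{i+1}\), averaged; boundary grid points use their
single neighbor; ties use mid-ranks. Across datasets the rule-of-thumb
\(\gamma\) is stable over a wide range of \(\nu\), whereas large \(\gamma\)
is stable only at large \(\nu\); the package tests assert this ordering
statistically on synthetic data. The shipped defaults are \(\nu = 0.2\) and
\(\gamma = (2D)^{-1}\).

Grid points where the solver cannot produce a fit are recorded as missing
values, not interpolated, and the profile reports per-\(\gamma\) coverage.
One systematic case: the libsvm backend rejects \(\nu = 1.0\) exactly, so the
last grid point is always a missing value. The sweep result is independent of
evaluation order.

## Numerical choices

* **Solver.** The SVM is libsvm via `e1071::svm` (type
  `one-classification`, radial kernel, no internal scaling). The
  termination tolerance is fixed at `1e-12`: at looser tolerances the
  decision values carry row-order-dependent noise around `1e-6`, large
  enough to reorder near-boundary genes; at `1e-12` decision values are
  invariant to row permutations to ~`1e-12`, making the documented
  equivariance guarantees (ranking invariance under row permutation,
  identical scores for duplicated rows) hold in practice at the `1e-9`
  tolerance the tests use. Fit time is unaffected at the problem sizes the
  package targets.
* **Sign convention.** Signed distances are negative outside the boundary.
  The GC baseline stores the *negated* absolute deviation from the median so
  that the same ascending-order convention applies everywhere.
* **Degenerate inputs.** Families need more than three genes; feature
  tables need at least four encodable rows; standardization needs at least
  two rows. Unencodable genes (all-N, no valid codon, …) are excluded and
  reported, not silently dropped.

## Redundancy reduction

Database records are massively redundant, and a family dominated by
near-copies of one gene would pull the learned boundary toward that gene.
`reduce_redundancy()` collapses sequences at a 95% identity level with a
greedy single pass: genes sorted by length descending, each joining the first
cluster whose founder shares at least the identity fraction of the shorter
sequence's 5-mers (set containment), else founding a new cluster. This is not
a reimplementation of a full clustering tool — the method only needs
redundancy *reduction* and is insensitive to the exact clusterer — and users
with an external clustering can supply its representative list directly
(`representatives =`). The estimate is intentionally conservative for
sequences too short to carry 5-mers (exact equality only). Word size and
coverage conventions of external tools are not mimicked; the greedy
substitute is an acknowledged approximation.

## Sliding-window mode

For a single genome without gene annotations, `sliding_window()` cuts
segments at starts 0, step, 2·step, … (0-based, half-open); after the last
full window a trailing truncated segment is kept iff its length is at least
half the window, a rule fixed so outputs are deterministic. Segments are
ranked either against their own statistics (`background = "self"`) or
against the feature rows of a whole family, which borrows strength from all
family genes — useful for small genomes with skewed composition. Family
background uses the family's standardization (center/scale) for the
segments, so segment scores live on the family's scale.

## Synthetic data: what it emulates, what it does not

`generate_family()` draws each gene as `ATG` + L sense codons i.i.d. from a
family-specific codon distribution + one stop codon (uniform over the three
stops), L uniform over a length range. A codon-level i.i.d. source was chosen
deliberately: one parameter set then induces family structure in *all* nine
signatures (word, codon, amino-acid, positional, GC). Defaults, chosen once
as a realistic viral CDS scale: 100–300 internal codons (300–900 nt),
Dirichlet(1) source weights over the 61 sense codons, internal stop weights
forced to zero.

`generate_benchmark()` interpolates each family's distribution between a
shared base and a family-unique distribution with a divergence handle
\(d \in [0, 1]\): at \(d = 0\) all families are statistically identical (an
injected outlier is undetectable by construction, AUC ≈ 0.5), at \(d = 1\)
maximally distinct. A `gc_matched` mode draws the unique distribution by
permuting base weights *within groups of codons of equal G+C count*, so
expected GC is identical across families while codon and word usage diverge —
the construction that isolates what signatures add beyond the GC baseline.

What the generator does **not** emulate: phylogenetic correlation between
genes of a family (real genes are not i.i.d.), gene amelioration over time,
length/composition coupling, sequencing artifacts, and the research-intensity
biases of real databases (a family dominated by one heavily sequenced
species). Passing benchmarks on this generator therefore demonstrates that
the machinery recovers compositional outliers under the model's assumptions —
not that real families are this easy. On real data, pre-existing true
outliers additionally remain unlabeled and compete with injected ones,
biasing measured AUC downward.

## Evaluation protocol

`inject_outliers()` amends a family of n genes with
`m = max(1, round(n·f/(1−f)))` genes drawn uniformly without replacement from
the genes of other families, so that the outlier share of the amended family
hits the target fraction (default 5%) where divisible and is never zero.
`compute_auc()` scores a ranking against the injected labels over *all*
cutoffs; tied signed distances contribute ½ (pair-counting convention, equal
to the trapezoid over tie blocks). The genes in the top 5% of the list are
reported separately as the called set, since AUC itself is cutoff-free. A
family prediction counts as a *success* if AUC exceeds 0.9 and a
*semi-success* if it only exceeds 0.8; "exceeds" is read strictly (0.9
exactly is semi-success, 0.8 exactly is none) — the boundary reading was an
open choice and is fixed here. A family-level call takes the best AUC over
the evaluated feature sets. Families beyond 25,000 genes are down-sampled
uniformly at random before analysis.

All randomness flows through explicit integer seeds recorded in output
manifests; identical configuration and seed give byte-identical outputs.

## Problem sizes used in the shipped checks

The package's own test suite and the acceptance script run entirely on
synthetic data at desk scale, chosen as the smallest sizes at which the
claims are comfortably measurable: benchmarks of 10 families × 200 genes
(the divergence ladder uses 6 × 60), a 500-gene family with 1,000 random-
ranking replicates for the null AUC, and reduced (γ, ν) grids for sweep
integration tests with the full 1,000-point grid reserved for the grid-
definition checks. The real-data corpus behind the original family studies
(tens of thousands of genes across 93 families) is deliberately out of
scope.

## Known limitations

* Only recently transferred genes are detectable in principle; ameliorated
  genes have already converged to the host signature.
* The method reports *atypicality*, not provenance or mechanism; manual
  interpretation is required, and contamination or unusual mutational biases
  also produce atypical composition.
* Very small families (just above the 4-gene floor) give unstable boundaries
  and noisy AUCs.
* The greedy clusterer's k-mer containment can merge sequences a
  full-alignment tool would keep separate (and vice versa) near the identity
  threshold.
* A family dominated by one species defines "typical" as that species; the
  package does not (yet) down-sample per species.
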