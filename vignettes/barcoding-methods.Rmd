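---
title: "Methods: distance-based barcode identification and species-boundary delimitation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: distance-based barcode identification and species-boundary delimitation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodetools)
```

## The problem

DNA barcoding assigns specimens to species by comparing a short standard
marker — for animals, the 658-bp 5′ fragment of mitochondrial COI —
against a reference library of sequences with known species labels. Two
things decide whether this works: the *barcode gap* (is the largest
intraspecific distance smaller than the smallest interspecific
distance?) and the *quality of the taxonomy behind the labels*. When
morphotypes of one biological species have been described as several
nominal species ("oversplitting"), interspecific divergences collapse
into the intraspecific range, identification protocols start returning
ambiguous or wrong answers, and the errors concentrate exactly in the
oversplit groups. `barcodetools` implements the full analysis chain used
to diagnose this situation and to delimit species boundaries: distances,
gap analysis, leave-one-out identification, threshold optimisation, a
neural-network classifier, haplotype networks, and NJ-tree monophyly —
plus a seeded simulator that generates libraries with known ground truth
so every stage is testable offline.

## Distance model

All distances are Kimura 2-parameter (K2P). For an aligned pair, sites
where either sequence carries a gap, `N` or another IUPAC ambiguity are
removed (*pairwise deletion*); over the remaining sites `P` is the
transition proportion (A↔G, C↔T) and `Q` the transversion proportion,
and

$$d = -\tfrac{1}{2}\ln(1 - 2P - Q) - \tfrac{1}{4}\ln(1 - 2Q).$$

Numerical choices:

* **Saturation** (`1−2P−Q ≤ 0` or `1−2Q ≤ 0`) is an *error*, not
  infinity — the formula is undefined there and in-domain barcode
  distances never approach it. `k2p_matrix()` converts per-pair
  saturation into `NA` with a warning; downstream consumers drop such
  pairs explicitly.
* **Ties are exact.** Distances are ratios of integer site counts, so
  two library sequences tie for "best match" only when their distances
  are *exactly* equal in floating point; no epsilon is applied.
* Distances are kept in substitutions/site everywhere; percentages
  appear only in formatted report tables (×100, two decimals).

Every pair falls in exactly one partition category: same species + same
population (`intra_within_pop`), same species + different populations
(`intra_between_pop`), different species (`inter`). The genus of a
species label defaults to its first whitespace-delimited token, which is
what congeners are grouped by; a `genus` metadata column overrides this.
An empty population string is treated as one (unknown) population per
species.

## Identification protocols

All three protocols run *leave-one-out* ("single-sequence-omission"):
each sequence is queried against the library with itself removed, so a
species needs ≥ 2 sequences to be queryable (≥ 3 for ASB, which must
keep two conspecifics after omission). Excluded queries are reported,
never silently dropped.

* **BM (best match)** — the species of the nearest barcode(s). Tie set
  exactly `{truth}` → *correct*; > 1 species including the truth →
  *ambiguous*; truth absent → *incorrect*. (The last rule is the
  TaxonDNA-style convention; the outcome table records
  `n_best_species` and `truth_in_best` so the alternative reading is
  reconstructible.)
* **BCM (best close match)** — BM plus a similarity threshold: a query
  whose best match is farther than the threshold is *no_match*. The
  default threshold is the 95th percentile (linear interpolation) of
  pooled intraspecific distances.
* **ASB (all species barcodes)** — correct only if *every* remaining
  conspecific barcode outranks *every* heterospecific barcode;
  no_match when the nearest conspecific exceeds the threshold.

ASB-correct implies BCM-correct; BCM at a threshold at or above the
largest best-match distance reproduces BM verdict-for-verdict. Both are
property-tested.

### Threshold optimisation

BCM outcomes at a threshold are classified as TP (kept, correct), FP
(kept, ambiguous or incorrect), FN (discarded, best match conspecific),
TN (discarded otherwise), with accuracy `(TP+TN)/total`, precision
`TP/(TP+FP)`, overall ID error `(FP+FN)/total` and relative ID error
`FP/(TP+FP)`; the last two are `NA` when nothing is kept.
`threshold_sweep()` evaluates 30 thresholds, linearly spaced and
descending from the largest query-best-match distance (where nothing is
discarded) to 0 (where only exact matches survive). The spacing is a
choice — the source protocol says only "arbitrary thresholds" — and a
custom grid can be supplied. `adhoc_threshold()` fits OLS of relative
error on threshold and solves for the threshold with fitted error 0.05;
a negative solution (typical when even a 0 threshold leaves > 5%
relative error) is reported with `attainable = FALSE`, because a
negative distance threshold cannot be applied.

## BP neural network

A single-hidden-layer feed-forward network (one-hot encoded columns ×
20 sigmoid hidden units × one sigmoid output per species) trained by
per-sample stochastic gradient descent with momentum. The stated
hyperparameters are learning rate 0.2, momentum 0.5 and MSE training
goal 1e-5; the epoch cap (50000), hidden width, encoding and activation
are this package's choices — the original tool's internals are
unpublished — and are all exposed in `bp_config()`. The reference/query
split is stratified by species at ~1:1 (`ceiling(n/2)` per species to
the reference), guaranteeing every species has reference barcodes;
singleton species cannot be split and are excluded with a report. All
randomness (weight init, sample order, split) is derived from explicit
seeds; no function touches global RNG state. A correct prediction counts
toward the success rate even when its winning activation is below the
low-confidence cutoff (default 0.95); the flag is reported alongside.

## Haplotype networks

Identical sequences collapse into haplotypes (exact string match;
representative = lexicographically smallest member id, so the result is
record-order independent). Steps between haplotypes are pairwise-deletion
Hamming counts, consistent with the distance module. The network is a
*minimum-spanning network*: Kruskal-style construction that, within each
weight class, keeps every edge joining components that were distinct
before the class — co-minimal alternatives are retained so "subclades"
do not depend on arbitrary MST tie-breaking. A statistical-parsimony
style connection limit is available as an explicit `max_steps` cut
(default none); the probability-of-parsimony computation of TCS is
deliberately not reproduced — component structure, minimum cross-group
steps and shared haplotypes, the quantities actually read off such
networks, do not need it. One caveat: TCS-style "mutational steps" may
count paths through inferred intermediate haplotypes; for closely
related haplotypes the raw pairwise count used here coincides with it,
but exact equality with TCS output is not guaranteed.

## NJ tree and monophyly

`nj_tree()` is a from-scratch Saitou–Nei implementation with two stated
conventions: Q-matrix ties break by the lexicographically smallest pair
of cluster labels (reproducible, input-order invariant), and negative
branch lengths are clamped to zero with the deficit moved to the sister
branch (path lengths through the parent are preserved). On additive
matrices the reconstruction is exact — the core test oracle.
Nonparametric bootstrap resamples alignment columns with replacement;
support is the percentage of replicates containing each original
internal-edge bipartition, and replicates with an undefined pair
distance are dropped and counted. A label is monophyletic on the
unrooted tree iff some edge bipartitions the leaves exactly into
label-vs-rest; single-leaf labels are monophyletic by convention, and
violations report the smallest symmetric difference between the label
set and any bipartition side.

## The synthetic stated world

`simulate_library()` evolves sequences under the K80 process
(closed-form per-site transition probabilities, κ = 2) on a star design:
common root → species ancestors (at `inter_target/2` each, so pairwise
species divergence ≈ `inter_target` = 0.06) → population ancestors
(`intra_between_pop_target/2`, default target 0.02) → individuals
(`intra_within_pop_target/2`, default target 0.005). The defaults encode
the survey pattern the package targets: within-population variation
< 1%, between-population variation < 3%, interspecific divergence of
several percent at 658 bp. Each individual carries another population's
haplotype with probability 0.1, creating the cross-population sharing
seen in real haplotype networks. An `oversplit_map` assigns distinct
nominal species labels to the populations of one true species; for
mapped species at least one cross-population copy is guaranteed, so
cross-*label* haplotype sharing — the constructed signature of
oversplitting — is present by design, not by luck of the draw.

A star phylogeny (rather than a coalescent) is used deliberately: the
quantities under test are distance summaries, which the star design
controls directly. What a green test therefore establishes: the
arithmetic of gap/overlap, the verdict logic, threshold behaviour,
monophyly and sharing detection are correct *given* well-separated or
oversplit clusters. What it does not establish: behaviour under
incomplete lineage sorting, rate variation across sites or lineages,
indels, or numts — none of which the generator emulates.

## Known limitations

* Real-data headline rates (e.g. ~92% BM correct on the original
  432-sequence grasshopper set) are not asserted anywhere: they require
  the deposited specimen alignment, and the BP figure additionally
  depends on an unpublished encoding. The package reproduces the
  *patterns* (errors confined to oversplit groups, unattainable ad hoc
  threshold when relative error exceeds 5% at threshold 0) on synthetic
  ground truth.
* The numt screen is translation-only (reading frame chosen per library
  as the frame minimising total stops; invertebrate mitochondrial code);
  the original BLAST screen against nr/nt needs network access.
* Distances other than K2P, median-joining networks with inferred
  median vectors, and parsimony/Bayesian tree inference are out of
  scope.

## A worked run

```{r, eval = FALSE}
sim <- simulate_library(sim_config(seed = 7))
res <- run_pipeline(sim$library, out_dir = "results_demo", seed = 7)
print(res)
```

See the README for the output this prints and how to read it.
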