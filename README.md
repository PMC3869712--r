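# barcodetools

Tools for DNA-barcode species identification and species-boundary
delimitation over aligned COI libraries (the standard 658-bp Folmer
fragment), aimed at taxonomists and molecular ecologists who need to ask
two questions of a barcode reference library: *does a barcode gap exist*,
and *when identification fails, is the taxonomy or the marker to blame?*

The package implements the full analysis chain:

- **K2P distances** with pairwise deletion:
  `d = -½ ln(1−2P−Q) − ¼ ln(1−2Q)` with transition proportion `P` and
  transversion proportion `Q`, partitioned into within-population /
  between-population / interspecific classes, with barcode-gap /
  overlap analysis and the 95th-percentile intraspecific threshold.
- **Leave-one-out identification** under three protocols: best match
  (BM), best close match (BCM, thresholded) and all species barcodes
  (ASB, every conspecific must outrank every heterospecific), with a
  TP/FP/TN/FN sweep over 30 distance thresholds and an *ad hoc*
  threshold solving the fitted relative identification error
  `FP/(TP+FP)` for 0.05 by linear regression.
- **A back-propagation neural network** classifier (one-hot columns,
  one hidden layer, per-sample SGD with momentum; learning rate 0.2,
  momentum 0.5, MSE goal 1e-5) on a stratified ~1:1 reference/query
  split.
- **Haplotype networks**: exact-match haplotype collapsing,
  minimum-spanning networks with co-minimal tie edges retained,
  mutational-step counts between groups, shared-haplotype reports, and
  an optional connection limit that splits the network into clades.
- **Neighbor-joining trees** from the K2P matrix (exact on additive
  input), nonparametric bootstrap over alignment columns, and unrooted
  monophyly assessment per species label.
- **A seeded synthetic-library generator** (K80 process on a star
  design) with known ground truth, including taxonomic *oversplitting*
  scenarios where several nominal labels sit on one biological species.
- A translation-based **numt screen** (stop codons under the
  invertebrate mitochondrial code, library-wide reading frame).

## Worked example

Simulate a well-behaved library — 6 species × 2 populations × 5
individuals at the default targets (within-population K2P ≈ 0.5%,
between-population ≈ 2%, interspecific ≈ 6%) — and run the pipeline:

```r
library(barcodetools)
sim <- simulate_library(sim_config(seed = 7))
res <- run_pipeline(sim$library, seed = 7)
print(res)
```

```
pipeline_result
barcode gap: 2.45% (from 4.06% to 6.51%)
threshold: 0.0342
BM identification (threshold none): 60 queries
   verdict  n pct
   correct 60 100
 ambiguous  0   0
 incorrect  0   0
  no_match  0   0
...
monophyletic labels: 6 of 6
```

All intraspecific variation stays below 4.06%, the smallest
interspecific divergence is 6.51% — a barcode gap of 2.45% — so every
leave-one-out query identifies correctly at the 95th-percentile
threshold (3.42%) and every species is monophyletic on the NJ tree.

Now put three nominal species labels on one biological species (the
oversplitting pattern):

```r
cfg <- sim_config(populations_per_species = c(3, rep(2L, 5)),
                  oversplit_map = list(species_01 = c("nomA", "nomB", "nomC")),
                  seed = 11)
res2 <- run_pipeline(simulate_library(cfg)$library, seed = 11)
print(res2$gap)
print(res2$identification$bcm)
```

```
overlap: 0.00% to 3.60% (no barcode gap)
BCM identification (threshold 0.0332): 65 queries
   verdict  n   pct
   correct 59 90.77
 ambiguous  4  6.15
 incorrect  2  3.08
  no_match  0  0.00
```

The "interspecific" divergences between nomA/nomB/nomC are really
intraspecific variation, so the distributions overlap from 0% (the
oversplit labels share a haplotype) to 3.60%, and every ambiguous or
incorrect verdict involves an oversplit label — the diagnostic signature
that the errors come from the taxonomy, not the marker. The monophyly
report flags the same labels, and
`shared_haplotypes(collapse_haplotypes(lib), "species")` lists the
haplotype carried by more than one nominal species.

Key entry points if you bring your own data:
`read_library("aln.fasta", "meta.tsv")` (TSV columns
`seq_id  species  population  locality`), then `k2p_matrix()`,
`partition_distances()`, `gap_analysis()`, `bm_identify()` /
`bcm_identify()` / `asb_identify()`, `threshold_sweep()` +
`adhoc_threshold()`, `bp_train()` + `bp_classify()`,
`build_network()`, `nj_bootstrap()`, `monophyly_report()`. A thin CLI
lives at `inst/cli/barcodetools.R` (`simulate`, `run`, `identify`
subcommands).

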