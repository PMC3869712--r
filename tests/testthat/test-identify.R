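# Toy libraries with hand-checkable rank lists, plus oracle equivalence
# on random libraries. The brute-force oracle lives in helper-fixtures.R.

two_species_lib <- function(L = 120, per_species = 5, seed = 2) {
  set.seed(seed)
  base <- rand_seq(L)
  anc1 <- base
  anc2 <- mutate_sites(base, 1:10, "tv")
  seqs <- c(vapply(seq_len(per_species), function(i)
    mutate_sites(anc1, 20 + i, "ts"), character(1)),
    vapply(seq_len(per_species), function(i)
      mutate_sites(anc2, 40 + i, "ts"), character(1)))
  make_lib(seqs, rep(c("spA", "spB"), each = per_species))
}

test_that("best_match finds the nearest barcode under leave-one-out", {
  set.seed(5)
  base <- rand_seq(100)
  # q1 identical to q2 (conspecific): distance 0, own species
  seqs <- c(base, base, mutate_sites(base, 1:6, "tv"))
  lib <- make_lib(seqs, c("spA", "spA", "spB"))
  dm <- k2p_matrix(lib)
  bm <- best_match("q01", dm, lib$meta)
  expect_equal(bm$best_distance, 0)
  expect_equal(bm$best_match_species, "spA")
  expect_equal(bm$ranked$id[1], "q02")

  # equidistant tie between a conspecific and a heterospecific
  seqs2 <- c(base, mutate_sites(base, 1, "ts"), mutate_sites(base, 2, "ts"))
  lib2 <- make_lib(seqs2, c("spA", "spA", "spB"))
  bm2 <- best_match("q01", k2p_matrix(lib2), lib2$meta)
  expect_equal(bm2$best_match_species, c("spA", "spB"))

  # random library: minimum equals brute-force scan
  lib3 <- random_library(n = 10, seed = 17)
  dm3 <- k2p_matrix(lib3)
  d3 <- oracle_dist_matrix(lib3)
  for (q in names(lib3$seq)) {
    others <- setdiff(names(lib3$seq), q)
    expect_equal(best_match(q, dm3, lib3$meta)$best_distance,
                 min(d3[q, others]), tolerance = 1e-12)
  }
})

test_that("BM: well-separated species identify perfectly, shared haplotypes tie", {
  lib <- two_species_lib()
  res <- bm_identify(lib)
  expect_equal(nrow(res$outcomes), 10)
  expect_true(all(res$outcomes$verdict == "correct"))
  expect_equal(res$summary$pct[res$summary$verdict == "correct"], 100)

  # a haplotype carried by both species: a query holding it ties at
  # distance 0 with a conspecific and a heterospecific copy -> ambiguous
  set.seed(6)
  base <- rand_seq(100)
  shared <- mutate_sites(base, 1:2, "ts")
  seqs <- c(shared, shared, shared, shared)
  lib2 <- make_lib(seqs, c("spA", "spA", "spB", "spB"))
  res2 <- bm_identify(lib2)
  v <- setNames(res2$outcomes$verdict, res2$outcomes$query_id)
  expect_equal(unname(v["q01"]), "ambiguous")
  expect_equal(unname(v["q03"]), "ambiguous")
})

test_that("species with a single sequence are excluded and reported", {
  lib <- two_species_lib(per_species = 3)
  meta <- lib$meta
  meta$species[6] <- "singleton"
  lib2 <- barcode_library(lib$seq, meta)
  res <- bm_identify(lib2)
  expect_equal(res$excluded, "q06")
  expect_equal(nrow(res$outcomes), 5)
})

test_that("BCM applies the distance threshold", {
  lib <- two_species_lib()
  dm <- k2p_matrix(lib)
  # any query whose nearest neighbour exceeds the threshold -> no_match
  res0 <- bcm_identify(lib, threshold = 1e-6, dm = dm)
  expect_true(all(res0$outcomes$verdict == "no_match"))

  # threshold beyond all best distances: BCM == BM verdict-for-verdict
  bm <- bm_identify(lib, dm)
  bcm <- bcm_identify(lib, threshold = Inf, dm = dm)
  expect_equal(bcm$outcomes$verdict, bm$outcomes$verdict)

  # negative threshold rejected
  expect_error(bcm_identify(lib, threshold = -0.01, dm = dm), "threshold")
})

test_that("ASB requires all conspecifics ahead of every heterospecific", {
  # 6-sequence toy, hand-built rank lists (L = 100 so distances are
  # monotone in the number of substitutions)
  set.seed(12)
  base <- rand_seq(100)
  seqs <- c(base,                              # a1
            mutate_sites(base, 1, "ts"),       # a2: 1 step from a1
            mutate_sites(base, c(1, 2), "ts"), # a3: 2 steps from a1
            mutate_sites(base, 50:54, "tv"),   # b1: far from all a
            mutate_sites(base, 50:55, "tv"),   # b2
            mutate_sites(base, 50:56, "tv"))   # b3
  lib <- make_lib(seqs, rep(c("spA", "spB"), each = 3))
  res <- asb_identify(lib, threshold = 0.5)
  expect_true(all(res$outcomes$verdict == "correct"))

  # interleave a heterospecific barcode among the conspecifics:
  # for query a1, b_near sits closer than a3
  seqs2 <- seqs
  seqs2[4] <- mutate_sites(base, c(1, 3), "ts")   # b1 now 2 steps from a1
  lib2 <- make_lib(seqs2, rep(c("spA", "spB"), each = 3))
  res2 <- asb_identify(lib2, threshold = 0.5)
  v <- setNames(res2$outcomes$verdict, res2$outcomes$query_id)
  expect_equal(unname(v["q01"]), "ambiguous")

  # nearest conspecific beyond the threshold -> no_match
  res3 <- asb_identify(lib, threshold = 1e-6)
  expect_true(all(res3$outcomes$verdict == "no_match"))

  # species with < 3 sequences are excluded from ASB queries
  lib3 <- make_lib(seqs[1:5], c("spA", "spA", "spA", "spB", "spB"))
  res4 <- asb_identify(lib3, threshold = 0.5)
  expect_setequal(res4$excluded, c("q04", "q05"))
})

test_that("protocols agree with the brute-force oracle on random libraries", {
  # scaled-down version of the acceptance sweep (full run in
  # test-acceptance.R): 40 random 15-sequence libraries
  for (s in 1:40) {
    lib <- random_library(n = 15, L = 120, n_species = 4, seed = s)
    dm <- k2p_matrix(lib)
    d <- dm$d
    thr <- 0.02
    expect_equal(setNames(bm_identify(lib, dm)$outcomes$verdict,
                          bm_identify(lib, dm)$outcomes$query_id),
                 oracle_identify(lib, d, "bm"), info = paste("seed", s))
    expect_equal(setNames(bcm_identify(lib, thr, dm)$outcomes$verdict,
                          bcm_identify(lib, thr, dm)$outcomes$query_id),
                 oracle_identify(lib, d, "bcm", thr),
                 info = paste("seed", s))
    expect_equal(setNames(asb_identify(lib, thr, dm)$outcomes$verdict,
                          asb_identify(lib, thr, dm)$outcomes$query_id),
                 oracle_identify(lib, d, "asb", thr),
                 info = paste("seed", s))
  }
})

test_that("ASB-correct implies BCM-correct; verdicts invariant to record order", {
  for (s in 1:10) {
    lib <- random_library(n = 12, L = 120, n_species = 3, seed = s + 50)
    dm <- k2p_matrix(lib)
    thr <- 0.03
    bcm <- bcm_identify(lib, thr, dm)$outcomes
    asb <- asb_identify(lib, thr, dm)$outcomes
    common <- intersect(asb$query_id, bcm$query_id)
    asb_correct <- asb$query_id[asb$verdict == "correct"]
    bcm_v <- setNames(bcm$verdict, bcm$query_id)
    expect_true(all(bcm_v[intersect(asb_correct, common)] == "correct"))

    # permuting the records never changes a verdict
    set.seed(s)
    ord <- sample(length(lib$seq))
    lib_p <- barcode_library(lib$seq[ord], lib$meta[ord, ])
    bcm_p <- bcm_identify(lib_p, thr)$outcomes
    expect_equal(setNames(bcm_p$verdict, bcm_p$query_id)[bcm$query_id],
                 bcm_v)
  }
})
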