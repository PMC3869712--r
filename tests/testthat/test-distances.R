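test_that("k2p matches the closed-form Kimura formula", {
  L <- 100
  set.seed(3)
  a <- rand_seq(L)
  # identity
  r0 <- k2p(a, a)
  expect_equal(r0$P, 0)
  expect_equal(r0$Q, 0)
  expect_identical(r0$d, 0)
  expect_equal(r0$sites_compared, L)

  # 10 transitions, no transversions: d = -0.5 log(0.8)
  b <- mutate_sites(a, 1:10, "ts")
  r1 <- k2p(a, b)
  expect_equal(r1$P, 0.10)
  expect_equal(r1$Q, 0)
  expect_equal(r1$d, -0.5 * log(0.8), tolerance = 1e-12)
  expect_equal(r1$d, 0.11157, tolerance = 1e-4)

  # 10 transversions, no transitions: d = -0.5 log(1-0.1) - 0.25 log(1-0.2)
  ctv <- mutate_sites(a, 1:10, "tv")
  r2 <- k2p(a, ctv)
  expect_equal(r2$P, 0)
  expect_equal(r2$Q, 0.10)
  expect_equal(r2$d, -0.5 * log(0.9) - 0.25 * log(0.8), tolerance = 1e-12)
})

test_that("k2p agrees with the character-level oracle on random pairs", {
  set.seed(11)
  for (i in 1:25) {
    a <- rand_seq(200)
    b <- mutate_sites(mutate_sites(a, sample(200, sample(5:25, 1)), "ts"),
                      sample(200, sample(0:15, 1)), "tv")
    expect_equal(k2p(a, b)$d, oracle_k2p(a, b), tolerance = 1e-12)
  }
})

test_that("k2p agrees with ape::dist.dna K80 under pairwise deletion", {
  lib <- random_library(n = 8, L = 300, seed = 5)
  dm <- k2p_matrix(lib)
  bin <- ape::as.DNAbin(t(sapply(lib$seq, function(s) strsplit(s, "")[[1]])))
  ref <- as.matrix(ape::dist.dna(bin, model = "K80",
                                 pairwise.deletion = TRUE))
  expect_equal(unname(dm$d), unname(ref[dm$ids, dm$ids]), tolerance = 1e-10)
})

test_that("pairwise deletion and saturation handling", {
  a <- "ACGTACGTAC"
  b <- "ACGTACGTAC"
  # identical gap columns inserted in both sequences leave d unchanged
  a2 <- paste0("AC--GTACGTAC")
  b2 <- paste0("AC--GTACGTAC")
  expect_equal(k2p(a2, b2)$d, k2p(a, b)$d)
  expect_equal(k2p(a2, b2)$sites_compared, 10)

  # N in one sequence removes the column from comparison
  expect_equal(k2p("ANGT", "AAGT")$sites_compared, 3)
  expect_equal(k2p("ANGT", "AAGT")$d, 0)

  # zero comparable sites
  expect_error(k2p("NNNN", "ACGT"), "zero comparable")
  # saturation: P = 0.5, Q = 0 -> 1 - 2P - Q = 0
  sat_a <- strrep("A", 10)
  sat_b <- paste0(strrep("G", 5), strrep("A", 5))
  expect_error(k2p(sat_a, sat_b), "saturation")
})

test_that("small-distance limit: d ~ P + Q to first order", {
  set.seed(9)
  for (i in 1:10) {
    a <- rand_seq(1000)
    n_mut <- sample(2:10, 1)  # P + Q <= 0.01
    b <- mutate_sites(a, sample(1000, n_mut),
                      sample(c("ts", "tv"), 1))
    r <- k2p(a, b)
    expect_equal(r$d, r$P + r$Q, tolerance = 0.05)
  }
})

test_that("distance matrix is symmetric with zero diagonal", {
  lib <- make_lib(rep(rand_seq(50), 3), rep("sp1", 3))
  dm0 <- k2p_matrix(lib)
  expect_true(all(dm0$d == 0))

  lib2 <- random_library(n = 10, seed = 2)
  dm <- k2p_matrix(lib2)
  expect_identical(dm$d, t(dm$d))
  expect_true(all(diag(dm$d) == 0))
  expect_equal(unname(dm$d), unname(oracle_dist_matrix(lib2)),
               tolerance = 1e-12)
})

test_that("partition assigns every pair to exactly one category", {
  # 2 species x 2 sequences -> 2 intra + 4 inter
  set.seed(4)
  base <- rand_seq(100)
  seqs <- c(base, mutate_sites(base, 1:2, "ts"),
            mutate_sites(base, 11:22, "tv"),
            mutate_sites(base, c(11:22, 30), "tv"))
  lib <- make_lib(seqs, c("sp1", "sp1", "sp2", "sp2"))
  part <- partition_distances(k2p_matrix(lib), lib$meta)
  expect_equal(sum(part$category == "intra_within_pop"), 2)
  expect_equal(sum(part$category == "inter"), 4)

  # one species, two populations of 2 -> 2 within + 4 between, 0 inter
  lib2 <- make_lib(seqs, rep("sp1", 4), population = c("p1", "p1", "p2", "p2"))
  part2 <- partition_distances(k2p_matrix(lib2), lib2$meta)
  expect_equal(sum(part2$category == "intra_within_pop"), 2)
  expect_equal(sum(part2$category == "intra_between_pop"), 4)
  expect_equal(sum(part2$category == "inter"), 0)

  # property: disjoint and exhaustive under random labelings
  for (s in 1:5) {
    lib3 <- random_library(n = 12, seed = s)
    meta <- lib3$meta
    set.seed(s + 100)
    meta$population <- sample(c("p1", "p2", ""), 12, replace = TRUE)
    part3 <- partition_distances(k2p_matrix(lib3), meta)
    expect_equal(nrow(part3), 12 * 11 / 2)
    expect_true(all(part3$category %in%
                      c("intra_within_pop", "intra_between_pop", "inter")))
  }
})

test_that("congeneric annotation uses the genus token", {
  set.seed(31)
  base <- rand_seq(60)
  seqs <- c(base, mutate_sites(base, 1:3, "ts"),
            mutate_sites(base, 10:15, "tv"))
  lib <- make_lib(seqs, c("Oedaleus decorus", "Oedaleus asiaticus",
                          "Calliptamus italicus"))
  part <- partition_distances(k2p_matrix(lib), lib$meta)
  cong <- part$congeneric[part$species1 == "Oedaleus decorus" &
                            part$species2 == "Oedaleus asiaticus"]
  expect_true(cong)
  expect_equal(sum(part$congeneric), 1)
})

test_that("gap analysis reports overlap and gap width correctly", {
  # constructed multisets with a conspicuous gap:
  # intra {0.002, 0.006}, inter {0.015, 0.018} -> gap 0.009
  fake_part <- data.frame(
    id1 = letters[1:4], id2 = LETTERS[1:4],
    species1 = "x", species2 = "y", population1 = "", population2 = "",
    distance = c(0.002, 0.006, 0.015, 0.018),
    category = c("intra_within_pop", "intra_between_pop", "inter", "inter"),
    congeneric = FALSE)
  class(fake_part) <- c("distance_partition", "data.frame")
  g <- gap_analysis(fake_part)
  expect_null(g$overlap)
  expect_equal(g$gap_width, 0.009)
  expect_equal(g$max_intra, 0.006)
  expect_equal(g$min_inter, 0.015)

  # boundary: max intra == min inter -> zero-width overlap interval
  fake_part$distance <- c(0.002, 0.015, 0.015, 0.018)
  g2 <- gap_analysis(fake_part)
  expect_equal(g2$overlap, c(0.015, 0.015))
  expect_equal(g2$gap_width, 0)

  # random multisets: endpoints equal brute-force min/max
  set.seed(21)
  for (i in 1:10) {
    d <- runif(10, 0, 0.1)
    fp <- fake_part[rep(1, 10), ]
    fp$distance <- d
    fp$category <- sample(c("intra_within_pop", "inter"), 10, replace = TRUE,
                          prob = c(0.5, 0.5))
    if (!any(fp$category == "inter") ||
        !any(fp$category == "intra_within_pop")) next
    g3 <- gap_analysis(fp)
    expect_equal(g3$max_intra, max(d[fp$category != "inter"]))
    expect_equal(g3$min_inter, min(d[fp$category == "inter"]))
  }

  # empty category errors
  fake_part$category <- "inter"
  expect_error(gap_analysis(fake_part), "intra")
})

test_that("intraspecific percentile threshold interpolates linearly", {
  mk <- function(d) {
    fp <- data.frame(id1 = "a", id2 = "b", species1 = "x", species2 = "x",
                     population1 = "", population2 = "",
                     distance = d, category = "intra_within_pop",
                     congeneric = FALSE)
    class(fp) <- c("distance_partition", "data.frame")
    fp
  }
  # constructed so order statistic 20 of 21 (h = 0.95*(n-1)+1) is 0.02
  expect_equal(intra_percentile_threshold(
    mk(c(seq(0, 0.02, length.out = 20), 0.03))), 0.02, tolerance = 1e-9)
  # all-zero distances -> threshold 0
  expect_equal(intra_percentile_threshold(mk(rep(0, 5))), 0)
  # large uniform sample: ~ q * upper bound
  set.seed(8)
  expect_equal(intra_percentile_threshold(mk(runif(1000, 0, 0.03))),
               0.0285, tolerance = 0.02)
  # matches sort-and-index oracle
  d <- runif(57, 0, 0.05)
  q <- intra_percentile_threshold(mk(d))
  expect_equal(q, unname(quantile(d, 0.95, type = 7)))
})

test_that("distance exports round-trip (square TSV) and emit PHYLIP triangles", {
  lib <- random_library(n = 5, seed = 6)
  dm <- k2p_matrix(lib)
  f_tsv <- tempfile(); f_phy <- tempfile()
  write_distances(dm, f_tsv, "tsv")
  back <- as.matrix(read.delim(f_tsv, row.names = 1))
  expect_equal(unname(back), unname(dm$d), tolerance = 1e-12)
  write_distances(dm, f_phy, "phylip")
  lines <- readLines(f_phy)
  expect_equal(lines[1], "5")
  expect_equal(length(lines), 6)
  last <- strsplit(lines[6], "\t")[[1]]
  expect_equal(as.numeric(last[last != "" & !grepl("q", last)]),
               unname(dm$d[5, 1:4]), tolerance = 1e-4)  # printed precision
})
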