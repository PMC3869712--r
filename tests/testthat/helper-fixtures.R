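# Fixture builders and independent oracles used across test files.
# Oracles deliberately use naive character-level implementations that
# share no code with the package's vectorised paths.

BASES <- c("A", "C", "G", "T")

rand_seq <- function(L) paste(sample(BASES, L, replace = TRUE), collapse = "")

# substitute given positions; mode "ts" = transition, "tv" = transversion
mutate_sites <- function(seq, pos, mode = "ts") {
  ch <- strsplit(seq, "")[[1]]
  ts_map <- c(A = "G", G = "A", C = "T", T = "C")
  tv_map <- c(A = "C", G = "T", C = "A", T = "G")
  ch[pos] <- if (mode == "ts") ts_map[ch[pos]] else tv_map[ch[pos]]
  paste(ch, collapse = "")
}

make_lib <- function(seqs, species, population = NULL, ids = NULL) {
  ids <- ids %||% sprintf("q%02d", seq_along(seqs))
  names(seqs) <- ids
  barcode_library(seqs, data.frame(
    seq_id = ids, species = species,
    population = population %||% rep("", length(seqs)),
    locality = ""))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# random library: n sequences derived from per-species ancestors so that
# species differ but some pairs can tie; labels round-robin
random_library <- function(n = 15, L = 120, n_species = 4, seed = 1) {
  set.seed(seed)
  base <- rand_seq(L)
  anc <- lapply(seq_len(n_species), function(s)
    mutate_sites(base, sample(L, 6), "tv"))
  sp_idx <- rep_len(seq_len(n_species), n)
  seqs <- vapply(sp_idx, function(s) {
    k <- sample(0:3, 1)
    if (k == 0) anc[[s]] else mutate_sites(anc[[s]], sample(L, k), "ts")
  }, character(1))
  make_lib(seqs, sprintf("sp%02d", sp_idx))
}

# ---- independent oracles ------------------------------------------------

# K2P from raw character comparison
oracle_k2p <- function(a, b) {
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  ts <- 0L; tv <- 0L; s <- 0L
  pur <- c("A", "G")
  for (i in seq_along(ca)) {
    if (ca[i] %in% BASES && cb[i] %in% BASES) {
      s <- s + 1L
      if (ca[i] != cb[i]) {
        if ((ca[i] %in% pur) == (cb[i] %in% pur)) ts <- ts + 1L
        else tv <- tv + 1L
      }
    }
  }
  P <- ts / s; Q <- tv / s
  -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
}

oracle_dist_matrix <- function(lib) {
  ids <- names(lib$seq)
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    d[i, j] <- d[j, i] <- oracle_k2p(lib$seq[[i]], lib$seq[[j]])
  d
}

# exhaustive rank-list identification, one protocol at a time
oracle_identify <- function(lib, d, protocol, threshold = Inf) {
  meta <- lib$meta
  min_size <- if (protocol == "asb") 3L else 2L
  tab <- table(meta$species)
  queries <- meta$seq_id[meta$species %in% names(tab)[tab >= min_size]]
  verdicts <- character(0)
  for (q in queries) {
    truth <- meta$species[meta$seq_id == q]
    others <- setdiff(meta$seq_id, q)
    dist <- d[q, others]
    sp <- meta$species[match(others, meta$seq_id)]
    best <- min(dist)
    best_sp <- sort(unique(sp[dist == best]))
    bm_v <- if (identical(best_sp, truth)) "correct"
    else if (truth %in% best_sp) "ambiguous" else "incorrect"
    v <- switch(protocol,
      bm = bm_v,
      bcm = if (best > threshold) "no_match" else bm_v,
      asb = {
        consp <- dist[sp == truth]
        het <- dist[sp != truth]
        if (min(consp) > threshold) "no_match"
        else if (!truth %in% best_sp) "incorrect"
        else if (any(het <= max(consp))) "ambiguous"
        else "correct"
      })
    verdicts[q] <- v
  }
  verdicts
}

# additive distance matrix from a random binary tree; returns matrix and
# the ape tree used to build it
random_additive <- function(n_taxa, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_taxa, rooted = FALSE,
                   br = function(k) runif(k, 0.5, 2))
  tr$tip.label <- sort(tr$tip.label)
  list(tree = tr, d = cophenetic(tr)[sort(tr$tip.label), sort(tr$tip.label)])
}

same_topology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2)) == 0
}
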