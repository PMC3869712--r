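# Neighbor-joining on the K2P matrix, nonparametric bootstrap over
# alignment columns, and unrooted monophyly assessment. Trees are
# returned as ape "phylo" objects so the usual toolchain (write.tree,
# plot.phylo, ...) applies directly.

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration by Q-matrix minimisation. Ties in Q
#' are broken by the lexicographically smallest pair of cluster labels
#' (the smallest leaf id in each cluster) so the result is reproducible
#' and independent of input order. Additive matrices are reconstructed
#' exactly. Negative branch lengths are clamped to zero with the deficit
#' moved to the sister branch, preserving the path length through the
#' parent node.
#'
#' @param dm a \code{\link{k2p_matrix}} result, or any list with
#'   \code{ids} and a symmetric numeric matrix \code{d}
#' @return an unrooted \code{ape::phylo} tree
#' @export
nj_tree <- function(dm) {
  d <- dm$d
  ids <- dm$ids
  n <- length(ids)
  if (n < 3L) stop("input error: neighbor-joining needs >= 3 taxa")
  if (any(!is.finite(d))) stop("input error: non-finite distances")
  # active clusters: newick fragment, tie-break label, working distances
  frag <- ids
  lab <- ids
  D <- d
  clamp <- function(b1, b2) {
    # negative length -> 0, deficit onto the sister branch
    if (b1 < 0) { b2 <- b2 + b1; b1 <- 0 }
    if (b2 < 0) { b1 <- max(0, b1 + b2); b2 <- 0 }
    c(b1, b2)
  }
  while (length(frag) > 3L) {
    r <- length(frag)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 0, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pair_lab <- apply(cand, 1, function(ij)
      paste(sort(c(lab[ij[1]], lab[ij[2]])), collapse = "\r"))
    pick <- cand[order(pair_lab)[1], ]
    i <- pick[1]; j <- pick[2]
    bi <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    bj <- D[i, j] - bi
    b <- clamp(bi, bj)
    new_frag <- sprintf("(%s:%.10g,%s:%.10g)", frag[i], b[1], frag[j], b[2])
    new_lab <- min(lab[i], lab[j])
    d_new <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], d_new[keep]),
               c(d_new[keep], 0))
    frag <- c(frag[keep], new_frag)
    lab <- c(lab[keep], new_lab)
  }
  # final three clusters: three-point formula
  b1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  b3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  b <- pmax(c(b1, b2, b3), 0)
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 frag[1], b[1], frag[2], b[2], frag[3], b[3])
  ape::read.tree(text = nwk)
}

# leaf-name sets of one side of every internal-edge bipartition
tree_bipartitions <- function(tree) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  sides <- lapply(pp, function(idx) labs[idx])
  # drop the trivial all-leaves part; keep clades of size 2..n-2 plus
  # their complements implicitly (callers compare against both sides)
  sides[lengths(sides) < length(labs)]
}

#' Neighbor-joining tree with nonparametric bootstrap support
#'
#' Alignment columns are resampled with replacement \code{n_reps} times;
#' each replicate gets its own K2P matrix and NJ tree, and the support of
#' each internal edge of the original tree is the percentage of
#' replicates containing the same leaf bipartition. Replicates in which
#' some pair has an undefined distance (no comparable sites, or
#' saturation) are dropped and counted.
#'
#' @param lib a \code{\link{barcode_library}}
#' @param n_reps bootstrap replicates (0 = tree without support values)
#' @param seed RNG seed; the whole run is reproducible under it
#' @param dm optional precomputed \code{\link{k2p_matrix}} of \code{lib}
#' @return an \code{ape::phylo} with integer node labels giving percent
#'   support (root label empty), plus attribute \code{dropped_replicates}.
#' @export
nj_bootstrap <- function(lib, n_reps = 1000L, seed = 1L, dm = NULL) {
  stopifnot(inherits(lib, "barcode_library"))
  dm <- dm %||% k2p_matrix(lib)
  tree <- nj_tree(dm)
  if (n_reps < 1L) return(tree)
  m <- seqs_to_int_matrix(lib$seq)
  ids <- names(lib$seq)
  rep_trees <- list()
  dropped <- 0L
  with_seed(seed, {
    for (b in seq_len(n_reps)) {
      cols <- sample.int(ncol(m), replace = TRUE)
      mb <- m[, cols, drop = FALSE]
      db <- tryCatch({
        n <- nrow(mb)
        dmat <- matrix(0, n, n, dimnames = list(ids, ids))
        for (jj in 2:n) for (ii in 1:(jj - 1)) {
          cnt <- k2p_counts(mb[ii, ], mb[jj, ])
          dmat[ii, jj] <- dmat[jj, ii] <- k2p_from_pq(cnt$P, cnt$Q)
        }
        dmat
      }, error = function(e) NULL)
      if (is.null(db)) { dropped <- dropped + 1L; next }
      tr <- tryCatch(nj_tree(list(ids = ids, d = db)),
                     error = function(e) NULL)
      if (is.null(tr)) { dropped <- dropped + 1L; next }
      rep_trees[[length(rep_trees) + 1L]] <- tr
    }
  })
  n_valid <- length(rep_trees)
  if (n_valid == 0L) {
    warning("all bootstrap replicates dropped; returning unsupported tree")
    return(tree)
  }
  key <- function(side, labs) {
    # canonical key: the side not containing the alphabetically first leaf
    if (sort(labs)[1] %in% side) side <- setdiff(labs, side)
    paste(sort(side), collapse = "\r")
  }
  labs <- tree$tip.label
  count <- new.env(parent = emptyenv())
  for (tr in rep_trees) {
    for (kk in unique(vapply(tree_bipartitions(tr), key, character(1),
                             labs = labs))) {
      assign(kk, get0(kk, envir = count, ifnotfound = 0L) + 1L,
             envir = count)
    }
  }
  pp <- ape::prop.part(tree)
  plabs <- attr(pp, "labels")
  support <- vapply(seq_along(pp), function(i) {
    side <- plabs[pp[[i]]]
    if (length(side) == length(plabs)) return(NA_real_)  # root
    100 * get0(key(side, labs), envir = count, ifnotfound = 0L) / n_valid
  }, numeric(1))
  tree$node.label <- ifelse(is.na(support), "", as.character(round(support)))
  attr(tree, "dropped_replicates") <- dropped
  attr(tree, "n_replicates") <- n_valid
  tree
}

#' Assess monophyly of a label on an unrooted tree
#'
#' A label set is monophyletic iff removing some edge bipartitions the
#' leaves exactly into the labelled set versus the rest. Single-leaf
#' labels (and a label covering every leaf) are monophyletic by
#' convention. When the label is not monophyletic the leaves in the
#' smallest symmetric difference between the label set and any
#' bipartition side are reported as violators.
#'
#' @param tree an \code{ape::phylo}
#' @param labels named character vector mapping every leaf to a label
#'   (e.g. species)
#' @param label_of_interest the label to test
#' @return list with \code{monophyletic}, \code{leaves} (the labelled
#'   leaf set) and \code{violators} (empty when monophyletic)
#' @export
monophyly <- function(tree, labels, label_of_interest) {
  leaves <- tree$tip.label
  if (!all(leaves %in% names(labels)))
    stop("input error: unlabeled leaves: ",
         paste(setdiff(leaves, names(labels)), collapse = ", "))
  target <- leaves[labels[leaves] == label_of_interest]
  if (!length(target))
    stop("input error: label absent from tree: ", label_of_interest)
  if (length(target) <= 1L || length(target) >= length(leaves) - 1L) {
    # 1 leaf (or complement of 1 leaf / all leaves): trivially one side
    # of a (possibly pendant) edge
    return(list(monophyletic = TRUE, leaves = target,
                violators = character(0)))
  }
  sides <- tree_bipartitions(tree)
  tset <- sort(target)
  best <- NULL
  for (side in sides) {
    for (s in list(side, setdiff(leaves, side))) {
      if (identical(sort(s), tset))
        return(list(monophyletic = TRUE, leaves = target,
                    violators = character(0)))
      sym <- union(setdiff(s, target), setdiff(target, s))
      if (is.null(best) || length(sym) < length(best)) best <- sym
    }
  }
  list(monophyletic = FALSE, leaves = target, violators = sort(best))
}

#' Monophyly report for every label
#'
#' @param tree an \code{ape::phylo}
#' @param labels named character vector mapping leaves to labels
#' @return data.frame: label, n_leaves, monophyletic, violators
#' @export
monophyly_report <- function(tree, labels) {
  out <- lapply(sort(unique(labels[tree$tip.label])), function(lab) {
    m <- monophyly(tree, labels, lab)
    data.frame(label = lab, n_leaves = length(m$leaves),
               monophyletic = m$monophyletic,
               violators = paste(m$violators, collapse = ";"),
               row.names = NULL)
  })
  do.call(rbind, out)
}
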