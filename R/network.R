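# Haplotype networks: mutational-step distances between haplotypes and a
# minimum-spanning network (MSN) over them. Statistical-parsimony style
# connection limits are available through an explicit max_steps cut; the
# quantities read off such networks for species-boundary work -- separate
# clades, minimum mutational steps between groups, shared haplotypes --
# are all computable from the step matrix and the MSN.

#' Pairwise mutational steps between haplotypes
#'
#' steps(i, j) = number of alignment columns where both haplotypes carry
#' an unambiguous base (A/C/G/T) and differ (Hamming count under pairwise
#' deletion), consistent with the site filtering of the distance module.
#'
#' @param hs a \code{\link{collapse_haplotypes}} result
#' @return symmetric integer matrix with haplotype representative ids as
#'   dimnames
#' @export
pairwise_steps <- function(hs) {
  stopifnot(inherits(hs, "haplotype_set"))
  m <- seqs_to_int_matrix(hs$seq)
  n <- nrow(m)
  steps <- matrix(0L, n, n, dimnames = list(rownames(m), rownames(m)))
  if (n < 2L) return(steps)
  for (j in 2:n) {
    for (i in 1:(j - 1)) {
      ok <- !is.na(m[i, ]) & !is.na(m[j, ])
      if (!any(ok))
        stop("zero comparable sites between haplotypes ",
             rownames(m)[i], " and ", rownames(m)[j])
      steps[i, j] <- steps[j, i] <- sum(m[i, ok] != m[j, ok])
    }
  }
  steps
}

#' Build a minimum-spanning haplotype network
#'
#' Kruskal-style construction processing edge weights in ascending order;
#' at each weight, every edge of that weight joining two components that
#' were distinct \emph{before} the weight class is retained, so co-minimal
#' alternative connections survive and "subclades" do not depend on
#' arbitrary spanning-tree tie-breaking. Edges longer than
#' \code{max_steps} are then removed, which may split the network into
#' separate clades.
#'
#' @param hs a \code{\link{collapse_haplotypes}} result
#' @param max_steps connection limit (default \code{Inf}: fully connected
#'   minimum-spanning network)
#' @return object of class \code{haplotype_network}: \code{nodes}
#'   (data.frame id/multiplicity/species/populations), \code{edges}
#'   (data.frame from/to/steps), \code{component} (named membership
#'   vector), \code{n_components}.
#' @export
build_network <- function(hs, max_steps = Inf) {
  stopifnot(inherits(hs, "haplotype_set"))
  steps <- pairwise_steps(hs)
  ids <- rownames(steps)
  n <- length(ids)
  if (n < 2L) stop("need >= 2 haplotypes")
  ut <- which(upper.tri(steps), arr.ind = TRUE)
  ew <- steps[ut]
  ord <- order(ew, ids[ut[, 1]], ids[ut[, 2]])
  comp <- seq_len(n)                      # union-find by relabelling
  keep <- logical(length(ew))
  for (w in sort(unique(ew))) {
    at <- which(ew == w)
    comp_before <- comp
    for (e in at) {
      i <- ut[e, 1]; j <- ut[e, 2]
      if (comp_before[i] != comp_before[j]) {
        keep[e] <- TRUE
        ci <- comp[i]; cj <- comp[j]
        if (ci != cj) comp[comp == cj] <- ci
      }
    }
  }
  edges <- data.frame(from = ids[ut[keep, 1]], to = ids[ut[keep, 2]],
                      steps = ew[keep], row.names = NULL)
  edges <- edges[edges$steps <= max_steps, , drop = FALSE]
  edges <- edges[order(edges$steps, edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = ids))
  memb <- igraph::components(g)$membership[ids]
  nodes <- data.frame(
    id = ids,
    multiplicity = unname(hs$multiplicity[ids]),
    species = vapply(hs$groups[ids], function(g)
      paste(sort(unique(g$species)), collapse = ";"), character(1)),
    populations = vapply(hs$groups[ids], function(g)
      paste(sort(unique(g$population)), collapse = ";"), character(1)),
    component = unname(memb),
    row.names = NULL)
  structure(list(nodes = nodes, edges = edges,
                 component = memb, n_components = max(memb),
                 max_steps = max_steps),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat("haplotype_network:", nrow(x$nodes), "haplotypes,",
      nrow(x$edges), "edges,", x$n_components, "component(s)\n")
  invisible(x)
}

#' Convert a haplotype network to an igraph object
#'
#' @param net a \code{\link{build_network}} result
#' @return an \code{igraph} graph with node attributes multiplicity,
#'   species, populations and edge attribute steps
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "haplotype_network"))
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = net$nodes)
}

#' Export a haplotype network
#'
#' Writes the edge list as TSV (hap_i, hap_j, steps) and, optionally, the
#' full graph with node attributes as GraphML.
#'
#' @param net a \code{\link{build_network}} result
#' @param edges_path TSV output path for the edge list
#' @param graphml_path optional GraphML output path
#' @return invisibly, \code{net}
#' @export
write_network <- function(net, edges_path, graphml_path = NULL) {
  stopifnot(inherits(net, "haplotype_network"))
  utils::write.table(net$edges, edges_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(graphml_path))
    igraph::write_graph(as_igraph(net), graphml_path, format = "graphml")
  invisible(net)
}

# haplotype ids having at least one member in a given group
haps_in_group <- function(hs, grouping, group) {
  col <- match.arg(grouping, c("species", "population"))
  hit <- vapply(hs$groups, function(g) group %in% g[[col]], logical(1))
  names(hs$seq)[hit]
}

#' Minimum mutational steps between two groups
#'
#' The minimum over all cross-group haplotype pairs of the pairwise step
#' count; groups sharing a haplotype are 0 steps apart.
#'
#' @param hs a \code{\link{collapse_haplotypes}} result
#' @param group_a,group_b group labels
#' @param grouping label type, \code{"species"} or \code{"population"}
#' @return integer step count
#' @export
min_steps_between <- function(hs, group_a, group_b, grouping = "species") {
  stopifnot(inherits(hs, "haplotype_set"))
  ha <- haps_in_group(hs, grouping, group_a)
  hb <- haps_in_group(hs, grouping, group_b)
  if (!length(ha)) stop("input error: unknown group label: ", group_a)
  if (!length(hb)) stop("input error: unknown group label: ", group_b)
  if (length(intersect(ha, hb))) return(0L)
  steps <- pairwise_steps(hs)
  min(steps[ha, hb, drop = FALSE])
}

#' Haplotypes shared across groups
#'
#' Lists each haplotype whose members span more than one group --
#' e.g. a haplotype carried by two nominal species, the classic signature
#' of oversplit taxa (or of incomplete lineage sorting).
#'
#' @param hs a \code{\link{collapse_haplotypes}} result
#' @param grouping \code{"species"} or \code{"population"}
#' @return data.frame with columns \code{haplotype}, \code{n_groups},
#'   \code{groups} (";"-joined), \code{multiplicity}; zero rows when no
#'   haplotype is shared.
#' @export
shared_haplotypes <- function(hs, grouping = "species") {
  stopifnot(inherits(hs, "haplotype_set"))
  col <- match.arg(grouping, c("species", "population"))
  glab <- lapply(hs$groups, function(g) sort(unique(g[[col]])))
  shared <- vapply(glab, length, integer(1)) > 1L
  data.frame(haplotype = names(hs$seq)[shared],
             n_groups = vapply(glab[shared], length, integer(1)),
             groups = vapply(glab[shared], paste, character(1),
                             collapse = ";"),
             multiplicity = unname(hs$multiplicity[shared]),
             row.names = NULL)
}
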