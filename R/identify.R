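# Leave-one-out species identification: BM, BCM and ASB protocols.
#
# All three protocols run "single-sequence-omission" simulations: each
# query is compared against the library with itself removed. BM assigns
# the species of the nearest barcode(s); BCM additionally requires the
# best match to lie within a distance threshold; ASB requires all
# conspecific barcodes to outrank every heterospecific barcode.

#' Best barcode match of a query under leave-one-out
#'
#' @param query_id id of the query sequence
#' @param dm a \code{\link{k2p_matrix}} result covering the query and the
#'   library
#' @param metadata data.frame with \code{seq_id} and \code{species}
#' @param depth number of ranked matches to return
#' @return list with \code{best_distance}, \code{best_match_species}
#'   (species labels tied at the exact minimal distance), and
#'   \code{ranked} (data.frame id/species/distance sorted by distance,
#'   ties broken by seq_id).
#' @export
best_match <- function(query_id, dm, metadata, depth = 10L) {
  stopifnot(inherits(dm, "k2p_dist"))
  if (!query_id %in% dm$ids) stop("unknown query id: ", query_id)
  lib_ids <- setdiff(dm$ids, query_id)
  if (!length(lib_ids)) stop("input error: empty library after omission")
  dist <- dm$d[query_id, lib_ids]
  if (anyNA(dist)) {
    lib_ids <- lib_ids[!is.na(dist)]
    dist <- dist[!is.na(dist)]
    if (!length(lib_ids)) stop("no defined distances for query ", query_id)
  }
  sp <- metadata$species[match(lib_ids, metadata$seq_id)]
  if (anyNA(sp)) stop("labeling error: no species for some library ids")
  ord <- order(dist, lib_ids)
  best_d <- unname(dist[ord[1]])
  tied <- dist == best_d          # exact equality: ties are rational coincidences
  list(best_distance = best_d,
       best_match_species = sort(unique(sp[tied])),
       ranked = data.frame(id = lib_ids[ord], species = sp[ord],
                           distance = unname(dist[ord]),
                           row.names = NULL)[seq_len(min(depth, length(ord))), ])
}

# Shared core: per-query best-match evidence for all queries of a library.
# A species is queryable when it has >= min_size members (so at least one
# conspecific remains after omission for min_size = 2).
loo_evidence <- function(lib, dm, min_size) {
  sp_tab <- table(lib$meta$species)
  ok_species <- names(sp_tab)[sp_tab >= min_size]
  queries <- lib$meta$seq_id[lib$meta$species %in% ok_species]
  excluded <- setdiff(lib$meta$seq_id, queries)
  ev <- lapply(queries, best_match, dm = dm, metadata = lib$meta)
  names(ev) <- queries
  list(queries = queries, excluded = excluded, evidence = ev)
}

bm_verdict <- function(truth, best_species) {
  if (identical(best_species, truth)) "correct"
  else if (truth %in% best_species) "ambiguous"   # tie including the truth
  else "incorrect"                                # truth absent from tie set
}

id_result <- function(outcomes, protocol, threshold, excluded, evidence) {
  counts <- table(factor(outcomes$verdict,
                         levels = c("correct", "ambiguous", "incorrect",
                                    "no_match")))
  summary <- data.frame(verdict = names(counts),
                        n = as.integer(counts),
                        pct = round(100 * as.integer(counts) /
                                      max(nrow(outcomes), 1L), 2))
  structure(list(outcomes = outcomes, summary = summary,
                 protocol = protocol, threshold = threshold,
                 n_queries = nrow(outcomes), excluded = excluded,
                 evidence = evidence),
            class = "id_result")
}

#' @export
print.id_result <- function(x, ...) {
  thr <- if (is.na(x$threshold)) "none" else sprintf("%.4f", x$threshold)
  cat(sprintf("%s identification (threshold %s): %d queries\n",
              toupper(x$protocol), thr, x$n_queries))
  print(x$summary, row.names = FALSE)
  if (length(x$excluded))
    cat("excluded (too few conspecifics):", length(x$excluded), "\n")
  invisible(x)
}

#' Best match (BM) identification
#'
#' Each query is assigned the species of its nearest library barcode(s),
#' with the query itself left out. Verdicts: \code{correct} when the tie
#' set at the minimal distance is exactly the query's species;
#' \code{ambiguous} when it contains the query's species among others;
#' \code{incorrect} when the query's species is absent. Species with
#' fewer than \code{min_species_size} sequences are excluded from the
#' query set (no conspecific would remain after omission) and reported.
#'
#' @param lib a \code{\link{barcode_library}}
#' @param dm optional precomputed \code{\link{k2p_matrix}}
#' @param min_species_size minimum sequences per queried species (>= 2)
#' @return an \code{id_result}: per-query outcome table, verdict summary
#'   with counts and percentages, excluded ids, and ranked-match evidence.
#' @export
bm_identify <- function(lib, dm = NULL, min_species_size = 2L) {
  dm <- dm %||% k2p_matrix(lib)
  lo <- loo_evidence(lib, dm, max(2L, min_species_size))
  truth <- lib$meta$species[match(lo$queries, lib$meta$seq_id)]
  rows <- mapply(function(q, tr, ev) {
    data.frame(query_id = q, protocol = "bm",
               verdict = bm_verdict(tr, ev$best_match_species),
               best_distance = ev$best_distance,
               best_species = paste(ev$best_match_species, collapse = ";"),
               n_best_species = length(ev$best_match_species),
               truth_in_best = tr %in% ev$best_match_species,
               row.names = NULL)
  }, lo$queries, truth, lo$evidence, SIMPLIFY = FALSE)
  id_result(do.call(rbind, rows), "bm", NA_real_, lo$excluded, lo$evidence)
}

#' Best close match (BCM) identification
#'
#' BM restricted to sufficiently similar matches: a query whose best
#' match lies beyond the threshold is \code{no_match}; otherwise BM
#' verdict rules apply. The default threshold is the 95th percentile of
#' the library's intraspecific distances
#' (\code{\link{intra_percentile_threshold}}).
#'
#' @inheritParams bm_identify
#' @param threshold distance threshold in substitutions/site, or
#'   \code{NULL} for the 95th-percentile default
#' @return an \code{id_result}
#' @export
bcm_identify <- function(lib, threshold = NULL, dm = NULL,
                         min_species_size = 2L) {
  dm <- dm %||% k2p_matrix(lib)
  if (is.null(threshold))
    threshold <- intra_percentile_threshold(partition_distances(dm, lib$meta))
  if (threshold < 0) stop("threshold must be >= 0")
  res <- bm_identify(lib, dm, min_species_size)
  out <- res$outcomes
  out$protocol <- "bcm"
  out$verdict[out$best_distance > threshold] <- "no_match"
  id_result(out, "bcm", threshold, res$excluded, res$evidence)
}

#' All species barcodes (ASB) identification
#'
#' The strictest protocol: a query is \code{correct} only when every one
#' of its remaining conspecific barcodes is closer than every
#' heterospecific barcode, i.e. the ranked match list starts with all
#' conspecifics. A query whose nearest conspecific lies beyond the
#' threshold is \code{no_match}. When a heterospecific barcode interleaves
#' among the conspecifics but the best-match set still contains the true
#' species the verdict is \code{ambiguous}; when the best-match set lacks
#' the true species it is \code{incorrect}. Queried species must retain at
#' least two barcodes after omission (i.e. hold >= 3 sequences); other
#' queries are excluded and reported.
#'
#' @inheritParams bcm_identify
#' @return an \code{id_result}
#' @export
asb_identify <- function(lib, threshold = NULL, dm = NULL) {
  dm <- dm %||% k2p_matrix(lib)
  if (is.null(threshold))
    threshold <- intra_percentile_threshold(partition_distances(dm, lib$meta))
  lo <- loo_evidence(lib, dm, 3L)
  truth <- lib$meta$species[match(lo$queries, lib$meta$seq_id)]
  rows <- mapply(function(q, tr, ev) {
    lib_ids <- setdiff(dm$ids, q)
    sp <- lib$meta$species[match(lib_ids, lib$meta$seq_id)]
    dist <- dm$d[q, lib_ids]
    keep <- !is.na(dist)
    sp <- sp[keep]; dist <- dist[keep]
    consp <- sp == tr
    verdict <- if (min(dist[consp]) > threshold) {
      "no_match"
    } else if (!tr %in% ev$best_match_species) {
      "incorrect"
    } else if (any(dist[!consp] <= max(dist[consp]))) {
      "ambiguous"
    } else {
      "correct"
    }
    data.frame(query_id = q, protocol = "asb", verdict = verdict,
               best_distance = ev$best_distance,
               best_species = paste(ev$best_match_species, collapse = ";"),
               n_best_species = length(ev$best_match_species),
               truth_in_best = tr %in% ev$best_match_species,
               row.names = NULL)
  }, lo$queries, truth, lo$evidence, SIMPLIFY = FALSE)
  id_result(do.call(rbind, rows), "asb", threshold, lo$excluded, lo$evidence)
}
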