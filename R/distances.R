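#' Kimura 2-parameter distance between two aligned sequences
#'
#' Sites where either sequence has a gap, N or another ambiguity code are
#' excluded (pairwise deletion). Over the remaining sites, \code{P} is the
#' proportion of transitions (A<->G, C<->T) and \code{Q} the proportion of
#' transversions; the distance is
#' \deqn{d = -\frac{1}{2}\log(1 - 2P - Q) - \frac{1}{4}\log(1 - 2Q).}
#'
#' @param a,b aligned sequences of equal length (character strings, or
#'   integer vectors as produced internally with A,C,G,T = 1..4).
#' @return list with elements \code{P}, \code{Q}, \code{sites_compared}
#'   and \code{d} (substitutions/site).
#' @section Errors: zero comparable sites is an error; so is saturation
#'   (\code{1-2P-Q <= 0} or \code{1-2Q <= 0}), where the K2P distance is
#'   undefined.
#' @export
k2p <- function(a, b) {
  ai <- if (is.character(a)) seq_to_int(a) else as.integer(a)
  bi <- if (is.character(b)) seq_to_int(b) else as.integer(b)
  if (length(ai) != length(bi)) stop("sequences must have equal length")
  cnt <- k2p_counts(ai, bi)
  d <- k2p_from_pq(cnt$P, cnt$Q)
  list(P = cnt$P, Q = cnt$Q, sites_compared = cnt$sites, d = d)
}

k2p_counts <- function(ai, bi) {
  ok <- !is.na(ai) & !is.na(bi)
  s <- sum(ok)
  if (s == 0L) stop("undefined distance: zero comparable sites")
  da <- ai[ok]; db <- bi[ok]
  ndiff <- sum(da != db)
  # transition iff both purines (A=1, G=3) or both pyrimidines (C=2, T=4)
  ts <- sum(da != db & (da %% 2L) == (db %% 2L))
  list(P = ts / s, Q = (ndiff - ts) / s, sites = s)
}

k2p_from_pq <- function(P, Q) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    stop("saturation: K2P distance undefined (P = ", signif(P, 4),
         ", Q = ", signif(Q, 4), ")")
  -0.5 * log(w1) - 0.25 * log(w2) + 0  # + 0 avoids returning negative zero
}

#' Pairwise K2P distance matrix for a library
#'
#' @param lib a \code{\link{barcode_library}}
#' @return object of class \code{k2p_dist}: list with \code{ids},
#'   symmetric matrix \code{d} (zero diagonal) and matrix \code{sites} of
#'   compared-site counts. Saturated pairs are set to \code{NA} with a
#'   warning and are excluded by downstream consumers.
#' @export
k2p_matrix <- function(lib) {
  stopifnot(inherits(lib, "barcode_library"))
  m <- seqs_to_int_matrix(lib$seq)
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 sequences for distances")
  ids <- names(lib$seq)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  sites <- matrix(nchar(lib$seq[[1]]), n, n, dimnames = list(ids, ids))
  bad <- character(0)
  for (j in 2:n) {
    for (i in 1:(j - 1)) {
      cnt <- k2p_counts(m[i, ], m[j, ])
      sites[i, j] <- sites[j, i] <- cnt$sites
      dij <- tryCatch(k2p_from_pq(cnt$P, cnt$Q), error = function(e) NA_real_)
      if (is.na(dij)) bad <- c(bad, paste0(ids[i], "/", ids[j]))
      d[i, j] <- d[j, i] <- dij
    }
  }
  if (length(bad))
    warning("saturated pairs excluded (distance set to NA): ",
            paste(bad, collapse = ", "))
  structure(list(ids = ids, d = d, sites = sites), class = "k2p_dist")
}

#' @export
print.k2p_dist <- function(x, ...) {
  off <- x$d[upper.tri(x$d)]
  cat("k2p_dist:", length(x$ids), "sequences; distance range ",
    sprintf("%.4f-%.4f", min(off, na.rm = TRUE), max(off, na.rm = TRUE)), "\n")
  invisible(x)
}

#' Export a distance matrix as TSV or PHYLIP lower triangle
#'
#' @param dm a \code{\link{k2p_matrix}} result
#' @param path output file
#' @param format \code{"tsv"} (square, with header) or \code{"phylip"}
#'   (taxon count line, then name + lower-triangle rows)
#' @return invisibly, \code{dm}
#' @export
write_distances <- function(dm, path, format = c("tsv", "phylip")) {
  stopifnot(inherits(dm, "k2p_dist"))
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(dm$d, path, sep = "\t", quote = FALSE,
                       col.names = NA)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    cat(length(dm$ids), "\n", sep = "", file = con)
    for (i in seq_along(dm$ids)) {
      cat(sprintf("%-10s", dm$ids[i]), file = con)
      if (i > 1)
        cat("\t", paste(sprintf("%.6f", dm$d[i, 1:(i - 1)]),
                        collapse = "\t"), sep = "", file = con)
      cat("\n", file = con)
    }
  }
  invisible(dm)
}

#' Partition pairwise distances by taxonomic category
#'
#' Every unordered pair of sequences falls in exactly one category:
#' \code{intra_within_pop} (same species, same population),
#' \code{intra_between_pop} (same species, different populations) or
#' \code{inter} (different species). Interspecific pairs are additionally
#' annotated as congeneric when the genus tokens of both species labels
#' agree (genus = first whitespace-delimited token, unless a
#' \code{genus} column is present in the metadata).
#'
#' @param dm a \code{\link{k2p_matrix}} result
#' @param metadata data.frame with \code{seq_id}, \code{species},
#'   \code{population} covering all matrix ids (a library's \code{$meta}).
#' @return data.frame (class \code{distance_partition}) with one row per
#'   pair: ids, labels, \code{distance}, \code{category}, \code{congeneric}.
#' @export
partition_distances <- function(dm, metadata) {
  stopifnot(inherits(dm, "k2p_dist"))
  idx <- match(dm$ids, metadata$seq_id)
  if (anyNA(idx))
    stop("labeling error: no metadata for ",
         paste(dm$ids[is.na(idx)], collapse = ", "))
  sp <- metadata$species[idx]
  pop <- metadata$population[idx]
  pop[is.na(pop)] <- ""
  gen <- if ("genus" %in% names(metadata)) metadata$genus[idx] else genus_of(sp)
  ut <- which(upper.tri(dm$d), arr.ind = TRUE)
  i <- ut[, 1]; j <- ut[, 2]
  dist <- dm$d[ut]
  cat_ <- ifelse(sp[i] == sp[j],
                 ifelse(pop[i] == pop[j], "intra_within_pop",
                        "intra_between_pop"),
                 "inter")
  out <- data.frame(id1 = dm$ids[i], id2 = dm$ids[j],
                    species1 = sp[i], species2 = sp[j],
                    population1 = pop[i], population2 = pop[j],
                    distance = dist,
                    category = cat_,
                    congeneric = cat_ == "inter" & gen[i] == gen[j],
                    row.names = NULL)
  if (anyNA(out$distance)) {
    warning("dropping ", sum(is.na(out$distance)), " saturated pair(s)")
    out <- out[!is.na(out$distance), , drop = FALSE]
  }
  class(out) <- c("distance_partition", "data.frame")
  out
}

intra_distances <- function(part) {
  part$distance[part$category %in% c("intra_within_pop", "intra_between_pop")]
}

#' Barcode gap / overlap analysis
#'
#' Compares the distribution of intraspecific variation (within- plus
#' between-population) with interspecific divergence. When the largest
#' intraspecific distance reaches or exceeds the smallest interspecific
#' distance the two distributions overlap on
#' \code{[min_inter, max_intra]}; otherwise there is a barcode gap of
#' width \code{min_inter - max_intra}.
#'
#' @param part a \code{\link{partition_distances}} result
#' @param bin_width histogram bin width in substitutions/site
#'   (default 0.005, i.e. 0.5\%)
#' @return list of class \code{gap_report}: \code{max_intra},
#'   \code{min_inter}, \code{overlap} (interval or NULL), \code{gap_width}
#'   (positive width or 0 when overlapping), \code{histogram} (data.frame
#'   of bin edges with intra/inter counts).
#' @export
gap_analysis <- function(part, bin_width = 0.005) {
  stopifnot(inherits(part, "distance_partition"))
  intra <- intra_distances(part)
  inter <- part$distance[part$category == "inter"]
  if (!length(intra)) stop("analysis error: empty category 'intra'")
  if (!length(inter)) stop("analysis error: empty category 'inter'")
  max_intra <- max(intra)
  min_inter <- min(inter)
  overlapping <- max_intra >= min_inter
  breaks <- seq(0, max(max_intra, max(inter)) + bin_width, by = bin_width)
  hh <- function(x) {
    b <- findInterval(x, breaks, rightmost.closed = TRUE)
    tabulate(b, nbins = length(breaks) - 1L)
  }
  hist_df <- data.frame(bin_low = breaks[-length(breaks)],
                        bin_high = breaks[-1],
                        intra = hh(intra), inter = hh(inter))
  structure(list(max_intra = max_intra,
                 min_inter = min_inter,
                 overlap = if (overlapping) c(min_inter, max_intra) else NULL,
                 gap_width = if (overlapping) 0 else min_inter - max_intra,
                 histogram = hist_df),
            class = "gap_report")
}

#' @export
print.gap_report <- function(x, ...) {
  if (is.null(x$overlap)) {
    cat(sprintf("barcode gap: %.2f%% (from %.2f%% to %.2f%%)\n",
                100 * x$gap_width, 100 * x$max_intra, 100 * x$min_inter))
  } else {
    cat(sprintf("overlap: %.2f%% to %.2f%% (no barcode gap)\n",
                100 * x$overlap[1], 100 * x$overlap[2]))
  }
  invisible(x)
}

#' Percentile threshold of pooled intraspecific distances
#'
#' The distance below which \code{q}\% of all intraspecific distances
#' fall, the standard data-driven threshold for best-close-match
#' identification (default the 95th percentile). Linear interpolation
#' between order statistics is used.
#'
#' @param part a \code{\link{partition_distances}} result
#' @param q percentile in (0, 100]
#' @return threshold in substitutions/site
#' @export
intra_percentile_threshold <- function(part, q = 95) {
  stopifnot(inherits(part, "distance_partition"))
  intra <- intra_distances(part)
  if (!length(intra)) stop("analysis error: no intraspecific distances")
  unname(stats::quantile(intra, q / 100, type = 7))
}
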