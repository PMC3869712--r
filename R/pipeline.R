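# End-to-end orchestration: distances -> gap -> identification ->
# threshold sweep / ad hoc fit -> optional BP classifier -> haplotype
# network -> NJ tree + monophyly, with all tables written to an output
# directory and a provenance record of seeds and parameters.

per_species_ranges <- function(part) {
  # per-species intraspecific range and per-pair interspecific range,
  # formatted like the delimitation tables (percent, 2 decimals)
  intra <- part[part$category != "inter", , drop = FALSE]
  inter <- part[part$category == "inter", , drop = FALSE]
  rng <- function(x) sprintf("%.2f~%.2f", 100 * min(x), 100 * max(x))
  intra_tab <- if (nrow(intra)) {
    do.call(rbind, lapply(split(intra$distance, intra$species1),
                          function(d) data.frame(range = rng(d))))
  } else NULL
  if (!is.null(intra_tab))
    intra_tab <- data.frame(species = rownames(intra_tab),
                            intra_range = intra_tab$range, row.names = NULL)
  inter_tab <- if (nrow(inter)) {
    key <- paste(pmin(inter$species1, inter$species2),
                 pmax(inter$species1, inter$species2), sep = " vs ")
    do.call(rbind, lapply(split(inter$distance, key), function(d)
      data.frame(inter_range = rng(d))))
  } else NULL
  if (!is.null(inter_tab))
    inter_tab <- data.frame(pair = rownames(inter_tab),
                            inter_range = inter_tab$inter_range,
                            row.names = NULL)
  list(intra = intra_tab, inter = inter_tab)
}

#' Run the full barcoding analysis pipeline
#'
#' Chains the analysis stages over one library: K2P distance matrix,
#' distance partition and per-species range tables, gap/overlap report,
#' BM/BCM/ASB identification summaries, a BCM threshold sweep with the ad
#' hoc regression threshold, optionally the BP classifier, the haplotype
#' network and the NJ tree with monophyly report. All artefacts are
#' returned and, when \code{out_dir} is given, written as TSV / JSON /
#' newick files together with a provenance record.
#'
#' @param lib a \code{\link{barcode_library}}
#' @param out_dir output directory (created), or \code{NULL} to skip
#'   writing
#' @param protocols subset of \code{c("bm", "bcm", "asb")}
#' @param threshold \code{"auto"} (95th percentile of intraspecific
#'   distances) or a fixed numeric threshold
#' @param sweep_points thresholds in the sweep (0 disables the sweep)
#' @param bootstrap_reps NJ bootstrap replicates (0 = no support values)
#' @param run_bp train and evaluate the BP classifier on a stratified
#'   ~1:1 split
#' @param bp_cfg a \code{\link{bp_config}} for the BP stage
#' @param seed seed for the seeded stages (split, bootstrap)
#' @return list of stage results (class \code{pipeline_result})
#' @export
run_pipeline <- function(lib, out_dir = NULL,
                         protocols = c("bm", "bcm", "asb"),
                         threshold = "auto", sweep_points = 30L,
                         bootstrap_reps = 0L, run_bp = FALSE,
                         bp_cfg = bp_config(), seed = 1L) {
  stopifnot(inherits(lib, "barcode_library"))
  protocols <- match.arg(protocols, c("bm", "bcm", "asb"),
                         several.ok = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  dm <- stage("distances", k2p_matrix(lib))
  part <- stage("partition", partition_distances(dm, lib$meta))
  gap <- stage("gap", gap_analysis(part))
  thr <- if (identical(threshold, "auto"))
    stage("threshold", intra_percentile_threshold(part)) else
      as.numeric(threshold)
  idres <- list()
  if ("bm" %in% protocols) idres$bm <- stage("bm", bm_identify(lib, dm))
  if ("bcm" %in% protocols)
    idres$bcm <- stage("bcm", bcm_identify(lib, thr, dm))
  if ("asb" %in% protocols)
    idres$asb <- stage("asb", asb_identify(lib, thr, dm))
  sweep <- adhoc <- NULL
  if (sweep_points >= 2L) {
    sweep <- stage("sweep", threshold_sweep(lib, dm, sweep_points))
    adhoc <- stage("adhoc", adhoc_threshold(sweep))
  }
  bp <- NULL
  if (run_bp) {
    bp <- stage("bpnet", {
      spl <- split_reference_query(lib, seed = seed)
      model <- bp_train(spl$reference, bp_cfg)
      c(bp_classify(model, spl$query), list(model = model, split = spl))
    })
  }
  hs <- stage("haplotypes", collapse_haplotypes(lib))
  net <- if (length(hs$seq) >= 2L) stage("network", build_network(hs)) else NULL
  tree <- NULL
  mono <- NULL
  if (length(lib$seq) >= 3L) {
    tree <- stage("njtree",
                  if (bootstrap_reps >= 1L)
                    nj_bootstrap(lib, bootstrap_reps, seed, dm)
                  else nj_tree(dm))
    labels <- stats::setNames(lib$meta$species, lib$meta$seq_id)
    mono <- stage("monophyly", monophyly_report(tree, labels))
  }
  res <- structure(list(distance_matrix = dm, partition = part,
                        ranges = per_species_ranges(part), gap = gap,
                        threshold = thr, identification = idres,
                        sweep = sweep, adhoc = adhoc, bp = bp,
                        haplotypes = hs, network = net,
                        tree = tree, monophyly = mono,
                        seed = seed),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline(res, lib, out_dir)
  res
}

write_pipeline <- function(res, lib, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  wt <- function(x, f) utils::write.table(x, p(f), sep = "\t",
                                          quote = FALSE, row.names = FALSE)
  utils::write.table(round(res$distance_matrix$d, 6), p("distances.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  wt(res$partition, "partition.tsv")
  if (!is.null(res$ranges$intra)) wt(res$ranges$intra, "intra_ranges.tsv")
  if (!is.null(res$ranges$inter)) wt(res$ranges$inter, "inter_ranges.tsv")
  jsonlite::write_json(list(max_intra = res$gap$max_intra,
                            min_inter = res$gap$min_inter,
                            overlap = res$gap$overlap,
                            gap_width = res$gap$gap_width),
                       p("gap.json"), auto_unbox = TRUE, digits = NA)
  wt(res$gap$histogram, "gap_histogram.tsv")
  for (nm in names(res$identification)) {
    wt(res$identification[[nm]]$outcomes, paste0("id_", nm, ".tsv"))
    wt(res$identification[[nm]]$summary, paste0("id_", nm, "_summary.tsv"))
  }
  if (!is.null(res$sweep)) wt(res$sweep, "sweep.tsv")
  if (!is.null(res$adhoc))
    jsonlite::write_json(unclass(res$adhoc), p("adhoc.json"),
                         auto_unbox = TRUE, digits = NA)
  if (!is.null(res$bp)) wt(res$bp$predictions, "bp_predictions.tsv")
  if (!is.null(res$network)) {
    wt(res$network$edges, "network_edges.tsv")
    wt(res$network$nodes, "network_nodes.tsv")
  }
  if (!is.null(res$tree)) ape::write.tree(res$tree, p("nj_tree.nwk"))
  if (!is.null(res$monophyly)) wt(res$monophyly, "monophyly.tsv")
  prov <- list(package = "barcodetools",
               version = as.character(utils::packageVersion("barcodetools")),
               n_sequences = length(lib$seq),
               alignment_length = lib$length,
               threshold = res$threshold,
               seed = res$seed)
  jsonlite::write_json(prov, p("provenance.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(res)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  print(x$gap)
  cat(sprintf("threshold: %.4f\n", x$threshold))
  for (nm in names(x$identification)) print(x$identification[[nm]])
  if (!is.null(x$adhoc)) print(x$adhoc)
  if (!is.null(x$bp))
    cat(sprintf("BP success rate: %.2f%%\n", 100 * x$bp$success_rate))
  if (!is.null(x$monophyly))
    cat("monophyletic labels:", sum(x$monophyly$monophyletic), "of",
        nrow(x$monophyly), "\n")
  invisible(x)
}
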