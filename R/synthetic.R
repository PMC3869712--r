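# Seeded simulator of barcode libraries with known ground truth.
#
# The generator states a simple world matched to what COI barcode surveys
# typically report: within-population K2P variation well under 1%,
# between-population variation under ~3%, interspecific divergence of
# several percent, occasional haplotypes shared across populations, and
# optional "oversplit" taxa where several nominal species labels sit on
# one biological species. Sequences evolve under the Kimura 2-parameter
# substitution process on a star design: a common root, one ancestor per
# true species, one per population, then individuals -- with branch
# lengths halved per lineage so pairwise expectations hit the configured
# targets (a pairwise distance is the sum of two branches).

#' Simulation configuration
#'
#' @param n_true_species number of biological species
#' @param populations_per_species scalar or per-species vector of
#'   population counts
#' @param individuals_per_population sampled individuals per population
#' @param alignment_length alignment columns (default 658, the COI
#'   Folmer fragment)
#' @param kappa transition/transversion rate ratio (default 2)
#' @param intra_within_pop_target expected pairwise K2P within a
#'   population (default 0.005)
#' @param intra_between_pop_target expected pairwise K2P between
#'   populations of one species (default 0.02)
#' @param inter_target expected pairwise K2P between true species
#'   (default 0.06)
#' @param oversplit_map optional named list: true-species name ->
#'   character vector of nominal species labels, one per population of
#'   that species. Unlisted species keep their true name as nominal
#'   label.
#' @param shared_haplotype_rate probability that an individual carries a
#'   haplotype copied from another population of the same species
#'   (default 0.1)
#' @param seed RNG seed; the whole library is reproducible under it
#' @return list of class \code{sim_config}
#' @export
sim_config <- function(n_true_species = 6L,
                       populations_per_species = 2L,
                       individuals_per_population = 5L,
                       alignment_length = 658L,
                       kappa = 2,
                       intra_within_pop_target = 0.005,
                       intra_between_pop_target = 0.02,
                       inter_target = 0.06,
                       oversplit_map = NULL,
                       shared_haplotype_rate = 0.1,
                       seed = 1L) {
  n_true_species <- as.integer(n_true_species)
  pops <- as.integer(populations_per_species)
  if (length(pops) == 1L) pops <- rep(pops, n_true_species)
  if (length(pops) != n_true_species)
    stop("populations_per_species must be scalar or length n_true_species")
  stopifnot(n_true_species >= 1, all(pops >= 1),
            individuals_per_population >= 1, alignment_length >= 1,
            kappa > 0, shared_haplotype_rate >= 0, shared_haplotype_rate <= 1)
  if (!(intra_within_pop_target >= 0 &&
        intra_within_pop_target <= intra_between_pop_target &&
        intra_between_pop_target < inter_target))
    stop("targets must satisfy 0 <= within <= between < inter")
  sp_names <- sprintf("species_%02d", seq_len(n_true_species))
  if (!is.null(oversplit_map)) {
    if (is.null(names(oversplit_map)) ||
        !all(names(oversplit_map) %in% sp_names))
      stop("configuration error: oversplit_map names must be true species (",
           paste(sp_names, collapse = ", "), ")")
    for (sp in names(oversplit_map)) {
      k <- pops[match(sp, sp_names)]
      if (length(oversplit_map[[sp]]) != k)
        stop("configuration error: oversplit_map for ", sp, " must give ",
             k, " nominal labels (one per population)")
    }
  }
  structure(list(n_true_species = n_true_species,
                 populations_per_species = pops,
                 individuals_per_population =
                   as.integer(individuals_per_population),
                 alignment_length = as.integer(alignment_length),
                 kappa = kappa,
                 intra_within_pop_target = intra_within_pop_target,
                 intra_between_pop_target = intra_between_pop_target,
                 inter_target = inter_target,
                 oversplit_map = oversplit_map,
                 shared_haplotype_rate = shared_haplotype_rate,
                 species_names = sp_names,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# K80 per-site substitution probabilities after expected distance d:
# transition rate alpha, each of two transversions beta, kappa = alpha/beta,
# d = (alpha + 2 beta) t.
k80_site_probs <- function(d, kappa) {
  bt <- d / (kappa + 2)
  at <- kappa * bt
  e1 <- exp(-4 * bt)
  e2 <- exp(-2 * (at + bt))
  p_ts <- 0.25 + 0.25 * e1 - 0.5 * e2
  p_tv <- 0.25 - 0.25 * e1           # per transversion target
  c(ts = p_ts, tv = p_tv)
}

#' Evolve a sequence under the Kimura 2-parameter process
#'
#' Sites evolve independently using closed-form K80 transition
#' probabilities at time \code{branch_length} (expected substitutions per
#' site), so repeated application composes correctly and the realised K2P
#' distance to the parent is an unbiased estimate of the branch length.
#' Uses the current RNG state; wrap in a seeded context for
#' reproducibility.
#'
#' @param seq character string over A/C/G/T (sites that are not A/C/G/T
#'   are left untouched)
#' @param branch_length expected substitutions/site (>= 0)
#' @param kappa transition/transversion rate ratio
#' @return the evolved sequence (character string)
#' @export
evolve_seq <- function(seq, branch_length, kappa = 2) {
  stopifnot(branch_length >= 0)
  if (branch_length == 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  v <- match(toupper(ch), .BASES)
  ok <- which(!is.na(v))
  if (!length(ok)) return(seq)
  pr <- k80_site_probs(branch_length, kappa)
  u <- runif(length(ok))
  # event per site: transition, transversion 1, transversion 2, or stay
  is_ts <- u < pr["ts"]
  is_tv1 <- !is_ts & u < pr["ts"] + pr["tv"]
  is_tv2 <- !is_ts & !is_tv1 & u < pr["ts"] + 2 * pr["tv"]
  b <- v[ok]
  # transition partner: A<->G (1<->3), C<->T (2<->4)
  ts_partner <- ifelse(b <= 2L, b + 2L, b - 2L)
  # transversion targets: the two bases of the other purine/pyrimidine class
  tv1 <- ifelse(b %% 2L == 1L, 2L, 1L)  # purine -> C, pyrimidine -> A
  tv2 <- ifelse(b %% 2L == 1L, 4L, 3L)  # purine -> T, pyrimidine -> G
  b[is_tv2] <- tv2[is_tv2]
  b[is_tv1] <- tv1[is_tv1]
  b[is_ts] <- ts_partner[is_ts]
  ch[ok] <- .BASES[b]
  paste(ch, collapse = "")
}

#' Simulate a barcode library with known ground truth
#'
#' See \code{\link{sim_config}} for the stated world. With an
#' \code{oversplit_map}, populations of the mapped species receive
#' distinct nominal labels and at least one cross-population haplotype
#' copy is guaranteed within each oversplit species (shared haplotypes
#' across nominal labels are the constructed signature of oversplitting).
#'
#' @param cfg a \code{\link{sim_config}}
#' @return list with \code{library} (a \code{\link{barcode_library}}
#'   whose metadata carries the \emph{nominal} species labels),
#'   \code{truth} (data.frame: seq_id, true_species, nominal_species,
#'   population, copied_from) and \code{config}.
#' @export
simulate_library <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    L <- cfg$alignment_length
    root <- int_to_seq(sample.int(4L, L, replace = TRUE))
    seqs <- character(0)
    meta <- list()
    truth <- list()
    idc <- 0L
    for (s in seq_len(cfg$n_true_species)) {
      sp <- cfg$species_names[s]
      sp_anc <- evolve_seq(root, cfg$inter_target / 2, cfg$kappa)
      n_pop <- cfg$populations_per_species[s]
      labels <- if (!is.null(cfg$oversplit_map) &&
                    sp %in% names(cfg$oversplit_map))
        cfg$oversplit_map[[sp]] else rep(sp, n_pop)
      sp_rows <- integer(0)                 # indices into seqs, this species
      sp_pops <- character(0)
      for (p in seq_len(n_pop)) {
        pop_name <- sprintf("%s_pop%d", sp, p)
        pop_anc <- evolve_seq(sp_anc, cfg$intra_between_pop_target / 2,
                              cfg$kappa)
        for (ind in seq_len(cfg$individuals_per_population)) {
          idc <- idc + 1L
          id <- sprintf("s%04d", idc)
          seqs[id] <- evolve_seq(pop_anc, cfg$intra_within_pop_target / 2,
                                 cfg$kappa)
          sp_rows <- c(sp_rows, length(seqs))
          sp_pops <- c(sp_pops, pop_name)
          meta[[id]] <- data.frame(seq_id = id, species = labels[p],
                                   population = pop_name,
                                   locality = pop_name)
          truth[[id]] <- data.frame(seq_id = id, true_species = sp,
                                    nominal_species = labels[p],
                                    population = pop_name,
                                    copied_from = NA_character_)
        }
      }
      # cross-population haplotype sharing within the true species
      if (n_pop >= 2L && cfg$shared_haplotype_rate > 0) {
        shared_any <- FALSE
        for (r in seq_along(sp_rows)) {
          if (runif(1) < cfg$shared_haplotype_rate) {
            donors <- sp_rows[sp_pops != sp_pops[r]]
            if (length(donors)) {
              don <- donors[sample.int(length(donors), 1L)]
              seqs[sp_rows[r]] <- seqs[don]
              truth[[sp_rows[r]]]$copied_from <- names(seqs)[don]
              shared_any <- TRUE
            }
          }
        }
        # oversplit species must exhibit cross-label sharing by construction
        if (!shared_any && !is.null(cfg$oversplit_map) &&
            sp %in% names(cfg$oversplit_map)) {
          rec <- sp_rows[sp_pops == sp_pops[length(sp_pops)]][1]
          don <- sp_rows[sp_pops == sp_pops[1]][1]
          seqs[rec] <- seqs[don]
          truth[[rec]]$copied_from <- names(seqs)[don]
        }
      }
    }
    lib <- barcode_library(seqs, do.call(rbind, meta))
    truth_df <- do.call(rbind, truth)
    rownames(truth_df) <- NULL
    list(library = lib, truth = truth_df, config = cfg)
  })
}

#' Expected leave-one-out BM verdict classes from ground truth
#'
#' Queries from nominal species that sit on an oversplit true species may
#' legitimately fail identification (their nearest neighbours can carry a
#' different nominal label); queries from well-separated nominal species
#' with at least two members must be identified correctly. Used by
#' ground-truth-driven tests.
#'
#' @param truth the \code{truth} data.frame from
#'   \code{\link{simulate_library}}
#' @return data.frame: seq_id, expectation in \code{must_be_correct},
#'   \code{may_fail}, \code{excluded} (fewer than 2 nominal conspecifics)
#' @export
expected_verdicts <- function(truth) {
  stopifnot(all(c("seq_id", "true_species", "nominal_species") %in%
                  names(truth)))
  n_by_nominal <- table(truth$nominal_species)
  labels_per_true <- tapply(truth$nominal_species, truth$true_species,
                            function(x) length(unique(x)))
  oversplit_true <- names(labels_per_true)[labels_per_true > 1L]
  expectation <- ifelse(n_by_nominal[truth$nominal_species] < 2L, "excluded",
                 ifelse(truth$true_species %in% oversplit_true, "may_fail",
                        "must_be_correct"))
  data.frame(seq_id = truth$seq_id, expectation = unname(expectation),
             row.names = NULL)
}
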