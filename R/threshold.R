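# Threshold optimisation for BCM: TP/FP/TN/FN classification of query
# outcomes across a sweep of distance thresholds, and the regression-based
# ad hoc threshold at which the fitted relative identification error
# equals a target (conventionally 0.05).

#' Classify BCM outcomes into TP/FP/TN/FN and derived metrics
#'
#' Queries retained at the threshold (not discarded) are true positives
#' when identified correctly and false positives when ambiguous or
#' incorrect. Discarded queries (best match beyond the threshold) are
#' false negatives when their best match is conspecific and true
#' negatives otherwise. Derived metrics: accuracy = (TP+TN)/total,
#' precision = TP/(TP+FP), overall ID error = (FP+FN)/total, relative ID
#' error = FP/(TP+FP). Precision and relative error are undefined
#' (\code{NA}) when no query is retained.
#'
#' @param res an \code{id_result} from \code{\link{bcm_identify}}
#' @return one-row data.frame (class \code{sweep_row}) with the counts
#'   and metrics at the result's threshold.
#' @export
confusion_classify <- function(res) {
  stopifnot(inherits(res, "id_result"))
  if (!identical(res$protocol, "bcm"))
    stop("input error: confusion classification is defined for BCM outcomes")
  out <- res$outcomes
  sweep_row(res$threshold,
            verdict = out$verdict,
            truth_in_best = out$truth_in_best)
}

sweep_row <- function(threshold, verdict, truth_in_best) {
  disc <- verdict == "no_match"
  tp <- sum(!disc & verdict == "correct")
  fp <- sum(!disc & verdict %in% c("ambiguous", "incorrect"))
  fn <- sum(disc & truth_in_best)
  tn <- sum(disc & !truth_in_best)
  total <- length(verdict)
  kept <- tp + fp
  out <- data.frame(
    THR_K2P = threshold,
    TP = tp, FP = fp, TN = tn, FN = fn,
    total = total, discarded = tn + fn,
    accuracy = (tp + tn) / total,
    precision = if (kept > 0) tp / kept else NA_real_,
    overall_ID_error = (fp + fn) / total,
    relative_ID_error = if (kept > 0) fp / kept else NA_real_)
  class(out) <- c("sweep_row", "data.frame")
  out
}

#' Sweep BCM performance across distance thresholds
#'
#' Thresholds are linearly spaced, descending, from the largest
#' query-best-match distance in the library (at which no query is
#' discarded, so BCM equals BM) down to 0 (at which only exact-match
#' queries are retained). Each threshold yields one row of TP/FP/TN/FN
#' counts and derived metrics.
#'
#' @inheritParams bm_identify
#' @param n_thresholds number of thresholds (default 30)
#' @param thresholds optional explicit threshold grid overriding the
#'   linear spacing
#' @return data.frame of class \code{threshold_sweep}, one row per
#'   threshold (descending).
#' @export
threshold_sweep <- function(lib, dm = NULL, n_thresholds = 30L,
                            thresholds = NULL, min_species_size = 2L) {
  dm <- dm %||% k2p_matrix(lib)
  bm <- bm_identify(lib, dm, min_species_size)
  out <- bm$outcomes
  if (is.null(thresholds)) {
    if (n_thresholds < 2L) stop("need at least 2 thresholds")
    top <- max(out$best_distance)
    if (top == 0) {
      warning("all best-match distances are 0; single-threshold table")
      thresholds <- 0
    } else {
      thresholds <- seq(top, 0, length.out = n_thresholds)
    }
  }
  rows <- lapply(thresholds, function(thr) {
    v <- out$verdict
    v[out$best_distance > thr] <- "no_match"
    sweep_row(thr, v, out$truth_in_best)
  })
  res <- do.call(rbind, rows)
  class(res) <- c("threshold_sweep", "data.frame")
  res
}

#' Ad hoc distance threshold by linear regression
#'
#' Fits ordinary least squares of the relative identification error on
#' the threshold over the sweep rows where the error is defined, and
#' solves the fitted line for the threshold at which the error equals
#' \code{target_error}. When the solution is negative -- e.g. when even a
#' threshold of 0 leaves the fitted error above the target -- no usable
#' ad hoc threshold exists and \code{attainable} is \code{FALSE} (a
#' negative distance threshold is impossible to apply).
#'
#' @param sweep a \code{\link{threshold_sweep}} table
#' @param target_error target relative identification error (default 0.05)
#' @return list of class \code{adhoc_fit}: \code{slope},
#'   \code{intercept}, \code{THR_K2P_0.05} (the solved threshold, possibly
#'   negative), \code{attainable}, \code{target_error}, \code{n_points}.
#' @export
adhoc_threshold <- function(sweep, target_error = 0.05) {
  stopifnot(inherits(sweep, "data.frame"))
  use <- !is.na(sweep$relative_ID_error)
  if (sum(use) < 2L)
    stop("fit error: fewer than 2 rows with defined relative ID error")
  fit <- stats::lm(relative_ID_error ~ THR_K2P, data = sweep[use, ])
  cf <- stats::coef(fit)
  intercept <- unname(cf[1])
  slope <- unname(cf[2])
  thr <- (target_error - intercept) / slope
  attainable <- is.finite(thr) && thr >= 0 &&
    !(slope <= 0 && intercept > target_error)
  structure(list(slope = slope, intercept = intercept,
                 THR_K2P_0.05 = thr, attainable = attainable,
                 target_error = target_error, n_points = sum(use)),
            class = "adhoc_fit")
}

#' @export
print.adhoc_fit <- function(x, ...) {
  cat(sprintf("ad hoc threshold fit: error = %.4f + %.4f * THR_K2P (n = %d)\n",
              x$intercept, x$slope, x$n_points))
  if (x$attainable) {
    cat(sprintf("threshold at error %.2f: %.4f\n",
                x$target_error, x$THR_K2P_0.05))
  } else if (!is.finite(x$THR_K2P_0.05)) {
    cat(sprintf("flat fit: no threshold at which the fitted error crosses %.2f\n",
                x$target_error))
  } else {
    cat(sprintf(paste0("no attainable threshold: solution %.4f ",
                       "(a negative threshold is impossible to apply)\n"),
                x$THR_K2P_0.05))
  }
  invisible(x)
}
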