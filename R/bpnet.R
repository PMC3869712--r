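# Back-propagation neural-network species assignment.
#
# A single-hidden-layer feed-forward network with sigmoid activations is
# trained by per-sample stochastic gradient descent with momentum on
# one-hot encoded alignment columns, with one output unit per reference
# species. Defaults mirror common practice for barcode classifiers:
# learning rate 0.2, momentum 0.5, mean-squared-error training goal 1e-5.

#' Back-propagation network configuration
#'
#' @param learning_rate SGD step size (> 0)
#' @param momentum momentum coefficient in [0, 1)
#' @param training_goal stop when the epoch mean squared error falls to
#'   or below this value
#' @param max_epochs hard cap on training epochs
#' @param hidden_units width of the single hidden layer
#' @param confidence_cutoff winning activations below this are flagged
#'   low-confidence
#' @param seed RNG seed for weight initialisation and sample order
#' @return list of class \code{bp_config}
#' @export
bp_config <- function(learning_rate = 0.2, momentum = 0.5,
                      training_goal = 1e-5, max_epochs = 50000L,
                      hidden_units = 20L, confidence_cutoff = 0.95,
                      seed = 1L) {
  stopifnot(learning_rate > 0, momentum >= 0, momentum < 1,
            training_goal > 0, max_epochs >= 1, hidden_units >= 1)
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 training_goal = training_goal,
                 max_epochs = as.integer(max_epochs),
                 hidden_units = as.integer(hidden_units),
                 confidence_cutoff = confidence_cutoff,
                 seed = as.integer(seed)),
            class = "bp_config")
}

#' One-hot encode aligned sequences for the classifier
#'
#' Each alignment column becomes an indicator quadruple over A/C/G/T;
#' gaps, N and other ambiguities encode as the all-zero quadruple. A
#' 658-column alignment therefore yields 2632 features per sequence.
#'
#' @param lib a \code{\link{barcode_library}}
#' @return numeric matrix, one row per sequence, \code{4 * length} columns
#' @export
encode_onehot <- function(lib) {
  stopifnot(inherits(lib, "barcode_library"))
  m <- seqs_to_int_matrix(lib$seq)
  n <- nrow(m); L <- ncol(m)
  X <- matrix(0, n, 4L * L, dimnames = list(rownames(m), NULL))
  cols <- rep(seq_len(L) - 1L, each = 1L)
  for (i in seq_len(n)) {
    v <- m[i, ]
    ok <- !is.na(v)
    X[i, 4L * (which(ok) - 1L) + v[ok]] <- 1
  }
  X
}

#' Stratified reference/query split
#'
#' Splits a library species by species: each species contributes
#' \code{ceiling(n * ratio)} sequences to the reference set and the rest
#' to the query set, so every species is represented in the reference.
#' Species with a single sequence cannot be split and are excluded (and
#' reported). Reproducible under \code{seed}.
#'
#' @param lib a \code{\link{barcode_library}}
#' @param ratio reference fraction (default 0.5 for the ~1:1 design)
#' @param seed RNG seed
#' @return list with \code{reference} and \code{query} libraries and
#'   \code{excluded} ids
#' @export
split_reference_query <- function(lib, ratio = 0.5, seed = 1L) {
  stopifnot(inherits(lib, "barcode_library"), ratio > 0, ratio < 1)
  sp_split <- split(lib$meta$seq_id, lib$meta$species)
  excluded <- unlist(sp_split[vapply(sp_split, length, integer(1)) < 2L],
                     use.names = FALSE)
  sp_split <- sp_split[vapply(sp_split, length, integer(1)) >= 2L]
  if (!length(sp_split)) stop("no species with >= 2 sequences to split")
  ref_ids <- with_seed(seed, {
    unlist(lapply(sp_split[order(names(sp_split))], function(ids) {
      n_ref <- min(max(1L, ceiling(length(ids) * ratio)), length(ids) - 1L)
      sort(ids)[sample.int(length(ids), n_ref)]
    }), use.names = FALSE)
  })
  qry_ids <- setdiff(unlist(sp_split, use.names = FALSE), ref_ids)
  list(reference = subset_library(lib, ref_ids),
       query = subset_library(lib, qry_ids),
       excluded = excluded %||% character(0))
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Train the back-propagation classifier
#'
#' @param reference a \code{\link{barcode_library}} with >= 2 species
#' @param cfg a \code{\link{bp_config}}
#' @return object of class \code{bp_model}: weight matrices, species
#'   level order, alignment length, per-epoch loss trace and a
#'   \code{converged} flag (with a warning when the goal was not reached
#'   within \code{max_epochs}).
#' @export
bp_train <- function(reference, cfg = bp_config()) {
  stopifnot(inherits(reference, "barcode_library"),
            inherits(cfg, "bp_config"))
  species <- sort(unique(reference$meta$species))
  if (length(species) < 2L)
    stop("configuration error: need >= 2 reference species")
  X <- encode_onehot(reference)
  y <- match(reference$meta$species[match(rownames(X),
                                          reference$meta$seq_id)], species)
  k <- length(species)
  Y <- matrix(0, nrow(X), k)
  Y[cbind(seq_len(nrow(X)), y)] <- 1
  p <- ncol(X)
  h <- cfg$hidden_units
  lr <- cfg$learning_rate
  mom <- cfg$momentum

  state <- with_seed(cfg$seed, {
    W1 <- matrix(runif(p * h, -0.5, 0.5), p, h)
    b1 <- runif(h, -0.5, 0.5)
    W2 <- matrix(runif(h * k, -0.5, 0.5), h, k)
    b2 <- runif(k, -0.5, 0.5)
    vW1 <- matrix(0, p, h); vb1 <- numeric(h)
    vW2 <- matrix(0, h, k); vb2 <- numeric(k)
    trace <- numeric(0)
    converged <- FALSE
    for (epoch in seq_len(cfg$max_epochs)) {
      for (i in sample.int(nrow(X))) {
        x <- X[i, ]
        hid <- sigmoid(drop(x %*% W1) + b1)
        out <- sigmoid(drop(hid %*% W2) + b2)
        delta_o <- (out - Y[i, ]) * out * (1 - out)
        delta_h <- drop(W2 %*% delta_o) * hid * (1 - hid)
        vW2 <- mom * vW2 - lr * tcrossprod(hid, delta_o)
        vb2 <- mom * vb2 - lr * delta_o
        vW1 <- mom * vW1 - lr * tcrossprod(x, delta_h)
        vb1 <- mom * vb1 - lr * delta_h
        W2 <- W2 + vW2; b2 <- b2 + vb2
        W1 <- W1 + vW1; b1 <- b1 + vb1
      }
      H <- sigmoid(sweep(X %*% W1, 2, b1, "+"))
      O <- sigmoid(sweep(H %*% W2, 2, b2, "+"))
      mse <- mean((O - Y)^2)
      trace[epoch] <- mse
      if (mse <= cfg$training_goal) { converged <- TRUE; break }
    }
    list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, trace = trace,
         converged = converged)
  })
  if (!state$converged)
    warning("training goal not reached within ", cfg$max_epochs, " epochs",
            " (final MSE ", signif(state$trace[length(state$trace)], 4), ")")
  structure(c(state, list(species = species, length = reference$length,
                          config = cfg)),
            class = "bp_model")
}

#' @export
print.bp_model <- function(x, ...) {
  cat(sprintf("bp_model: %d species, %d hidden units, %d epochs (MSE %.2e)%s\n",
              length(x$species), x$config$hidden_units, length(x$trace),
              x$trace[length(x$trace)],
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Classify query sequences with a trained network
#'
#' Winner-take-all over output activations; the winning activation is
#' reported as confidence and flagged when below the configured cutoff.
#' A correct prediction counts toward the success rate regardless of the
#' confidence flag.
#'
#' @param model a \code{\link{bp_train}} result
#' @param query a \code{\link{barcode_library}} with the model's
#'   alignment length
#' @return list with \code{predictions} (data.frame: query_id, truth,
#'   predicted, confidence, low_confidence) and \code{success_rate}
#'   (proportion correct, \code{NA} when query truth labels are absent
#'   from the model's species set).
#' @export
bp_classify <- function(model, query) {
  stopifnot(inherits(model, "bp_model"), inherits(query, "barcode_library"))
  if (query$length != model$length)
    stop("input error: query alignment length ", query$length,
         " != model length ", model$length)
  X <- encode_onehot(query)
  H <- sigmoid(sweep(X %*% model$W1, 2, model$b1, "+"))
  O <- sigmoid(sweep(H %*% model$W2, 2, model$b2, "+"))
  win <- max.col(O, ties.method = "first")
  conf <- O[cbind(seq_len(nrow(O)), win)]
  truth <- query$meta$species[match(rownames(X), query$meta$seq_id)]
  pred <- data.frame(query_id = rownames(X),
                     truth = truth,
                     predicted = model$species[win],
                     confidence = conf,
                     low_confidence = conf < model$config$confidence_cutoff,
                     row.names = NULL)
  rate <- if (all(is.na(truth))) NA_real_ else mean(pred$predicted == truth)
  list(predictions = pred, success_rate = rate)
}
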