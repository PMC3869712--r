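# Internal helpers shared across modules.

# Map nucleotide characters to integers 1:4 (A,C,G,T); anything else
# (gaps, N, other IUPAC ambiguities) becomes NA and is treated as missing
# by distance and step computations (pairwise deletion).
.BASES <- c("A", "C", "G", "T")

seq_to_int <- function(x) {
  match(strsplit(toupper(x), "", fixed = TRUE)[[1]], .BASES)
}

# n x L integer matrix for a vector of equal-length sequences
seqs_to_int_matrix <- function(seqs) {
  L <- nchar(seqs[[1]])
  m <- matrix(NA_integer_, nrow = length(seqs), ncol = L)
  for (i in seq_along(seqs)) m[i, ] <- seq_to_int(seqs[[i]])
  rownames(m) <- names(seqs)
  m
}

int_to_seq <- function(v) {
  out <- .BASES[v]
  out[is.na(v)] <- "-"
  paste(out, collapse = "")
}

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's
# RNG state afterwards. All exported stochastic operations funnel through
# this so no function mutates global RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# genus = first whitespace-delimited token of a species label
genus_of <- function(species) sub("\\s.*$", "", species)
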