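#' Construct a barcode library from sequences and metadata
#'
#' A barcode library is the central container of the package: a set of
#' aligned, equal-length nucleotide sequences (the standard animal barcode
#' is the 658-bp 5' COI Folmer fragment) together with a metadata table
#' giving, for every sequence, a nominal species label and optional
#' population and locality labels.
#'
#' @param sequences named character vector of aligned sequences over
#'   \code{A,C,G,T,-,N} and IUPAC ambiguity codes; names are sequence ids.
#'   Input case is ignored; sequences are stored upper-case.
#' @param metadata data.frame with columns \code{seq_id}, \code{species}
#'   and optionally \code{population} and \code{locality}. Every sequence
#'   id must appear exactly once; species labels must be non-empty.
#' @return an object of class \code{barcode_library} with elements
#'   \code{seq} (named character vector, FASTA order), \code{meta}
#'   (data.frame aligned to \code{seq}) and \code{length} (alignment
#'   columns).
#' @export
barcode_library <- function(sequences, metadata) {
  if (length(sequences) == 0L) stop("empty library: no sequences")
  ids <- names(sequences)
  if (is.null(ids) || any(ids == ""))
    stop("all sequences must be named with a seq_id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate seq_id in library: ", paste(dup, collapse = ", "))
  sequences <- toupper(sequences)
  lens <- nchar(sequences)
  L <- as.integer(lens[[1]])
  if (any(lens != L)) {
    bad <- ids[lens != L]
    stop("alignment error: sequences not all of length ", L, ": ",
         paste(bad, collapse = ", "))
  }
  if (!is.data.frame(metadata) || !all(c("seq_id", "species") %in% names(metadata)))
    stop("metadata must be a data.frame with columns seq_id and species")
  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  if (!"population" %in% names(metadata)) metadata$population <- ""
  if (!"locality" %in% names(metadata)) metadata$locality <- ""
  metadata$population[is.na(metadata$population)] <- ""
  dupm <- unique(metadata$seq_id[duplicated(metadata$seq_id)])
  if (length(dupm))
    stop("duplicate seq_id in metadata: ", paste(dupm, collapse = ", "))
  missing <- setdiff(ids, metadata$seq_id)
  if (length(missing))
    stop("metadata error: ids missing from metadata: ",
         paste(missing, collapse = ", "))
  meta <- metadata[match(ids, metadata$seq_id),
                   c("seq_id", "species", "population", "locality"),
                   drop = FALSE]
  rownames(meta) <- NULL
  if (any(is.na(meta$species) | meta$species == ""))
    stop("metadata error: empty species label for: ",
         paste(meta$seq_id[is.na(meta$species) | meta$species == ""],
               collapse = ", "))
  structure(list(seq = sequences, meta = meta, length = L),
            class = "barcode_library")
}

#' Read an aligned barcode library from FASTA plus metadata TSV
#'
#' @param fasta_path path to an aligned multi-FASTA; all sequences must have
#'   the same length. The FASTA id is the first whitespace-delimited token
#'   of each header.
#' @param metadata_path path to a tab-separated table with header line
#'   \code{seq_id\tspecies\tpopulation\tlocality}. Every FASTA id must be
#'   present. An empty population string is allowed and is treated as one
#'   (unknown) population per species.
#' @return a \code{\link{barcode_library}}
#' @export
read_library <- function(fasta_path, metadata_path) {
  ss <- Biostrings::readBStringSet(fasta_path)
  if (length(ss) == 0L) stop("no sequences in ", fasta_path)
  ids <- sub("\\s.*$", "", names(ss))
  seqs <- stats::setNames(as.character(ss), ids)
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE,
                            colClasses = "character")
  need <- c("seq_id", "species", "population", "locality")
  if (!all(need %in% names(meta)))
    stop("metadata error: header must contain ",
         paste(need, collapse = ", "))
  barcode_library(seqs, meta)
}

#' Write a barcode library to FASTA and metadata TSV
#'
#' @param lib a \code{\link{barcode_library}}
#' @param fasta_path,metadata_path output paths
#' @return invisibly, the library
#' @export
write_library <- function(lib, fasta_path, metadata_path = NULL) {
  stopifnot(inherits(lib, "barcode_library"))
  con <- file(fasta_path, "w")
  on.exit(close(con))
  for (i in seq_along(lib$seq))
    cat(">", names(lib$seq)[i], "\n", lib$seq[[i]], "\n",
        sep = "", file = con)
  if (!is.null(metadata_path))
    utils::write.table(lib$meta, metadata_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(lib)
}

#' @export
print.barcode_library <- function(x, ...) {
  cat("barcode_library:", length(x$seq), "sequences,",
      x$length, "aligned columns,",
      length(unique(x$meta$species)), "species\n")
  invisible(x)
}

# subset keeping FASTA order
subset_library <- function(lib, ids) {
  keep <- names(lib$seq) %in% ids
  barcode_library(lib$seq[keep], lib$meta[keep, , drop = FALSE])
}

#' Collapse identical sequences into haplotypes
#'
#' Two records carry the same haplotype iff their aligned sequences are
#' identical character-for-character. The representative id of each
#' haplotype is the lexicographically smallest member seq_id; haplotypes
#' are ordered by representative id so the result does not depend on
#' record order.
#'
#' @param lib a \code{\link{barcode_library}}
#' @return a \code{haplotype_set}: list with \code{seq} (named character
#'   vector, one entry per haplotype, names = representative ids),
#'   \code{members} (list of member seq_id vectors in input order),
#'   \code{multiplicity}, \code{groups} (data.frame of distinct
#'   (species, population) label pairs per haplotype) and \code{meta}
#'   (the library metadata).
#' @export
collapse_haplotypes <- function(lib) {
  stopifnot(inherits(lib, "barcode_library"))
  ids <- names(lib$seq)
  grp <- split(ids, factor(lib$seq, levels = unique(lib$seq)))
  reps <- vapply(grp, function(m) sort(m)[1], character(1))
  ord <- order(reps)
  grp <- grp[ord]
  reps <- reps[ord]
  haps <- stats::setNames(names(grp), reps)  # names(grp) are the sequences
  members <- stats::setNames(unname(grp), reps)
  groups <- lapply(members, function(m) {
    g <- unique(lib$meta[lib$meta$seq_id %in% m,
                         c("species", "population"), drop = FALSE])
    rownames(g) <- NULL
    g
  })
  structure(list(seq = haps,
                 members = members,
                 multiplicity = vapply(members, length, integer(1)),
                 groups = groups,
                 meta = lib$meta,
                 length = lib$length),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat("haplotype_set:", length(x$seq), "haplotypes from",
      sum(x$multiplicity), "records\n")
  invisible(x)
}

# codon -> amino acid for one genetic code; any codon containing a
# non-ACGT character translates to "X" (unknown), never to a stop.
translate_codons <- function(s, frame, code) {
  chars <- strsplit(gsub("-", "", s, fixed = TRUE), "", fixed = TRUE)[[1]]
  if (frame > 0) chars <- chars[-seq_len(frame)]
  n_codon <- length(chars) %/% 3L
  if (n_codon == 0L) return(character(0))
  chars <- chars[seq_len(n_codon * 3L)]
  codons <- paste0(chars[c(TRUE, FALSE, FALSE)],
                   chars[c(FALSE, TRUE, FALSE)],
                   chars[c(FALSE, FALSE, TRUE)])
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  aa
}

#' Screen a library for numt-like sequences by translation
#'
#' Nuclear copies of mitochondrial genes (numts) often carry frameshifts
#' or in-frame stop codons. Each sequence is translated (alignment gaps
#' are dropped before codon assembly; codons containing N or other
#' ambiguities translate to unknown, never to a stop) and flagged when the
#' translation contains at least one stop codon.
#'
#' With \code{frame = "auto"} a single reading frame is chosen for the
#' whole library -- the frame minimising the total stop count across all
#' records -- so that an individual frameshifted sequence still shows
#' stops in the library frame rather than shopping for its own frame.
#'
#' @param lib a \code{\link{barcode_library}}
#' @param code_table NCBI genetic code id; defaults to \code{"5"}, the
#'   invertebrate mitochondrial code.
#' @param frame \code{"auto"} or a fixed frame offset 0, 1 or 2.
#' @return data.frame (class \code{numt_report}) with columns
#'   \code{seq_id}, \code{frame}, \code{stop_codons}, \code{flagged}.
#' @export
screen_numts <- function(lib, code_table = "5", frame = "auto") {
  stopifnot(inherits(lib, "barcode_library"))
  code <- Biostrings::getGeneticCode(as.character(code_table))
  stops_in <- function(s, f) sum(translate_codons(s, f, code) == "*")
  if (identical(frame, "auto")) {
    totals <- vapply(0:2, function(f)
      sum(vapply(lib$seq, stops_in, numeric(1), f = f)), numeric(1))
    use_frame <- which.min(totals) - 1L
  } else {
    use_frame <- as.integer(frame)
    if (!use_frame %in% 0:2) stop("frame must be 'auto', 0, 1 or 2")
  }
  n_stops <- vapply(lib$seq, stops_in, numeric(1), f = use_frame)
  out <- data.frame(seq_id = names(lib$seq),
                    frame = use_frame,
                    stop_codons = as.integer(n_stops),
                    flagged = n_stops > 0,
                    row.names = NULL)
  class(out) <- c("numt_report", "data.frame")
  out
}
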