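#' Read protein sequences from a FASTA file
#'
#' Sequence identifiers are taken from the header line up to the first
#' whitespace. Record order is preserved. Duplicate identifiers are an
#' error (the offending ids are listed), because downstream mapping keys
#' records by id.
#'
#' @param path Path to a FASTA file.
#' @param source_tag Free-form provenance label attached to every record.
#' @return A `data.frame` with columns `id`, `sequence`, `source_tag`.
#' @export
read_fasta <- function(path, source_tag = basename(path)) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate sequence ids in ", path, ": ", paste(dup, collapse = ", "))
  }
  data.frame(id = ids,
             sequence = toupper(as.character(set)),
             source_tag = source_tag,
             stringsAsFactors = FALSE)
}

#' Write sequence records (or an alignment) to FASTA
#'
#' @param x A `data.frame` with `id` and `sequence` columns, or an [msa]
#'   object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (inherits(x, "msa")) {
    seqs <- x$seqs
    ids <- x$ids
  } else {
    seqs <- x$sequence
    ids <- x$id
  }
  set <- Biostrings::BStringSet(seqs)
  names(set) <- ids
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Multiple sequence alignment container
#'
#' A rectangular gapped alignment with named rows, a subset of which are
#' flagged as structure-linked reference rows. Reference rows anchor the
#' structure-to-alignment mapping and define the trimmed background used
#' by all variability comparisons.
#'
#' @param ids Character vector of unique row identifiers.
#' @param seqs Character vector of equal-length gapped sequences
#'   (alphabet: 20 canonical residues plus `-`).
#' @param reference_ids Subset of `ids` linked to structures.
#' @return An object of class `msa`: a list with elements `ids`, `seqs`,
#'   `reference_ids`, `n_columns`.
#' @export
msa <- function(ids, seqs, reference_ids = character()) {
  if (length(ids) != length(seqs)) {
    stop("ids and seqs must have equal length")
  }
  if (length(ids) == 0L) {
    stop("alignment must contain at least one row")
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate row ids: ", paste(dup, collapse = ", "))
  }
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) {
    stop("alignment rows have unequal lengths (",
         paste(range(widths), collapse = "-"),
         "); not a valid alignment")
  }
  missing_ref <- setdiff(reference_ids, ids)
  if (length(missing_ref) > 0L) {
    stop("reference_ids not present in alignment: ",
         paste(missing_ref, collapse = ", "))
  }
  structure(list(ids = as.character(ids),
                 seqs = toupper(as.character(seqs)),
                 reference_ids = as.character(reference_ids),
                 n_columns = widths[1L]),
            class = "msa")
}

#' Read a gapped FASTA alignment as an [msa]
#'
#' @inheritParams read_fasta
#' @param reference_ids Row ids to flag as structure-linked references.
#' @return An [msa] object.
#' @export
read_msa <- function(path, reference_ids = character()) {
  rec <- read_fasta(path)
  msa(rec$id, rec$sequence, reference_ids = reference_ids)
}

#' @export
print.msa <- function(x, ...) {
  cat("Multiple sequence alignment: ", length(x$ids), " rows x ",
      x$n_columns, " columns (", length(x$reference_ids),
      " reference rows)\n", sep = "")
  invisible(x)
}

#' @export
dim.msa <- function(x) c(length(x$ids), x$n_columns)

#' Character-matrix view of an alignment
#'
#' @param x An [msa] object.
#' @param ... Unused.
#' @return A character matrix (rows = sequences, named by row id).
#' @export
as.matrix.msa <- function(x, ...) {
  m <- matrix(unlist(strsplit(x$seqs, "", fixed = TRUE), use.names = FALSE),
              nrow = length(x$ids), ncol = x$n_columns, byrow = TRUE)
  rownames(m) <- x$ids
  m
}
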