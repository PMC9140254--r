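#' Sequence motif pattern
#'
#' An ordered list of position classes, each the set of residues allowed at
#' that position. A sequence carries the motif if some contiguous window
#' satisfies every position class.
#'
#' @param name Pattern label.
#' @param elements List of character vectors, one per motif position; each
#'   must be a non-empty subset of the 20 canonical residues.
#' @return An object of class `motif_pattern`.
#' @export
motif_pattern <- function(name, elements) {
  if (length(elements) == 0L) stop("motif must have at least one position")
  for (i in seq_along(elements)) {
    el <- elements[[i]]
    if (length(el) == 0L) {
      stop("motif position ", i, " allows no residues")
    }
    bad <- setdiff(el, AA_STANDARD)
    if (length(bad) > 0L) {
      stop("motif position ", i, " contains non-canonical letters: ",
           paste(bad, collapse = ", "))
    }
  }
  structure(list(name = name, elements = lapply(elements, unique)),
            class = "motif_pattern")
}

#' Residues of the "small" (Sm) class
#'
#' Taylor's small class: the default residue set matched by the Sm position
#' of the epoxide-hydrolase G-X-Sm-X-S/T motif.
#' @export
SMALL_RESIDUES <- c("A", "C", "D", "G", "N", "P", "S", "T", "V")

AROMATIC_RESIDUES <- c("F", "H", "W", "Y")

#' Catalytic epoxide-hydrolase motifs
#'
#' `motif_hgxp()` builds the H-G-X-P oxyanion-hole motif and
#' `motif_gxsmxst()` the G-X-Sm-X-S/T nucleophile-elbow motif. X matches
#' any canonical residue by default; X is often aromatic in epoxide
#' hydrolases, and `aromatic_x = TRUE` restricts it to F/H/W/Y.
#'
#' @param aromatic_x Restrict X positions to aromatic residues.
#' @param small Residue set for the Sm position (default [SMALL_RESIDUES]).
#' @return A [motif_pattern].
#' @export
motif_hgxp <- function(aromatic_x = FALSE) {
  x_set <- if (aromatic_x) AROMATIC_RESIDUES else AA_STANDARD
  motif_pattern("H-G-X-P", list("H", "G", x_set, "P"))
}

#' @rdname motif_hgxp
#' @export
motif_gxsmxst <- function(aromatic_x = FALSE, small = SMALL_RESIDUES) {
  x_set <- if (aromatic_x) AROMATIC_RESIDUES else AA_STANDARD
  motif_pattern("G-X-Sm-X-S/T", list("G", x_set, small, x_set, c("S", "T")))
}

#' Remove duplicate sequences
#'
#' Keeps the first record of every identical sequence string; the order of
#' retained records is preserved. Deduplication is by sequence, not id.
#'
#' @param records A `data.frame` of sequence records (see [read_fasta]).
#' @return The deduplicated `data.frame`.
#' @export
deduplicate <- function(records) {
  records[!duplicated(records$sequence), , drop = FALSE]
}

#' Test whether a sequence carries a motif
#'
#' True iff some contiguous window of the (ungapped) sequence satisfies
#' every position class of the pattern.
#'
#' @param seq Ungapped amino-acid string.
#' @param pattern A [motif_pattern].
#' @return Logical scalar.
#' @export
has_motif <- function(seq, pattern) {
  stopifnot(inherits(pattern, "motif_pattern"))
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  k <- length(pattern$elements)
  n <- length(chars)
  if (n < k) return(FALSE)
  # per-position membership vectors, then AND across window offsets
  ok <- rep(TRUE, n - k + 1L)
  for (j in seq_len(k)) {
    ok <- ok & (chars[j:(n - k + j)] %in% pattern$elements[[j]])
    if (!any(ok)) return(FALSE)
  }
  TRUE
}

#' Filter sequence records by conserved motifs
#'
#' A record is kept iff it carries every pattern. Records containing
#' non-canonical letters (B, J, O, U, X, Z, ...) have undefined motif
#' semantics: by default they are flagged and excluded from motif testing;
#' with `strict = TRUE` they are an error.
#'
#' @param records Sequence record `data.frame`.
#' @param patterns List of [motif_pattern] objects. An empty list keeps
#'   everything.
#' @param strict Error on non-canonical letters instead of flagging.
#' @return A list with elements `kept`, `discarded`, `flagged` (record
#'   `data.frame`s partitioning the input) and `report` (per-record id,
#'   length, one logical column per motif, and `status`).
#' @export
filter_by_motifs <- function(records, patterns, strict = FALSE) {
  n <- nrow(records)
  canonical <- vapply(records$sequence, is_canonical_seq, logical(1),
                      USE.NAMES = FALSE)
  if (strict && any(!canonical)) {
    bad <- records$id[!canonical]
    stop("non-canonical letters in: ", paste(bad, collapse = ", "))
  }
  motif_ok <- matrix(NA, nrow = n, ncol = length(patterns))
  if (length(patterns) > 0L) {
    colnames(motif_ok) <- vapply(patterns, function(p) p$name, character(1))
    for (j in seq_along(patterns)) {
      motif_ok[canonical, j] <- vapply(records$sequence[canonical],
                                       has_motif, logical(1),
                                       pattern = patterns[[j]],
                                       USE.NAMES = FALSE)
    }
  }
  all_ok <- if (length(patterns) == 0L) rep(TRUE, n) else {
    apply(motif_ok, 1L, function(r) all(r))
  }
  status <- ifelse(!canonical, "flagged",
                   ifelse(all_ok, "kept", "discarded"))
  report <- data.frame(id = records$id,
                       length = nchar(records$sequence),
                       stringsAsFactors = FALSE)
  if (length(patterns) > 0L) report <- cbind(report, motif_ok)
  report$status <- status
  list(kept = records[status == "kept", , drop = FALSE],
       discarded = records[status == "discarded", , drop = FALSE],
       flagged = records[status == "flagged", , drop = FALSE],
       report = report)
}

#' Report sequences exceeding a length cutoff
#'
#' Long sequences typically carry an additional fused domain (e.g. a
#' phosphatase domain) and were excised by hand guided by the hydrolase
#' domain; this function only reports the candidates, it never trims.
#'
#' @param records Sequence record `data.frame`.
#' @param max_len Length cutoff (residues); records strictly longer are
#'   reported. Must be positive.
#' @return `data.frame` with columns `id`, `length` for flagged records.
#' @export
flag_long_sequences <- function(records, max_len = 420) {
  if (!is.numeric(max_len) || length(max_len) != 1L || max_len <= 0) {
    stop("max_len must be a positive number")
  }
  len <- nchar(records$sequence)
  over <- len > max_len
  data.frame(id = records$id[over], length = len[over],
             stringsAsFactors = FALSE)
}

#' Write a curation report as TSV
#'
#' @param report The `report` element of [filter_by_motifs] output.
#' @param path Output path.
#' @export
write_curation_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
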