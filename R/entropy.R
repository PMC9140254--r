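#' Residue frequencies of one alignment column
#'
#' Under the default gap policy (`"exclude"`) gaps are dropped and the
#' frequencies renormalize over the 20-residue alphabet; under
#' `"gap21"` the gap is counted as a 21st symbol. An all-gap column (under
#' `"exclude"`) returns an all-zero vector carrying attribute
#' `all_gap = TRUE`.
#'
#' @param x An [msa] object.
#' @param col Column index (1-based), `1 <= col <= n_columns`.
#' @param gap_policy `"exclude"` or `"gap21"`.
#' @return Named numeric frequency vector over the alphabet.
#' @export
column_frequencies <- function(x, col, gap_policy = c("exclude", "gap21")) {
  gap_policy <- match.arg(gap_policy)
  if (!is.numeric(col) || length(col) != 1L || col < 1L || col > x$n_columns) {
    stop("column index out of range: ", col)
  }
  chars <- substring(x$seqs, col, col)
  alphabet <- if (gap_policy == "gap21") c(AA_STANDARD, GAP_CHAR) else AA_STANDARD
  counts <- table(factor(chars, levels = alphabet))
  counts <- as.numeric(counts)
  names(counts) <- alphabet
  total <- sum(counts)
  if (total == 0) {
    freq <- counts
    attr(freq, "all_gap") <- TRUE
    return(freq)
  }
  counts / total
}

#' Schneider entropy of a frequency vector
#'
#' Normalized Shannon entropy: `S = -(1/ln K) * sum(p_a ln p_a)` over the
#' K-letter alphabet (K = 20 residues; 21 when the gap is counted as a
#' symbol). S = 0 for a single-symbol column and S = 1 for the uniform
#' distribution; the base of the logarithm cancels in the normalization.
#'
#' @param freq Non-negative frequency vector (renormalized internally).
#' @return Entropy in \[0, 1\].
#' @export
schneider_entropy <- function(freq) {
  if (!is.numeric(freq) || any(freq < 0)) {
    stop("freq must be a non-negative numeric vector")
  }
  total <- sum(freq)
  if (total == 0) {
    stop("entropy undefined for an all-zero frequency vector (all-gap column)")
  }
  p <- freq / total
  p <- p[p > 0]
  s <- -sum(p * log(p)) / log(length(freq))
  min(max(s, 0), 1)
}

#' Per-column Schneider entropy profile of an alignment
#'
#' One entropy value per alignment column. Columns that are entirely gaps
#' carry `NA` (an explicit missing marker, never a fabricated zero) and are
#' excluded from every downstream median and test.
#'
#' @param x An [msa] object.
#' @param gap_policy Gap handling rule; see [column_frequencies].
#' @return An object of class `entropy_profile`: list with `values`
#'   (numeric, `NA` for all-gap columns), `n_columns`, `n_nongap`
#'   (non-gap symbols per column), `gap_policy`.
#' @export
entropy_profile <- function(x, gap_policy = c("exclude", "gap21")) {
  gap_policy <- match.arg(gap_policy)
  stopifnot(inherits(x, "msa"))
  m <- as.matrix(x)
  alphabet <- if (gap_policy == "gap21") c(AA_STANDARD, GAP_CHAR) else AA_STANDARD
  k <- length(alphabet)
  idx <- match(m, alphabet)            # NA for gaps under "exclude"
  dim(idx) <- dim(m)
  logk <- log(k)
  values <- numeric(x$n_columns)
  n_nongap <- integer(x$n_columns)
  gap_idx <- match(GAP_CHAR, alphabet)
  for (j in seq_len(x$n_columns)) {
    cnt <- tabulate(idx[, j], nbins = k)
    n_nongap[j] <- sum(cnt) - if (is.na(gap_idx)) 0L else cnt[gap_idx]
    tot <- sum(cnt)
    if (tot == 0L || n_nongap[j] == 0L) {
      values[j] <- NA_real_
      next
    }
    p <- cnt[cnt > 0] / tot
    values[j] <- min(max(-sum(p * log(p)) / logk, 0), 1)
  }
  structure(list(values = values,
                 n_columns = x$n_columns,
                 n_nongap = n_nongap,
                 gap_policy = gap_policy),
            class = "entropy_profile")
}

#' @export
print.entropy_profile <- function(x, ...) {
  defined <- sum(!is.na(x$values))
  cat("Schneider entropy profile: ", x$n_columns, " columns (",
      defined, " defined), gap policy '", x$gap_policy, "'\n", sep = "")
  cat("  range: ",
      paste(signif(range(x$values, na.rm = TRUE), 4), collapse = " - "),
      "\n", sep = "")
  invisible(x)
}

#' Trim an alignment to structure-covered columns
#'
#' Retains exactly the columns at which at least one reference
#' (structure-linked) row has a non-gap residue. The retained set is the
#' background universe for all variability comparisons.
#'
#' @param x An [msa] with non-empty `reference_ids`.
#' @return An object of class `column_mask`: sorted integer vector of
#'   retained column indices (1-based) with attribute `n_columns`.
#' @export
trim_columns <- function(x) {
  stopifnot(inherits(x, "msa"))
  if (length(x$reference_ids) == 0L) {
    stop("trim_columns requires at least one reference row")
  }
  m <- as.matrix(x)[x$reference_ids, , drop = FALSE]
  retained <- which(colSums(m != GAP_CHAR) > 0L)
  structure(as.integer(retained), class = "column_mask",
            n_columns = x$n_columns)
}

#' @export
print.column_mask <- function(x, ...) {
  cat("Column mask: ", length(x), " of ", attr(x, "n_columns"),
      " columns retained\n", sep = "")
  invisible(x)
}

#' Write an entropy profile as TSV
#'
#' Columns: `column` (1-based index), `entropy` (`NA` for all-gap columns),
#' `n_nongap`.
#'
#' @param profile An [entropy_profile] object.
#' @param path Output path.
#' @export
write_entropy_tsv <- function(profile, path) {
  df <- data.frame(column = seq_len(profile$n_columns),
                   entropy = profile$values,
                   n_nongap = profile$n_nongap)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a column mask as a one-column index file
#'
#' @param mask A `column_mask`.
#' @param path Output path.
#' @export
write_mask_tsv <- function(mask, path) {
  utils::write.table(data.frame(column = as.integer(mask)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
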