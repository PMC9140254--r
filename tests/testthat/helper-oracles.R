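# Independent brute-force oracles used by unit and acceptance tests.
# These deliberately avoid the package's own code paths.

# normalized Shannon entropy of one alignment column, straight from the
# definition: count, drop gaps, renormalize, -sum p log p / log 20
oracle_column_entropy <- function(column_chars) {
  chars <- column_chars[column_chars != "-"]
  if (length(chars) == 0L) return(NA_real_)
  counts <- table(chars)
  p <- as.numeric(counts) / sum(counts)
  -sum(p * log(p)) / log(20)
}

# exhaustive window scan for a motif, no early exit, no vectorization
oracle_has_motif <- function(seq, elements) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  k <- length(elements)
  if (length(chars) < k) return(FALSE)
  for (start in 1:(length(chars) - k + 1)) {
    hit <- TRUE
    for (j in 1:k) {
      if (!(chars[start + j - 1] %in% elements[[j]])) {
        hit <- FALSE
        break
      }
    }
    if (hit) return(TRUE)
  }
  FALSE
}

# full 361-cell re-enumeration of the dual-threshold scan, recomputing
# the thresholded sets and the Jaccard distance from scratch per cell
oracle_scan <- function(occ_a, occ_b, taus = seq(0.05, 0.95, by = 0.05)) {
  key_a <- paste0(occ_a$residues$chain, ":", occ_a$residues$resseq)
  key_b <- paste0(occ_b$residues$chain, ":", occ_b$residues$resseq)
  oa <- occ_a$residues$occurrence
  ob <- occ_b$residues$occurrence
  best <- NULL
  for (ta in taus) {
    for (tb in taus) {
      sa <- key_a[oa > max(oa) * ta]
      sb <- key_b[ob > max(ob) * tb]
      if (length(sa) == 0L || length(sb) == 0L) next
      inter <- sum(sa %in% sb)
      uni <- length(sa) + length(sb) - inter
      d <- (uni - inter) / uni
      if (is.null(best) || d < best$d) best <- list(d = d, ta = ta, tb = tb)
    }
  }
  best
}

# random occurrence table for oracle comparisons
random_occurrence_table <- function(id, source = "crystal", n = 10,
                                    max_occ = 50) {
  res <- data.frame(chain = "A",
                    resseq = sample(1:40, n),
                    resname = "ALA",
                    occurrence = sample(seq_len(max_occ), n, replace = TRUE))
  nf <- if (source == "md") max_occ else NA_integer_
  occurrence_table(id, source, res, n_frames = nf)
}

# small in-memory alignment builder for entropy/mapping tests
make_msa <- function(rows, refs = character()) {
  msa(names(rows), unlist(rows, use.names = FALSE), reference_ids = refs)
}
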