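#' Tunnel-lining residue occurrence table
#'
#' Per-residue occurrence counts for one tunnel. For a crystal structure,
#' the occurrence of a residue is the number of its atoms identified as
#' tunnel-forming (all atoms weighted equally); for molecular-dynamics
#' results it is the number of snapshots in which the residue lines the
#' tunnel cluster, between 1 and the total snapshot count.
#'
#' @param tunnel_id Tunnel label (e.g. `"Tc/m"`, `"Tm1"`).
#' @param source `"crystal"` or `"md"`.
#' @param residues `data.frame` with columns `chain`, `resseq`, `resname`,
#'   `occurrence` (positive integers).
#' @param n_frames Total MD snapshot count (`md` source only).
#' @return Object of class `occurrence_table`.
#' @export
occurrence_table <- function(tunnel_id, source = c("crystal", "md"),
                             residues, n_frames = NA_integer_) {
  source <- match.arg(source)
  needed <- c("chain", "resseq", "resname", "occurrence")
  missing <- setdiff(needed, names(residues))
  if (length(missing) > 0L) {
    stop("residue table lacks columns: ", paste(missing, collapse = ", "))
  }
  if (nrow(residues) == 0L) stop("empty occurrence table for ", tunnel_id)
  if (any(residues$occurrence < 1)) {
    stop("occurrences must be >= 1 (tunnel ", tunnel_id, ")")
  }
  key <- residue_label(residues$chain, residues$resseq)
  if (anyDuplicated(key)) {
    stop("duplicate residues in occurrence table for ", tunnel_id)
  }
  if (source == "md") {
    if (is.na(n_frames)) stop("md occurrence table requires n_frames")
    if (any(residues$occurrence > n_frames)) {
      stop("occurrence exceeds n_frames in tunnel ", tunnel_id)
    }
  }
  structure(list(tunnel_id = tunnel_id, source = source,
                 residues = residues, n_frames = n_frames),
            class = "occurrence_table")
}

#' @export
print.occurrence_table <- function(x, ...) {
  cat("Occurrence table '", x$tunnel_id, "' (", x$source, "): ",
      nrow(x$residues), " residues, max occurrence ",
      max(x$residues$occurrence),
      if (x$source == "md") paste0(" of ", x$n_frames, " frames"), "\n",
      sep = "")
  invisible(x)
}

#' Threshold an occurrence table into a residue set
#'
#' Retains a residue iff its occurrence `o` strictly exceeds
#' `max(o) * tau`. The inequality is strict, so residues at the maximal
#' occurrence are always retained for any `tau < 1`.
#'
#' @param table An [occurrence_table].
#' @param tau Threshold in the open interval (0, 1).
#' @return Character vector of residue labels (`"chain:resseq"`).
#' @export
apply_threshold <- function(table, tau) {
  stopifnot(inherits(table, "occurrence_table"))
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0 || tau >= 1) {
    stop("tau must lie strictly between 0 and 1")
  }
  o <- table$residues$occurrence
  keep <- o > max(o) * tau
  residue_label(table$residues$chain[keep], table$residues$resseq[keep])
}

#' Jaccard distance between two residue sets
#'
#' `d = (|union| - |intersection|) / |union|`: 0 for identical sets, 1 for
#' disjoint sets. Undefined when both sets are empty.
#'
#' @param ta,tb Character vectors (residue sets; duplicates ignored).
#' @return Numeric scalar in \[0, 1\].
#' @export
jaccard_distance <- function(ta, tb) {
  ta <- unique(ta); tb <- unique(tb)
  u <- length(union(ta, tb))
  if (u == 0L) stop("Jaccard distance undefined for two empty sets")
  (u - length(intersect(ta, tb))) / u
}

#' Default dual-threshold grid
#'
#' @return `seq(0.05, 0.95, by = 0.05)` (19 values; the two-sided grid has
#'   361 combinations).
#' @export
tau_grid <- function() seq(0.05, 0.95, by = 0.05)

#' Scan the dual-threshold grid for the minimal Jaccard distance
#'
#' Thresholds both occurrence tables independently at every combination of
#' `taus` x `taus` and reports the combination minimizing the Jaccard
#' distance between the thresholded residue sets. Ties are broken toward
#' the lexicographically smallest `(tau_a, tau_b)`. Grid cells where a
#' thresholded set is empty are skipped (unreachable for `tau < 1`, where
#' maximal-occurrence residues always survive).
#'
#' @param a,b [occurrence_table]s (e.g. crystal and MD).
#' @param taus Threshold grid (default [tau_grid]).
#' @return List of class `tau_scan`: `d_min`, `tau_a`, `tau_b`, `grid`
#'   (distance matrix, `taus` x `taus`, `NA` for skipped cells),
#'   `n_evaluated`.
#' @export
scan_thresholds <- function(a, b, taus = tau_grid()) {
  sets_a <- lapply(taus, function(t) apply_threshold(a, t))
  sets_b <- lapply(taus, function(t) apply_threshold(b, t))
  grid <- matrix(NA_real_, length(taus), length(taus),
                 dimnames = list(tau_a = taus, tau_b = taus))
  best <- list(d = Inf, i = NA_integer_, j = NA_integer_)
  for (i in seq_along(taus)) {
    for (j in seq_along(taus)) {
      if (length(sets_a[[i]]) == 0L || length(sets_b[[j]]) == 0L) next
      d <- jaccard_distance(sets_a[[i]], sets_b[[j]])
      grid[i, j] <- d
      if (d < best$d) best <- list(d = d, i = i, j = j)
    }
  }
  n_eval <- sum(!is.na(grid))
  if (n_eval == 0L) {
    stop("all grid cells degenerate: no threshold combination evaluable")
  }
  structure(list(d_min = best$d, tau_a = taus[best$i], tau_b = taus[best$j],
                 grid = grid, n_evaluated = n_eval),
            class = "tau_scan")
}

#' @export
print.tau_scan <- function(x, ...) {
  cat(sprintf("Threshold scan: d_min = %.4f at (tau_a = %.2f, tau_b = %.2f); %d cells evaluated\n",
              x$d_min, x$tau_a, x$tau_b, x$n_evaluated))
  invisible(x)
}

#' Match crystal tunnels to MD tunnels
#'
#' Builds the full crystal x MD matrix of threshold-optimized Jaccard
#' distances ([scan_thresholds] per cell), then pairs tunnels by greedy
#' global-minimum selection: repeatedly take the smallest remaining cell
#' and remove its row and column. Ties break toward the lowest row, then
#' column, index. Unpaired leftovers (when the two sides differ in count)
#' are listed.
#'
#' @param crystal List of crystal-source [occurrence_table]s.
#' @param md List of md-source [occurrence_table]s.
#' @param taus Threshold grid passed to [scan_thresholds].
#' @return List of class `tunnel_match`: `distance` (matrix, rows =
#'   crystal tunnels), `tau_crystal`, `tau_md` (matrices of optimal
#'   thresholds per cell), `pairs` (`data.frame`: `crystal_id`, `md_id`,
#'   `distance`, `tau_crystal`, `tau_md`), `unpaired_crystal`,
#'   `unpaired_md`.
#' @export
match_tunnels <- function(crystal, md, taus = tau_grid()) {
  if (length(crystal) == 0L || length(md) == 0L) {
    stop("need at least one occurrence table on each side")
  }
  cid <- vapply(crystal, function(t) t$tunnel_id, character(1))
  mid <- vapply(md, function(t) t$tunnel_id, character(1))
  nd <- matrix(NA_real_, length(crystal), length(md),
               dimnames = list(crystal = cid, md = mid))
  ta <- nd; tb <- nd
  for (i in seq_along(crystal)) {
    for (j in seq_along(md)) {
      sc <- scan_thresholds(crystal[[i]], md[[j]], taus = taus)
      nd[i, j] <- sc$d_min
      ta[i, j] <- sc$tau_a
      tb[i, j] <- sc$tau_b
    }
  }
  # greedy assignment on the distance matrix
  d <- nd
  pairs <- list()
  while (any(is.finite(d))) {
    k <- which(d == min(d, na.rm = TRUE), arr.ind = TRUE)
    k <- k[order(k[, 1], k[, 2]), , drop = FALSE][1, ]
    i <- k[[1]]; j <- k[[2]]
    pairs[[length(pairs) + 1L]] <-
      data.frame(crystal_id = cid[i], md_id = mid[j], distance = nd[i, j],
                 tau_crystal = ta[i, j], tau_md = tb[i, j],
                 stringsAsFactors = FALSE)
    d[i, ] <- NA_real_
    d[, j] <- NA_real_
  }
  pairs <- do.call(rbind, pairs)
  structure(list(distance = nd, tau_crystal = ta, tau_md = tb,
                 pairs = pairs,
                 unpaired_crystal = setdiff(cid, pairs$crystal_id),
                 unpaired_md = setdiff(mid, pairs$md_id)),
            class = "tunnel_match")
}

#' @export
print.tunnel_match <- function(x, ...) {
  cat("Tunnel correspondence (", nrow(x$distance), " crystal x ",
      ncol(x$distance), " MD):\n", sep = "")
  print(x$pairs)
  if (length(x$unpaired_crystal)) {
    cat("unpaired crystal:", paste(x$unpaired_crystal, collapse = ", "), "\n")
  }
  if (length(x$unpaired_md)) {
    cat("unpaired md:", paste(x$unpaired_md, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read occurrence tables from TSV
#'
#' Long-format TSV with columns `tunnel_id`, `source`, `chain`, `resseq`,
#' `resname`, `occurrence` and (for md rows) `n_frames`; one
#' [occurrence_table] is built per `tunnel_id`.
#'
#' @param path TSV path.
#' @return Named list of [occurrence_table]s.
#' @export
read_occurrence_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("tunnel_id", "source", "chain", "resseq", "resname",
              "occurrence")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0L) {
    stop("occurrence table lacks columns: ", paste(missing, collapse = ", "))
  }
  if (!"n_frames" %in% names(df)) df$n_frames <- NA_integer_
  out <- lapply(split(df, df$tunnel_id), function(g) {
    occurrence_table(g$tunnel_id[1L], g$source[1L],
                     g[, c("chain", "resseq", "resname", "occurrence")],
                     n_frames = g$n_frames[1L])
  })
  out[unique(df$tunnel_id)]
}

#' Write occurrence tables to TSV
#'
#' @param tables List of [occurrence_table]s.
#' @param path Output path.
#' @export
write_occurrence_tsv <- function(tables, path) {
  rows <- lapply(tables, function(t) {
    cbind(data.frame(tunnel_id = t$tunnel_id, source = t$source,
                     stringsAsFactors = FALSE),
          t$residues[, c("chain", "resseq", "resname", "occurrence")],
          data.frame(n_frames = t$n_frames))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a tunnel match result to TSV files
#'
#' Writes `<prefix>_matrix.tsv` (optimized distance matrix) and
#' `<prefix>_pairs.tsv` (greedy pairing with optimal thresholds).
#'
#' @param match A `tunnel_match`.
#' @param prefix Output path prefix.
#' @export
write_match_tsv <- function(match, prefix) {
  mat <- data.frame(crystal_id = rownames(match$distance), match$distance,
                    check.names = FALSE)
  utils::write.table(mat, paste0(prefix, "_matrix.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(match$pairs, paste0(prefix, "_pairs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
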