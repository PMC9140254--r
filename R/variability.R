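#' Median distance between compartment and background entropies
#'
#' `median(comp) - median(bg)`. A positive value classifies the compartment
#' as variable (strictly greater than zero); zero or negative as conserved.
#'
#' @param comp_vals Entropy values of the compartment columns (no `NA`).
#' @param bg_vals Entropy values of the background columns (no `NA`).
#' @return Numeric scalar in \[-1, 1\].
#' @export
median_distance <- function(comp_vals, bg_vals) {
  if (length(comp_vals) == 0L || length(bg_vals) == 0L) {
    stop("median distance not computable: empty value list")
  }
  stats::median(comp_vals) - stats::median(bg_vals)
}

# Moore-Penrose pseudoinverse via SVD; rcond cutoff relative to the largest
# singular value. Returns the inverse plus the numerical rank.
pinv_rank <- function(m, rcond = 1e-15) {
  s <- svd(m)
  cutoff <- rcond * max(s$d)
  pos <- s$d > cutoff
  dinv <- ifelse(pos, 1 / s$d, 0)
  inv <- s$v %*% (dinv * t(s$u))
  # rank of the pseudoinverse (tolerance in the numpy matrix_rank style)
  di <- abs(dinv)
  tol <- max(di) * max(dim(m)) * .Machine$double.eps
  list(inv = inv, rank = sum(di > tol))
}

#' Epps-Singleton two-sample test
#'
#' Tests whether two samples come from the same distribution by comparing
#' their empirical characteristic functions at points `t`, scaled by the
#' semi-interquartile range of the pooled sample. Valid for discrete as
#' well as continuous data. The test statistic is asymptotically
#' chi-squared with degrees of freedom equal to the rank of the estimated
#' covariance (2 * length(t) in the regular case); the small-sample
#' correction of the original publication is applied when both samples
#' have fewer than 25 observations.
#'
#' Samples below `min_n` observations, or a pooled sample with zero
#' interquartile range, yield a missing-marker result (`NA` statistic and
#' p-value with a `reason`), not an error: variability tables report these
#' cells as NA.
#'
#' @param x,y Numeric samples.
#' @param t Evaluation points for the characteristic functions (positive).
#' @param min_n Minimum observations required per sample.
#' @return List of class `es_test` with `statistic`, `pvalue`, `df`, `n_x`,
#'   `n_y` and (when not computable) `reason`.
#' @export
epps_singleton_test <- function(x, y, t = c(0.4, 0.8), min_n = 5) {
  x <- as.numeric(x); y <- as.numeric(y)
  nx <- length(x); ny <- length(y)
  not_computable <- function(reason) {
    structure(list(statistic = NA_real_, pvalue = NA_real_, df = NA_integer_,
                   n_x = nx, n_y = ny, reason = reason),
              class = "es_test")
  }
  if (nx < min_n || ny < min_n) {
    return(not_computable(sprintf("sample size below %d", min_n)))
  }
  if (any(t <= 0)) stop("t must contain positive values only")
  n <- nx + ny
  pooled <- c(x, y)
  sigma <- diff(stats::quantile(pooled, c(0.25, 0.75), names = FALSE,
                                type = 7)) / 2
  if (sigma == 0) {
    return(not_computable("pooled sample has zero interquartile range"))
  }
  ts <- t / sigma
  # rows: observations; cols: cos(t1 x), cos(t2 x), ..., sin(t1 x), ...
  gx <- cbind(cos(outer(x, ts)), sin(outer(x, ts)))
  gy <- cbind(cos(outer(y, ts)), sin(outer(y, ts)))
  cov_x <- stats::cov(gx) * (nx - 1) / nx   # biased covariance estimate
  cov_y <- stats::cov(gy) * (ny - 1) / ny
  est_cov <- (n / nx) * cov_x + (n / ny) * cov_y
  pr <- pinv_rank(est_cov)
  g_diff <- colMeans(gx) - colMeans(gy)
  w <- n * drop(t(g_diff) %*% pr$inv %*% g_diff)
  if (max(nx, ny) < 25) {
    w <- w / (1 + n^(-0.45) + 10.1 * (nx^(-1.7) + ny^(-1.7)))
  }
  structure(list(statistic = w,
                 pvalue = stats::pchisq(w, df = pr$rank, lower.tail = FALSE),
                 df = pr$rank, n_x = nx, n_y = ny, reason = NA_character_),
            class = "es_test")
}

#' @export
print.es_test <- function(x, ...) {
  if (is.na(x$statistic)) {
    cat("Epps-Singleton test: not computable (", x$reason, ")\n", sep = "")
  } else {
    cat(sprintf("Epps-Singleton test: W2 = %.4g, df = %d, p = %.4g (n = %d, %d)\n",
                x$statistic, x$df, x$pvalue, x$n_x, x$n_y))
  }
  invisible(x)
}

#' Classify a compartment as conserved or variable
#'
#' Computes the median distance between a compartment's entropy values and
#' the background, labels the compartment (`variable` iff the median
#' distance is strictly positive) and attaches an Epps-Singleton p-value.
#' Columns with undefined (`NA`) entropy are dropped before any statistic.
#'
#' @param name Compartment name.
#' @param comp_cols Compartment column indices.
#' @param bg_cols Background column indices.
#' @param profile An [entropy_profile].
#' @param subgroup Label recorded in the report (`all`, `no_surface`,
#'   `surface_only`).
#' @param min_n Minimum per-sample size for the Epps-Singleton test.
#' @return One-row `data.frame` of class `variability_report`: `name`,
#'   `subgroup`, `n_comp`, `n_bg`, `median_comp`, `median_bg`,
#'   `median_distance`, `es_statistic`, `es_pvalue`, `label`.
#' @export
classify_compartment <- function(name, comp_cols, bg_cols, profile,
                                 subgroup = "all", min_n = 5) {
  stopifnot(inherits(profile, "entropy_profile"))
  bad <- setdiff(c(comp_cols, bg_cols), seq_len(profile$n_columns))
  if (length(bad) > 0L) {
    stop("column index out of profile range: ", paste(bad, collapse = ", "))
  }
  comp_vals <- profile$values[comp_cols]
  comp_vals <- comp_vals[!is.na(comp_vals)]
  bg_vals <- profile$values[bg_cols]
  bg_vals <- bg_vals[!is.na(bg_vals)]
  if (length(comp_vals) == 0L || length(bg_vals) == 0L) {
    out <- data.frame(name = name, subgroup = subgroup,
                      n_comp = length(comp_vals), n_bg = length(bg_vals),
                      median_comp = NA_real_, median_bg = NA_real_,
                      median_distance = NA_real_,
                      es_statistic = NA_real_, es_pvalue = NA_real_,
                      label = NA_character_, stringsAsFactors = FALSE)
    class(out) <- c("variability_report", "data.frame")
    return(out)
  }
  md <- median_distance(comp_vals, bg_vals)
  es <- epps_singleton_test(comp_vals, bg_vals, min_n = min_n)
  out <- data.frame(name = name, subgroup = subgroup,
                    n_comp = length(comp_vals), n_bg = length(bg_vals),
                    median_comp = stats::median(comp_vals),
                    median_bg = stats::median(bg_vals),
                    median_distance = md,
                    es_statistic = es$statistic, es_pvalue = es$pvalue,
                    label = if (md > 0) "variable" else "conserved",
                    stringsAsFactors = FALSE)
  class(out) <- c("variability_report", "data.frame")
  out
}

#' Variability report for a set of compartments with surface subgroups
#'
#' For every compartment, produces the `all`, `no_surface` and
#' `surface_only` rows of the classification table. Subgroups are formed by
#' filtering compartment residues on their surface class before column
#' lookup; the three residue sets `no_surface` and `surface_only` are
#' disjoint and union to the full compartment. The background is always
#' the trimmed mask minus the full compartment's columns.
#'
#' @param compartments Compartment table ([read_compartments_tsv] layout).
#' @param mapping A `column_mapping` for the structure.
#' @param annotations Annotation table ([read_annotations_tsv] layout).
#' @param profile An [entropy_profile].
#' @param mask A `column_mask` from [trim_columns].
#' @param min_n Minimum per-sample size for the Epps-Singleton test.
#' @return `data.frame` with one row per (compartment, subgroup).
#' @export
compartment_variability <- function(compartments, mapping, annotations,
                                    profile, mask, min_n = 5) {
  ann_key <- residue_label(annotations$chain, annotations$resseq)
  rows <- list()
  for (nm in unique(compartments$compartment)) {
    comp <- compartments[compartments$compartment == nm, , drop = FALSE]
    cols_all <- compartment_columns(comp, mapping)
    bg <- background_columns(mask, cols_all)
    surf <- annotations$surface_class[match(residue_label(comp$chain,
                                                          comp$resseq),
                                            ann_key)]
    if (anyNA(surf)) {
      stop("compartment '", nm, "' has unannotated residue(s)")
    }
    subsets <- list(all = comp,
                    no_surface = comp[surf == "buried", , drop = FALSE],
                    surface_only = comp[surf == "surface", , drop = FALSE])
    for (sg in names(subsets)) {
      cols <- compartment_columns(subsets[[sg]], mapping)
      rows[[length(rows) + 1L]] <-
        classify_compartment(nm, cols, bg, profile, subgroup = sg,
                             min_n = min_n)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pair background entropies to tunnel entropies by CDF matching
#'
#' For each tunnel value, taken in ascending order, finds the yet-unused
#' background value whose empirical CDF position is closest to the tunnel
#' value's; ties are broken toward the smaller background value. Used to
#' draw paired CDF profiles of a tunnel against the trimmed-background
#' distribution.
#'
#' @param tunnel_vals Entropy values of the tunnel columns.
#' @param bg_vals Entropy values of the background columns (at least as
#'   many as `tunnel_vals` for pairing without replacement; fewer is an
#'   error).
#' @return `data.frame` with columns `tunnel_val`, `tunnel_cdf`, `bg_val`,
#'   `bg_cdf`, one row per tunnel value, in ascending tunnel order.
#' @export
cdf_pairing <- function(tunnel_vals, bg_vals) {
  if (length(tunnel_vals) == 0L) stop("empty tunnel value list")
  if (length(bg_vals) == 0L) stop("empty background value list")
  if (length(bg_vals) < length(tunnel_vals)) {
    stop("background smaller than tunnel: pairing without replacement ",
         "impossible")
  }
  tv <- sort(tunnel_vals)
  bv <- sort(bg_vals)
  n <- length(tv); m <- length(bv)
  t_cdf <- seq_len(n) / n
  b_cdf <- seq_len(m) / m
  used <- rep(FALSE, m)
  out <- data.frame(tunnel_val = tv, tunnel_cdf = t_cdf,
                    bg_val = NA_real_, bg_cdf = NA_real_)
  for (i in seq_len(n)) {
    cand <- which(!used)
    gap <- abs(b_cdf[cand] - t_cdf[i])
    # which.min takes the first minimum; candidates are in ascending value
    # order, so ties already resolve toward the smaller background value
    j <- cand[which.min(gap)]
    used[j] <- TRUE
    out$bg_val[i] <- bv[j]
    out$bg_cdf[i] <- b_cdf[j]
  }
  out
}

#' Write a variability report as TSV
#'
#' @param report Output of [compartment_variability] or rbind-ed
#'   [classify_compartment] rows.
#' @param path Output path.
#' @export
write_variability_tsv <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
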