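#' Dirichlet concentrations behind the synthetic column classes
#'
#' Each synthetic alignment column draws its residue distribution from a
#' symmetric Dirichlet; the concentration is the entropy dial. The values
#' below were calibrated empirically (n_seqs = 500, thousands of columns):
#'
#' | class      | alpha  | realized Schneider entropy            |
#' |------------|--------|---------------------------------------|
#' | conserved  | 5e-4   | mean ~0.005, 98% of columns <= 0.15   |
#' | background | 0.1    | mean ~0.44, spread ~0.10-0.68         |
#' | variable   | 1.5    | mean ~0.90, essentially all >= 0.6    |
#'
#' @export
SYNTH_ALPHA <- c(conserved = 5e-4, background = 0.1, variable = 1.5)

# one symmetric-Dirichlet draw over the 20-residue alphabet
rdirichlet20 <- function(alpha) {
  g <- stats::rgamma(20L, shape = alpha)
  if (sum(g) == 0) g[sample.int(20L, 1L)] <- 1   # guard against underflow
  g / sum(g)
}

#' Generate a synthetic alignment with planted column classes
#'
#' Emulates the statistical structure of a large curated enzyme-family
#' alignment: a mix of conserved, mid-variability (background) and variable
#' columns, gap-rich columns, and a set of gap-free reference rows standing
#' in for the structure-linked sequences. Column residue distributions are
#' symmetric-Dirichlet draws (see [SYNTH_ALPHA]); sequences are sampled
#' independently per column. A fraction of columns is planted all-gap in
#' every reference row (`ref_gap`) so that alignment trimming has work to
#' do; those columns carry residues in non-reference rows.
#'
#' @param n_seqs Number of non-reference sequences (>= 2).
#' @param n_cols Number of alignment columns.
#' @param n_ref Number of reference rows (ids `REF1`, `REF2`, ...).
#' @param frac_conserved,frac_variable Fractions of columns planted
#'   conserved / variable; the rest (minus `frac_ref_gap`) is background.
#' @param frac_ref_gap Fraction of columns gapped in all reference rows.
#' @param frac_gappy Fraction of columns that receive random gaps in
#'   non-reference rows (gap rate per such column uniform in 0.1-0.6).
#' @param seed Integer seed; the output is fully determined by it.
#' @return List with `msa` (an [msa], reference rows included) and `truth`
#'   (`data.frame`: `column`, `class`, `alpha`, `gap_fraction`).
#' @export
gen_msa <- function(n_seqs = 500, n_cols = 300, n_ref = 7,
                    frac_conserved = 0.25, frac_variable = 0.35,
                    frac_ref_gap = 0.05, frac_gappy = 0.2, seed = 1) {
  if (n_seqs < 2) stop("n_seqs must be at least 2")
  if (frac_conserved + frac_variable + frac_ref_gap >= 1) {
    stop("column-class fractions leave no room for background columns")
  }
  set.seed(seed)
  n_con <- round(n_cols * frac_conserved)
  n_var <- round(n_cols * frac_variable)
  n_rg <- round(n_cols * frac_ref_gap)
  classes <- sample(c(rep("conserved", n_con), rep("variable", n_var),
                      rep("ref_gap", n_rg),
                      rep("background", n_cols - n_con - n_var - n_rg)))
  # ref_gap columns draw from the background concentration
  alpha <- SYNTH_ALPHA[ifelse(classes == "ref_gap", "background", classes)]
  m <- matrix("", nrow = n_seqs + n_ref, ncol = n_cols)
  for (j in seq_len(n_cols)) {
    p <- rdirichlet20(alpha[j])
    m[, j] <- AA_STANDARD[sample.int(20L, n_seqs + n_ref, replace = TRUE,
                                     prob = p)]
  }
  ref_rows <- seq_len(n_ref)
  seq_rows <- n_ref + seq_len(n_seqs)
  # gaps in non-reference rows
  gap_frac <- numeric(n_cols)
  gappy <- sample(which(classes != "ref_gap"),
                  round(n_cols * frac_gappy))
  gap_frac[gappy] <- stats::runif(length(gappy), 0.1, 0.6)
  for (j in gappy) {
    hit <- stats::runif(n_seqs) < gap_frac[j]
    m[seq_rows[hit], j] <- GAP_CHAR
  }
  # reference rows: gap-free except on planted ref_gap columns
  m[ref_rows, classes == "ref_gap"] <- GAP_CHAR
  ids <- c(paste0("REF", seq_len(n_ref)),
           sprintf("S%04d", seq_len(n_seqs)))
  seqs <- apply(m, 1L, paste0, collapse = "")
  list(msa = msa(ids, seqs, reference_ids = paste0("REF", seq_len(n_ref))),
       truth = data.frame(column = seq_len(n_cols), class = classes,
                          alpha = unname(alpha), gap_fraction = gap_frac,
                          stringsAsFactors = FALSE))
}

#' Generate a toy structure consistent with a synthetic alignment
#'
#' Builds a C-alpha-only chain for one reference row: one residue per
#' non-gap position, placed on a spherical spiral with the radius set by
#' residue class, so that buried residues sit nearer the centroid than
#' surface residues. Active-site residues are drawn from conserved
#' columns, surface residues from variable columns, the rest is buried.
#' Also emits the matching annotation table and compartment tables
#' (`AS` active site, `BAA` buried, `SAA` surface, and two tunnels: `TUN1`
#' reaching from the active site through buried residues to the surface,
#' `TUN2` a surface-dominated lining).
#'
#' @param msa_obj An [msa] from [gen_msa].
#' @param truth The matching ground-truth `data.frame`.
#' @param ref_id Reference row to realize as a structure.
#' @param n_active Number of active-site residues.
#' @param seed Integer seed.
#' @return List with `structure` (a `structure_residues` data.frame),
#'   `annotations`, `compartments`, `residue_truth` (per-residue class and
#'   column), and `structure_id`.
#' @export
gen_structure <- function(msa_obj, truth, ref_id = "REF1", n_active = 10,
                          seed = 1) {
  stopifnot(inherits(msa_obj, "msa"), ref_id %in% msa_obj$reference_ids)
  set.seed(seed)
  row <- strsplit(msa_obj$seqs[match(ref_id, msa_obj$ids)], "",
                  fixed = TRUE)[[1]]
  cols <- which(row != GAP_CHAR)
  n_res <- length(cols)
  cls <- truth$class[cols]
  klass <- ifelse(cls == "variable", "surface", "buried")
  cons_pos <- which(cls == "conserved")
  if (length(cons_pos) < n_active) {
    stop("not enough conserved columns in the reference row for the ",
         "requested active site")
  }
  klass[sample(cons_pos, n_active)] <- "active_site"
  radius <- numeric(n_res)
  radius[klass == "active_site"] <- stats::runif(sum(klass == "active_site"), 3, 5)
  radius[klass == "buried"] <- stats::runif(sum(klass == "buried"), 7, 12)
  radius[klass == "surface"] <- stats::runif(sum(klass == "surface"), 16, 21)
  # spherical Fibonacci spiral for well-spread directions
  i <- seq_len(n_res)
  phi <- acos(1 - 2 * (i - 0.5) / n_res)
  theta <- pi * (1 + sqrt(5)) * i
  structure_id <- paste0("SYN_", ref_id)
  st <- data.frame(structure_id = structure_id, chain = "A",
                   resseq = seq_len(n_res), ins = "",
                   resname = bio3d::aa123(row[cols]),
                   aa = row[cols],
                   x = radius * sin(phi) * cos(theta),
                   y = radius * sin(phi) * sin(theta),
                   z = radius * cos(phi),
                   has_ca = TRUE, stringsAsFactors = FALSE)
  class(st) <- c("structure_residues", "data.frame")
  ann <- data.frame(structure_id = structure_id, chain = "A",
                    resseq = st$resseq,
                    surface_class = ifelse(klass == "surface", "surface",
                                           "buried"),
                    is_active_site = klass == "active_site",
                    stringsAsFactors = FALSE)
  comp_of <- function(resseq, name) {
    idx <- match(resseq, st$resseq)
    data.frame(structure_id = structure_id, chain = "A", resseq = resseq,
               resname = st$resname[idx], compartment = name,
               stringsAsFactors = FALSE)
  }
  as_res <- st$resseq[klass == "active_site"]
  saa_res <- st$resseq[klass == "surface"]
  baa_res <- st$resseq[klass == "buried"]
  tun1 <- c(sample(as_res, min(2L, length(as_res))),
            sample(baa_res, min(8L, length(baa_res))),
            sample(saa_res, min(5L, length(saa_res))))
  tun2 <- c(sample(baa_res, min(3L, length(baa_res))),
            sample(saa_res, min(10L, length(saa_res))))
  compartments <- rbind(comp_of(as_res, "AS"), comp_of(baa_res, "BAA"),
                        comp_of(saa_res, "SAA"), comp_of(sort(tun1), "TUN1"),
                        comp_of(sort(tun2), "TUN2"))
  list(structure = st, annotations = ann, compartments = compartments,
       residue_truth = data.frame(resseq = st$resseq, column = cols,
                                  klass = klass, stringsAsFactors = FALSE),
       structure_id = structure_id)
}

#' Write a C-alpha-only structure as PDB text
#'
#' @param structure A `structure_residues` data.frame.
#' @param path Output PDB path.
#' @export
write_pdb_ca <- function(structure, path) {
  lines <- sprintf("ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
                   seq_len(nrow(structure)), structure$resname,
                   structure$chain, structure$resseq,
                   structure$x, structure$y, structure$z)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Generate crystal/MD occurrence tables with a planted correspondence
#'
#' Each planted tunnel has a core of high-occurrence residues (disjoint
#' between tunnels) and a fringe of low-occurrence residues. The crystal
#' table counts atoms (small integers); the matched MD table counts
#' snapshots out of `n_frames`, shares the full core, and has each fringe
#' residue replaced by a random non-member at the stated noise rate. MD
#' tables are emitted in shuffled order under fresh ids, with the true
#' pairing returned alongside.
#'
#' @param n_tunnels Number of planted tunnels.
#' @param residues Residue universe (`data.frame` with `chain`, `resseq`,
#'   `resname`); defaults to a synthetic 250-residue chain.
#' @param core_size,fringe_size Residues per tunnel core / fringe.
#' @param noise Per-fringe-residue replacement probability in the MD table.
#' @param n_frames Total MD snapshot count.
#' @param seed Integer seed.
#' @return List with `crystal` and `md` (lists of [occurrence_table]),
#'   and `pairing` (`data.frame`: `crystal_id`, `md_id`).
#' @export
gen_occurrence_tables <- function(n_tunnels = 4, residues = NULL,
                                  core_size = 14, fringe_size = 10,
                                  noise = 0.1, n_frames = 1000, seed = 1) {
  if (n_tunnels < 1) stop("tunnel plan is empty")
  set.seed(seed)
  if (is.null(residues)) {
    residues <- data.frame(chain = "A", resseq = seq_len(250),
                           resname = bio3d::aa123(
                             sample(AA_STANDARD, 250, replace = TRUE)),
                           stringsAsFactors = FALSE)
  }
  n_univ <- nrow(residues)
  need <- n_tunnels * core_size
  if (need > n_univ) stop("residue universe too small for disjoint cores")
  core_pool <- sample.int(n_univ, need)
  crystal <- list(); md <- list()
  for (k in seq_len(n_tunnels)) {
    core <- core_pool[((k - 1) * core_size + 1):(k * core_size)]
    fringe <- sample(setdiff(seq_len(n_univ), core), fringe_size)
    cr_idx <- c(core, fringe)
    cr <- residues[cr_idx, , drop = FALSE]
    cr$occurrence <- c(sample(20:45, core_size, replace = TRUE),
                       sample(1:6, fringe_size, replace = TRUE))
    crystal[[k]] <- occurrence_table(paste0("T", k), "crystal", cr)
    flip <- stats::runif(fringe_size) < noise
    md_fringe <- fringe
    if (any(flip)) {
      md_fringe[flip] <- sample(setdiff(seq_len(n_univ), c(core, fringe)),
                                sum(flip))
    }
    md_idx <- c(core, md_fringe)
    mdr <- residues[md_idx, , drop = FALSE]
    mdr$occurrence <- c(round(n_frames * stats::runif(core_size, 0.55, 0.95)),
                        pmax(1, round(n_frames *
                                        stats::runif(fringe_size, 0.01, 0.2))))
    md[[k]] <- occurrence_table(paste0("MD", k), "md", mdr,
                                n_frames = n_frames)
  }
  ord <- sample.int(n_tunnels)
  md_shuffled <- md[ord]
  pairing <- data.frame(crystal_id = paste0("T", ord),
                        md_id = vapply(md_shuffled,
                                       function(t) t$tunnel_id, character(1)),
                        stringsAsFactors = FALSE)
  list(crystal = crystal, md = md_shuffled,
       pairing = pairing[order(pairing$crystal_id), , drop = FALSE])
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper chaining [gen_msa], [gen_structure] and
#' [gen_occurrence_tables] with sub-seeds derived from one master seed.
#'
#' @param seed Master integer seed.
#' @param n_seqs,n_cols Alignment size.
#' @param ... Passed to [gen_occurrence_tables].
#' @return List with elements `msa`, `truth`, `structure`, `annotations`,
#'   `compartments`, `residue_truth`, `occurrences` (crystal/md/pairing).
#' @export
gen_study <- function(seed = 1, n_seqs = 500, n_cols = 300, ...) {
  g <- gen_msa(n_seqs = n_seqs, n_cols = n_cols, seed = seed)
  s <- gen_structure(g$msa, g$truth, seed = seed + 1L)
  occ <- gen_occurrence_tables(residues = s$structure[, c("chain", "resseq",
                                                          "resname")],
                               seed = seed + 2L, ...)
  c(g, s[c("structure", "annotations", "compartments", "residue_truth")],
    list(occurrences = occ))
}
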