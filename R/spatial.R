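#' Geometric centre of the C-alpha atoms
#'
#' Arithmetic mean of the C-alpha coordinates; residues lacking a C-alpha
#' are excluded.
#'
#' @param structure A `structure_residues` data.frame ([read_structure]).
#' @return Numeric length-3 vector (Angstrom).
#' @export
ca_centroid <- function(structure) {
  ok <- structure$has_ca
  if (!any(ok)) stop("no C-alpha atoms in structure")
  c(mean(structure$x[ok]), mean(structure$y[ok]), mean(structure$z[ok]))
}

#' Distance of a residue's C-alpha from a reference point
#'
#' @param structure A `structure_residues` data.frame.
#' @param chain,resseq Residue selector.
#' @param centroid Reference point (e.g. [ca_centroid]).
#' @return Euclidean distance in Angstrom; `NA` for a residue lacking a
#'   C-alpha.
#' @export
residue_distance <- function(structure, chain, resseq, centroid) {
  i <- match(residue_label(chain, resseq),
             residue_label(structure$chain, structure$resseq))
  if (is.na(i)) stop("residue not in structure: ", residue_label(chain, resseq))
  if (!structure$has_ca[i]) return(NA_real_)
  sqrt((structure$x[i] - centroid[1])^2 +
       (structure$y[i] - centroid[2])^2 +
       (structure$z[i] - centroid[3])^2)
}

#' Entropy-versus-distance profile of a tunnel
#'
#' One point per tunnel residue with defined entropy: its Schneider
#' entropy (from the mapped alignment column), its C-alpha distance from
#' the protein's C-alpha centroid, and its residue class. Active-site
#' membership overrides the surface/buried class for the three-way
#' colouring. A marginal histogram of entropy counts per class is attached
#' as attribute `histogram`.
#'
#' @param tunnel `data.frame` of tunnel residues (`chain`, `resseq`).
#' @param mapping A `column_mapping` ([map_structure_to_msa]).
#' @param profile An [entropy_profile].
#' @param annotations Annotation table ([read_annotations_tsv] layout).
#' @param structure A `structure_residues` data.frame.
#' @param bin_width Entropy histogram bin width (default 0.05).
#' @return `data.frame` of class `spatial_profile` with columns `chain`,
#'   `resseq`, `resname`, `entropy`, `distance`, `klass` (one of
#'   `active_site`, `surface`, `buried`).
#' @export
build_spatial_profile <- function(tunnel, mapping, profile, annotations,
                                  structure, bin_width = 0.05) {
  cols <- compartment_columns(tunnel, mapping)
  key <- residue_label(tunnel$chain, tunnel$resseq)
  ann_idx <- match(key, residue_label(annotations$chain, annotations$resseq))
  if (anyNA(ann_idx)) {
    stop("unannotated tunnel residue(s): ",
         paste(key[is.na(ann_idx)], collapse = ", "))
  }
  klass <- ifelse(annotations$is_active_site[ann_idx], "active_site",
                  annotations$surface_class[ann_idx])
  centroid <- ca_centroid(structure)
  dist <- vapply(seq_len(nrow(tunnel)), function(i) {
    residue_distance(structure, tunnel$chain[i], tunnel$resseq[i], centroid)
  }, numeric(1))
  struct_idx <- match(key, residue_label(structure$chain, structure$resseq))
  out <- data.frame(chain = tunnel$chain, resseq = tunnel$resseq,
                    resname = structure$resname[struct_idx],
                    entropy = profile$values[cols],
                    distance = dist, klass = klass,
                    stringsAsFactors = FALSE)
  out <- out[!is.na(out$entropy), , drop = FALSE]
  breaks <- seq(0, 1, by = bin_width)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  hist_tab <- table(klass = out$klass,
                    bin = cut(out$entropy, breaks = breaks,
                              include.lowest = TRUE))
  class(out) <- c("spatial_profile", "data.frame")
  attr(out, "histogram") <- hist_tab
  attr(out, "centroid") <- centroid
  out
}

#' Write a spatial profile as plot-ready TSV
#'
#' @param sp A `spatial_profile`.
#' @param path Output path.
#' @export
write_spatial_tsv <- function(sp, path) {
  utils::write.table(as.data.frame(sp), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
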