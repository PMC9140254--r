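#' Read protein residues and C-alpha coordinates from a PDB file
#'
#' Returns one entry per protein residue in file order (author numbering,
#' insertion codes preserved in the ordering). HETATM records (ligands,
#' waters) are skipped. Residues lacking a C-alpha atom are retained but
#' flagged (`has_ca = FALSE`, `NA` coordinates).
#'
#' @param path PDB file path.
#' @param structure_id Identifier attached to the residues (default: file
#'   name without extension).
#' @param chain Optional chain id(s) to restrict to.
#' @param resid_range Optional length-2 integer vector `c(first, last)`
#'   restricting author residue numbers, e.g. to a single catalytic domain.
#' @return `data.frame` of class `structure_residues` with columns
#'   `structure_id`, `chain`, `resseq`, `ins`, `resname`, `aa` (one-letter),
#'   `x`, `y`, `z` (C-alpha, Angstrom), `has_ca`.
#' @export
read_structure <- function(path, structure_id = NULL, chain = NULL,
                           resid_range = NULL) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  if (is.null(structure_id)) {
    structure_id <- tools::file_path_sans_ext(basename(path))
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (!is.null(chain)) at <- at[at$chain %in% chain, , drop = FALSE]
  if (!is.null(resid_range)) {
    at <- at[at$resno >= resid_range[1] & at$resno <= resid_range[2], ,
             drop = FALSE]
  }
  if (nrow(at) == 0L) stop("no protein ATOM records in ", path)
  ins <- ifelse(is.na(at$insert), "", at$insert)
  res_key <- paste(at$chain, at$resno, ins, sep = "|")
  first <- !duplicated(res_key)
  res <- data.frame(structure_id = structure_id,
                    chain = at$chain[first],
                    resseq = at$resno[first],
                    ins = ins[first],
                    resname = at$resid[first],
                    stringsAsFactors = FALSE)
  ca <- at[at$elety == "CA", , drop = FALSE]
  ca_key <- paste(ca$chain, ca$resno, ifelse(is.na(ca$insert), "", ca$insert),
                  sep = "|")
  ord <- match(paste(res$chain, res$resseq, res$ins, sep = "|"), ca_key)
  res$aa <- bio3d::aa321(res$resname)
  res$x <- ca$x[ord]
  res$y <- ca$y[ord]
  res$z <- ca$z[ord]
  res$has_ca <- !is.na(ord)
  class(res) <- c("structure_residues", "data.frame")
  res
}

#' @keywords internal
residue_label <- function(chain, resseq) paste0(chain, ":", resseq)

#' Map structure residues onto alignment columns
#'
#' The k-th structure residue maps to the column of the k-th non-gap symbol
#' of the structure's reference row. The ungapped reference row must equal
#' the structure-derived one-letter sequence exactly; a mismatch is a data
#' error and reported at its first position — there is no silent
#' realignment.
#'
#' @param structure A `structure_residues` data.frame ([read_structure]).
#' @param x An [msa].
#' @param ref_id Reference row id (must be in `x$reference_ids`).
#' @return `data.frame` of class `column_mapping` with the structure
#'   residue columns plus `column` (1-based alignment column); attributes
#'   `structure_id` and `ref_id`.
#' @export
map_structure_to_msa <- function(structure, x, ref_id) {
  stopifnot(inherits(x, "msa"))
  if (!ref_id %in% x$reference_ids) {
    stop("'", ref_id, "' is not a reference row of this alignment")
  }
  row <- x$seqs[match(ref_id, x$ids)]
  chars <- strsplit(row, "", fixed = TRUE)[[1]]
  nongap_cols <- which(chars != GAP_CHAR)
  ref_seq <- chars[nongap_cols]
  struct_seq <- structure$aa
  if (length(struct_seq) != length(ref_seq)) {
    stop("structure has ", length(struct_seq), " residues but reference row '",
         ref_id, "' has ", length(ref_seq), " non-gap positions")
  }
  mismatch <- which(struct_seq != ref_seq)
  if (length(mismatch) > 0L) {
    k <- mismatch[1L]
    stop("structure sequence disagrees with reference row '", ref_id,
         "' at position ", k, ": structure '", struct_seq[k],
         "' vs alignment '", ref_seq[k], "'")
  }
  out <- structure
  out$column <- nongap_cols
  class(out) <- c("column_mapping", "data.frame")
  attr(out, "structure_id") <- structure$structure_id[1L]
  attr(out, "ref_id") <- ref_id
  out
}

#' Read a compartment definition table
#'
#' TSV with columns `structure_id`, `chain`, `resseq`, `resname`,
#' `compartment` — one row per (residue, compartment) membership.
#'
#' @param path TSV path.
#' @return `data.frame` with those columns.
#' @export
read_compartments_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("structure_id", "chain", "resseq", "resname", "compartment")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0L) {
    stop("compartment table lacks columns: ", paste(missing, collapse = ", "))
  }
  df
}

#' Read a per-residue annotation table
#'
#' TSV with columns `structure_id`, `chain`, `resseq`, `surface_class`
#' (`surface` or `buried`) and `is_active_site` (logical). Annotations are
#' consumed, never predicted, by this package.
#'
#' @param path TSV path.
#' @return `data.frame`.
#' @export
read_annotations_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("structure_id", "chain", "resseq", "surface_class",
              "is_active_site")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0L) {
    stop("annotation table lacks columns: ", paste(missing, collapse = ", "))
  }
  bad <- setdiff(unique(df$surface_class), c("surface", "buried"))
  if (length(bad) > 0L) {
    stop("unknown surface_class value(s): ", paste(bad, collapse = ", "))
  }
  df$is_active_site <- as.logical(df$is_active_site)
  df
}

#' Alignment columns of a compartment
#'
#' Looks up every compartment residue (by chain and author residue number)
#' in a [map_structure_to_msa] mapping. Injective: the output has exactly
#' one column per residue.
#'
#' @param comp `data.frame` with `chain` and `resseq` columns (one row per
#'   compartment residue).
#' @param mapping A `column_mapping`.
#' @return Integer vector of alignment columns (1-based).
#' @export
compartment_columns <- function(comp, mapping) {
  if (nrow(comp) == 0L) return(integer())
  idx <- match(residue_label(comp$chain, comp$resseq),
               residue_label(mapping$chain, mapping$resseq))
  if (anyNA(idx)) {
    bad <- residue_label(comp$chain, comp$resseq)[is.na(idx)]
    stop("compartment residue(s) absent from structure mapping: ",
         paste(bad, collapse = ", "))
  }
  mapping$column[idx]
}

#' Background columns for a compartment comparison
#'
#' The retained (structure-trimmed) columns minus the compartment's own
#' columns: positions where no residue of the analysed compartment is
#' present but at least one reference structure has a residue.
#'
#' @param mask A `column_mask` from [trim_columns].
#' @param comp_cols Integer vector of compartment columns.
#' @return Integer vector of background columns.
#' @export
background_columns <- function(mask, comp_cols) {
  outside <- setdiff(comp_cols, as.integer(mask))
  if (length(outside) > 0L) {
    warning("compartment column(s) outside the trimmed mask: ",
            paste(outside, collapse = ", "))
  }
  setdiff(as.integer(mask), as.integer(comp_cols))
}
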