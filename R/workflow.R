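#' Read and validate a run configuration
#'
#' YAML key/value configuration driving the pipeline stages. Every
#' behavioural default that the analysis depends on is an explicit key:
#' motif definitions, the length cutoff, the gap policy, the
#' Epps-Singleton minimum sample size, the threshold grid, the seed.
#'
#' @param path YAML file path.
#' @return List of class `run_config` (defaults filled in).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  defaults <- list(seed = 1L, out_dir = ".",
                   max_len = 420, strict_alphabet = FALSE,
                   aromatic_x = FALSE, gap_policy = "exclude",
                   es_min_n = 5,
                   tau_min = 0.05, tau_max = 0.95, tau_step = 0.05,
                   reference_ids = NULL,
                   msa = NULL, sequences = NULL, structure = NULL,
                   ref_id = NULL, compartments = NULL, annotations = NULL,
                   occurrences = NULL, tunnel = NULL)
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  structure(cfg, class = "run_config")
}

#' @keywords internal
config_taus <- function(cfg) {
  seq(cfg$tau_min, cfg$tau_max, by = cfg$tau_step)
}

# validate the input paths a subcommand needs; all problems at once
check_inputs <- function(cfg, keys) {
  problems <- character()
  for (k in keys) {
    p <- cfg[[k]]
    if (is.null(p)) {
      problems <- c(problems, sprintf("config key '%s' is required", k))
    } else if (!file.exists(p)) {
      problems <- c(problems, sprintf("input '%s' not found: %s", k, p))
    }
  }
  if (length(problems) > 0L) {
    stop("configuration invalid:\n  ", paste(problems, collapse = "\n  "))
  }
  invisible(TRUE)
}

# run manifest: inputs with checksums, settings in effect, package version.
# No timestamps: re-running on unchanged inputs must be byte-identical.
write_manifest <- function(cfg, command, inputs, outputs, extra = list()) {
  existing <- if (length(inputs) == 0L) list() else {
    inputs[file.exists(unlist(inputs))]
  }
  manifest <- list(command = command,
                   package = "tunvar",
                   version = as.character(utils::packageVersion("tunvar")),
                   seed = cfg$seed,
                   settings = cfg[setdiff(names(unclass(cfg)),
                                          c("msa", "sequences", "structure",
                                            "compartments", "annotations",
                                            "occurrences", "tunnel",
                                            "out_dir"))],
                   inputs = lapply(existing, function(p) {
                     list(path = p, md5 = unname(tools::md5sum(p)))
                   }),
                   outputs = outputs)
  manifest <- c(manifest, extra)
  path <- file.path(cfg$out_dir, paste0(command, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Pipeline subcommands
#'
#' Each subcommand reads its inputs from a [read_run_config] configuration,
#' runs one pipeline stage, writes the stage's TSV artifacts into
#' `cfg$out_dir` and drops a JSON manifest recording the inputs (with
#' checksums), every setting in effect and the package version. Outputs
#' are deterministic: re-running on unchanged inputs reproduces them
#' byte-identically.
#'
#' * `cmd_synth`: generate a full synthetic study (alignment FASTA,
#'   PDB, compartment/annotation/occurrence TSVs, ground-truth JSON).
#' * `cmd_curate`: deduplicate + motif-filter + length-flag sequences.
#' * `cmd_entropy`: entropy profile and trimmed-column mask of an MSA.
#' * `cmd_classify`: compartment variability report.
#' * `cmd_match`: crystal-vs-MD tunnel correspondence.
#' * `cmd_profile`: entropy-versus-distance tunnel profile.
#'
#' @param cfg A `run_config`.
#' @return The stage's main result, invisibly.
#' @name cli_commands
NULL

#' @rdname cli_commands
#' @export
cmd_synth <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  study <- gen_study(seed = cfg$seed)
  out <- function(f) file.path(cfg$out_dir, f)
  write_fasta(study$msa, out("synthetic_msa.fasta"))
  write_pdb_ca(study$structure, out("synthetic_structure.pdb"))
  utils::write.table(study$compartments, out("synthetic_compartments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$annotations, out("synthetic_annotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_occurrence_tsv(c(study$occurrences$crystal, study$occurrences$md),
                       out("synthetic_occurrences.tsv"))
  jsonlite::write_json(list(column_truth = study$truth,
                            residue_truth = study$residue_truth,
                            pairing = study$occurrences$pairing,
                            reference_ids = study$msa$reference_ids),
                       out("synthetic_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_manifest(cfg, "synth", list(),
                 outputs = c("synthetic_msa.fasta", "synthetic_structure.pdb",
                             "synthetic_compartments.tsv",
                             "synthetic_annotations.tsv",
                             "synthetic_occurrences.tsv",
                             "synthetic_truth.json"))
  invisible(study)
}

#' @rdname cli_commands
#' @export
cmd_curate <- function(cfg) {
  check_inputs(cfg, "sequences")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  records <- read_fasta(cfg$sequences)
  records <- deduplicate(records)
  patterns <- list(motif_hgxp(aromatic_x = cfg$aromatic_x),
                   motif_gxsmxst(aromatic_x = cfg$aromatic_x))
  flt <- filter_by_motifs(records, patterns, strict = cfg$strict_alphabet)
  long <- flag_long_sequences(flt$kept, max_len = cfg$max_len)
  out <- function(f) file.path(cfg$out_dir, f)
  write_fasta(flt$kept, out("curated.fasta"))
  write_curation_report(flt$report, out("curation_report.tsv"))
  utils::write.table(long, out("long_sequences.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_manifest(cfg, "curate", list(sequences = cfg$sequences),
                 outputs = c("curated.fasta", "curation_report.tsv",
                             "long_sequences.tsv"),
                 extra = list(n_input = nrow(records),
                              n_kept = nrow(flt$kept),
                              n_discarded = nrow(flt$discarded),
                              n_flagged = nrow(flt$flagged),
                              n_long = nrow(long)))
  invisible(flt)
}

#' @rdname cli_commands
#' @export
cmd_entropy <- function(cfg) {
  check_inputs(cfg, "msa")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  aln <- read_msa(cfg$msa, reference_ids = cfg$reference_ids)
  profile <- entropy_profile(aln, gap_policy = cfg$gap_policy)
  mask <- trim_columns(aln)
  out <- function(f) file.path(cfg$out_dir, f)
  write_entropy_tsv(profile, out("entropy_profile.tsv"))
  write_mask_tsv(mask, out("column_mask.tsv"))
  write_manifest(cfg, "entropy", list(msa = cfg$msa),
                 outputs = c("entropy_profile.tsv", "column_mask.tsv"),
                 extra = list(n_columns = profile$n_columns,
                              n_retained = length(mask)))
  invisible(list(profile = profile, mask = mask))
}

#' @rdname cli_commands
#' @export
cmd_classify <- function(cfg) {
  check_inputs(cfg, c("msa", "structure", "compartments", "annotations"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  aln <- read_msa(cfg$msa, reference_ids = cfg$reference_ids)
  profile <- entropy_profile(aln, gap_policy = cfg$gap_policy)
  mask <- trim_columns(aln)
  st <- read_structure(cfg$structure)
  mapping <- map_structure_to_msa(st, aln, cfg$ref_id)
  comps <- read_compartments_tsv(cfg$compartments)
  ann <- read_annotations_tsv(cfg$annotations)
  report <- compartment_variability(comps, mapping, ann, profile, mask,
                                    min_n = cfg$es_min_n)
  out <- file.path(cfg$out_dir, "variability_report.tsv")
  write_variability_tsv(report, out)
  write_manifest(cfg, "classify",
                 list(msa = cfg$msa, structure = cfg$structure,
                      compartments = cfg$compartments,
                      annotations = cfg$annotations),
                 outputs = "variability_report.tsv",
                 extra = list(n_compartments =
                                length(unique(comps$compartment))))
  invisible(report)
}

#' @rdname cli_commands
#' @export
cmd_match <- function(cfg) {
  check_inputs(cfg, "occurrences")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  tables <- read_occurrence_tsv(cfg$occurrences)
  src <- vapply(tables, function(t) t$source, character(1))
  taus <- config_taus(cfg)
  match <- match_tunnels(tables[src == "crystal"], tables[src == "md"],
                         taus = taus)
  prefix <- file.path(cfg$out_dir, "tunnel_match")
  write_match_tsv(match, prefix)
  write_manifest(cfg, "match", list(occurrences = cfg$occurrences),
                 outputs = c("tunnel_match_matrix.tsv",
                             "tunnel_match_pairs.tsv"),
                 extra = list(n_crystal = sum(src == "crystal"),
                              n_md = sum(src == "md"),
                              n_grid_combinations = length(taus)^2))
  invisible(match)
}

#' @rdname cli_commands
#' @export
cmd_profile <- function(cfg) {
  check_inputs(cfg, c("msa", "structure", "compartments", "annotations"))
  if (is.null(cfg$tunnel)) stop("config key 'tunnel' is required")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  aln <- read_msa(cfg$msa, reference_ids = cfg$reference_ids)
  profile <- entropy_profile(aln, gap_policy = cfg$gap_policy)
  st <- read_structure(cfg$structure)
  mapping <- map_structure_to_msa(st, aln, cfg$ref_id)
  comps <- read_compartments_tsv(cfg$compartments)
  tunnel <- comps[comps$compartment == cfg$tunnel, , drop = FALSE]
  if (nrow(tunnel) == 0L) {
    stop("tunnel compartment '", cfg$tunnel, "' not in compartment table")
  }
  ann <- read_annotations_tsv(cfg$annotations)
  sp <- build_spatial_profile(tunnel, mapping, profile, ann, st)
  out <- file.path(cfg$out_dir, "spatial_profile.tsv")
  write_spatial_tsv(sp, out)
  write_manifest(cfg, "profile",
                 list(msa = cfg$msa, structure = cfg$structure,
                      compartments = cfg$compartments,
                      annotations = cfg$annotations),
                 outputs = "spatial_profile.tsv",
                 extra = list(tunnel = cfg$tunnel, n_points = nrow(sp)))
  invisible(sp)
}
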