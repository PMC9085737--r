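# Single-call orchestration: align the mimotope, map the region onto the
# structure, compute accessibility, interface properties and epitope
# groups, optionally interface energetics and affinity, and emit a
# machine-readable report.

#' Pipeline configuration
#'
#' @param query Mimotope peptide sequence.
#' @param antigen_seq Antigen sequence (the region the alignment is run
#'   against).
#' @param antigen_offset Author residue number of the first character of
#'   `antigen_seq`.
#' @param structure_file Path to a PDB-format structure of the antigen
#'   (complex).
#' @param antigen_chains Chains forming the antigen oligomer used for the
#'   accessibility context (e.g. the two chains of a homodimer).
#' @param epitope_chain The antigen chain on which the mapped region is
#'   reported.
#' @param partner_chains Chains against which inter-chain neighbors and
#'   hydrogen bonds are detected (e.g. the other chain of the homodimer).
#' @param receptor_chains Optional receptor chains for interface energetics
#'   and affinity prediction.
#' @param temperature Kelvin for the dG to Kd conversion.
#' @param align_params [alignment_params()].
#' @param sasa_params [sasa_params()].
#' @param neighbor_criteria [neighbor_criteria()].
#' @param hbond_criteria [hbond_criteria()].
#' @param out_dir Optional directory for report.json / residues.tsv.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(query, antigen_seq, antigen_offset,
                            structure_file, antigen_chains, epitope_chain,
                            partner_chains, receptor_chains = NULL,
                            temperature = 298.15,
                            align_params = alignment_params(),
                            sasa_params = epitomap::sasa_params(),
                            neighbor_criteria = epitomap::neighbor_criteria(),
                            hbond_criteria = epitomap::hbond_criteria(),
                            out_dir = NULL) {
  if (length(intersect(antigen_chains, receptor_chains)))
    stop("antigen and receptor chain groups must be disjoint")
  structure(list(query = query, antigen_seq = antigen_seq,
                 antigen_offset = antigen_offset,
                 structure_file = structure_file,
                 antigen_chains = antigen_chains,
                 epitope_chain = epitope_chain,
                 partner_chains = partner_chains,
                 receptor_chains = receptor_chains,
                 temperature = temperature,
                 align_params = align_params, sasa_params = sasa_params,
                 neighbor_criteria = neighbor_criteria,
                 hbond_criteria = hbond_criteria, out_dir = out_dir),
            class = "pipeline_config")
}

.config_hash <- function(config) {
  x <- config
  x$out_dir <- NULL
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA,
                              force = TRUE), f)
  unname(tools::md5sum(f))
}

#' Run the full epitope-mapping pipeline
#'
#' Stages: overlap alignment -> region mapping -> accessibility on the
#' antigen oligomer -> inter-chain neighbors and hydrogen bonds for the
#' mapped region -> epitope grouping and candidate ranking -> (optionally)
#' receptor-interface selection and contact-based affinity.
#'
#' @param config A [pipeline_config()].
#' @return List of class `epitope_report` with blocks `alignment`,
#'   `region`, `residues` (per-residue table), `candidates`, `affinity`
#'   (NULL without receptor chains) and `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!file.exists(config$structure_file))
    stop("structure file not found: ", config$structure_file)

  aln <- align_overlap(config$query, config$antigen_seq, config$align_params)
  metrics <- alignment_metrics(aln)
  region <- map_region(aln, config$antigen_offset)

  st <- read_structure(config$structure_file)
  sasa <- residue_sasa(st, config$sasa_params, chains = config$antigen_chains)
  rt <- residue_table(st, chains = config$epitope_chain)
  wanted <- seq(region$start, region$end)
  present <- rt[rt$resno %in% wanted, , drop = FALSE]
  if (nrow(present) < length(wanted))
    warning("mapped region residues absent from the structure: ",
            paste(setdiff(wanted, present$resno), collapse = ", "),
            "; producing a partial report")
  region_keys <- present$key
  acc <- sasa[sasa$key %in% region_keys, , drop = FALSE]

  nb <- interchain_neighbors(st, config$epitope_chain, config$partner_chains,
                             config$neighbor_criteria)
  hb <- interchain_hbonds(st, config$epitope_chain, config$partner_chains,
                          config$hbond_criteria)
  records <- classify_epitope_residues(
    acc, intersect(nb, region_keys),
    intersect(unique(hb$res_a), region_keys))

  affinity <- NULL
  receptor_contacts <- character(0)
  if (length(config$receptor_chains)) {
    sel <- interface_selection(st, config$antigen_chains,
                               config$receptor_chains, cutoff = 5.0)
    receptor_contacts <- sel$a
    affinity <- predict_affinity(st, config$antigen_chains,
                                 config$receptor_chains,
                                 temperature = config$temperature,
                                 sasa_params = config$sasa_params)
    affinity <- c(unclass(affinity), list(receptor_interface = sel))
  }
  candidates <- nominate_candidates(records, receptor_contacts)

  report <- structure(list(
    alignment = list(
      query = config$query, target = config$antigen_seq,
      aligned_query = paste(aln$columns$query_char, collapse = ""),
      aligned_target = paste(aln$columns$target_char, collapse = ""),
      score = aln$score, identity_pct = metrics$identity_pct,
      similarity_pct = metrics$similarity_pct, n_columns = metrics$n_columns),
    region = region,
    residues = records,
    candidates = candidates,
    affinity = affinity,
    provenance = list(package_version = as.character(utils::packageVersion("epitomap")),
                      config_hash = .config_hash(config),
                      timestamp = format(Sys.time(), tz = "UTC"))),
    class = "epitope_report")
  if (!is.null(config$out_dir)) write_epitope_report(report, config$out_dir)
  report
}

#' Write an epitope report as JSON and TSV
#'
#' @param report An `epitope_report`.
#' @param dir Output directory (created if needed).
#' @param timestamp Include the timestamp field in the JSON (default TRUE;
#'   disable for byte-reproducible output).
#' @return Invisibly, the path of the JSON file.
#' @export
write_epitope_report <- function(report, dir, timestamp = TRUE) {
  stopifnot(inherits(report, "epitope_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  x <- unclass(report)
  if (!timestamp) x$provenance$timestamp <- NULL
  json <- file.path(dir, "report.json")
  jsonlite::write_json(x, json, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", force = TRUE, pretty = TRUE)
  utils::write.table(report$residues, file.path(dir, "residues.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(json)
}

#' @export
print.epitope_report <- function(x, ...) {
  cat("epitope report\n")
  cat(sprintf("  alignment: identity %.2f%%, similarity %.2f%% over %d columns\n",
              x$alignment$identity_pct, x$alignment$similarity_pct,
              x$alignment$n_columns))
  cat(sprintf("  region: %d-%d, query gaps at %s\n", x$region$start,
              x$region$end,
              if (length(x$region$gap_positions))
                paste(x$region$gap_positions, collapse = ", ") else "none"))
  g <- split(x$residues$key, x$residues$epitope_group)
  for (nm in names(g))
    cat(sprintf("  group %s: %s\n", nm, paste(g[[nm]], collapse = ", ")))
  if (!is.null(x$affinity))
    cat(sprintf("  affinity: dG %.2f kcal/mol, Kd %.2e M at %.2f K\n",
                x$affinity$dg, x$affinity$kd, x$affinity$temperature))
  invisible(x)
}
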