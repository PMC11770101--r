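#' Run the full analysis pipeline
#'
#' Orchestrates the four analysis stages over one input bundle: proteome KC
#' distances, site quantification, flanking-sequence motif enrichment, and
#' KC-distance class comparison. Inputs may be file paths (TSV / FASTA / a
#' directory of PDB files) or the in-memory objects the stage functions
#' accept. Stage outputs are written as TSVs to `out_dir` together with a
#' machine-readable JSON run report (parameters, input checksums, row counts
#' per stage, package version). Without a localization table the comparison
#' stage runs without compartment stratification and a warning is issued.
#'
#' @param structures Directory of `*.pdb` files, file paths, or a list of
#'   `pdb_structure` objects.
#' @param fasta Path to the proteome FASTA or a sequences data frame.
#' @param sites Path to the site table TSV or a site data frame.
#' @param design Path to the design TSV or a data frame.
#' @param proteins Optional protein table path / data frame (protein-level
#'   correction is skipped without it).
#' @param localization Optional localization table path / data frame.
#' @param out_dir Output directory (created if needed).
#' @param w Motif half-width.
#' @param fc_threshold,alpha Classification cut-offs.
#' @param cross_chain,min_plddt Passed to [compute_kc_table()].
#' @param control,treated Group labels in the design.
#' @return Invisibly, a list with `kc`, `quant`, `enrichment`, `patterns`,
#'   `comparison` and `report`.
#' @export
run_pipeline <- function(structures, fasta, sites, design,
                         proteins = NULL, localization = NULL,
                         out_dir, w = 6L, fc_threshold = 2.0, alpha = 0.05,
                         cross_chain = FALSE, min_plddt = NULL,
                         control = "control", treated = "treated") {
  paths <- Filter(function(p) is.character(p) && length(p) == 1,
                  list(structures = structures, fasta = fasta, sites = sites,
                       design = design, proteins = proteins,
                       localization = localization))
  missing_in <- names(paths)[!file.exists(unlist(paths))]
  if (length(missing_in) > 0) {
    stop("input path(s) do not exist: ",
         paste(sprintf("%s (%s)", missing_in, unlist(paths[missing_in])),
               collapse = ", "), call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (is.character(fasta)) fasta <- read_fasta(fasta)
  if (is.character(sites)) sites <- read_site_table(sites)
  if (is.character(design)) design <- read_design(design)
  if (is.character(proteins)) proteins <- read_protein_table(proteins)
  if (is.character(localization)) localization <- read_localization(localization)

  ## stage 1: KC distances over the structure set
  kc <- compute_kc_proteome(structures, cross_chain = cross_chain,
                            min_plddt = min_plddt)
  write_tsv(kc, file.path(out_dir, "kc.tsv"))

  ## stage 2: quantification and classification
  quant <- quantify_sites(sites, design, proteins = proteins,
                          control = control, treated = treated,
                          fc_threshold = fc_threshold, alpha = alpha)
  write_tsv(quant$table, file.path(out_dir, "quant.tsv"))

  ## stage 3: motif enrichment
  win <- extract_windows(fasta, sites, w = w)
  enrichment <- position_enrichment(win)
  write_tsv(enrichment, file.path(out_dir, "enrich.tsv"))
  patterns <- count_cys_patterns(win)

  ## stage 4: KC-distance class comparison
  if (is.null(localization)) {
    warning("no localization table: compartment stratification skipped",
            call. = FALSE)
  }
  annotated <- annotate_sites_with_kc(quant$table, kc)
  strat <- stratify_sites(kc, annotated, localization)
  comparison <- compare_kc_distributions(strat)
  write_tsv(comparison$summary, file.path(out_dir, "class_summary.tsv"))
  write_tsv(comparison$tests, file.path(out_dir, "class_tests.tsv"))

  checksums <- if (length(paths) > 0) {
    files <- unlist(lapply(unlist(paths), function(p) {
      if (dir.exists(p)) list.files(p, full.names = TRUE) else p
    }))
    as.list(tools::md5sum(sort(files)))
  } else {
    list()
  }
  report <- list(
    package = "lactylKC",
    version = as.character(utils::packageVersion("lactylKC")),
    parameters = list(w = w, fc_threshold = fc_threshold, alpha = alpha,
                      cross_chain = cross_chain,
                      min_plddt = min_plddt, control = control,
                      treated = treated,
                      protein_corrected = quant$protein_corrected),
    input_checksums = checksums,
    rows = list(kc = nrow(kc), quant = nrow(quant$table),
                enrichment = nrow(enrichment),
                class_summary = nrow(comparison$summary),
                class_tests = nrow(comparison$tests))
  )
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")

  invisible(list(kc = kc, quant = quant, enrichment = enrichment,
                 patterns = patterns, comparison = comparison,
                 report = report))
}
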