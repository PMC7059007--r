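## End-to-end orchestration: (simulate) -> normalize -> impute ->
## differential -> pathways -> cluster, writing every intermediate to the
## output directory together with a run manifest (config hash, seeds), so
## identical configs reproduce identical outputs.

#' Pipeline configuration
#'
#' Either point `matrix_path`/`catalogue_path` (TSV/CSV dialects of
#' [write_abundance_tsv()] / [write_catalogue_csv()], optionally
#' `pathways_gmt` and `edges_path`) at existing files, or leave
#' `matrix_path` `NULL` to simulate a cohort from `sim` first.
#'
#' @param out_dir output directory (created, must not be an existing
#'   non-empty run unless `overwrite`).
#' @param matrix_path,catalogue_path,pathways_gmt,edges_path input files.
#' @param sim a [sim_config()] used when `matrix_path` is `NULL`.
#' @param z_max outlier threshold (normalization).
#' @param k_neighbours K for the KNN-TN imputation.
#' @param fdr FDR level for the significance flags.
#' @param k_clusters k for the residual clustering.
#' @param seed root seed; per-stage seeds are derived from it.
#' @param overwrite allow writing into an existing directory.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir, matrix_path = NULL,
                            catalogue_path = NULL, pathways_gmt = NULL,
                            edges_path = NULL, sim = sim_config(),
                            z_max = 4, k_neighbours = 10, fdr = 0.10,
                            k_clusters = 3, seed = 1L,
                            overwrite = FALSE) {
  for (p in c(matrix_path, catalogue_path, pathways_gmt, edges_path))
    if (!is.null(p) && !file.exists(p)) stop("input path not found: ", p)
  if (!is.null(matrix_path) && is.null(catalogue_path))
    stop("a catalogue path is required with a user-supplied matrix")
  structure(list(out_dir = out_dir, matrix_path = matrix_path,
                 catalogue_path = catalogue_path,
                 pathways_gmt = pathways_gmt, edges_path = edges_path,
                 sim = sim, z_max = z_max,
                 k_neighbours = as.integer(k_neighbours), fdr = fdr,
                 k_clusters = as.integer(k_clusters),
                 seed = as.integer(seed), overwrite = overwrite),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages: simulate (when no matrix is supplied) -> normalization chain ->
#' KNN-TN imputation -> blocked moderated differential abundance (all
#' contrasts) -> pathway enrichment + topology impact (hits of the first
#' contrast at `fdr`) -> k-means of the patient-centred residuals. Every
#' intermediate table is written under `out_dir`; `manifest.json` records
#' the configuration, its hash and the derived per-stage seeds. Rerunning
#' with the same config reproduces the outputs bit-identically.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list of in-memory stage results: `catalogue`,
#'   `matrix_raw`, `truth` (when simulated), `preprocessed`, `imputed`,
#'   `differential`, `pathways`, `clusters`, `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (dir.exists(config$out_dir) &&
      length(list.files(config$out_dir)) && !config$overwrite)
    stop("output directory ", config$out_dir,
         " is not empty (set overwrite = TRUE to reuse it)")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage_seeds <- .with_seed(config$seed,
                            sample.int(.Machine$integer.max - 1L, 6))

  if (is.null(config$matrix_path)) {
    sim <- config$sim
    sim$seed <- stage_seeds[1]
    catalogue <- generate_catalogue(sim)
    gen <- generate_abundances(catalogue, sim)
    mat_raw <- gen$matrix
    truth <- gen$truth
    pathways <- catalogue_pathways(catalogue)
    graphs <- generate_pathway_graphs(pathways, seed = stage_seeds[2])
    write_catalogue_csv(catalogue, file.path(config$out_dir, "catalogue.csv"))
    write_abundance_tsv(mat_raw, file.path(config$out_dir, "matrix_raw.tsv"))
    write_truth_json(truth, file.path(config$out_dir, "truth.json"))
    write_gmt(pathways, file.path(config$out_dir, "pathways.gmt"))
    write_edges_tsv(graphs, file.path(config$out_dir, "pathway_edges.tsv"))
  } else {
    catalogue <- read_catalogue_csv(config$catalogue_path)
    mat_raw <- read_abundance_tsv(config$matrix_path)
    truth <- NULL
    pathways <- if (!is.null(config$pathways_gmt))
      read_gmt(config$pathways_gmt) else catalogue_pathways(catalogue)
    graphs <- if (!is.null(config$edges_path))
      read_edges_tsv(config$edges_path) else list()
  }

  pre <- preprocess(mat_raw, catalogue, z_max = config$z_max)
  write_abundance_tsv(pre$matrix,
                      file.path(config$out_dir, "matrix_normalized.tsv"))
  write.table(pre$provenance,
              file.path(config$out_dir, "provenance.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, na = "")

  imp <- impute_knn_tn(pre$matrix,
                       impute_config(k_neighbours = config$k_neighbours))
  write_abundance_tsv(imp$matrix,
                      file.path(config$out_dir, "matrix_imputed.tsv"))
  write.csv(imp$fits, file.path(config$out_dir, "truncated_fits.csv"),
            row.names = FALSE)
  write.table(imp$log, file.path(config$out_dir, "imputation_log.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  design <- design_spec(imp$matrix$samples)
  diff <- differential_abundance(imp$matrix, design)
  write.table(diff$table,
              file.path(config$out_dir, "differential.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  main_contrast <- rownames(design$L)[1]
  volcano <- volcano_table(diff$table, main_contrast, catalogue,
                           fdr = config$fdr)
  write.table(volcano, file.path(config$out_dir, "volcano.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, na = "")

  ## universe: analysed metabolites carrying >= 1 pathway annotation
  analysed <- colnames(imp$matrix$values)
  annotated <- unique(unlist(pathways))
  universe <- intersect(analysed, annotated)
  hits <- intersect(volcano$metabolite_id[volcano$significant], universe)
  pw_res <- pathway_analysis(hits, universe, pathways, graphs)
  write.table(pw_res, file.path(config$out_dir, "pathway_results.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, na = "")

  clu <- kmeans_residuals(diff$fit$residuals_patient,
                          k = config$k_clusters,
                          seed = stage_seeds[5])
  assign_tab <- merge(clu$assignments, imp$matrix$samples,
                      by = "sample_id", sort = TRUE)
  write.table(assign_tab, file.path(config$out_dir, "clusters.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  cfg_ser <- config
  cfg_ser$out_dir <- NULL  # hash invariant to where the run lands
  cfg_json <- jsonlite::toJSON(unclass(cfg_ser), auto_unbox = TRUE,
                               digits = NA, force = TRUE)
  tf <- tempfile()
  writeLines(cfg_json, tf)
  manifest <- list(config = jsonlite::fromJSON(cfg_json),
                   config_hash = unname(tools::md5sum(tf)),
                   stage_seeds = stage_seeds,
                   n_metabolites_analysed = length(analysed),
                   n_significant = sum(volcano$significant),
                   consensus_rho = diff$fit$consensus_rho)
  unlink(tf)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(catalogue = catalogue, matrix_raw = mat_raw,
                 truth = truth, preprocessed = pre, imputed = imp,
                 differential = diff, pathways = pw_res, clusters = clu,
                 out_dir = config$out_dir))
}
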