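#' Run the full analysis pipeline on simulated or provided data
#'
#' Wires the stages end to end — simulate (or read) an FPKM matrix,
#' average replicates, classify, correlate and cluster, build the
#' enrichment network, summarise — and writes every result plus a JSON run
#' manifest (config snapshot, seed, file digests, package version) to
#' `out_dir`. Re-running with the same seed and config reproduces all
#' deterministic outputs byte-identically.
#'
#' @param out_dir output directory (created if absent).
#' @param sim a [simulation_config()], or `NULL` to read existing data.
#' @param matrix_path,annotation_path input TSVs, used when `sim` is NULL.
#' @param config a [classifier_config()].
#' @param focus tissues used for network focus filtering (default: the
#'   lymphohematopoietic set intersected with the panel).
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(out_dir, sim = simulation_config(),
                         matrix_path = NULL, annotation_path = NULL,
                         config = classifier_config(),
                         focus = lymphohematopoietic_tissues()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)

  if (!is.null(sim)) {
    simres <- simulate_fpkm(sim)
    x <- simres$expression
    write_expression_set(x, p("matrix.tsv"), p("annotation.tsv"))
    utils::write.table(simres$truth, p("truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    if (is.null(matrix_path) || is.null(annotation_path))
      fail("either 'sim' or both input paths must be given")
    x <- read_expression_set(matrix_path, annotation_path)
  }

  profile <- average_replicates(x)
  write_profile(profile, p("tissue_profile.tsv"))
  write_profile(detection_mask(profile, config$detection_cutoff),
                p("detection_mask.tsv"))

  cls <- classify_profile(profile, config)
  write_classification(cls, p("classification.tsv"))

  rho <- correlation_matrix(x, level = "tissue")
  write_profile(rho, p("tissue_correlations.tsv"))
  hc <- cluster_samples(x)
  as_newick(hc, p("dendrogram.nwk"))

  focus <- intersect(focus, colnames(profile))
  g <- build_network(cls, focus = focus)
  export_graph(g, p("network.sif"), "sif")
  export_graph(g, p("network.graphml"), "graphml")

  summ <- summarize_classification(cls)
  jsonlite::write_json(
    list(counts = as.list(summ$counts),
         percent = as.list(summ$percent),
         elevated = as.list(summ$elevated),
         per_tissue = summ$per_tissue),
    p("summary.json"), auto_unbox = TRUE, digits = NA)

  outputs <- list.files(out_dir, full.names = TRUE)
  outputs <- setdiff(outputs, p("manifest.json"))
  manifest <- list(
    tool = "tissuespec",
    version = as.character(utils::packageVersion("tissuespec")),
    seed = if (!is.null(sim)) sim$seed else NA,
    config = unclass(config),
    simulation = if (!is.null(sim))
      unclass(sim)[setdiff(names(sim), "config")] else NULL,
    outputs = stats::setNames(
      as.list(unname(tools::md5sum(outputs))), basename(outputs)))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(manifest)
}
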