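## End-to-end orchestration: run every stage from one configuration,
## write stage TSVs and a reproducibility manifest.

#' Read a pipeline run configuration
#'
#' A YAML document with optional blocks `pipeline:` (fields of
#' [pipeline_config()]), `synthetic:` (fields of [synthetic_config()]; its
#' presence switches the run to simulated inputs) and, for real inputs,
#' top-level `transcriptome:`, `translatome:`, `metadata:` and optionally
#' `annotation:` file paths plus `scenario:`.
#'
#' @param path YAML file.
#' @return named list.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stopf("malformed config: %s", path)
  cfg
}

#' Run the full analysis pipeline
#'
#' Stages, in order: coupling -> network conservation -> cell-type DE ->
#' motifs -> enrichment. Inputs are either TSV files named in the config
#' or a synthetic dataset generated from its `synthetic:` block. All
#' stage outputs are written as TSVs under `outdir`, together with a JSON
#' run manifest recording the configuration, seed, package version, stage
#' timings and MD5 checksums of every emitted file. A fixed seed makes
#' every stochastic stage reproducible (per-stage substream seeds are
#' derived from the master seed).
#'
#' @param config named list (see [load_run_config()]) or path to a YAML
#'   file.
#' @param outdir output directory (created if missing).
#' @param seed master seed; overrides the config's seed when given.
#' @param verbose print stage progress.
#' @return (invisibly) list with the stage result objects and the
#'   manifest.
#' @export
run_pipeline <- function(config, outdir = "coupletrans_out", seed = NULL,
                         verbose = TRUE) {
  if (is.character(config)) config <- load_run_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  pl <- do.call(pipeline_config, config$pipeline %||% list())
  if (!is.null(seed)) pl$seed <- as.integer(seed)
  seeds <- derive_seeds(pl$seed, 6L)
  scenario <- config$scenario %||% "common"
  say <- function(...) if (verbose) message(format(Sys.time(), "%H:%M:%S "), ...)

  synthetic <- !is.null(config$synthetic) || isTRUE(config$use_synthetic)
  if (synthetic) {
    say("generating synthetic dataset")
    sc_args <- config$synthetic %||% list()
    if (is.null(sc_args$seed)) sc_args$seed <- seeds[1]
    syn <- generate_paired_dataset(do.call(synthetic_config, sc_args))
    x_tr <- syn$x_tr; x_tl <- syn$x_tl; map <- syn$map
    ann <- generate_annotation(syn$truth, seed = seeds[2])
    write_expression_matrix(x_tr, file.path(outdir, "transcriptome.tsv"))
    write_expression_matrix(x_tl, file.path(outdir, "translatome.tsv"))
    write_sample_map(map, file.path(outdir, "metadata.tsv"))
    utils::write.table(syn$truth$classes, file.path(outdir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    for (f in c("transcriptome", "translatome", "metadata"))
      if (is.null(config[[f]]) || !file.exists(config[[f]]))
        stopf("config error: '%s' must name an existing file", f)
    x_tr <- load_expression_matrix(config$transcriptome)
    x_tl <- load_expression_matrix(config$translatome)
    map <- load_sample_map(config$metadata)
    ann <- if (!is.null(config$annotation)) load_annotation(config$annotation)
  }

  timings <- c(); results <- list()
  stage <- function(name, fun) {
    say("stage: ", name)
    t0 <- proc.time()[["elapsed"]]
    r <- fun()
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    results[[name]] <<- r
    r
  }

  pl_c <- pl; pl_c$seed <- seeds[3]
  cp <- stage("coupling", function()
    coupling_analysis(x_tr, x_tl, map, scenario, pl_c))
  write_coupling_result(cp, file.path(outdir, "coupling.tsv"))

  pl_e <- pl; pl_e$seed <- seeds[4]
  ec <- stage("netcons", function()
    ec_analysis(x_tr, x_tl, map, scenario, pl_e,
                genes = config$netcons_genes))
  utils::write.table(as.data.frame(ec), file.path(outdir, "ec.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(fmc = attr(ec, "fmc"), p_lower = attr(ec, "fmc_p_lower"),
               n_boot = pl$n_boot),
    file.path(outdir, "network_summary.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  g_tr <- threshold_graph(attr(ec, "a_tr"), pl$t_edge)
  np <- node_properties(g_tr, pl$alpha_centrality_factor)
  utils::write.table(np, file.path(outdir, "node_properties_tr.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_edge_list(attr(ec, "a_tr"), file.path(outdir, "edges_tr.tsv"))

  de <- stage("celltype_de", function()
    celltype_de(x_tr, x_tl, map, scenario, pl))
  for (lv in names(de$anova))
    utils::write.table(de$anova[[lv]],
                       file.path(outdir, paste0("anova_", lv, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  sv <- similarity_vectors(de)
  utils::write.table(sv, file.path(outdir, "similarity_vectors.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  pl_m <- pl; pl_m$seed <- seeds[5]
  mt <- stage("motifs", function() motif_analysis(de, pl_m))
  for (lv in names(mt))
    utils::write.table(as.data.frame(mt[[lv]]),
                       file.path(outdir, paste0("motifs_", lv, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  if (!is.null(ann)) {
    en <- stage("enrichment", function() {
      study <- cp$gene_id[cp$coupling_class == "coupled"]
      enrich(study, ann, population = cp$gene_id, q = pl$fdr_q)
    })
    utils::write.table(as.data.frame(en), file.path(outdir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  outputs <- sort(list.files(outdir, pattern = "\\.tsv$"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("coupletrans")),
    seed = pl$seed,
    scenario = scenario,
    synthetic = synthetic,
    config = config,
    pipeline = unclass(pl),
    stage_timings_sec = as.list(timings),
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(file.path(outdir, outputs))), outputs)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("done: ", outdir)
  invisible(c(results, list(manifest = manifest)))
}
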