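# One-command pipeline driver: ri -> degs -> intersect -> weigh -> enrich ->
# network, with a JSON run report and a plain-text log of every threshold
# actually applied.

#' Pipeline configuration
#'
#' @param components,ladder,target_map,disease,de,gmt paths to the input
#'   files (the bundle layout written by [generate_bundle()]).
#' @param ppi optional PPI edge-list path; if `NULL` the PPI stage is
#'   skipped.
#' @param out_dir output directory.
#' @param fdr_max,lfc_min DEG thresholds (see [select_degs()]).
#' @param ppi_min_conf PPI confidence threshold (see [filter_ppi_edges()]).
#' @param k_min minimum overlap for a pathway to be tested.
#' @param content_scale `"percent"` or `"fraction"` (see
#'   [component_table()]).
#' @param ppi_scale PPI score dialect (see [filter_ppi_edges()]).
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(components, ladder, target_map, disease, de, gmt,
                            ppi = NULL, out_dir = "wcnp_out",
                            fdr_max = 0.05, lfc_min = 1,
                            ppi_min_conf = 0.9, k_min = 0,
                            content_scale = "percent", ppi_scale = "auto") {
  cfg <- list(components = components, ladder = ladder,
              target_map = target_map, disease = disease, de = de, gmt = gmt,
              ppi = ppi, out_dir = out_dir,
              fdr_max = as.numeric(fdr_max), lfc_min = as.numeric(lfc_min),
              ppi_min_conf = as.numeric(ppi_min_conf),
              k_min = as.numeric(k_min),
              content_scale = match.arg(content_scale, c("percent", "fraction")),
              ppi_scale = match.arg(ppi_scale, c("auto", "s1000", "unit")))
  req <- c("components", "ladder", "target_map", "disease", "de", "gmt")
  missing <- req[!vapply(cfg[req], file.exists, logical(1))]
  if (length(missing))
    validation_error("input file(s) not found: ",
                     paste(unlist(cfg[missing]), collapse = ", "))
  if (!is.null(cfg$ppi) && !file.exists(cfg$ppi))
    validation_error("PPI file not found: ", cfg$ppi)
  if (cfg$fdr_max <= 0 || cfg$fdr_max > 1)
    validation_error("fdr_max must be in (0, 1]")
  if (cfg$lfc_min < 0) validation_error("lfc_min must be >= 0")
  if (cfg$ppi_min_conf < 0 || cfg$ppi_min_conf > 1)
    validation_error("ppi_min_conf must be in [0, 1]")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML/JSON
#'
#' A flat key-value file whose keys are the arguments of
#' [pipeline_config()]; relative input paths are resolved against the config
#' file's directory.
#'
#' @param path config file path.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (k in c("components", "ladder", "target_map", "disease", "de", "gmt",
              "ppi", "out_dir")) {
    if (!is.null(raw[[k]]) && !grepl("^(/|[A-Za-z]:)", raw[[k]]))
      raw[[k]] <- file.path(base, raw[[k]])
  }
  do.call(pipeline_config, raw)
}

#' Run the full pipeline
#'
#' Stages: annotate retention indices; select DEGs; intersect component
#' targets, disease genes and DEGs into the key-target set; compute A/B/C
#' weights; hypergeometric enrichment of the key targets and weight-based
#' re-ranking; tripartite network construction and export (plus PPI
#' filtering when a PPI file is configured). Writes every stage table under
#' `out_dir` together with `run_report.json` (stage counts) and `run.log`
#' (thresholds and scale switches actually applied). If the key-target set
#' is empty, enrichment and network stages are skipped with an explicit
#' notice in the report.
#'
#' @param config a [pipeline_config()] (or a path to a YAML config).
#' @return invisibly, the run report as a list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  log_lines <- character(0)
  note <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(c(log_lines, paste0("FAILED at stage ", name, ": ",
                                     conditionMessage(e))), log_path)
      stop_wcnp("stage ", name, ": ", conditionMessage(e),
                class = "wcnp_stage_error")
    })
  }
  report <- list(stages = list(), outputs = list(), notices = list())
  out <- function(name) file.path(config$out_dir, name)

  note("thresholds: fdr_max=", config$fdr_max, " (strict <), lfc_min=",
       config$lfc_min, " (inclusive >=), ppi_min_conf=", config$ppi_min_conf,
       " (strict >), k_min=", config$k_min)
  note("scales: content=", config$content_scale, ", ppi=", config$ppi_scale)

  comps <- stage("ri", {
    tab <- read_component_table(config$components,
                                content_scale = config$content_scale)
    lad <- read_alkane_ladder(config$ladder)
    tab <- annotate_retention_index(tab, lad)
    write_component_table(tab, out("components_annotated.csv"))
    tab
  })
  report$stages$n_components <- nrow(comps)
  report$outputs$components <- "components_annotated.csv"

  degs <- stage("degs", {
    de <- read_de_table(config$de)
    res <- select_degs(de, fdr_max = config$fdr_max,
                       lfc_min = config$lfc_min)
    write_gene_list(res$selected, out("deg_genes.txt"))
    res
  })
  report$stages$n_degs <- length(degs$selected)
  report$stages$n_degs_up <- degs$n_up
  report$stages$n_degs_down <- degs$n_down
  report$outputs$degs <- "deg_genes.txt"
  note("degs: ", length(degs$selected), " selected (", degs$n_up, " up, ",
       degs$n_down, " down)")

  edges <- stage("intersect", read_target_map(config$target_map))
  disease <- stage("intersect", read_gene_list(config$disease, "disease"))
  key <- stage("intersect", {
    k <- three_way_intersection(gene_set("targets", edges$target),
                                disease, degs$selected)
    write_gene_list(k, out("key_targets.txt"))
    k
  })
  report$stages$n_component_targets <- length(unique(edges$target))
  report$stages$n_disease_genes <- length(disease)
  report$stages$n_key_targets <- length(key)
  report$outputs$key_targets <- "key_targets.txt"
  note("intersection: ", length(key), " key targets")

  pathways <- stage("weigh", read_gmt(config$gmt))
  weights <- stage("weigh", {
    w <- weight_table(comps, edges, pathways)
    write_weight_reports(w, config$out_dir)
    w
  })
  report$stages$n_scored_targets <- length(weights$b_scores)
  report$stages$n_pathways <- length(pathways$sets)
  report$outputs$weights <- c("component_weights.tsv", "target_weights.tsv",
                              "pathway_weights.tsv")

  if (length(key) == 0) {
    report$notices <- c(report$notices,
                        "key-target set empty: enrichment and network stages skipped")
    note("key-target set empty: enrichment and network stages skipped")
  } else {
    enr <- stage("enrich", {
      res <- hypergeom_enrich(key, pathways, k_min = config$k_min)
      write_enrichment(res, out("enrichment_unweighted.tsv"))
      res2 <- rerank_by_weight(res, weights$c_scores)
      write_enrichment(res2, out("enrichment_reranked.tsv"))
      res2
    })
    report$stages$n_pathways_tested <- nrow(enr)
    report$stages$n_pathways_fdr05 <- sum(enr$fdr_bh < 0.05)
    report$outputs$enrichment <- c("enrichment_unweighted.tsv",
                                   "enrichment_reranked.tsv")
    top <- enr$pathway_id[enr$weighted_rank == 1]
    note("enrichment: ", nrow(enr), " pathways tested; top by weight: ", top)

    net <- stage("network", {
      n <- build_tripartite(comps, edges, pathways, key)
      export_sif(n, out("network.sif"))
      export_graphml(n, out("network.graphml"))
      n
    })
    report$stages$n_network_nodes <- nrow(net$nodes)
    report$stages$n_network_edges <- nrow(net$edges)
    report$outputs$network <- c("network.sif", "network.graphml")
  }

  if (!is.null(config$ppi)) {
    ppi <- stage("ppi", {
      e <- read_ppi_edges(config$ppi)
      f <- filter_ppi_edges(e, min_confidence = config$ppi_min_conf,
                            scale = config$ppi_scale)
      write_ppi_edges(f, out("ppi_filtered.tsv"))
      list(raw = e, filtered = f)
    })
    report$stages$n_ppi_edges <- nrow(ppi$raw)
    report$stages$n_ppi_edges_retained <- nrow(ppi$filtered)
    report$outputs$ppi <- "ppi_filtered.tsv"
    note("ppi: ", nrow(ppi$filtered), "/", nrow(ppi$raw),
         " edges above confidence ", config$ppi_min_conf)
  }

  writeLines(log_lines, log_path)
  jsonlite::write_json(report, out("run_report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(report)
}
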