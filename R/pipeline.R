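# End-to-end orchestration of the screening chain from a single config:
# compounds -> superior-property screen -> target clusters -> intersection
# -> PPI triple-median filter -> enrichment -> tripartite degree ranking,
# with a machine-readable run report whose stage counts are checked for
# internal consistency.

#' Run configuration
#'
#' @param compounds,descriptors,predictions,ppi,gmt Input file paths.
#' @param disease Named character vector of per-source disease-target CSV
#'   paths (columns `target`, `score`, `score_name`).
#' @param out_dir Output directory for intermediates and the run report.
#' @param top_n_disease Per-source top-N cut for ranked sources.
#' @param ranked_sources Sources ranked by score before the union; the
#'   remaining sources pass through unranked.
#' @param top_pathways,top_targets,top_compounds Ranking cuts.
#' @param thresholds,ellipse,violation_scope Screening configuration.
#' @param enrich_method `"hypergeometric"` or `"ease"`.
#' @param min_score Optional PPI confidence cutoff.
#' @return A `run_config` list.
#' @export
run_config <- function(compounds, descriptors, predictions, disease, ppi, gmt,
                       out_dir = tempfile("netpharm_run_"),
                       top_n_disease = 1000L,
                       ranked_sources = c("CTD", "GeneCards"),
                       top_pathways = 10L, top_targets = 9L,
                       top_compounds = 5L,
                       thresholds = default_rule_thresholds(),
                       ellipse = default_gi_ellipse(),
                       violation_scope = "passed_only",
                       enrich_method = "hypergeometric",
                       min_score = 0) {
  cfg <- list(compounds = compounds, descriptors = descriptors,
              predictions = predictions, disease = disease, ppi = ppi,
              gmt = gmt, out_dir = out_dir, top_n_disease = top_n_disease,
              ranked_sources = ranked_sources, top_pathways = top_pathways,
              top_targets = top_targets, top_compounds = top_compounds,
              thresholds = thresholds, ellipse = ellipse,
              violation_scope = violation_scope,
              enrich_method = enrich_method, min_score = min_score)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' File paths in the YAML are resolved relative to the YAML file's
#' directory. Threshold and ellipse blocks are optional and default to the
#' published values.
#'
#' @param path Path to a YAML config.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(startsWith(p, "/"), p, file.path(base, p))
  disease <- unlist(y$inputs$disease)
  run_config(
    compounds = resolve(y$inputs$compounds),
    descriptors = resolve(y$inputs$descriptors),
    predictions = resolve(y$inputs$predictions),
    disease = setNames(resolve(disease), names(disease)),
    ppi = resolve(y$inputs$ppi),
    gmt = resolve(y$inputs$gmt),
    out_dir = y$out_dir %||% tempfile("netpharm_run_"),
    top_n_disease = y$params$top_n_disease %||% 1000L,
    ranked_sources = y$params$ranked_sources %||% c("CTD", "GeneCards"),
    top_pathways = y$params$top_pathways %||% 10L,
    top_targets = y$params$top_targets %||% 9L,
    top_compounds = y$params$top_compounds %||% 5L,
    violation_scope = y$params$violation_scope %||% "passed_only",
    enrich_method = y$params$enrich_method %||% "hypergeometric",
    min_score = y$params$min_score %||% 0
  )
}

stage <- function(name, expr, out_dir) {
  tryCatch(expr, error = function(e) {
    if (!is.null(out_dir)) {
      try(writeLines(sprintf("FAILED at stage '%s': %s", name,
                             conditionMessage(e)),
                     file.path(out_dir, "FAILED")), silent = TRUE)
    }
    stop(errorCondition(
      sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
      class = c("np_stage_error", "netpharm_error")))
  })
}

#' Run the screening pipeline end-to-end
#'
#' Executes every stage from the configured input files, writes plain-text
#' intermediates (CSV / symbol lists / SIF / GraphML) plus a JSON run
#' report, and returns the report. Deterministic given the inputs: no stage
#' uses random numbers.
#'
#' @param config A `run_config` (from [run_config()] or
#'   [read_run_config()]), or a path to a YAML config file.
#' @return A `run_report` list of per-stage counts and rankings.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  od <- cfg$out_dir

  parsed <- stage("compounds", parse_compound_table(cfg$compounds), od)
  library_tbl <- deduplicate_by_cid(parsed$compounds)

  superior <- stage("adme", {
    if (nrow(library_tbl) == 0) {
      np_stop("np_value_error", "compound library is empty")
    }
    desc_tab <- readr::read_csv(cfg$descriptors, show_col_types = FALSE,
                                progress = FALSE)
    with_desc <- attach_descriptors(library_tbl, desc_tab)
    report <- druglikeness_report(with_desc, cfg$thresholds, cfg$ellipse,
                                  cfg$violation_scope)
    screen_superior(report)
  }, od)

  compound_targets <- stage("targets", {
    preds <- readr::read_csv(cfg$predictions, show_col_types = FALSE,
                             progress = FALSE)
    preds <- filter_predictions(preds[preds$cid %in% superior, , drop = FALSE])
    preds
  }, od)
  compound_cluster <- sort(unique(compound_targets$target))

  disease_sets <- stage("disease", {
    sets <- lapply(names(cfg$disease), function(s) {
      tab <- readr::read_csv(cfg$disease[[s]], show_col_types = FALSE,
                             progress = FALSE)
      if (s %in% cfg$ranked_sources) {
        top_n_by_score(tab, cfg$top_n_disease, source = s)
      } else {
        unique(normalize_symbols(tab$target))
      }
    })
    setNames(sets, names(cfg$disease))
  }, od)
  disease_cluster <- union_disease_targets(disease_sets)
  intersection <- intersect_clusters(compound_cluster, disease_cluster)

  ppi_net <- stage("ppi", parse_string_tsv(cfg$ppi, min_score = cfg$min_score),
                   od)
  crucial <- stage("ppi", {
    net <- ppi_net
    cent <- centralities(net)
    readr::write_csv(cent, file.path(od, "centralities.csv"),
                     progress = FALSE)
    write_sif(net, file.path(od, "ppi.sif"))
    write_graphml(net, file.path(od, "ppi.graphml"))
    median_filter(cent)
  }, od)

  enrichment <- stage("enrich", {
    terms <- read_gmt(cfg$gmt)
    res <- enrich(crucial, terms, method = cfg$enrich_method)
    flat <- res
    flat$overlap_genes <- vapply(res$overlap_genes, paste, character(1),
                                 collapse = ";")
    readr::write_csv(flat, file.path(od, "enrichment.csv"), progress = FALSE)
    res
  }, od)
  top_kegg <- top_terms(enrichment, "KEGG", cfg$top_pathways, "count_desc")

  net_report <- stage("ctpnet", {
    # target nodes: crucial targets annotated to at least one top pathway
    # (pathway-connected core targets); compound-target edges restricted to
    # those targets
    tp_pairs <- do.call(rbind, lapply(seq_len(nrow(top_kegg)), function(i) {
      genes <- intersect(top_kegg$overlap_genes[[i]], crucial)
      if (length(genes) == 0) return(NULL)
      data.frame(from = genes, to = top_kegg$term_id[i])
    }))
    net_targets <- sort(unique(tp_pairs$from))
    ct_pairs <- compound_targets[compound_targets$target %in% net_targets,
                                 c("cid", "target")]
    net_compounds <- sort(unique(as.character(ct_pairs$cid)))
    ct_pairs$cid <- as.character(ct_pairs$cid)
    net <- build_tripartite(net_compounds, net_targets, top_kegg$term_id,
                            ct_edges = ct_pairs, tp_edges = tp_pairs)
    write_sif(net, file.path(od, "ctp.sif"))
    write_graphml(net, file.path(od, "ctp.graphml"))
    list(net = net,
         top_targets = rank_by_degree(net, "target", cfg$top_targets),
         top_compounds = rank_by_degree(net, "compound", cfg$top_compounds),
         top_pathways = rank_by_degree(net, "pathway", nrow(top_kegg)))
  }, od)

  writeLines(compound_cluster, file.path(od, "compound_targets.txt"))
  writeLines(disease_cluster, file.path(od, "disease_targets.txt"))
  writeLines(intersection, file.path(od, "intersection_targets.txt"))
  writeLines(crucial, file.path(od, "crucial_targets.txt"))

  report <- list(
    counts = list(
      library_rows = nrow(parsed$compounds) + parsed$n_rejected,
      library_compounds = nrow(library_tbl),
      superior_compounds = length(superior),
      compound_targets = length(compound_cluster),
      disease_targets = length(disease_cluster),
      intersection_targets = length(intersection),
      ppi_nodes = length(ppi_net$nodes),
      ppi_edges = nrow(ppi_net$edges),
      crucial_targets = length(crucial),
      network_nodes = nrow(net_report$net$nodes),
      network_edges = nrow(net_report$net$edges)
    ),
    superior_cids = superior,
    top_targets = net_report$top_targets,
    top_compounds = net_report$top_compounds,
    top_pathways = net_report$top_pathways,
    config = list(top_n_disease = cfg$top_n_disease,
                  top_pathways = cfg$top_pathways,
                  top_targets = cfg$top_targets,
                  top_compounds = cfg$top_compounds,
                  enrich_method = cfg$enrich_method,
                  violation_scope = cfg$violation_scope)
  )
  check_report_consistency(report)
  class(report) <- "run_report"
  jsonlite::write_json(unclass(report), file.path(od, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  report
}

check_report_consistency <- function(report) {
  cts <- report$counts
  ok <- cts$superior_compounds <= cts$library_compounds &&
    cts$library_compounds <= cts$library_rows &&
    cts$intersection_targets <= min(cts$compound_targets,
                                    cts$disease_targets) &&
    cts$crucial_targets <= cts$ppi_nodes &&
    cts$network_nodes >= 0
  if (!ok) {
    np_stop("np_data_error", "run report failed internal count consistency")
  }
  invisible(report)
}

#' @export
print.run_report <- function(x, ...) {
  cat("netpharm run report\n")
  for (nm in names(x$counts)) {
    cat(sprintf("  %-22s %d\n", nm, x$counts[[nm]]))
  }
  cat("  top targets:", paste(x$top_targets$node, collapse = ", "), "\n")
  cat("  top compounds:", paste(x$top_compounds$node, collapse = ", "), "\n")
  invisible(x)
}
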