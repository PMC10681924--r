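# End-to-end orchestration: compound screen -> target union/intersection ->
# bipartite network -> PPI core extraction -> over-representation analysis,
# with a JSON run report of stage-by-stage counts.

#' Pipeline configuration
#'
#' Collects file paths and thresholds for a full screening run. The
#' defaults are the conventional screening thresholds: peak area > 0.12%,
#' target-prediction score >= 0.8, PPI confidence >= 0.9, enrichment
#' p <= 0.05, top 10 GO terms per branch and top 30 pathways.
#'
#' @param compound_table path to the compound TSV.
#' @param compound_dialect dialect for [parse_compound_table()].
#' @param disease_lists character vector of disease gene-list paths.
#' @param target_map path to the compound-to-target TSV.
#' @param ppi_edges path to the PPI edge-list TSV.
#' @param gmt_files named character vector of GMT paths; names are the
#'   categories (`BP`, `CC`, `MF`, `pathway`).
#' @param out_dir output directory for all artifacts.
#' @param min_peak_area_pct,target_score_floor,ppi_min_score,enrich_alpha
#'   stage thresholds.
#' @param core_metrics centrality metrics for the median filter.
#' @param core_rounds number of median-filter rounds.
#' @param core_mode `"all"` or `"any"` (see [median_filter_round()]).
#' @param top_go,top_pathway per-category caps for [select_top()].
#' @param enrich_on `"common"` (default: enrich the full drug-disease
#'   common set) or `"core"` (the extracted core genes).
#' @param rules [screen_rules()] for the ADMET stage.
#' @param seed integer seed recorded in the report (the run itself is
#'   deterministic).
#' @return a list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(compound_table,
                            disease_lists,
                            target_map,
                            ppi_edges,
                            gmt_files,
                            out_dir,
                            compound_dialect = "canonical",
                            min_peak_area_pct = 0.12,
                            target_score_floor = 0.8,
                            ppi_min_score = 0.9,
                            enrich_alpha = 0.05,
                            core_metrics = c("dc", "bc", "cc", "ec"),
                            core_rounds = 2L,
                            core_mode = "all",
                            top_go = 10L,
                            top_pathway = 30L,
                            enrich_on = c("common", "core"),
                            rules = NULL,
                            seed = 1L) {
  cfg <- list(compound_table = compound_table,
              compound_dialect = compound_dialect,
              disease_lists = disease_lists, target_map = target_map,
              ppi_edges = ppi_edges, gmt_files = gmt_files,
              out_dir = out_dir,
              min_peak_area_pct = min_peak_area_pct,
              target_score_floor = target_score_floor,
              ppi_min_score = ppi_min_score, enrich_alpha = enrich_alpha,
              core_metrics = core_metrics, core_rounds = as.integer(core_rounds),
              core_mode = core_mode,
              top_go = as.integer(top_go), top_pathway = as.integer(top_pathway),
              enrich_on = match.arg(enrich_on),
              rules = rules %||% screen_rules(min_peak_area_pct = min_peak_area_pct),
              seed = as.integer(seed))
  if (cfg$ppi_min_score < 0 || cfg$ppi_min_score > 1)
    np_stop("pipeline_config: ppi_min_score must lie in [0, 1]")
  if (cfg$enrich_alpha <= 0 || cfg$enrich_alpha > 1)
    np_stop("pipeline_config: enrich_alpha must lie in (0, 1]")
  structure(cfg, class = "pipeline_config")
}

run_stage <- function(report, stage, out_dir, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(force(expr), error = function(e) e)
  if (inherits(res, "error")) {
    writeLines(sprintf("stage %s failed: %s", stage, conditionMessage(res)),
               file.path(out_dir, "FAILED"))
    np_stop("pipeline stage '%s' failed: %s", stage, conditionMessage(res))
  }
  message(sprintf("[netpharm] stage %-12s %.2fs", stage,
                  proc.time()[["elapsed"]] - t0))
  res
}

#' Run the screening pipeline end to end
#'
#' Executes compound screening, disease-target union, drug-disease
#' intersection, bipartite-network construction, PPI core extraction and
#' over-representation analysis, writing every intermediate artifact under
#' `cfg$out_dir` plus `report.json` / `report.md` with stage-by-stage
#' counts. Rerunning with identical inputs reproduces an identical report
#' (no timestamps enter the report files; timings go to stderr).
#'
#' @param cfg a [pipeline_config()].
#' @return the run report, an object of class `"run_report"` (a named
#'   list; see `inst/schema/report-schema.json` for the layout), invisibly
#'   also written to disk.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  if (file.exists(file.path(out, "FAILED")))
    unlink(file.path(out, "FAILED"))
  report <- list(seed = cfg$seed, flags = character(0))

  # --- compound screen ---
  compounds <- run_stage(report, "compounds", out, {
    tab <- parse_compound_table(cfg$compound_table,
                                dialect = cfg$compound_dialect)
    n_in <- nrow(tab)
    if (!anyNA(tab$peak_area_pct)) tab <- filter_peaks(tab, cfg$rules)
    kept <- admet_filter(tab, cfg$rules)
    write_compound_table(kept, file.path(out, "compounds_passed.tsv"))
    utils::write.table(admet_rejections(kept),
                       file.path(out, "compounds_rejected.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(tab = kept, n_in = n_in)
  })
  report$compounds <- list(n_in = compounds$n_in,
                           n_passed = nrow(compounds$tab))

  # --- disease-target union ---
  disease <- run_stage(report, "disease", out, {
    sets <- lapply(cfg$disease_lists, load_gene_list, kind = "disease")
    u <- union_disease_targets(sets)
    write_gene_list(u, file.path(out, "disease_union.txt"))
    utils::write.table(venn_counts(sets), file.path(out, "venn.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(sets = sets, union = u)
  })
  report$disease <- list(
    per_source = as.list(attr(disease$union, "source_counts")),
    union_size = length(disease$union$genes))

  # --- drug targets of passing compounds + intersection ---
  common <- run_stage(report, "intersect", out, {
    map <- read_target_map(cfg$target_map,
                           score_floor = cfg$target_score_floor)
    map <- map[names(map) %in% compounds$tab$name]
    drug <- target_set(unlist(map), name = "drug_targets", kind = "drug")
    cm <- intersect_drug_disease(drug, disease$union)
    write_gene_list(cm, file.path(out, "common_targets.txt"))
    list(map = map, drug = drug, common = cm)
  })
  report$targets <- list(drug_targets = length(common$drug$genes),
                         common_targets = length(common$common$genes))
  if (length(common$common$genes) == 0L)
    report$flags <- c(report$flags, "no_common_targets")

  # --- bipartite compound-target network ---
  bip <- run_stage(report, "bipartite", out, {
    net <- build_bipartite(common$map, common$common)
    write_sif(net, file.path(out, "compound_target.sif"))
    net
  })
  report$bipartite <- list(compounds = length(bip$compounds),
                           targets = length(bip$targets),
                           edges = nrow(bip$edges))

  # --- PPI core extraction ---
  core <- run_stage(report, "ppi_core", out, {
    edges <- read_ppi_edges(cfg$ppi_edges)
    g <- ppi_graph(edges, min_score = cfg$ppi_min_score)
    g <- induced_subgraph(g, common$common$genes)
    if (length(g$nodes)) {
      write_centrality_table(centrality_table(g),
                             file.path(out, "centrality.tsv"))
      ce <- extract_core(g, metrics = cfg$core_metrics,
                         rounds = cfg$core_rounds, mode = cfg$core_mode)
      write_gene_list(ce$core_nodes, file.path(out, "core_targets.txt"))
      write_sif(ce$graph, file.path(out, "core_network.sif"))
    } else {
      ce <- structure(list(rounds = data.frame(), core_nodes = character(0),
                           graph = g, exhausted = FALSE),
                      class = "core_extraction")
      write_gene_list(character(0), file.path(out, "core_targets.txt"))
    }
    list(graph = g, core = ce)
  })
  report$ppi <- list(
    nodes = length(core$graph$nodes),
    edges = nrow(core$graph$edges),
    rounds = if (nrow(core$core$rounds))
      lapply(seq_len(nrow(core$core$rounds)), function(r)
        list(nodes = core$core$rounds$nodes[r],
             edges = core$core$rounds$edges[r]))
    else list(),
    core_size = length(core$core$core_nodes),
    core_genes = core$core$core_nodes,
    exhausted = core$core$exhausted)

  # --- over-representation analysis ---
  enrich <- run_stage(report, "enrichment", out, {
    coll <- NULL
    for (i in seq_along(cfg$gmt_files)) {
      ci <- read_gmt(cfg$gmt_files[[i]],
                     category = names(cfg$gmt_files)[i])
      coll <- if (is.null(coll)) ci else c(coll, ci)
    }
    query <- if (cfg$enrich_on == "core") core$core$core_nodes else
      common$common$genes
    if (length(query)) {
      res <- suppressMessages(run_ora(query, coll))
      caps <- c(BP = cfg$top_go, CC = cfg$top_go, MF = cfg$top_go,
                pathway = cfg$top_pathway)
      top <- select_top(res, per_category = caps, alpha = cfg$enrich_alpha)
    } else {
      res <- suppressMessages(run_ora(character(0), coll,
                                      universe = unlist(lapply(coll, `[[`, "members"))))
      top <- res
    }
    utils::write.table(res, file.path(out, "enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(top, file.path(out, "enrichment_top.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(res = res, top = top)
  })
  report$enrichment <- list(
    tested_terms = nrow(enrich$res),
    significant = sum(enrich$res$p_value <= cfg$enrich_alpha),
    reported = nrow(enrich$top))

  class(report) <- "run_report"
  jsonlite::write_json(unclass(report), file.path(out, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(format_report_md(report), file.path(out, "report.md"))
  invisible(report)
}

format_report_md <- function(r) {
  c("# netpharm run report", "",
    sprintf("- compounds: %d in, %d passed screening",
            r$compounds$n_in, r$compounds$n_passed),
    sprintf("- disease targets: %d after de-duplication across %d sources",
            r$disease$union_size, length(r$disease$per_source)),
    sprintf("- drug targets: %d; drug-disease common targets: %d",
            r$targets$drug_targets, r$targets$common_targets),
    sprintf("- bipartite network: %d compounds x %d targets, %d edges",
            r$bipartite$compounds, r$bipartite$targets, r$bipartite$edges),
    sprintf("- PPI graph: %d nodes, %d edges; core of %d genes%s",
            r$ppi$nodes, r$ppi$edges, r$ppi$core_size,
            if (isTRUE(r$ppi$exhausted)) " (early stop)" else ""),
    sprintf("- enrichment: %d terms tested, %d significant, %d reported",
            r$enrichment$tested_terms, r$enrichment$significant,
            r$enrichment$reported),
    if (length(r$flags)) sprintf("- flags: %s",
                                 paste(r$flags, collapse = ", ")) else
                                   "- flags: none")
}

#' @export
print.run_report <- function(x, ...) {
  cat(paste(format_report_md(x), collapse = "\n"), "\n")
  invisible(x)
}

#' Validate a run report against the shipped schema
#'
#' Structural validation of a [run_pipeline()] report against the JSON
#' schema in `inst/schema/report-schema.json`: checks that every required
#' field is present and has the declared primitive type.
#'
#' @param report a `"run_report"` (or a list parsed from `report.json`).
#' @return `TRUE`, or an error describing the first violation.
#' @export
validate_report <- function(report) {
  schema <- jsonlite::read_json(
    system.file("schema", "report-schema.json", package = "netpharm"))
  check_obj <- function(obj, spec, where) {
    for (field in names(spec$required_fields)) {
      if (is.null(obj[[field]]))
        np_stop("report schema: missing field '%s' in %s", field, where)
      type <- spec$required_fields[[field]]
      val <- obj[[field]]
      ok <- switch(as.character(type),
                   integer = is.numeric(val),
                   number = is.numeric(val),
                   string = is.character(val),
                   boolean = is.logical(val),
                   array = is.list(val) || is.vector(val),
                   object = is.list(val),
                   TRUE)
      if (!ok)
        np_stop("report schema: field '%s' in %s has type %s, expected %s",
                field, where, class(val)[1], type)
    }
    invisible(TRUE)
  }
  check_obj(report, schema, "report")
  for (sect in names(schema$sections))
    check_obj(report[[sect]], schema$sections[[sect]], sect)
  TRUE
}
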