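# Seeded generators for every input the pipeline consumes, each planting
# recoverable ground truth recorded in a manifest. All draws are pure
# functions of the config: one master seed drives a named substream per
# generator, so identical configs give byte-identical files.

#' Synthetic-data configuration
#'
#' Bundles every knob of the synthetic generators. Defaults mirror the
#' scale of a typical essential-oil screening study where one is printed
#' (21 compounds, five disease sources, seven assay doses, two filter
#' rounds, STRING-style 0.9 edge scores) at desk-size networks (a 100-node
#' interactome, a few hundred background genes).
#'
#' @param seed master integer seed; every generator derives its own
#'   substream from it.
#' @param n_compounds compound rows to generate.
#' @param admet_pass_fraction fraction of compounds passing the default
#'   [screen_rules()]; exactly `round(n * fraction)` rows pass.
#' @param n_sources number of disease-target sources.
#' @param source_sizes per-source gene counts (length `n_sources`).
#' @param overlap_gene_count genes present in *every* disease source.
#' @param gene_pool_size size of the synthetic gene universe
#'   (`G000001`-style tokens).
#' @param ppi_nodes,ppi_core_size interactome size and planted-core size.
#' @param core_density,periphery_density edge probability within the
#'   planted core vs among periphery pairs; the core must be denser.
#' @param cross_density core-periphery edge probability; defaults to the
#'   geometric mean of the two densities, giving the planted core hub-like
#'   (rich-club) wiring so that it is high on betweenness as well as
#'   degree.
#' @param edge_score_range range of uniform PPI confidence scores.
#' @param n_terms,term_size_range random gene-set count and size range.
#' @param planted_term_overlap genes shared between the planted term and
#'   the emitted query.
#' @param query_size size of the emitted ORA query.
#' @param doses assay concentrations (ug/mL).
#' @param n_replicates replicate wells per plate row.
#' @param ic50_true,hill_true true 4PL parameters of the generated plate.
#' @param od_blank,od_control noise-free blank/control optical densities.
#' @param od_noise_sd Gaussian OD noise as a fraction of the
#'   blank-to-control dynamic range.
#' @return a validated list of class `"synth_config"`.
#' @export
synth_config <- function(seed = 1L,
                         n_compounds = 21L,
                         admet_pass_fraction = 0.6,
                         n_sources = 5L,
                         source_sizes = c(240L, 60L, 40L, 50L, 80L),
                         overlap_gene_count = 12L,
                         gene_pool_size = 800L,
                         ppi_nodes = 100L,
                         ppi_core_size = 10L,
                         core_density = 0.9,
                         periphery_density = 0.03,
                         cross_density = sqrt(core_density * periphery_density),
                         edge_score_range = c(0.9, 1.0),
                         n_terms = 200L,
                         term_size_range = c(10L, 60L),
                         planted_term_overlap = 15L,
                         query_size = 20L,
                         doses = c(50, 100, 200, 400, 600, 800, 1000),
                         n_replicates = 3L,
                         ic50_true = 524,
                         hill_true = 2,
                         od_blank = 0.08,
                         od_control = 0.85,
                         od_noise_sd = 0.03) {
  cfg <- list(seed = as.integer(seed), n_compounds = as.integer(n_compounds),
              admet_pass_fraction = admet_pass_fraction,
              n_sources = as.integer(n_sources),
              source_sizes = as.integer(source_sizes),
              overlap_gene_count = as.integer(overlap_gene_count),
              gene_pool_size = as.integer(gene_pool_size),
              ppi_nodes = as.integer(ppi_nodes),
              ppi_core_size = as.integer(ppi_core_size),
              core_density = core_density,
              periphery_density = periphery_density,
              cross_density = cross_density,
              edge_score_range = edge_score_range,
              n_terms = as.integer(n_terms),
              term_size_range = as.integer(term_size_range),
              planted_term_overlap = as.integer(planted_term_overlap),
              query_size = as.integer(query_size),
              doses = doses, n_replicates = as.integer(n_replicates),
              ic50_true = ic50_true, hill_true = hill_true,
              od_blank = od_blank, od_control = od_control,
              od_noise_sd = od_noise_sd)
  with(cfg, {
    if (admet_pass_fraction < 0 || admet_pass_fraction > 1)
      np_stop("synth_config: admet_pass_fraction must lie in [0, 1]")
    if (length(source_sizes) != n_sources)
      np_stop("synth_config: source_sizes must have length n_sources")
    if (any(source_sizes < overlap_gene_count))
      np_stop("synth_config: every source must hold the shared core")
    if (ppi_core_size >= ppi_nodes)
      np_stop("synth_config: ppi_core_size must be smaller than ppi_nodes")
    if (core_density < periphery_density)
      np_stop("synth_config: core_density must be >= periphery_density")
    if (any(edge_score_range < 0) || any(edge_score_range > 1) ||
        edge_score_range[1] > edge_score_range[2])
      np_stop("synth_config: edge_score_range must be an increasing pair in [0, 1]")
    if (planted_term_overlap > query_size)
      np_stop("synth_config: planted_term_overlap cannot exceed query_size")
    if (gene_pool_size < max(source_sizes) + ppi_nodes)
      np_stop("synth_config: gene_pool_size too small for the requested sets")
  })
  structure(cfg, class = "synth_config")
}

gene_token <- function(i) sprintf("G%06d", i)

#' Generate a synthetic compound table
#'
#' Writes `compounds.tsv` (canonical dialect) with valid elemental
#' formulas, opaque SMILES-like strings, retention times, peak areas above
#' the default 0.12% cut, and ADMET flags arranged so that exactly
#' `round(n_compounds * admet_pass_fraction)` rows pass the default
#' [screen_rules()]. The manifest records which rows pass.
#'
#' @param cfg a [synth_config()].
#' @param dir output directory (created if needed).
#' @return list with `path` and `manifest` (`pass_names`, `n_pass`).
#' @export
gen_compounds <- function(cfg, dir) {
  stopifnot(inherits(cfg, "synth_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- cfg$n_compounds
  with_substream(cfg$seed, "compounds", {
    name <- sprintf("CMP%03d", seq_len(n))
    formula <- vapply(seq_len(n), function(i) {
      nc <- sample(5:20, 1); nh <- sample(6:30, 1)
      no <- sample(0:4, 1); nn <- sample(0:2, 1)
      paste0("C", nc, "H", nh,
             if (nn > 0) paste0("N", if (nn > 1) nn else "") else "",
             if (no > 0) paste0("O", if (no > 1) no else "") else "")
    }, character(1))
    smiles <- vapply(seq_len(n), function(i)
      paste(sample(c("C", "O", "N", "c", "1", "="), sample(8:20, 1),
                   replace = TRUE), collapse = ""), character(1))
    rt <- sort(round(stats::runif(n, 5, 50), 2))
    area <- round(stats::runif(n, 0.13, 15), 3)
    n_pass <- round(n * cfg$admet_pass_fraction)
    pass <- seq_len(n) %in% sample.int(n, n_pass)
    gi <- ifelse(pass, "High", "High")
    bbb <- sample(c("Yes", "No"), n, replace = TRUE)
    pgp <- ifelse(pass, "No", "No")
    dl_pass <- rep(TRUE, n)
    dl_viol <- ifelse(pass, sample(0:1, n, replace = TRUE), 0L)
    # failing rows break exactly one randomly chosen rule
    for (i in which(!pass)) {
      how <- sample(c("gi", "pgp", "dl", "viol"), 1)
      if (how == "gi") gi[i] <- "Low"
      else if (how == "pgp") pgp[i] <- "Yes"
      else if (how == "dl") dl_pass[i] <- FALSE
      else dl_viol[i] <- sample(2:3, 1)
    }
    df <- data.frame(
      name = name, formula = formula, smiles = smiles,
      cid = sprintf("%06d", sample.int(999999, n)),
      retention_time = sprintf("%.2f", rt),
      peak_area_pct = sprintf("%.3f", area),
      gi_absorption = gi, bbb = bbb, pgp_substrate = pgp,
      drug_likeness = sprintf("%s; %d violation",
                              ifelse(dl_pass, "Yes", "No"), dl_viol),
      stringsAsFactors = FALSE
    )
    path <- file.path(dir, "compounds.tsv")
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    list(path = path,
         manifest = list(pass_names = name[pass], n_pass = n_pass))
  })
}

#' Generate per-source disease-target gene lists
#'
#' Writes one plain-text gene list per source with a designated shared
#' core present in every source; the manifest states the exact union and
#' pairwise-intersection sizes as computed from the generated lists.
#'
#' @param cfg a [synth_config()].
#' @param dir output directory.
#' @param disjoint if `TRUE`, sources are pairwise disjoint (no shared
#'   core) and the union size is the sum of the source sizes.
#' @return list with `paths`, and `manifest` holding `source_sizes`,
#'   `union`, `union_size`, `pairwise` (intersection-count matrix) and
#'   `core_genes`.
#' @export
gen_target_universe <- function(cfg, dir, disjoint = FALSE) {
  stopifnot(inherits(cfg, "synth_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pool <- gene_token(seq_len(cfg$gene_pool_size))
  with_substream(cfg$seed, "targets", {
    sources <- vector("list", cfg$n_sources)
    if (disjoint) {
      offsets <- cumsum(c(0L, cfg$source_sizes))
      for (s in seq_len(cfg$n_sources))
        sources[[s]] <- pool[(offsets[s] + 1):offsets[s + 1]]
    } else {
      core <- sample(pool, cfg$overlap_gene_count)
      rest <- setdiff(pool, core)
      for (s in seq_len(cfg$n_sources))
        sources[[s]] <- c(core,
                          sample(rest, cfg$source_sizes[s] -
                                   cfg$overlap_gene_count))
    }
    names(sources) <- sprintf("source_%02d", seq_len(cfg$n_sources))
    paths <- character(cfg$n_sources)
    for (s in seq_len(cfg$n_sources)) {
      paths[s] <- file.path(dir, paste0(names(sources)[s], ".txt"))
      writeLines(sort(sources[[s]]), paths[s])
    }
    pairwise <- outer(seq_len(cfg$n_sources), seq_len(cfg$n_sources),
                      Vectorize(function(i, j)
                        length(intersect(sources[[i]], sources[[j]]))))
    dimnames(pairwise) <- list(names(sources), names(sources))
    un <- sort(unique(unlist(sources)))
    list(paths = paths,
         manifest = list(source_sizes = lengths(sources),
                         union = un, union_size = length(un),
                         pairwise = pairwise,
                         core_genes = if (disjoint) character(0) else
                           sort(core)))
  })
}

#' Generate a weighted PPI edge list with a planted core
#'
#' The graph is an Erdos-Renyi periphery at `periphery_density` plus a
#' planted near-clique of `ppi_core_size` nodes at `core_density`;
#' core-periphery pairs are wired at `cross_density` (by default the
#' geometric mean of the two densities), which gives the planted core the
#' hub-like character — high degree *and* betweenness — of real
#' interactome cores. Edge confidence scores are uniform in
#' `edge_score_range`. The manifest lists the planted core nodes.
#'
#' @param cfg a [synth_config()].
#' @param dir output directory.
#' @param node_names optional character vector of node names (length
#'   `ppi_nodes`); defaults to `G`-tokens.
#' @return list with `path` and `manifest` (`nodes`, `core_nodes`,
#'   `n_edges`).
#' @export
gen_ppi <- function(cfg, dir, node_names = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- cfg$ppi_nodes
  nodes <- node_names %||% gene_token(seq_len(n))
  if (length(nodes) != n)
    np_stop("gen_ppi: node_names must have length ppi_nodes")
  with_substream(cfg$seed, "ppi", {
    core_idx <- sort(sample.int(n, cfg$ppi_core_size))
    is_core <- seq_len(n) %in% core_idx
    pairs <- utils::combn(n, 2L)
    i <- pairs[1L, ]; j <- pairs[2L, ]
    p <- ifelse(is_core[i] & is_core[j], cfg$core_density,
                ifelse(is_core[i] | is_core[j], cfg$cross_density,
                       cfg$periphery_density))
    keep <- stats::runif(length(p)) < p
    score <- round(stats::runif(sum(keep), cfg$edge_score_range[1],
                                cfg$edge_score_range[2]), 4)
    df <- data.frame(a = nodes[i[keep]], b = nodes[j[keep]],
                     score = sprintf("%.4f", score),
                     stringsAsFactors = FALSE)
    path <- file.path(dir, "ppi_edges.tsv")
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    list(path = path,
         manifest = list(nodes = nodes, core_nodes = nodes[core_idx],
                         n_edges = nrow(df)))
  })
}

#' Generate gene-set collections with one planted enriched term
#'
#' Writes one GMT file per category (random terms split evenly) plus a
#' query gene list. The planted term (`T_PLANTED`, in the `pathway` file)
#' shares exactly `planted_term_overlap` genes with the emitted query; all
#' other terms are random draws from the gene pool. The manifest names the
#' planted term.
#'
#' @param cfg a [synth_config()].
#' @param dir output directory.
#' @param query optional query gene vector; defaults to a random draw of
#'   `query_size` pool genes.
#' @param categories categories to emit, one GMT per category.
#' @return list with `gmt_paths`, `query_path` and `manifest`
#'   (`planted_term`, `planted_overlap`, `query`).
#' @export
gen_gene_sets <- function(cfg, dir, query = NULL,
                          categories = c("BP", "CC", "MF", "pathway")) {
  stopifnot(inherits(cfg, "synth_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pool <- gene_token(seq_len(cfg$gene_pool_size))
  with_substream(cfg$seed, "gene_sets", {
    if (is.null(query)) query <- sample(pool, cfg$query_size)
    query <- sort(unique(norm_symbol(query)))
    if (cfg$planted_term_overlap > length(query))
      np_stop("gen_gene_sets: planted overlap exceeds query size")
    per_cat <- rep(cfg$n_terms %/% length(categories), length(categories))
    per_cat[1] <- per_cat[1] + cfg$n_terms %% length(categories)
    gmt_paths <- character(length(categories))
    term_no <- 0L
    for (ci in seq_along(categories)) {
      lines <- character(per_cat[ci])
      for (t in seq_len(per_cat[ci])) {
        term_no <- term_no + 1L
        size <- sample(cfg$term_size_range[1]:cfg$term_size_range[2], 1)
        members <- sort(sample(pool, size))
        lines[t] <- paste(c(sprintf("T%04d", term_no),
                            sprintf("random term %d", term_no), members),
                          collapse = "\t")
      }
      if (categories[ci] == "pathway") {
        shared <- if (cfg$planted_term_overlap > 0)
          sample(query, cfg$planted_term_overlap) else character(0)
        filler_n <- max(cfg$term_size_range[1],
                        round(mean(cfg$term_size_range))) - length(shared)
        filler <- sample(setdiff(pool, query), max(filler_n, 0L))
        lines <- c(lines, paste(c("T_PLANTED", "planted enriched term",
                                  sort(c(shared, filler))),
                                collapse = "\t"))
      }
      gmt_paths[ci] <- file.path(dir, sprintf("sets_%s.gmt", categories[ci]))
      writeLines(lines, gmt_paths[ci])
    }
    query_path <- file.path(dir, "query.txt")
    writeLines(query, query_path)
    list(gmt_paths = stats::setNames(gmt_paths, categories),
         query_path = query_path,
         manifest = list(planted_term = "T_PLANTED",
                         planted_overlap = cfg$planted_term_overlap,
                         query = query))
  })
}

#' Generate a synthetic viability plate
#'
#' Draws optical densities from a four-parameter logistic curve (upper
#' asymptote 100%, lower 0%) at the configured doses, maps viability to OD
#' through the blank/control dynamic range, and adds Gaussian noise with
#' standard deviation `od_noise_sd` times that range. Blank and control
#' wells receive the same noise model. The manifest records the true IC50
#' and Hill slope.
#'
#' @param cfg a [synth_config()].
#' @param dir output directory.
#' @return list with `path` and `manifest` (`ic50_true`, `hill_true`).
#' @export
gen_plate <- function(cfg, dir) {
  stopifnot(inherits(cfg, "synth_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_substream(cfg$seed, "plate", {
    rng <- cfg$od_control - cfg$od_blank
    v_true <- fourpl(cfg$doses, 0, 100, cfg$hill_true, cfg$ic50_true)
    nrep <- cfg$n_replicates
    noise <- function(k) stats::rnorm(k, 0, cfg$od_noise_sd * rng)
    row_od <- function(od) sprintf("%.6f", od + noise(nrep))
    rows <- c(
      paste(c("blank", "", row_od(cfg$od_blank)), collapse = "\t"),
      paste(c("control", "", row_od(cfg$od_control)), collapse = "\t"),
      vapply(seq_along(cfg$doses), function(i)
        paste(c("treated", sprintf("%g", cfg$doses[i]),
                row_od(cfg$od_blank + v_true[i] / 100 * rng)),
              collapse = "\t"), character(1))
    )
    header <- paste(c("type", "dose", sprintf("od_%d", seq_len(nrep))),
                    collapse = "\t")
    path <- file.path(dir, "plate.tsv")
    writeLines(c(header, rows), path)
    list(path = path,
         manifest = list(ic50_true = cfg$ic50_true,
                         hill_true = cfg$hill_true))
  })
}

#' Generate a complete, internally consistent fixture set
#'
#' Runs every generator and wires their ground truths together so the
#' pipeline's stage counts are predictable from the manifest: the PPI
#' nodes are a draw of `ppi_nodes` genes from the disease union (the
#' planted "common targets"); the compound-target map assigns every common
#' target to at least one ADMET-passing compound and pads the drug pool
#' with genes outside the disease union; the ORA query defaults to the
#' common set; the planted enriched term overlaps it.
#'
#' @param cfg a [synth_config()].
#' @param dir output directory.
#' @return list of all generator outputs plus `target_map_path` and a
#'   merged `manifest` (also written to `manifest.json` in `dir`).
#' @export
gen_all <- function(cfg, dir) {
  stopifnot(inherits(cfg, "synth_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cmp <- gen_compounds(cfg, dir)
  tgt <- gen_target_universe(cfg, dir)
  un <- tgt$manifest$union
  if (length(un) < cfg$ppi_nodes)
    np_stop("gen_all: disease union (%d) smaller than ppi_nodes (%d)",
            length(un), cfg$ppi_nodes)
  map_out <- with_substream(cfg$seed, "target_map", {
    common <- sort(sample(un, cfg$ppi_nodes))
    extras <- sort(sample(setdiff(gene_token(seq_len(cfg$gene_pool_size)),
                                  un), 20))
    drug_pool <- c(common, extras)
    passing <- cmp$manifest$pass_names
    all_cmp <- sprintf("CMP%03d", seq_len(cfg$n_compounds))
    rows <- list()
    for (cn in all_cmp) {
      k <- sample(5:30, 1)
      rows[[cn]] <- data.frame(compound = cn,
                               gene = sample(drug_pool, k),
                               stringsAsFactors = FALSE)
    }
    edges <- do.call(rbind, rows)
    # every common target must reach at least one passing compound
    covered <- unique(edges$gene[edges$compound %in% passing])
    missing <- setdiff(common, covered)
    if (length(missing) && length(passing))
      edges <- rbind(edges, data.frame(
        compound = sample(passing, length(missing), replace = TRUE),
        gene = missing, stringsAsFactors = FALSE))
    edges <- unique(edges[order(edges$compound, edges$gene), ])
    path <- file.path(dir, "target_map.tsv")
    utils::write.table(edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    list(path = path, common = common)
  })
  ppi <- gen_ppi(cfg, dir, node_names = map_out$common)
  sets <- gen_gene_sets(cfg, dir, query = map_out$common)
  plate <- gen_plate(cfg, dir)
  manifest <- list(
    seed = cfg$seed,
    compounds = cmp$manifest,
    disease = tgt$manifest[c("source_sizes", "union_size", "core_genes")],
    common_targets = map_out$common,
    n_common = length(map_out$common),
    ppi = ppi$manifest[c("core_nodes", "n_edges")],
    gene_sets = sets$manifest[c("planted_term", "planted_overlap")],
    plate = plate$manifest
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  list(compounds = cmp, targets = tgt, target_map_path = map_out$path,
       ppi = ppi, gene_sets = sets, plate = plate, manifest = manifest)
}
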