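# Gene-symbol target sets: loading, union, Venn intersection, bipartite net.

#' Construct a target set
#'
#' A named set of gene symbols from one source (a drug-target prediction or
#' a disease database). Symbols are trimmed, uppercased, de-duplicated and
#' sorted; no alias resolution is attempted.
#'
#' @param genes character vector of gene symbols.
#' @param name source label.
#' @param kind `"drug"`, `"disease"` or `"common"`.
#' @return object of class `"target_set"`: a list with `name`, `kind` and
#'   the sorted `genes` vector.
#' @export
target_set <- function(genes, name = "set",
                       kind = c("disease", "drug", "common")) {
  kind <- match.arg(kind)
  raw <- norm_symbol(genes)
  out <- structure(
    list(name = as.character(name), kind = kind,
         genes = sort(unique(raw))),
    class = "target_set"
  )
  attr(out, "raw_n") <- length(raw)
  out
}

#' @export
print.target_set <- function(x, ...) {
  cat(sprintf("Target set '%s' (%s): %d genes\n", x$name, x$kind,
              length(x$genes)))
  preview <- utils::head(x$genes, 8L)
  if (length(preview))
    cat("  ", paste(preview, collapse = ", "),
        if (length(x$genes) > 8L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
length.target_set <- function(x) length(x$genes)

#' Load a gene list from a one-symbol-per-line file
#'
#' Blank lines are ignored; symbols are normalized and de-duplicated. The
#' raw and unique line counts are kept as attributes `raw_n` / `unique_n`.
#'
#' @param path file path.
#' @param name source label (defaults to the file name).
#' @param kind `"disease"`, `"drug"` or `"common"`.
#' @return a [target_set()].
#' @export
load_gene_list <- function(path, name = NULL,
                           kind = c("disease", "drug", "common")) {
  if (!file.exists(path))
    np_stop("load_gene_list: cannot read '%s'", path)
  lines <- readLines(path, warn = FALSE)
  ts <- target_set(lines, name = name %||% basename(path),
                   kind = match.arg(kind))
  attr(ts, "unique_n") <- length(ts$genes)
  ts
}

#' Write a gene list, one symbol per line
#'
#' @param set a [target_set()] or character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(set, path) {
  genes <- if (inherits(set, "target_set")) set$genes else
    sort(unique(norm_symbol(set)))
  writeLines(genes, path)
  invisible(path)
}

#' Union of disease target sets
#'
#' Merges per-database disease target lists into one de-duplicated set (the
#' "eliminate duplicate targets" step), recording per-source counts for the
#' Venn report.
#'
#' @param sets list of [target_set()]s, all of kind `"disease"`.
#' @param name name of the merged set.
#' @return a `"disease"` [target_set()] with attribute `source_counts`, a
#'   named integer vector of per-source set sizes.
#' @export
union_disease_targets <- function(sets, name = "disease_union") {
  if (inherits(sets, "target_set")) sets <- list(sets)
  kinds <- vapply(sets, function(s) s$kind, character(1))
  if (any(kinds != "disease"))
    np_stop("union_disease_targets: mixed kinds (found: %s)",
            paste(unique(kinds), collapse = ", "))
  genes <- sort(unique(unlist(lapply(sets, `[[`, "genes"))))
  out <- target_set(genes, name = name, kind = "disease")
  attr(out, "source_counts") <- stats::setNames(
    vapply(sets, function(s) length(s$genes), integer(1)),
    vapply(sets, function(s) s$name, character(1))
  )
  out
}

#' Venn / UpSet membership counts over target sets
#'
#' Counts genes in every non-empty membership combination of the given
#' sets, the tabular equivalent of a Venn diagram.
#'
#' @param sets list of [target_set()]s.
#' @return data frame with columns `combination` (source names joined by
#'   `&`), `n_sources` and `count`, plus one `total_union` row.
#' @export
venn_counts <- function(sets) {
  nms <- vapply(sets, function(s) s$name, character(1))
  all_genes <- sort(unique(unlist(lapply(sets, `[[`, "genes"))))
  member <- vapply(sets, function(s) all_genes %in% s$genes,
                   logical(length(all_genes)))
  if (length(all_genes) == 1L) member <- matrix(member, nrow = 1L)
  combo <- apply(member, 1L, function(row) paste(nms[row], collapse = "&"))
  tab <- table(combo)
  out <- data.frame(
    combination = names(tab),
    n_sources = lengths(strsplit(names(tab), "&", fixed = TRUE)),
    count = as.integer(tab),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$n_sources, out$combination), , drop = FALSE]
  rbind(out,
        data.frame(combination = "total_union", n_sources = length(sets),
                   count = length(all_genes), stringsAsFactors = FALSE))
}

#' Intersect drug and disease targets (the Venn step)
#'
#' Returns the drug-disease common target set. Symmetric in its arguments
#' up to the output name.
#'
#' @param drug,disease [target_set()]s (or character vectors).
#' @param name name of the resulting common set.
#' @return a `"common"` [target_set()].
#' @export
intersect_drug_disease <- function(drug, disease, name = "common_targets") {
  g1 <- if (inherits(drug, "target_set")) drug$genes else norm_symbol(drug)
  g2 <- if (inherits(disease, "target_set")) disease$genes else
    norm_symbol(disease)
  target_set(intersect(g1, g2), name = name, kind = "common")
}

#' Read a compound-to-target map
#'
#' Reads a headerless two-column (compound TAB gene) or three-column
#' (compound TAB gene TAB score) TSV. When a score column is present,
#' rows with score below `score_floor` are dropped (inclusive `>=` keeps
#' ties at the floor).
#'
#' @param path file path.
#' @param score_floor minimum prediction score in `[0, 1]`.
#' @return named list mapping compound name to a character vector of
#'   normalized gene symbols.
#' @export
read_target_map <- function(path, score_floor = 0.8) {
  if (!file.exists(path))
    np_stop("read_target_map: cannot read '%s'", path)
  raw <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "")
  if (ncol(raw) < 2L)
    np_stop("read_target_map: expected at least 2 tab-separated columns")
  if (ncol(raw) >= 3L) {
    score <- suppressWarnings(as.numeric(raw[[3]]))
    if (anyNA(score))
      np_stop("read_target_map: non-numeric score column")
    if (any(score < 0 | score > 1))
      np_stop("read_target_map: scores must lie in [0, 1]")
    raw <- raw[score >= score_floor, , drop = FALSE]
  }
  split_genes <- split(norm_symbol(raw[[2]]), raw[[1]])
  lapply(split_genes, function(g) sort(unique(g)))
}

#' Build the compound-target bipartite network
#'
#' Edges are exactly the (compound, gene) pairs whose gene survives the
#' common-target filter; compounds with no surviving edge are dropped.
#'
#' @param map named list compound -> gene symbols (see
#'   [read_target_map()]).
#' @param keep the drug-disease common [target_set()] (or character
#'   vector) of genes to retain.
#' @return object of class `"bipartite_network"`: list with `compounds`,
#'   `targets` and an `edges` data frame (`compound`, `gene`).
#' @export
build_bipartite <- function(map, keep) {
  keep_genes <- if (inherits(keep, "target_set")) keep$genes else
    sort(unique(norm_symbol(keep)))
  edges <- do.call(rbind, lapply(names(map), function(cmp) {
    g <- intersect(sort(unique(norm_symbol(map[[cmp]]))), keep_genes)
    if (!length(g)) return(NULL)
    data.frame(compound = cmp, gene = g, stringsAsFactors = FALSE)
  }))
  if (is.null(edges))
    edges <- data.frame(compound = character(0), gene = character(0),
                        stringsAsFactors = FALSE)
  structure(
    list(compounds = unique(edges$compound),
         targets = sort(unique(edges$gene)),
         edges = edges),
    class = "bipartite_network"
  )
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf("Bipartite compound-target network: %d compounds, %d targets, %d edges\n",
              length(x$compounds), length(x$targets), nrow(x$edges)))
  invisible(x)
}

#' Write a network in SIF format
#'
#' Writes `source<TAB>interaction<TAB>target` triples importable by
#' Cytoscape.
#'
#' @param net a `"bipartite_network"` or `"ppi_graph"`.
#' @param path output path.
#' @param interaction interaction label, default `"interacts"`.
#' @return `path`, invisibly.
#' @export
write_sif <- function(net, path, interaction = "interacts") {
  lines <- if (inherits(net, "bipartite_network")) {
    sprintf("%s\t%s\t%s", net$edges$compound, interaction, net$edges$gene)
  } else if (inherits(net, "ppi_graph")) {
    e <- graph_edges(net)
    sprintf("%s\t%s\t%s", e$a, interaction, e$b)
  } else np_stop("write_sif: unsupported object of class '%s'", class(net)[1])
  writeLines(lines, path)
  invisible(path)
}
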