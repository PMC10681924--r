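# Score-thresholded PPI graphs, four centralities implemented from scratch,
# and iterative above-median core-subnetwork extraction.

#' Read a PPI edge list
#'
#' Reads a headerless TSV of `geneA TAB geneB TAB score` (or two columns,
#' in which case every edge gets score 1).
#'
#' @param path file path.
#' @return data frame with columns `a`, `b`, `score`.
#' @export
read_ppi_edges <- function(path) {
  if (!file.exists(path))
    np_stop("read_ppi_edges: cannot read '%s'", path)
  raw <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "")
  if (ncol(raw) < 2L)
    np_stop("read_ppi_edges: expected at least 2 tab-separated columns")
  score <- if (ncol(raw) >= 3L) suppressWarnings(as.numeric(raw[[3]])) else
    rep(1, nrow(raw))
  if (anyNA(score)) np_stop("read_ppi_edges: non-numeric score column")
  data.frame(a = as.character(raw[[1]]), b = as.character(raw[[2]]),
             score = score, stringsAsFactors = FALSE)
}

#' Build a score-thresholded PPI graph
#'
#' Keeps edges with confidence score `>= min_score` (inclusive, matching
#' the conventional "minimum interaction score" cutoff), drops self-loops,
#' and collapses duplicate pairs to their maximum score before
#' thresholding. Endpoints of dropped edges are not added as isolated
#' nodes.
#'
#' @param edges data frame with columns `a`, `b` and optionally `score`
#'   (default 1).
#' @param min_score minimum confidence score in `[0, 1]`; default 0.9.
#' @return object of class `"ppi_graph"`: list with sorted `nodes`, an
#'   integer edge matrix `edges` (columns `i < j` indexing `nodes`) and an
#'   adjacency list `adj`.
#' @export
ppi_graph <- function(edges, min_score = 0.9) {
  if (!is.numeric(min_score) || length(min_score) != 1L ||
      min_score < 0 || min_score > 1)
    np_stop("ppi_graph: min_score must be a number in [0, 1]")
  a <- norm_symbol(edges$a)
  b <- norm_symbol(edges$b)
  if (length(a) != length(b))
    np_stop("ppi_graph: empty endpoint symbols in edge list")
  score <- if (is.null(edges$score)) rep(1, length(a)) else
    as.numeric(edges$score)
  if (any(!is.finite(score) | score < 0 | score > 1))
    np_stop("ppi_graph: scores must lie in [0, 1]")
  ok <- a != b                        # drop self-loops
  a <- a[ok]; b <- b[ok]; score <- score[ok]
  lo <- pmin(a, b); hi <- pmax(a, b)  # canonical pair order
  key <- paste(lo, hi, sep = "\r")
  best <- tapply(score, key, max)     # duplicates keep max score
  if (!length(best))
    return(graph_from_pairs(character(0), character(0),
                            nodes = character(0)))
  keep <- best >= min_score
  pairs <- strsplit(names(best)[keep], "\r", fixed = TRUE)
  lo <- vapply(pairs, `[`, character(1), 1L)
  hi <- vapply(pairs, `[`, character(1), 2L)
  nodes <- sort(unique(c(lo, hi)))
  graph_from_pairs(lo, hi, nodes = nodes,
                   scores = as.numeric(best[keep]))
}

# Internal constructor from canonical (already deduplicated) pairs.
graph_from_pairs <- function(a, b, nodes = NULL, scores = NULL) {
  nodes <- nodes %||% sort(unique(c(a, b)))
  i <- match(pmin(a, b), nodes)
  j <- match(pmax(a, b), nodes)
  o <- order(i, j)
  em <- cbind(i = i[o], j = j[o])
  adj <- rep(list(integer(0)), length(nodes))
  for (k in seq_len(nrow(em))) {
    adj[[em[k, 1L]]] <- c(adj[[em[k, 1L]]], em[k, 2L])
    adj[[em[k, 2L]]] <- c(adj[[em[k, 2L]]], em[k, 1L])
  }
  adj <- lapply(adj, sort)
  structure(
    list(nodes = nodes, edges = em, adj = adj,
         scores = if (is.null(scores)) NULL else scores[o]),
    class = "ppi_graph"
  )
}

#' @export
print.ppi_graph <- function(x, ...) {
  cat(sprintf("PPI graph: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Number of nodes / edges of a PPI graph
#'
#' @param g a `"ppi_graph"`.
#' @return integer count.
#' @export
graph_order <- function(g) length(g$nodes)

#' @rdname graph_order
#' @export
graph_size <- function(g) nrow(g$edges)

#' Edge data frame of a PPI graph
#'
#' @param g a `"ppi_graph"`.
#' @return data frame with gene-symbol columns `a`, `b` and `score`.
#' @export
graph_edges <- function(g) {
  data.frame(a = g$nodes[g$edges[, 1L]], b = g$nodes[g$edges[, 2L]],
             score = g$scores %||% rep(1, nrow(g$edges)),
             stringsAsFactors = FALSE)
}

#' Induced subgraph on a node subset
#'
#' @param g a `"ppi_graph"`.
#' @param nodes character vector of node names to keep.
#' @return a `"ppi_graph"` on `nodes` with all edges among them.
#' @export
induced_subgraph <- function(g, nodes) {
  nodes <- sort(intersect(unique(nodes), g$nodes))
  if (!length(nodes))
    return(graph_from_pairs(character(0), character(0), nodes = character(0)))
  keep <- g$nodes[g$edges[, 1L]] %in% nodes & g$nodes[g$edges[, 2L]] %in% nodes
  graph_from_pairs(g$nodes[g$edges[keep, 1L]], g$nodes[g$edges[keep, 2L]],
                   nodes = nodes,
                   scores = (g$scores %||% rep(1, nrow(g$edges)))[keep])
}

# BFS from source `s` (integer index); returns integer distance vector,
# -1 for unreachable.
bfs_distances <- function(adj, s) {
  n <- length(adj)
  d <- rep(-1L, n)
  d[s] <- 0L
  queue <- integer(n)
  queue[1L] <- s
  head <- 1L; tail <- 1L
  while (head <= tail) {
    v <- queue[head]; head <- head + 1L
    for (w in adj[[v]]) {
      if (d[w] < 0L) {
        d[w] <- d[v] + 1L
        tail <- tail + 1L
        queue[tail] <- w
      }
    }
  }
  d
}

#' Degree centrality
#'
#' `dc(v)` is the neighbor count of `v`.
#'
#' @param g a `"ppi_graph"`.
#' @return named integer vector over the graph's nodes.
#' @export
centrality_degree <- function(g) {
  stats::setNames(lengths(g$adj), g$nodes)
}

#' Betweenness centrality (Brandes' algorithm)
#'
#' Unnormalized shortest-path betweenness on the unweighted graph:
#' `bc(v) = sum over pairs s < t (both != v) of sigma_st(v) / sigma_st`,
#' where `sigma_st` counts shortest s-t paths. Endpoints are excluded and
#' each unordered pair is counted once.
#'
#' @param g a `"ppi_graph"`.
#' @return named numeric vector.
#' @export
centrality_betweenness <- function(g) {
  n <- length(g$nodes)
  cb <- numeric(n)
  if (n == 0L) return(stats::setNames(cb, g$nodes))
  adj <- g$adj
  for (s in seq_len(n)) {
    stack <- integer(n); sp <- 0L
    preds <- rep(list(integer(0)), n)
    sigma <- numeric(n); sigma[s] <- 1
    d <- rep(-1L, n); d[s] <- 0L
    queue <- integer(n); queue[1L] <- s
    head <- 1L; tail <- 1L
    while (head <= tail) {
      v <- queue[head]; head <- head + 1L
      sp <- sp + 1L; stack[sp] <- v
      for (w in adj[[v]]) {
        if (d[w] < 0L) {
          d[w] <- d[v] + 1L
          tail <- tail + 1L; queue[tail] <- w
        }
        if (d[w] == d[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (k in seq.int(sp, 1L)) {
      w <- stack[k]
      coef <- (1 + delta[w]) / sigma[w]
      for (v in preds[[w]]) delta[v] <- delta[v] + sigma[v] * coef
      if (w != s) cb[w] <- cb[w] + delta[w]
    }
  }
  stats::setNames(cb / 2, g$nodes)  # each unordered pair visited twice
}

#' Closeness centrality (component-wise)
#'
#' Within a node's connected component `C`,
#' `cc(v) = (|C| - 1) / sum of distances from v`, giving values in
#' `[0, 1]`; isolated nodes get 0. Disconnected graphs are handled
#' per component.
#'
#' @param g a `"ppi_graph"`.
#' @return named numeric vector.
#' @export
centrality_closeness <- function(g) {
  n <- length(g$nodes)
  cc <- numeric(n)
  for (v in seq_len(n)) {
    d <- bfs_distances(g$adj, v)
    reach <- d >= 0L
    csize <- sum(reach)
    cc[v] <- if (csize > 1L) (csize - 1) / sum(d[reach]) else 0
  }
  stats::setNames(cc, g$nodes)
}

# Connected components; returns integer membership vector.
graph_components <- function(g) {
  n <- length(g$nodes)
  comp <- rep(0L, n)
  cid <- 0L
  for (v in seq_len(n)) {
    if (comp[v] == 0L) {
      cid <- cid + 1L
      d <- bfs_distances(g$adj, v)
      comp[d >= 0L] <- cid
    }
  }
  comp
}

#' Eigenvector centrality
#'
#' Principal-eigenvector score of the adjacency matrix of the largest
#' connected component, computed by power iteration and normalized so the
#' maximum entry is 1; nodes outside the largest component get 0. Ties in
#' component size are broken towards the component containing the
#' lexicographically smallest node name. The iteration runs on `A + I`
#' (a spectral shift that leaves the eigenvector unchanged but guarantees a
#' strictly dominant eigenvalue, so bipartite components converge too) and
#' stops when the successive-iterate max-difference falls below `tol`.
#'
#' @param g a nonempty `"ppi_graph"`.
#' @param tol convergence tolerance on the max-normalized iterate.
#' @param max_iter maximum iterations; non-convergence is an error carrying
#'   the iteration count.
#' @return named numeric vector, max entry 1.
#' @export
centrality_eigenvector <- function(g, tol = 1e-10, max_iter = 10000L) {
  n <- length(g$nodes)
  if (n == 0L) np_stop("centrality_eigenvector: empty graph")
  comp <- graph_components(g)
  sizes <- tabulate(comp)
  big <- which(sizes == max(sizes))[1L]  # nodes sorted => smallest name first
  idx <- which(comp == big)
  m <- length(idx)
  ec <- numeric(n)
  if (m == 1L) {
    ec[idx] <- 1
    return(stats::setNames(ec, g$nodes))
  }
  A <- matrix(0, m, m)
  pos <- match(seq_len(n), idx)
  for (k in seq_len(nrow(g$edges))) {
    i <- pos[g$edges[k, 1L]]; j <- pos[g$edges[k, 2L]]
    if (!is.na(i) && !is.na(j)) A[i, j] <- A[j, i] <- 1
  }
  x <- rep(1 / m, m)                   # deterministic uniform start
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    y <- as.vector(A %*% x) + x        # (A + I) x
    y <- y / max(y)
    if (max(abs(y - x)) < tol) { x <- y; converged <- TRUE; break }
    x <- y
  }
  if (!converged)
    stop(structure(
      class = c("netpharm_no_convergence", "error", "condition"),
      list(message = sprintf(
        "centrality_eigenvector: no convergence after %d iterations", max_iter),
        call = NULL, iterations = max_iter)))
  ec[idx] <- x / max(x)
  stats::setNames(ec, g$nodes)
}

#' Centrality table for a PPI graph
#'
#' Computes all four centralities and returns them in the conventional
#' hub-table layout.
#'
#' @param g a `"ppi_graph"`.
#' @return data frame with columns `Gene`, `Betweenness`, `Closeness`,
#'   `Degree`, `Eigenvector`, sorted by degree descending (ties by gene
#'   name).
#' @export
centrality_table <- function(g) {
  if (length(g$nodes) == 0L)
    return(data.frame(Gene = character(0), Betweenness = numeric(0),
                      Closeness = numeric(0), Degree = integer(0),
                      Eigenvector = numeric(0)))
  out <- data.frame(
    Gene = g$nodes,
    Betweenness = unname(centrality_betweenness(g)),
    Closeness = unname(centrality_closeness(g)),
    Degree = unname(centrality_degree(g)),
    Eigenvector = unname(centrality_eigenvector(g)),
    stringsAsFactors = FALSE
  )
  out[order(-out$Degree, out$Gene), , drop = FALSE]
}

compute_metrics <- function(g, metrics) {
  res <- list()
  if ("dc" %in% metrics) res$dc <- as.numeric(centrality_degree(g))
  if ("bc" %in% metrics) res$bc <- as.numeric(centrality_betweenness(g))
  if ("cc" %in% metrics) res$cc <- as.numeric(centrality_closeness(g))
  if ("ec" %in% metrics) res$ec <- as.numeric(centrality_eigenvector(g))
  res
}

#' One round of above-median centrality filtering
#'
#' Computes the selected centralities, takes each metric's median over the
#' current nodes, keeps nodes *strictly* greater than the median on every
#' selected metric (`mode = "all"`, the CytoNCA-style double screen) or on
#' at least one (`mode = "any"`), and returns the induced subgraph.
#'
#' @param g a `"ppi_graph"`.
#' @param metrics subset of `c("dc", "bc", "cc", "ec")`.
#' @param mode `"all"` (conjunctive, default) or `"any"`.
#' @return the filtered `"ppi_graph"`, with the per-metric medians in
#'   attribute `"medians"`.
#' @export
median_filter_round <- function(g, metrics = c("dc", "bc", "cc", "ec"),
                                mode = c("all", "any")) {
  mode <- match.arg(mode)
  metrics <- match.arg(metrics, several.ok = TRUE)
  if (length(g$nodes) == 0L) return(g)
  vals <- compute_metrics(g, metrics)
  meds <- vapply(vals, stats::median, numeric(1))
  above <- vapply(vals, function(v) v > stats::median(v),
                  logical(length(g$nodes)))
  if (length(g$nodes) == 1L) above <- matrix(above, nrow = 1L)
  keep <- if (mode == "all") apply(above, 1L, all) else apply(above, 1L, any)
  out <- induced_subgraph(g, g$nodes[keep])
  attr(out, "medians") <- meds
  out
}

#' Iterative core-subnetwork extraction
#'
#' Applies [median_filter_round()] repeatedly (default two rounds, the
#' usual two-stage hub screen), recording per-round node/edge counts and
#' metric medians. If a round would empty the graph, extraction stops
#' early, the previous subgraph is kept as the core and the result is
#' flagged `exhausted`.
#'
#' @param g a `"ppi_graph"`.
#' @param metrics subset of `c("dc", "bc", "cc", "ec")`.
#' @param rounds number of filter rounds, `>= 1`.
#' @param mode `"all"` or `"any"` (see [median_filter_round()]).
#' @return object of class `"core_extraction"`: list with `rounds` (data
#'   frame of per-round `nodes`, `edges` and medians), `core_nodes`
#'   (ranked by degree within the final core, ties broken by gene name),
#'   the final `graph`, and logical `exhausted`.
#' @export
extract_core <- function(g, metrics = c("dc", "bc", "cc", "ec"),
                         rounds = 2L, mode = c("all", "any")) {
  mode <- match.arg(mode)
  if (!is.numeric(rounds) || rounds < 1L)
    np_stop("extract_core: rounds must be >= 1")
  metrics <- match.arg(metrics, several.ok = TRUE)
  cur <- g
  log_rows <- list()
  exhausted <- FALSE
  for (r in seq_len(rounds)) {
    nxt <- median_filter_round(cur, metrics = metrics, mode = mode)
    if (length(nxt$nodes) == 0L) { exhausted <- TRUE; break }
    meds <- attr(nxt, "medians")
    log_rows[[r]] <- data.frame(
      round = r, nodes = length(nxt$nodes), edges = nrow(nxt$edges),
      t(meds), stringsAsFactors = FALSE
    )
    cur <- nxt
  }
  round_log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(round = integer(0), nodes = integer(0), edges = integer(0))
  dc <- centrality_degree(cur)
  ord <- order(-as.numeric(dc), names(dc))
  structure(
    list(rounds = round_log,
         core_nodes = names(dc)[ord],
         graph = cur,
         exhausted = exhausted),
    class = "core_extraction"
  )
}

#' @export
print.core_extraction <- function(x, ...) {
  cat("Core-subnetwork extraction\n")
  if (nrow(x$rounds)) {
    for (r in seq_len(nrow(x$rounds)))
      cat(sprintf("  round %d: %d nodes, %d edges\n",
                  x$rounds$round[r], x$rounds$nodes[r], x$rounds$edges[r]))
  }
  if (x$exhausted) cat("  (stopped early: next round would be empty)\n")
  cat(sprintf("  core: %d genes: %s%s\n", length(x$core_nodes),
              paste(utils::head(x$core_nodes, 8L), collapse = ", "),
              if (length(x$core_nodes) > 8L) ", ..." else ""))
  invisible(x)
}

#' Write the centrality table as TSV
#'
#' @param tab value of [centrality_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_centrality_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
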