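# Hypergeometric over-representation analysis against GMT gene-set
# collections, with Benjamini-Hochberg correction and top-N reporting.

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, `term_id TAB description TAB gene ...`.
#' Duplicate genes within a line are de-duplicated.
#'
#' @param path file path.
#' @param category category label attached to every set in the file
#'   (`"BP"`, `"CC"`, `"MF"` or `"pathway"`).
#' @return object of class `"gene_set_collection"`: a list of sets, each a
#'   list with `term_id`, `term_name`, `category` and `members`.
#' @export
read_gmt <- function(path, category = c("pathway", "BP", "CC", "MF")) {
  category <- match.arg(category)
  if (!file.exists(path))
    np_stop("read_gmt: cannot read '%s'", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      np_stop("read_gmt: line %d has %d field(s); expected term, description and at least one gene",
              i, length(fields))
    sets[[i]] <- list(
      term_id = fields[1L],
      term_name = fields[2L],
      category = category,
      members = sort(unique(norm_symbol(fields[-(1:2)])))
    )
  }
  ids <- vapply(sets, `[[`, character(1), "term_id")
  if (anyDuplicated(ids))
    np_stop("read_gmt: duplicate term_id '%s'", ids[duplicated(ids)][1L])
  structure(sets, class = "gene_set_collection")
}

#' Combine gene-set collections
#'
#' @param ... `"gene_set_collection"` objects.
#' @return the concatenated collection.
#' @export
c.gene_set_collection <- function(...) {
  structure(do.call(c, lapply(list(...), unclass)),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cats <- table(vapply(x, `[[`, character(1), "category"))
  cat(sprintf("Gene-set collection: %d terms (%s)\n", length(x),
              paste(sprintf("%s: %d", names(cats), cats), collapse = ", ")))
  invisible(x)
}

#' Write a gene-set collection as GMT
#'
#' @param collection a `"gene_set_collection"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(collection, function(s)
    paste(c(s$term_id, s$term_name, s$members), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of
#' drawing at least `k` annotated genes when `n` genes are drawn without
#' replacement from a universe of `N` genes of which `K` are annotated.
#' Evaluated through the log-space-stable distribution function, exact for
#' small `N`.
#'
#' @param k observed overlap, `0 <= k <= min(K, n)`.
#' @param K annotated (term) genes in the universe.
#' @param n query size.
#' @param N universe size.
#' @return p-value in `(0, 1]`. Vectorized with recycling.
#' @export
hypergeom_tail <- function(k, K, n, N) {
  len <- max(length(k), length(K), length(n), length(N))
  k <- rep_len(as.numeric(k), len); K <- rep_len(as.numeric(K), len)
  n <- rep_len(as.numeric(n), len); N <- rep_len(as.numeric(N), len)
  bad <- k < 0 | K < 0 | n < 0 | N < 1 | K > N | n > N | k > pmin(K, n)
  if (any(bad))
    np_stop("hypergeom_tail: impossible counts (k=%s, K=%s, n=%s, N=%s)",
            k[bad][1], K[bad][1], n[bad][1], N[bad][1])
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Over-representation analysis of a query gene set
#'
#' Tests every term of the collection for enrichment of the query against
#' the universe with the hypergeometric upper tail, adjusting p-values by
#' Benjamini-Hochberg within each category. Terms are intersected with the
#' universe before testing; query genes outside the universe are dropped
#' (with a message). Terms with zero overlap are omitted, matching common
#' ORA-tool behavior.
#'
#' @param query [target_set()] or character vector of query genes.
#' @param collection a `"gene_set_collection"`.
#' @param universe background gene set; defaults to the union of all
#'   collection members (reported by message, since the background choice
#'   materially affects p-values).
#' @return data frame of class `"ora_result"` with columns `term_id`,
#'   `term_name`, `category`, `k`, `K`, `n`, `N`, `p_value`, `p_adjusted`,
#'   sorted by `p_value` ascending with ties broken by `term_id`.
#' @export
run_ora <- function(query, collection, universe = NULL) {
  q <- if (inherits(query, "target_set")) query$genes else
    sort(unique(norm_symbol(query)))
  if (is.null(universe)) {
    universe <- sort(unique(unlist(lapply(collection, `[[`, "members"))))
    message(sprintf(
      "run_ora: universe defaulted to the union of all collection members (%d genes)",
      length(universe)))
  } else {
    universe <- if (inherits(universe, "target_set")) universe$genes else
      sort(unique(norm_symbol(universe)))
  }
  if (!length(universe)) np_stop("run_ora: empty universe")
  dropped <- sum(!q %in% universe)
  if (dropped > 0)
    message(sprintf("run_ora: dropped %d query gene(s) outside the universe",
                    dropped))
  q <- intersect(q, universe)
  n <- length(q); N <- length(universe)
  rows <- lapply(collection, function(s) {
    members <- intersect(s$members, universe)
    k <- length(intersect(q, members))
    if (k == 0L) return(NULL)
    data.frame(term_id = s$term_id, term_name = s$term_name,
               category = s$category, k = k, K = length(members),
               n = n, N = N, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    out <- data.frame(term_id = character(0), term_name = character(0),
                      category = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p_value = numeric(0),
                      p_adjusted = numeric(0), stringsAsFactors = FALSE)
    class(out) <- c("ora_result", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  out$p_value <- hypergeom_tail(out$k, out$K, out$n, out$N)
  out$p_adjusted <- stats::ave(out$p_value, out$category,
                               FUN = function(p) stats::p.adjust(p, "BH"))
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ora_result", "data.frame")
  out
}

#' Keep the significant top-N terms per category
#'
#' Filters to terms at or below `alpha` (on raw p by default, mirroring the
#' common "p <= 0.05" reporting convention; switch `filter_on` to
#' `"p_adjusted"` for FDR filtering), then keeps the first N per category
#' in the existing p-value order.
#'
#' @param records an `"ora_result"` as produced by [run_ora()].
#' @param per_category named integer vector of per-category caps.
#' @param alpha significance threshold (inclusive `<=`).
#' @param filter_on `"p_value"` (default) or `"p_adjusted"`.
#' @return the filtered `"ora_result"`.
#' @export
select_top <- function(records,
                       per_category = c(BP = 10, CC = 10, MF = 10,
                                        pathway = 30),
                       alpha = 0.05,
                       filter_on = c("p_value", "p_adjusted")) {
  filter_on <- match.arg(filter_on)
  sig <- records[records[[filter_on]] <= alpha, , drop = FALSE]
  keep <- unlist(lapply(split(seq_len(nrow(sig)), sig$category),
                        function(idx) {
                          cap <- unname(per_category[sig$category[idx[1L]]])
                          if (is.na(cap)) cap <- Inf
                          utils::head(idx, cap)
                        }))
  out <- sig[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ora_result", "data.frame")
  out
}
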