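# Compound-table parsing, peak-area and ADMET screening, molecular weight.

# IUPAC standard *average* atomic masses, 4 decimals. Average (not
# monoisotopic) masses are used because integer-rounded table MWs in
# GC-MS compound listings match average masses.
ATOMIC_MASS <- c(
  H = 1.008, C = 12.0110, N = 14.0070, O = 15.9990, F = 18.9984,
  Na = 22.9898, Mg = 24.3050, Si = 28.0850, P = 30.9738, S = 32.0600,
  Cl = 35.4500, K = 39.0983, Ca = 40.0780, Br = 79.9040, I = 126.9045
)

#' Molecular weight from an elemental formula
#'
#' Computes the average molecular weight (unified atomic mass units) of a
#' Hill-style molecular formula such as `"C10H16O"`. Element symbols are an
#' uppercase letter optionally followed by one lowercase letter, each
#' optionally followed by an integer count (default 1). The built-in mass
#' table covers C, H, N, O, S, P, F, Cl, Br, I and a few common metals.
#'
#' @param formula character vector of molecular formulas.
#' @return numeric vector of molecular weights in u.
#' @examples
#' molecular_weight("C9H10O")   # 134.18
#' molecular_weight("H2")       # 2.016
#' @export
molecular_weight <- function(formula) {
  vapply(as.character(formula), mw_one, numeric(1), USE.NAMES = FALSE)
}

mw_one <- function(f) {
  if (is.na(f) || !nzchar(trimws(f)))
    np_stop("molecular_weight: empty formula")
  f <- trimws(f)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f, perl = TRUE)[[1]]
  toks <- regmatches(f, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(f))
    np_stop("molecular_weight: cannot parse formula '%s'", f)
  total <- 0
  for (tok in toks) {
    el <- sub("[0-9]*$", "", tok)
    cnt_str <- sub("^[A-Za-z]+", "", tok)
    cnt <- if (nzchar(cnt_str)) as.integer(cnt_str) else 1L
    if (!el %in% names(ATOMIC_MASS))
      np_stop("molecular_weight: unknown element '%s' in formula '%s'", el, f)
    if (cnt == 0L)
      np_stop("molecular_weight: zero count for element '%s' in formula '%s'",
              el, f)
    total <- total + ATOMIC_MASS[[el]] * cnt
  }
  total
}

#' Compound screening rules
#'
#' Bundles the chromatographic and pharmacokinetic screening thresholds.
#' The default rule set keeps peaks with area strictly greater than 0.12%,
#' requires high GI absorption, rejects P-gp substrates and drug-likeness
#' failures, tolerates up to one drug-likeness violation, and does not
#' constrain BBB permeation (published compound tables routinely retain
#' BBB-negative compounds despite a stated BBB screen). The
#' `"strict_swissadme"` preset additionally requires BBB = Yes and allows
#' unlimited violations as long as drug-likeness passes.
#'
#' @param min_peak_area_pct minimum chromatographic peak area, percent;
#'   filtering is strict (`>`).
#' @param gi_absorption required GI absorption level, `"High"`, `"Low"` or
#'   `"any"`.
#' @param bbb required blood-brain-barrier flag, `"Yes"`, `"No"` or `"any"`.
#' @param pgp_substrate required P-glycoprotein substrate flag, `"Yes"`,
#'   `"No"` or `"any"`.
#' @param dl_pass if `TRUE`, require the drug-likeness assessment to pass.
#' @param max_dl_violations maximum tolerated drug-likeness violations
#'   (`Inf` for unbounded).
#' @param preset optional named preset, currently `"strict_swissadme"`.
#' @return an object of class `"screen_rules"`.
#' @examples
#' screen_rules()
#' screen_rules(preset = "strict_swissadme")
#' @export
screen_rules <- function(min_peak_area_pct = 0.12,
                         gi_absorption = "High",
                         bbb = "any",
                         pgp_substrate = "No",
                         dl_pass = TRUE,
                         max_dl_violations = 1,
                         preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, "strict_swissadme")
    if (missing(bbb)) bbb <- "Yes"
    if (missing(max_dl_violations)) max_dl_violations <- Inf
  }
  if (!is.numeric(min_peak_area_pct) || min_peak_area_pct < 0)
    np_stop("screen_rules: min_peak_area_pct must be >= 0")
  gi_absorption <- match.arg(gi_absorption, c("High", "Low", "any"))
  bbb <- match.arg(bbb, c("Yes", "No", "any"))
  pgp_substrate <- match.arg(pgp_substrate, c("Yes", "No", "any"))
  stopifnot(is.logical(dl_pass), length(dl_pass) == 1L)
  if (!is.numeric(max_dl_violations) || max_dl_violations < 0)
    np_stop("screen_rules: max_dl_violations must be >= 0 or Inf")
  structure(
    list(min_peak_area_pct = min_peak_area_pct,
         gi_absorption = gi_absorption, bbb = bbb,
         pgp_substrate = pgp_substrate, dl_pass = dl_pass,
         max_dl_violations = max_dl_violations),
    class = "screen_rules"
  )
}

#' @export
print.screen_rules <- function(x, ...) {
  cat("Compound screening rules:\n")
  cat(sprintf("  peak area        > %g %%\n", x$min_peak_area_pct))
  cat(sprintf("  GI absorption    : %s\n", x$gi_absorption))
  cat(sprintf("  BBB              : %s\n", x$bbb))
  cat(sprintf("  P-gp substrate   : %s\n", x$pgp_substrate))
  cat(sprintf("  drug-likeness    : %s (max violations %s)\n",
              if (x$dl_pass) "must pass" else "any", x$max_dl_violations))
  invisible(x)
}

# Column mappings for the supported table dialects.
.table1_map <- c(
  "Time" = "retention_time", "CID No" = "cid", "Name" = "name",
  "Formula" = "formula", "Canonical SMILES" = "smiles", "MW" = "mw_printed",
  "Drug likeness (DL)" = "drug_likeness", "GI absorption (OB)" = "gi_absorption",
  "P-gp substrate" = "pgp_substrate", "BBB" = "bbb"
)

#' Parse a compound table
#'
#' Reads a delimited compound table into a validated data frame with one
#' row per compound, carrying the elemental formula, opaque SMILES text,
#' optional retention time / peak area, and the ADMET profile (GI
#' absorption, BBB, P-gp substrate, drug-likeness). The molecular weight is
#' derived from the formula; a printed MW column, when present, is kept as
#' `mw_printed` for cross-checking.
#'
#' @param path path to a delimited text file with a header row.
#' @param dialect `"canonical"` expects lowercase column names
#'   (`name, formula, smiles, cid, retention_time, peak_area_pct,
#'   gi_absorption, bbb, pgp_substrate, drug_likeness`); `"table1"` maps the
#'   headers used by published GC-MS/SwissADME compound listings.
#' @param sep field separator, tab by default.
#' @param col_map optional named character vector mapping file headers to
#'   canonical names, overriding the dialect.
#' @return a `data.frame` of class `"compound_table"` with columns `name`,
#'   `formula`, `smiles`, `cid`, `retention_time`, `peak_area_pct`, `mw`,
#'   `mw_printed`, `gi_absorption`, `bbb`, `pgp_substrate`, `dl_pass`,
#'   `dl_violations`.
#' @export
parse_compound_table <- function(path, dialect = c("canonical", "table1"),
                                 sep = "\t", col_map = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    np_stop("parse_compound_table: cannot read '%s'", path)
  raw <- utils::read.delim(path, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  map <- col_map %||% if (dialect == "table1") .table1_map else
    stats::setNames(colnames(raw), colnames(raw))
  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (src in names(map)) {
    if (src %in% colnames(raw)) out[[map[[src]]]] <- raw[[src]]
  }
  need <- c("name", "formula")
  miss <- setdiff(need, colnames(out))
  if (length(miss))
    np_stop("parse_compound_table: missing required column(s): %s",
            paste(miss, collapse = ", "))
  for (opt in c("smiles", "cid", "retention_time", "peak_area_pct",
                "mw_printed"))
    if (is.null(out[[opt]])) out[[opt]] <- NA
  out$retention_time <- suppressWarnings(as.numeric(out$retention_time))
  out$peak_area_pct <- suppressWarnings(as.numeric(out$peak_area_pct))
  out$mw_printed <- suppressWarnings(as.numeric(out$mw_printed))

  # drug-likeness: either a combined "Yes; 1 violation" column or separate
  # dl_pass / dl_violations columns
  if (!is.null(out$drug_likeness)) {
    dl <- parse_drug_likeness(out$drug_likeness)
    out$dl_pass <- dl$pass
    out$dl_violations <- dl$violations
    out$drug_likeness <- NULL
  }
  if (is.null(out$dl_pass)) out$dl_pass <- NA
  if (is.null(out$dl_violations)) out$dl_violations <- NA_integer_

  # row-level validation
  out$mw <- NA_real_
  for (i in seq_len(nrow(out))) {
    mw_i <- tryCatch(molecular_weight(out$formula[i]), error = function(e) e)
    if (inherits(mw_i, "error"))
      np_stop("parse_compound_table: row %d, column 'formula': %s",
              i, conditionMessage(mw_i))
    out$mw[i] <- mw_i
    check_enum(out$gi_absorption[i], c("High", "Low"), i, "gi_absorption")
    check_enum(out$bbb[i], c("Yes", "No"), i, "bbb")
    check_enum(out$pgp_substrate[i], c("Yes", "No"), i, "pgp_substrate")
    if (!is.na(out$peak_area_pct[i]) &&
        (!is.finite(out$peak_area_pct[i]) || out$peak_area_pct[i] < 0))
      np_stop("parse_compound_table: row %d, column 'peak_area_pct': must be finite and >= 0", i)
  }
  cols <- c("name", "formula", "smiles", "cid", "retention_time",
            "peak_area_pct", "mw", "mw_printed", "gi_absorption", "bbb",
            "pgp_substrate", "dl_pass", "dl_violations")
  out <- out[, intersect(cols, colnames(out))]
  class(out) <- c("compound_table", "data.frame")
  out
}

parse_drug_likeness <- function(x) {
  x <- as.character(x)
  pass <- grepl("^\\s*yes", x, ignore.case = TRUE)
  viol <- suppressWarnings(as.integer(sub(".*?(\\d+)\\s*violation.*", "\\1", x)))
  viol[is.na(viol)] <- 0L
  list(pass = pass, violations = viol)
}

check_enum <- function(val, allowed, row, col) {
  if (is.null(val) || is.na(val)) return(invisible(NULL))
  if (!val %in% allowed)
    np_stop("parse_compound_table: row %d, column '%s': invalid value '%s' (allowed: %s)",
            row, col, val, paste(allowed, collapse = ", "))
  invisible(NULL)
}

#' Filter compounds by chromatographic peak area
#'
#' Keeps compounds whose peak area is strictly greater than the rule
#' threshold (default 0.12%), preserving input order.
#'
#' @param compounds a `compound_table` (or data frame with a
#'   `peak_area_pct` column).
#' @param rules a [screen_rules()] object.
#' @return the retained subset, same class and column layout.
#' @export
filter_peaks <- function(compounds, rules = screen_rules()) {
  stopifnot(inherits(rules, "screen_rules"))
  area <- compounds$peak_area_pct
  if (is.null(area) || anyNA(area))
    np_stop("filter_peaks: every record needs a peak_area_pct value")
  compounds[area > rules$min_peak_area_pct, , drop = FALSE]
}

#' Apply pharmacokinetic (ADMET) screening rules
#'
#' Retains compounds satisfying every active rule: GI absorption, BBB
#' permeation, P-gp substrate status, drug-likeness pass flag and violation
#' count. Rules set to `"any"` are inactive. Each rejected compound is
#' logged with the *first* failed rule (checked in the order GI, BBB, P-gp,
#' drug-likeness pass, violation count); retrieve the log with
#' [admet_rejections()].
#'
#' @param compounds a `compound_table` with complete ADMET columns.
#' @param rules a [screen_rules()] object.
#' @return the retained subset (order preserved) with the rejection log in
#'   attribute `"rejections"`.
#' @export
admet_filter <- function(compounds, rules = screen_rules()) {
  stopifnot(inherits(rules, "screen_rules"))
  need <- c("gi_absorption", "bbb", "pgp_substrate", "dl_pass",
            "dl_violations")
  for (col in need)
    if (is.null(compounds[[col]]) || anyNA(compounds[[col]]))
      np_stop("admet_filter: column '%s' must be present and complete", col)
  failed <- character(nrow(compounds))
  for (i in seq_len(nrow(compounds))) {
    failed[i] <-
      if (rules$gi_absorption != "any" &&
          compounds$gi_absorption[i] != rules$gi_absorption) "gi_absorption"
      else if (rules$bbb != "any" && compounds$bbb[i] != rules$bbb) "bbb"
      else if (rules$pgp_substrate != "any" &&
               compounds$pgp_substrate[i] != rules$pgp_substrate) "pgp_substrate"
      else if (rules$dl_pass && !compounds$dl_pass[i]) "dl_pass"
      else if (compounds$dl_violations[i] > rules$max_dl_violations) "dl_violations"
      else ""
  }
  keep <- !nzchar(failed)
  out <- compounds[keep, , drop = FALSE]
  attr(out, "rejections") <- data.frame(
    name = compounds$name[!keep],
    failed_rule = failed[!keep],
    stringsAsFactors = FALSE
  )
  out
}

#' Rejection log of an ADMET screen
#'
#' @param x the value returned by [admet_filter()].
#' @return data frame with columns `name` and `failed_rule`.
#' @export
admet_rejections <- function(x) {
  attr(x, "rejections") %||%
    data.frame(name = character(0), failed_rule = character(0))
}

#' Write a compound table and rejection log
#'
#' @param compounds a `compound_table`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_compound_table <- function(compounds, path) {
  utils::write.table(as.data.frame(compounds), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
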