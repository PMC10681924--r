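# Bioassay arithmetic: viability normalization, 4PL dose-response IC50
# fitting, and flow-cytometry quadrant summaries.

#' Cell viability from optical densities
#'
#' Normalizes a treated-well OD against blank and untreated-control wells:
#' `viability = (OD_treated - OD_blank) / (OD_control - OD_blank) * 100`.
#' Values may exceed 100% or fall below 0% under noise; no clamping is
#' applied.
#'
#' @param od_treated,od_blank,od_control optical densities (finite,
#'   `>= 0`); vectorized with recycling.
#' @return viability percent.
#' @examples
#' viability_pct(0.5, 0.1, 0.9)  # 50
#' @export
viability_pct <- function(od_treated, od_blank, od_control) {
  len <- max(length(od_treated), length(od_blank), length(od_control))
  t <- rep_len(as.numeric(od_treated), len)
  b <- rep_len(as.numeric(od_blank), len)
  c0 <- rep_len(as.numeric(od_control), len)
  if (any(!is.finite(t) | !is.finite(b) | !is.finite(c0)) ||
      any(t < 0 | b < 0 | c0 < 0))
    np_stop("viability_pct: ODs must be finite and >= 0")
  if (any(c0 == b))
    np_stop("viability_pct: od_control equals od_blank (division by zero)")
  (t - b) / (c0 - b) * 100
}

#' Read a viability plate table
#'
#' Expects a TSV with header `type, dose, od_1, ..., od_r`: one `blank`
#' row, one `control` row (dose empty/NA) and one `treated` row per dose.
#'
#' @param path file path.
#' @return data frame with columns `type`, `dose` and the replicate OD
#'   columns.
#' @export
read_plate <- function(path) {
  if (!file.exists(path)) np_stop("read_plate: cannot read '%s'", path)
  plate <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("type", "dose") %in% colnames(plate)))
    np_stop("read_plate: plate file needs 'type' and 'dose' columns")
  if (!any(plate$type == "blank") || !any(plate$type == "control"))
    np_stop("read_plate: plate file needs 'blank' and 'control' rows")
  plate
}

#' Per-dose viability from a plate table
#'
#' Averages replicate ODs (blank and control wells too) before applying
#' [viability_pct()].
#'
#' @param plate data frame as returned by [read_plate()].
#' @return data frame with columns `dose` and `viability_pct`, dose
#'   ascending.
#' @export
plate_viability <- function(plate) {
  od_cols <- grep("^od", colnames(plate), value = TRUE)
  if (!length(od_cols)) np_stop("plate_viability: no od_* columns")
  mean_od <- rowMeans(plate[, od_cols, drop = FALSE])
  blank <- mean(mean_od[plate$type == "blank"])
  control <- mean(mean_od[plate$type == "control"])
  trt <- plate$type == "treated"
  out <- data.frame(
    dose = as.numeric(plate$dose[trt]),
    viability_pct = viability_pct(mean_od[trt], blank, control)
  )
  out[order(out$dose), , drop = FALSE]
}

# 4PL on log-dose: v(d) = lower + (upper - lower) / (1 + exp(hill * (log(d) - log(ic50))))
# hill > 0 gives a decreasing curve from `upper` to `lower`; ic50 is the
# inflection dose (relative IC50).
fourpl <- function(dose, lower, upper, hill, ic50) {
  lower + (upper - lower) / (1 + exp(hill * (log(dose) - log(ic50))))
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares 4PL fit on log-dose, estimating lower and upper
#' asymptotes, Hill slope and IC50. Replicate viability values at the same
#' dose are averaged before fitting. By default the IC50 is the curve's
#' inflection dose (midpoint between the fitted asymptotes, the *relative*
#' IC50); `variant = "absolute"` instead solves for the dose where the
#' fitted curve crosses 50% viability.
#'
#' The fit is deterministic: starting values are derived from the data and
#' refined by Levenberg-Marquardt least squares. A fitted IC50 outside
#' `[min(dose)/10, max(dose)*10]` or a non-positive Hill slope (e.g. from
#' monotone increasing viability) is flagged `out_of_range` with a warning.
#'
#' @param dose concentrations (e.g. ug/mL), strictly positive; at least 4
#'   distinct levels.
#' @param viability viability percent, same length as `dose`.
#' @param variant `"relative"` (inflection dose, default) or
#'   `"absolute"` (50%-crossing dose).
#' @return object of class `"ic50_fit"` with coefficients `lower`,
#'   `upper`, `hill`, `ic50`; methods: `print`, `summary`, `coef`,
#'   `predict`, `fitted`, `residuals`, `plot`.
#' @examples
#' d <- c(50, 100, 200, 400, 600, 800, 1000)
#' v <- 100 / (1 + (d / 500)^2)
#' fit <- fit_ic50(d, v)
#' coef(fit)["ic50"]
#' @export
fit_ic50 <- function(dose, viability, variant = c("relative", "absolute")) {
  variant <- match.arg(variant)
  dose <- as.numeric(dose); viability <- as.numeric(viability)
  if (length(dose) != length(viability))
    np_stop("fit_ic50: dose and viability lengths differ")
  if (any(!is.finite(dose) | dose <= 0))
    np_stop("fit_ic50: doses must be strictly positive")
  # average replicates per dose
  agg <- tapply(viability, dose, mean)
  d <- as.numeric(names(agg)); v <- as.numeric(agg)
  o <- order(d); d <- d[o]; v <- v[o]
  if (length(d) < 4L)
    np_stop("fit_ic50: at least 4 distinct dose levels required for a 4-parameter fit")

  upper0 <- max(v); lower0 <- min(v)
  mid <- (upper0 + lower0) / 2
  lic0 <- log(d[which.min(abs(v - mid))])
  start <- c(lower = lower0, upper = upper0, hill = 1, lic = lic0)
  resid_fn <- function(p)
    v - (p[["lower"]] + (p[["upper"]] - p[["lower"]]) /
           (1 + exp(p[["hill"]] * (log(d) - p[["lic"]]))))
  fit <- minpack.lm::nls.lm(
    par = start, fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15))
  if (!fit$info %in% 1:4)
    np_stop("fit_ic50: 4PL fit failed to converge after %d iterations (%s); residual SD %g",
            fit$niter, fit$message, stats::sd(resid_fn(fit$par)))
  cf <- fit$par
  ic50 <- unname(exp(cf[["lic"]]))
  if (variant == "absolute") {
    # dose where fitted curve crosses 50
    ratio <- (cf[["upper"]] - cf[["lower"]]) / (50 - cf[["lower"]]) - 1
    if (!is.finite(ratio) || ratio <= 0)
      np_stop("fit_ic50: fitted curve never crosses 50%% viability; absolute IC50 undefined")
    ic50 <- unname(exp(cf[["lic"]] + log(ratio) / cf[["hill"]]))
  }
  # an increasing dose-response shows up either as hill <= 0 or as
  # swapped asymptotes (upper fitted below lower)
  out_of_range <- cf[["hill"]] <= 0 || cf[["upper"]] <= cf[["lower"]] ||
    ic50 < min(d) / 10 || ic50 > max(d) * 10
  if (out_of_range)
    warning("fit_ic50: IC50 out of the credible dose range (flagged); check that viability decreases with dose",
            call. = FALSE)
  structure(
    list(coefficients = c(lower = unname(cf[["lower"]]),
                          upper = unname(cf[["upper"]]),
                          hill = unname(cf[["hill"]]),
                          ic50 = ic50),
         variant = variant,
         dose = d, viability = v,
         fitted = fourpl(d, cf[["lower"]], cf[["upper"]], cf[["hill"]],
                         exp(cf[["lic"]])),
         lic = cf[["lic"]],
         optim = fit,
         out_of_range = out_of_range),
    class = "ic50_fit"
  )
}

#' @export
print.ic50_fit <- function(x, ...) {
  cat("Four-parameter logistic dose-response fit\n")
  cat(sprintf("  IC50 (%s): %.4g\n", x$variant, x$coefficients[["ic50"]]))
  cat(sprintf("  asymptotes: lower %.4g, upper %.4g; Hill slope %.4g\n",
              x$coefficients[["lower"]], x$coefficients[["upper"]],
              x$coefficients[["hill"]]))
  if (x$out_of_range) cat("  WARNING: IC50 flagged out of range\n")
  invisible(x)
}

#' @export
coef.ic50_fit <- function(object, ...) object$coefficients

#' @export
fitted.ic50_fit <- function(object, ...) object$fitted

#' @export
residuals.ic50_fit <- function(object, ...) object$viability - object$fitted

#' @export
summary.ic50_fit <- function(object, ...) {
  rss <- sum(residuals(object)^2)
  df <- length(object$dose) - 4L
  out <- list(coefficients = object$coefficients,
              residual_se = sqrt(rss / max(df, 1L)),
              n_doses = length(object$dose),
              variant = object$variant,
              out_of_range = object$out_of_range)
  class(out) <- "summary.ic50_fit"
  out
}

#' @export
print.summary.ic50_fit <- function(x, ...) {
  cat("4PL dose-response summary\n")
  print(round(x$coefficients, 4))
  cat(sprintf("residual SE: %.4g over %d dose levels\n", x$residual_se,
              x$n_doses))
  invisible(x)
}

#' @export
predict.ic50_fit <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object$dose else
    if (is.data.frame(newdata)) newdata$dose else as.numeric(newdata)
  cf <- object$coefficients
  fourpl(d, cf[["lower"]], cf[["upper"]], cf[["hill"]], exp(object$lic))
}

#' @export
plot.ic50_fit <- function(x, ...) {
  graphics::plot(x$dose, x$viability, log = "x",
                 xlab = "dose", ylab = "viability (%)",
                 main = "Dose-response (4PL fit)", pch = 19, ...)
  dd <- exp(seq(log(min(x$dose)), log(max(x$dose)), length.out = 200))
  graphics::lines(dd, predict(x, dd))
  graphics::abline(v = x$coefficients[["ic50"]], lty = 2)
  invisible(x)
}

#' Flow-cytometry quadrant rates
#'
#' Converts annexin/PI quadrant event counts into percentages. The total
#' apoptosis rate is `(early + late) / total * 100`.
#'
#' @param viable,early_apoptotic,late_apoptotic,necrotic event counts
#'   (`>= 0`, total `> 0`).
#' @return named numeric vector of the four percentages plus
#'   `total_apoptosis`; the four quadrant percentages sum to 100.
#' @examples
#' quadrant_rates(600, 150, 200, 50)["total_apoptosis"]  # 35
#' @export
quadrant_rates <- function(viable, early_apoptotic, late_apoptotic,
                           necrotic) {
  counts <- c(viable = viable, early_apoptotic = early_apoptotic,
              late_apoptotic = late_apoptotic, necrotic = necrotic)
  if (any(!is.finite(counts) | counts < 0))
    np_stop("quadrant_rates: counts must be finite and >= 0")
  total <- sum(counts)
  if (total <= 0) np_stop("quadrant_rates: total event count must be > 0")
  pct <- counts / total * 100
  c(pct, total_apoptosis = unname(pct[["early_apoptotic"]] +
                                    pct[["late_apoptotic"]]))
}

#' Total apoptosis rate from quadrant counts
#'
#' @inheritParams quadrant_rates
#' @return percent of events in the early + late apoptotic quadrants.
#' @examples
#' apoptosis_rate(600, 150, 200, 50)  # 35
#' @export
apoptosis_rate <- function(viable, early_apoptotic, late_apoptotic,
                           necrotic) {
  unname(quadrant_rates(viable, early_apoptotic, late_apoptotic,
                        necrotic)[["total_apoptosis"]])
}
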