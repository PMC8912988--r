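#' @include growth.R peaks.R
NULL

#' The six simulated-freshwater conditions
#'
#' The condition matrix crossing nutrient level with dissolved organic
#' carbon (DOC, supplied as glucose): low nutrient = 0.3 mg/L nitrate and
#' no added phosphate; high nutrient = 50 mg/L nitrate and 0.1 mg/L
#' phosphate; DOC at 0 (none), 5 (limited) or 800 (excess) mg/L.
#'
#' @return A data.frame with columns \code{label}, \code{nitrate_mg_per_l},
#'   \code{phosphate_mg_per_l}, \code{doc_mg_per_l}, \code{description},
#'   ordered SFW0 to SFW5.
#' @export
sfwConditions <- function() {
  data.frame(
    label = paste0("SFW", 0:5),
    nitrate_mg_per_l   = c(0.3, 50, 0.3, 50, 0.3, 50),
    phosphate_mg_per_l = c(0, 0.1, 0, 0.1, 0, 0.1),
    doc_mg_per_l       = c(0, 0, 5, 5, 800, 800),
    description = c("Low nutrient, no DOC",  "High nutrient, no DOC",
                    "Low nutrient, limited DOC", "High nutrient, limited DOC",
                    "Low nutrient, excess DOC",  "High nutrient, excess DOC"),
    stringsAsFactors = FALSE
  )
}

# nearest integer, ties away from zero ("half-up" for positives)
.roundHalfUp <- function(x) floor(x + 0.5)

#' Per-peak share of total per-cell fluorescence
#'
#' Given the enumeration-corrected fluorescence of Peaks T, C and C+ (QSU
#' per 10^6 CFU), computes their sum \code{f_total} and each peak's integer
#' percent share (nearest integer, ties half-up).
#'
#' @param fT,fC,fCplus per-cell fluorescence of Peaks T, C, C+ (>= 0, not
#'   all zero).
#' @return A \code{\linkS4class{FractionTable}}.
#' @examples
#' ft <- peakFractionTable(391.8, 346.5, 237.0)
#' fTotal(ft)            # 975.3
#' fractionPercent(ft)   # 40, 36, 24
#' @export
peakFractionTable <- function(fT, fC, fCplus) {
  f <- c("T" = unname(fT), "C" = unname(fC), "C+" = unname(fCplus))
  if (any(f < 0)) stop("per-cell fluorescence values must be >= 0")
  if (all(f == 0))
    stop("all three peaks are zero: fraction shares undefined")
  total <- sum(f)
  new("FractionTable", f = f, percent = .roundHalfUp(100 * f / total),
      fTotal = total)
}

#' @describeIn peakFractionTable integer percent shares
#' @param x a \code{FractionTable}
#' @export
setMethod("fractionPercent", "FractionTable", function(x) x@percent)

#' @describeIn peakFractionTable per-peak f values (QSU per 10^6 CFU)
#' @export
setMethod("fractionF", "FractionTable", function(x) x@f)

#' @describeIn peakFractionTable total per-cell fluorescence
#' @export
setMethod("fTotal", "FractionTable", function(x) x@fTotal)

setMethod("show", "FractionTable", function(object) {
  cat("FractionTable (QSU per 10^6 CFU):\n")
  for (p in names(object@f))
    cat(sprintf("  %-3s f = %8.1f  (%d%%)\n", p, object@f[p],
                as.integer(object@percent[p])))
  cat(sprintf("  f_total = %.1f\n", object@fTotal))
  invisible(NULL)
})

#' @export
as.data.frame.FractionTable <- function(x, ...) {
  data.frame(peak = names(x@f), f = unname(x@f),
             percent = unname(x@percent), f_total = x@fTotal,
             row.names = NULL)
}

#' Replicate mean and spread at an endpoint time
#'
#' Per peak: mean and sample standard deviation (n - 1 denominator) of the
#' replicate intensities at one sampling time, the shape of an endpoint
#' intensity table.
#'
#' @param seriesList list of at least two replicate
#'   \code{\linkS4class{PeakSeries}} objects sharing peak labels.
#' @param timeH the endpoint time (h); must be present in every replicate.
#' @return A data.frame with columns \code{peak}, \code{mean}, \code{sd},
#'   \code{n}.
#' @export
endpointTable <- function(seriesList, timeH) {
  if (length(seriesList) < 2L)
    stop("endpoint statistics need at least 2 replicates")
  rows <- lapply(seriesList, function(s) {
    i <- which(abs(s@timesH - timeH) < 1e-9)
    if (!length(i))
      stop(sprintf("replicate '%s' (%s) has no sample at %g h",
                   s@replicate, s@condition, timeH))
    s@values[i, , drop = TRUE]
  })
  labels <- colnames(seriesList[[1]]@values)
  m <- do.call(rbind, rows)
  data.frame(peak = labels,
             mean = colMeans(m),
             sd = apply(m, 2, stats::sd),
             n = nrow(m), row.names = NULL)
}

# condition-level f curve: replicate mean of f at each (peak, time)
.conditionFCurve <- function(pcs, peak) {
  rows <- do.call(rbind, lapply(pcs, function(pc)
    pc[pc$peak == peak, c("time_h", "f")]))
  if (is.null(rows) || !nrow(rows))
    stop(sprintf("no per-cell values for peak %s", peak))
  agg <- stats::aggregate(f ~ time_h, data = rows, FUN = mean)
  agg[order(agg$time_h), ]
}

.conditionF <- function(pcs, peak, mode, timeH) {
  curve <- .conditionFCurve(pcs, peak)
  if (mode == "max") return(max(curve$f))
  i <- which(abs(curve$time_h - timeH) < 1e-9)
  if (!length(i))
    stop(sprintf("no per-cell value for peak %s at %g h", peak, timeH))
  curve$f[i]
}

#' Assemble per-condition summary tables
#'
#' For each condition: the endpoint intensity table (replicate mean and SD
#' at \code{endpointTimeH}), the per-cell fraction table, and the long-form
#' peak / growth series.  The f value entering the fraction table is each
#' peak's per-condition maximum: replicate f values are averaged at every
#' sampling time and the maximum of that mean curve is taken (\code{mode =
#' "max"}, the default), or its endpoint-time value is used (\code{mode =
#' "endpoint"}).  Conditions are processed in the fixed order SFW0 to SFW5.
#'
#' @param data named list, one entry per condition label, each a list with
#'   elements \code{series} (list of \code{\linkS4class{PeakSeries}}
#'   replicates) and \code{growth} (list of matching
#'   \code{\linkS4class{GrowthCurve}} replicates, same order).
#' @param conditions condition metadata (default \code{\link{sfwConditions}}
#'   restricted to the labels present in \code{data}); labels absent from
#'   the standard mapping are an error.
#' @param mode how f enters the fraction table: \code{"max"} or
#'   \code{"endpoint"}.
#' @param endpointTimeH endpoint time for the intensity table (default 48).
#' @param outDir optional directory; when given, writes
#'   \code{endpoint_table.tsv}, \code{fraction_table.tsv} and per-condition
#'   \code{series_<label>.tsv} files (tab-delimited, full precision except
#'   the integer percent column).
#' @return A list with elements \code{endpoint} (data.frame),
#'   \code{fractions} (data.frame), \code{perCell} (long data.frame) and
#'   \code{conditions}.
#' @export
conditionReport <- function(data, conditions = NULL,
                            mode = c("max", "endpoint"),
                            endpointTimeH = 48, outDir = NULL) {
  mode <- match.arg(mode)
  std <- sfwConditions()
  if (is.null(conditions)) {
    conditions <- std[std$label %in% names(data), , drop = FALSE]
    unknown <- setdiff(names(data), std$label)
  } else unknown <- setdiff(conditions$label, std$label)
  if (length(unknown))
    stop("condition label(s) not in the SFW mapping: ",
         paste(unknown, collapse = ", "))
  conditions <- conditions[order(conditions$label), , drop = FALSE]
  missing <- setdiff(conditions$label, names(data))
  if (length(missing))
    stop("no data supplied for condition(s): ",
         paste(missing, collapse = ", "))

  endpoints <- list(); fracs <- list(); percell <- list()
  for (lab in conditions$label) {
    d <- data[[lab]]
    if (is.null(d$series) || !length(d$series))
      stop(sprintf("condition %s has no fluorescence series", lab))
    if (is.null(d$growth) || !length(d$growth))
      stop(sprintf("condition %s has no growth data", lab))
    if (length(d$series) != length(d$growth))
      stop(sprintf("condition %s: %d series but %d growth curves", lab,
                   length(d$series), length(d$growth)))
    ep <- endpointTable(d$series, endpointTimeH)
    ep$condition <- lab
    endpoints[[lab]] <- ep
    pcs <- Map(perCellSeries, d$series, d$growth)
    percell[[lab]] <- do.call(rbind, pcs)
    fBar <- vapply(c("T", "C", "C+"), function(p)
      .conditionF(pcs, p, mode, endpointTimeH), 0)
    ft <- peakFractionTable(fBar["T"], fBar["C"], fBar["C+"])
    fd <- as.data.frame(ft)
    fd$condition <- lab
    fracs[[lab]] <- fd
  }
  out <- list(
    endpoint = do.call(rbind, c(endpoints, list(make.row.names = FALSE))),
    fractions = do.call(rbind, c(fracs, list(make.row.names = FALSE))),
    perCell = do.call(rbind, c(percell, list(make.row.names = FALSE))),
    conditions = conditions
  )
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(out$endpoint, file.path(outDir, "endpoint_table.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(out$fractions, file.path(outDir, "fraction_table.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    for (lab in conditions$label)
      utils::write.table(percell[[lab]],
                         file.path(outDir, sprintf("series_%s.tsv", lab)),
                         sep = "\t", row.names = FALSE, quote = FALSE)
  }
  out
}
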