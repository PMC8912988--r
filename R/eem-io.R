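#' @include eem-model.R
NULL

# The on-disk EEM dialect ("axes-in-headers"): delimited text, first row =
# excitation wavelengths (leading corner cell empty), first column =
# emission wavelengths, body = intensities.  Masked cells serialize as the
# sentinel "NA".  Comma or tab delimiter, auto-detected from the header.

.MASK_SENTINEL <- "NA"

.sniffDelim <- function(line) {
  nTab <- lengths(regmatches(line, gregexpr("\t", line, fixed = TRUE)))
  nCom <- lengths(regmatches(line, gregexpr(",", line, fixed = TRUE)))
  if (nTab >= nCom && nTab > 0) "\t" else ","
}

.parseNumeric <- function(tokens, where) {
  suppressWarnings(v <- as.numeric(tokens))
  bad <- which(is.na(v) & tokens != .MASK_SENTINEL)
  if (length(bad))
    stop(sprintf("non-numeric value '%s' at %s, column %d",
                 tokens[bad[1]], where, bad[1]))
  v
}

#' Read an EEM from delimited text
#'
#' Reads the axes-in-headers dialect: excitation wavelengths across the
#' header row, emission wavelengths down the first column, intensities in
#' the body.  Cells equal to \code{"NA"} are restored as masked.  The
#' delimiter (comma or tab) is sniffed from the header row.
#'
#' @param path file to read.
#' @param unit unit tag to attach (\code{"raw"} default, or \code{"QSU"}).
#' @param meta optional metadata list.
#' @return An \code{\linkS4class{EEMatrix}}.
#' @seealso \code{\link{writeEEM}}
#' @export
readEEM <- function(path, unit = "raw", meta = list()) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop(sprintf("'%s': need a header row and at least one data row", path))
  delim <- .sniffDelim(lines[1])
  rows <- strsplit(lines, delim, fixed = TRUE)
  width <- length(rows[[1]])
  ragged <- which(lengths(rows) != width)
  if (length(ragged))
    stop(sprintf("'%s': ragged row %d (%d fields, expected %d)",
                 path, ragged[1], lengths(rows)[ragged[1]], width))
  header <- trimws(rows[[1]])
  ex <- .parseNumeric(header[-1], "header row")
  if (anyNA(ex) || is.unsorted(ex, strictly = TRUE))
    stop(sprintf("'%s': excitation header is not strictly increasing", path))
  body <- rows[-1]
  em <- numeric(length(body))
  grid <- matrix(NA_real_, length(body), length(ex))
  mask <- matrix(FALSE, length(body), length(ex))
  for (i in seq_along(body)) {
    tok <- trimws(body[[i]])
    v <- .parseNumeric(tok, sprintf("row %d", i + 1L))
    if (is.na(v[1]))
      stop(sprintf("'%s': missing emission wavelength at row %d", path, i + 1L))
    em[i] <- v[1]
    grid[i, ] <- v[-1]
    mask[i, ] <- tok[-1] == .MASK_SENTINEL
  }
  if (is.unsorted(em, strictly = TRUE))
    stop(sprintf("'%s': emission column is not strictly increasing", path))
  grid[mask] <- 0
  EEMatrix(grid, excitation = ex, emission = em, unit = unit, mask = mask,
           meta = meta)
}

.fmtNum <- function(x) formatC(x, digits = 12, format = "g")

#' Write an EEM as delimited text
#'
#' Inverse of \code{\link{readEEM}}; numbers carry 12 significant digits so
#' a read/write round trip preserves intensities well beyond instrument
#' precision.  Masked cells are written as the sentinel \code{"NA"}.
#'
#' @param eem an \code{\linkS4class{EEMatrix}}.
#' @param path output file.
#' @param delim field delimiter, \code{","} (default) or \code{"\t"}.
#' @export
writeEEM <- function(eem, path, delim = ",") {
  stopifnot(is(eem, "EEMatrix"), delim %in% c(",", "\t"))
  body <- matrix(.fmtNum(eem@intensity), nrow(eem@intensity))
  body[eem@mask] <- .MASK_SENTINEL
  lines <- c(
    paste(c("", .fmtNum(eem@excitation)), collapse = delim),
    vapply(seq_len(nrow(body)), function(i)
      paste(c(.fmtNum(eem@emission[i]), body[i, ]), collapse = delim), "")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a two-column absorbance file
#'
#' Plain delimited text: wavelength (nm) then absorbance.  A non-numeric
#' first line is treated as a header.  Negative absorbances are clipped to
#' zero by the \code{\link{AbsorbanceSpectrum}} constructor.
#'
#' @param path file to read.
#' @return An \code{\linkS4class{AbsorbanceSpectrum}}.
#' @export
readAbsorbance <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop(sprintf("'%s': empty absorbance file", path))
  delim <- .sniffDelim(lines[1])
  first <- strsplit(lines[1], delim, fixed = TRUE)[[1]]
  if (suppressWarnings(is.na(as.numeric(trimws(first[1])))))
    lines <- lines[-1]
  rows <- strsplit(lines, delim, fixed = TRUE)
  bad <- which(lengths(rows) < 2L)
  if (length(bad))
    stop(sprintf("'%s': row %d has fewer than two columns", path, bad[1]))
  wl <- vapply(rows, function(r) suppressWarnings(as.numeric(trimws(r[1]))), 0)
  ab <- vapply(rows, function(r) suppressWarnings(as.numeric(trimws(r[2]))), 0)
  if (anyNA(wl) || anyNA(ab))
    stop(sprintf("'%s': non-numeric absorbance data", path))
  AbsorbanceSpectrum(wl, ab)
}

#' @rdname readAbsorbance
#' @param spec an \code{AbsorbanceSpectrum} to write.
#' @param delim field delimiter.
#' @export
writeAbsorbance <- function(spec, path, delim = ",") {
  writeLines(c(paste("wavelength_nm", "absorbance", sep = delim),
               paste(.fmtNum(spec@wavelength), .fmtNum(spec@absorbance),
                     sep = delim)), path)
  invisible(path)
}

#' Construct a growth curve
#'
#' @param timesH numeric sampling times (h), strictly increasing.
#' @param cfuPerMl numeric CFU per ml (positive, or \code{NA} for below
#'   detection).
#' @param replicate,condition identifying labels.
#' @param meta optional attribute list.
#' @return A \code{\linkS4class{GrowthCurve}}.
#' @export
GrowthCurve <- function(timesH, cfuPerMl, replicate = "rep1",
                        condition = "unknown", meta = list()) {
  new("GrowthCurve", timesH = as.numeric(timesH),
      cfuPerMl = as.numeric(cfuPerMl), replicate = replicate,
      condition = condition, meta = meta)
}

#' @describeIn GrowthCurve sampling times (h)
#' @param x a \code{GrowthCurve}
#' @export
setMethod("sampleTimes", "GrowthCurve", function(x) x@timesH)

#' @describeIn GrowthCurve viable counts (CFU per ml)
#' @export
setMethod("cfuPerMl", "GrowthCurve", function(x) x@cfuPerMl)

setMethod("show", "GrowthCurve", function(object) {
  obs <- object@cfuPerMl[!is.na(object@cfuPerMl)]
  cat(sprintf(
    "GrowthCurve [%s / %s]: %d time points over %g-%g h, %.3g-%.3g CFU/ml\n",
    object@condition, object@replicate, length(object@timesH),
    min(object@timesH), max(object@timesH),
    if (length(obs)) min(obs) else NA, if (length(obs)) max(obs) else NA))
  invisible(NULL)
})

#' Read growth curves from delimited text
#'
#' Accepts either a \code{cfu_per_ml} column or the plate-count triple
#' \code{colonies}, \code{dilution}, \code{volume_ml} (converted through
#' \code{\link{cfuFromPlate}}; zero colonies become \code{NA}, below
#' detection).  Optional \code{replicate} and \code{condition} columns split
#' the file into one curve per combination.
#'
#' @param path file with a header row; comma or tab delimited.
#' @return A list of \code{\linkS4class{GrowthCurve}} objects.
#' @export
readGrowthCurves <- function(path) {
  delim <- .sniffDelim(readLines(path, n = 1L))
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE)
  if (!"time_h" %in% names(df))
    stop(sprintf("'%s': missing column 'time_h'", path))
  if (!"cfu_per_ml" %in% names(df)) {
    need <- c("colonies", "dilution", "volume_ml")
    if (!all(need %in% names(df)))
      stop(sprintf("'%s': need 'cfu_per_ml' or columns %s", path,
                   paste(need, collapse = ", ")))
    df$cfu_per_ml <- cfuFromPlate(df$colonies, df$dilution, df$volume_ml)
  }
  df$cfu_per_ml[!is.na(df$cfu_per_ml) & df$cfu_per_ml == 0] <- NA_real_
  if (!"replicate" %in% names(df)) df$replicate <- "rep1"
  if (!"condition" %in% names(df)) df$condition <- "unknown"
  parts <- split(df, list(df$condition, df$replicate), drop = TRUE)
  lapply(unname(parts), function(p) {
    p <- p[order(p$time_h), , drop = FALSE]
    GrowthCurve(p$time_h, p$cfu_per_ml, replicate = p$replicate[1],
                condition = p$condition[1])
  })
}

#' @rdname readGrowthCurves
#' @param curves a list of \code{GrowthCurve} objects (or a single one).
#' @param delim field delimiter.
#' @export
writeGrowthCurves <- function(curves, path, delim = ",") {
  if (is(curves, "GrowthCurve")) curves <- list(curves)
  rows <- do.call(rbind, lapply(curves, function(g)
    data.frame(time_h = g@timesH, cfu_per_ml = g@cfuPerMl,
               replicate = g@replicate, condition = g@condition)))
  utils::write.table(rows, path, sep = delim, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
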