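#' Genetic map (bp to cM)
#'
#' A genetic map ties physical positions (base pairs) on one chromosome to
#' genetic positions (centiMorgans). Physical positions must be strictly
#' increasing and genetic positions non-decreasing; at least two anchor
#' points are required so that interpolation is defined.
#'
#' @param chrom Chromosome label (a single string; a leading `"chr"` prefix
#'   is stripped so `"chr9"` and `"9"` refer to the same chromosome).
#' @param bp Integer vector of physical positions, strictly increasing.
#' @param cm Numeric vector of genetic positions in cM, non-decreasing,
#'   with `cm[1] >= 0`. Same length as `bp`.
#' @return An object of class `genetic_map`: a data frame with columns
#'   `chrom`, `bp`, `cm`.
#' @seealso [read_genetic_map()], [cm_at()], [bp_at()]
#' @export
genetic_map <- function(chrom, bp, cm) {
  chrom <- norm_chrom(chrom)
  if (length(chrom) != 1L) stop("'chrom' must be a single label")
  bp <- as.numeric(bp)
  cm <- as.numeric(cm)
  if (length(bp) != length(cm)) stop("'bp' and 'cm' must have equal length")
  if (length(bp) < 2L) stop("genetic map needs >=2 points")
  if (any(diff(bp) <= 0)) stop("'bp' must be strictly increasing")
  if (any(diff(cm) < 0)) stop("'cm' must be non-decreasing")
  if (cm[1L] < 0) stop("'cm' must be non-negative")
  structure(
    data.frame(chrom = chrom, bp = bp, cm = cm),
    class = c("genetic_map", "data.frame")
  )
}

#' Read a HapMap-format genetic map
#'
#' Expects the HapMap recombination-map dialect: whitespace- or tab-separated
#' columns chromosome, position (bp), recombination rate (cM/Mb) and
#' cumulative map (cM), with or without a header line.
#'
#' @param path Path to the map file.
#' @return A [genetic_map()].
#' @export
read_genetic_map <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("[A-Za-z]{2,}", sub("^chr[0-9XY]+", "", first))
  dat <- utils::read.table(path, header = has_header, stringsAsFactors = FALSE)
  if (ncol(dat) < 4L) stop("expected 4 columns: chrom, position, rate, map")
  genetic_map(chrom = unique(dat[[1L]]), bp = dat[[2L]], cm = dat[[4L]])
}

#' Interpolate genetic position
#'
#' Linear interpolation of cM at physical positions. Positions outside the
#' map's range are clamped to the nearest endpoint by default; with
#' `extrapolate = TRUE` the terminal slope is extended instead.
#'
#' @param map A [genetic_map()].
#' @param bp Physical positions (bp).
#' @param extrapolate Extend the terminal slopes beyond the map range
#'   instead of clamping. Default `FALSE`.
#' @return Numeric vector of cM positions.
#' @export
cm_at <- function(map, bp, extrapolate = FALSE) {
  stopifnot(inherits(map, "genetic_map"))
  out <- stats::approx(map$bp, map$cm, xout = bp, rule = 2, ties = "ordered")$y
  if (extrapolate) {
    n <- nrow(map)
    lo <- bp < map$bp[1L]
    hi <- bp > map$bp[n]
    if (any(lo)) {
      s <- (map$cm[2L] - map$cm[1L]) / (map$bp[2L] - map$bp[1L])
      out[lo] <- map$cm[1L] + s * (bp[lo] - map$bp[1L])
    }
    if (any(hi)) {
      s <- (map$cm[n] - map$cm[n - 1L]) / (map$bp[n] - map$bp[n - 1L])
      out[hi] <- map$cm[n] + s * (bp[hi] - map$bp[n])
    }
  }
  out
}

#' Inverse map: physical position at a genetic position
#'
#' @param map A [genetic_map()].
#' @param cm Genetic positions (cM); clamped to the map range.
#' @return Numeric vector of bp positions.
#' @export
bp_at <- function(map, cm) {
  stopifnot(inherits(map, "genetic_map"))
  stats::approx(map$cm, map$bp, xout = cm, rule = 2, ties = "ordered")$y
}

# strip "chr" prefixes so chromosome labels compare across sources
norm_chrom <- function(x) sub("^chr", "", as.character(x))
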