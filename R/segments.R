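#' IBD segment table
#'
#' Detected or simulated identity-by-descent tracts are kept in an ordinary
#' data frame of class `ibd_segments` with one row per maximal shared tract
#' between two haplotypes. Columns:
#' \describe{
#'   \item{sample1, hap1, sample2, hap2}{the unordered haplotype pair
#'     (sample IDs and haplotype index 0/1), canonicalized so that
#'     `sample1 <= sample2` in panel order (and `hap1 < hap2` within a
#'     sample).}
#'   \item{chrom}{chromosome label.}
#'   \item{bp_start, bp_end}{physical span, 0-based half-open.}
#'   \item{cm_start, cm_end, length_cm}{genetic span;
#'     `length_cm = cm_end - cm_start`.}
#'   \item{n_sites, n_mismatch}{markers spanned and mismatching markers
#'     tolerated inside the tract.}
#' }
#'
#' @param df Data frame with the columns above (missing `cm_start`/`cm_end`
#'   are filled with `NA`).
#' @return An `ibd_segments` data frame.
#' @export
ibd_segments <- function(df) {
  need <- c("sample1", "hap1", "sample2", "hap2", "chrom",
            "bp_start", "bp_end", "length_cm", "n_sites", "n_mismatch")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing segment columns: ", paste(miss, collapse = ", "))
  if (is.null(df$cm_start)) df$cm_start <- NA_real_
  if (is.null(df$cm_end)) df$cm_end <- NA_real_
  if (any(df$length_cm < 0)) stop("negative length_cm")
  if (any(df$bp_end <= df$bp_start)) stop("bp_end must exceed bp_start")
  df$chrom <- norm_chrom(df$chrom)
  cols <- c("sample1", "hap1", "sample2", "hap2", "chrom", "bp_start",
            "bp_end", "cm_start", "cm_end", "length_cm", "n_sites", "n_mismatch")
  df <- df[, cols]
  class(df) <- c("ibd_segments", "data.frame")
  df
}

empty_segments <- function() {
  ibd_segments(data.frame(
    sample1 = character(), hap1 = integer(), sample2 = character(),
    hap2 = integer(), chrom = character(), bp_start = numeric(),
    bp_end = numeric(), cm_start = numeric(), cm_end = numeric(),
    length_cm = numeric(), n_sites = integer(), n_mismatch = integer(),
    stringsAsFactors = FALSE
  ))
}

match_cols <- c("sample1", "hap1", "sample2", "hap2", "chrom",
                "bp_start", "bp_end", "cm_length", "n_sites", "n_mismatch")

#' Write / read the match-file dialect
#'
#' The on-disk exchange format for detected segments is a TSV with exactly
#' the columns `sample1, hap1, sample2, hap2, chrom, bp_start, bp_end,
#' cm_length, n_sites, n_mismatch`. `read_match_file(write_match_file(x))`
#' restores those ten columns losslessly (`cm_start`/`cm_end` are not
#' persisted; recompute from a map if needed).
#'
#' @param segments An [ibd_segments()] data frame.
#' @param path File path.
#' @return `write_match_file` returns `path` invisibly; `read_match_file`
#'   returns an [ibd_segments()] data frame.
#' @export
write_match_file <- function(segments, path) {
  out <- as.data.frame(segments)[, c("sample1", "hap1", "sample2", "hap2",
                                     "chrom", "bp_start", "bp_end",
                                     "length_cm", "n_sites", "n_mismatch")]
  names(out)[8L] <- "cm_length"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_match_file
#' @export
read_match_file <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty match file")
  hdr <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (!identical(hdr, match_cols)) stop("bad match-file header")
  if (length(lines) == 1L) return(empty_segments())
  parts <- strsplit(lines[-1L], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 10L)) {
    stop(sprintf("malformed match-file line %d: expected 10 fields, got %d",
                 which(nf != 10L)[1L] + 1L, nf[nf != 10L][1L]))
  }
  m <- do.call(rbind, parts)
  num <- function(j, na_ok = FALSE) {
    x <- suppressWarnings(as.numeric(m[, j]))
    bad <- is.na(x) & !(na_ok & m[, j] == "NA")
    if (any(bad)) {
      stop(sprintf("malformed match-file line %d: non-numeric '%s'",
                   which(bad)[1L] + 1L, m[which(bad)[1L], j]))
    }
    x
  }
  ibd_segments(data.frame(
    sample1 = m[, 1L], hap1 = as.integer(num(2L)), sample2 = m[, 3L],
    hap2 = as.integer(num(4L)), chrom = m[, 5L], bp_start = num(6L),
    bp_end = num(7L), length_cm = num(8L),
    n_sites = as.integer(num(9L, na_ok = TRUE)),
    n_mismatch = as.integer(num(10L, na_ok = TRUE)), stringsAsFactors = FALSE
  ))
}
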