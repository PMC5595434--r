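#' Read a phenotype table
#'
#' Reads a TSV with a header containing at least `sample`; recognised
#' columns are `sex` (F/M), `age` (years), `height_raw` (inches; may be a
#' feet-and-inches string like `5'8"` which is converted), `birthplace`,
#' `icd9_codes` (semicolon- or comma-separated ICD9 strings) and
#' `carrier_status` (0/1/2 or NA). Unknown columns are kept untouched.
#'
#' @param path Path to a TSV with header.
#' @return A data frame of class `phenotype_table`; `icd9_codes` becomes a
#'   list-column of character vectors.
#' @export
read_phenotypes <- function(path) {
  dat <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = NA, na.strings = c("NA", ""))
  if (!"sample" %in% names(dat)) stop("phenotype table needs a 'sample' column")
  if (anyDuplicated(dat$sample)) {
    stop("duplicate sample ID: ", dat$sample[duplicated(dat$sample)][1L])
  }
  if ("height_raw" %in% names(dat) && is.character(dat$height_raw)) {
    dat$height_raw <- parse_height_inches(dat$height_raw)
  }
  if ("icd9_codes" %in% names(dat)) {
    raw <- as.character(dat$icd9_codes)
    codes <- strsplit(ifelse(is.na(raw), "", raw), "[;,]")
    codes <- lapply(codes, function(x) {
      x <- trimws(x[nzchar(trimws(x))])
      bad <- x[!grepl("^\\d{3}(\\.\\d{1,2})?$", x)]
      if (length(bad)) stop("invalid ICD9 code: ", bad[1L])
      x
    })
    dat$icd9_codes <- codes
  }
  pheno_validate(dat)
  class(dat) <- c("phenotype_table", "data.frame")
  dat
}

pheno_validate <- function(dat) {
  if ("sex" %in% names(dat) && !all(dat$sex %in% c("F", "M", NA))) {
    stop("'sex' must be F or M")
  }
  if ("age" %in% names(dat) && any(dat$age < 0, na.rm = TRUE)) {
    stop("'age' must be non-negative")
  }
  if ("height_raw" %in% names(dat) && any(dat$height_raw <= 0, na.rm = TRUE)) {
    stop("'height_raw' must be positive where present")
  }
  invisible(dat)
}

# "5'8\"" or "5'8.5" -> inches; plain numbers pass through
parse_height_inches <- function(x) {
  out <- suppressWarnings(as.numeric(x))
  ft <- grepl("'", x)
  if (any(ft, na.rm = TRUE)) {
    p <- regmatches(x[ft], regexec("^\\s*(\\d+)'\\s*([0-9.]*)\"?\\s*$", x[ft]))
    conv <- vapply(p, function(m) {
      if (length(m) < 2L || !nzchar(m[2L])) return(NA_real_)
      inch <- if (nzchar(m[3L])) as.numeric(m[3L]) else 0
      12 * as.numeric(m[2L]) + inch
    }, numeric(1))
    out[ft] <- conv
  }
  out
}

#' Write a phenotype table
#'
#' @param pheno A `phenotype_table` (or plain data frame).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(pheno, path) {
  out <- as.data.frame(pheno)
  if ("icd9_codes" %in% names(out) && is.list(out$icd9_codes)) {
    out$icd9_codes <- vapply(out$icd9_codes, paste, character(1), collapse = ";")
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED region mask
#'
#' BED input is 0-based half-open, matching the internal convention, so
#' intervals are taken as-is. Intervals may overlap; the mask has union
#' semantics.
#'
#' @param path Path to a BED file (>= 3 columns, no header).
#' @return A data frame of class `region_mask` with columns
#'   `chrom`, `bp_start`, `bp_end`.
#' @export
read_mask <- function(path) {
  dat <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  region_mask(dat[[1L]], dat[[2L]], dat[[3L]])
}

#' Construct a region mask
#'
#' @param chrom Chromosome labels.
#' @param bp_start,bp_end Interval bounds, 0-based half-open.
#' @return A `region_mask` data frame.
#' @export
region_mask <- function(chrom, bp_start, bp_end) {
  bp_start <- as.numeric(bp_start)
  bp_end <- as.numeric(bp_end)
  if (any(bp_start < 0)) stop("mask starts must be non-negative")
  if (any(bp_end <= bp_start)) stop("mask intervals need start < end")
  structure(
    data.frame(chrom = norm_chrom(chrom), bp_start = bp_start, bp_end = bp_end),
    class = c("region_mask", "data.frame")
  )
}
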