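#' Phased haplotype panel
#'
#' Container for phased diploid genotypes: a binary allele matrix `H` with
#' two rows per sample (rows `2i - 1` and `2i` are the two haplotypes of
#' sample `i`, in input order) and one column per site.
#'
#' @param samples Character vector of sample IDs (unique).
#' @param sites Data frame with columns `chrom`, `bp`, `allele0`, `allele1`,
#'   sorted by (chrom, bp). `bp` is the 0-based position of the site.
#' @param H Integer matrix in \{0, 1\} of dimension `2 * length(samples)`
#'   by `nrow(sites)`.
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(samples, sites, H) {
  samples <- as.character(samples)
  if (anyDuplicated(samples)) stop("duplicate sample IDs")
  need <- c("chrom", "bp", "allele0", "allele1")
  if (!all(need %in% names(sites))) {
    stop("'sites' must have columns chrom, bp, allele0, allele1")
  }
  sites$chrom <- norm_chrom(sites$chrom)
  H <- as.matrix(H)
  storage.mode(H) <- "integer"
  if (nrow(H) != 2L * length(samples)) {
    stop("H must have 2 rows per sample")
  }
  if (ncol(H) != nrow(sites)) stop("H column count must equal site count")
  if (any(H != 0L & H != 1L)) stop("H entries must be 0/1")
  ord <- order(sites$chrom, sites$bp)
  if (is.unsorted(ord)) {
    sites <- sites[ord, , drop = FALSE]
    H <- H[, ord, drop = FALSE]
  }
  rownames(H) <- paste0(rep(samples, each = 2L), "_", rep(0:1, length(samples)))
  structure(
    list(samples = samples, sites = sites, H = H),
    class = "haplotype_panel"
  )
}

#' @exportS3Method print haplotype_panel
print.haplotype_panel <- function(x, ...) {
  cat(sprintf(
    "<haplotype_panel> %d samples (%d haplotypes) x %d sites on chrom %s\n",
    length(x$samples), nrow(x$H), ncol(x$H),
    paste(unique(x$sites$chrom), collapse = ",")
  ))
  invisible(x)
}

#' @exportS3Method dim haplotype_panel
dim.haplotype_panel <- function(x) dim(x$H)

#' Rows of the allele matrix belonging to a sample
#'
#' @param panel A [haplotype_panel()].
#' @param sample Sample ID or index.
#' @return Integer vector of length 2: the two haplotype row indices.
#' @export
hap_rows <- function(panel, sample) {
  i <- if (is.character(sample)) match(sample, panel$samples) else as.integer(sample)
  if (is.na(i) || i < 1L || i > length(panel$samples)) stop("unknown sample")
  c(2L * i - 1L, 2L * i)
}

#' Minor allele frequencies of panel sites
#'
#' @param panel A [haplotype_panel()].
#' @return Numeric vector of per-site minor allele frequencies.
#' @export
site_maf <- function(panel) {
  f <- colMeans(panel$H)
  pmin(f, 1 - f)
}

#' Drop low-frequency sites
#'
#' Filters a panel to sites with minor allele frequency above a threshold;
#' the standard input filter before IBD detection.
#'
#' @param panel A [haplotype_panel()].
#' @param min_maf Minimum (exclusive) minor allele frequency. Default 0.01.
#' @return A filtered [haplotype_panel()].
#' @export
filter_maf <- function(panel, min_maf = 0.01) {
  keep <- site_maf(panel) > min_maf
  haplotype_panel(panel$samples, panel$sites[keep, , drop = FALSE],
                  panel$H[, keep, drop = FALSE])
}

#' Read phased haplotypes
#'
#' Reads a phased VCF (all genotypes separated by `|`) or a simple
#' haplotype-matrix TSV with two rows per sample. Multi-allelic sites are
#' rejected; an unphased or non-diploid genotype is an error naming the
#' offending site.
#'
#' VCF positions (1-based) are converted to the internal 0-based convention.
#'
#' @param path Input file path.
#' @param format `"vcf"` or `"hapmatrix"`.
#' @return A [haplotype_panel()].
#' @export
read_phased_haplotypes <- function(path, format = c("vcf", "hapmatrix")) {
  format <- match.arg(format)
  if (format == "vcf") read_panel_vcf(path) else read_panel_hapmatrix(path)
}

read_panel_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  bad <- grepl(",", alt)
  if (any(bad)) {
    stop(sprintf("multi-allelic site at %s:%s", fix[which(bad)[1L], "CHROM"],
                 fix[which(bad)[1L], "POS"]))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1L)
  site_of <- function(flags) (which(flags)[1L] - 1L) %% nrow(gt) + 1L
  unphased <- grepl("/", gt)
  if (any(unphased)) {
    i <- site_of(unphased)
    stop(sprintf("unphased genotype at site %s:%s", fix[i, "CHROM"], fix[i, "POS"]))
  }
  nond <- !grepl("^[01]\\|[01]$", gt)
  if (any(nond)) {
    i <- site_of(nond)
    stop(sprintf("mixed ploidy or bad genotype at site %s:%s",
                 fix[i, "CHROM"], fix[i, "POS"]))
  }
  samples <- colnames(gt)
  m <- nrow(gt)
  n <- length(samples)
  # gt is sites x samples; expand to haplotype rows
  a0 <- substr(gt, 1L, 1L) != "0"
  a1 <- substr(gt, 3L, 3L) != "0"
  H <- matrix(0L, nrow = 2L * n, ncol = m)
  H[seq(1L, 2L * n, by = 2L), ] <- t(matrix(as.integer(a0), nrow = m))
  H[seq(2L, 2L * n, by = 2L), ] <- t(matrix(as.integer(a1), nrow = m))
  sites <- data.frame(
    chrom = norm_chrom(fix[, "CHROM"]),
    bp = as.numeric(fix[, "POS"]) - 1,
    allele0 = fix[, "REF"],
    allele1 = alt,
    stringsAsFactors = FALSE
  )
  haplotype_panel(samples, sites, H)
}

read_panel_hapmatrix <- function(path) {
  dat <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  # first two columns: sample, hap; remaining columns: chrom:bp:a0:a1 headers
  if (ncol(dat) < 3L) stop("hapmatrix needs sample, hap and >=1 site column")
  ids <- dat[[1L]]
  haps <- dat[[2L]]
  if (nrow(dat) %% 2L != 0L) stop("hapmatrix must have 2 rows per sample")
  samples <- ids[seq(1L, nrow(dat), by = 2L)]
  ok <- all(ids[seq(2L, nrow(dat), by = 2L)] == samples) &&
    all(haps == rep(0:1, length(samples)))
  if (!ok) stop("hapmatrix rows must alternate hap 0/1 per sample")
  meta <- do.call(rbind, strsplit(names(dat)[-(1:2)], ":", fixed = TRUE))
  if (ncol(meta) != 4L) stop("site columns must be named chrom:bp:allele0:allele1")
  sites <- data.frame(
    chrom = norm_chrom(meta[, 1L]), bp = as.numeric(meta[, 2L]),
    allele0 = meta[, 3L], allele1 = meta[, 4L], stringsAsFactors = FALSE
  )
  H <- as.matrix(dat[, -(1:2), drop = FALSE])
  dimnames(H) <- NULL
  haplotype_panel(samples, sites, H)
}

#' Write a panel as phased VCF or haplotype-matrix TSV
#'
#' @param panel A [haplotype_panel()].
#' @param path Output path.
#' @param format `"vcf"` or `"hapmatrix"`.
#' @return `path`, invisibly.
#' @export
write_phased_haplotypes <- function(panel, path, format = c("vcf", "hapmatrix")) {
  format <- match.arg(format)
  if (format == "vcf") {
    n <- length(panel$samples)
    odd <- seq(1L, 2L * n, by = 2L)
    gt <- matrix(paste0(t(panel$H[odd, , drop = FALSE]), "|",
                        t(panel$H[odd + 1L, , drop = FALSE])),
                 nrow = ncol(panel$H))
    lines <- c(
      "##fileformat=VCFv4.2",
      '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
              "FORMAT", panel$samples), collapse = "\t"),
      paste(panel$sites$chrom, format(panel$sites$bp + 1, scientific = FALSE, trim = TRUE),
            ".", panel$sites$allele0, panel$sites$allele1, ".", "PASS", ".", "GT",
            apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
    )
    writeLines(lines, path)
  } else {
    hdr <- c("sample", "hap",
             paste(panel$sites$chrom, panel$sites$bp,
                   panel$sites$allele0, panel$sites$allele1, sep = ":"))
    body <- cbind(rep(panel$samples, each = 2L),
                  rep(0:1, length(panel$samples)),
                  panel$H)
    utils::write.table(rbind(hdr, body), path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
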