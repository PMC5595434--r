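#' IBD detector parameters
#'
#' Defaults mirror the standard founder-population settings: minimum
#' reported length 3 cM, word size 25 markers, up to 2 mismatching markers
#' tolerated per word during extension, haploid matching (each haplotype
#' is matched independently, every allele difference counts once, and the
#' homozygous-mismatch budget is unused).
#'
#' @param min_m Minimum segment length to report, cM.
#' @param err_hom Homozygous-site mismatch budget per word (unused in
#'   haploid mode, kept for interface fidelity).
#' @param err_het Mismatch budget per word during extension.
#' @param bits Word size in markers (8--64).
#' @param haploid Haploid matching; only `TRUE` is implemented.
#' @return A list of class `ibd_params`.
#' @export
ibd_params <- function(min_m = 3, err_hom = 0, err_het = 2, bits = 25,
                       haploid = TRUE) {
  if (min_m <= 0) stop("'min_m' must be positive")
  if (bits < 8 || bits > 64) stop("'bits' must be in 8..64")
  if (err_hom < 0 || err_het < 0) stop("error budgets must be >= 0")
  if (!haploid) stop("only haploid matching is implemented")
  structure(list(min_m = min_m, err_hom = err_hom, err_het = err_het,
                 bits = as.integer(bits), haploid = haploid),
            class = "ibd_params")
}

#' Detect pairwise IBD segments
#'
#' Word-hash scan over a phased panel: the marker axis is cut into
#' consecutive words of `bits` markers; haplotype pairs sharing an
#' identical word are seed pairs; seeds are extended word-by-word while a
#' word's mismatch count stays within `err_het` (extension runs are
#' maximal, so same-pair segments are disjoint by construction); segment
#' ends are refined to the outermost matching marker; segments of genetic
#' length at least `min_m` cM are reported. Output is deterministic and
#' canonical (pairs ordered by panel sample order), so it is invariant
#' under permuting samples. A tract can only be seeded if it contains one
#' aligned, fully identical word, the defining granularity of hash-seeded
#' detection.
#'
#' @param panel A [haplotype_panel()].
#' @param map A [genetic_map()] covering the panel's chromosome(s).
#' @param params An [ibd_params()].
#' @return An [ibd_segments()] data frame.
#' @export
detect_ibd <- function(panel, map, params = ibd_params()) {
  stopifnot(inherits(panel, "haplotype_panel"), inherits(params, "ibd_params"))
  maps <- if (inherits(map, "genetic_map")) list(map) else map
  map_chroms <- vapply(maps, function(m) m$chrom[1L], character(1))
  chroms <- unique(panel$sites$chrom)
  out <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    mi <- match(ch, map_chroms)
    if (is.na(mi)) stop("no genetic map for chromosome ", ch)
    sel <- which(panel$sites$chrom == ch)
    cm <- cm_at(maps[[mi]], panel$sites$bp[sel])
    hits <- detect_ibd_cpp(panel$H[, sel, drop = FALSE], cm,
                           bits = params$bits, err_het = params$err_het,
                           min_m = params$min_m)
    if (!nrow(hits)) {
      out[[ci]] <- empty_segments()
      next
    }
    bp <- panel$sites$bp[sel]
    s0 <- hits$site_start + 1L
    s1 <- hits$site_end + 1L
    segs <- hap_pairs_to_segments(
      hits$hap_i, hits$hap_j, bp[s0], bp[s1] + 1,
      panel$samples, chrom = ch, map = maps[[mi]],
      n_sites = s1 - s0 + 1L, n_mismatch = hits$n_mismatch
    )
    # genetic span is between the first and last marker of the tract
    segs$cm_start <- cm[s0]
    segs$cm_end <- cm[s1]
    segs$length_cm <- segs$cm_end - segs$cm_start
    out[[ci]] <- segs
  }
  res <- do.call(rbind, lapply(out, as.data.frame))
  res <- res[order(match(res$sample1, panel$samples), res$hap1,
                   match(res$sample2, panel$samples), res$hap2,
                   res$chrom, res$bp_start), , drop = FALSE]
  rownames(res) <- NULL
  ibd_segments(res)
}

#' Total pairwise IBD sharing
#'
#' Sums segment genetic lengths over all tracts of each sample pair,
#' regardless of which haplotypes are involved. Pairs sharing no tract do
#' not appear.
#'
#' @param segments An [ibd_segments()] data frame.
#' @return Data frame with columns `sample1`, `sample2`, `total_cm`,
#'   `n_tracts`.
#' @export
sum_pairwise_sharing <- function(segments) {
  if (!nrow(segments)) {
    return(data.frame(sample1 = character(), sample2 = character(),
                      total_cm = numeric(), n_tracts = integer(),
                      stringsAsFactors = FALSE))
  }
  key <- paste(segments$sample1, segments$sample2, sep = "\r")
  tot <- rowsum(segments$length_cm, key)
  cnt <- rowsum(rep(1L, nrow(segments)), key)
  parts <- strsplit(rownames(tot), "\r", fixed = TRUE)
  data.frame(
    sample1 = vapply(parts, `[`, character(1), 1L),
    sample2 = vapply(parts, `[`, character(1), 2L),
    total_cm = as.numeric(tot), n_tracts = as.integer(cnt),
    stringsAsFactors = FALSE
  )
}
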