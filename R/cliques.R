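#' Remove segments overlapping a region mask
#'
#' A segment overlapping any masked interval (centromere, telomere,
#' low-complexity region) is removed entirely -- a single base of overlap
#' suffices; survivors are untouched.
#'
#' @param segments An [ibd_segments()] data frame.
#' @param mask A [region_mask()].
#' @param min_m Unused filter floor kept in the signature for pipeline
#'   symmetry (masking never shortens a segment).
#' @return Filtered [ibd_segments()].
#' @export
apply_mask <- function(segments, mask, min_m = 3) {
  if (!nrow(segments) || !nrow(mask)) return(segments)
  drop <- rep(FALSE, nrow(segments))
  for (k in seq_len(nrow(mask))) {
    drop <- drop | (segments$chrom == mask$chrom[k] &
                      segments$bp_start < mask$bp_end[k] &
                      segments$bp_end > mask$bp_start[k])
  }
  out <- segments[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exclude regions of excessive IBD sharing depth
#'
#' Computes, at every marker site, the number of segments containing it
#' (the sharing depth). Sites whose depth exceeds the genome-wide mean by
#' more than `n_sd` standard deviations define excluded regions (maximal
#' runs of flagged sites); segments are truncated at excluded-region
#' boundaries and resulting pieces shorter than `min_m` cM are dropped.
#' A single pass, not iterated to a fixed point.
#'
#' @param segments An [ibd_segments()] data frame.
#' @param sites Data frame of marker sites (`chrom`, `bp`), typically
#'   `panel$sites`: the grid on which depth is measured.
#' @param map A [genetic_map()] (or list of maps) for re-deriving genetic
#'   lengths of truncated pieces.
#' @param min_m Minimum piece length to keep, cM.
#' @param n_sd Exclusion threshold in standard deviations. Default 4.
#' @return List with `segments` (filtered [ibd_segments()]) and `profile`
#'   (data frame `chrom`, `bp`, `depth` plus attributes `mean`, `sd`,
#'   `threshold`).
#' @export
depth_filter <- function(segments, sites, map, min_m = 3, n_sd = 4) {
  if (!nrow(segments)) stop("depth_filter needs >= 1 segment")
  maps <- if (inherits(map, "genetic_map")) list(map) else map
  map_chroms <- vapply(maps, function(m) m$chrom[1L], character(1))
  depth <- integer(nrow(sites))
  for (ch in unique(sites$chrom)) {
    ssel <- which(sites$chrom == ch)
    seg <- segments[segments$chrom == ch, , drop = FALSE]
    if (!nrow(seg)) next
    bp <- sites$bp[ssel]
    # depth via interval start/end events on the sorted site grid
    i0 <- findInterval(seg$bp_start, bp, left.open = TRUE) + 1L
    i1 <- findInterval(seg$bp_end - 1, bp)
    keep <- i0 <= i1
    d <- integer(length(bp) + 1L)
    tab0 <- tabulate(i0[keep], nbins = length(bp))
    tab1 <- tabulate(i1[keep] + 1L, nbins = length(bp) + 1L)
    d <- cumsum(tab0 - tab1[seq_along(bp)])
    depth[ssel] <- d
  }
  mu <- mean(depth)
  sdd <- stats::sd(depth)
  if (is.na(sdd)) sdd <- 0
  thr <- mu + n_sd * sdd
  flagged <- depth > thr
  profile <- data.frame(chrom = sites$chrom, bp = sites$bp, depth = depth)
  attr(profile, "mean") <- mu
  attr(profile, "sd") <- sdd
  attr(profile, "threshold") <- thr
  if (!any(flagged)) {
    return(list(segments = segments, profile = profile))
  }
  # excluded regions: maximal runs of flagged sites, extended halfway to
  # the neighbouring unflagged site
  excl <- do.call(rbind, lapply(unique(sites$chrom), function(ch) {
    ssel <- which(sites$chrom == ch)
    f <- flagged[ssel]
    if (!any(f)) return(NULL)
    r <- rle(f)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    bp <- sites$bp[ssel]
    lo <- bp[starts[runs]]
    hi <- bp[ends[runs]] + 1
    data.frame(chrom = ch, lo = lo, hi = hi, stringsAsFactors = FALSE)
  }))
  pieces <- vector("list", nrow(segments))
  for (i in seq_len(nrow(segments))) {
    seg <- segments[i, ]
    ex <- excl[excl$chrom == seg$chrom & excl$lo < seg$bp_end &
                 excl$hi > seg$bp_start, , drop = FALSE]
    if (!nrow(ex)) {
      pieces[[i]] <- seg
      next
    }
    ex <- ex[order(ex$lo), , drop = FALSE]
    cuts_lo <- c(seg$bp_start, pmin(ex$hi, seg$bp_end))
    cuts_hi <- c(pmax(ex$lo, seg$bp_start), seg$bp_end)
    ok <- cuts_hi > cuts_lo
    if (!any(ok)) next
    mi <- match(seg$chrom, map_chroms)
    sub <- seg[rep(1L, sum(ok)), , drop = FALSE]
    sub$bp_start <- cuts_lo[ok]
    sub$bp_end <- cuts_hi[ok]
    sub$cm_start <- cm_at(maps[[mi]], sub$bp_start)
    sub$cm_end <- cm_at(maps[[mi]], sub$bp_end)
    sub$length_cm <- sub$cm_end - sub$cm_start
    pieces[[i]] <- sub[sub$length_cm >= min_m, , drop = FALSE]
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  list(segments = ibd_segments(out), profile = profile)
}

#' Cluster IBD segments into cliques
#'
#' Slides non-overlapping windows of `window_cm` (anchored at cM 0) along
#' each chromosome. Within a window, nodes are haplotypes whose segments
#' fully cover the window (guaranteeing pairwise overlap of at least the
#' window length), edges are segment pairs, and connected components with
#' at least `min_size` haplotypes become cliques. Components with
#' identical membership in adjacent windows are merged; a clique's
#' interval is the union of its windows.
#'
#' @param segments An [ibd_segments()] data frame (mask- and
#'   depth-filtered).
#' @param samples Character vector fixing sample order (for deterministic
#'   output and dosage rows); defaults to order of appearance.
#' @param map A [genetic_map()] (or list) used to locate window bounds in
#'   bp.
#' @param window_cm Window (and minimum overlap) size in cM. Default 0.5.
#' @param min_size Minimum haplotypes per clique. Default 3.
#' @return A list of class `ibd_cliques`; each element has `id`, `chrom`,
#'   `cm_lo`, `cm_hi`, `bp_lo`, `bp_hi`, `members` (haplotype keys
#'   `sample|hap`), `tract_cm_lo`, `tract_cm_hi` (intersection of member
#'   tracts, for fine-mapping). The sample vector is kept as an attribute.
#' @export
cluster_cliques <- function(segments, samples = NULL, map = NULL,
                            window_cm = 0.5, min_size = 3) {
  if (window_cm <= 0) stop("'window_cm' must be positive")
  if (is.null(samples)) {
    samples <- unique(c(segments$sample1, segments$sample2))
  }
  maps <- if (inherits(map, "genetic_map")) list(map) else map
  map_chroms <- if (!is.null(maps)) {
    vapply(maps, function(m) m$chrom[1L], character(1))
  } else character()
  if (nrow(segments) && anyNA(segments$cm_start)) {
    stop("segments need cm_start/cm_end; recompute from a map first")
  }
  cliques <- list()
  for (ch in unique(segments$chrom)) {
    seg <- segments[segments$chrom == ch, , drop = FALSE]
    if (!nrow(seg)) next
    # haplotype ids: 0-based 2 * sample_index + hap
    h1 <- 2L * (match(seg$sample1, samples) - 1L) + seg$hap1
    h2 <- 2L * (match(seg$sample2, samples) - 1L) + seg$hap2
    if (anyNA(h1) || anyNA(h2)) stop("segment sample not in 'samples'")
    cc <- cluster_cliques_cpp(h1, h2, seg$cm_start, seg$cm_end,
                              window_cm, as.integer(min_size))
    if (!length(cc$cm_lo)) next
    mi <- match(ch, map_chroms)
    new <- lapply(seq_along(cc$cm_lo), function(i) {
      mh <- cc$members[[i]]
      list(chrom = ch, cm_lo = cc$cm_lo[i], cm_hi = cc$cm_hi[i],
           bp_lo = if (!is.na(mi)) bp_at(maps[[mi]], cc$cm_lo[i]) else NA_real_,
           bp_hi = if (!is.na(mi)) bp_at(maps[[mi]], cc$cm_hi[i]) else NA_real_,
           tract_cm_lo = cc$tract_cm_lo[i], tract_cm_hi = cc$tract_cm_hi[i],
           member_haps = mh,
           members = paste(samples[mh %/% 2L + 1L], mh %% 2L, sep = "|"))
    })
    cliques <- c(cliques, new)
  }
  # deterministic order: chrom, start, member list
  if (length(cliques)) {
    ord <- order(
      vapply(cliques, function(x) x$chrom, character(1)),
      vapply(cliques, function(x) x$cm_lo, numeric(1)),
      vapply(cliques, function(x) paste(x$member_haps, collapse = ","),
             character(1))
    )
    cliques <- cliques[ord]
    for (i in seq_along(cliques)) cliques[[i]]$id <- sprintf("clq%06d", i)
  }
  structure(cliques, samples = samples, class = "ibd_cliques")
}

#' @exportS3Method print ibd_cliques
print.ibd_cliques <- function(x, ...) {
  sizes <- vapply(x, function(cl) length(cl$members), integer(1))
  cat(sprintf("<ibd_cliques> %d cliques; sizes %s\n", length(x),
              if (length(x)) paste(range(sizes), collapse = "-") else "-"))
  invisible(x)
}

#' Remove cliques with excessive membership
#'
#' Drops cliques whose haplotype count exceeds the mean clique size by
#' more than `n_sd` standard deviations.
#'
#' @param cliques An `ibd_cliques` list.
#' @param n_sd Threshold in standard deviations. Default 4.
#' @return Filtered `ibd_cliques`.
#' @export
filter_cliques <- function(cliques, n_sd = 4) {
  if (!length(cliques)) stop("filter_cliques needs >= 1 clique")
  sizes <- vapply(cliques, function(cl) length(cl$members), integer(1))
  sdd <- stats::sd(sizes)
  if (is.na(sdd)) sdd <- 0
  keep <- sizes <= mean(sizes) + n_sd * sdd
  structure(cliques[keep], samples = attr(cliques, "samples"),
            class = "ibd_cliques")
}

#' Encode clique membership as 0/1/2 dosages
#'
#' A sample scores 2 if both of its haplotypes belong to the clique, 1 if
#' one does, 0 otherwise.
#'
#' @param cliques An `ibd_cliques` list.
#' @param samples Sample IDs fixing row order (defaults to the attribute
#'   stored by [cluster_cliques()]).
#' @return Integer matrix samples x cliques, dimnames set.
#' @export
encode_dosage <- function(cliques, samples = attr(cliques, "samples")) {
  D <- matrix(0L, nrow = length(samples), ncol = length(cliques),
              dimnames = list(samples,
                              vapply(cliques, function(cl) cl$id, character(1))))
  for (j in seq_along(cliques)) {
    si <- clique_sample_index(cliques[[j]], samples)
    tab <- tabulate(si, nbins = length(samples))
    D[, j] <- as.integer(tab)
  }
  D
}

clique_sample_index <- function(cl, samples) {
  if (!is.null(cl$member_haps)) {
    cl$member_haps %/% 2L + 1L
  } else {
    match(sub("\\|[01]$", "", cl$members), samples)
  }
}

#' Homozygote counts per clique
#'
#' Number of samples with both haplotypes in each clique, computed
#' without materializing the full dosage matrix -- used to pre-select
#' cliques for a recessive scan.
#'
#' @param cliques An `ibd_cliques` list.
#' @param samples Sample IDs (defaults to the stored attribute).
#' @return Integer vector, one count per clique.
#' @export
clique_hom_counts <- function(cliques, samples = attr(cliques, "samples")) {
  vapply(cliques, function(cl) {
    si <- clique_sample_index(cl, samples)
    sum(tabulate(si, nbins = length(samples)) == 2L)
  }, integer(1))
}

#' Clique allele frequencies
#'
#' @param cliques An `ibd_cliques` list.
#' @param n_samples Population size used in the denominator `2 n`.
#' @return Numeric vector of clique frequencies.
#' @export
clique_frequency <- function(cliques, n_samples = length(attr(cliques, "samples"))) {
  vapply(cliques, function(cl) length(cl$members), integer(1)) / (2 * n_samples)
}
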