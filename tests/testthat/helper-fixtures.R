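# Shared fixture builders and independent oracles.

# uniform map: `cm_per_site` spacing between consecutive markers
uniform_map_panel <- function(n_hap, n_sites, cm_per_site = 0.1, seed = NULL,
                              p = 0.5) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_hap %% 2 == 0)
  bp <- seq(0, by = round(cm_per_site * 1e6), length.out = n_sites)
  H <- matrix(rbinom(n_hap * n_sites, 1, p), nrow = n_hap)
  panel <- haplotype_panel(
    sprintf("S%03d", seq_len(n_hap / 2)),
    data.frame(chrom = "1", bp = bp, allele0 = "A", allele1 = "G"),
    H
  )
  map <- genetic_map("1", bp = c(0, max(bp) + round(cm_per_site * 1e6)),
                     cm = c(0, (n_sites) * cm_per_site))
  list(panel = panel, map = map, cm = cm_per_site * (seq_len(n_sites) - 1))
}

# copy a marker block from one haplotype row to another, flipping the
# flanking markers so the identical run is exactly [from, to]
plant_block <- function(panel, row_a, row_b, from, to) {
  m <- ncol(panel$H)
  panel$H[row_b, from:to] <- panel$H[row_a, from:to]
  if (from > 1) panel$H[row_b, from - 1] <- 1L - panel$H[row_a, from - 1]
  if (to < m) panel$H[row_b, to + 1] <- 1L - panel$H[row_a, to + 1]
  panel
}

# brute-force oracle: maximal identical runs >= min_m cM over all
# haplotype pairs, O(pairs x sites)
brute_force_ibd <- function(panel, cm, min_m = 3) {
  nh <- nrow(panel$H)
  out <- list()
  for (i in seq_len(nh - 1)) {
    for (j in (i + 1):nh) {
      eq <- panel$H[i, ] == panel$H[j, ]
      r <- rle(eq)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        if (cm[ends[k]] - cm[starts[k]] >= min_m) {
          out[[length(out) + 1L]] <- data.frame(
            hap_i = i, hap_j = j, s0 = starts[k], s1 = ends[k]
          )
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(hap_i = integer(), hap_j = integer(),
                      s0 = integer(), s1 = integer()))
  }
  do.call(rbind, out)
}

# detected segments -> comparable (hap_i, hap_j, s0, s1) keys
segments_to_keys <- function(segments, panel) {
  si <- match(segments$sample1, panel$samples)
  sj <- match(segments$sample2, panel$samples)
  hi <- 2L * (si - 1L) + segments$hap1 + 1L
  hj <- 2L * (sj - 1L) + segments$hap2 + 1L
  s0 <- match(segments$bp_start, panel$sites$bp)
  s1 <- match(segments$bp_end - 1, panel$sites$bp)
  sprintf("%d:%d:%d:%d", pmin(hi, hj), pmax(hi, hj), s0, s1)
}

# random synthetic segment table for round-trip tests
random_segments <- function(n, seed = 1) {
  set.seed(seed)
  start <- sort(sample.int(1e8, n))
  len <- sample.int(5e6, n) + 1e5
  ibd_segments(data.frame(
    sample1 = sprintf("S%03d", sample.int(50, n, replace = TRUE)),
    hap1 = sample(0:1, n, replace = TRUE),
    sample2 = sprintf("T%03d", sample.int(50, n, replace = TRUE)),
    hap2 = sample(0:1, n, replace = TRUE),
    chrom = as.character(sample(1:22, n, replace = TRUE)),
    bp_start = start, bp_end = start + len,
    cm_start = NA_real_, cm_end = NA_real_,
    length_cm = round(len / 1e6, 4),
    n_sites = sample.int(1000, n), n_mismatch = sample(0:3, n, replace = TRUE),
    stringsAsFactors = FALSE
  ))
}

# transitive-closure oracle for clique membership on an explicit
# overlap graph (boolean matrix powering)
transitive_closure_components <- function(n_nodes, edges) {
  A <- diag(TRUE, n_nodes)
  for (k in seq_len(nrow(edges))) {
    A[edges[k, 1], edges[k, 2]] <- TRUE
    A[edges[k, 2], edges[k, 1]] <- TRUE
  }
  repeat {
    A2 <- (A %*% A) > 0
    if (identical(A2, A)) break
    A <- A2
  }
  comp <- rep(NA_integer_, n_nodes)
  cid <- 0L
  for (v in seq_len(n_nodes)) {
    if (is.na(comp[v])) {
      cid <- cid + 1L
      comp[which(A[v, ])] <- cid
    }
  }
  comp
}

# hand-rolled Benjamini-Hochberg for oracle comparison
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}
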