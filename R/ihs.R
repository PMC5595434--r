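#' Integrated haplotype score (iHS) scan
#'
#' For each core site, extended haplotype homozygosity (EHH) of the
#' ancestral and the derived allele is computed outward marker by marker:
#' at distance x, carriers of the core allele are partitioned by their
#' haplotype over the interval core..x and
#' `EHH(x) = sum_h C(n_h, 2) / C(n_a, 2)` over the distinct extended
#' haplotypes h. EHH is integrated by the trapezoid rule on the cM scale
#' in both directions until it falls below `ehh_cut` (the first point
#' below the cut closes the integral) or the chromosome end is reached
#' (such sites are flagged truncated). The unstandardized score is
#' `uihs = log(iHH_A / iHH_D)`; iHS standardizes uihs to mean 0, s.d. 1
#' within derived-allele-frequency bins of width `bin_width`.
#'
#' @param panel A [haplotype_panel()].
#' @param map A [genetic_map()].
#' @param anc_alleles Integer vector (0/1) giving the ancestral allele
#'   code per site; defaults to 0 (the reference allele) with a warning.
#' @param maf_min Sites below this minor allele frequency are skipped.
#' @param ehh_cut EHH truncation threshold. Default 0.05.
#' @param bin_width Width of the derived-frequency standardization bins.
#' @return Data frame of class `ihs_scan`: `site`, `bp`, `freq_derived`,
#'   `ihh_a`, `ihh_d`, `uihs`, `ihs`, `truncated`.
#' @export
ihs_scan <- function(panel, map, anc_alleles = NULL, maf_min = 0.05,
                     ehh_cut = 0.05, bin_width = 0.02) {
  stopifnot(inherits(panel, "haplotype_panel"))
  m <- ncol(panel$H)
  if (is.null(anc_alleles)) {
    warning("ancestral alleles not supplied; assuming the reference (0) allele")
    anc_alleles <- rep(0L, m)
  }
  cm <- cm_at(map, panel$sites$bp)
  H <- panel$H
  derived <- colMeans(H != rep(anc_alleles, each = nrow(H)))
  maf <- pmin(derived, 1 - derived)
  res <- lapply(seq_len(m), function(s) {
    if (maf[s] < maf_min) return(NULL)
    anc_rows <- which(H[, s] == anc_alleles[s])
    der_rows <- which(H[, s] != anc_alleles[s])
    a <- integrate_ehh(H, cm, s, anc_rows, ehh_cut)
    d <- integrate_ehh(H, cm, s, der_rows, ehh_cut)
    data.frame(site = s, bp = panel$sites$bp[s], freq_derived = derived[s],
               ihh_a = a$ihh, ihh_d = d$ihh,
               truncated = a$truncated || d$truncated)
  })
  res <- do.call(rbind, res)
  if (is.null(res)) {
    res <- data.frame(site = integer(), bp = numeric(),
                      freq_derived = numeric(), ihh_a = numeric(),
                      ihh_d = numeric(), uihs = numeric(), ihs = numeric(),
                      truncated = logical())
    class(res) <- c("ihs_scan", "data.frame")
    return(res)
  }
  res$uihs <- ifelse(res$ihh_a > 0 & res$ihh_d > 0,
                     log(res$ihh_a / res$ihh_d), NA_real_)
  bin <- floor(res$freq_derived / bin_width)
  res$ihs <- NA_real_
  for (b in unique(bin)) {
    sel <- which(bin == b & is.finite(res$uihs))
    if (length(sel) >= 2L) {
      res$ihs[sel] <- (res$uihs[sel] - mean(res$uihs[sel])) / stats::sd(res$uihs[sel])
    }
  }
  class(res) <- c("ihs_scan", "data.frame")
  res
}

# EHH decay of one core allele, integrated outward in both directions
integrate_ehh <- function(H, cm, core, rows, ehh_cut) {
  n <- length(rows)
  if (n < 2L) return(list(ihh = NA_real_, truncated = FALSE))
  m <- length(cm)
  total <- 0
  truncated <- FALSE
  for (dir in c(-1L, 1L)) {
    grp <- rep(1L, n)
    ehh_prev <- 1
    cm_prev <- cm[core]
    s <- core + dir
    while (s >= 1L && s <= m) {
      key <- grp * 2L + H[rows, s]
      grp <- match(key, unique(key))
      cnt <- tabulate(grp)
      ehh <- sum(cnt * (cnt - 1)) / (n * (n - 1))
      total <- total + (ehh_prev + ehh) / 2 * abs(cm[s] - cm_prev)
      if (ehh < ehh_cut) break
      ehh_prev <- ehh
      cm_prev <- cm[s]
      s <- s + dir
    }
    if (s < 1L || s > m) truncated <- TRUE
  }
  list(ihh = total, truncated = truncated)
}

#' EHH of one allele at one core site
#'
#' Convenience accessor for the decay curve itself (mainly for plots and
#' tests); `EHH(0) = 1` by definition for any allele with at least two
#' carriers.
#'
#' @param panel A [haplotype_panel()].
#' @param map A [genetic_map()].
#' @param core Core site index.
#' @param allele Core allele (0/1).
#' @return Data frame `site`, `cm_dist`, `ehh` (both directions,
#'   including the core at distance 0).
#' @export
ehh_curve <- function(panel, map, core, allele) {
  H <- panel$H
  cm <- cm_at(map, panel$sites$bp)
  rows <- which(H[, core] == allele)
  n <- length(rows)
  if (n < 2L) stop("allele has fewer than 2 carriers")
  out <- data.frame(site = core, cm_dist = 0, ehh = 1)
  m <- length(cm)
  for (dir in c(-1L, 1L)) {
    grp <- rep(1L, n)
    s <- core + dir
    while (s >= 1L && s <= m) {
      key <- grp * 2L + H[rows, s]
      grp <- match(key, unique(key))
      cnt <- tabulate(grp)
      ehh <- sum(cnt * (cnt - 1)) / (n * (n - 1))
      out <- rbind(out, data.frame(site = s, cm_dist = dir * abs(cm[s] - cm[core]),
                                   ehh = ehh))
      if (ehh == 0) break
      s <- s + dir
    }
  }
  out[order(out$cm_dist), ]
}
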