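#' Population medians of pairwise IBD sharing
#'
#' For each population, the median of total pairwise sharing over all
#' within-population pairs that share at least one tract, with a
#' percentile bootstrap confidence interval over pairs.
#'
#' @param pair_sums Output of [sum_pairwise_sharing()].
#' @param population_labels Named character vector mapping sample ID to
#'   population label.
#' @param n_boot Bootstrap replicates. Default 1000.
#' @param conf Confidence level. Default 0.95.
#' @param seed Optional seed for the bootstrap.
#' @return Data frame: `population`, `n_pairs`, `median_cm`, `ci_lo`,
#'   `ci_hi`.
#' @export
sharing_summary <- function(pair_sums, population_labels, n_boot = 1000,
                            conf = 0.95, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p1 <- population_labels[pair_sums$sample1]
  p2 <- population_labels[pair_sums$sample2]
  within <- !is.na(p1) & !is.na(p2) & p1 == p2
  pops <- sort(unique(stats::na.omit(c(p1, p2))))
  out <- lapply(pops, function(pop) {
    x <- pair_sums$total_cm[within & p1 == pop]
    if (sum(population_labels == pop, na.rm = TRUE) < 2L || length(x) < 1L) {
      warning("population '", pop, "' has fewer than 2 samples with sharing; skipped")
      return(NULL)
    }
    boots <- vapply(seq_len(n_boot), function(b) {
      stats::median(x[sample.int(length(x), replace = TRUE)])
    }, numeric(1))
    a <- (1 - conf) / 2
    data.frame(population = pop, n_pairs = length(x),
               median_cm = stats::median(x),
               ci_lo = unname(stats::quantile(boots, a)),
               ci_hi = unname(stats::quantile(boots, 1 - a)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Tract-length spectrum
#'
#' Bins pairwise tract lengths by `floor(length / bin_cm)` and normalizes
#' counts by the number of possible pairs `N (N - 1) / 2`.
#'
#' @param segments An [ibd_segments()] data frame, or a numeric vector of
#'   tract lengths in cM.
#' @param N Population size (for the pair-count denominator), `N >= 2`.
#' @param bin_cm Bin width in cM. Default 0.01.
#' @return Data frame of class `ibd_spectrum`: `bin_lo`, `count`, `share`;
#'   attributes `N`, `bin_cm`, `n_pairs`.
#' @export
tract_spectrum <- function(segments, N, bin_cm = 0.01) {
  if (N < 2) stop("'N' must be >= 2")
  lens <- if (is.numeric(segments)) segments else segments$length_cm
  n_pairs <- N * (N - 1) / 2
  if (!length(lens)) {
    out <- data.frame(bin_lo = numeric(), count = integer(), share = numeric())
  } else {
    bin <- floor(lens / bin_cm)
    tab <- table(bin)
    out <- data.frame(bin_lo = as.numeric(names(tab)) * bin_cm,
                      count = as.integer(tab))
    out$share <- out$count / n_pairs
  }
  attr(out, "N") <- N
  attr(out, "bin_cm") <- bin_cm
  attr(out, "n_pairs") <- n_pairs
  class(out) <- c("ibd_spectrum", "data.frame")
  out
}

#' Carrier statistics by population
#'
#' Counts heterozygotes and homozygotes of a variant per population and
#' reports the conventional carrier ratio string `"1:k"` with
#' `k = round(n / n_het)`, and the minor allele frequency
#' `(n_het + 2 n_hom) / (2 n)`.
#'
#' @param dosage Integer vector in \{0, 1, 2\} (NA allowed, dropped).
#' @param population_labels Population label per sample.
#' @return Data frame: `population`, `n`, `n_het`, `n_hom`,
#'   `carrier_ratio`, `maf`.
#' @export
carrier_stats <- function(dosage, population_labels) {
  if (!all(dosage %in% c(0L, 1L, 2L, NA))) stop("dosage must be 0/1/2")
  keep <- !is.na(dosage)
  dosage <- dosage[keep]
  pop <- population_labels[keep]
  out <- lapply(sort(unique(pop)), function(pp) {
    d <- dosage[pop == pp]
    n <- length(d)
    n_het <- sum(d == 1L)
    n_hom <- sum(d == 2L)
    ratio <- if (n_het == 0L) sprintf("0:%d", n) else sprintf("1:%d", round(n / n_het))
    data.frame(population = pp, n = n, n_het = n_het, n_hom = n_hom,
               carrier_ratio = ratio, maf = (n_het + 2 * n_hom) / (2 * n),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Expected tract-length spectrum under a demography
#'
#' Closed-form expectation used by the effective-population-size fit.
#' With coalescence distribution `c(g)` ([coalescence_pmf()]) and, given
#' coalescence at generation `g`, an expected
#' `Lambda(u | g) = (2 g L + K - 2 g K u) exp(-2 g u)` maximal segments of
#' genetic length at least `u` Morgans per haplotype pair (genome of `K`
#' chromosomes totalling `L` Morgans; this is the exact finite-chromosome
#' count, whose long-genome limit is the familiar
#' `(2 g L + K) exp(-2 g u)`), the expected count in a length bin is
#' `sum_g c(g) (Lambda(u_lo | g) - Lambda(u_hi | g))`.
#'
#' @param ne_trajectory Effective sizes per generation before present
#'   (coalescence beyond the horizon is lumped at the final generation).
#' @param genome_cm Genome length in cM.
#' @param n_chrom Number of chromosomes.
#' @param bins Numeric vector of bin breaks in cM (ascending, length
#'   `nbin + 1`); the last break may be `Inf`.
#' @return Numeric vector of expected counts per haplotype pair, one per
#'   bin.
#' @export
expected_spectrum <- function(ne_trajectory, genome_cm, n_chrom, bins) {
  if (any(ne_trajectory < 2)) stop("all Ne must be >= 2")
  if (length(bins) < 2L || any(diff(bins) <= 0)) {
    stop("'bins' must be ascending breaks")
  }
  cg <- coalescence_pmf(ne_trajectory)
  g <- seq_along(cg)
  L <- genome_cm / 100
  l <- L / n_chrom
  u <- bins / 100
  # Lambda matrix: generations x breaks. Per chromosome of length l the
  # exact expected count of maximal pieces >= u under Poisson(2g)
  # breakpoints is (1 + 2g(l - u)) exp(-2gu); summed over K chromosomes
  # this is (2gL + K - 2gKu) exp(-2gu), the familiar (2gL + K) exp(-2gu)
  # in the long-genome limit, and 0 beyond the chromosome length.
  uc <- pmin(u, l)
  lam <- (outer(2 * g, pmax(l - uc, 0)) * n_chrom + n_chrom) *
    exp(-2 * outer(g, uc))
  lam[, u > l] <- 0
  colSums(cg * (lam[, -ncol(lam), drop = FALSE] - lam[, -1L, drop = FALSE]))
}

#' Estimate historical effective population size from the IBD spectrum
#'
#' Fits a piecewise-constant (per-epoch) log effective size to the
#' observed tract-length spectrum by minimizing the Poisson deviance
#' between observed bin counts and `n_pairs` times the per-pair
#' expectation of [expected_spectrum()], plus a second-difference
#' smoothness penalty on `log N_g`. Optimization is multi-start
#' (deterministic starts) L-BFGS-B; confidence intervals come from
#' refitting Poisson-resampled bin counts.
#'
#' @param spectrum An `ibd_spectrum` from [tract_spectrum()], or a data
#'   frame with `bin_lo` and `count`.
#' @param n_pairs Number of haplotype pairs the spectrum was computed
#'   from.
#' @param epochs Integer vector of epoch assignments for generations
#'   `1..G` (non-decreasing, e.g. `rep(1:5, each = 5)`), or a single
#'   integer G for one free parameter per generation.
#' @param min_length_cm Fit only bins at or above this length. Default 3.
#' @param genome_cm,n_chrom Genome size the spectrum refers to.
#' @param fit_bin_cm Bin width used for fitting (observed bins are
#'   re-aggregated); wider bins stabilise the Poisson counts. Default 0.1.
#' @param max_length_cm Upper end of the fitted spectrum. Default 50.
#' @param lambda_smooth Smoothness penalty weight (applied to the
#'   per-pair-normalized deviance). Default 1e-4.
#' @param n_boot Bootstrap replicates for CIs. Default 0 (no CIs).
#' @param seed Optional seed (bootstrap only).
#' @return Object of class `ne_fit`: data frame `generation`, `ne`
#'   (+ `ci_lo`, `ci_hi` when bootstrapped), attributes `deviance`,
#'   `epochs`, `generation_time_years` (25).
#' @export
estimate_ne <- function(spectrum, n_pairs, epochs, min_length_cm = 3,
                        genome_cm = 3500, n_chrom = 22, fit_bin_cm = 0.1,
                        max_length_cm = 50, lambda_smooth = 1e-4,
                        n_boot = 0, seed = NULL) {
  if (length(epochs) == 1L) epochs <- seq_len(epochs)
  G <- length(epochs)
  if (G > 50L) stop("trajectory horizon G must be <= 50")
  if (any(diff(epochs) < 0) || epochs[1L] != 1L) {
    stop("'epochs' must be a non-decreasing assignment starting at 1")
  }
  n_ep <- max(epochs)
  breaks <- seq(min_length_cm, max_length_cm, by = fit_bin_cm)
  breaks <- c(breaks, Inf)
  if (length(breaks) - 1L < n_ep) stop("fewer bins than epochs")
  obs <- rebin_counts(spectrum, breaks)
  fit1 <- ne_deviance_fit(obs, n_pairs, epochs, breaks, genome_cm, n_chrom,
                          lambda_smooth)
  out <- data.frame(generation = seq_len(G), ne = fit1$ne[epochs])
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    bb <- matrix(NA_real_, n_boot, n_ep)
    for (b in seq_len(n_boot)) {
      ob <- stats::rpois(length(obs), pmax(obs, 0))
      bb[b, ] <- ne_deviance_fit(ob, n_pairs, epochs, breaks, genome_cm,
                                 n_chrom, lambda_smooth,
                                 start = log(fit1$ne))$ne
    }
    out$ci_lo <- apply(bb, 2L, stats::quantile, 0.025)[epochs]
    out$ci_hi <- apply(bb, 2L, stats::quantile, 0.975)[epochs]
  }
  structure(out, deviance = fit1$deviance, epochs = epochs,
            generation_time_years = 25, class = c("ne_fit", "data.frame"))
}

#' @exportS3Method print ne_fit
print.ne_fit <- function(x, ...) {
  cat(sprintf("<ne_fit> %d generations (%d epochs), deviance %.1f\n",
              nrow(x), length(unique(attr(x, "epochs"))), attr(x, "deviance")))
  gmin <- x$generation[which.min(x$ne)]
  cat(sprintf("  minimum Ne = %.0f at generation %d (~%d years ago)\n",
              min(x$ne), gmin, gmin * attr(x, "generation_time_years")))
  invisible(x)
}

#' @exportS3Method summary ne_fit
summary.ne_fit <- function(object, ...) {
  print(object)
  ep <- attr(object, "epochs")
  agg <- object[!duplicated(ep), , drop = FALSE]
  agg$epoch <- unique(ep)
  print(as.data.frame(agg), row.names = FALSE)
  invisible(object)
}

#' @exportS3Method plot ne_fit
plot.ne_fit <- function(x, ...) {
  graphics::plot(x$generation, x$ne, type = "s", log = "y",
                 xlab = "generations before present",
                 ylab = expression(N[e]), ...)
  if (!is.null(x$ci_lo)) {
    graphics::lines(x$generation, x$ci_lo, type = "s", lty = 2)
    graphics::lines(x$generation, x$ci_hi, type = "s", lty = 2)
  }
  invisible(x)
}

rebin_counts <- function(spectrum, breaks) {
  lens <- rep(spectrum$bin_lo, spectrum$count)
  bin <- findInterval(lens, breaks)
  keep <- bin >= 1L & bin <= length(breaks) - 1L
  tabulate(bin[keep], nbins = length(breaks) - 1L)
}

ne_deviance_fit <- function(obs, n_pairs, epochs, breaks, genome_cm, n_chrom,
                            lambda_smooth, start = NULL) {
  n_ep <- max(epochs)
  objective <- function(logn) {
    ne <- exp(logn)[epochs]
    mu <- n_pairs * expected_spectrum(ne, genome_cm, n_chrom, breaks)
    mu <- pmax(mu, 1e-12)
    dev <- 2 * sum(mu - obs + ifelse(obs > 0, obs * log(obs / mu), 0))
    logn_g <- logn[epochs]
    pen <- if (length(logn_g) >= 3L) sum(diff(logn_g, differences = 2)^2) else 0
    # per-pair normalization makes the fit invariant to scaling counts
    # and pairs together
    dev / n_pairs + lambda_smooth * pen
  }
  run <- function(par, obj) {
    stats::optim(par, obj, method = "L-BFGS-B", lower = log(2),
                 upper = log(1e7), control = list(maxit = 1000, factr = 1e4))
  }
  # coarse-to-fine: constant profile, then a handful of coarse blocks,
  # then the full epoch set -- finds localized features (bottlenecks)
  # that flat starts miss
  const_fit <- stats::optimize(function(x) objective(rep(x, n_ep)),
                               interval = log(c(10, 1e6)))
  warm <- rep(const_fit$minimum, n_ep)
  for (n_block in c(3L, 6L)) {
    if (n_ep <= n_block) break
    block <- ceiling(seq_len(n_ep) / (n_ep / n_block))
    bfit <- run(tapply(warm, block, mean),
                function(pb) objective(pb[block]))
    warm <- bfit$par[block]
  }
  starts <- list(warm, rep(const_fit$minimum, n_ep),
                 rep(log(1000), n_ep), rep(log(10000), n_ep),
                 seq(log(50000), log(1000), length.out = n_ep),
                 seq(log(1000), log(50000), length.out = n_ep))
  if (!is.null(start)) starts <- c(list(start), starts)
  best <- NULL
  for (s in starts) {
    fit <- run(s, objective)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  list(ne = exp(best$par), deviance = best$value)
}
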