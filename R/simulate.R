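#' Simulation configuration for a founder-population cohort
#'
#' Bundles the parameters of the forward Wright-Fisher generator. The
#' default demography is a bottlenecked founder population: ancestral
#' size 10000 (generations 15 and older), a dip to 2500 during
#' generations 9--14, and growth to 50000 in the most recent 8
#' generations, over `n_generations = 25` generations in total.
#'
#' A rare variant is planted on a single founder haplotype chosen so that
#' the realized carrier rate approximates `planted_carrier_rate`
#' (default 2\%, i.e. ~1 carrier in 50). Founder populations show marked
#' homozygote excess relative to panmixia, so a deterministic
#' `round(n_samples * hom_rate)` individuals are generated from endogamous
#' unions of two carrier parents with forced transmission of the carrying
#' haplotype at the planted site; under random mating a planted haplotype
#' at frequency ~1\% would essentially never yield the several homozygotes
#' that a recessive design needs to be estimable.
#'
#' @param n_samples Number of diploid samples drawn from the final
#'   generation.
#' @param n_sites Number of biallelic marker sites.
#' @param chrom_length_cm Chromosome length in cM (uniform 1 cM = 1 Mb).
#' @param ne_trajectory Integer vector of effective sizes, element `g`
#'   giving Ne at generation `g` before present, length `n_generations`.
#' @param n_generations Number of generations simulated.
#' @param founder_maf_shape Shape parameters of the Beta distribution of
#'   founder allele frequencies, truncated to \[0.02, 0.98).
#' @param planted_carrier_rate Target carrier (heterozygote) rate of the
#'   planted variant; `0` disables planting.
#' @param hom_rate Fraction of samples produced by endogamous carrier
#'   unions (planted homozygotes).
#' @param beta_hom Homozygote trait shift in s.d. units (recessive).
#' @param h2_poly Variance of the polygenic trait component, in \[0, 1).
#' @param code_specs Data frame with columns `code`, `prev`, `or`: ICD9
#'   code label, baseline prevalence, and carrier odds ratio.
#' @param seed Mandatory integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 500,
                       n_sites = 1000,
                       chrom_length_cm = 100,
                       ne_trajectory = default_ne_trajectory(n_generations),
                       n_generations = 25,
                       founder_maf_shape = c(0.8, 0.8),
                       planted_carrier_rate = 0.02,
                       hom_rate = 0.002,
                       beta_hom = -3.78,
                       h2_poly = 0.4,
                       code_specs = default_code_specs(),
                       seed) {
  if (missing(seed)) stop("'seed' is mandatory")
  if (any(ne_trajectory < 2)) stop("all Ne must be >= 2")
  if (length(ne_trajectory) != n_generations) {
    stop("ne_trajectory must have one entry per generation")
  }
  if (planted_carrier_rate < 0 || planted_carrier_rate >= 0.5) {
    stop("planted_carrier_rate must be in [0, 0.5)")
  }
  structure(list(
    n_samples = as.integer(n_samples), n_sites = as.integer(n_sites),
    chrom_length_cm = chrom_length_cm, ne_trajectory = ne_trajectory,
    n_generations = as.integer(n_generations),
    founder_maf_shape = founder_maf_shape,
    planted_carrier_rate = planted_carrier_rate, hom_rate = hom_rate,
    beta_hom = beta_hom, h2_poly = h2_poly, code_specs = code_specs,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Default bottleneck demography
#'
#' @param n_generations Trajectory length.
#' @return Integer vector of Ne by generation before present.
#' @export
default_ne_trajectory <- function(n_generations = 25) {
  g <- seq_len(n_generations)
  ifelse(g < 9, 50000L, ifelse(g <= 14, 2500L, 10000L))
}

#' Default diagnosis-code generating model
#'
#' Three musculoskeletal-style codes enriched in carriers (odds ratios in
#' the 5--35 range at sub-percent baseline prevalence) plus null codes.
#'
#' @return Data frame with columns `code`, `prev`, `or`.
#' @export
default_code_specs <- function() {
  data.frame(
    code = c("730.08", "721.00", "716.98", "622.10", "789.10",
             "401.10", "250.00", "530.81"),
    prev = c(0.0013, 0.0165, 0.0107, 0.0138, 0.0038, 0.25, 0.12, 0.08),
    or = c(34.5, 5.4, 5.8, 5.4, 11.6, 1, 1, 1),
    stringsAsFactors = FALSE
  )
}

#' Simulate a founder-population cohort with known ground truth
#'
#' Runs a forward Wright-Fisher simulation with founder-label copying:
#' founder haplotypes carry unique labels, each offspring haplotype is a
#' recombinant mosaic of one parent's two haplotypes (crossovers Poisson
#' with rate 1 per Morgan), and true IBD between two final haplotypes is a
#' maximal run of equal founder labels. Marker alleles are copied from
#' founder haplotypes whose allele frequencies are drawn from a truncated
#' Beta distribution, so true IBD is exact by construction.
#'
#' @param config A [sim_config()].
#' @param truth_segments Compute the all-pairs true IBD segment list
#'   (quadratic in haplotype count; disable for large cohorts where only
#'   the planted dosage is needed). Default `TRUE`.
#' @param truth_floor_cm Reporting floor for true segments (cM).
#' @return A list of class `sim_cohort` with elements `panel`
#'   ([haplotype_panel()]), `pheno` (`phenotype_table`), `map`
#'   ([genetic_map()]) and `truth` (list: `planted_site_index`,
#'   `planted_label`, `dosage`, `liability`, `segments`).
#' @export
simulate_cohort <- function(config, truth_segments = TRUE,
                            truth_floor_cm = 0.2) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  morgans <- config$chrom_length_cm / 100
  n_hom <- if (config$planted_carrier_rate > 0) {
    as.integer(round(n * config$hom_rate))
  } else 0L
  sim <- wf_simulate_cpp(
    ne = as.numeric(config$ne_trajectory), n_samples = n, morgans = morgans,
    planted_pos = morgans / 2,
    target_freq = config$planted_carrier_rate / 2, n_hom = n_hom,
    min_freq = config$planted_carrier_rate / 10
  )
  # shuffle individuals so endogamous offspring are not grouped at the end
  perm <- sample.int(n)
  hap_perm <- as.vector(rbind(2L * perm - 1L, 2L * perm))
  mos <- reorder_mosaic(sim, hap_perm)
  m <- config$n_sites
  bp <- round((seq_len(m) - 0.5) / m * config$chrom_length_cm * 1e6)
  site_pos_m <- bp / 1e8
  p <- rbeta_truncated(m, config$founder_maf_shape)
  H <- build_alleles_cpp(mos$off, mos$end, mos$lab, site_pos_m, p)
  carries <- sim$hap_carries[hap_perm]
  planted_site <- if (config$planted_carrier_rate > 0) {
    which.min(abs(site_pos_m - morgans / 2))
  } else NA_integer_
  if (!is.na(planted_site)) H[, planted_site] <- as.integer(carries)
  samples <- sprintf("S%04d", seq_len(n))
  sites <- data.frame(chrom = "1", bp = bp, allele0 = "A", allele1 = "G",
                      stringsAsFactors = FALSE)
  panel <- haplotype_panel(samples, sites, H)
  map <- genetic_map("1", bp = c(0, config$chrom_length_cm * 1e6),
                     cm = c(0, config$chrom_length_cm))
  dosage <- carries[seq(1L, 2L * n, by = 2L)] + carries[seq(2L, 2L * n, by = 2L)]
  trait <- simulate_trait(dosage, beta_hom = config$beta_hom,
                          h2_poly = config$h2_poly)
  segs <- NULL
  if (truth_segments) {
    ts <- true_segments_cpp(mos$off, mos$end, mos$lab, truth_floor_cm / 100)
    segs <- hap_pairs_to_segments(ts$hap_i, ts$hap_j,
                                  ts$start_m * 1e8, ts$end_m * 1e8,
                                  samples, chrom = "1", map = map)
  }
  pheno <- make_pheno(samples, trait, dosage, config)
  structure(list(
    panel = panel, pheno = pheno, map = map,
    truth = list(planted_site_index = planted_site,
                 planted_label = sim$planted_label,
                 dosage = as.integer(dosage), liability = trait,
                 hap_carries = as.logical(carries), segments = segs)
  ), class = "sim_cohort")
}

#' @exportS3Method print sim_cohort
print.sim_cohort <- function(x, ...) {
  cat(sprintf(
    "<sim_cohort> %d samples, %d sites; planted dosage: %d het, %d hom\n",
    length(x$panel$samples), ncol(x$panel$H),
    sum(x$truth$dosage == 1L), sum(x$truth$dosage == 2L)
  ))
  invisible(x)
}

# reorder the flat mosaic arrays to a new haplotype order
reorder_mosaic <- function(sim, hap_perm) {
  nseg <- diff(sim$off)
  starts <- sim$off[-length(sim$off)]
  idx <- sequence(nseg[hap_perm]) + rep(starts[hap_perm], nseg[hap_perm])
  list(off = c(0L, cumsum(nseg[hap_perm])),
       end = sim$end[idx], lab = sim$lab[idx])
}

rbeta_truncated <- function(m, shape, lo = 0.02, hi = 0.98) {
  p <- stats::rbeta(m, shape[1L], shape[2L])
  bad <- p < lo | p >= hi
  while (any(bad)) {
    p[bad] <- stats::rbeta(sum(bad), shape[1L], shape[2L])
    bad <- p < lo | p >= hi
  }
  p
}

# convert 0-based haplotype-index pairs to a canonical segment table
hap_pairs_to_segments <- function(hap_i, hap_j, bp_start, bp_end,
                                  samples, chrom, map,
                                  n_sites = NA_integer_,
                                  n_mismatch = 0L) {
  si <- hap_i %/% 2L + 1L
  sj <- hap_j %/% 2L + 1L
  hi <- hap_i %% 2L
  hj <- hap_j %% 2L
  swap <- sj < si | (sj == si & hj < hi)
  s1 <- ifelse(swap, sj, si); h1 <- ifelse(swap, hj, hi)
  s2 <- ifelse(swap, si, sj); h2 <- ifelse(swap, hi, hj)
  cm_start <- cm_at(map, bp_start)
  cm_end <- cm_at(map, bp_end)
  ibd_segments(data.frame(
    sample1 = samples[s1], hap1 = h1, sample2 = samples[s2], hap2 = h2,
    chrom = chrom, bp_start = bp_start, bp_end = bp_end,
    cm_start = cm_start, cm_end = cm_end, length_cm = cm_end - cm_start,
    n_sites = n_sites, n_mismatch = n_mismatch, stringsAsFactors = FALSE
  ))
}

make_pheno <- function(samples, trait, dosage, config) {
  n <- length(samples)
  sex <- ifelse(stats::runif(n) < 0.5, "F", "M")
  age <- round(stats::runif(n, 20, 79))
  mean_in <- ifelse(sex == "M", 68.2, 62.8)
  sd_in <- ifelse(sex == "M", 3.2, 2.8)
  # mild age-related height decline so the age adjustment has work to do
  logh <- log(mean_in) - 0.0004 * (age - 50) + trait * (sd_in / mean_in)
  codes <- simulate_codes(dosage, config$code_specs,
                          covariates = data.frame(age = age, sex = sex))
  dat <- data.frame(
    sample = samples, sex = sex, age = age,
    height_raw = exp(logh), birthplace = "simulated",
    carrier_status = as.integer(dosage), stringsAsFactors = FALSE
  )
  dat$icd9_codes <- codes
  class(dat) <- c("phenotype_table", "data.frame")
  dat
}

#' Simulate a recessive quantitative trait
#'
#' Trait on the z scale: `beta_hom` for planted homozygotes (dosage 2;
#' heterozygotes receive no effect), plus a polygenic component of variance
#' `h2_poly` and residual noise of variance `1 - h2_poly`.
#'
#' @param truth A `sim_cohort` truth list, or directly an integer dosage
#'   vector in \{0, 1, 2\}.
#' @param beta_hom Homozygote shift in s.d. units; `abs(beta_hom) <= 10`.
#' @param h2_poly Polygenic variance fraction in \[0, 1).
#' @param seed Optional seed (the caller's RNG stream is used otherwise).
#' @return Numeric trait vector.
#' @export
simulate_trait <- function(truth, beta_hom = -3.78, h2_poly = 0.4,
                           seed = NULL) {
  dosage <- if (is.list(truth)) truth$dosage else truth
  if (abs(beta_hom) > 10) stop("'beta_hom' must satisfy abs(beta_hom) <= 10")
  if (h2_poly < 0 || h2_poly >= 1) stop("'h2_poly' must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  n <- length(dosage)
  poly <- stats::rnorm(n, 0, sqrt(h2_poly))
  noise <- stats::rnorm(n, 0, sqrt(1 - h2_poly))
  beta_hom * (dosage == 2L) + poly + noise
}

#' Simulate carrier-enriched diagnosis codes
#'
#' Each code is Bernoulli per sample under a logistic model:
#' `logit(P) = logit(prev) + log(OR) * carrier + 0.01 * (age - 50) +
#' 0.1 * (sex == "F")`.
#'
#' @param truth A `sim_cohort` truth list or a dosage vector; carrier is
#'   `dosage >= 1`.
#' @param code_specs Data frame with columns `code`, `prev` (baseline
#'   prevalence in (0,1)) and `or` (carrier odds ratio > 0).
#' @param covariates Data frame with columns `age` and `sex`.
#' @param seed Optional seed.
#' @return List of character vectors: per-sample code sets.
#' @export
simulate_codes <- function(truth, code_specs, covariates, seed = NULL) {
  dosage <- if (is.list(truth) && !is.null(truth$dosage)) truth$dosage else truth
  if (any(code_specs$prev <= 0 | code_specs$prev >= 1)) {
    stop("baseline prevalence must be in (0, 1)")
  }
  if (any(code_specs$or <= 0)) stop("odds ratios must be positive")
  if (!is.null(seed)) set.seed(seed)
  carrier <- as.integer(dosage >= 1L)
  n <- length(carrier)
  eta_cov <- 0.01 * (covariates$age - 50) + 0.1 * (covariates$sex == "F")
  out <- vector("list", n)
  for (k in seq_len(nrow(code_specs))) {
    eta <- stats::qlogis(code_specs$prev[k]) + log(code_specs$or[k]) * carrier + eta_cov
    hit <- stats::runif(n) < stats::plogis(eta)
    idx <- which(hit)
    for (i in idx) out[[i]] <- c(out[[i]], code_specs$code[k])
  }
  lapply(out, function(x) if (is.null(x)) character() else x)
}

#' Simulate pairwise IBD segment lengths under a demography
#'
#' The closed-form fitting oracle: for each haplotype pair a coalescence
#' generation `g` is drawn from the coalescence distribution implied by the
#' trajectory (mass beyond the trajectory's horizon lumped at the final
#' generation), recombination breakpoints are placed as a Poisson process
#' of rate `2 g` per Morgan on each chromosome, and the resulting piece
#' lengths are emitted.
#'
#' @param ne_trajectory Effective sizes per generation before present.
#' @param n_pairs Number of haplotype pairs.
#' @param genome_cm Total genome length (cM).
#' @param n_chrom Number of equally long chromosomes.
#' @param seed Optional seed.
#' @param min_cm Only emit pieces at least this long (cM); keeps the
#'   output small when only the long-tract spectrum is needed.
#' @return Numeric vector of segment lengths in cM.
#' @export
simulate_pair_segments <- function(ne_trajectory, n_pairs, genome_cm = 3500,
                                   n_chrom = 22, seed = NULL, min_cm = 0) {
  if (!is.null(seed)) set.seed(seed)
  cg <- coalescence_pmf(ne_trajectory)
  G <- length(cg)
  g <- sample.int(G, n_pairs, replace = TRUE, prob = cg)
  chrom_m <- genome_cm / n_chrom / 100
  # pieces of a Poisson(rate) process on [0, l]: conditional on nb
  # breakpoints the nb + 1 spacings are l times a Dirichlet(1, ..., 1)
  # vector, i.e. normalized iid exponentials -- no sorting required
  chunk <- 2000L
  out <- vector("list", ceiling(n_pairs / chunk))
  for (ci in seq_along(out)) {
    sel <- ((ci - 1L) * chunk + 1L):min(ci * chunk, n_pairs)
    rate <- rep(2 * g[sel], each = n_chrom)
    nb <- stats::rpois(length(rate), rate * chrom_m)
    npiece <- nb + 1L
    grp <- rep.int(seq_along(npiece), npiece)
    e <- stats::rexp(sum(npiece))
    tot <- rowsum(e, grp, reorder = FALSE)
    lens <- e / tot[grp] * chrom_m * 100
    out[[ci]] <- lens[lens >= min_cm]
  }
  unlist(out, use.names = FALSE)
}

#' Coalescence-time distribution of a haplotype pair
#'
#' `c(g) = (1 / (2 N_g)) * prod_{j < g} (1 - 1 / (2 N_j))`, with the
#' residual mass beyond the trajectory horizon assigned to the final
#' generation.
#'
#' @param ne_trajectory Effective sizes per generation before present.
#' @return Probability vector over generations `1..G`, summing to one.
#' @export
coalescence_pmf <- function(ne_trajectory) {
  if (any(ne_trajectory < 2)) stop("all Ne must be >= 2")
  G <- length(ne_trajectory)
  surv <- cumprod(1 - 1 / (2 * ne_trajectory))
  cg <- (1 / (2 * ne_trajectory)) * c(1, surv[-G])
  cg[G] <- cg[G] + surv[G]
  cg
}
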