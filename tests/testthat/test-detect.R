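test_that("a perfectly shared region is reported as one full-length segment", {
  fx <- uniform_map_panel(6, 500, cm_per_site = 0.1, seed = 21)
  # identical block of 101 markers = 10 cM between two haplotypes
  fx$panel <- plant_block(fx$panel, 1, 3, 101, 201)
  segs <- detect_ibd(fx$panel, fx$map)
  expect_equal(nrow(segs), 1L)
  expect_gte(segs$length_cm, 10)
  expect_equal(segs$n_mismatch, 0L)
  expect_lte(segs$bp_start, fx$panel$sites$bp[101])
  expect_gte(segs$bp_end, fx$panel$sites$bp[201])
})

test_that("an identical run just under the length threshold is not reported", {
  fx <- uniform_map_panel(4, 500, cm_per_site = 0.1, seed = 22)
  # 30 markers span 2.9 cM < 3 cM
  fx$panel <- plant_block(fx$panel, 1, 3, 101, 130)
  expect_equal(nrow(detect_ibd(fx$panel, fx$map)), 0L)
  # one marker more reaches 3.0 cM and is reported
  fx$panel <- plant_block(fx$panel, 1, 3, 101, 131)
  segs <- detect_ibd(fx$panel, fx$map)
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$length_cm, 3)
})

test_that("with a zero error budget the detector equals the brute-force oracle", {
  # markers every 0.05 cM: any >=3 cM run spans >=61 markers, so it always
  # contains an aligned identical word of 25 markers and is seedable
  for (rep in 1:50) {
    set.seed(3000 + rep)
    n_hap <- 2 * sample(2:10, 1)
    n_sites <- sample(200:500, 1)
    fx <- uniform_map_panel(n_hap, n_sites, cm_per_site = 0.05)
    for (b in seq_len(sample(1:4, 1))) {
      rows <- sample(n_hap, 2)
      len <- sample(50:150, 1)
      from <- sample(n_sites - len - 1, 1) + 1
      fx$panel <- plant_block(fx$panel, rows[1], rows[2], from, from + len)
    }
    segs <- detect_ibd(fx$panel, fx$map,
                       ibd_params(min_m = 3, err_het = 0, bits = 25))
    oracle <- brute_force_ibd(fx$panel, fx$cm, min_m = 3)
    got <- sort(segments_to_keys(segs, fx$panel))
    want <- sort(sprintf("%d:%d:%d:%d", oracle$hap_i, oracle$hap_j,
                         oracle$s0, oracle$s1))
    expect_identical(got, want, info = paste("rep", rep))
  }
})

test_that("detection is invariant under permuting the sample order", {
  cfg <- sim_config(n_samples = 60, n_sites = 600, seed = 31)
  coh <- simulate_cohort(cfg, truth_segments = FALSE)
  segs <- detect_ibd(coh$panel, coh$map)
  perm <- sample(length(coh$panel$samples))
  hap_perm <- as.vector(rbind(2L * perm - 1L, 2L * perm))
  panel2 <- haplotype_panel(coh$panel$samples[perm], coh$panel$sites,
                            coh$panel$H[hap_perm, , drop = FALSE])
  segs2 <- detect_ibd(panel2, coh$map)
  key <- function(s) {
    a <- sprintf("%s|%d", s$sample1, s$hap1)
    b <- sprintf("%s|%d", s$sample2, s$hap2)
    sort(sprintf("%s--%s:%0.0f-%0.0f", pmin(a, b), pmax(a, b),
                 s$bp_start, s$bp_end))
  }
  expect_identical(key(segs), key(segs2))
})

test_that("raising the length cutoff only removes or preserves segments", {
  cfg <- sim_config(n_samples = 80, n_sites = 800, seed = 32)
  coh <- simulate_cohort(cfg, truth_segments = FALSE)
  s3 <- detect_ibd(coh$panel, coh$map, ibd_params(min_m = 3))
  s5 <- detect_ibd(coh$panel, coh$map, ibd_params(min_m = 5))
  expect_lte(nrow(s5), nrow(s3))
  # every min_m = 5 segment is contained in a min_m = 3 segment
  k3 <- paste(s3$sample1, s3$hap1, s3$sample2, s3$hap2)
  k5 <- paste(s5$sample1, s5$hap1, s5$sample2, s5$hap2)
  contained <- vapply(seq_len(nrow(s5)), function(i) {
    j <- which(k3 == k5[i] & s3$bp_start <= s5$bp_start[i] &
                 s3$bp_end >= s5$bp_end[i])
    length(j) > 0
  }, logical(1))
  expect_true(all(contained))
})

test_that("the detector recovers most long true segments on simulated cohorts", {
  cfg <- sim_config(n_samples = 250, seed = 33)
  coh <- simulate_cohort(cfg, truth_segments = TRUE)
  segs <- detect_ibd(coh$panel, coh$map)
  truth <- coh$truth$segments
  long <- truth[truth$length_cm >= 5, , drop = FALSE]
  expect_gt(nrow(long), 50)
  kd <- paste(segs$sample1, segs$hap1, segs$sample2, segs$hap2)
  kt <- paste(long$sample1, long$hap1, long$sample2, long$hap2)
  recovered <- vapply(seq_len(nrow(long)), function(i) {
    j <- which(kd == kt[i])
    if (!length(j)) return(FALSE)
    ov <- pmin(segs$bp_end[j], long$bp_end[i]) -
      pmax(segs$bp_start[j], long$bp_start[i])
    any(ov >= 0.5 * (long$bp_end[i] - long$bp_start[i]) &
          ov >= 0.5 * (segs$bp_end[j] - segs$bp_start[j]))
  }, logical(1))
  expect_gte(mean(recovered), 0.9)
})

test_that("pairwise sharing sums tracts per sample pair", {
  segs <- ibd_segments(data.frame(
    sample1 = c("A", "A", "A"), hap1 = c(0L, 1L, 0L),
    sample2 = c("B", "B", "C"), hap2 = c(0L, 0L, 1L),
    chrom = "1", bp_start = c(0, 2e7, 0), bp_end = c(4e6, 25e6, 6e6),
    cm_start = NA_real_, cm_end = NA_real_, length_cm = c(4, 5, 6),
    n_sites = 1L, n_mismatch = 0L, stringsAsFactors = FALSE
  ))
  ps <- sum_pairwise_sharing(segs)
  expect_equal(ps$total_cm[ps$sample1 == "A" & ps$sample2 == "B"], 9)
  expect_equal(ps$n_tracts[ps$sample1 == "A" & ps$sample2 == "B"], 2L)
  expect_equal(nrow(ps), 2L)
  expect_equal(nrow(sum_pairwise_sharing(empty_segments())), 0L)
})

test_that("detected pair sharing tracks true pair sharing on simulations", {
  cfg <- sim_config(n_samples = 250, seed = 34)
  coh <- simulate_cohort(cfg, truth_segments = TRUE)
  det <- sum_pairwise_sharing(detect_ibd(coh$panel, coh$map))
  tru <- coh$truth$segments
  tru <- sum_pairwise_sharing(tru[tru$length_cm >= 3, , drop = FALSE])
  key <- function(d) paste(d$sample1, d$sample2)
  common <- intersect(key(det), key(tru))
  expect_gt(length(common), 100)
  r <- cor(det$total_cm[match(common, key(det))],
           tru$total_cm[match(common, key(tru))])
  expect_gt(r, 0.8)
})
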