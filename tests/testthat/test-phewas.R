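test_that("the code matrix applies the minimum-carrier-observation filter", {
  codes <- list(c("730.08", "721.00"), c("730.08"), c("730.08", "721.00"),
                c("721.00"), character(), c("730.08"))
  carrier <- c(1L, 1L, 1L, 0L, 0L, 1L)
  M <- build_code_matrix(codes, carrier, min_carrier_obs = 3)
  expect_equal(colnames(M), "730.08")  # 721.00 seen in only 2 carriers
  expect_equal(unname(attr(M, "carrier_counts")), 4)
  expect_equal(nrow(M), 6L)  # empty-record sample keeps its all-zero row
  expect_equal(sum(M[5, ]), 0)
  expect_error(build_code_matrix(codes, c(2L, carrier[-1])), "homozygotes")
  # Table-2-style carrier percentage arithmetic: 3 of 106 = 2.8%
  expect_equal(round(100 * 3 / 106, 1), 2.8)
})

test_that("the three engines agree on a balanced common outcome", {
  set.seed(21)
  n <- 4000
  carrier <- rbinom(n, 1, 0.5)
  eta <- -0.6 + 0.35 * carrier
  y <- rbinom(n, 1, plogis(eta))
  M <- matrix(y, ncol = 1, dimnames = list(NULL, "code"))
  ps <- lapply(c("glm", "firth", "spa"), function(m) {
    phewas_test(M, carrier, method = m)$p
  })
  expect_lt(abs(ps[[1]] - ps[[2]]) / ps[[1]], 0.1)
  expect_lt(abs(ps[[1]] - ps[[3]]) / ps[[1]], 0.1)
  # and the glm odds ratio is near the generating one
  or <- phewas_test(M, carrier, method = "glm")$or
  expect_lt(abs(log(or) - 0.35), 0.2)
})

test_that("Firth regression stays finite under complete separation", {
  # quasi-separated toy: every case is a carrier
  y <- c(rep(1, 3), rep(0, 40))
  carrier <- c(rep(1, 3), rep(0, 20), rep(1, 20))
  M <- matrix(y, ncol = 1, dimnames = list(NULL, "x"))
  g <- phewas_test(M, carrier, method = "glm")
  f <- phewas_test(M, carrier, method = "firth")
  expect_false(g$converged)
  expect_true(is.finite(f$or) && f$or > 0)
  expect_true(f$converged)
  # 100 random separated data sets all give finite Firth estimates
  set.seed(22)
  for (r in 1:100) {
    n <- sample(20:60, 1)
    x <- rbinom(n, 1, runif(1, 0.2, 0.8))
    y <- x  # complete separation
    fit <- firth_fit(cbind(1, x), y)
    expect_true(all(is.finite(fit$beta)))
    expect_lt(abs(fit$beta[2]), 20)
  }
})

test_that("the saddlepoint tail matches the normal tail for balanced designs", {
  set.seed(23)
  n <- 10000
  carrier <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, 0.5 + 0.012 * carrier)
  fit0 <- glm(y ~ 1, family = binomial())
  mu <- fitted(fit0)
  g <- carrier - mean(carrier)
  s <- sum(g * (y - mu))
  p_spa <- 2 * min(as.numeric(ibdmapr:::spa_tail(abs(s), g, mu)), 0.5)
  p_norm <- 2 * pnorm(abs(s) / sqrt(sum(mu * (1 - mu) * g^2)),
                      lower.tail = FALSE)
  expect_lt(abs(p_spa - p_norm) / p_norm, 0.05)
})

test_that("Benjamini-Hochberg adjustment matches the hand computation", {
  expect_equal(fdr_bh(0.01)$p_adjusted, 0.01)
  p <- c(0.01, 0.02, 0.03)
  expect_equal(fdr_bh(p)$p_adjusted, c(0.03, 0.03, 0.03))
  expect_equal(fdr_bh(p)$p_adjusted, bh_oracle(p))
  expect_false(any(fdr_bh(rep(1, 5))$significant))
  # random vectors agree with the oracle and stay monotone in p order
  set.seed(24)
  for (r in 1:20) {
    p <- runif(sample(3:30, 1))
    adj <- fdr_bh(p)$p_adjusted
    expect_equal(adj, bh_oracle(p))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
  expect_error(fdr_bh(c(0.5, 0)), "0, 1")
})

test_that("exact 2x2 tests match hypergeometric enumeration", {
  # chart-review comparison: 13/34 carriers vs 4/31 controls
  t1 <- matrix(c(13, 21, 4, 27), 2, byrow = TRUE)
  expect_lte(fisher_exact(t1, "one")$p, 0.03)
  # closed-form enumeration oracle for [[5,29],[0,31]]
  t2 <- matrix(c(5, 29, 0, 31), 2, byrow = TRUE)
  expect_equal(fisher_exact(t2, "one")$p, choose(34, 5) / choose(65, 5),
               tolerance = 1e-10)
  expect_equal(round(fisher_exact(t2, "one")$p, 3), 0.034)
  # symmetric table
  expect_equal(fisher_exact(matrix(1, 2, 2))$p, 1)
  # two-sided point-probability rule against direct enumeration
  set.seed(25)
  for (r in 1:20) {
    tab <- matrix(rpois(4, 6), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    m <- sum(tab[1, ]); nn <- sum(tab[2, ]); k <- sum(tab[, 1])
    x <- tab[1, 1]
    support <- max(0, k - nn):min(k, m)
    probs <- dhyper(support, m, nn, k)
    p_enum <- sum(probs[probs <= dhyper(x, m, nn, k) * (1 + 1e-7)])
    expect_equal(fisher_exact(tab, "two")$p, p_enum, tolerance = 1e-7)
  }
  # zero margin: p = 1 and the odds ratio is flagged undefined
  z <- fisher_exact(matrix(c(0, 0, 3, 4), 2, byrow = TRUE))
  expect_equal(z$p, 1)
  expect_true(z$or_undefined)
  expect_error(fisher_exact(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("chart-review tables recompute percentages from counts", {
  group <- rep(c("carrier", "control"), c(34, 31))
  spine <- c(rep(TRUE, 13), rep(FALSE, 21), rep(TRUE, 4), rep(FALSE, 27))
  stenosis <- c(rep(TRUE, 5), rep(FALSE, 29), rep(FALSE, 31))
  tab <- chart_review_table(list(spine_degeneration = spine,
                                 cervical_stenosis = stenosis), group)
  expect_equal(tab$pct1, c(38, 15))  # 13/34 = 38%, 5/34 = 15%
  expect_equal(tab$pct2, c(13, 0))   # 4/31 = 13%, 0/31 = 0%
  expect_lte(tab$p_one_sided[1], 0.03)
  expect_lte(tab$p_one_sided[2], 0.05)
  expect_error(chart_review_table(list(x = spine), rep("a", 65)), "two levels")
})

test_that("phewas results are internally consistent and deterministic", {
  cfg <- sim_config(n_samples = 1200, n_sites = 100, seed = 26)
  coh <- simulate_cohort(cfg, truth_segments = FALSE)
  keep <- coh$truth$dosage < 2L
  ph <- coh$pheno[keep, ]
  carrier <- as.integer(coh$truth$dosage[keep] == 1L)
  M <- build_code_matrix(ph, carrier, min_carrier_obs = 3)
  expect_gt(ncol(M), 0)
  covar <- data.frame(age = ph$age, sex = ph$sex)
  res <- phewas_test(M, carrier, covar, method = "firth")
  # percentages recompute from counts
  expect_equal(res$pct_carrier, 100 * res$n_carrier_cases / sum(carrier == 1))
  expect_true(all(res$or > 0, na.rm = TRUE))
  expect_true(all(res$ci_lo <= res$or & res$or <= res$ci_hi, na.rm = TRUE))
  res2 <- phewas_test(M, carrier, covar, method = "firth")
  expect_identical(res, res2)
  # the strongly enriched planted code ranks first when present
  if ("730.08" %in% res$code && sum(M[carrier == 1, "730.08"]) >= 3) {
    expect_lte(res$p[res$code == "730.08"], sort(res$p)[2])
  }
})
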