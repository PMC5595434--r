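#' Build the binary diagnosis-code matrix
#'
#' Encodes each ICD9 code as 1 when present in a sample's record and 0
#' otherwise, then drops codes observed in fewer than `min_carrier_obs`
#' carriers -- the standard guard against spurious rare-code hits.
#' Homozygotes must be excluded upstream: the carrier vector may only
#' contain 0/1.
#'
#' @param pheno A `phenotype_table` with an `icd9_codes` list-column (or a
#'   plain list of per-sample code sets).
#' @param carrier Integer 0/1 vector aligned with samples.
#' @param min_carrier_obs Minimum carrier observations per retained code.
#' @return Object of class `code_matrix`: binary matrix samples x codes
#'   with attributes `carrier_counts` and `noncarrier_counts`.
#' @export
build_code_matrix <- function(pheno, carrier, min_carrier_obs = 3) {
  codes_list <- if (is.data.frame(pheno)) pheno$icd9_codes else pheno
  if (is.null(codes_list)) stop("no 'icd9_codes' column")
  if (any(carrier == 2L, na.rm = TRUE)) {
    stop("carrier vector contains homozygotes (dosage 2); exclude them upstream")
  }
  n <- length(codes_list)
  if (length(carrier) != n) stop("carrier vector length mismatch")
  all_codes <- sort(unique(unlist(codes_list)))
  M <- matrix(0L, n, length(all_codes),
              dimnames = list(NULL, all_codes))
  for (i in seq_len(n)) {
    M[i, match(unique(codes_list[[i]]), all_codes)] <- 1L
  }
  cc <- colSums(M[carrier == 1L, , drop = FALSE])
  keep <- cc >= min_carrier_obs
  M <- M[, keep, drop = FALSE]
  structure(M,
            carrier_counts = cc[keep],
            noncarrier_counts = colSums(M[carrier == 0L, , drop = FALSE]),
            n_carrier = sum(carrier == 1L),
            n_noncarrier = sum(carrier == 0L),
            class = c("code_matrix", "matrix", "array"))
}

#' Phenome-wide association of a rare carrier predictor
#'
#' Tests each binary diagnosis code against carrier status with the
#' chosen engine, adjusting for covariates:
#' \describe{
#'   \item{glm}{maximum-likelihood logistic regression, Wald p-value.}
#'   \item{firth}{Jeffreys-prior penalized logistic regression (Newton
#'     with step-halving, tolerance 1e-8, at most 50 iterations),
#'     penalized-likelihood-ratio p-value; estimates stay finite under
#'     separation.}
#'   \item{spa}{score test for the carrier coefficient after covariate
#'     projection, tail probability from a saddlepoint approximation of
#'     the score's cumulant generating function (safeguarded Newton,
#'     tolerance 1e-10), falling back to the normal approximation when
#'     the saddle solve fails (flagged).}
#' }
#'
#' @param codes A `code_matrix` from [build_code_matrix()] (or any binary
#'   matrix samples x codes).
#' @param carrier Integer 0/1 carrier vector.
#' @param covariates Optional numeric data frame/matrix (age, sex, PCs).
#' @param method `"glm"`, `"firth"` or `"spa"`.
#' @param fdr_q FDR level for the significance flags. Default 0.05.
#' @return Data frame of class `phewas_result`: `code`, `method`,
#'   `n_carrier_cases`, `pct_carrier`, `n_noncarrier_cases`,
#'   `pct_noncarrier`, `or`, `ci_lo`, `ci_hi`, `p`, `p_fdr`,
#'   `significant`, `converged`.
#' @export
phewas_test <- function(codes, carrier, covariates = NULL,
                        method = c("glm", "firth", "spa"), fdr_q = 0.05) {
  method <- match.arg(method)
  M <- unclass(codes)
  n <- nrow(M)
  carrier <- as.numeric(carrier)
  X <- cbind(`(Intercept)` = rep(1, n), make_numeric_covariates(covariates, n))
  res <- lapply(seq_len(ncol(M)), function(j) {
    y <- M[, j]
    eng <- switch(method,
                  glm = engine_glm(y, carrier, X),
                  firth = engine_firth(y, carrier, X),
                  spa = engine_spa(y, carrier, X))
    nc <- sum(y == 1 & carrier == 1)
    nn <- sum(y == 1 & carrier == 0)
    data.frame(
      code = colnames(M)[j] %||% as.character(j), method = method,
      n_carrier_cases = nc,
      pct_carrier = 100 * nc / sum(carrier == 1),
      n_noncarrier_cases = nn,
      pct_noncarrier = 100 * nn / sum(carrier == 0),
      or = eng$or, ci_lo = eng$ci[1L], ci_hi = eng$ci[2L], p = eng$p,
      converged = eng$converged, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  fdr <- fdr_bh(out$p, q = fdr_q)
  out$p_fdr <- fdr$p_adjusted
  out$significant <- fdr$significant
  rownames(out) <- NULL
  class(out) <- c("phewas_result", "data.frame")
  out
}

#' @exportS3Method print phewas_result
print.phewas_result <- function(x, ...) {
  cat(sprintf("<phewas_result> %d codes, method %s; %d significant at FDR\n",
              nrow(x), x$method[1L], sum(x$significant)))
  print(utils::head(as.data.frame(x[order(x$p), ]), 10L), row.names = FALSE)
  invisible(x)
}

make_numeric_covariates <- function(covariates, n) {
  if (is.null(covariates)) return(NULL)
  C <- as.data.frame(covariates)
  for (k in seq_along(C)) {
    if (!is.numeric(C[[k]])) C[[k]] <- as.numeric(factor(C[[k]])) - 1
  }
  C <- as.matrix(C)
  if (nrow(C) != n) stop("covariate rows must match samples")
  C
}

engine_glm <- function(y, carrier, X) {
  dat <- as.data.frame(X[, -1L, drop = FALSE])
  dat$y <- y
  dat$carrier <- carrier
  fit <- suppressWarnings(stats::glm(y ~ ., data = dat, family = stats::binomial()))
  co <- summary(fit)$coefficients
  if (!"carrier" %in% rownames(co) || !fit$converged ||
      abs(co["carrier", 1L]) > 15) {
    b <- if ("carrier" %in% rownames(co)) co["carrier", 1L] else NA_real_
    return(list(or = exp(b), ci = c(NA_real_, NA_real_),
                p = if ("carrier" %in% rownames(co)) co["carrier", 4L] else NA_real_,
                converged = FALSE))
  }
  b <- co["carrier", 1L]
  se <- co["carrier", 2L]
  list(or = exp(b), ci = exp(b + c(-1, 1) * 1.959964 * se),
       p = co["carrier", 4L], converged = TRUE)
}

# Jeffreys-prior penalized logistic regression
engine_firth <- function(y, carrier, X) {
  Xf <- cbind(X, carrier = carrier)
  full <- firth_fit(Xf, y)
  # profile fit: carrier coefficient pinned at 0 but the penalty still
  # uses the full design, as the penalized likelihood-ratio test requires
  red <- firth_fit(Xf, y, fixed = ncol(Xf))
  k <- ncol(Xf)
  b <- full$beta[k]
  se <- sqrt(full$cov[k, k])
  stat <- 2 * (full$loglik - red$loglik)
  p <- stats::pchisq(max(stat, 0), df = 1, lower.tail = FALSE)
  list(or = exp(b), ci = exp(b + c(-1, 1) * 1.959964 * se), p = p,
       converged = full$converged && red$converged)
}

#' Firth-penalized logistic regression
#'
#' Maximizes the Jeffreys-prior penalized log-likelihood
#' `l(beta) + 0.5 log det I(beta)` by Newton iterations with
#' step-halving. Estimates are finite even under complete separation.
#'
#' @param X Design matrix (including intercept).
#' @param y Binary response.
#' @param tol Convergence tolerance on the score. Default 1e-8.
#' @param max_iter Maximum Newton iterations. Default 50.
#' @param fixed Indices of coefficients constrained to zero (profile fits
#'   for the penalized likelihood-ratio test; the Jeffreys penalty keeps
#'   the full design).
#' @return List: `beta`, `cov` (inverse penalized information),
#'   `loglik` (penalized), `converged`.
#' @export
firth_fit <- function(X, y, tol = 1e-8, max_iter = 50, fixed = integer(0)) {
  X <- as.matrix(X)
  p <- ncol(X)
  free <- setdiff(seq_len(p), fixed)
  beta <- rep(0, p)
  penalized_ll <- function(beta) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    W <- mu * (1 - mu)
    info <- crossprod(X * W, X)
    ll <- sum(y * eta - log1p(exp(eta)))
    ll + 0.5 * determinant(info, logarithm = TRUE)$modulus
  }
  ll_old <- penalized_ll(beta)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    W <- mu * (1 - mu)
    XW <- X * W
    info <- crossprod(XW, X)
    info_inv <- solve(info)
    # hat diagonal of the weighted design (full design, even when some
    # coefficients are profiled out)
    h <- rowSums((X %*% info_inv) * XW)
    U <- drop(crossprod(X, y - mu + h * (0.5 - mu)))[free]
    if (max(abs(U)) < tol) {
      converged <- TRUE
      break
    }
    step <- numeric(p)
    step[free] <- drop(solve(info[free, free, drop = FALSE], U))
    # step-halving on the penalized likelihood
    lam <- 1
    repeat {
      ll_new <- penalized_ll(beta + lam * step)
      if (is.finite(ll_new) && ll_new >= ll_old - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-6) break
    }
    beta <- beta + lam * step
    ll_old <- penalized_ll(beta)
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  info <- crossprod(X * (mu * (1 - mu)), X)
  list(beta = beta, cov = solve(info), loglik = as.numeric(ll_old),
       converged = converged)
}

# saddlepoint-approximation score test for the carrier coefficient
engine_spa <- function(y, carrier, X) {
  null <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
  mu <- null$fitted.values
  W <- mu * (1 - mu)
  # project the carrier vector out of the covariate space under null weights
  XtWX <- crossprod(X * W, X)
  gtilde <- carrier - drop(X %*% solve(XtWX, crossprod(X * W, carrier)))
  s <- sum(gtilde * (y - mu))
  var_s <- sum(W * gtilde^2)
  if (var_s <= 0) return(list(or = NA_real_, ci = c(NA_real_, NA_real_),
                              p = NA_real_, converged = FALSE))
  tail <- spa_tail(abs(s), gtilde, mu)
  p2 <- 2 * min(as.numeric(tail), 0.5)
  # report the score-implied effect on the odds scale for reference
  b <- s / var_s
  se <- 1 / sqrt(var_s)
  list(or = exp(b), ci = exp(b + c(-1, 1) * 1.959964 * se),
       p = min(p2, 1), converged = isTRUE(attr(tail, "saddle")))
}

# P(S >= q) for S = sum g_i (y_i - mu_i) by Barndorff-Nielsen's formula
spa_tail <- function(q, g, mu, tol = 1e-10) {
  K <- function(t) sum(log(1 - mu + mu * exp(g * t))) - t * sum(g * mu)
  K1 <- function(t) sum(mu * g * exp(g * t) / (1 - mu + mu * exp(g * t))) -
    sum(g * mu)
  K2 <- function(t) {
    e <- exp(g * t)
    sum((1 - mu) * mu * g^2 * e / (1 - mu + mu * e)^2)
  }
  var_s <- sum(mu * (1 - mu) * g^2)
  z <- q / sqrt(var_s)
  normal_p <- stats::pnorm(z, lower.tail = FALSE)
  if (q == 0) return(structure(0.5, saddle = TRUE))
  # safeguarded Newton for K'(t) = q
  t <- q / var_s
  lo <- 0; hi <- NA_real_
  ok <- FALSE
  for (it in 1:100) {
    f <- K1(t) - q
    if (is.finite(f) && abs(f) < tol * max(1, q)) {
      ok <- TRUE
      break
    }
    if (!is.finite(f)) break
    if (f > 0) hi <- t else lo <- t
    d <- K2(t)
    tn <- if (is.finite(d) && d > 0) t - f / d else NA_real_
    if (!is.finite(tn) || tn <= lo || (!is.na(hi) && tn >= hi)) {
      tn <- if (is.na(hi)) 2 * t + 0.1 else (lo + hi) / 2
    }
    t <- tn
  }
  if (!ok || t <= 0) return(structure(normal_p, saddle = FALSE))
  w <- sqrt(2 * (t * q - K(t)))
  v <- t * sqrt(K2(t))
  if (!is.finite(w) || w <= 0 || !is.finite(v) || v <= 0 ||
      abs(w) < 1e-4) {
    return(structure(normal_p, saddle = FALSE))
  }
  structure(stats::pnorm(w + log(v / w) / w, lower.tail = FALSE), saddle = TRUE)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values (via [stats::p.adjust()]) and significance
#' flags at level `q`.
#'
#' @param p_values Numeric p-values in (0, 1].
#' @param q FDR level. Default 0.05.
#' @return List: `p_adjusted`, `significant`.
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  if (any(p_values <= 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must be in (0, 1]")
  }
  adj <- stats::p.adjust(p_values, method = "BH")
  list(p_adjusted = adj, significant = !is.na(adj) & adj < q)
}

#' Exact test for a 2x2 table
#'
#' Hypergeometric enumeration conditional on the margins. The two-sided
#' p-value uses the point-probability rule and the odds ratio is the
#' conditional maximum-likelihood estimate (both via
#' [stats::fisher.test()]); the one-sided p-value is the upper
#' (greater-association) hypergeometric tail computed directly.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @param sided `"two"` or `"one"`.
#' @return List: `p`, `or` (`NA` with `or_undefined = TRUE` when a margin
#'   is zero).
#' @export
fisher_exact <- function(tab, sided = c("two", "one")) {
  sided <- match.arg(sided)
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("table must contain non-negative integers")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(p = 1, or = NA_real_, or_undefined = TRUE))
  }
  ft <- stats::fisher.test(tab)
  p <- if (sided == "two") {
    ft$p.value
  } else {
    # upper tail: P(X >= tab[1,1]) with X ~ Hypergeom(margins)
    stats::phyper(tab[1L, 1L] - 1L, rowSums(tab)[1L], rowSums(tab)[2L],
                  colSums(tab)[1L], lower.tail = FALSE)
  }
  list(p = unname(p), or = unname(ft$estimate), or_undefined = FALSE)
}

#' Chart-review comparison table
#'
#' Builds a case/control characteristics table: per binary feature, the
#' count and percentage in each group and a Fisher exact p-value
#' (both sidedness conventions, since published comparisons rarely state
#' one).
#'
#' @param features Named list of logical vectors (one per feature),
#'   aligned with samples.
#' @param group Factor/vector with two levels; the first level is the
#'   carrier/case group.
#' @return Data frame: `feature`, `n1`, `pct1`, `n2`, `pct2`,
#'   `p_two_sided`, `p_one_sided`. Percentages are `round(100 k / n)`,
#'   recomputed from counts.
#' @export
chart_review_table <- function(features, group) {
  lev <- unique(group)
  if (length(lev) != 2L) stop("'group' must have exactly two levels")
  g1 <- group == lev[1L]
  g2 <- group == lev[2L]
  if (!any(g1) || !any(g2)) stop("empty group")
  out <- lapply(names(features), function(fn) {
    f <- features[[fn]]
    k1 <- sum(f & g1)
    k2 <- sum(f & g2)
    tab <- matrix(c(k1, sum(g1) - k1, k2, sum(g2) - k2), 2L, byrow = TRUE)
    data.frame(
      feature = fn, n1 = k1, pct1 = round(100 * k1 / sum(g1)),
      n2 = k2, pct2 = round(100 * k2 / sum(g2)),
      p_two_sided = fisher_exact(tab, "two")$p,
      p_one_sided = fisher_exact(tab, "one")$p,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}
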