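#' Sex-stratified, age-adjusted height z-scores
#'
#' Applies the standard adult inclusion window (females at least 18,
#' males at least 22, both under 80 years), log-transforms height, and
#' within each sex regresses log height on age; the z-score is the
#' studentized residual (residual divided by the residual standard
#' deviation), so included z-scores have mean ~0 and s.d. ~1 within sex.
#'
#' @param pheno A `phenotype_table` with `sample`, `sex`, `age`,
#'   `height_raw` (inches).
#' @return Data frame of class `trait_z`: `sample`, `z`, `included`,
#'   `reason` (exclusion reason or `""`).
#' @export
height_zscores <- function(pheno) {
  n <- nrow(pheno)
  reason <- rep("", n)
  reason[is.na(pheno$height_raw)] <- "missing height"
  young <- (pheno$sex == "F" & pheno$age < 18) |
    (pheno$sex == "M" & pheno$age < 22)
  reason[young & reason == ""] <- "below age minimum"
  reason[pheno$age >= 80 & reason == ""] <- "above age maximum"
  included <- reason == ""
  z <- rep(NA_real_, n)
  for (sx in unique(pheno$sex[included])) {
    sel <- included & pheno$sex == sx
    logh <- log(pheno$height_raw[sel])
    if (sum(sel) < 3L || stats::var(pheno$age[sel]) == 0) {
      z[sel] <- (logh - mean(logh)) / stats::sd(logh)
    } else {
      fit <- stats::lm(logh ~ age, data = data.frame(logh = logh,
                                                     age = pheno$age[sel]))
      r <- stats::residuals(fit)
      z[sel] <- r / stats::sd(r)
    }
  }
  out <- data.frame(sample = pheno$sample, z = z, included = included,
                    reason = reason, stringsAsFactors = FALSE)
  class(out) <- c("trait_z", "data.frame")
  out
}

#' Flag clinically short stature
#'
#' Short stature is a z-score at least two standard deviations below the
#' sex-specific mean; the boundary `z = -2` is inclusive.
#'
#' @param z Numeric z-score vector (sex-specific standardization done
#'   upstream, so no sex argument is needed beyond the z itself).
#' @return Logical vector.
#' @export
short_stature_flags <- function(z) {
  !is.na(z) & z <= -2
}

#' Recessive-model association scan over dosage columns
#'
#' For each dosage column with at least `min_hom` homozygotes, fits the
#' linear model `z ~ 1[dosage == 2] + covariates` by least squares and
#' reports the homozygote effect with a two-sided t-test. Columns with
#' fewer homozygotes are not tested; the Bonferroni threshold is
#' `alpha / m` over the `m` columns actually tested.
#'
#' @param dosage Integer matrix samples x predictors in \{0, 1, 2\}
#'   (e.g. from [encode_dosage()]).
#' @param z Trait vector aligned with the rows (NA rows are dropped).
#' @param covariates Optional numeric matrix/data frame of covariates
#'   (e.g. principal-component eigenvectors); collinear columns are
#'   dropped with a warning.
#' @param min_hom Minimum homozygote count for a predictor to be tested.
#' @param alpha Family-wise error rate for the Bonferroni threshold.
#' @return Data frame of class `recessive_scan`: `id`, `n`, `n_hom`,
#'   `freq`, `beta`, `se`, `p`; attributes `bonferroni` and `n_tested`.
#' @export
recessive_scan <- function(dosage, z, covariates = NULL, min_hom = 3,
                           alpha = 0.05) {
  if (min_hom < 1) stop("'min_hom' must be >= 1")
  dosage <- as.matrix(dosage)
  keep <- !is.na(z)
  z <- z[keep]
  dosage <- dosage[keep, , drop = FALSE]
  n <- length(z)
  X0 <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(covariates)) {
    C <- as.matrix(covariates)[keep, , drop = FALSE]
    X0 <- cbind(X0, C)
    qrX <- qr(X0)
    if (qrX$rank < ncol(X0)) {
      dropc <- setdiff(seq_len(ncol(X0)), qrX$pivot[seq_len(qrX$rank)])
      warning("dropping collinear covariate(s): ",
              paste(colnames(X0)[dropc], collapse = ", "))
      X0 <- X0[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    }
  }
  hom_counts <- colSums(dosage == 2L)
  test_cols <- which(hom_counts >= min_hom)
  res <- lapply(test_cols, function(j) {
    r <- as.numeric(dosage[, j] == 2L)
    if (stats::var(r) == 0) return(NULL)
    X <- cbind(X0, r = r)
    fit <- stats::lm.fit(X, z)
    rdf <- n - fit$rank
    s2 <- sum(fit$residuals^2) / rdf
    XtXinv <- chol2inv(qr.R(fit$qr))
    pos <- which(fit$qr$pivot == ncol(X))  # the recessive indicator column
    se <- sqrt(s2 * XtXinv[pos, pos])
    beta <- fit$coefficients["r"]
    data.frame(
      id = colnames(dosage)[j] %||% as.character(j), n = n,
      n_hom = hom_counts[j], freq = sum(dosage[, j]) / (2 * n),
      beta = beta, se = se,
      p = 2 * stats::pt(abs(beta / se), rdf, lower.tail = FALSE),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(id = character(), n = integer(), n_hom = integer(),
                      freq = numeric(), beta = numeric(), se = numeric(),
                      p = numeric(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "n_tested") <- nrow(out)
  attr(out, "bonferroni") <- if (nrow(out)) bonferroni_threshold(alpha, nrow(out)) else NA_real_
  class(out) <- c("recessive_scan", "data.frame")
  out
}

#' @exportS3Method print recessive_scan
print.recessive_scan <- function(x, ...) {
  cat(sprintf("<recessive_scan> %d predictors tested; Bonferroni p < %.3g\n",
              attr(x, "n_tested"), attr(x, "bonferroni")))
  print(utils::head(as.data.frame(x[order(x$p), ]), 10L), row.names = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bonferroni significance threshold
#'
#' @param alpha Family-wise error rate.
#' @param m Number of tests, `m >= 1`.
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (m < 1) stop("'m' must be >= 1")
  alpha / m
}

#' Genomic-control inflation factor
#'
#' `lambda = median(qchisq(1 - p, 1)) / 0.4549364` (the null median of a
#' 1-d.f. chi-square). `gc_adjust_p` converts p-values to their
#' genomic-control-adjusted version by deflating the implied chi-square
#' statistics by lambda.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return `genomic_lambda`: scalar lambda. `gc_adjust_p`: adjusted
#'   p-values.
#' @export
genomic_lambda <- function(p_values) {
  if (!length(p_values)) stop("empty p-value list")
  if (any(p_values <= 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must be in (0, 1]")
  }
  chisq <- stats::qchisq(stats::median(p_values, na.rm = TRUE), df = 1,
                         lower.tail = FALSE)
  chisq / stats::qchisq(0.5, df = 1)
}

#' @rdname genomic_lambda
#' @param lambda Inflation factor to adjust by (e.g. from
#'   [genomic_lambda()]).
#' @export
gc_adjust_p <- function(p_values, lambda = genomic_lambda(p_values)) {
  chisq <- stats::qchisq(p_values, df = 1, lower.tail = FALSE)
  stats::pchisq(chisq / lambda, df = 1, lower.tail = FALSE)
}
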