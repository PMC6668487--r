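#' Covariate residualization
#'
#' Removes covariate effects by ordinary least squares: `values` are
#' regressed on the covariates (plus intercept) and the residuals returned.
#' Subjects with any missing covariate are dropped (with a message); the
#' retained row indices are attached as attribute `"used"`. For rank-based
#' analyses, rank-transform the analysis variables before calling (the
#' covariates enter untransformed).
#'
#' @param values numeric vector, one value per subject.
#' @param covariates data.frame of numeric/binary covariates, same row
#'   order; factors/characters are expanded via `model.matrix`.
#' @return Residual vector of `length(values)` with `NA` at dropped rows.
#' @export
adjustCovariates <- function(values, covariates) {
  stopifnot(length(values) == nrow(covariates))
  keep <- complete.cases(covariates) & !is.na(values)
  if (!all(keep))
    message(sprintf("adjustCovariates: dropping %d subject(s) with missing values",
                    sum(!keep)))
  X <- stats::model.matrix(~ ., data = as.data.frame(covariates)[keep, , drop = FALSE])
  ## constant columns carry no information beyond the intercept
  const <- c(FALSE, apply(X[, -1, drop = FALSE], 2, function(col)
    length(unique(col)) == 1L))
  X <- X[, !const, drop = FALSE]
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])]
    stop("rank-deficient covariate matrix; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  res <- rep(NA_real_, length(values))
  res[keep] <- lm.fit(X, values[keep])$residuals
  attr(res, "used") <- which(keep)
  res
}

#' Welch two-sample t-test (raw data or summary statistics)
#'
#' `welchTest()` compares two groups of raw values with the unequal-variance
#' (Welch) t-test, two-sided. `tTestFromSummary()` computes the same test
#' from group summaries (n, mean, SD) with the Welch–Satterthwaite degrees
#' of freedom, which allows checking published demographic tables.
#'
#' If both groups have zero variance and equal means, `t = 0, p = 1` by
#' convention.
#'
#' @param a,b numeric vectors (each of length >= 2).
#' @param n1,mean1,sd1,n2,mean2,sd2 group summaries; `n >= 2`, `sd > 0`.
#' @return A list with `t`, `df`, `p`.
#' @export
welchTest <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1))
    stop("both groups constant with different means: t undefined")
  }
  tt <- t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' @rdname welchTest
#' @export
tTestFromSummary <- function(n1, mean1, sd1, n2, mean2, sd2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 > 0, sd2 > 0)
  se2 <- sd1^2 / n1 + sd2^2 / n2
  t <- (mean1 - mean2) / sqrt(se2)
  df <- se2^2 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided exact test for association in a 2x2 contingency table (counts
#' `a`, `b` in the first row, `c`, `d` in the second), via the exact
#' hypergeometric distribution.
#'
#' @param a,b,c,d nonnegative integer cell counts.
#' @return The two-sided p-value.
#' @export
fisherExact2x2 <- function(a, b, c, d) {
  cnt <- c(a, b, c, d)
  stopifnot(all(cnt >= 0), all(cnt == floor(cnt)))
  tab <- matrix(cnt, 2, 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate 2x2 table: a margin is zero")
  fisher.test(tab)$p.value
}

#' Permutation test for a group difference in means
#'
#' Nonparametric group comparison by label permutation: subjects are
#' randomly reassigned to two groups of the original sizes, the group mean
#' difference recomputed for each of `B` shuffles (default 5,000), and the
#' 95th percentile of the null distribution used as the critical value. The
#' empirical p-value uses the +1 correction, `p = (1 + #extreme) / (B + 1)`,
#' so it is never exactly zero.
#'
#' `direction` selects the tail: `"greater"`/`"less"` test the stated
#' one-tailed hypothesis against the 95th/5th percentile; `"two.sided"`
#' compares |difference|; the default `"auto"` tests the observed direction
#' one-tailed and doubles the p-value (capped at 1), which is the
#' conservative choice when the direction was not fixed a priori.
#'
#' @param values numeric vector, one per subject (finite).
#' @param labels group label per subject (two groups).
#' @param B number of permutations (default 5000; < 100 warns).
#' @param seed integer seed; results are fully reproducible.
#' @param direction `"auto"`, `"greater"`, `"less"` or `"two.sided"`.
#' @param groups optional length-2 vector fixing which label is the first
#'   group; the observed difference is mean(first) - mean(second). Defaults
#'   to `c("PSD", "PSND")` when present, else sorted unique labels.
#' @param metricName label carried into the result.
#' @return A list of class `"permutationResult"`: `metric_name`,
#'   `observed_diff`, `null_quantile_95` (critical value in the tested
#'   direction), `p_perm`, `B`, `seed`, `direction`, `null` (the null
#'   differences).
#' @export
permutationTest <- function(values, labels, B = 5000, seed = 1L,
                            direction = c("auto", "greater", "less",
                                          "two.sided"),
                            groups = NULL, metricName = "metric") {
  direction <- match.arg(direction)
  stopifnot(length(values) == length(labels), all(is.finite(values)))
  if (B < 100) warning("B < 100 permutations gives a very coarse p-value")
  labels <- as.character(labels)
  if (is.null(groups)) {
    u <- sort(unique(labels))
    groups <- if (all(c("PSD", "PSND") %in% u)) c("PSD", "PSND") else u
  }
  if (!setequal(unique(labels), groups) || length(groups) != 2)
    stop("labels must contain exactly the two groups: ",
         paste(groups, collapse = ", "))
  isA <- labels == groups[1]
  n <- length(values); nA <- sum(isA); nB <- n - nA
  if (nA == 0 || nB == 0) stop("both groups must be non-empty")
  obs <- mean(values[isA]) - mean(values[!isA])
  total <- sum(values)
  null <- .withSeed(seed, {
    vapply(seq_len(B), function(b) {
      sa <- sum(values[sample.int(n, nA)])
      sa / nA - (total - sa) / nB
    }, numeric(1))
  })
  ## tie comparisons get a spread-relative tolerance so the p-value is
  ## exactly invariant under affine rescaling of the metric
  eps <- 1e-9 * max(diff(range(c(null, obs))), abs(obs), 1e-300)
  p1g <- (1 + sum(null >= obs - eps)) / (B + 1)
  p1l <- (1 + sum(null <= obs + eps)) / (B + 1)
  res <- switch(direction,
    greater = list(p = p1g, crit = unname(quantile(null, 0.95))),
    less = list(p = p1l, crit = unname(quantile(null, 0.05))),
    two.sided = list(p = (1 + sum(abs(null) >= abs(obs) - eps)) / (B + 1),
                     crit = unname(quantile(abs(null), 0.95))),
    auto = if (obs >= 0)
      list(p = min(1, 2 * p1g), crit = unname(quantile(null, 0.95)))
    else
      list(p = min(1, 2 * p1l), crit = unname(quantile(null, 0.05)))
  )
  out <- list(metric_name = metricName, observed_diff = obs,
              null_quantile_95 = res$crit, p_perm = res$p, B = B,
              seed = as.integer(seed), direction = direction, null = null)
  class(out) <- "permutationResult"
  out
}

#' @export
print.permutationResult <- function(x, ...) {
  cat(sprintf("permutation test (%s): diff = %.4g, p = %.4g (B = %d, %s)\n",
              x$metric_name, x$observed_diff, x$p_perm, x$B, x$direction))
  invisible(x)
}

#' Spearman rank correlation, optionally covariate-adjusted
#'
#' Spearman correlation with average-tie ranks. With covariates, both
#' analysis variables are rank-transformed, residualized on the covariates
#' ([adjustCovariates()]), and the Pearson correlation of the residuals is
#' taken (a partial Spearman correlation). The p-value uses the
#' t-approximation with `n - 2` degrees of freedom (`n - 2 - k` when `k`
#' covariate columns are adjusted for).
#'
#' @param x,y numeric vectors (n >= 4 complete pairs).
#' @param covariates optional data.frame of covariates.
#' @param metricName,scoreName labels carried into the result.
#' @return A list of class `"correlationResult"`: `metric_name`,
#'   `score_name`, `rho`, `p_raw`, `n`, `covariates` (names adjusted for).
#' @export
spearmanCor <- function(x, y, covariates = NULL,
                        metricName = "metric", scoreName = "score") {
  keep <- !is.na(x) & !is.na(y)
  if (!is.null(covariates)) keep <- keep & complete.cases(covariates)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete paired observations")
  if (sd(x) == 0 || sd(y) == 0)
    stop("constant input: Spearman correlation undefined")
  rx <- rank(x); ry <- rank(y)
  k <- 0L
  if (is.null(covariates)) {
    rho <- cor(rx, ry)
    covNames <- character()
  } else {
    cv <- as.data.frame(covariates)[keep, , drop = FALSE]
    ex <- adjustCovariates(rx, cv)
    ey <- adjustCovariates(ry, cv)
    rho <- cor(ex, ey)
    k <- ncol(stats::model.matrix(~ ., data = cv)) - 1L
    covNames <- names(cv)
  }
  df <- n - 2 - k
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt(df / (1 - rho^2))
    2 * pt(-abs(tstat), df)
  }
  out <- list(metric_name = metricName, score_name = scoreName,
              rho = rho, p_raw = p, n = n, covariates = covNames)
  class(out) <- "correlationResult"
  out
}

#' @export
print.correlationResult <- function(x, ...) {
  cat(sprintf("Spearman %s ~ %s: rho = %.3f, p = %.4g, n = %d%s\n",
              x$metric_name, x$score_name, x$rho, x$p_raw, x$n,
              if (length(x$covariates))
                paste0(" (adjusted for ", paste(x$covariates, collapse = ", "), ")")
              else ""))
  invisible(x)
}

#' Bonferroni correction
#'
#' Multiplies each p-value by the family size and caps at 1. The family
#' size is recorded in attribute `"family_size"`; it defaults to the number
#' of p-values but should be set explicitly when the tested family is
#' larger than the vector at hand.
#'
#' @param p numeric p-values in \[0, 1\].
#' @param familySize number of tests in the family (default `length(p)`).
#' @return Adjusted p-values, capped at 1.
#' @export
bonferroni <- function(p, familySize = length(p)) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE), familySize >= 1)
  out <- pmin(1, p * familySize)
  attr(out, "family_size") <- familySize
  out
}
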