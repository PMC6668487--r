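#' Per-subject network metrics for a whole cohort
#'
#' Preprocesses every subject (fiber threshold, ipsilesional orientation
#' when the lesion side is known, max-normalization) and computes the
#' global and nodal measures; optionally the small-world normalization
#' (gamma, lambda, sigma) against degree-preserving surrogates.
#'
#' @param cohort a cohort list (from [generateCohort()] / [readCohort()]):
#'   needs `$connectomes`.
#' @param wMin fiber-count threshold (default 10).
#' @param nRandom surrogates per subject for small-world normalization;
#'   `0` skips it.
#' @param seed master seed for surrogate generation.
#' @param orient apply ipsilesional orientation (default TRUE).
#' @return List with data.frames `global` (one row per subject; includes
#'   `gamma`, `lambda`, `sigma`, `n_random_effective` when `nRandom > 0`)
#'   and `nodal` (one row per subject x region).
#' @export
cohortMetrics <- function(cohort, wMin = 10, nRandom = 0, seed = 1L,
                          orient = TRUE) {
  gl <- list(); nd <- list()
  for (i in seq_along(cohort$connectomes)) {
    x <- cohort$connectomes[[i]]
    proc <- suppressWarnings(preprocessConnectome(x, wMin = wMin,
                                                  orient = orient))
    m <- computeMetrics(proc)
    if (nRandom > 0) {
      sw <- smallWorldParams(proc, nRandom = nRandom,
                             seed = .deriveSeed(seed, i))
      m$global$gamma <- sw$gamma
      m$global$lambda <- sw$lambda
      m$global$sigma <- sw$sigma
      m$global$n_random_effective <- sw$n_random
    }
    gl[[i]] <- m$global
    nd[[i]] <- m$nodal
  }
  list(global = do.call(rbind, gl), nodal = do.call(rbind, nd))
}

.GLOBAL_METRICS <- c("clustering_C", "path_length_L", "eff_global",
                     "eff_local")
.NODAL_METRICS <- c("degree", "clustering", "betweenness", "eff_nodal")
.DEFAULT_COVARIATES <- c("age", "sex", "infarct_size_cm3", "hypertension",
                         "diabetes", "cholesterol")

## numeric covariate design from the clinical table
.covariateFrame <- function(clinical, covariates) {
  cv <- clinical[, covariates, drop = FALSE]
  if ("sex" %in% names(cv)) cv$sex <- as.integer(cv$sex == "male")
  cv
}

#' Covariate-adjusted group comparison of network metrics
#'
#' For each global metric (and, when a nodal table is supplied, each region
#' x nodal metric), the subject values are residualized on the covariates,
#' then compared between groups with both a Welch t-test and a label
#' permutation test ([permutationTest()]); p-values are Bonferroni-adjusted
#' within families (the global metrics as one family; each nodal metric
#' across its regions as one family).
#'
#' @param metrics result of [cohortMetrics()] (list with `global` and
#'   optionally `nodal`).
#' @param clinical clinical data.frame with `subject_id`, `group` and the
#'   covariate columns.
#' @param covariates covariate column names (default: age, sex, infarct
#'   size, hypertension, diabetes, cholesterol).
#' @param B permutations (default 5000).
#' @param seed master seed; one child seed per tested series.
#' @param direction passed to [permutationTest()].
#' @return data.frame with columns `level`, `metric`, `region_id`,
#'   `region`, `observed_diff` (PSD - PSND, adjusted), `t`, `df`, `p_t`,
#'   `p_perm`, `crit95`, `p_t_adj`, `p_perm_adj`, `family_size`.
#' @export
runGroupComparison <- function(metrics, clinical,
                               covariates = .DEFAULT_COVARIATES,
                               B = 5000, seed = 1L, direction = "auto") {
  rows <- list(); k <- 0L
  testSeries <- function(values, labels, cv, metric, level,
                         region_id = NA, region = NA) {
    res <- adjustCovariates(values, cv)
    used <- attr(res, "used")
    r <- res[used]; lab <- labels[used]
    tt <- welchTest(r[lab == "PSD"], r[lab == "PSND"])
    k <<- k + 1L
    pt <- permutationTest(r, lab, B = B, seed = .deriveSeed(seed, k),
                          direction = direction, metricName = metric)
    data.frame(level = level, metric = metric, region_id = region_id,
               region = region, observed_diff = pt$observed_diff,
               t = tt$t, df = tt$df, p_t = tt$p, p_perm = pt$p_perm,
               crit95 = pt$null_quantile_95, stringsAsFactors = FALSE)
  }
  g <- merge(metrics$global, clinical, by = "subject_id")
  cvg <- .covariateFrame(g, covariates)
  glob <- lapply(.GLOBAL_METRICS, function(mn)
    testSeries(g[[mn]], g$group, cvg, mn, "global"))
  glob <- do.call(rbind, glob)
  glob$p_t_adj <- as.numeric(bonferroni(glob$p_t, nrow(glob)))
  glob$p_perm_adj <- as.numeric(bonferroni(glob$p_perm, nrow(glob)))
  glob$family_size <- nrow(glob)
  out <- glob
  if (!is.null(metrics$nodal)) {
    nd <- merge(metrics$nodal, clinical, by = "subject_id")
    nodalRows <- list()
    for (mn in intersect(.NODAL_METRICS, names(nd))) {
      per <- lapply(sort(unique(nd$region_id)), function(rid) {
        s <- nd[nd$region_id == rid, ]
        testSeries(s[[mn]], s$group, .covariateFrame(s, covariates),
                   mn, "nodal", region_id = rid, region = s$region[1])
      })
      per <- do.call(rbind, per)
      per$p_t_adj <- as.numeric(bonferroni(per$p_t, nrow(per)))
      per$p_perm_adj <- as.numeric(bonferroni(per$p_perm, nrow(per)))
      per$family_size <- nrow(per)
      nodalRows[[mn]] <- per
    }
    out <- rbind(out, do.call(rbind, nodalRows))
  }
  rownames(out) <- NULL
  out
}

#' Covariate-adjusted Spearman correlations with clinical scores
#'
#' Correlates network metrics with functional assessment scores within one
#' group (by default the depressed group, mirroring how depression-severity
#' associations are studied), using rank-based covariate adjustment
#' ([spearmanCor()]) and a Bonferroni family of all metric x score pairs
#' tested.
#'
#' @param metricsWide data.frame: `subject_id` plus one column per metric.
#' @param clinical clinical data.frame.
#' @param scores score columns to correlate (default `"hamd"` plus any of
#'   nihss/mrs/bi/mmse present).
#' @param covariates covariate columns (default as in
#'   [runGroupComparison()]); `NULL` for unadjusted.
#' @param group restrict to this group (default `"PSD"`; `NULL` for all).
#' @return data.frame: `metric`, `score`, `rho`, `p_raw`, `p_bonferroni`,
#'   `n`, `family_size`.
#' @export
runCorrelations <- function(metricsWide, clinical,
                            scores = intersect(c("hamd", "nihss", "mrs",
                                                 "bi", "mmse"),
                                               names(clinical)),
                            covariates = .DEFAULT_COVARIATES,
                            group = "PSD") {
  d <- merge(metricsWide, clinical, by = "subject_id",
             suffixes = c("", ".clin"))
  if (!is.null(group)) d <- d[d$group == group, ]
  metricCols <- setdiff(names(metricsWide), "subject_id")
  cv <- if (is.null(covariates)) NULL else .covariateFrame(d, covariates)
  rows <- list()
  for (mn in metricCols) for (sc in scores) {
    r <- spearmanCor(d[[mn]], d[[sc]], covariates = cv,
                     metricName = mn, scoreName = sc)
    rows[[paste(mn, sc)]] <- data.frame(metric = mn, score = sc,
                                        rho = r$rho, p_raw = r$p_raw,
                                        n = r$n, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  fam <- nrow(out)
  out$p_bonferroni <- as.numeric(bonferroni(out$p_raw, fam))
  out$family_size <- fam
  rownames(out) <- NULL
  out
}

#' Threshold-sweep stability of group differences
#'
#' Re-runs preprocessing and the global metrics at every fiber-count
#' threshold in `sweep` (default 5..15) and tabulates the adjusted group
#' mean difference (PSD - PSND) per metric, to check that conclusions do
#' not hinge on the particular threshold.
#'
#' @param cohort cohort list with `$connectomes` and `$clinical`.
#' @param sweep integer thresholds (default `5:15`).
#' @param covariates covariate columns for adjustment.
#' @param metrics which global metrics to track.
#' @return data.frame: `w_min`, `metric`, `observed_diff`, `sign`.
#' @export
thresholdSweep <- function(cohort, sweep = 5:15,
                           covariates = .DEFAULT_COVARIATES,
                           metrics = c("eff_global", "eff_local")) {
  rows <- list()
  for (wm in sweep) {
    mt <- cohortMetrics(cohort, wMin = wm, nRandom = 0)
    g <- merge(mt$global, cohort$clinical, by = "subject_id")
    cv <- .covariateFrame(g, covariates)
    for (mn in metrics) {
      res <- adjustCovariates(g[[mn]], cv)
      used <- attr(res, "used")
      d <- mean(res[used][g$group[used] == "PSD"]) -
        mean(res[used][g$group[used] == "PSND"])
      rows[[paste(wm, mn)]] <- data.frame(w_min = wm, metric = mn,
                                          observed_diff = d,
                                          sign = sign(d),
                                          stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a cohort and write it to disk
#'
#' Thin wrapper: [generateCohort()] then [writeCohort()].
#'
#' @param spec a [CohortSpec-class] (default [cohortSpec()]).
#' @param dir output directory.
#' @return The cohort, invisibly.
#' @export
simulateCohortToDisk <- function(spec = cohortSpec(), dir) {
  cohort <- generateCohort(spec)
  writeCohort(cohort, dir)
  invisible(cohort)
}

#' Run the full study replica
#'
#' End-to-end orchestration: take (or simulate) a cohort, compute
#' per-subject metrics with small-world normalization, run the
#' covariate-adjusted group comparisons (t + permutation + Bonferroni), the
#' within-PSD Spearman correlations with the functional scores, and the
#' threshold-sweep stability table; optionally write the tidy CSVs and a
#' JSON run manifest to `outDir`.
#'
#' @param cohort cohort list; if `NULL`, simulated from `spec`.
#' @param spec generator spec used when `cohort` is NULL.
#' @param wMin fiber threshold (default 10).
#' @param sweep thresholds for the stability table (`NULL` to skip).
#' @param nRandom surrogates per subject (default 100; 0 skips
#'   small-world normalization).
#' @param B permutations (default 5000).
#' @param alpha significance level for the report (default 0.05).
#' @param seed master seed.
#' @param covariates covariate columns.
#' @param outDir optional output directory for CSVs + manifest.
#' @return List of class `"psdnetStudy"`: `metrics`, `smallWorld` (per-group
#'   mean/SD of gamma, lambda, sigma and small-world verdicts), `comparison`,
#'   `correlations`, `sweepTable`, `config`.
#' @export
runStudy <- function(cohort = NULL, spec = cohortSpec(), wMin = 10,
                     sweep = 5:15, nRandom = 100, B = 5000, alpha = 0.05,
                     seed = 1L, covariates = .DEFAULT_COVARIATES,
                     outDir = NULL) {
  if (is.null(cohort)) cohort <- generateCohort(spec)
  metrics <- cohortMetrics(cohort, wMin = wMin, nRandom = nRandom,
                           seed = .deriveSeed(seed, 1L))
  comparison <- runGroupComparison(metrics, cohort$clinical,
                                   covariates = covariates, B = B,
                                   seed = .deriveSeed(seed, 2L))
  gw <- metrics$global[, c("subject_id", .GLOBAL_METRICS)]
  correlations <- runCorrelations(gw, cohort$clinical,
                                  covariates = covariates)
  sw <- NULL
  if (nRandom > 0) {
    g <- merge(metrics$global, cohort$clinical[, c("subject_id", "group")],
               by = "subject_id")
    agg <- function(v, g_) c(mean = mean(v), sd = sd(v))
    sw <- do.call(rbind, lapply(split(g, g$group), function(s) {
      data.frame(group = s$group[1],
                 gamma_mean = mean(s$gamma), gamma_sd = sd(s$gamma),
                 lambda_mean = mean(s$lambda), lambda_sd = sd(s$lambda),
                 sigma_mean = mean(s$sigma), sigma_sd = sd(s$sigma),
                 frac_small_world = mean(vapply(seq_len(nrow(s)), function(i)
                   as.logical(isSmallWorld(list(gamma = s$gamma[i],
                                                lambda = s$lambda[i],
                                                sigma = s$sigma[i]))),
                   logical(1))),
                 stringsAsFactors = FALSE)
    }))
    rownames(sw) <- NULL
  }
  sweepTable <- if (!is.null(sweep)) thresholdSweep(cohort, sweep = sweep,
                                                    covariates = covariates)
  else NULL
  config <- list(wMin = wMin, sweep = sweep, nRandom = nRandom, B = B,
                 alpha = alpha, seed = as.integer(seed),
                 covariates = covariates,
                 version = as.character(utils::packageVersion("psdnet")))
  out <- list(metrics = metrics, smallWorld = sw, comparison = comparison,
              correlations = correlations, sweepTable = sweepTable,
              config = config)
  class(out) <- "psdnetStudy"
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    write.csv(metrics$global, file.path(outDir, "metrics_global.csv"),
              row.names = FALSE)
    write.csv(metrics$nodal, file.path(outDir, "metrics_nodal.csv"),
              row.names = FALSE)
    write.csv(comparison, file.path(outDir, "group_comparison.csv"),
              row.names = FALSE)
    write.csv(correlations, file.path(outDir, "correlations.csv"),
              row.names = FALSE)
    if (!is.null(sw))
      write.csv(sw, file.path(outDir, "small_world.csv"), row.names = FALSE)
    if (!is.null(sweepTable))
      write.csv(sweepTable, file.path(outDir, "threshold_sweep.csv"),
                row.names = FALSE)
    jsonlite::write_json(config, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' @export
print.psdnetStudy <- function(x, ...) {
  cat("psdnet study run\n")
  if (!is.null(x$smallWorld)) {
    cat("small-world normalization (per-group mean +/- SD):\n")
    for (i in seq_len(nrow(x$smallWorld)))
      cat(sprintf("  %-5s gamma %.2f+/-%.2f  lambda %.2f+/-%.2f  sigma %.2f  small-world in %.0f%%\n",
                  x$smallWorld$group[i], x$smallWorld$gamma_mean[i],
                  x$smallWorld$gamma_sd[i], x$smallWorld$lambda_mean[i],
                  x$smallWorld$lambda_sd[i], x$smallWorld$sigma_mean[i],
                  100 * x$smallWorld$frac_small_world[i]))
  }
  gl <- x$comparison[x$comparison$level == "global", ]
  cat("global metric group differences (PSD - PSND, covariate-adjusted):\n")
  for (i in seq_len(nrow(gl)))
    cat(sprintf("  %-13s diff %+.4f  p_t %.4g  p_perm %.4g (Bonferroni %.4g)\n",
                gl$metric[i], gl$observed_diff[i], gl$p_t[i], gl$p_perm[i],
                gl$p_perm_adj[i]))
  sig <- x$correlations[x$correlations$p_bonferroni < x$config$alpha, ]
  cat(sprintf("correlations (within PSD, rank-adjusted): %d of %d significant after Bonferroni\n",
              nrow(sig), nrow(x$correlations)))
  for (i in seq_len(nrow(sig)))
    cat(sprintf("  %s ~ %s: rho = %.3f, p_adj = %.4g\n", sig$metric[i],
                sig$score[i], sig$rho[i], sig$p_bonferroni[i]))
  invisible(x)
}
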