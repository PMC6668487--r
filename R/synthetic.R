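#' CohortSpec: parameterization of the synthetic cohort generator
#'
#' Full description of a simulated two-group connectome study: group sizes,
#' network topology, fiber-count weight model, planted group effects,
#' depression-score model, covariate distributions, and the master seed.
#' Identical specs generate identical cohorts.
#'
#' Defaults emulate the post-stroke depression study design the package is
#' modelled on: 31 depressed (PSD) vs 23 non-depressed (PSND) stroke
#' patients on a 90-region parcellation; modular small-world networks with
#' log-normal integer fiber counts and strong, low-variability homotopic
#' (interhemispheric) connections; the depressed group gets long-range
#' (non-homotopic inter-module) weights reduced and additional short-range
#' (intra-module) connections — lowering global efficiency and raising
#' local efficiency, the lattice-like reorganization such studies report —
#' plus strength degradation at designated "lesioned" regions; HAMD scores
#' with group means 8.5 +/- 1.8 and 3.7 +/- 0.8, respecting the >= 7 / < 7
#' group rule, rank-coupled to each depressed subject's local efficiency
#' through a Gaussian copula.
#'
#' @slot nPSD,nPSND group sizes (defaults 31 and 23).
#' @slot nNodes region count (default 90).
#' @slot topology list: `nModules` (per hemisphere, default 3), `pIntra`,
#'   `pInter`, `pHomotopic` edge probabilities.
#' @slot weightModel list: `meanlog`, `sdlog` of the log-normal fiber-count
#'   distribution (rounded to integers, minimum 1) plus `homotopicMeanlog`,
#'   `homotopicSdlog` for the stronger, tighter homotopic connections.
#' @slot effects list: `globalEffDrop` (fraction in \[0, 1) by which
#'   long-range weights are multiplied down), `localEffBoost` (probability
#'   in \[0, 1) that each absent intra-module pair gains a connection),
#'   `lesionedNodes` (0-based region ids, canonical ipsilesional-left
#'   space), `lesionReduction`.
#' @slot hamdModel list: `psdMean`, `psdSd`, `psndMean`, `psndSd`,
#'   `coupling` (Gaussian-copula correlation in \[0, 1) between PSD local
#'   efficiency and HAMD).
#' @slot covariateModel list of per-group distribution parameters for age,
#'   sex, infarct size, lesion side, vascular covariates and the optional
#'   functional scores.
#' @slot masterSeed integer; all randomness derives from it.
#' @seealso [cohortSpec()], [generateCohort()], [writeCohort()]
#' @export
setClass("CohortSpec",
  representation(
    nPSD = "integer", nPSND = "integer", nNodes = "integer",
    topology = "list", weightModel = "list", effects = "list",
    hamdModel = "list", covariateModel = "list", masterSeed = "integer"
  )
)

setValidity("CohortSpec", function(object) {
  msgs <- character()
  if (object@nPSD < 2 || object@nPSND < 2)
    msgs <- c(msgs, "group sizes must be >= 2")
  tp <- object@topology
  if (object@nNodes %% (2L * tp$nModules) != 0)
    msgs <- c(msgs, "nNodes must be divisible by 2 * nModules")
  fr <- c(object@effects$globalEffDrop, object@effects$localEffBoost,
          object@effects$lesionReduction)
  if (any(fr < 0 | fr >= 1))
    msgs <- c(msgs, "effect fractions must lie in [0, 1)")
  cp <- object@hamdModel$coupling
  if (cp < 0 || cp >= 1)
    msgs <- c(msgs, "hamd coupling must lie in [0, 1)")
  pr <- c(tp$pIntra, tp$pInter, tp$pHomotopic)
  if (any(pr < 0 | pr > 1)) msgs <- c(msgs, "edge probabilities must be in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Construct a CohortSpec
#'
#' All arguments default to the study-design values described in
#' [CohortSpec-class]; list arguments are merged over the defaults, so
#' `cohortSpec(effects = list(globalEffDrop = 0))` changes one field only.
#'
#' @param nPSD,nPSND,nNodes,masterSeed scalars; see [CohortSpec-class].
#' @param topology,weightModel,effects,hamdModel,covariateModel named lists
#'   merged over the defaults.
#' @return A validated [CohortSpec-class] object.
#' @examples
#' cohortSpec(masterSeed = 42)
#' @export
cohortSpec <- function(nPSD = 31, nPSND = 23, nNodes = 90,
                       topology = list(), weightModel = list(),
                       effects = list(), hamdModel = list(),
                       covariateModel = list(), masterSeed = 20190776) {
  def_top <- list(nModules = 3L, pIntra = 0.6, pInter = 0.06,
                  pHomotopic = 0.9)
  def_wm <- list(meanlog = 3.4, sdlog = 0.6,
                 homotopicMeanlog = 5.2, homotopicSdlog = 0.2)
  def_eff <- list(globalEffDrop = 0.5, localEffBoost = 0.5,
                  lesionedNodes = c(1L, 17L, 87L), lesionReduction = 0.3)
  def_hamd <- list(psdMean = 8.5, psdSd = 1.8, psndMean = 3.7, psndSd = 0.8,
                   coupling = 0.79)
  def_cov <- list(
    age = list(PSD = c(mean = 64, sd = 10), PSND = c(mean = 67, sd = 12)),
    maleP = c(PSD = 0.55, PSND = 0.65),
    infarct = list(PSD = c(mean = 5.6, sd = 10.1),
                   PSND = c(mean = 4.8, sd = 9.8)),
    leftLesionP = c(PSD = 17 / 31, PSND = 12 / 23),
    hypertensionP = c(PSD = 0.52, PSND = 0.48),
    diabetesP = c(PSD = 0.16, PSND = 0.17),
    cholesterol = list(PSD = c(mean = 4.8, sd = 1.3),
                       PSND = c(mean = 4.4, sd = 1.5)),
    nihss = list(PSD = c(mean = 4, sd = 3), PSND = c(mean = 2, sd = 2)),
    mrs = list(PSD = c(mean = 2, sd = 1), PSND = c(mean = 1.3, sd = 0.8)),
    bi = list(PSD = c(mean = 80, sd = 15), PSND = c(mean = 90, sd = 10)),
    mmse = list(PSD = c(mean = 26, sd = 3), PSND = c(mean = 27, sd = 2))
  )
  new("CohortSpec",
      nPSD = as.integer(nPSD), nPSND = as.integer(nPSND),
      nNodes = as.integer(nNodes),
      topology = utils::modifyList(def_top, topology),
      weightModel = utils::modifyList(def_wm, weightModel),
      effects = utils::modifyList(def_eff, effects),
      hamdModel = utils::modifyList(def_hamd, hamdModel),
      covariateModel = utils::modifyList(def_cov, covariateModel),
      masterSeed = as.integer(masterSeed))
}

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf("CohortSpec: %d PSD + %d PSND subjects, %d regions, seed %d\n",
              object@nPSD, object@nPSND, object@nNodes, object@masterSeed))
  cat(sprintf("  topology: %d modules/hemisphere, pIntra=%.2f pInter=%.2f pHomotopic=%.2f\n",
              object@topology$nModules, object@topology$pIntra,
              object@topology$pInter, object@topology$pHomotopic))
  cat(sprintf("  effects: global drop %.2f, local boost %.2f, %d lesioned nodes (x%.2f)\n",
              object@effects$globalEffDrop, object@effects$localEffBoost,
              length(object@effects$lesionedNodes),
              1 - object@effects$lesionReduction))
  cat(sprintf("  HAMD coupling to local efficiency: %.2f\n",
              object@hamdModel$coupling))
})

## module index (1-based) per node: modules are mirrored across hemispheres
## but counted separately, so homotopic/interhemispheric edges are
## long-range (inter-module) except where noted.
.moduleMap <- function(spec) {
  n <- spec@nNodes; h <- n %/% 2L
  per <- h %/% spec@topology$nModules
  base <- ((seq_len(n) - 1L) %% h) %/% per
  base + 1L + spec@topology$nModules * as.integer(seq_len(n) > h)
}

## pair classification matrices: intra-module, homotopic
.pairClasses <- function(spec) {
  n <- spec@nNodes; h <- n %/% 2L
  mod <- .moduleMap(spec)
  intra <- outer(mod, mod, "==")
  hom <- matrix(FALSE, n, n)
  hom[cbind(seq_len(h), seq_len(h) + h)] <- TRUE
  hom <- hom | t(hom)
  list(intra = intra, homotopic = hom)
}

#' Generate one subject's base connectome
#'
#' Draws a modular small-world weighted network: nodes are split into
#' hemispheres and mirrored modules; edges appear with probability
#' `pIntra` within a module, `pInter` between modules, and `pHomotopic`
#' for homotopic left/right pairs; integer fiber-count weights are drawn
#' log-normal and rounded, with homotopic pairs drawn from a stronger,
#' tighter distribution (emulating the consistently heavy interhemispheric
#' tracts, which also makes the normalizing maximum weight stable across
#' subjects). The matrix is symmetric with zero diagonal, and the draw is
#' retried (bounded) until the network is connected after the default
#' fiber threshold of 10.
#'
#' @param spec a [CohortSpec-class].
#' @param subjectSeed integer seed for this subject.
#' @param regions region table (defaults to [regionTable()] for 90 nodes,
#'   else a generic table).
#' @return A raw-state [Connectome-class] in the canonical orientation.
#' @export
generateBaseConnectome <- function(spec, subjectSeed,
                                   regions = NULL) {
  if (is.null(regions))
    regions <- if (spec@nNodes == 90) regionTable() else
      makeRegionTable(spec@nNodes)
  n <- spec@nNodes
  cls <- .pairClasses(spec)
  up <- upper.tri(matrix(0, n, n))
  pmat <- matrix(spec@topology$pInter, n, n)
  pmat[cls$intra] <- spec@topology$pIntra
  pmat[cls$homotopic] <- spec@topology$pHomotopic
  homUp <- cls$homotopic[up]
  for (try in seq_len(20)) {
    w <- .withSeed(.deriveSeed(subjectSeed, try), {
      edge <- runif(sum(up)) < pmat[up]
      wts <- pmax(1, round(rlnorm(sum(up), spec@weightModel$meanlog,
                                  spec@weightModel$sdlog)))
      wh <- pmax(1, round(rlnorm(sum(up), spec@weightModel$homotopicMeanlog,
                                 spec@weightModel$homotopicSdlog)))
      m <- matrix(0, n, n)
      m[up] <- ifelse(edge, ifelse(homUp, wh, wts), 0)
      m + t(m)
    })
    thr <- w; thr[thr < 10] <- 0
    if (connectedComponents(thr)[1] == n)
      return(connectome(w, regions = regions,
                        subjectID = "base", lesionSide = "unknown",
                        state = "raw"))
  }
  stop("could not generate a post-threshold-connected network in 20 tries; ",
       "increase edge probabilities or weights")
}

#' Plant the group effect on a base connectome
#'
#' For PSD-like subjects the network is reorganized toward a lattice-like
#' configuration: long-range (non-homotopic inter-module) weights are
#' multiplied by `1 - globalEffDrop`, each absent intra-module region pair
#' gains a new connection with probability `localEffBoost` (weight drawn
#' from the fiber-count model; lesioned regions gain none), and all
#' rows/columns of the lesioned
#' regions are multiplied by `1 - lesionReduction`; weights are re-rounded
#' to integer fiber counts. PSND-like subjects pass through unchanged.
#'
#' The planted directions are a lower global efficiency (weakened
#' integration across modules) and a higher local efficiency (denser,
#' more clustered modules) in the PSD-like group, with degree/nodal
#' efficiency degradation at the lesioned regions. Homotopic connections
#' are exempt from the long-range reduction so that the normalizing
#' maximum weight stays comparable across groups and the planted contrast
#' survives max-normalization.
#'
#' @param x raw-state [Connectome-class] in canonical orientation.
#' @param spec a [CohortSpec-class].
#' @param group `"PSD"` or `"PSND"`.
#' @param seed integer seed for the added-connection draws.
#' @return A raw-state `Connectome`.
#' @export
applyGroupEffect <- function(x, spec, group = c("PSD", "PSND"), seed = 1L) {
  group <- match.arg(group)
  if (group == "PSND") return(x)
  w <- x@weights
  cls <- .pairClasses(spec)
  longRange <- !cls$intra & !cls$homotopic
  w[longRange] <- w[longRange] * (1 - spec@effects$globalEffDrop)
  les <- spec@effects$lesionedNodes + 1L   # 0-based ids -> row indices
  if (spec@effects$localEffBoost > 0) {
    up <- upper.tri(w)
    cand <- which(up & cls$intra & w == 0, arr.ind = TRUE)
    ## lesioned regions do not gain connections
    if (length(les))
      cand <- cand[!(cand[, 1] %in% les | cand[, 2] %in% les), ,
                   drop = FALSE]
    if (nrow(cand)) {
      sel <- .withSeed(.deriveSeed(seed, 424243L), {
        add <- runif(nrow(cand)) < spec@effects$localEffBoost
        wts <- pmax(1, round(rlnorm(nrow(cand), spec@weightModel$meanlog,
                                    spec@weightModel$sdlog)))
        list(add = add, wts = wts)
      })
      pick <- cand[sel$add, , drop = FALSE]
      w[pick] <- sel$wts[sel$add]
      w[pick[, c(2, 1), drop = FALSE]] <- sel$wts[sel$add]
    }
  }
  if (length(les)) {
    w[les, ] <- w[les, ] * (1 - spec@effects$lesionReduction)
    w[, les] <- w[, les] * (1 - spec@effects$lesionReduction)
  }
  w <- round(w)
  initialize(x, weights = w)
}

## truncated-normal inverse CDF on [lower, Inf)
.qtruncnorm <- function(u, mean, sd, lower) {
  plo <- pnorm((lower - mean) / sd)
  mean + sd * qnorm(plo + u * (1 - plo))
}

#' Generate the clinical table for a simulated cohort
#'
#' Draws HAMD depression scores from the group-specific normal models
#' (resampled/truncated so that PSD-like subjects score >= 7 and PSND-like
#' subjects < 7), with the PSD-like scores rank-coupled to each subject's
#' network local efficiency through a Gaussian copula at the configured
#' coupling strength, so the planted association is exactly what a Spearman
#' correlation estimates. Age, sex, infarct size (log-normal,
#' moment-matched), lesion side, vascular covariates and the optional
#' functional scores (NIHSS, mRs, BI, MMSE) are drawn from the per-group
#' distributions in the spec.
#'
#' @param spec a [CohortSpec-class].
#' @param subjectIDs character vector of subject ids.
#' @param group group label per subject (`"PSD"`/`"PSND"`).
#' @param lesionSide lesion side per subject.
#' @param effLocal mean local efficiency per subject (used for the HAMD
#'   coupling in the PSD-like group; may be NA for PSND-like subjects).
#' @return data.frame with the documented clinical columns.
#' @export
generateClinical <- function(spec, subjectIDs, group, lesionSide, effLocal) {
  n <- length(subjectIDs)
  stopifnot(length(group) == n, length(lesionSide) == n,
            length(effLocal) == n)
  hm <- spec@hamdModel
  cm <- spec@covariateModel
  seed <- .deriveSeed(spec@masterSeed, 900001L)
  .withSeed(seed, {
    hamd <- integer(n)
    isPSD <- group == "PSD"
    ## PSD: Gaussian copula between local-efficiency ranks and HAMD
    if (any(isPSD)) {
      el <- effLocal[isPSD]
      if (anyNA(el)) stop("effLocal required for every PSD-like subject")
      z <- qnorm((rank(el, ties.method = "average") - 0.5) / sum(isPSD))
      zz <- hm$coupling * z + sqrt(1 - hm$coupling^2) * rnorm(sum(isPSD))
      u <- pnorm(zz)
      h <- .qtruncnorm(u, hm$psdMean, hm$psdSd, lower = 7)
      hamd[isPSD] <- pmax(7L, as.integer(round(h)))
    }
    if (any(!isPSD)) {
      m <- sum(!isPSD)
      h <- numeric(m)
      for (i in seq_len(m)) {
        repeat {
          v <- round(rnorm(1, hm$psndMean, hm$psndSd))
          if (v >= 0 && v < 7) break
        }
        h[i] <- v
      }
      hamd[!isPSD] <- as.integer(h)
    }
    grab <- function(par, g) par[[g]]
    num2 <- function(par) vapply(group, function(g) {
      p <- grab(par, g); rnorm(1, p["mean"], p["sd"])
    }, numeric(1))
    age <- pmin(95, pmax(40, round(num2(cm$age))))
    male <- rbinom(n, 1, cm$maleP[group])
    ## infarct volume: log-normal with moments matched per group
    infarct <- vapply(group, function(g) {
      p <- grab(cm$infarct, g)
      s2 <- log(1 + (p["sd"] / p["mean"])^2)
      rlnorm(1, log(p["mean"]) - s2 / 2, sqrt(s2))
    }, numeric(1))
    hyper <- rbinom(n, 1, cm$hypertensionP[group])
    diab <- rbinom(n, 1, cm$diabetesP[group])
    chol <- pmax(1, num2(cm$cholesterol))
    nihss <- pmax(0, round(num2(cm$nihss)))
    mrs <- pmin(5, pmax(0, round(num2(cm$mrs))))
    bi <- pmin(100, pmax(0, round(num2(cm$bi))))
    mmse <- pmin(30, pmax(0, round(num2(cm$mmse))))
    data.frame(
      subject_id = subjectIDs, group = group, hamd = hamd, age = age,
      sex = ifelse(male == 1, "male", "female"),
      infarct_size_cm3 = round(infarct, 2), lesion_side = lesionSide,
      hypertension = hyper, diabetes = diab, cholesterol = round(chol, 2),
      nihss = nihss, mrs = mrs, bi = bi, mmse = mmse,
      stringsAsFactors = FALSE
    )
  })
}

#' Generate a full synthetic cohort
#'
#' Runs the whole generator: per subject, a base modular small-world
#' connectome (seed derived from the master seed and the subject index),
#' the planted group effect in canonical (ipsilesional-left) space, a drawn
#' lesion side with a hemisphere flip for right-sided subjects (so the raw
#' matrices are in natural orientation, as tractography would produce), and
#' finally the clinical table with HAMD coupled to each depressed subject's
#' local efficiency (computed at the default preprocessing: threshold 10,
#' max-normalization).
#'
#' @param spec a [CohortSpec-class].
#' @return A list of class `"connectomeCohort"`: `connectomes` (named list
#'   of raw [Connectome-class]), `clinical` (data.frame), `spec`.
#' @export
generateCohort <- function(spec) {
  nTot <- spec@nPSD + spec@nPSND
  group <- c(rep("PSD", spec@nPSD), rep("PSND", spec@nPSND))
  ids <- c(sprintf("psd%02d", seq_len(spec@nPSD)),
           sprintf("psnd%02d", seq_len(spec@nPSND)))
  regions <- if (spec@nNodes == 90) regionTable() else
    makeRegionTable(spec@nNodes)
  lp <- spec@covariateModel$leftLesionP
  sides <- .withSeed(.deriveSeed(spec@masterSeed, 800001L), {
    unname(ifelse(runif(nTot) < lp[group], "left", "right"))
  })
  conns <- vector("list", nTot)
  effLocal <- rep(NA_real_, nTot)
  for (i in seq_len(nTot)) {
    base <- generateBaseConnectome(spec, .deriveSeed(spec@masterSeed, i),
                                   regions = regions)
    x <- applyGroupEffect(base, spec, group[i],
                          seed = .deriveSeed(spec@masterSeed, 100000L + i))
    x <- initialize(x, subjectID = ids[i], lesionSide = sides[i])
    if (group[i] == "PSD") {
      proc <- suppressWarnings(preprocessConnectome(x, wMin = 10,
                                                    orient = FALSE))
      effLocal[i] <- mean(localEfficiency(proc))
    }
    ## store in natural orientation: flip right-lesion subjects out of the
    ## canonical space the effects were planted in
    if (sides[i] == "right") x <- flipHemispheres(x)
    conns[[i]] <- x
  }
  names(conns) <- ids
  clinical <- generateClinical(spec, ids, group, sides, effLocal)
  out <- list(connectomes = conns, clinical = clinical, spec = spec)
  class(out) <- "connectomeCohort"
  out
}

#' @export
print.connectomeCohort <- function(x, ...) {
  cat(sprintf("connectomeCohort: %d subjects (%d PSD, %d PSND), %d regions\n",
              length(x$connectomes), sum(x$clinical$group == "PSD"),
              sum(x$clinical$group == "PSND"),
              nrow(x$connectomes[[1]]@weights)))
  invisible(x)
}

#' Write / read a cohort as a file tree
#'
#' `writeCohort()` writes `matrices/<subject_id>.csv` (90x90 comma-delimited
#' fiber counts, no header), `regions.csv`, `clinical.csv` and a
#' `manifest.json` capturing the generator spec and package version.
#' Re-running with the same spec reproduces identical files.
#' `readCohort()` reads such a tree back into a cohort object using
#' [readConnectome()].
#'
#' @param cohort result of [generateCohort()].
#' @param dir output / input directory.
#' @return `writeCohort()`: the directory, invisibly. `readCohort()`: a
#'   cohort list (`connectomes`, `clinical`; no spec unless the manifest
#'   carries one).
#' @export
writeCohort <- function(cohort, dir) {
  mdir <- file.path(dir, "matrices")
  dir.create(mdir, recursive = TRUE, showWarnings = FALSE)
  for (x in cohort$connectomes)
    write.table(x@weights, file.path(mdir, paste0(x@subjectID, ".csv")),
                sep = ",", row.names = FALSE, col.names = FALSE)
  reg <- cohort$connectomes[[1]]@regions
  write.csv(reg, file.path(dir, "regions.csv"), row.names = FALSE,
            quote = FALSE)
  write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
            row.names = FALSE, quote = FALSE)
  manifest <- list(
    package = "psdnet",
    version = as.character(utils::packageVersion("psdnet")),
    n_subjects = length(cohort$connectomes),
    spec = .specAsList(cohort$spec)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname writeCohort
#' @export
readCohort <- function(dir) {
  regions <- readRegionTable(file.path(dir, "regions.csv"))
  clinical <- read.csv(file.path(dir, "clinical.csv"),
                       stringsAsFactors = FALSE)
  conns <- lapply(seq_len(nrow(clinical)), function(i) {
    readConnectome(file.path(dir, "matrices",
                             paste0(clinical$subject_id[i], ".csv")),
                   regions = regions,
                   subjectID = clinical$subject_id[i],
                   lesionSide = clinical$lesion_side[i])
  })
  names(conns) <- clinical$subject_id
  out <- list(connectomes = conns, clinical = clinical)
  class(out) <- "connectomeCohort"
  out
}

.specAsList <- function(spec) {
  if (is.null(spec)) return(NULL)
  list(nPSD = spec@nPSD, nPSND = spec@nPSND, nNodes = spec@nNodes,
       topology = spec@topology, weightModel = spec@weightModel,
       effects = spec@effects, hamdModel = spec@hamdModel,
       covariateModel = spec@covariateModel, masterSeed = spec@masterSeed)
}
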