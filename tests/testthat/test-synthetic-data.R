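test_that("base connectome generation is deterministic, valid and degenerate-limit correct", {
  spec <- cohortSpec()
  a <- generateBaseConnectome(spec, 42)
  b <- generateBaseConnectome(spec, 42)
  expect_identical(connWeights(a), connWeights(b))
  expect_false(identical(connWeights(a),
                         connWeights(generateBaseConnectome(spec, 43))))

  w <- connWeights(a)
  expect_true(validObject(a))
  expect_true(all(w == floor(w)))
  th <- w; th[th < 10] <- 0
  expect_equal(connectedComponents(th)[1], 90)

  # p_intra = 1, p_inter/homotopic subsumed, one module pair: complete graph
  sp1 <- cohortSpec(nPSD = 2, nPSND = 2, nNodes = 10,
                    topology = list(nModules = 1L, pIntra = 1, pInter = 1,
                                    pHomotopic = 1))
  cg <- generateBaseConnectome(sp1, 5)
  expect_equal(nodeDegree(cg), rep(9L, 10))
})

test_that("group effects plant the intended directions and vanish at zero fractions", {
  spec <- cohortSpec()
  null_spec <- cohortSpec(effects = list(globalEffDrop = 0, localEffBoost = 0,
                                         lesionReduction = 0))
  base <- generateBaseConnectome(spec, 17)
  expect_identical(connWeights(applyGroupEffect(base, null_spec, "PSD", seed = 1)),
                   connWeights(base))
  expect_identical(connWeights(applyGroupEffect(base, spec, "PSND")),
                   connWeights(base))

  # paired within-subject contrast over a few bases: E_glob down, E_loc up
  ev <- function(x) {
    p <- suppressWarnings(preprocessConnectome(x, orient = FALSE))
    d <- shortestPathLengths(p)
    c(globalEfficiency(d), mean(localEfficiency(p)))
  }
  deltas <- vapply(1:5, function(s) {
    b <- generateBaseConnectome(spec, 200 + s)
    ev(applyGroupEffect(b, spec, "PSD", seed = s)) - ev(b)
  }, numeric(2))
  expect_lt(mean(deltas[1, ]), 0)   # global efficiency reduced
  expect_gt(mean(deltas[2, ]), 0)   # local efficiency raised

  # lesioned nodes lose degree and nodal efficiency
  les <- spec@effects$lesionedNodes + 1
  ddeg <- vapply(1:5, function(s) {
    b <- generateBaseConnectome(spec, 300 + s)
    pa <- suppressWarnings(preprocessConnectome(
      applyGroupEffect(b, spec, "PSD", seed = s), orient = FALSE))
    pb <- suppressWarnings(preprocessConnectome(b, orient = FALSE))
    mean(nodeDegree(pa)[les] - nodeDegree(pb)[les])
  }, numeric(1))
  expect_lt(mean(ddeg), 0)
})

test_that("clinical generation respects the HAMD group rule and its moments", {
  spec <- cohortSpec()
  ids <- c(sprintf("p%02d", 1:31), sprintf("q%02d", 1:23))
  grp <- c(rep("PSD", 31), rep("PSND", 23))
  side <- rep(c("left", "right"), 27)
  psdMeans <- psndMeans <- numeric(20)
  for (s in 1:20) {
    sp <- cohortSpec(masterSeed = 5000 + s)
    el <- c(runif(31, 0.05, 0.1), rep(NA, 23))
    cl <- generateClinical(sp, ids, grp, side, el)
    expect_true(all(cl$hamd[cl$group == "PSD"] >= 7))
    expect_true(all(cl$hamd[cl$group == "PSND"] < 7))
    expect_true(all(cl$hamd >= 0))
    psdMeans[s] <- mean(cl$hamd[cl$group == "PSD"])
    psndMeans[s] <- mean(cl$hamd[cl$group == "PSND"])
  }
  expect_lt(abs(mean(psdMeans) - 8.5), 1.0)
  expect_lt(abs(mean(psndMeans) - 3.7), 0.6)

  # infarct volumes positive; sex/lesion coded as documented
  cl <- generateClinical(spec, ids, grp, side, c(runif(31, 0.05, 0.1),
                                                 rep(NA, 23)))
  expect_true(all(cl$infarct_size_cm3 > 0))
  expect_true(all(cl$sex %in% c("male", "female")))
  expect_true(all(cl$hypertension %in% 0:1))
})

test_that("the HAMD copula coupling spans independence to near-determinism", {
  ids <- sprintf("p%02d", 1:31)
  grp <- rep("PSD", 31)
  side <- rep("left", 31)
  el <- sort(runif(31, 0.05, 0.12))

  rho0 <- vapply(1:10, function(s) {
    sp <- cohortSpec(hamdModel = list(coupling = 0), masterSeed = 7000 + s)
    cl <- generateClinical(sp, ids, grp, side, el)
    cor(rank(el), rank(cl$hamd))
  }, numeric(1))
  expect_lt(abs(mean(rho0)), 0.2)

  sp99 <- cohortSpec(hamdModel = list(coupling = 0.99), masterSeed = 7100)
  cl99 <- generateClinical(sp99, ids, grp, side, el)
  expect_gt(cor(rank(el), rank(cl99$hamd)), 0.9)

  expect_error(cohortSpec(hamdModel = list(coupling = 1.2)), "coupling")
})

test_that("cohorts are reproducible and round-trip through the file tree", {
  cohort <- smallCohort(101)
  cohort2 <- generateCohort(smallSpec(101))
  expect_identical(cohort$clinical, cohort2$clinical)
  expect_identical(connWeights(cohort$connectomes[[1]]),
                   connWeights(cohort2$connectomes[[1]]))

  expect_equal(length(cohort$connectomes), 11)
  expect_identical(cohort$clinical$subject_id, names(cohort$connectomes))

  dir <- file.path(tempfile(), "cohort")
  writeCohort(cohort, dir)
  expect_equal(length(list.files(file.path(dir, "matrices"))), 11)
  expect_true(file.exists(file.path(dir, "manifest.json")))

  back <- readCohort(dir)
  expect_identical(connWeights(back$connectomes[["psd03"]]),
                   connWeights(cohort$connectomes[["psd03"]]))
  expect_equal(back$clinical$hamd, cohort$clinical$hamd)
  expect_identical(lesionSide(back$connectomes[[5]]),
                   lesionSide(cohort$connectomes[[5]]))

  # a different master seed changes at least one matrix
  other <- generateCohort(smallSpec(102))
  expect_false(identical(connWeights(other$connectomes[[1]]),
                         connWeights(cohort$connectomes[[1]])))

  # manifest records the generator parameterization
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$spec$masterSeed, 101)
  expect_equal(man$n_subjects, 11)
})
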