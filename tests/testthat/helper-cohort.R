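# Shared small synthetic cohort for unit tests (built once per test run).
# 30 regions, 6+5 subjects: big enough to exercise every pipeline stage,
# small enough to keep the suite fast.

smallSpec <- function(seed = 101) {
  cohortSpec(nPSD = 6, nPSND = 5, nNodes = 30,
             effects = list(lesionedNodes = c(1L, 20L)),
             masterSeed = seed)
}

.cohortCache <- new.env(parent = emptyenv())

smallCohort <- function(seed = 101) {
  key <- paste0("c", seed)
  if (is.null(.cohortCache[[key]]))
    .cohortCache[[key]] <- generateCohort(smallSpec(seed))
  .cohortCache[[key]]
}

# one processed (normalized) 90-region synthetic subject
processedSubject <- function(seed = 7) {
  key <- paste0("s", seed)
  if (is.null(.cohortCache[[key]])) {
    x <- generateBaseConnectome(cohortSpec(), seed)
    .cohortCache[[key]] <- suppressWarnings(
      preprocessConnectome(x, orient = FALSE))
  }
  .cohortCache[[key]]
}

writeMatrixFile <- function(w, path = tempfile(fileext = ".csv")) {
  write.table(w, path, sep = ",", row.names = FALSE, col.names = FALSE)
  path
}
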