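#' Region tables for the 90-region parcellation
#'
#' The analysis parcellates gray matter into 90 cortical and subcortical
#' regions (cerebellum excluded), 45 per hemisphere, following the AAL
#' naming scheme. `regionTable()` loads the table shipped with the package;
#' `readRegionTable()` reads a user-supplied CSV with the same columns;
#' `makeRegionTable()` builds a generic table of any even size for toy
#' networks and examples.
#'
#' Layout convention: region ids are 0-based; ids `0..44` are left-hemisphere
#' regions and `45..89` their right-hemisphere homotopic partners
#' (`homotopic_id = id +/- 45`). This declared pairing map is what
#' [orientIpsilesional()] uses to flip hemispheres for right-sided lesions.
#'
#' @param path CSV file with columns `id`, `name`, `hemisphere`,
#'   `homotopic_id` (ids 0-based).
#' @param n number of regions (even), for `makeRegionTable()`.
#' @return A data.frame with columns `id`, `name`, `hemisphere`,
#'   `homotopic_id`.
#' @examples
#' head(regionTable())
#' makeRegionTable(4)
#' @export
regionTable <- function() {
  readRegionTable(system.file("extdata", "aal90_regions.csv",
                              package = "psdnet", mustWork = TRUE))
}

#' @rdname regionTable
#' @export
readRegionTable <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  .validateRegionTable(df)
  df
}

#' @rdname regionTable
#' @export
makeRegionTable <- function(n) {
  if (n %% 2 != 0)
    stop("generic region tables need an even region count for homotopic pairing")
  h <- n %/% 2
  df <- data.frame(
    id = seq_len(n) - 1L,
    name = c(sprintf("Region_%02d_L", seq_len(h)),
             sprintf("Region_%02d_R", seq_len(h))),
    hemisphere = rep(c("left", "right"), each = h),
    homotopic_id = c(seq_len(h) - 1L + h, seq_len(h) - 1L),
    stringsAsFactors = FALSE
  )
  df
}

.validateRegionTable <- function(df) {
  need <- c("id", "name", "hemisphere", "homotopic_id")
  if (!all(need %in% names(df)))
    stop("region table must have columns ", paste(need, collapse = ", "))
  n <- nrow(df)
  if (anyDuplicated(df$name)) stop("region names must be unique")
  if (!identical(sort(df$id), seq_len(n) - 1L) &&
      !identical(as.integer(sort(df$id)), seq_len(n) - 1L))
    stop("region ids must be 0..", n - 1)
  if (!all(df$hemisphere %in% c("left", "right", "midline")))
    stop("hemisphere must be left/right/midline")
  ## pairing map must be an involution pairing left with right
  m <- match(df$homotopic_id, df$id)
  if (anyNA(m)) stop("homotopic_id refers to unknown region id")
  if (!all(df$homotopic_id[m] == df$id))
    stop("homotopic pairing is not symmetric")
  lr <- df$hemisphere != "midline"
  if (any(df$hemisphere[lr] == df$hemisphere[m][lr]))
    stop("homotopic pairs must join opposite hemispheres")
  invisible(TRUE)
}
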