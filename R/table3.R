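#' Packaged reference reclassification counts
#'
#' 3 x 3 risk-group migration counts for a published 450-subject lung
#' screening test set (53 biopsy-proven cancers, 397 negatives), in which
#' subjects initially stratified by Lung-RADS, by the Brock model, or by an
#' image-based risk scorer applied to real baseline / follow-up nodules were
#' reclassified by the same risk scorer applied to model-predicted follow-up
#' nodule images. Four comparison blocks: `lungrads`, `brock`,
#' `lcrp_baseline`, `lcrp_followup`.
#'
#' @param path Optional CSV path with columns
#'   `block, outcome, initial, low, medium, high` (defaults to the packaged
#'   fixture).
#' @return Named list of `reclass_table`s, one per block.
#' @export
reference_reclass_tables <- function(path = NULL) {
  path <- path %||% system.file("extdata", "reclassification_counts.csv",
                                package = "nodulegp")
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("block", "outcome", "initial", "low", "medium", "high")
  if (!all(need %in% names(d))) stop("malformed reclassification counts file")
  lv <- c("low", "medium", "high")
  out <- lapply(split(d, d$block), function(b) {
    grab <- function(which) {
      m <- b[b$outcome == which, ]
      m <- m[match(lv, m$initial), c("low", "medium", "high")]
      as.matrix(m)
    }
    reclass_table(grab("event"), grab("nonevent"))
  })
  out[unique(d$block)]
}

#' Recompute NRI statistics for the packaged reclassification blocks
#'
#' Runs [nri()] and [nri_z_test()] on every block of
#' [reference_reclass_tables()] and reports event / nonevent / overall NRI
#' (raw and rounded half-up to 2 decimals, the presentation convention of the
#' source tables) with Z-statistics and p-values.
#'
#' @param tables Optional list of `reclass_table`s (defaults to the packaged
#'   counts).
#' @return Data frame, one row per block.
#' @export
reproduce_table3 <- function(tables = reference_reclass_tables()) {
  rows <- lapply(names(tables), function(nm) {
    zt <- nri_z_test(tables[[nm]])
    r <- zt$nri
    data.frame(block = nm,
               event_nri = r$event_nri,
               nonevent_nri = r$nonevent_nri,
               overall_nri = r$overall_nri,
               event_nri_2dp = round_half_up(r$event_nri, 2),
               nonevent_nri_2dp = round_half_up(r$nonevent_nri, 2),
               overall_nri_2dp = round_half_up(r$overall_nri, 2),
               z_event = zt$z_event, p_event = zt$p_event,
               z_nonevent = zt$z_nonevent, p_nonevent = zt$p_nonevent,
               z_overall = zt$z_overall, p_overall = zt$p_overall,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Round half away from zero at a given number of decimals
#'
#' Presentation rounding used by the reference tables (R's `round()` rounds
#' half to even).
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}
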