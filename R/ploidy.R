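#' Valid life-stage labels for nucleus records
#' @return Character vector of stage labels, in life-cycle order.
#' @export
nucleus_stages <- function() {
  c("haploid_complement", "gamete", "zygote", "multinuc_juv_in_test",
    "multinuc_juvenile", "multinuc_adult_V1", "multinuc_adult_V2",
    "multinuc_adult_MB", "multinuc_adult_H", "multinuc_adult_other",
    "uninuc_juv_in_test", "uninuc_juvenile", "uninuc_adult_VB",
    "uninuc_adult_VL", "zerfall_nucleus", "zerfall_cell")
}

#' Attach C-values to nucleus records
#'
#' DNA content in C units is each nucleus's total fluorescence expressed as
#' a proportion of the median total fluorescence of gamete nuclei (the
#' putatively haploid, 1C reference). Because both numerator and
#' denominator are fluorescences, C-values are invariant under global gain
#' changes.
#'
#' @param records Data frame with at least a `total_fluor` column.
#' @param gamete_fluors Total fluorescences of the gamete reference nuclei,
#'   pooled across cells; non-empty, all positive.
#' @return `records` with a `c_value` column added/overwritten.
#' @export
c_values <- function(records, gamete_fluors) {
  if (!length(gamete_fluors))
    stop("no 1C reference: gamete fluorescence list is empty")
  if (any(gamete_fluors <= 0)) stop("gamete fluorescences must be positive")
  records$c_value <- records$total_fluor / stats::median(gamete_fluors)
  records
}

#' Stage-wise summary of nucleus measurements
#'
#' Produces one row per stage with counts and the median and quartiles
#' (linear interpolation between closest ranks) of volume, total
#' fluorescence, and C-value. Border-flagged objects are excluded by
#' default; stages with no records are omitted.
#'
#' @param records Data frame with columns `stage`, `volume_um3`,
#'   `total_fluor`, and optionally `c_value`, `cell_id`, `touches_border`.
#' @param exclude_border Drop rows with `touches_border == TRUE`
#'   (default TRUE when the column is present).
#' @return Data frame of stage summaries.
#' @export
stage_summary <- function(records, exclude_border = TRUE) {
  if (!nrow(records)) stop("no records to summarize")
  if (is.null(records$stage) || anyNA(records$stage))
    stop("every record needs a stage label")
  if (exclude_border && !is.null(records$touches_border))
    records <- records[!records$touches_border, , drop = FALSE]
  stages <- intersect(nucleus_stages(), unique(records$stage))
  stages <- c(stages, setdiff(unique(records$stage), stages))
  rows <- lapply(stages, function(st) {
    r <- records[records$stage == st, , drop = FALSE]
    if (!nrow(r)) return(NULL)
    qs <- function(col) {
      if (is.null(r[[col]]) || all(is.na(r[[col]])))
        return(c(q25 = NA_real_, median = NA_real_, q75 = NA_real_))
      quartiles(r[[col]][!is.na(r[[col]])])
    }
    v <- qs("volume_um3"); f <- qs("total_fluor"); cc <- qs("c_value")
    data.frame(
      stage = st,
      n_cells = if (!is.null(r$cell_id)) length(unique(r$cell_id))
                else NA_integer_,
      n_nuclei = nrow(r),
      vol_q25 = v[["q25"]], vol_median = v[["median"]], vol_q75 = v[["q75"]],
      fluor_q25 = f[["q25"]], fluor_median = f[["median"]],
      fluor_q75 = f[["q75"]],
      c_q25 = cc[["q25"]], c_median = cc[["median"]], c_q75 = cc[["q75"]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fold range of a positive measurement
#'
#' `max/min` over all values: e.g. nuclear volumes spanning 0.25 to
#' 36,000 um^3 give a 144,000-fold range.
#'
#' @param values Positive numeric vector.
#' @return Dimensionless ratio.
#' @export
fold_range <- function(values) {
  if (!length(values)) stop("empty value list")
  if (any(values <= 0)) stop("fold range requires strictly positive values")
  max(values) / min(values)
}

#' Ratio of stage-summary medians
#'
#' Compares the median of one measurement field between two stage-summary
#' rows, e.g. the DNA content of V1 nuclei relative to MB or H nuclei.
#'
#' @param summary_a,summary_b Single rows of a [stage_summary()] result.
#' @param field Median column to compare, e.g. `"c_median"`.
#' @return List with `ratio` and its nearest-integer `rounded` value.
#' @export
median_ratio <- function(summary_a, summary_b, field = "c_median") {
  if (is.null(summary_a[[field]]) || is.null(summary_b[[field]]))
    stop("field '", field, "' missing from summaries")
  den <- summary_b[[field]]
  if (!is.finite(den) || den == 0) stop("zero or missing denominator median")
  r <- summary_a[[field]] / den
  list(ratio = r, rounded = round(r))
}
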