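#' Fit a bp-per-fluorescence calibration standard
#'
#' A standard is a species of known genome size whose nuclei were imaged
#' under the same staining protocol. Its bp/F ratio converts integrated
#' fluorescence to base pairs:
#' `bp_per_F = genome_size_bp_1C * assumed_C / mean(nucleus_fluors)`.
#'
#' @param species Species name (e.g. `"S. cerevisiae"`).
#' @param genome_size_bp_1C Haploid genome size in base pairs.
#' @param assumed_C Assumed ploidy (in C) of the measured standard nuclei.
#'   The staining protocol does not reveal this, so it is explicit
#'   configuration, not a constant.
#' @param nucleus_fluors Total fluorescence (F) of each measured standard
#'   nucleus; all must be positive.
#' @return A `calibration_standard` with fields `bp_per_F`, `n` and the
#'   coefficient of variation `cv` of the fluorescences.
#' @export
fit_standard <- function(species, genome_size_bp_1C, assumed_C,
                         nucleus_fluors) {
  if (genome_size_bp_1C <= 0) stop("genome_size_bp_1C must be positive")
  if (assumed_C <= 0) stop("assumed_C must be positive")
  if (!length(nucleus_fluors)) stop("nucleus_fluors must be non-empty")
  if (any(nucleus_fluors <= 0)) stop("all nucleus fluorescences must be > 0")
  m <- mean(nucleus_fluors)
  structure(
    list(species = species, genome_size_bp_1C = genome_size_bp_1C,
         assumed_C = assumed_C, nucleus_fluors = as.numeric(nucleus_fluors),
         bp_per_F = genome_size_bp_1C * assumed_C / m,
         n = length(nucleus_fluors),
         cv = if (length(nucleus_fluors) > 1)
           stats::sd(nucleus_fluors) / m else 0),
    class = "calibration_standard")
}

#' @export
print.calibration_standard <- function(x, ...) {
  cat("<calibration_standard> ", x$species, ": 1C = ",
      format(x$genome_size_bp_1C, big.mark = ","), " bp, assumed ",
      x$assumed_C, "C, n = ", x$n, ", bp/F = ",
      signif(x$bp_per_F, 4), "\n", sep = "")
  invisible(x)
}

#' Estimate DNA content, method 1 (single-standard ratio)
#'
#' Multiplies a nucleus's total fluorescence by the yeast bp/F ratio. This
#' is the estimator preferred for inferred-haploid nuclei, which are
#' closest in size and fluorescence to yeast.
#'
#' @param total_fluor Total fluorescence in F (positive scalar or vector).
#' @param yeast_standard A [fit_standard()] object.
#' @return Estimated base pairs (same length as `total_fluor`).
#' @export
estimate_bp_method1 <- function(total_fluor, yeast_standard) {
  stopifnot(inherits(yeast_standard, "calibration_standard"))
  if (any(total_fluor <= 0)) stop("total_fluor must be positive")
  total_fluor * yeast_standard$bp_per_F
}

# mean per-nucleus bp/F ratio pooled over all standard nuclei
pooled_ratio <- function(standards, pooling = c("nuclei", "species")) {
  pooling <- match.arg(pooling)
  if (!length(standards)) stop("at least one standard is required")
  if (inherits(standards, "calibration_standard")) standards <- list(standards)
  if (pooling == "species")
    return(mean(vapply(standards, function(s) s$bp_per_F, numeric(1))))
  ratios <- unlist(lapply(standards, function(s)
    s$genome_size_bp_1C * s$assumed_C / s$nucleus_fluors))
  mean(ratios)
}

#' Estimate DNA content, method 2 (pooled multi-standard ratio)
#'
#' Multiplies total fluorescence by the average bp/F ratio across all
#' standard nuclei. By default each standard *nucleus* contributes one
#' per-nucleus ratio to the pool; `pooling = "species"` instead averages
#' the per-species ratios.
#'
#' @param total_fluor Total fluorescence in F.
#' @param standards List of [fit_standard()] objects (one is allowed).
#' @param pooling `"nuclei"` (default) or `"species"`.
#' @return Estimated base pairs.
#' @export
estimate_bp_method2 <- function(total_fluor, standards,
                                pooling = c("nuclei", "species")) {
  if (any(total_fluor <= 0)) stop("total_fluor must be positive")
  total_fluor * pooled_ratio(standards, match.arg(pooling))
}

#' Dispersion ratio of the two bp estimators
#'
#' Standard deviation of method-2 estimates divided by that of method-1
#' estimates over the same set of nuclei. Because both estimators are
#' linear in fluorescence, this equals the ratio of the two calibration
#' constants exactly.
#'
#' @param fluors Total fluorescences (>= 2 values, non-constant).
#' @param yeast_standard Standard used by method 1.
#' @param standards Standards pooled by method 2.
#' @param pooling Pooling rule for method 2.
#' @return The dimensionless sd ratio.
#' @export
method_dispersion <- function(fluors, yeast_standard, standards,
                              pooling = c("nuclei", "species")) {
  if (length(fluors) < 2) stop("need at least two fluorescence values")
  sd1 <- stats::sd(estimate_bp_method1(fluors, yeast_standard))
  sd2 <- stats::sd(estimate_bp_method2(fluors, standards,
                                       match.arg(pooling)))
  if (sd1 == 0) stop("undefined ratio: zero variance in fluorescences")
  sd2 / sd1
}
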