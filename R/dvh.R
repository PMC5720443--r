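#' Differential dose-volume histograms
#'
#' A differential DVH (dDVH) records, for contiguous half-open dose bins
#' `(lower, upper]` of a common width, the percentage of the target volume
#' receiving a dose in each bin. It is the carrier of the per-bin doses and
#' fractional volumes that the survival-averaged BED formulas consume.
#'
#' @param bins data.frame with numeric columns `lower`, `upper` (Gy) and
#'   `volume` (percent of target volume), rows sorted by dose.
#' @param bin_width common bin width in Gy.
#' @param dose_scale `"per_fraction"` or `"total_course"`: whether the dose
#'   axis is a single-fraction dose or the accumulated course dose. BED
#'   formulas require the per-fraction axis; [rescale_dose_axis()] converts.
#' @param label free-text identifier (e.g. patient/fraction id).
#' @param partial if `TRUE`, the histogram is a fragment of a full dDVH and
#'   the volumes are not required to sum to 100. Fragments support the
#'   descriptive statistics but are rejected by the BED functions.
#' @return An object of class `ddvh`.
#' @seealso [build_ddvh()] to bin raw dose samples, [read_ddvh_csv()].
#' @examples
#' d <- ddvh(data.frame(lower = c(3.3, 3.4), upper = c(3.4, 3.5),
#'                      volume = c(40, 60)),
#'           bin_width = 0.1, dose_scale = "per_fraction")
#' mean_dose(d)
#' @export
ddvh <- function(bins, bin_width, dose_scale = c("per_fraction", "total_course"),
                 label = "", partial = FALSE) {
  dose_scale <- match.arg(dose_scale)
  stopifnot(is.data.frame(bins), all(c("lower", "upper", "volume") %in% names(bins)))
  bins <- as.data.frame(bins)[c("lower", "upper", "volume")]
  obj <- structure(
    list(bins = bins, bin_width = as.numeric(bin_width),
         dose_scale = dose_scale, label = as.character(label),
         partial = isTRUE(partial)),
    class = "ddvh")
  validate_ddvh(obj)
  obj
}

#' Validate a differential DVH
#'
#' Checks the structural invariants: positive common bin width, contiguous
#' non-overlapping ascending bins, non-negative volumes, and (unless the
#' object is flagged partial) volumes summing to 100 within `tol`.
#'
#' @param x a `ddvh` object.
#' @param tol absolute tolerance on the 100 percent volume sum.
#' @return `x`, invisibly; errors on violation.
#' @export
validate_ddvh <- function(x, tol = 1e-6) {
  stopifnot(inherits(x, "ddvh"))
  b <- x$bins
  if (nrow(b) < 1L) stop("ddvh must contain at least one bin")
  if (!(x$bin_width > 0)) stop("bin_width must be positive")
  w <- b$upper - b$lower
  if (any(w <= 0)) stop("each bin must satisfy lower < upper")
  if (any(abs(w - x$bin_width) > 1e-9 * max(1, x$bin_width)))
    stop("all bins must share the common bin_width")
  if (nrow(b) > 1L) {
    gap <- b$lower[-1L] - b$upper[-nrow(b)]
    if (any(abs(gap) > 1e-9 * max(1, x$bin_width)))
      stop("bins must be contiguous, non-overlapping and sorted ascending")
  }
  if (any(b$volume < 0)) stop("fractional volumes must be non-negative")
  if (!x$partial && abs(sum(b$volume) - 100) > tol)
    stop(sprintf("fractional volumes must sum to 100%% (got %.8f)", sum(b$volume)))
  invisible(x)
}

#' @export
print.ddvh <- function(x, ...) {
  cat(sprintf("Differential DVH%s: %d bins of %g Gy (%s axis), %.6g..%.6g Gy, total %.4f%%\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              nrow(x$bins), x$bin_width, x$dose_scale,
              min(x$bins$lower), max(x$bins$upper), sum(x$bins$volume)))
  invisible(x)
}

# bin index on the grid (k-1)*w < dose <= k*w, robust to doses sitting on an
# edge to within ~1e-9 relative floating error
.bin_index <- function(dose, bin_width) {
  as.integer(ceiling(dose / bin_width - 1e-9))
}

#' Bin dose samples into a differential DVH
#'
#' Each sample's volume weight is assigned to the unique half-open bin
#' `(lower, upper]` of width `bin_width` on the grid anchored at 0 Gy that
#' contains its dose; a dose exactly on an edge belongs to the bin below.
#' Fractional volumes are normalised to sum to 100 percent, and empty bins
#' interior to the occupied range are kept (zero volume) so the result is
#' contiguous.
#'
#' @param doses numeric vector of non-negative doses (Gy).
#' @param weights volume weights, recycled to `length(doses)`; default equal.
#' @param bin_width bin width in Gy (default 0.1).
#' @inheritParams ddvh
#' @return a `ddvh`.
#' @export
build_ddvh <- function(doses, weights = NULL, bin_width = 0.1,
                       dose_scale = c("per_fraction", "total_course"),
                       label = "") {
  dose_scale <- match.arg(dose_scale)
  if (length(doses) < 1L) stop("at least one dose sample is required")
  if (any(!is.finite(doses)) || any(doses < 0)) stop("doses must be finite and non-negative")
  if (!(bin_width > 0)) stop("bin_width must be positive")
  if (is.null(weights)) weights <- rep(1, length(doses))
  weights <- rep_len(weights, length(doses))
  if (any(!is.finite(weights)) || any(weights < 0)) stop("weights must be finite and non-negative")
  if (sum(weights) <= 0) stop("total sample weight must be positive")

  idx <- .bin_index(doses, bin_width)
  lo <- min(idx); hi <- max(idx)
  vol <- numeric(hi - lo + 1L)
  tab <- tapply(weights, idx, sum)
  vol[as.integer(names(tab)) - lo + 1L] <- as.numeric(tab)
  vol <- 100 * vol / sum(vol)
  k <- seq.int(lo, hi)
  ddvh(data.frame(lower = (k - 1L) * bin_width, upper = k * bin_width, volume = vol),
       bin_width = bin_width, dose_scale = dose_scale, label = label)
}

#' Fraction of volume within an edge-aligned dose range
#'
#' Sums the fractional volumes of the bins fully inside the half-open range
#' `(low, high]`. The range must align with bin edges; a misaligned range is
#' an error naming the nearest aligned edges rather than silently
#' interpolating inside a bin.
#'
#' @param x a `ddvh`.
#' @param low,high range bounds in Gy, `low < high`, on bin edges.
#' @return percent of target volume.
#' @export
fraction_in_range <- function(x, low, high) {
  validate_ddvh(x)
  if (!(low < high)) stop("low must be < high")
  edges <- c(x$bins$lower, x$bins$upper[nrow(x$bins)])
  tol <- 1e-9 * max(1, x$bin_width)
  snap <- function(v) {
    if (v <= edges[1L] + tol || v >= edges[length(edges)] - tol) return(v)
    d <- abs(edges - v)
    if (min(d) > tol) {
      near <- sort(edges[order(d)][1:2])
      stop(sprintf("range bound %.6g Gy is not on a bin edge; nearest aligned edges are %.6g and %.6g Gy",
                   v, near[1L], near[2L]))
    }
    edges[which.min(d)]
  }
  low <- snap(low); high <- snap(high)
  keep <- x$bins$lower >= low - tol & x$bins$upper <= high + tol
  sum(x$bins$volume[keep])
}

#' Volume-weighted mean dose of a differential DVH
#'
#' Uses the bin midpoint as the representative dose of each bin.
#'
#' @param x a `ddvh` (fragments allowed).
#' @return mean dose in Gy.
#' @export
mean_dose <- function(x) {
  validate_ddvh(x)
  mid <- (x$bins$lower + x$bins$upper) / 2
  sum(x$bins$volume * mid) / sum(x$bins$volume)
}

#' Modal (most probable) dose of a differential DVH
#'
#' Midpoint of the bin holding the largest fractional volume; ties are broken
#' deterministically towards the lowest dose.
#'
#' @inheritParams mean_dose
#' @return modal dose in Gy.
#' @export
modal_dose <- function(x) {
  validate_ddvh(x)
  i <- which.max(x$bins$volume)  # which.max returns the first (lowest-dose) maximum
  (x$bins$lower[i] + x$bins$upper[i]) / 2
}

#' Group-average differential DVH
#'
#' Per-bin arithmetic mean of fractional volumes across a set of dDVHs
#' sharing bin width and dose axis; supports are unioned with zero fill, so
#' a bin absent from a histogram contributes zero volume for it.
#'
#' @param xs list of `ddvh` objects.
#' @param label label for the averaged histogram.
#' @return a `ddvh`.
#' @export
group_average <- function(xs, label = "group average") {
  if (!is.list(xs) || length(xs) < 1L) stop("xs must be a non-empty list of ddvh objects")
  lapply(xs, validate_ddvh)
  bw <- xs[[1L]]$bin_width
  scale <- xs[[1L]]$dose_scale
  for (x in xs) {
    if (abs(x$bin_width - bw) > 1e-12) stop("all dDVHs must share bin_width")
    if (!identical(x$dose_scale, scale)) stop("all dDVHs must share dose_scale")
  }
  lo <- min(vapply(xs, function(x) .bin_index(x$bins$upper[1L], bw), integer(1)))
  hi <- max(vapply(xs, function(x) .bin_index(x$bins$upper[nrow(x$bins)], bw), integer(1)))
  acc <- numeric(hi - lo + 1L)
  for (x in xs) {
    k <- .bin_index(x$bins$upper, bw)
    acc[k - lo + 1L] <- acc[k - lo + 1L] + x$bins$volume
  }
  acc <- acc / length(xs)
  k <- seq.int(lo, hi)
  ddvh(data.frame(lower = (k - 1L) * bw, upper = k * bw, volume = acc),
       bin_width = bw, dose_scale = scale, label = label,
       partial = any(vapply(xs, function(x) x$partial, logical(1))))
}

#' Rescale the dose axis of a differential DVH
#'
#' Multiplies all bin edges (and the bin width) by `factor`, leaving volumes
#' untouched. Used to convert between the total-course and per-fraction dose
#' axes (factor `1/n` or `n`); the survival-averaged BED formulas consume the
#' per-fraction axis.
#'
#' @param x a `ddvh`.
#' @param factor positive scale factor for the dose axis.
#' @param dose_scale dose axis of the result; defaults to that of `x`.
#' @return a `ddvh`.
#' @export
rescale_dose_axis <- function(x, factor, dose_scale = x$dose_scale) {
  validate_ddvh(x)
  if (!(factor > 0)) stop("factor must be positive")
  b <- x$bins
  ddvh(data.frame(lower = b$lower * factor, upper = b$upper * factor,
                  volume = b$volume),
       bin_width = x$bin_width * factor, dose_scale = dose_scale,
       label = x$label, partial = x$partial)
}

#' Cumulative dose-volume histogram
#'
#' Percent of target volume receiving more than each threshold dose
#' (volume at-or-above in the half-open bin convention).
#'
#' @param thresholds ascending dose thresholds (Gy).
#' @param volume_at_or_above percent volume receiving dose above each
#'   threshold; non-increasing.
#' @param label free-text identifier.
#' @return an object of class `cdvh`.
#' @export
cdvh <- function(thresholds, volume_at_or_above, label = "") {
  if (length(thresholds) != length(volume_at_or_above))
    stop("thresholds and volume_at_or_above must have equal length")
  if (is.unsorted(thresholds, strictly = TRUE)) stop("thresholds must be strictly ascending")
  if (any(diff(volume_at_or_above) > 1e-9))
    stop("volume_at_or_above must be non-increasing in threshold")
  structure(list(thresholds = as.numeric(thresholds),
                 volume_at_or_above = as.numeric(volume_at_or_above),
                 label = as.character(label)),
            class = "cdvh")
}

#' @export
print.cdvh <- function(x, ...) {
  cat(sprintf("Cumulative DVH%s: %d thresholds, %.6g..%.6g Gy, top volume %.4f%%\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              length(x$thresholds), min(x$thresholds), max(x$thresholds),
              x$volume_at_or_above[1L]))
  invisible(x)
}

#' Convert between differential and cumulative DVHs
#'
#' The cumulative value at a bin's lower edge is the suffix sum of the
#' differential volumes from that bin upward, so the round trip
#' differential -> cumulative -> differential is exact to floating rounding.
#'
#' @param x a `ddvh` (or, for the inverse, a `cdvh` whose thresholds lie on
#'   a uniform grid of `bin_width`).
#' @return a `cdvh` / `ddvh`.
#' @export
cumulative_from_differential <- function(x) {
  validate_ddvh(x)
  cdvh(thresholds = x$bins$lower,
       volume_at_or_above = rev(cumsum(rev(x$bins$volume))),
       label = x$label)
}

#' @rdname cumulative_from_differential
#' @param bin_width bin width (Gy) of the reconstructed differential DVH;
#'   must match the threshold spacing.
#' @param dose_scale dose axis of the reconstructed dDVH.
#' @param partial mark the reconstruction as a fragment (volumes need not sum
#'   to 100).
#' @export
differential_from_cumulative <- function(x, bin_width,
                                         dose_scale = c("per_fraction", "total_course"),
                                         partial = FALSE) {
  dose_scale <- match.arg(dose_scale)
  stopifnot(inherits(x, "cdvh"))
  if (any(abs(diff(x$thresholds) - bin_width) > 1e-9 * max(1, bin_width)))
    stop("cdvh thresholds must be spaced by bin_width")
  vol <- -diff(c(x$volume_at_or_above, 0))
  ddvh(data.frame(lower = x$thresholds, upper = x$thresholds + bin_width,
                  volume = vol),
       bin_width = bin_width, dose_scale = dose_scale, label = x$label,
       partial = partial)
}
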