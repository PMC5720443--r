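#' Linear-quadratic log cell survival for uniform irradiation
#'
#' Returns ln S = -alpha * n * d * (1 + d / (alpha/beta)), the log survival
#' fraction after n fractions of d Gy each under the linear-quadratic model,
#' without the repopulation term. The value is kept in the log domain because
#' per-bin exponents in balloon brachytherapy exceed the double-precision
#' exponent range (|ln S| > 2000 near the balloon surface); callers
#' exponentiate only under a log-sum-exp shift.
#'
#' @param dose_per_fraction dose per fraction in Gy (>= 0); vectorised.
#' @param n number of fractions.
#' @param params an [endpoint_params()].
#' @return ln S (dimensionless, <= 0).
#' @export
survival_uniform <- function(dose_per_fraction, n, params) {
  stopifnot(inherits(params, "endpoint_params"), all(dose_per_fraction >= 0))
  -params$alpha * n * dose_per_fraction * (1 + dose_per_fraction / params$alpha_beta)
}

#' Repopulation correction of the BED
#'
#' (ln 2) * T / (alpha * Teff) in Gy, subtracted from the dose-response part
#' of the BED, or 0 for endpoints without repopulation.
#'
#' @param params an [endpoint_params()].
#' @param elapsed_time overall treatment time T in days.
#' @return Gy.
#' @export
repopulation_term <- function(params, elapsed_time) {
  stopifnot(inherits(params, "endpoint_params"), elapsed_time >= 0)
  if (!params$includes_repopulation) return(0)
  log(2) * elapsed_time / (params$alpha * params$teff)
}

.bed_value <- function(value, endpoint, method, repop) {
  structure(list(value = value, endpoint = endpoint, method = method,
                 repopulation_component = repop),
            class = "bed_value")
}

#' @export
print.bed_value <- function(x, ...) {
  cat(sprintf("BED [%s, %s]: %.1f Gy (repopulation component %.2f Gy)\n",
              x$method, x$endpoint$name, x$value, x$repopulation_component))
  invisible(x)
}

#' Conventional BED of a uniform fractionation scheme
#'
#' BED = n d (1 + d/(alpha/beta)) - (ln 2) T / (alpha Teff), assuming every
#' cell of the target receives the prescribed fractional dose d in each of
#' the n fractions. The repopulation subtraction applies only to endpoints
#' with `includes_repopulation = TRUE`.
#'
#' @param scheme a [fractionation_scheme()].
#' @param params an [endpoint_params()].
#' @return a `bed_value` with method `"conventional"`.
#' @examples
#' bed_conventional(fractionation_scheme(10, 3.4),
#'                  endpoint_params("fibrosis", 2))  # 91.8 Gy
#' @export
bed_conventional <- function(scheme, params) {
  stopifnot(inherits(scheme, "fractionation_scheme"))
  repop <- repopulation_term(params, scheme$elapsed_time)
  d <- scheme$fraction_dose
  val <- scheme$n_fractions * d * (1 + d / params$alpha_beta) - repop
  .bed_value(val, params, "conventional", repop)
}

#' Negative log of a volume-weighted survival sum
#'
#' Computes -ln( sum_i v_i exp(ls_i) ) for unit-fraction weights v_i and log
#' survivals ls_i, by shifting all exponents by max(ls_i) before
#' exponentiating (log-sum-exp), so that exponents far beyond the
#' double-precision underflow threshold (|ls| >> 700) still yield a finite,
#' accurate result.
#'
#' @param weights non-negative weights summing to 1 within `tol`.
#' @param log_survivals log survival fractions, same length as `weights`.
#' @param tol tolerance on the weight sum.
#' @param renormalize if `TRUE`, weights off by more than `tol` are rescaled
#'   to sum to 1 instead of raising an error.
#' @return dimensionless negative log survival (alpha * BED, before the
#'   repopulation subtraction).
#' @export
neg_log_weighted_survival <- function(weights, log_survivals, tol = 1e-6,
                                      renormalize = FALSE) {
  if (length(weights) != length(log_survivals))
    stop("weights and log_survivals must have equal length")
  if (any(weights < 0)) stop("weights must be non-negative")
  s <- sum(weights)
  if (abs(s - 1) > tol) {
    if (!renormalize)
      stop(sprintf("weights must sum to 1 within %g (got %.10f); set renormalize = TRUE to rescale", tol, s))
    weights <- weights / s
  }
  keep <- weights > 0
  w <- weights[keep]; ls <- log_survivals[keep]
  m <- max(ls)
  -(m + log(sum(w * exp(ls - m))))
}

.require_per_fraction <- function(x) {
  validate_ddvh(x)
  if (x$partial) stop("BED calculations require a full (non-partial) dDVH")
  if (!identical(x$dose_scale, "per_fraction"))
    stop("dDVH is on the total_course axis; convert with rescale_dose_axis(x, 1/n, \"per_fraction\")")
  invisible(x)
}

# midpoint doses and unit-fraction volumes of the occupied bins
.ddvh_dv <- function(x) {
  keep <- x$bins$volume > 0
  list(d = (x$bins$lower[keep] + x$bins$upper[keep]) / 2,
       v = x$bins$volume[keep] / 100)
}

#' Heterogeneity-corrected BED, constant case
#'
#' Survival-averaged BED assuming the nonuniform dose distribution of the
#' differential DVH recurs unchanged in every one of the n fractions
#' (constant case, CC):
#' BED = -(1/alpha) ln( sum_i v_i exp(-alpha n d_i (1 + d_i/(alpha/beta))) )
#' minus the repopulation term. Bin representative dose d_i is the bin
#' midpoint; the aggregation runs in the log domain.
#'
#' @param x a `ddvh` on the per-fraction dose axis.
#' @inheritParams bed_conventional
#' @param renormalize passed to [neg_log_weighted_survival()].
#' @return a `bed_value` with method `"heterogeneous_cc"`.
#' @export
bed_heterogeneous_cc <- function(x, scheme, params, renormalize = FALSE) {
  .require_per_fraction(x)
  stopifnot(inherits(scheme, "fractionation_scheme"))
  dv <- .ddvh_dv(x)
  ls <- survival_uniform(dv$d, scheme$n_fractions, params)
  repop <- repopulation_term(params, scheme$elapsed_time)
  val <- neg_log_weighted_survival(dv$v, ls, renormalize = renormalize) / params$alpha - repop
  .bed_value(val, params, "heterogeneous_cc", repop)
}

#' Per-fraction heterogeneity-corrected BED
#'
#' BED contribution of one delivered fraction with its own dose
#' distribution:
#' BED_f = -(1/alpha) ln( sum_i v_i exp(-alpha d_i (1 + d_i/(alpha/beta))) )
#' minus 1/n of the course repopulation term, the repopulation correction
#' being independent of the per-fraction dose distribution and therefore
#' shared equally across the n fractions of the scheme.
#'
#' @inheritParams bed_heterogeneous_cc
#' @return a `bed_value` with method `"fractional_ivc"`.
#' @export
bed_fraction_ivc <- function(x, scheme, params, renormalize = FALSE) {
  .require_per_fraction(x)
  stopifnot(inherits(scheme, "fractionation_scheme"))
  dv <- .ddvh_dv(x)
  ls <- survival_uniform(dv$d, 1L, params)
  repop <- repopulation_term(params, scheme$elapsed_time) / scheme$n_fractions
  val <- neg_log_weighted_survival(dv$v, ls, renormalize = renormalize) / params$alpha - repop
  .bed_value(val, params, "fractional_ivc", repop)
}

#' Total BED under interfraction dose variation
#'
#' Sum of [bed_fraction_ivc()] over the delivered fractions, each with its
#' own differential DVH (interfraction variation case, IVC). When fewer
#' dDVHs than `scheme$n_fractions` are supplied, only the delivered
#' fractions' dose response and repopulation shares are accumulated.
#'
#' @param xs list of per-fraction `ddvh`s, one per delivered fraction.
#' @inheritParams bed_heterogeneous_cc
#' @return a `bed_value` with method `"total_ivc"`.
#' @export
bed_total_ivc <- function(xs, scheme, params, renormalize = FALSE) {
  if (!is.list(xs) || length(xs) < 1L) stop("xs must be a non-empty list of per-fraction dDVHs")
  parts <- lapply(xs, bed_fraction_ivc, scheme = scheme, params = params,
                  renormalize = renormalize)
  .bed_value(sum(vapply(parts, function(b) b$value, numeric(1))),
             params, "total_ivc",
             sum(vapply(parts, function(b) b$repopulation_component, numeric(1))))
}
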