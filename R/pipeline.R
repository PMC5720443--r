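#' Round half away from zero
#'
#' Report-display rounding (1 decimal by default) that rounds .5 away from
#' zero, matching clinical table style, unlike base `round()`'s
#' round-half-even.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return numeric.
#' @export
round_half_away <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

.comparison_row <- function(patient_id, endpoint, bed_a, bed_b, delivered = NA_integer_) {
  data.frame(patient = patient_id, endpoint = endpoint$name,
             alpha_beta = endpoint$alpha_beta,
             bed_a = bed_a, bed_b = bed_b,
             diff = bed_b - bed_a, rel_diff = 100 * (bed_b - bed_a) / bed_a,
             delivered_fractions = delivered)
}

#' Constant case versus interfraction variation case
#'
#' For one patient, compares the constant-case BED (fraction 1's dose
#' distribution assumed to recur in every fraction) against the
#' interfraction-variation total (each delivered fraction contributing its
#' own distribution). When fewer fractions than `scheme$n_fractions` were
#' delivered (missing pre-fraction imaging), the delivered count replaces n
#' in both arms so the comparison stays consistent.
#'
#' @param ddvhs list of per-fraction `ddvh`s, fraction 1 first.
#' @param scheme a [fractionation_scheme()].
#' @param endpoint an [endpoint_params()].
#' @param patient_id identifier recorded in the result row.
#' @return one-row data.frame: `bed_a` = CC, `bed_b` = IVC, `diff` = b - a,
#'   `rel_diff` = 100 diff / a.
#' @export
compare_cc_ivc <- function(ddvhs, scheme, endpoint, patient_id = "") {
  if (!is.list(ddvhs) || length(ddvhs) < 1L)
    stop("fraction 1 dDVH is required")
  delivered <- length(ddvhs)
  eff <- fractionation_scheme(n_fractions = delivered,
                              fraction_dose = scheme$fraction_dose,
                              elapsed_time = scheme$elapsed_time)
  cc <- bed_heterogeneous_cc(ddvhs[[1L]], eff, endpoint)
  ivc <- bed_total_ivc(ddvhs, eff, endpoint)
  .comparison_row(patient_id, endpoint, cc$value, ivc$value, delivered)
}

#' Heterogeneity-corrected versus conventional BED
#'
#' Compares the conventional BED (uniform prescription dose; C-method)
#' against the survival-averaged BED of the fraction-1 dose distribution
#' assumed constant over the course (H-method).
#'
#' @param x fraction-1 `ddvh` on the per-fraction axis.
#' @inheritParams compare_cc_ivc
#' @return one-row data.frame: `bed_a` = conventional, `bed_b` =
#'   heterogeneity-corrected.
#' @export
compare_h_c <- function(x, scheme, endpoint, patient_id = "") {
  cv <- bed_conventional(scheme, endpoint)
  h <- bed_heterogeneous_cc(x, scheme, endpoint)
  .comparison_row(patient_id, endpoint, cv$value, h$value, scheme$n_fractions)
}

#' Cohort summary of comparison rows
#'
#' Average, sample standard deviation (n - 1 denominator), and minimum /
#' maximum with the patient attaining them, for both the Gy difference and
#' the relative (percent) difference.
#'
#' @param rows data.frame of comparison rows for one endpoint (>= 2 rows).
#' @return one-row data.frame with `*_gy` and `*_pct` summary columns.
#' @export
summarize_comparisons <- function(rows) {
  if (!is.data.frame(rows) || nrow(rows) < 2L)
    stop("at least 2 comparison rows are required")
  stat <- function(v) list(avg = mean(v), sd = stats::sd(v),
                           min = min(v), argmin = rows$patient[which.min(v)],
                           max = max(v), argmax = rows$patient[which.max(v)])
  g <- stat(rows$diff); p <- stat(rows$rel_diff)
  data.frame(endpoint = rows$endpoint[1L], alpha_beta = rows$alpha_beta[1L],
             n = nrow(rows),
             avg_gy = g$avg, sd_gy = g$sd,
             min_gy = g$min, min_patient = g$argmin,
             max_gy = g$max, max_patient = g$argmax,
             avg_pct = p$avg, sd_pct = p$sd,
             min_pct = p$min, min_pct_patient = p$argmin,
             max_pct = p$max, max_pct_patient = p$argmax)
}

.round_df <- function(df, digits = 1) {
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], round_half_away, digits = digits)
  df
}

#' Run the full cohort BED study
#'
#' For every endpoint: per-patient constant-case versus
#' interfraction-variation rows with cohort summaries, per-patient
#' heterogeneity-corrected versus conventional rows with summaries, the
#' conventional reference value, and per-patient CC/IVC BED values over the
#' alpha/beta grid (curve table). Optionally writes each table as CSV
#' (values displayed at 1 decimal) and the whole bundle as JSON (unrounded).
#'
#' @param cohort a `synthetic_cohort`, or a list (per patient id) of lists
#'   of per-fraction `ddvh`s as returned by [read_cohort_manifest()]`$ddvhs`.
#' @param scheme a [fractionation_scheme()].
#' @param endpoints named list of [endpoint_params()]; default the registry
#'   of [default_endpoints()].
#' @param out_dir if non-NULL, directory to write `cc_ivc_rows.csv`,
#'   `cc_ivc_summary.csv`, `h_c_rows.csv`, `h_c_summary.csv`,
#'   `c_method.csv`, `bed_curves.csv` and `report.json`.
#' @return list of the tables described above, invisibly also written to
#'   `out_dir` when given.
#' @export
run_study <- function(cohort, scheme = fractionation_scheme(),
                      endpoints = default_endpoints(), out_dir = NULL) {
  if (inherits(cohort, "synthetic_cohort")) {
    ddvhs <- stats::setNames(lapply(cohort$patients, `[[`, "ddvhs"),
                             vapply(cohort$patients, `[[`, character(1), "id"))
  } else ddvhs <- cohort
  if (!is.list(ddvhs) || is.null(names(ddvhs)))
    stop("cohort must be a synthetic_cohort or a named list of per-fraction dDVH lists")
  for (e in endpoints)
    if (!inherits(e, "endpoint_params")) stop("endpoints must be endpoint_params objects")
  cc_rows <- list(); hc_rows <- list()
  for (en in names(endpoints)) {
    ep <- endpoints[[en]]
    for (pid in names(ddvhs)) {
      cc_rows[[length(cc_rows) + 1L]] <- compare_cc_ivc(ddvhs[[pid]], scheme, ep, pid)
      hc_rows[[length(hc_rows) + 1L]] <- compare_h_c(ddvhs[[pid]][[1L]], scheme, ep, pid)
    }
  }
  cc_rows <- do.call(rbind, cc_rows); hc_rows <- do.call(rbind, hc_rows)
  by_ep <- function(rows) do.call(rbind, lapply(split(rows, rows$endpoint)[unique(rows$endpoint)],
                                                summarize_comparisons))
  cc_sum <- by_ep(cc_rows); hc_sum <- by_ep(hc_rows)
  c_method <- do.call(rbind, lapply(endpoints, function(ep)
    data.frame(endpoint = ep$name, alpha_beta = ep$alpha_beta,
               bed_conventional = bed_conventional(scheme, ep)$value)))
  curves <- data.frame(patient = cc_rows$patient, alpha_beta = cc_rows$alpha_beta,
                       endpoint = cc_rows$endpoint,
                       bed_cc = cc_rows$bed_a, bed_ivc = cc_rows$bed_b)
  curves <- curves[order(curves$patient, curves$alpha_beta), , drop = FALSE]
  rownames(cc_rows) <- rownames(hc_rows) <- rownames(cc_sum) <-
    rownames(hc_sum) <- rownames(c_method) <- rownames(curves) <- NULL
  report <- list(cc_ivc_rows = cc_rows, cc_ivc_summary = cc_sum,
                 h_c_rows = hc_rows, h_c_summary = hc_sum,
                 c_method = c_method, bed_curves = curves,
                 scheme = unclass(scheme))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in c("cc_ivc_rows", "cc_ivc_summary", "h_c_rows", "h_c_summary",
                 "c_method", "bed_curves"))
      utils::write.csv(.round_df(report[[nm]]), file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE, quote = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  report
}
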