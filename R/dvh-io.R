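#' Read and write differential DVHs as CSV
#'
#' File format: UTF-8 CSV with header
#' `bin_low_gy,bin_high_gy,fractional_volume_pct`, one row per bin in
#' ascending dose order, '.' decimal separator. The reader validates the
#' dDVH invariants on load.
#'
#' @param path file path.
#' @param dose_scale dose axis of the stored histogram.
#' @param label label for the loaded object; defaults to the file name.
#' @param partial allow a fragment whose volumes do not sum to 100.
#' @return a `ddvh`.
#' @export
read_ddvh_csv <- function(path, dose_scale = c("per_fraction", "total_course"),
                          label = basename(path), partial = FALSE) {
  dose_scale <- match.arg(dose_scale)
  df <- utils::read.csv(path, colClasses = "numeric")
  need <- c("bin_low_gy", "bin_high_gy", "fractional_volume_pct")
  if (!all(need %in% names(df)))
    stop("dDVH CSV must have columns ", paste(need, collapse = ", "))
  w <- df$bin_high_gy - df$bin_low_gy
  ddvh(data.frame(lower = df$bin_low_gy, upper = df$bin_high_gy,
                  volume = df$fractional_volume_pct),
       bin_width = stats::median(w), dose_scale = dose_scale,
       label = label, partial = partial)
}

#' @rdname read_ddvh_csv
#' @param x a `ddvh` to write.
#' @param digits significant digits used when formatting values; the default
#'   round-trips doubles exactly.
#' @export
write_ddvh_csv <- function(x, path, digits = 17L) {
  validate_ddvh(x)
  b <- x$bins[order(x$bins$lower), , drop = FALSE]
  lines <- c("bin_low_gy,bin_high_gy,fractional_volume_pct",
             sprintf("%s,%s,%s",
                     formatC(b$lower, digits = digits, format = "g"),
                     formatC(b$upper, digits = digits, format = "g"),
                     formatC(b$volume, digits = digits, format = "g")))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read and write a cohort manifest
#'
#' A cohort on disk is one dDVH CSV per patient-fraction plus a manifest CSV
#' with columns `patient,fraction,path,dose_scale`; paths are relative to the
#' manifest's directory.
#'
#' @param path manifest CSV path.
#' @return `read_cohort_manifest()`: a list with `manifest` (data.frame) and
#'   `ddvhs`, a list (per patient id) of lists of `ddvh` ordered by fraction.
#' @export
read_cohort_manifest <- function(path) {
  mf <- utils::read.csv(path, colClasses = c("character", "integer", "character", "character"))
  need <- c("patient", "fraction", "path", "dose_scale")
  if (!all(need %in% names(mf))) stop("manifest must have columns ", paste(need, collapse = ", "))
  base <- dirname(path)
  ddvhs <- list()
  for (pid in unique(mf$patient)) {
    rows <- mf[mf$patient == pid, , drop = FALSE]
    rows <- rows[order(rows$fraction), , drop = FALSE]
    ddvhs[[pid]] <- lapply(seq_len(nrow(rows)), function(i) {
      read_ddvh_csv(file.path(base, rows$path[i]), dose_scale = rows$dose_scale[i],
                    label = sprintf("%s_f%d", pid, rows$fraction[i]))
    })
  }
  list(manifest = mf, ddvhs = ddvhs)
}

#' @rdname read_cohort_manifest
#' @param ddvhs list (per patient id) of lists of per-fraction `ddvh`s.
#' @param dir output directory; created if needed.
#' @return `write_cohort_csv()`: the manifest path, invisibly.
#' @export
write_cohort_csv <- function(ddvhs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (pid in names(ddvhs)) {
    for (f in seq_along(ddvhs[[pid]])) {
      fn <- sprintf("%s_f%d.csv", pid, f)
      write_ddvh_csv(ddvhs[[pid]][[f]], file.path(dir, fn))
      rows[[length(rows) + 1L]] <- data.frame(
        patient = pid, fraction = f, path = fn,
        dose_scale = ddvhs[[pid]][[f]]$dose_scale)
    }
  }
  mf <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(mf, mpath, row.names = FALSE, quote = FALSE)
  invisible(mpath)
}
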