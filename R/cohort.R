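#' Interfraction geometric perturbation model
#'
#' Distributions of the per-fraction changes of the applicator: Gaussian
#' balloon-radius and chain-offset perturbations (truncated so the geometry
#' stays valid) and a uniform trapped-air-gap volume fraction that adds to
#' the excluded cap. The magnitudes are study inputs, not measurements; the
#' defaults are small, plausible values and any quantitative study should
#' set them explicitly.
#'
#' @param radius_sd SD of the balloon-radius change in cm.
#' @param offset_sd per-axis SD of the chain-offset change in cm.
#' @param airgap_fraction_range range (length-2) of the uniform air-gap
#'   volume fraction.
#' @param seed base integer seed of the perturbation and sampling streams.
#' @return an object of class `perturbation_model`.
#' @export
perturbation_model <- function(radius_sd = 0.05, offset_sd = 0.2,
                               airgap_fraction_range = c(0, 0.05),
                               seed = 1L) {
  stopifnot(radius_sd >= 0, offset_sd >= 0,
            length(airgap_fraction_range) == 2,
            all(airgap_fraction_range >= 0), all(airgap_fraction_range < 0.5),
            airgap_fraction_range[1] <= airgap_fraction_range[2])
  structure(list(radius_sd = radius_sd, offset_sd = offset_sd,
                 airgap_fraction_range = as.numeric(airgap_fraction_range),
                 seed = as.integer(seed)),
            class = "perturbation_model")
}

# per-fraction geometry draw; fraction 1 is the unperturbed plan
.perturb_geometry <- function(geom, perturbation, patient_index, fraction_index) {
  if (fraction_index == 1L ||
      (perturbation$radius_sd == 0 && perturbation$offset_sd == 0 &&
       diff(perturbation$airgap_fraction_range) == 0 &&
       perturbation$airgap_fraction_range[1] == 0))
    return(geom)
  s <- .substream_seed(perturbation$seed, patient_index, fraction_index)
  .with_seed(s, {
    dr <- stats::rnorm(1, 0, perturbation$radius_sd)
    dr <- max(dr, -0.5 * geom$balloon_radius)           # keep radius positive
    off <- geom$source_offset + stats::rnorm(3, 0, perturbation$offset_sd)
    half_span <- (geom$dwell_positions - 1) * geom$dwell_spacing / 2
    lim <- 0.9 * (geom$balloon_radius + dr + 1 - half_span)
    off <- pmin(pmax(off, -lim), lim)                   # chain stays inside
    air <- stats::runif(1, perturbation$airgap_fraction_range[1],
                        perturbation$airgap_fraction_range[2])
    excl <- min(geom$excluded_volume_fraction + air, 0.49)
    balloon_geometry(balloon_radius = geom$balloon_radius + dr,
                     prescription_dose = geom$prescription_dose,
                     dwell_positions = geom$dwell_positions,
                     dwell_spacing = geom$dwell_spacing,
                     source_offset = off,
                     cold_axis_halfangle = geom$cold_axis_halfangle,
                     cold_axis_factor = geom$cold_axis_factor,
                     excluded_volume_fraction = excl)
  })
}

#' Differential DVH of one delivered fraction
#'
#' Draws the fraction's applicator geometry from the perturbation model
#' (fraction 1 is the unperturbed plan), evaluates the dose of a per-patient
#' point cloud under that geometry while keeping the dose normalisation of
#' the unperturbed fraction-1 plan (the plan's dwell configuration is
#' delivered unmodified in every fraction), and bins the doses on the
#' per-fraction axis. The point cloud is seeded by (seed, patient) and the
#' geometry draw by (seed, patient, fraction), so with a zero-spread
#' perturbation every fraction reproduces fraction 1 exactly.
#'
#' @param geom the patient's planned [balloon_geometry()].
#' @param perturbation a [perturbation_model()].
#' @param patient_index integer patient tag entering the seed streams.
#' @param fraction_index fraction number (1-based).
#' @param bin_width dDVH bin width in Gy on the per-fraction axis; the
#'   default 0.01 Gy corresponds to 0.1 Gy bins on a 10-fraction
#'   total-course axis.
#' @param n_samples points in the per-patient cloud.
#' @return a `ddvh` on the per-fraction axis.
#' @export
generate_fraction_ddvh <- function(geom, perturbation, patient_index,
                                   fraction_index, bin_width = 0.01,
                                   n_samples = 200000) {
  stopifnot(inherits(geom, "balloon_geometry"),
            inherits(perturbation, "perturbation_model"))
  cloud <- .shell_cloud(n_samples, .substream_seed(perturbation$seed, patient_index))
  g <- .perturb_geometry(geom, perturbation, patient_index, fraction_index)
  dose <- .cloud_doses(g, cloud, norm = .dose_norm(geom))
  build_ddvh(dose, bin_width = bin_width, dose_scale = "per_fraction",
             label = sprintf("p%d_f%d", patient_index, fraction_index))
}

#' Synthetic cohort configuration
#'
#' Defaults follow the clinical setting the generator emulates: 19 patients,
#' balloon diameters uniform on 4.0--5.5 cm with 7--10 dwell positions by
#' diameter, 3.4 Gy per fraction in 10 fractions prescribed at the 1 cm
#' balloon expansion, an axial cold cone, and small skin/lung exclusion caps.
#'
#' @param n_patients number of patients.
#' @param diameter_range balloon diameter range in cm.
#' @param n_fractions fractions per patient.
#' @param prescription_dose Gy per fraction.
#' @param bin_width dDVH bin width (Gy, per-fraction axis).
#' @param n_samples point-cloud size per patient.
#' @param dwell_spacing cm between dwell positions.
#' @param cold_axis_halfangle,cold_axis_factor axial cold-cone parameters.
#' @param excluded_range range of the per-patient skin/lung exclusion cap
#'   fraction.
#' @param perturbation a [perturbation_model()]; its `seed` is overridden by
#'   `seed`.
#' @param seed master integer seed of the whole cohort.
#' @return a named list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 19, diameter_range = c(4.0, 5.5),
                          n_fractions = 10, prescription_dose = 3.4,
                          bin_width = 0.01, n_samples = 200000,
                          dwell_spacing = 0.3,
                          cold_axis_halfangle = 25, cold_axis_factor = 0.75,
                          excluded_range = c(0, 0.1),
                          perturbation = perturbation_model(),
                          seed = 1L) {
  stopifnot(n_patients >= 1, length(diameter_range) == 2,
            diameter_range[1] > 0, diameter_range[1] <= diameter_range[2],
            n_fractions >= 1, prescription_dose > 0, bin_width > 0,
            n_samples >= 1, all(excluded_range >= 0), all(excluded_range < 0.5))
  perturbation$seed <- as.integer(seed)
  structure(list(n_patients = as.integer(n_patients),
                 diameter_range = diameter_range,
                 n_fractions = as.integer(n_fractions),
                 prescription_dose = prescription_dose,
                 bin_width = bin_width, n_samples = as.integer(n_samples),
                 dwell_spacing = dwell_spacing,
                 cold_axis_halfangle = cold_axis_halfangle,
                 cold_axis_factor = cold_axis_factor,
                 excluded_range = excluded_range,
                 perturbation = perturbation, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate a synthetic balloon-brachytherapy cohort
#'
#' Draws per-patient balloon geometries from the configuration and produces
#' one per-fraction differential DVH per patient-fraction. Identical
#' configuration and seed reproduce the cohort exactly.
#'
#' @param config a [cohort_config()].
#' @return an object of class `synthetic_cohort`: list with `patients`
#'   (each `id`, `geometry`, `ddvhs`), `n_fractions`, `bin_width`, `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  draws <- .with_seed(.substream_seed(config$seed, 0L), {
    list(diam = stats::runif(config$n_patients, config$diameter_range[1],
                             config$diameter_range[2]),
         excl = stats::runif(config$n_patients, config$excluded_range[1],
                             config$excluded_range[2]))
  })
  patients <- vector("list", config$n_patients)
  for (p in seq_len(config$n_patients)) {
    geom <- balloon_geometry(
      balloon_radius = draws$diam[p] / 2,
      prescription_dose = config$prescription_dose,
      dwell_positions = dwell_count_for_diameter(draws$diam[p]),
      dwell_spacing = config$dwell_spacing,
      cold_axis_halfangle = config$cold_axis_halfangle,
      cold_axis_factor = config$cold_axis_factor,
      excluded_volume_fraction = draws$excl[p])
    dd <- lapply(seq_len(config$n_fractions), function(f)
      generate_fraction_ddvh(geom, config$perturbation, p, f,
                             bin_width = config$bin_width,
                             n_samples = config$n_samples))
    patients[[p]] <- list(id = sprintf("patient%02d", p), geometry = geom, ddvhs = dd)
  }
  structure(list(patients = patients, n_fractions = config$n_fractions,
                 bin_width = config$bin_width, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d patients x %d fractions, bin width %g Gy, seed %d\n",
              length(x$patients), x$n_fractions, x$bin_width, x$config$seed))
  invisible(x)
}

#' Write a synthetic cohort as CSV files plus a manifest
#'
#' Uses the per-patient-fraction CSV layout of [write_cohort_csv()].
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory.
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dd <- stats::setNames(lapply(cohort$patients, `[[`, "ddvhs"),
                        vapply(cohort$patients, `[[`, character(1), "id"))
  write_cohort_csv(dd, dir)
}
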