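# fixtures built in code; no data files

# the published four-bin fragment around the prescription dose (percent
# volumes; a fragment, so volumes do not sum to 100)
table1_fragment <- function() {
  ddvh(data.frame(lower = c(33.8, 33.9, 34.0, 34.1),
                  upper = c(33.9, 34.0, 34.1, 34.2),
                  volume = c(0.229, 0.239, 0.251, 0.264)),
       bin_width = 0.1, dose_scale = "total_course",
       label = "group-average fragment", partial = TRUE)
}

# all volume in the single bin containing `dose`
delta_ddvh <- function(dose, bin_width = 0.1, dose_scale = "per_fraction") {
  build_ddvh(dose, bin_width = bin_width, dose_scale = dose_scale)
}

two_bin_ddvh <- function(d = c(3.0, 3.8), v = c(50, 50), bin_width = 0.1) {
  build_ddvh(d - bin_width / 2, weights = v, bin_width = bin_width,
             dose_scale = "per_fraction")
}

# random full dDVH with volumes on a contiguous bin range
random_ddvh <- function(n_bins = 50, bin_width = 0.1, first_bin = 10L,
                        dose_scale = "per_fraction", seed = 1L) {
  set.seed(seed)
  v <- stats::rgamma(n_bins, shape = 0.8)
  v <- 100 * v / sum(v)
  k <- seq.int(first_bin, first_bin + n_bins - 1L)
  ddvh(data.frame(lower = (k - 1L) * bin_width, upper = k * bin_width, volume = v),
       bin_width = bin_width, dose_scale = dose_scale, seed_label(seed))
}

seed_label <- function(seed) sprintf("random_%d", seed)

# small, fast cohort configuration for unit tests
small_cohort_config <- function(seed = 11L, ...) {
  cohort_config(n_patients = 3, n_fractions = 3, n_samples = 5000,
                bin_width = 0.05, seed = seed, ...)
}

late_endpoint <- function(ab = 2) endpoint_params("late", ab)
acute_endpoint <- function(ab = 8) endpoint_params("acute", ab, includes_repopulation = TRUE)
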