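#' Balloon applicator geometry for synthetic dose distributions
#'
#' Abstract geometry of a balloon brachytherapy applicator: a spherical
#' balloon of radius `balloon_radius` centred at the origin, a catheter along
#' the z axis carrying `dwell_positions` equally weighted source dwell
#' positions spaced `dwell_spacing` apart and centred on
#' `source_offset`, and a prescription isodose at `balloon_radius + 1` cm.
#' The line-source anisotropy that produces the clinical cold spot along the
#' catheter axis is emulated by a multiplicative dose attenuation
#' (`cold_axis_factor`) inside a cone of `cold_axis_halfangle` degrees about
#' the axis; skin and lung/pectoralis exclusions are emulated by removing a
#' contiguous cap of `excluded_volume_fraction` of the shell.
#'
#' @param balloon_radius balloon radius in cm (> 0).
#' @param prescription_dose prescribed dose per fraction in Gy at the 1 cm
#'   expansion of the balloon surface.
#' @param dwell_positions number of dwell positions (>= 1); default derived
#'   from the balloon diameter via [dwell_count_for_diameter()].
#' @param dwell_spacing spacing between dwell positions in cm.
#' @param source_offset 3-vector (cm) displacing the dwell chain centre from
#'   the target centre.
#' @param cold_axis_halfangle half-angle in degrees of the axial cold cone
#'   (0 disables it).
#' @param cold_axis_factor multiplicative dose factor (< 1) inside the cone.
#' @param excluded_volume_fraction fraction of the shell removed as a
#'   contiguous cap (in [0, 0.5)); the cap faces the +x direction,
#'   perpendicular to the catheter axis.
#' @return an object of class `balloon_geometry`.
#' @export
balloon_geometry <- function(balloon_radius,
                             prescription_dose = 3.4,
                             dwell_positions = dwell_count_for_diameter(2 * balloon_radius),
                             dwell_spacing = 0.3,
                             source_offset = c(0, 0, 0),
                             cold_axis_halfangle = 25,
                             cold_axis_factor = 0.75,
                             excluded_volume_fraction = 0) {
  stopifnot(balloon_radius > 0, prescription_dose > 0, dwell_positions >= 1,
            dwell_spacing > 0, length(source_offset) == 3,
            cold_axis_halfangle >= 0, cold_axis_factor > 0, cold_axis_factor <= 1,
            excluded_volume_fraction >= 0, excluded_volume_fraction < 0.5)
  half_span <- (dwell_positions - 1) * dwell_spacing / 2
  if (half_span + max(abs(source_offset)) >= balloon_radius + 1)
    stop("dwell chain must lie inside the prescription radius")
  structure(list(balloon_radius = balloon_radius,
                 prescription_radius = balloon_radius + 1.0,
                 prescription_dose = prescription_dose,
                 dwell_positions = as.integer(dwell_positions),
                 dwell_spacing = dwell_spacing,
                 source_offset = as.numeric(source_offset),
                 cold_axis_halfangle = cold_axis_halfangle,
                 cold_axis_factor = cold_axis_factor,
                 excluded_volume_fraction = excluded_volume_fraction),
            class = "balloon_geometry")
}

#' @export
print.balloon_geometry <- function(x, ...) {
  cat(sprintf("Balloon: radius %g cm (prescription %g Gy at %g cm), %d dwells @ %g cm, cold cone %g deg x%.2f, excluded %.3f\n",
              x$balloon_radius, x$prescription_dose, x$prescription_radius,
              x$dwell_positions, x$dwell_spacing,
              x$cold_axis_halfangle, x$cold_axis_factor,
              x$excluded_volume_fraction))
  invisible(x)
}

#' Dwell-position count as a function of balloon diameter
#'
#' Linear map from the clinical balloon diameter range 4.0--5.5 cm to 7--10
#' available dwell positions, rounded to the nearest integer.
#'
#' @param diameter_cm balloon diameter in cm.
#' @return integer dwell count.
#' @export
dwell_count_for_diameter <- function(diameter_cm) {
  as.integer(round(7 + (diameter_cm - 4.0) / 1.5 * 3))
}

# dwell coordinates, n x 3
.dwell_coords <- function(geom) {
  m <- geom$dwell_positions
  z <- (seq_len(m) - (m + 1) / 2) * geom$dwell_spacing
  cbind(geom$source_offset[1], geom$source_offset[2], geom$source_offset[3] + z)
}

# exact spherical average over the origin-centred sphere of radius r of
# 1/|p - a|^2 for a point source at distance a < r from the centre:
# (1/(2 a r)) ln((r + a)/(r - a)); limit 1/r^2 as a -> 0
.sphere_avg_invsq <- function(r, a) {
  ifelse(a < 1e-12, 1 / r^2, log((r + a) / (r - a)) / (2 * a * r))
}

# normalisation constant: raw inverse-square superposition averaged over the
# prescription sphere (equal dwell weights)
.dose_norm <- function(geom) {
  a <- sqrt(rowSums(.dwell_coords(geom)^2))
  if (any(a >= geom$prescription_radius))
    stop("dwell positions must lie inside the prescription sphere")
  sum(.sphere_avg_invsq(geom$prescription_radius, a))
}

#' Dose at points around a balloon applicator
#'
#' Superposition of equal-weight inverse-square contributions from the dwell
#' positions, normalised so that the spherical average of the dose over the
#' prescription sphere (origin-centred, radius `balloon_radius + 1` cm)
#' equals `prescription_dose`. For a single centred dwell this reduces to
#' D(r) = D_rx (r0 / r)^2. The axial cold cone is not applied here; it is a
#' property of the sampled target dose (see [sample_ptv_eval()]).
#'
#' @param geom a [balloon_geometry()].
#' @param points numeric matrix (n x 3) or length-3 vector of coordinates in
#'   cm.
#' @param norm normalisation divisor; defaults to the value implied by
#'   `geom`. Supplying the fraction-1 plan's divisor keeps a perturbed
#'   delivery normalised to the unperturbed plan.
#' @return numeric vector of doses in Gy.
#' @export
dose_at_point <- function(geom, points, norm = NULL) {
  stopifnot(inherits(geom, "balloon_geometry"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  if (is.null(norm)) norm <- .dose_norm(geom)
  dp <- .dwell_coords(geom)
  raw <- numeric(nrow(points))
  for (j in seq_len(nrow(dp))) {
    d2 <- (points[, 1] - dp[j, 1])^2 + (points[, 2] - dp[j, 2])^2 +
      (points[, 3] - dp[j, 3])^2
    if (any(d2 < 1e-18)) stop("point coincides with a dwell position")
    raw <- raw + 1 / d2
  }
  geom$prescription_dose * raw / norm
}

# run expr under a temporary RNG state seeded by `seed`
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# deterministic sub-seed from a base seed and integer tags, kept < 2^31
.substream_seed <- function(seed, ...) {
  tags <- c(...)
  s <- as.double(seed %% 2147483647L)
  for (t in tags) s <- (s * 48271 + as.double(t) * 16807 + 1) %% 2147483647
  as.integer(s)
}

# uniform-by-volume point cloud in a unit-parameterised shell: returns
# direction cosines and the volume quantile u; radii are derived later so the
# same cloud can be reused under perturbed shell radii
.shell_cloud <- function(n, seed) {
  .with_seed(seed, {
    list(u = stats::runif(n),
         cz = stats::runif(n, -1, 1),
         phi = stats::runif(n, 0, 2 * pi))
  })
}

.cloud_points <- function(cloud, r_inner, r_outer) {
  r <- (r_inner^3 + cloud$u * (r_outer^3 - r_inner^3))^(1 / 3)
  sz <- sqrt(pmax(0, 1 - cloud$cz^2))
  cbind(x = r * sz * cos(cloud$phi), y = r * sz * sin(cloud$phi), z = r * cloud$cz)
}

# doses of a point cloud in geometry `geom`, cold cone applied about the
# applicator (dwell-chain) axis, exclusion cap removed about +x
.cloud_doses <- function(geom, cloud, norm = NULL) {
  pts <- .cloud_points(cloud, geom$balloon_radius, geom$prescription_radius)
  dose <- dose_at_point(geom, pts, norm = norm)
  if (geom$cold_axis_halfangle > 0 && geom$cold_axis_factor < 1) {
    rel <- sweep(pts, 2, geom$source_offset)
    cosax <- abs(rel[, 3]) / sqrt(rowSums(rel^2))
    dose[cosax >= cos(geom$cold_axis_halfangle * pi / 180)] <-
      dose[cosax >= cos(geom$cold_axis_halfangle * pi / 180)] * geom$cold_axis_factor
  }
  if (geom$excluded_volume_fraction > 0) {
    cosx <- .cloud_points(cloud, 1, 1)[, 1]  # direction cosine towards +x
    dose <- dose[cosx < 1 - 2 * geom$excluded_volume_fraction]
  }
  dose
}

#' Sample target-shell doses around a balloon applicator
#'
#' Draws points uniformly by volume in the 1 cm target shell
#' `[balloon_radius, balloon_radius + 1]`, computes their dose by
#' inverse-square superposition, attenuates points inside the axial cold
#' cone by `cold_axis_factor` (line-source cold-spot emulation), and removes
#' the exclusion cap. Weights are equal.
#'
#' @param geom a [balloon_geometry()].
#' @param n_samples number of points to draw (before cap removal).
#' @param seed integer seed; the same seed yields the identical sample
#'   sequence.
#' @return data.frame with columns `dose` (Gy) and `weight`.
#' @export
sample_ptv_eval <- function(geom, n_samples, seed = 1L) {
  stopifnot(inherits(geom, "balloon_geometry"), n_samples >= 1)
  cloud <- .shell_cloud(n_samples, seed)
  dose <- .cloud_doses(geom, cloud)
  data.frame(dose = dose, weight = rep(1, length(dose)))
}
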