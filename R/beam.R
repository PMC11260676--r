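#' PBS machine beam model
#'
#' Parameters of the simplified analytic pencil-beam machine model: a
#' power-law range--energy relation, an energy-dependent in-air spot sigma
#' interpolated between the machine's measured anchors (7.2 mm at 70 MeV,
#' 2.6 mm at 230 MeV), an analytic Bragg depth-dose curve, and the delivery
#' time-structure constants (spot drilling, spot switching, energy-layer
#' switching, inter-field gap).
#'
#' @param range_alpha,range_p power-law range fit `R[cm] = alpha * E^p`
#'   (standard literature values for protons in water).
#' @param sigma_anchor_lo,sigma_anchor_hi `(energy MeV, sigma mm)` pairs the
#'   lateral spot-size model interpolates between.
#' @param mu_rate spot drilling rate in MU/s.
#' @param scan_speed lateral scanning speed in mm/s.
#' @param layer_switch_s energy-layer switching dead time in seconds.
#' @param interfield_gap_s gap between fields in seconds.
#' @param sigma_depth_k depth-broadening slope: the effective lateral sigma
#'   at water-equivalent depth d is `sqrt(sigma_air^2 + (k d)^2)`.
#' @param plateau,plateau_slope entrance-plateau level (relative to the peak)
#'   and its fractional rise towards the peak.
#' @param peak_sigma_min minimum Gaussian peak width in mm (range straggling
#'   `0.012 R^0.935` is used when larger).
#' @param calibration dose calibration constant in Gy mm^2 per MU, fixing the
#'   absolute scale of the analytic model (arbitrary; chosen so the default
#'   plan normalizes near 1).
#' @param rbe constant proton relative biological effectiveness factor.
#' @param energy_range_mev deliverable energy interval in MeV.
#' @return object of class `beam_model`.
#' @export
beam_model <- function(range_alpha = 0.0022, range_p = 1.77,
                       sigma_anchor_lo = c(70, 7.2),
                       sigma_anchor_hi = c(230, 2.6),
                       mu_rate = 100, scan_speed = 10000,
                       layer_switch_s = 1.0, interfield_gap_s = 5.0,
                       sigma_depth_k = 0.02,
                       plateau = 0.35, plateau_slope = 0.05,
                       peak_sigma_min = 2.0,
                       calibration = 400, rbe = 1.1,
                       energy_range_mev = c(70, 230)) {
  stopifnot(range_alpha > 0, range_p > 0, mu_rate > 0, scan_speed > 0,
            layer_switch_s > 0, interfield_gap_s >= 0, peak_sigma_min > 0,
            calibration > 0, rbe > 0)
  if (sigma_anchor_hi[2] >= sigma_anchor_lo[2])
    stop("spot sigma must decrease with energy between the anchors")
  structure(list(range_alpha = range_alpha, range_p = range_p,
                 sigma_anchor_lo = sigma_anchor_lo,
                 sigma_anchor_hi = sigma_anchor_hi,
                 mu_rate = mu_rate, scan_speed = scan_speed,
                 layer_switch_s = layer_switch_s,
                 interfield_gap_s = interfield_gap_s,
                 sigma_depth_k = sigma_depth_k,
                 plateau = plateau, plateau_slope = plateau_slope,
                 peak_sigma_min = peak_sigma_min,
                 calibration = calibration, rbe = rbe,
                 energy_range_mev = energy_range_mev),
            class = "beam_model")
}

.check_energy <- function(energy, beam) {
  rng <- beam$energy_range_mev
  if (any(energy < rng[1] - 1e-9 | energy > rng[2] + 1e-9))
    stop("energy outside deliverable range [", rng[1], ", ", rng[2],
         "] MeV", call. = FALSE)
}

#' Proton range in water from beam energy
#'
#' Power-law fit `R = 10 * alpha * E^p` millimetres; strictly increasing in
#' energy.
#'
#' @param energy beam energy in MeV (vectorized).
#' @param beam a [beam_model()].
#' @return range in mm water-equivalent depth.
#' @export
range_from_energy <- function(energy, beam = beam_model()) {
  .check_energy(energy, beam)
  10 * beam$range_alpha * energy^beam$range_p
}

#' Beam energy whose range equals a given water-equivalent depth
#'
#' Closed-form inverse of [range_from_energy()].
#'
#' @param range_mm water-equivalent range in mm (vectorized).
#' @param beam a [beam_model()].
#' @export
energy_from_range <- function(range_mm, beam = beam_model()) {
  if (any(range_mm <= 0)) stop("range must be positive")
  e <- (range_mm / (10 * beam$range_alpha))^(1 / beam$range_p)
  .check_energy(e, beam)
  e
}

#' In-air lateral spot sigma at a given energy
#'
#' Linear interpolation between the machine anchors (70 MeV, 7.2 mm) and
#' (230 MeV, 2.6 mm); monotone decreasing in energy.
#'
#' @inheritParams range_from_energy
#' @return sigma in mm.
#' @export
sigma_at_energy <- function(energy, beam = beam_model()) {
  .check_energy(energy, beam)
  lo <- beam$sigma_anchor_lo; hi <- beam$sigma_anchor_hi
  s <- lo[2] + (energy - lo[1]) * (hi[2] - lo[2]) / (hi[1] - lo[1])
  # the anchors themselves are exact machine data points
  s[energy == lo[1]] <- lo[2]
  s[energy == hi[1]] <- hi[2]
  s
}

#' Gaussian width of the Bragg peak for a given energy
#' @inheritParams range_from_energy
#' @return peak sigma in mm (range straggling, floored at `peak_sigma_min`).
#' @export
bragg_peak_sigma <- function(energy, beam = beam_model()) {
  r <- range_from_energy(energy, beam)
  pmax(beam$peak_sigma_min, 0.012 * r^0.935)
}

#' Analytic integral depth-dose (Bragg) curve
#'
#' Relative dose per MU at water-equivalent depth `depth` for a beam of the
#' given energy. The curve is a rising entrance plateau plus a Gaussian peak
#' whose maximum lies exactly at [range_from_energy()]; beyond the range the
#' whole curve decays with the peak Gaussian and is cut to zero past
#' `range + 3 * peak sigma`.
#'
#' @param depth water-equivalent depth in mm (vectorized).
#' @param energy beam energy in MeV (scalar).
#' @param beam a [beam_model()].
#' @return relative dose per MU (peak value `1 + plateau * (1 + slope)`).
#' @export
bragg_idd <- function(depth, energy, beam = beam_model()) {
  if (length(energy) != 1L) stop("'energy' must be a scalar")
  r <- range_from_energy(energy, beam)
  sp <- bragg_peak_sigma(energy, beam)
  core <- exp(-((depth - r)^2) / (2 * sp^2))
  p0 <- beam$plateau; sl <- beam$plateau_slope
  out <- ifelse(depth <= r,
                p0 * (1 + sl * depth / r) + core,
                (1 + p0 * (1 + sl)) * core)
  out[depth < 0 | depth > r + 3 * sp] <- 0
  out
}

#' Radiological (water-equivalent) depth along a ray
#'
#' Trapezoidal line integral of relative density from `entry_point` to
#' `point` along `direction`, sampled at steps no larger than half the
#' smallest voxel dimension.
#'
#' @param density a `volume_grid` of relative density.
#' @param entry_point mm 3-vector where the ray enters.
#' @param direction unit 3-vector of travel.
#' @param point mm 3-vector at which the depth is evaluated (must lie on the
#'   forward ray).
#' @return water-equivalent path length in mm.
#' @export
radiological_depth <- function(density, entry_point, direction, point) {
  direction <- direction / sqrt(sum(direction^2))
  len <- sum((point - entry_point) * direction)
  if (abs(len) < 1e-12) return(0)
  if (len < 0) stop("'point' lies behind 'entry_point' along the ray")
  step <- min(density$spacing) / 2
  n <- max(2L, ceiling(len / step) + 1L)
  t <- seq(0, len, length.out = n)
  pts <- cbind(entry_point[1] + t * direction[1],
               entry_point[2] + t * direction[2],
               entry_point[3] + t * direction[3])
  rho <- interp_trilinear(density, pts, outside = 0)
  h <- len / (n - 1)
  h * (sum(rho) - (rho[1] + rho[n]) / 2)
}
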