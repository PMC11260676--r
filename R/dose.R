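#' Beam's-eye-view frame of a coplanar field
#'
#' Fields are parallel beams in the axial plane rotating about the
#' isocenter. For gantry angle theta (degrees) the beam travels along
#' `b = (sin theta, -cos theta, 0)`; the lateral axes are
#' `e1 = (cos theta, sin theta, 0)` (transverse) and `e2 = (0, 0, 1)`
#' (superior-inferior). Spot coordinates (x, y) are offsets along (e1, e2)
#' at the isocenter plane.
#'
#' @param gantry_angle degrees.
#' @return list with unit vectors `b`, `e1`, `e2`.
#' @export
field_frame <- function(gantry_angle) {
  th <- gantry_angle * pi / 180
  list(b = c(sin(th), -cos(th), 0),
       e1 = c(cos(th), sin(th), 0),
       e2 = c(0, 0, 1))
}

# Per-field geometry cache: water-equivalent depth of every voxel plus the
# lateral BEV coordinates. WEPL is computed by resampling the density on a
# beam-aligned lattice, cumulative (midpoint) integration along the beam
# axis, and trilinear sampling back at the voxel centres.
field_geometry <- function(density, gantry_angle, iso, step = 1) {
  fr <- field_frame(gantry_angle)
  d <- dim(density$values)
  ax <- grid_axes(density)
  # voxel lateral coordinates: lu depends on (x, y) only, lv = z - iso_z
  lu <- outer((ax$x - iso[1]) * fr$e1[1], (ax$y - iso[2]) * fr$e1[2], "+")
  lv <- ax$z - iso[3]
  # beam-aligned lattice bounds from the grid corners
  corners <- as.matrix(expand.grid(range(ax$x), range(ax$y), range(ax$z)))
  cc <- sweep(corners, 2, iso)
  t_rng <- range(cc %*% fr$b)
  u_rng <- range(cc %*% fr$e1)
  us <- seq(u_rng[1], u_rng[2], by = density$spacing[1])
  vs <- lv
  ts <- seq(t_rng[1], t_rng[2], by = step)
  nu <- length(us); nv <- length(vs); nt <- length(ts)
  # sample density on the lattice (u fastest, then v, then t)
  pu <- rep(us, times = nv * nt)
  pv <- rep(rep(vs, each = nu), times = nt)
  pt <- rep(ts, each = nu * nv)
  pts <- cbind(iso[1] + pu * fr$e1[1] + pt * fr$b[1],
               iso[2] + pu * fr$e1[2] + pt * fr$b[2],
               iso[3] + pv)
  rho <- array(interp_trilinear(density, pts, outside = 0), dim = c(nu, nv, nt))
  # cumulative WEPL along t (midpoint rule)
  wepl_lat <- aperm(apply(rho, c(1, 2), function(r) (cumsum(r) - r / 2) * step),
                    c(2, 3, 1))
  lat <- list(values = wepl_lat, spacing = c(density$spacing[1], 1, step),
              origin = c(us[1], 1, ts[1]))
  # sample WEPL back at all voxel centres, in lattice coordinates (u, v-index, t)
  vox_u <- rep(as.vector(lu), times = d[3])
  vox_vi <- rep(seq_len(d[3]), each = d[1] * d[2])
  xy_t <- outer((ax$x - iso[1]) * fr$b[1], (ax$y - iso[2]) * fr$b[2], "+")
  vox_t <- rep(as.vector(xy_t), times = d[3])
  wepl <- interp_trilinear(lat, cbind(vox_u, vox_vi, vox_t), outside = 0)
  list(frame = fr, lu = lu, lv = lv, wepl = wepl, dim = d, iso = iso)
}

# Dose deposited by the spots of one energy layer into a flat dose vector.
# spots: data.frame(x, y, mu). Lateral Gaussian truncated at `cutoff_sigmas`
# standard deviations; depth contributions beyond the Bragg tail are skipped.
.layer_dose <- function(dose_flat, geom, spots, energy, beam,
                        cutoff_sigmas = 3.5) {
  d <- geom$dim
  nxy <- d[1] * d[2]
  idd <- bragg_idd(geom$wepl, energy, beam)
  live <- idd > 1e-7
  if (!any(live)) return(dose_flat)
  s0 <- sigma_at_energy(energy, beam)
  rmax <- range_from_energy(energy, beam) + 3 * bragg_peak_sigma(energy, beam)
  sig_max <- sqrt(s0^2 + (beam$sigma_depth_k * rmax)^2)
  cutoff <- cutoff_sigmas * sig_max
  lu_flat <- as.vector(geom$lu)
  const <- beam$calibration * beam$rbe
  k2 <- beam$sigma_depth_k^2
  for (s in seq_len(nrow(spots))) {
    sx <- spots$x[s]; sy <- spots$y[s]; mu <- spots$mu[s]
    a_sel <- which(abs(lu_flat - sx) <= cutoff)
    z_sel <- which(abs(geom$lv - sy) <= cutoff)
    if (!length(a_sel) || !length(z_sel)) next
    flat <- rep(a_sel, times = length(z_sel)) +
      rep((z_sel - 1L) * nxy, each = length(a_sel))
    keep <- live[flat]
    flat <- flat[keep]
    if (!length(flat)) next
    idd_k <- idd[flat]
    du2 <- (lu_flat[a_sel] - sx)^2
    dv2 <- (geom$lv[z_sel] - sy)^2
    r2 <- (rep(du2, times = length(z_sel)) +
             rep(dv2, each = length(du2)))[keep]
    sig2 <- s0^2 + k2 * geom$wepl[flat]^2
    dose_flat[flat] <- dose_flat[flat] +
      mu * const * idd_k * exp(-r2 / (2 * sig2)) / (2 * pi * sig2)
  }
  dose_flat
}

#' Dose of a single spot
#'
#' Dose contribution of one spot on the grid: MU times the Bragg depth-dose
#' at the voxel's water-equivalent depth, times a depth-broadened lateral
#' Gaussian in the beam's-eye-view frame, times the RBE and calibration
#' constants. Linear in MU.
#'
#' @param spot list or one-row data.frame with `x`, `y`, `mu`.
#' @param gantry_angle field gantry angle in degrees.
#' @param energy beam energy MeV.
#' @param grid dose grid frame (`volume_grid`).
#' @param density relative-density `volume_grid` on the same frame.
#' @param beam a [beam_model()].
#' @param iso isocenter (mm); defaults to the grid centre.
#' @return `volume_grid` of dose in Gy(RBE).
#' @export
spot_dose <- function(spot, gantry_angle, energy, grid, density,
                      beam = beam_model(), iso = NULL) {
  if (!same_frame(grid, density)) .stop_frame()
  if (is.null(iso))
    iso <- grid$origin + (dim(grid$values) - 1) / 2 * grid$spacing
  geom <- field_geometry(density, gantry_angle, iso)
  flat <- .layer_dose(numeric(length(grid$values)), geom,
                      data.frame(x = spot$x, y = spot$y, mu = spot$mu),
                      energy, beam)
  volume_grid(array(flat, dim = dim(grid$values)),
              spacing = grid$spacing, origin = grid$origin)
}

#' Total plan dose on a grid
#'
#' Sum of the spot doses over all fields and energy layers, multiplied by
#' the plan normalization factor. Dose grids carry a `provenance` attribute.
#'
#' @param plan a `pbs_plan`.
#' @param grid dose grid frame (`volume_grid`).
#' @param density relative density on the same frame.
#' @param beam a [beam_model()].
#' @param provenance tag stored on the result ("static3D", "subplan", ...).
#' @return `volume_grid` of dose in Gy(RBE).
#' @export
plan_dose <- function(plan, grid, density, beam = beam_model(),
                      provenance = "static3D") {
  if (!same_frame(grid, density)) .stop_frame()
  flat <- numeric(length(grid$values))
  for (fld in plan$fields) {
    geom <- field_geometry(density, fld$gantry_angle, plan$iso)
    for (lay in fld$layers) {
      if (nrow(lay$spots) == 0) next
      flat <- .layer_dose(flat, geom, lay$spots, lay$energy, beam)
    }
  }
  out <- volume_grid(array(flat * plan$normalization_factor,
                           dim = dim(grid$values)),
                     spacing = grid$spacing, origin = grid$origin)
  attr(out, "provenance") <- provenance
  out
}

# Influence matrix restricted to a voxel subset: A[v, s] = dose per MU of
# spot s at subset voxel v (normalization factor excluded). Used by the
# weight optimizer.
plan_influence <- function(plan, grid, density, beam, voxel_idx) {
  d <- dim(grid$values)
  nxy <- d[1] * d[2]
  iz <- (voxel_idx - 1L) %/% nxy + 1L
  ixy <- (voxel_idx - 1L) %% nxy + 1L
  nv <- length(voxel_idx)
  ns <- sum(vapply(plan$fields, function(f)
    sum(vapply(f$layers, function(l) nrow(l$spots), 0L)), 0L))
  A <- matrix(0, nrow = nv, ncol = ns)
  const <- beam$calibration * beam$rbe
  k2 <- beam$sigma_depth_k^2
  col <- 0L
  for (fld in plan$fields) {
    geom <- field_geometry(density, fld$gantry_angle, plan$iso)
    lu_v <- as.vector(geom$lu)[ixy]
    lv_v <- geom$lv[iz]
    wepl_v <- geom$wepl[voxel_idx]
    for (lay in fld$layers) {
      if (nrow(lay$spots) == 0) next
      idd_v <- bragg_idd(wepl_v, lay$energy, beam)
      s0 <- sigma_at_energy(lay$energy, beam)
      sig2 <- s0^2 + k2 * wepl_v^2
      gnorm <- 1 / (2 * pi * sig2)
      for (s in seq_len(nrow(lay$spots))) {
        col <- col + 1L
        r2 <- (lu_v - lay$spots$x[s])^2 + (lv_v - lay$spots$y[s])^2
        A[, col] <- const * idd_v * exp(-r2 / (2 * sig2)) * gnorm
      }
    }
  }
  A
}
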