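#' Periodic cardiorespiratory motion model
#'
#' Analytic periodic motion for the synthetic 4D phantom. Two modes are
#' provided:
#' \describe{
#'   \item{respiratory}{a time-dependent translation `amplitude * w(phi)`
#'     applied inside a spherical core (`envelope = 1`), cosine-tapered to
#'     zero between `r_core` and `r_outer` so motion vanishes at the body
#'     edge. Default peak amplitude (0, 2, 8) mm LR/AP/SI, period 4 s.}
#'   \item{cardiac}{a radial contraction/expansion about `center`: inside
#'     the core the map is the affine scaling
#'     `p -> center + (1 + A w(phi) / r0) (p - center)`, i.e. a point at
#'     radius `r0` moves by the peak amplitude `A`; outside the core the
#'     displacement tapers to zero. Default A = 2.5 mm at r0 = 25 mm,
#'     period 0.8 s (75 bpm).}
#' }
#' The temporal waveform `w` maps phase fraction to [0, 1] and satisfies
#' `w(0) = 0`, so the 0% phase is the undisplaced reference.
#'
#' @param mode "respiratory" or "cardiac".
#' @param period_s motion period in seconds.
#' @param amplitude_mm peak displacement: length-3 vector (respiratory) or
#'   scalar radial amplitude at `r0` (cardiac).
#' @param n_phases number of motion phases (10, as in 4DCT/4DcCT binning).
#' @param center envelope centre (respiratory) / cardiac centre, mm.
#' @param r0 cardiac amplitude reference radius in mm.
#' @param r_core radius of the rigid/affine core in mm (envelope = 1).
#' @param r_outer radius where the displacement has tapered to zero, mm.
#' @param waveform function mapping phase fraction to [0, 1].
#' @return object of class `motion_model`.
#' @export
motion_model <- function(mode = c("respiratory", "cardiac"),
                         period_s = NULL, amplitude_mm = NULL,
                         n_phases = 10L, center = c(56, 56, 56),
                         r0 = 25, r_core = 30, r_outer = 52,
                         waveform = function(phi) (1 - cos(2 * pi * phi)) / 2) {
  mode <- match.arg(mode)
  if (is.null(period_s)) period_s <- if (mode == "respiratory") 4.0 else 0.8
  if (is.null(amplitude_mm))
    amplitude_mm <- if (mode == "respiratory") c(0, 2, 8) else 2.5
  stopifnot(period_s > 0, n_phases >= 1, all(amplitude_mm >= 0),
            r_outer > r_core, r_core > 0, r0 > 0)
  if (abs(waveform(0)) > 1e-12)
    stop("waveform(0) must be 0: the 0% phase is the reference")
  structure(list(mode = mode, period_s = period_s,
                 amplitude_mm = amplitude_mm, n_phases = as.integer(n_phases),
                 center = center, r0 = r0, r_core = r_core, r_outer = r_outer,
                 waveform = waveform),
            class = "motion_model")
}

# smooth envelope weight in [0,1]: 1 inside r_core, cosine taper to r_outer
.envelope <- function(r, r_core, r_outer) {
  w <- numeric(length(r))
  w[r <= r_core] <- 1
  mid <- r > r_core & r < r_outer
  w[mid] <- 0.5 * (1 + cos(pi * (r[mid] - r_core) / (r_outer - r_core)))
  w
}

#' Analytic displacement of a point at a motion phase
#'
#' Displacement (mm) of reference-phase points at a given phase fraction;
#' the map sends reference coordinates to phase coordinates. Periodic in the
#' phase fraction with period 1, and identically zero at phase fraction 0.
#'
#' @param motion a [motion_model()].
#' @param point numeric 3-vector, or an N x 3 matrix of points (mm).
#' @param phase_fraction scalar in `[0, 1)` (values outside are wrapped).
#' @return displacement matrix of the same number of rows as `point`.
#' @export
analytic_displacement <- function(motion, point, phase_fraction) {
  pts <- if (is.matrix(point)) point else matrix(point, ncol = 3)
  w <- motion$waveform(phase_fraction %% 1)
  dx <- pts[, 1] - motion$center[1]
  dy <- pts[, 2] - motion$center[2]
  dz <- pts[, 3] - motion$center[3]
  r <- sqrt(dx^2 + dy^2 + dz^2)
  if (motion$mode == "respiratory") {
    e <- .envelope(r, motion$r_core, motion$r_outer)
    u <- cbind(e * motion$amplitude_mm[1],
               e * motion$amplitude_mm[2],
               e * motion$amplitude_mm[3]) * w
  } else {
    # radial magnitude: A*w*r/r0 inside the core, tapered to 0 at r_outer
    a <- motion$amplitude_mm[1] * w / motion$r0
    mag <- a * pmin(r, motion$r_core)
    taper <- .envelope(r, motion$r_core, motion$r_outer)
    taper[r <= motion$r_core] <- 1
    mag <- mag * taper
    f <- ifelse(r > 1e-12, mag / r, 0)
    u <- cbind(f * dx, f * dy, f * dz)
  }
  u
}

#' Displacement vector field on a grid for one motion phase
#'
#' Samples [analytic_displacement()] at every voxel centre with phase
#' fraction `phase_index / n_phases`. The field maps reference-phase
#' coordinates to phase-k coordinates; the phase-0 field is identically
#' zero.
#'
#' @param motion a [motion_model()].
#' @param grid a `volume_grid` defining the frame.
#' @param phase_index integer in `[0, n_phases)`.
#' @return object of class `displacement_field` with a 4D `vectors` array
#'   (x, y, z, component).
#' @export
sample_dvf <- function(motion, grid, phase_index) {
  if (phase_index < 0 || phase_index >= motion$n_phases)
    stop("phase_index out of range [0, ", motion$n_phases - 1, "]")
  d <- dim(grid$values)
  ax <- grid_axes(grid)
  pts <- cbind(rep(ax$x, times = d[2] * d[3]),
               rep(rep(ax$y, each = d[1]), times = d[3]),
               rep(ax$z, each = d[1] * d[2]))
  u <- analytic_displacement(motion, pts, phase_index / motion$n_phases)
  structure(list(vectors = array(u, dim = c(d, 3L)),
                 spacing = grid$spacing, origin = grid$origin,
                 phase_index = as.integer(phase_index)),
            class = "displacement_field")
}

#' Geometric structure primitive
#'
#' @param name label of the structure.
#' @param kind one of "sphere", "shell", "cylinder", "box".
#' @param role one of "target", "oar", "body".
#' @param center mm 3-vector.
#' @param radius sphere/cylinder radius (mm).
#' @param radius_inner inner radius for shells (mm).
#' @param half_length cylinder half-length along z (mm).
#' @param half_widths box half-widths, mm 3-vector.
#' @param density relative density of the primitive when stamped into the
#'   density volume (bodies default to water, 1.0).
#' @export
structure_primitive <- function(name, kind = c("sphere", "shell", "cylinder", "box"),
                                role = c("oar", "target", "body"),
                                center, radius = NULL, radius_inner = NULL,
                                half_length = NULL, half_widths = NULL,
                                density = 1.0) {
  kind <- match.arg(kind); role <- match.arg(role)
  structure(list(name = name, kind = kind, role = role,
                 center = as.numeric(center), radius = radius,
                 radius_inner = radius_inner, half_length = half_length,
                 half_widths = half_widths, density = density),
            class = "structure_primitive")
}

#' Rasterize a primitive into a binary mask
#'
#' A voxel belongs to the mask when its centre lies inside the primitive
#' (no partial-volume weighting).
#'
#' @param prim a [structure_primitive()].
#' @param grid a `volume_grid` defining the frame.
#' @return binary `volume_grid` (0/1 values).
#' @export
rasterize_primitive <- function(prim, grid) {
  d <- dim(grid$values)
  ax <- grid_axes(grid)
  dx2 <- (ax$x - prim$center[1])^2
  dy2 <- (ax$y - prim$center[2])^2
  dz2 <- (ax$z - prim$center[3])^2
  inside <- switch(prim$kind,
    sphere = {
      r2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
      r2 <= prim$radius^2
    },
    shell = {
      r2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
      r2 <= prim$radius^2 & r2 >= prim$radius_inner^2
    },
    cylinder = {
      ax2 <- outer(dx2, dy2, "+") <= prim$radius^2
      zin <- abs(ax$z - prim$center[3]) <= prim$half_length
      outer(ax2, zin, "&")
    },
    box = {
      xin <- abs(ax$x - prim$center[1]) <= prim$half_widths[1]
      yin <- abs(ax$y - prim$center[2]) <= prim$half_widths[2]
      zin <- abs(ax$z - prim$center[3]) <= prim$half_widths[3]
      outer(outer(xin, yin, "&"), zin, "&")
    })
  volume_grid(array(as.numeric(inside), dim = d),
              spacing = grid$spacing, origin = grid$origin)
}

# largest distance from prim centre to any of its points (bounding radius)
.prim_bound <- function(prim) {
  switch(prim$kind,
         sphere = prim$radius,
         shell = prim$radius,
         cylinder = sqrt(prim$radius^2 + prim$half_length^2),
         box = sqrt(sum(prim$half_widths^2)))
}

# transform a primitive to its position at a motion phase (exact: pure
# translation for respiratory, affine scaling for cardiac; validity requires
# the primitive to lie inside the motion core, checked at config time)
.transform_primitive <- function(prim, motion, phase_fraction) {
  w <- motion$waveform(phase_fraction %% 1)
  out <- prim
  if (motion$mode == "respiratory") {
    out$center <- prim$center + motion$amplitude_mm * w
  } else {
    s <- 1 + motion$amplitude_mm[1] * w / motion$r0
    out$center <- motion$center + s * (prim$center - motion$center)
    if (!is.null(out$radius)) out$radius <- prim$radius * s
    if (!is.null(out$radius_inner)) out$radius_inner <- prim$radius_inner * s
    if (!is.null(out$half_length)) out$half_length <- prim$half_length * s
    if (!is.null(out$half_widths)) out$half_widths <- prim$half_widths * s
  }
  out
}

#' Synthetic 4D phantom configuration
#'
#' Defines the grid, the homogeneous water body, the target (CTV analogue),
#' the adjacent OAR primitives, both motion modes, and the seed controlling
#' stochastic geometry jitter across synthetic "patients". The default is a
#' 58^3 grid at 2 mm, a 55-mm water sphere body, a 10-mm target sphere at
#' the body centre, and two spherical OARs near the target.
#'
#' @param grid_shape integer 3-vector of voxel counts.
#' @param spacing voxel spacing mm.
#' @param origin grid origin mm.
#' @param body body primitive (role "body", water density).
#' @param target target primitive (role "target").
#' @param oars list of OAR primitives (may be empty).
#' @param respiratory,cardiac [motion_model()] objects for the two modes.
#' @param heterogeneity if `TRUE`, a low-density cylindrical insert is added
#'   upstream of the target to exercise the WEPL path (off by default:
#'   homogeneous water keeps per-phase doses analytic-depth-exact).
#' @param seed integer seed for all stochastic phantom choices.
#' @return object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(57, 57, 57), spacing = c(2, 2, 2),
                           origin = c(0, 0, 0),
                           body = NULL, target = NULL, oars = NULL,
                           respiratory = NULL, cardiac = NULL,
                           heterogeneity = FALSE, seed = 1L) {
  ctr <- origin + (grid_shape - 1) / 2 * spacing
  if (is.null(body))
    body <- structure_primitive("BODY", "sphere", "body", ctr, radius = 55)
  if (is.null(target))
    target <- structure_primitive("CTV", "sphere", "target", ctr, radius = 10)
  if (is.null(oars))
    oars <- list(
      structure_primitive("OAR_A", "sphere", "oar", ctr + c(0, -20, 0), radius = 8),
      structure_primitive("OAR_B", "sphere", "oar", ctr + c(16, 0, 0), radius = 8))
  if (is.null(respiratory))
    respiratory <- motion_model("respiratory", center = target$center)
  if (is.null(cardiac))
    cardiac <- motion_model("cardiac", center = target$center + c(0, -12, 0))
  cfg <- structure(list(grid_shape = as.integer(grid_shape),
                        spacing = spacing, origin = origin,
                        body = body, target = target, oars = oars,
                        respiratory = respiratory, cardiac = cardiac,
                        heterogeneity = isTRUE(heterogeneity),
                        seed = as.integer(seed)),
                   class = "phantom_config")
  validate_phantom_config(cfg)
  cfg
}

#' Validate a phantom configuration
#'
#' Checks that every structure lies inside the body, the target inside the
#' body with margin, and (for exact per-phase rasterization) each structure
#' inside the rigid/affine core of both motion modes including its motion
#' excursion.
#'
#' @param config a [phantom_config()].
#' @return the config, invisibly; errors on violation.
#' @export
validate_phantom_config <- function(config) {
  body <- config$body
  inside_body <- function(prim) {
    sqrt(sum((prim$center - body$center)^2)) + .prim_bound(prim) <=
      .prim_bound(body) + 1e-9
  }
  for (prim in c(list(config$target), config$oars)) {
    if (!inside_body(prim))
      stop("structure '", prim$name, "' extends outside the body",
           call. = FALSE)
    for (m in list(config$respiratory, config$cardiac)) {
      ex <- if (m$mode == "respiratory") 0 else
        .prim_bound(prim) * max(m$amplitude_mm) / m$r0
      if (sqrt(sum((prim$center - m$center)^2)) + .prim_bound(prim) + ex >
          m$r_core + 1e-9)
        stop("structure '", prim$name, "' extends outside the ", m$mode,
             " motion core; per-phase masks would not be exact",
             call. = FALSE)
    }
  }
  invisible(config)
}

#' Build the reference-phase anatomy
#'
#' Rasterizes the homogeneous water body (density 1.0 inside, 0 outside)
#' and, when heterogeneity is enabled, stamps a low-density cylindrical
#' insert between the beam entrance and the target.
#'
#' @param config a [phantom_config()].
#' @return list with `density` (a `volume_grid`) and `structures` (the
#'   primitives: target then OARs).
#' @export
build_reference_anatomy <- function(config) {
  validate_phantom_config(config)
  frame <- volume_grid(array(0, dim = config$grid_shape),
                       spacing = config$spacing, origin = config$origin)
  density <- rasterize_primitive(config$body, frame)
  density$values <- density$values * config$body$density
  if (config$heterogeneity) {
    ins <- structure_primitive("INSERT", "cylinder", "oar",
                               config$target$center + c(0, -30, 0),
                               radius = 10, half_length = 10, density = 0.3)
    m <- rasterize_primitive(ins, frame)
    density$values[m$values > 0] <- ins$density
  }
  list(density = density, structures = c(list(config$target), config$oars))
}

#' Generate the full 10-phase 4D phantom
#'
#' Produces, for one motion mode, the per-phase densities, the per-phase
#' displacement fields (reference to phase), and exact per-phase structure
#' masks rasterized from the analytically transformed primitives (no
#' interpolation on the mask path).
#'
#' @param config a [phantom_config()].
#' @param mode "respiratory" or "cardiac".
#' @return object of class `phase_set` with elements `motion`,
#'   `reference_phase` (0), `densities`, `dvfs`, `masks` (per phase, a named
#'   list of binary masks), `structures`, `grid`, `homogeneous`.
#' @export
generate_phase_set <- function(config, mode = c("respiratory", "cardiac")) {
  mode <- match.arg(mode)
  motion <- config[[mode]]
  anat <- build_reference_anatomy(config)
  grid <- anat$density
  n <- motion$n_phases
  dvfs <- vector("list", n)
  masks <- vector("list", n)
  densities <- vector("list", n)
  homogeneous <- !config$heterogeneity
  for (k in seq_len(n) - 1L) {
    dvfs[[k + 1L]] <- sample_dvf(motion, grid, k)
    phase_masks <- lapply(anat$structures, function(prim) {
      rasterize_primitive(.transform_primitive(prim, motion, k / n), grid)
    })
    names(phase_masks) <- vapply(anat$structures, `[[`, "", "name")
    masks[[k + 1L]] <- phase_masks
    if (homogeneous || k == 0L) {
      densities[[k + 1L]] <- grid
    } else {
      # small-displacement pull-back of the reference density
      d <- dim(grid$values); ax <- grid_axes(grid)
      pts <- cbind(rep(ax$x, times = d[2] * d[3]),
                   rep(rep(ax$y, each = d[1]), times = d[3]),
                   rep(ax$z, each = d[1] * d[2]))
      u <- matrix(dvfs[[k + 1L]]$vectors, ncol = 3)
      rho <- interp_trilinear(grid, pts - u, outside = 0)
      densities[[k + 1L]] <- volume_grid(array(rho, dim = d),
                                         spacing = grid$spacing,
                                         origin = grid$origin)
    }
  }
  structure(list(motion = motion, reference_phase = 0L,
                 densities = densities, dvfs = dvfs, masks = masks,
                 structures = anat$structures, grid = grid,
                 homogeneous = homogeneous, config = config),
            class = "phase_set")
}

#' Average intensity projection of a phase set
#'
#' Voxelwise arithmetic mean of the per-phase density volumes, the synthetic
#' analogue of the AIP CT.
#'
#' @param phase_set a `phase_set` from [generate_phase_set()].
#' @return a `volume_grid`.
#' @export
make_aip <- function(phase_set) {
  dens <- phase_set$densities
  ref <- dens[[1]]
  for (d in dens[-1]) if (!same_frame(ref, d)) .stop_frame()
  acc <- ref$values
  for (d in dens[-1]) acc <- acc + d$values
  volume_grid(acc / length(dens), spacing = ref$spacing, origin = ref$origin)
}
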