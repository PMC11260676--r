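#' Prescription
#'
#' @param dose_gy prescribed dose in Gy(RBE) (single fraction, 25 Gy by
#'   default as in cardiac SBRT).
#' @param coverage_percent percent of the ITV the prescription must cover.
#' @param fractions number of fractions.
#' @param rbe constant RBE factor applied by the dose engine.
#' @export
prescription <- function(dose_gy = 25, coverage_percent = 95,
                         fractions = 1L, rbe = 1.1) {
  stopifnot(dose_gy > 0, coverage_percent > 0, coverage_percent < 100,
            fractions >= 1)
  structure(list(dose_gy = dose_gy, coverage_percent = coverage_percent,
                 fractions = as.integer(fractions), rbe = rbe),
            class = "prescription")
}

#' MU bounds of the machine
#' @keywords internal
MU_MIN <- 0.02
MU_MAX <- 4

#' Select energy layers tiling a water-equivalent depth interval
#'
#' Returns energies, distal first, whose ranges tile `[wepl_min, wepl_max]`
#' with spacing at most `layer_step`.
#'
#' @param wepl_min,wepl_max water-equivalent depth interval (mm).
#' @param layer_step maximum range spacing between consecutive layers (mm).
#' @param beam a [beam_model()].
#' @return numeric vector of energies in MeV, strictly descending.
#' @export
select_layers <- function(wepl_min, wepl_max, layer_step = 5,
                          beam = beam_model()) {
  stopifnot(wepl_min > 0, wepl_max >= wepl_min, layer_step > 0)
  r <- wepl_max
  energies <- numeric(0)
  repeat {
    energies <- c(energies, energy_from_range(r, beam))
    if (r <= wepl_min + 1e-9) break
    r <- max(r - layer_step, wepl_min)
  }
  energies
}

#' Place spots covering one layer's target projection
#'
#' Spots are laid on a rectangular grid (spacing `lateral_spacing`, aligned
#' to multiples of the spacing) over the beam's-eye-view projection of the
#' target slab for the layer, expanded by `margin`; initial weight 1 MU.
#' Delivery order is a serpentine raster: rows of constant y, x alternating
#' direction row by row.
#'
#' @param layer_energy beam energy in MeV.
#' @param target_mask binary `volume_grid` of the planning target.
#' @param gantry_angle field gantry angle (degrees).
#' @param density planning density `volume_grid` (for the WEPL slab).
#' @param beam a [beam_model()].
#' @param lateral_spacing spot grid spacing in mm.
#' @param margin lateral expansion of the projection in mm.
#' @param iso isocenter (mm).
#' @param slab_halfwidth half-thickness of the WEPL slab assigned to the
#'   layer (mm); defaults to `lateral_spacing`.
#' @param geom optional precomputed field geometry (internal fast path).
#' @return data.frame with columns `x`, `y`, `mu` in delivery order (possibly
#'   zero rows when the projection is empty).
#' @export
place_spots <- function(layer_energy, target_mask, gantry_angle, density,
                        beam = beam_model(), lateral_spacing = 5, margin = 5,
                        iso = NULL, slab_halfwidth = NULL, geom = NULL) {
  stopifnot(lateral_spacing > 0)
  if (is.null(iso))
    iso <- target_mask$origin + (dim(target_mask$values) - 1) / 2 *
      target_mask$spacing
  if (is.null(geom)) geom <- field_geometry(density, gantry_angle, iso)
  if (is.null(slab_halfwidth)) slab_halfwidth <- lateral_spacing
  d <- geom$dim
  nxy <- d[1] * d[2]
  tgt <- which(target_mask$values > 0)
  if (!length(tgt)) return(data.frame(x = numeric(0), y = numeric(0),
                                      mu = numeric(0)))
  r_layer <- range_from_energy(layer_energy, beam)
  in_slab <- abs(geom$wepl[tgt] - r_layer) <= slab_halfwidth
  tgt <- tgt[in_slab]
  if (!length(tgt)) return(data.frame(x = numeric(0), y = numeric(0),
                                      mu = numeric(0)))
  pu <- as.vector(geom$lu)[(tgt - 1L) %% nxy + 1L]
  pv <- geom$lv[(tgt - 1L) %/% nxy + 1L]
  s <- lateral_spacing
  gx <- seq(floor((min(pu) - margin) / s), ceiling((max(pu) + margin) / s)) * s
  gy <- seq(floor((min(pv) - margin) / s), ceiling((max(pv) + margin) / s)) * s
  cand <- expand.grid(x = gx, y = gy)
  # keep candidates within `margin` (plus half a voxel diagonal) of the
  # projected slab voxels, so disjoint slab components are each covered
  vox_tol <- sqrt(2) * max(target_mask$spacing[1:2]) / 2
  keep <- vapply(seq_len(nrow(cand)), function(i) {
    min((pu - cand$x[i])^2 + (pv - cand$y[i])^2) <= (margin + vox_tol)^2
  }, logical(1))
  cand <- cand[keep, , drop = FALSE]
  if (!nrow(cand)) return(data.frame(x = numeric(0), y = numeric(0),
                                     mu = numeric(0)))
  # serpentine raster order
  rows <- sort(unique(cand$y))
  ord <- unlist(lapply(seq_along(rows), function(ri) {
    idx <- which(cand$y == rows[ri])
    idx[order(cand$x[idx], decreasing = (ri %% 2 == 0))]
  }))
  data.frame(x = cand$x[ord], y = cand$y[ord], mu = 1)
}

#' Build an unoptimized PBS plan for a target
#'
#' Creates coplanar fields at the given gantry angles; per field, energy
#' layers tiling the target's water-equivalent depth interval (distal
#' first), and serpentine spot rasters per layer with unit weights.
#'
#' @param target_mask binary `volume_grid` the plan must cover (the ITV).
#' @param density planning density (the AIP).
#' @param beam a [beam_model()].
#' @param rx a [prescription()].
#' @param gantry_angles degrees; default three coplanar fields.
#' @param spot_spacing,layer_step,margin plan geometry parameters (mm).
#' @param layer_margin distal/proximal WEPL expansion (mm).
#' @return object of class `pbs_plan`.
#' @export
make_plan <- function(target_mask, density, beam = beam_model(),
                      rx = prescription(),
                      gantry_angles = c(0, 120, 240),
                      spot_spacing = 5, layer_step = 5, margin = 5,
                      layer_margin = 2) {
  if (!same_frame(target_mask, density)) .stop_frame()
  tgt <- which(target_mask$values > 0)
  if (!length(tgt)) stop("empty target mask")
  d <- dim(target_mask$values)
  nxy <- d[1] * d[2]
  ax <- grid_axes(target_mask)
  cx <- mean(ax$x[(tgt - 1L) %% d[1] + 1L])
  cy <- mean(ax$y[((tgt - 1L) %/% d[1]) %% d[2] + 1L])
  cz <- mean(ax$z[(tgt - 1L) %/% nxy + 1L])
  iso <- c(cx, cy, cz)
  # shallowest deliverable Bragg peak; targets extending proximal of this
  # are covered by the lowest-energy layer's peak width (no range shifter)
  wepl_floor <- range_from_energy(beam$energy_range_mev[1], beam)
  fields <- lapply(gantry_angles, function(ga) {
    geom <- field_geometry(density, ga, iso)
    wepl_t <- geom$wepl[tgt]
    wepl_lo <- max(min(wepl_t) - layer_margin, wepl_floor)
    wepl_hi <- max(wepl_t) + layer_margin
    if (wepl_lo > wepl_hi)
      stop("target lies entirely shallower than the machine's minimum range")
    energies <- select_layers(wepl_lo, wepl_hi, layer_step, beam)
    layers <- lapply(energies, function(e) {
      list(energy = e,
           spots = place_spots(e, target_mask, ga, density, beam,
                               lateral_spacing = spot_spacing,
                               margin = margin, iso = iso, geom = geom))
    })
    layers <- Filter(function(l) nrow(l$spots) > 0, layers)
    list(gantry_angle = ga, layers = layers)
  })
  structure(list(fields = fields, prescription = rx,
                 normalization_factor = 1, iso = iso),
            class = "pbs_plan")
}

#' Total spot count of a plan
#' @param plan a `pbs_plan`.
#' @export
n_spots <- function(plan) {
  sum(vapply(plan$fields, function(f)
    sum(vapply(f$layers, function(l) nrow(l$spots), 0L)), 0L))
}

#' Total MU of a plan
#' @param plan a `pbs_plan`.
#' @export
total_mu <- function(plan) {
  sum(vapply(plan$fields, function(f)
    sum(vapply(f$layers, function(l) sum(l$spots$mu), 0)), 0))
}

# flatten spot weights to one vector in delivery order, and write them back
.get_weights <- function(plan) {
  unlist(lapply(plan$fields, function(f)
    lapply(f$layers, function(l) l$spots$mu)), use.names = FALSE)
}

.set_weights <- function(plan, w) {
  i <- 0L
  for (fi in seq_along(plan$fields)) {
    for (li in seq_along(plan$fields[[fi]]$layers)) {
      n <- nrow(plan$fields[[fi]]$layers[[li]]$spots)
      if (n > 0)
        plan$fields[[fi]]$layers[[li]]$spots$mu <- w[i + seq_len(n)]
      i <- i + n
    }
  }
  plan
}

#' Iterative bounded spot-weight optimization
#'
#' Multiplicative per-spot correction driving the target voxel doses toward
#' the prescription: each iteration multiplies every weight by the
#' influence-weighted mean of `prescription / dose` over the voxels the spot
#' irradiates, then clips to the machine MU bounds [0.02, 4]. Deterministic
#' for fixed inputs.
#'
#' @param plan a `pbs_plan`.
#' @param density planning density `volume_grid`.
#' @param itv binary target mask (`volume_grid`).
#' @param beam a [beam_model()].
#' @param n_iter number of correction iterations.
#' @return the plan with optimized weights; attribute `cv_trace` records the
#'   in-target coefficient of variation per iteration.
#' @export
optimize_weights <- function(plan, density, itv, beam = beam_model(),
                             n_iter = 40) {
  vox <- which(itv$values > 0)
  A <- plan_influence(plan, itv, density, beam, vox)
  if (all(A == 0)) stop("all-zero influence: target not reachable")
  w <- .get_weights(plan)
  p <- plan$prescription$dose_gy
  colsA <- colSums(A)
  cv <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    dvox <- as.vector(A %*% w)
    cv[it] <- stats::sd(dvox) / mean(dvox)
    ratio <- colSums(A * (p / pmax(dvox, 1e-9))) / pmax(colsA, 1e-300)
    w <- pmin(pmax(w * ratio, MU_MIN), MU_MAX)
  }
  out <- .set_weights(plan, w)
  attr(out, "cv_trace") <- cv
  out
}

#' Normalize a dose to the prescription
#'
#' Computes the scale factor making the dose covering
#' `coverage_percent` of the target equal the prescribed dose (so
#' D95(ITV) = 25 Gy for the defaults), and returns the scaled dose. The
#' factor is meant to be stored as the plan's `normalization_factor`; spot
#' MUs are untouched, mirroring TPS plan normalization.
#'
#' @param dose `volume_grid` of unnormalized dose.
#' @param itv binary target mask.
#' @param rx a [prescription()].
#' @return list with `scale` and `dose` (scaled `volume_grid`).
#' @export
normalize_to_prescription <- function(dose, itv, rx = prescription()) {
  dcov <- dose_at_volume(dose, itv, rx$coverage_percent)
  if (!is.finite(dcov) || dcov <= 0)
    stop("zero target dose: cannot normalize")
  scale <- rx$dose_gy / dcov
  dose$values <- dose$values * scale
  list(scale = scale, dose = dose)
}

#' Serialize a plan to JSON
#'
#' Full-precision (bit-exact round-trip) JSON with the schema
#' `{prescription, normalization_factor, iso, fields:[{gantry_angle,
#' layers:[{energy, spots:[{x,y,mu}]}]}]}`.
#'
#' @param plan a `pbs_plan`.
#' @param path output file.
#' @export
plan_to_json <- function(plan, path) {
  obj <- list(
    prescription = plan$prescription[c("dose_gy", "coverage_percent",
                                       "fractions", "rbe")],
    normalization_factor = plan$normalization_factor,
    iso = plan$iso,
    fields = lapply(plan$fields, function(f)
      list(gantry_angle = f$gantry_angle,
           layers = lapply(f$layers, function(l)
             list(energy = l$energy, spots = l$spots)))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       dataframe = "columns")
  invisible(path)
}

#' Read a plan written by [plan_to_json()]
#' @param path JSON file.
#' @return a `pbs_plan`.
#' @export
plan_from_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  rx <- do.call(prescription, lapply(raw$prescription, identity))
  fields <- lapply(raw$fields, function(f) {
    layers <- lapply(f$layers, function(l) {
      sp <- l$spots
      list(energy = as.numeric(l$energy),
           spots = data.frame(x = as.numeric(unlist(sp$x)),
                              y = as.numeric(unlist(sp$y)),
                              mu = as.numeric(unlist(sp$mu))))
    })
    list(gantry_angle = as.numeric(f$gantry_angle), layers = layers)
  })
  structure(list(fields = fields, prescription = rx,
                 normalization_factor = as.numeric(raw$normalization_factor),
                 iso = as.numeric(unlist(raw$iso))),
            class = "pbs_plan")
}

#' Check plan invariants
#'
#' Verifies MU bounds on every spot, descending layer energies within each
#' field, and a positive normalization factor.
#'
#' @param plan a `pbs_plan`.
#' @return TRUE invisibly; errors on violation.
#' @export
validate_plan <- function(plan) {
  if (length(plan$fields) < 1) stop("plan must have at least one field")
  for (f in plan$fields) {
    e <- vapply(f$layers, `[[`, 0, "energy")
    if (length(e) > 1 && any(diff(e) >= 0))
      stop("layer energies must be strictly descending")
    for (l in f$layers) {
      if (nrow(l$spots) &&
          (any(l$spots$mu < MU_MIN - 1e-12) || any(l$spots$mu > MU_MAX + 1e-12)))
        stop("spot MU outside [", MU_MIN, ", ", MU_MAX, "]")
    }
  }
  if (plan$normalization_factor <= 0) stop("normalization factor must be > 0")
  invisible(TRUE)
}
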