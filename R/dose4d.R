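#' Warp a phase dose onto the reference phase
#'
#' Trilinear pull-back through the reference-to-phase displacement field:
#' the output value at x is the phase dose sampled at `x + u(x)`;
#' out-of-grid samples contribute zero dose.
#'
#' @param dose_phase `volume_grid` of dose computed on the phase geometry.
#' @param dvf `displacement_field` mapping reference coordinates to the
#'   phase.
#' @return `volume_grid` of dose on the reference frame.
#' @export
warp_dose_to_reference <- function(dose_phase, dvf) {
  if (!identical(dim(dose_phase$values), dim(dvf$vectors)[1:3]) ||
      any(abs(dose_phase$spacing - dvf$spacing) > 1e-6) ||
      any(abs(dose_phase$origin - dvf$origin) > 1e-6)) .stop_frame()
  d <- dim(dose_phase$values)
  ax <- grid_axes(dose_phase)
  pts <- cbind(rep(ax$x, times = d[2] * d[3]),
               rep(rep(ax$y, each = d[1]), times = d[3]),
               rep(ax$z, each = d[1] * d[2]))
  u <- matrix(dvf$vectors, ncol = 3)
  vals <- interp_trilinear(dose_phase, pts + u, outside = 0)
  volume_grid(array(vals, dim = d), spacing = dose_phase$spacing,
              origin = dose_phase$origin)
}

#' 3D static dose on the AIP
#'
#' The plan dose on the average-intensity-projection geometry, ignoring
#' motion; this is the dose all static (ITV/IRV) metrics are read from.
#'
#' @param plan a normalized `pbs_plan`.
#' @param aip AIP density `volume_grid`.
#' @param beam a [beam_model()].
#' @return `volume_grid` of dose (provenance "static3D").
#' @export
static_3d <- function(plan, aip, beam = beam_model()) {
  plan_dose(plan, aip, aip, beam, provenance = "static3D")
}

#' 4D accumulated dose (dose blurring only)
#'
#' The full plan is transplanted onto every phase geometry; each phase dose
#' is warped to the reference phase and the ten warped doses are averaged
#' with equal weights, emulating spots uniformly distributed across the
#' phases.
#'
#' @param plan a normalized `pbs_plan`.
#' @param phase_set a `phase_set`.
#' @param beam a [beam_model()].
#' @param reuse_dose optional precomputed full-plan dose on the reference
#'   geometry; valid only for homogeneous phantoms, where the per-phase
#'   plan doses are identical in room coordinates.
#' @return `volume_grid` of dose on the reference frame
#'   (provenance "accumulated4D").
#' @export
accumulate_4d <- function(plan, phase_set, beam = beam_model(),
                          reuse_dose = NULL) {
  n <- phase_set$motion$n_phases
  grid <- phase_set$grid
  acc <- NULL
  if (phase_set$homogeneous) {
    d_room <- if (is.null(reuse_dose))
      plan_dose(plan, grid, phase_set$densities[[1]], beam) else reuse_dose
    for (k in seq_len(n)) {
      wk <- warp_dose_to_reference(d_room, phase_set$dvfs[[k]])
      acc <- if (is.null(acc)) wk$values else acc + wk$values
    }
  } else {
    for (k in seq_len(n)) {
      dk <- plan_dose(plan, grid, phase_set$densities[[k]], beam)
      wk <- warp_dose_to_reference(dk, phase_set$dvfs[[k]])
      acc <- if (is.null(acc)) wk$values else acc + wk$values
    }
  }
  out <- volume_grid(acc / n, spacing = grid$spacing, origin = grid$origin)
  attr(out, "provenance") <- "accumulated4D"
  out
}

#' 4D dynamic dose (dose blurring plus interplay)
#'
#' The plan is split into per-phase sub-plans from the delivery timeline;
#' each sub-plan's dose is computed on its phase geometry, warped to the
#' reference phase, and the warped doses are summed.
#'
#' @param plan a normalized `pbs_plan`.
#' @param timeline the plan's [simulate_timeline()] result.
#' @param phase_set a `phase_set` (its motion period defines the binning).
#' @param beam a [beam_model()].
#' @param reset_each_field passed to [split_into_subplans()].
#' @return `volume_grid` of dose on the reference frame
#'   (provenance "dynamic4D").
#' @export
dynamic_4d <- function(plan, timeline, phase_set, beam = beam_model(),
                       reset_each_field = FALSE) {
  n <- phase_set$motion$n_phases
  grid <- phase_set$grid
  subplans <- split_into_subplans(plan, timeline,
                                  period_s = phase_set$motion$period_s,
                                  n_phases = n,
                                  reset_each_field = reset_each_field)
  acc <- array(0, dim = dim(grid$values))
  for (k in seq_len(n)) {
    if (n_spots(subplans[[k]]) == 0) next
    dk <- plan_dose(subplans[[k]], grid, phase_set$densities[[k]], beam,
                    provenance = "subplan")
    wk <- warp_dose_to_reference(dk, phase_set$dvfs[[k]])
    acc <- acc + wk$values
  }
  out <- volume_grid(acc, spacing = grid$spacing, origin = grid$origin)
  attr(out, "provenance") <- "dynamic4D"
  out
}

#' Reconstruct the static, accumulated, and dynamic doses for one mode
#'
#' Convenience orchestration of [static_3d()], [accumulate_4d()] and
#' [dynamic_4d()] for one motion mode.
#'
#' @param plan normalized `pbs_plan`.
#' @param phase_set a `phase_set`.
#' @param aip the AIP density `volume_grid`.
#' @param beam a [beam_model()].
#' @param timeline optional precomputed timeline.
#' @return list of class `dose4d_result` with `static3d`, `accumulated4d`,
#'   `dynamic4d`, `mode`, `timeline`.
#' @export
reconstruct_doses <- function(plan, phase_set, aip, beam = beam_model(),
                              timeline = NULL) {
  if (is.null(timeline)) timeline <- simulate_timeline(plan, beam)
  st <- static_3d(plan, aip, beam)
  reuse <- if (phase_set$homogeneous) st else NULL
  acc <- accumulate_4d(plan, phase_set, beam, reuse_dose = reuse)
  dyn <- dynamic_4d(plan, timeline, phase_set, beam)
  structure(list(static3d = st, accumulated4d = acc, dynamic4d = dyn,
                 mode = phase_set$motion$mode, timeline = timeline),
            class = "dose4d_result")
}
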