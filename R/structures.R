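#' Voxelwise union of binary masks (motion envelope)
#'
#' Logical OR over a list of per-phase masks on a common frame; the ITV/IRV
#' construction maps every phase structure to the reference frame and merges
#' them into one envelope.
#'
#' @param masks non-empty list of binary `volume_grid`s on one frame.
#' @return binary `volume_grid`.
#' @export
union_envelope <- function(masks) {
  if (!is.list(masks) || length(masks) == 0)
    stop("'masks' must be a non-empty list")
  ref <- masks[[1]]
  acc <- ref$values > 0
  for (m in masks[-1]) {
    if (!same_frame(ref, m)) .stop_frame()
    acc <- acc | (m$values > 0)
  }
  volume_grid(array(as.numeric(acc), dim = dim(ref$values)),
              spacing = ref$spacing, origin = ref$origin)
}

#' Warp a binary mask through a displacement field
#'
#' Pull-back resampling: the output voxel at x takes the linearly
#' interpolated mask value at `x + u(x)` and is thresholded at 0.5. This is
#' the interpolating counterpart of the exact primitive-based masks and is
#' retained to quantify interpolation loss.
#'
#' @param mask binary `volume_grid`.
#' @param dvf `displacement_field` (reference to phase) on the same frame.
#' @return binary `volume_grid`.
#' @export
warp_mask <- function(mask, dvf) {
  if (!identical(dim(mask$values), dim(dvf$vectors)[1:3]) ||
      any(abs(mask$spacing - dvf$spacing) > 1e-6) ||
      any(abs(mask$origin - dvf$origin) > 1e-6)) .stop_frame()
  d <- dim(mask$values)
  ax <- grid_axes(mask)
  pts <- cbind(rep(ax$x, times = d[2] * d[3]),
               rep(rep(ax$y, each = d[1]), times = d[3]),
               rep(ax$z, each = d[1] * d[2]))
  u <- matrix(dvf$vectors, ncol = 3)
  vals <- interp_trilinear(mask, pts + u, outside = 0)
  volume_grid(array(as.numeric(vals >= 0.5), dim = d),
              spacing = mask$spacing, origin = mask$origin)
}

#' Synthetic OAR_real: the OAR contour on the AIP
#'
#' Stand-in for manual re-delineation on the AIP image: the primitive is
#' rasterized at its time-averaged displaced position (the transform
#' averaged over the 10 phase fractions).
#'
#' @param primitive a [structure_primitive()] with role "oar".
#' @param motion a [motion_model()].
#' @param grid `volume_grid` frame to rasterize on.
#' @return binary `volume_grid`.
#' @export
oar_real_on_aip <- function(primitive, motion, grid) {
  if (primitive$role != "oar")
    stop("'primitive' must have role 'oar'")
  n <- motion$n_phases
  fr <- (seq_len(n) - 1) / n
  wbar <- mean(vapply(fr, motion$waveform, numeric(1)))
  mean_motion <- motion
  # reuse the phase transform with an effective waveform value of wbar
  mean_motion$waveform <- function(phi) wbar
  rasterize_primitive(.transform_primitive(primitive, mean_motion, 0.5), grid)
}

#' Absolute volume of a binary mask in cc
#'
#' @param mask binary `volume_grid`.
#' @return volume in cubic centimetres (voxel count x voxel volume / 1000).
#' @export
volume_cc <- function(mask) {
  sum(mask$values > 0) * voxel_volume_mm3(mask) / 1000
}

#' Build the full structure set for one motion mode
#'
#' Assembles, on the common reference frame: the reference-phase CTV and
#' OARs, the motion-envelope ITV (union of per-phase target masks) and
#' per-OAR IRVs, the AIP-contoured `OAR_real` surrogates, and the body.
#'
#' @param phase_set a `phase_set` from [generate_phase_set()].
#' @return object of class `structure_set`: list with `frame`, `masks`
#'   (named binary volumes), and `roles` (named character vector with values
#'   in CTV/ITV/OAR/IRV/OAR_real/BODY).
#' @export
build_structure_set <- function(phase_set) {
  grid <- phase_set$grid
  n <- phase_set$motion$n_phases
  target_name <- phase_set$structures[[1]]$name
  masks <- list(); roles <- character()
  ctv <- phase_set$masks[[1]][[target_name]]
  masks[["CTV"]] <- ctv; roles["CTV"] <- "CTV"
  itv <- union_envelope(lapply(seq_len(n), function(k)
    phase_set$masks[[k]][[target_name]]))
  masks[["ITV"]] <- itv; roles["ITV"] <- "ITV"
  for (prim in phase_set$structures[-1]) {
    nm <- prim$name
    masks[[nm]] <- phase_set$masks[[1]][[nm]]; roles[nm] <- "OAR"
    irv <- union_envelope(lapply(seq_len(n), function(k)
      phase_set$masks[[k]][[nm]]))
    masks[[paste0("IRV_", nm)]] <- irv
    roles[paste0("IRV_", nm)] <- "IRV"
    masks[[paste0(nm, "_real")]] <-
      oar_real_on_aip(prim, phase_set$motion, grid)
    roles[paste0(nm, "_real")] <- "OAR_real"
  }
  body <- rasterize_primitive(phase_set$config$body, grid)
  masks[["BODY"]] <- body; roles["BODY"] <- "BODY"
  structure(list(frame = list(spacing = grid$spacing, origin = grid$origin,
                              shape = dim(grid$values)),
                 masks = masks, roles = roles),
            class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  cat("structure_set with", length(x$masks), "masks:\n")
  for (nm in names(x$masks))
    cat(sprintf("  %-12s %-8s %8.2f cc\n", nm, x$roles[nm],
                volume_cc(x$masks[[nm]])))
  invisible(x)
}
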