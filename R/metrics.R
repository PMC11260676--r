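# sorted unique doses (descending) and cumulative volume fractions for the
# continuous DVH convention: the point (u_k, f_k) says a fraction f_k of the
# structure receives at least u_k; D and V interpolate linearly between the
# points and are exact inverses of each other.
.dvh_points <- function(doses) {
  n <- length(doses)
  u <- sort(unique(doses), decreasing = TRUE)
  counts <- cumsum(tabulate(match(doses, u), nbins = length(u)))
  if (length(u) > 1) {
    # merge nodes closer than a relative 1e-9: floating-point near-duplicates
    # (e.g. from symmetric spot placement) would otherwise create spurious
    # near-vertical DVH segments
    tol <- 1e-9 * max(abs(u[1]), 1)
    grp <- cumsum(c(TRUE, u[-length(u)] - u[-1] > tol))
    u <- unname(vapply(split(u, grp), mean, 0))
    counts <- unname(vapply(split(counts, grp), max, 0))
  }
  list(u = u, f = counts / n)
}

#' Cumulative dose-volume histogram
#'
#' Fraction of the structure receiving at least each dose level, on a
#' uniform dose axis.
#'
#' @param dose `volume_grid` of dose.
#' @param mask binary `volume_grid` on the same frame.
#' @param bin_gy dose bin width in Gy (default 0.01).
#' @return object of class `dvh_curve`: list with `dose` (Gy) and `volume`
#'   (fraction in [0, 1], non-increasing, starting at 1 at 0 Gy).
#' @export
cumulative_dvh <- function(dose, mask, bin_gy = 0.01) {
  if (!same_frame(dose, mask)) .stop_frame()
  d <- dose$values[mask$values > 0]
  if (!length(d)) stop("empty mask")
  edges <- seq(0, max(d) + bin_gy, by = bin_gy)
  vol <- vapply(edges, function(x) mean(d >= x), numeric(1))
  structure(list(dose = edges, volume = vol, bin_gy = bin_gy),
            class = "dvh_curve")
}

#' Dose covering x percent of a structure (Dx)
#'
#' Minimum dose received by the hottest x% of the structure volume, with
#' linear interpolation between sorted voxel doses (continuous DVH
#' convention). `x = 100` returns the minimum voxel dose; as x tends to 0
#' the value tends to the maximum.
#'
#' @param dose `volume_grid` of dose.
#' @param mask binary `volume_grid` on the same frame.
#' @param x volume percentage in (0, 100].
#' @return dose in Gy.
#' @export
dose_at_volume <- function(dose, mask, x) {
  stopifnot(x > 0, x <= 100)
  if (!same_frame(dose, mask)) .stop_frame()
  d <- dose$values[mask$values > 0]
  if (!length(d)) stop("empty mask")
  p <- .dvh_points(d)
  v <- x / 100
  if (v <= p$f[1]) return(p$u[1])
  stats::approx(p$f, p$u, xout = v, ties = "ordered")$y
}

#' Volume receiving at least x Gy (Vx)
#'
#' For structures the continuous DVH convention is used (linear
#' interpolation between sorted voxel doses, the exact inverse of
#' [dose_at_volume()]); with `interpolate = FALSE`, or when `mask` is
#' `NULL` (whole-grid isodose volumes), plain voxel counting is used.
#'
#' @param dose `volume_grid` of dose.
#' @param mask binary `volume_grid`, or `NULL` for the whole grid.
#' @param x dose threshold in Gy (>= 0).
#' @param unit "percent" of the structure volume or absolute "cc".
#' @param interpolate use the continuous convention (structures only).
#' @return volume in the requested unit.
#' @export
volume_at_dose <- function(dose, mask = NULL, x, unit = c("percent", "cc"),
                           interpolate = !is.null(mask)) {
  unit <- match.arg(unit)
  stopifnot(x >= 0)
  if (is.null(mask)) {
    d <- as.vector(dose$values)
    interpolate <- FALSE
  } else {
    if (!same_frame(dose, mask)) .stop_frame()
    d <- dose$values[mask$values > 0]
    if (!length(d)) stop("empty mask")
  }
  frac <- if (!interpolate) {
    mean(d >= x)
  } else {
    p <- .dvh_points(d)
    if (x > p$u[1]) 0
    else if (x <= p$u[length(p$u)]) 1
    else stats::approx(rev(p$u), rev(p$f), xout = x, ties = "ordered")$y
  }
  if (unit == "percent") 100 * frac
  else frac * length(d) * voxel_volume_mm3(dose) / 1000
}

#' Paddick conformity index
#'
#' `CI = V_T25^2 / (V_T * V_25Gy)` where `V_T25` is the volume of the
#' target intersected with the prescription isodose region, `V_T` the
#' target volume, and `V_25Gy` the whole-grid prescription isodose volume.
#' CI lies in [0, 1], 1 meaning perfect conformity.
#'
#' @param dose `volume_grid` of dose.
#' @param itv binary target mask.
#' @param rx_gy prescription isodose level in Gy.
#' @return CI, or `NA` when no voxel reaches the isodose level.
#' @export
conformity_index <- function(dose, itv, rx_gy) {
  if (!same_frame(dose, itv)) .stop_frame()
  hot <- dose$values >= rx_gy
  v_iso <- sum(hot)
  if (v_iso == 0) return(NA_real_)
  v_t <- sum(itv$values > 0)
  if (v_t == 0) stop("empty target mask")
  v_both <- sum(hot & itv$values > 0)
  v_both^2 / (v_t * v_iso)
}

#' Homogeneity index
#'
#' `HI = (D2 - D98) / Dmean` over the structure; 0 for a perfectly uniform
#' dose, larger for hot/cold spots.
#'
#' @param dose `volume_grid` of dose.
#' @param mask binary structure mask.
#' @return HI, or `NA` when the mean dose is zero.
#' @export
homogeneity_index <- function(dose, mask) {
  if (!same_frame(dose, mask)) .stop_frame()
  d <- dose$values[mask$values > 0]
  if (!length(d)) stop("empty mask")
  dmean <- mean(d)
  if (dmean <= 0) return(NA_real_)
  (dose_at_volume(dose, mask, 2) - dose_at_volume(dose, mask, 98)) / dmean
}

#' Gradient indices
#'
#' `GI = V50% / V100%`, `GI_high = V75% / V100%`, `GI_low = V25% / V100%`,
#' where `Vp` is the whole-grid volume receiving at least `p` percent of the
#' prescription (12.5, 18.75, 6.25, 25 Gy for a 25-Gy prescription). Lower
#' values mean steeper dose falloff.
#'
#' @param dose `volume_grid` of dose.
#' @param rx_gy prescription dose in Gy.
#' @return named numeric vector `c(GI, GI_high, GI_low)`, `NA` when no
#'   voxel reaches the prescription isodose.
#' @export
gradient_indexes <- function(dose, rx_gy) {
  v100 <- sum(dose$values >= rx_gy)
  if (v100 == 0)
    return(c(GI = NA_real_, GI_high = NA_real_, GI_low = NA_real_))
  c(GI = sum(dose$values >= 0.5 * rx_gy) / v100,
    GI_high = sum(dose$values >= 0.75 * rx_gy) / v100,
    GI_low = sum(dose$values >= 0.25 * rx_gy) / v100)
}

#' Full metric report for one dose distribution
#'
#' Target metrics: V25 (%), D99/D98/D95/D50/D2/D1 (Gy), Dmax/Dmin/Dmean
#' (voxel extremes and mean, Gy), CI, HI, GI, GI_high, GI_low. For each
#' other requested structure: D50, Dmax (and optionally D5 and Vx in cc).
#'
#' @param dose `volume_grid` of dose.
#' @param structures a `structure_set` (or a named list of binary masks).
#' @param rx a [prescription()].
#' @param target name of the target structure in `structures`.
#' @param oars names of the OAR structures to report (default: none).
#' @param oar_vx_gy dose levels (Gy) reported as absolute Vx (cc) per OAR.
#' @return data.frame of class `metrics_report` with columns `structure`,
#'   `metric`, `value`.
#' @export
metrics_report <- function(dose, structures, rx = prescription(),
                           target = "ITV", oars = character(0),
                           oar_vx_gy = numeric(0)) {
  masks <- if (inherits(structures, "structure_set")) structures$masks
           else structures
  tgt <- masks[[target]]
  if (is.null(tgt)) stop("target structure '", target, "' not found")
  rxg <- rx$dose_gy
  dvals <- function(m, x) dose_at_volume(dose, m, x)
  gi <- gradient_indexes(dose, rxg)
  rows <- data.frame(
    structure = target,
    metric = c("V25", "D99", "D98", "D95", "D50", "D2", "D1",
               "Dmax", "Dmin", "Dmean", "CI", "HI", "GI", "GI_high", "GI_low"),
    value = c(volume_at_dose(dose, tgt, rxg, "percent"),
              dvals(tgt, 99), dvals(tgt, 98), dvals(tgt, 95),
              dvals(tgt, 50), dvals(tgt, 2), dvals(tgt, 1),
              max(dose$values[tgt$values > 0]),
              min(dose$values[tgt$values > 0]),
              mean(dose$values[tgt$values > 0]),
              conformity_index(dose, tgt, rxg),
              homogeneity_index(dose, tgt),
              gi["GI"], gi["GI_high"], gi["GI_low"]))
  for (nm in oars) {
    m <- masks[[nm]]
    if (is.null(m)) stop("structure '", nm, "' not found")
    vals <- data.frame(
      structure = nm,
      metric = c("D50", "D5", "Dmax"),
      value = c(dvals(m, 50), dvals(m, 5), max(dose$values[m$values > 0])))
    for (x in oar_vx_gy) {
      vals <- rbind(vals, data.frame(
        structure = nm, metric = sprintf("V%g_cc", x),
        value = volume_at_dose(dose, m, x, "cc")))
    }
    rows <- rbind(rows, vals)
  }
  rownames(rows) <- NULL
  class(rows) <- c("metrics_report", "data.frame")
  rows
}
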