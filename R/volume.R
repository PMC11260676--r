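#' Regular volumetric grid
#'
#' A `volume_grid` holds a 3D scalar field (relative density, a binary mask,
#' or dose in Gy(RBE)) on a regular axis-aligned grid. Coordinates follow the
#' patient LPS convention in millimetres: the centre of voxel `[i, j, k]`
#' (1-based array index) sits at `origin + (c(i, j, k) - 1) * spacing`.
#'
#' @param values numeric 3D array.
#' @param spacing positive length-3 numeric, voxel spacing in mm.
#' @param origin length-3 numeric, coordinate of the first voxel centre (mm).
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(values, spacing = c(2, 2, 2), origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be three positive numbers")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("'origin' must be three finite numbers")
  if (any(!is.finite(values)))
    stop("'values' must be finite")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat("volume_grid:", paste(dim(x$values), collapse = " x "),
      "voxels, spacing", paste(x$spacing, collapse = "/"), "mm\n")
  cat("  origin (mm):", paste(signif(x$origin, 6), collapse = ", "), "\n")
  cat("  value range:", paste(signif(range(x$values), 6), collapse = " .. "), "\n")
  invisible(x)
}

#' Voxel-centre coordinate axes of a grid
#'
#' @param grid a `volume_grid` (or any object with `spacing`, `origin` and a
#'   `values` array).
#' @return list with numeric vectors `x`, `y`, `z` of voxel-centre
#'   coordinates in mm.
#' @export
grid_axes <- function(grid) {
  d <- dim(grid$values)
  list(x = grid$origin[1] + (seq_len(d[1]) - 1) * grid$spacing[1],
       y = grid$origin[2] + (seq_len(d[2]) - 1) * grid$spacing[2],
       z = grid$origin[3] + (seq_len(d[3]) - 1) * grid$spacing[3])
}

#' Test whether two grids share one frame
#'
#' @param a,b `volume_grid` objects.
#' @param tol coordinate tolerance in mm.
#' @export
same_frame <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

.stop_frame <- function(msg = "volumes are not on a common grid frame") {
  stop(msg, call. = FALSE)
}

#' Volume of one voxel in mm^3
#' @param grid a `volume_grid`.
#' @export
voxel_volume_mm3 <- function(grid) prod(grid$spacing)

#' Trilinear interpolation of a volume at arbitrary points
#'
#' Samples `grid$values` at the physical points `pts` (mm) by trilinear
#' interpolation. Points outside the grid return `outside`.
#'
#' @param grid a `volume_grid`.
#' @param pts numeric matrix with three columns (x, y, z in mm).
#' @param outside value returned for out-of-grid samples (default 0, the
#'   convention used for dose warping).
#' @return numeric vector of sampled values.
#' @export
interp_trilinear <- function(grid, pts, outside = 0) {
  d <- dim(grid$values)
  # continuous 1-based index coordinates
  fx <- (pts[, 1] - grid$origin[1]) / grid$spacing[1] + 1
  fy <- (pts[, 2] - grid$origin[2]) / grid$spacing[2] + 1
  fz <- (pts[, 3] - grid$origin[3]) / grid$spacing[3] + 1
  ok <- fx >= 1 & fx <= d[1] & fy >= 1 & fy <= d[2] & fz >= 1 & fz <= d[3]
  out <- rep.int(as.numeric(outside), length(fx))
  if (!any(ok)) return(out)
  fx <- fx[ok]; fy <- fy[ok]; fz <- fz[ok]
  i0 <- pmin(floor(fx), d[1] - 1L); j0 <- pmin(floor(fy), d[2] - 1L)
  k0 <- pmin(floor(fz), d[3] - 1L)
  # degenerate single-slab axes
  if (d[1] == 1L) i0 <- rep.int(1, length(fx))
  if (d[2] == 1L) j0 <- rep.int(1, length(fy))
  if (d[3] == 1L) k0 <- rep.int(1, length(fz))
  tx <- fx - i0; ty <- fy - j0; tz <- fz - k0
  i1 <- pmin(i0 + 1, d[1]); j1 <- pmin(j0 + 1, d[2]); k1 <- pmin(k0 + 1, d[3])
  v <- grid$values
  nxy <- d[1] * d[2]
  idx <- function(i, j, k) i + (j - 1) * d[1] + (k - 1) * nxy
  c000 <- v[idx(i0, j0, k0)]; c100 <- v[idx(i1, j0, k0)]
  c010 <- v[idx(i0, j1, k0)]; c110 <- v[idx(i1, j1, k0)]
  c001 <- v[idx(i0, j0, k1)]; c101 <- v[idx(i1, j0, k1)]
  c011 <- v[idx(i0, j1, k1)]; c111 <- v[idx(i1, j1, k1)]
  c00 <- c000 * (1 - tx) + c100 * tx
  c10 <- c010 * (1 - tx) + c110 * tx
  c01 <- c001 * (1 - tx) + c101 * tx
  c11 <- c011 * (1 - tx) + c111 * tx
  c0 <- c00 * (1 - ty) + c10 * ty
  c1 <- c01 * (1 - ty) + c11 * ty
  out[ok] <- c0 * (1 - tz) + c1 * tz
  out
}

#' Write a volume to NIfTI
#'
#' Scalar volumes are written as 3D NIfTI images; displacement fields
#' (4D arrays with a trailing component axis) as 4D images. Spacing and
#' origin are carried in the qform/sform.
#'
#' @param grid a `volume_grid` (or a `displacement_field`).
#' @param path output file (`.nii` or `.nii.gz`).
#' @export
write_volume <- function(grid, path) {
  vals <- if (inherits(grid, "displacement_field")) grid$vectors else grid$values
  img <- RNifti::asNifti(vals)
  RNifti::pixdim(img) <- grid$spacing
  m <- diag(c(grid$spacing, 1))
  m[1:3, 4] <- grid$origin
  RNifti::qform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a volume written by [write_volume()]
#'
#' @param path NIfTI file.
#' @return a `volume_grid` (3D images) or a plain list with `vectors` for 4D
#'   displacement images.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  m <- RNifti::xform(img)
  spacing <- abs(diag(m)[1:3]); attributes(spacing) <- NULL
  origin <- m[1:3, 4]; attributes(origin) <- NULL
  arr <- array(as.numeric(img), dim = dim(img))
  if (length(dim(arr)) == 3L)
    return(volume_grid(arr, spacing = spacing, origin = origin))
  structure(list(vectors = arr, spacing = spacing, origin = origin),
            class = "displacement_field")
}
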