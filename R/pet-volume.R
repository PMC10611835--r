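#' PET volume container
#'
#' Construct a 3D PET volume in standardised-uptake-value (SUV) units on a
#' regular, possibly anisotropic grid.  All geometric operations in the
#' package use a fixed convention: voxel indices are 0-based and the world
#' coordinate (mm) of a voxel centre is `origin_mm + (index + 0.5) *
#' spacing_mm`.  In R code, array element `[i, j, k]` (1-based) therefore
#' sits at `origin_mm + (c(i, j, k) - 0.5) * spacing_mm`.
#'
#' @param data 3D numeric array of SUV values; must be finite and
#'   non-negative.
#' @param spacing_mm length-3 positive numeric, voxel size per axis in mm.
#' @param origin_mm length-3 numeric, world coordinate of the corner of
#'   voxel `[0, 0, 0]` (default the zero vector).
#' @param frame_time_min optional scalar, acquisition mid-time of this
#'   frame in minutes (used for dynamic series).
#' @return An object of class `pet_volume`.
#' @examples
#' v <- pet_volume(array(1, c(4, 4, 2)), spacing_mm = c(2, 2, 3))
#' v
#' @export
pet_volume <- function(data, spacing_mm, origin_mm = c(0, 0, 0),
                       frame_time_min = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3D array")
  storage.mode(data) <- "double"
  if (anyNA(data) || any(!is.finite(data)))
    stop("'data' must be finite")
  if (any(data < 0))
    stop("SUV values must be non-negative")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    stop("'spacing_mm' must be three strictly positive values")
  origin_mm <- as.numeric(origin_mm)
  if (length(origin_mm) != 3L || any(!is.finite(origin_mm)))
    stop("'origin_mm' must be three finite values")
  if (!is.null(frame_time_min)) {
    frame_time_min <- as.numeric(frame_time_min)
    if (length(frame_time_min) != 1L || !is.finite(frame_time_min) ||
        frame_time_min < 0)
      stop("'frame_time_min' must be a single non-negative number")
  }
  structure(
    list(data = data, spacing_mm = spacing_mm, origin_mm = origin_mm,
         frame_time_min = frame_time_min),
    class = "pet_volume"
  )
}

#' @export
print.pet_volume <- function(x, ...) {
  d <- dim(x$data)
  cat("PET volume: ", paste(d, collapse = " x "), " voxels, spacing ",
      paste(format(x$spacing_mm, digits = 6), collapse = " x "), " mm\n",
      sep = "")
  cat(sprintf("  SUV range [%.3f, %.3f]", min(x$data), max(x$data)))
  if (!is.null(x$frame_time_min))
    cat(sprintf(", frame mid-time %.1f min", x$frame_time_min))
  cat("\n")
  invisible(x)
}

#' @export
dim.pet_volume <- function(x) dim(x$data)

# recognised mask roles; 'ground_truth' is used by the phantom generator
.voi_roles <- c("background_crescent", "static_sphere", "gtv0", "btv",
                "dyn_sphere_1ml", "ground_truth")

#' Binary volume-of-interest mask
#'
#' A binary mask sharing the grid (shape, spacing, origin) of a
#' [pet_volume()].  Masks are role-tagged so that downstream reports can
#' tell a background crescent from a final tumour volume.
#'
#' @param data 3D logical (or 0/1 numeric) array.
#' @param spacing_mm,origin_mm grid geometry, as for [pet_volume()].
#' @param role one of `"background_crescent"`, `"static_sphere"`,
#'   `"gtv0"`, `"btv"`, `"dyn_sphere_1ml"`, `"ground_truth"`.
#' @param label free-text label.
#' @param allow_empty logical; an empty mask is normally rejected, but a
#'   thresholding step may legitimately produce one (photopenic case) and
#'   passes `TRUE`.
#' @return An object of class `voi_mask`.
#' @export
voi_mask <- function(data, spacing_mm, origin_mm = c(0, 0, 0),
                     role = "ground_truth", label = "",
                     allow_empty = FALSE) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3D array")
  if (!is.logical(data)) {
    vals <- unique(as.vector(data))
    if (!all(vals %in% c(0, 1)))
      stop("mask payload must be binary (0/1)")
    data <- array(as.logical(data), dim(data))
  }
  if (anyNA(data)) stop("mask must not contain NA")
  role <- match.arg(role, .voi_roles)
  if (!allow_empty && !any(data))
    stop("mask is empty; pass allow_empty = TRUE if this is intended")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("'spacing_mm' must be three strictly positive values")
  origin_mm <- as.numeric(origin_mm)
  if (length(origin_mm) != 3L || any(!is.finite(origin_mm)))
    stop("'origin_mm' must be three finite values")
  structure(
    list(data = data, spacing_mm = spacing_mm, origin_mm = origin_mm,
         role = role, label = as.character(label)[1]),
    class = "voi_mask"
  )
}

#' @export
print.voi_mask <- function(x, ...) {
  cat("VOI mask [", x$role, "]: ", sum(x$data), " voxels, ",
      sprintf("%.3f cm^3", mask_volume_cm3(x)), "\n", sep = "")
  invisible(x)
}

#' @export
dim.voi_mask <- function(x) dim(x$data)

# shared-grid check used by every pairwise/mask-on-volume operation
check_same_grid <- function(a, b, tol_mm = 1e-6) {
  if (!identical(dim(a$data), dim(b$data)))
    stop("grid mismatch: array shapes differ (",
         paste(dim(a$data), collapse = "x"), " vs ",
         paste(dim(b$data), collapse = "x"), ")")
  if (max(abs(a$spacing_mm - b$spacing_mm)) > tol_mm)
    stop("grid mismatch: voxel spacings differ beyond ", tol_mm, " mm")
  # origins survive NIfTI headers only at float32 precision
  if (max(abs(a$origin_mm - b$origin_mm)) > max(tol_mm, 1e-3))
    stop("grid mismatch: origins differ beyond ", max(tol_mm, 1e-3), " mm")
  invisible(TRUE)
}

#' Mask volume in cubic centimetres
#'
#' @param m a [voi_mask()].
#' @return Voxel count times the voxel volume (product of spacings),
#'   divided by 1000 to convert mm^3 to cm^3.
#' @examples
#' m <- voi_mask(array(TRUE, c(10, 10, 10)), c(2.03135, 2.03135, 3))
#' mask_volume_cm3(m)  # 1000 voxels -> 12.379 cm^3
#' @export
mask_volume_cm3 <- function(m) {
  stopifnot(inherits(m, "voi_mask"))
  sum(m$data) * prod(m$spacing_mm) / 1000
}

# world coordinates (mm, n x 3) of the voxel centres of 1-based index rows
voxel_centers_mm <- function(idx, spacing_mm, origin_mm) {
  if (is.null(dim(idx))) idx <- matrix(idx, ncol = 3)
  sweep(sweep(idx - 0.5, 2, spacing_mm, "*"), 2, origin_mm, "+")
}

# 1-based voxel index (n x 3, fractional) of world coordinates
world_to_voxel <- function(xyz, spacing_mm, origin_mm) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
  sweep(xyz, 2, origin_mm, "-") %*% diag(1 / spacing_mm) + 0.5
}

# n x 3 matrix of 1-based indices of TRUE voxels
mask_indices <- function(mask_array) {
  which(mask_array, arr.ind = TRUE)
}

# logical array: ball of given radius around a world-mm centre;
# a voxel belongs to the ball iff its centre lies within the radius
ball_mask_array <- function(dim3, spacing_mm, origin_mm, center_mm,
                            radius_mm) {
  dx2 <- (origin_mm[1] + (seq_len(dim3[1]) - 0.5) * spacing_mm[1] -
            center_mm[1])^2
  dy2 <- (origin_mm[2] + (seq_len(dim3[2]) - 0.5) * spacing_mm[2] -
            center_mm[2])^2
  dz2 <- (origin_mm[3] + (seq_len(dim3[3]) - 0.5) * spacing_mm[3] -
            center_mm[3])^2
  d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
  array(d2 <= radius_mm^2, dim3)
}
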