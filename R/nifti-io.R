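#' Read and write PET volumes and VOI masks as NIfTI
#'
#' NIfTI-1 (`.nii` / `.nii.gz`) is the canonical interchange format of the
#' package.  Volumes are written with a float64 payload so that a
#' write/read round trip reproduces SUV data bit-exactly; masks are
#' written as uint8.  Mask role and label, and the frame mid-time of a
#' dynamic frame, travel in a JSON sidecar (`<file>.json` next to the
#' image) because NIfTI has no standard slot for them.
#'
#' @param path file path ending in `.nii` or `.nii.gz`.
#' @param v a [pet_volume()].
#' @return `read_volume()` returns a [pet_volume()]; `write_volume()`
#'   returns `path` invisibly.
#' @name nifti_io
NULL

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

nifti_affine <- function(spacing_mm, origin_mm) {
  aff <- diag(c(spacing_mm, 1))
  # qform offset addresses the centre of voxel [0,0,0]; our origin is the
  # grid corner, so shift by half a voxel
  aff[1:3, 4] <- origin_mm + 0.5 * spacing_mm
  aff
}

write_nifti_grid <- function(data, spacing_mm, origin_mm, path, datatype) {
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- spacing_mm
  RNifti::qform(img) <- structure(nifti_affine(spacing_mm, origin_mm),
                                  code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

read_nifti_grid <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) stop("expected a 3D NIfTI image, got ",
                            length(d), " dimensions")
  aff <- RNifti::xform(img)
  spacing <- RNifti::pixdim(img)[1:3]
  if (any(spacing <= 0)) stop("non-positive voxel spacing in ", path)
  origin <- aff[1:3, 4] - 0.5 * spacing
  list(data = array(as.vector(img), d), spacing_mm = as.numeric(spacing),
       origin_mm = as.numeric(origin))
}

#' @rdname nifti_io
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "pet_volume"))
  write_nifti_grid(v$data, v$spacing_mm, v$origin_mm, path, "double")
  meta <- list(kind = "pet_volume")
  if (!is.null(v$frame_time_min)) meta$frame_time_min <- v$frame_time_min
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname nifti_io
#' @export
read_volume <- function(path) {
  g <- read_nifti_grid(path)
  frame_time <- NULL
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (!is.null(meta$frame_time_min)) frame_time <- meta$frame_time_min
  }
  pet_volume(g$data, g$spacing_mm, g$origin_mm, frame_time_min = frame_time)
}

#' @param m a [voi_mask()].
#' @param role,label role/label to assign on read; when omitted they are
#'   taken from the JSON sidecar (falling back to `"ground_truth"`).
#' @param reference optional [pet_volume()]; when supplied the mask grid
#'   is checked against it and a mismatch raises a geometry error.
#' @rdname nifti_io
#' @export
write_mask <- function(m, path) {
  stopifnot(inherits(m, "voi_mask"))
  write_nifti_grid(m$data + 0L, m$spacing_mm, m$origin_mm, path, "uint8")
  jsonlite::write_json(list(kind = "voi_mask", role = m$role,
                            label = m$label),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname nifti_io
#' @export
read_mask <- function(path, role = NULL, label = NULL, reference = NULL) {
  g <- read_nifti_grid(path)
  vals <- unique(as.vector(g$data))
  if (!all(vals %in% c(0, 1)))
    stop("mask payload in ", path, " is not binary; found values ",
         paste(utils::head(sort(vals), 5), collapse = ", "))
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (is.null(role)) role <- meta$role
    if (is.null(label)) label <- meta$label
  }
  if (is.null(role)) role <- "ground_truth"
  if (is.null(label)) label <- ""
  m <- voi_mask(array(g$data > 0, dim(g$data)), g$spacing_mm, g$origin_mm,
                role = role, label = label, allow_empty = TRUE)
  if (!is.null(reference)) check_same_grid(m, reference)
  m
}
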