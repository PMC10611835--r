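#' Specification of a synthetic FET PET brain phantom
#'
#' The phantom emulates the ingredients the delineation workflow has to
#' cope with on a reconstructed amino-acid PET of the brain: an
#' ellipsoidal brain with grey/white compartments around a configurable
#' mean background uptake, a lesion of known volume and
#' tumour-to-background ratio (TBR), a scalp/sinus-like confounder of
#' elevated uptake outside the brain, Gaussian point-spread blur, and
#' additive Gaussian noise in SUV space.  Ground truth (pre-blur masks,
#' true background, true TBR) is returned alongside every simulated
#' image, so segmentation and agreement statistics can be validated
#' exactly.
#'
#' @param grid_shape integer length-3, voxels per axis.
#' @param spacing_mm voxel size per axis in mm; the default matches a
#'   common clinical brain PET reconstruction grid.
#' @param background_mean_suv mean SUV of normal brain.
#' @param gm_wm_contrast fractional grey/white contrast around the mean:
#'   grey matter is `background_mean_suv * (1 + c)`, white matter
#'   `background_mean_suv * (1 - c)`.  Set to 0 for a uniform brain.
#' @param lesion_center_mm lesion centre in world mm; `NULL` places it in
#'   the right hemisphere at a typical supratentorial position.
#' @param lesion_volume_cm3 true lesion volume in cm^3.
#' @param lesion_tbr true lesion-to-background uptake ratio; must exceed
#'   the 1.6 segmentation threshold for the phantom to be segmentable.
#' @param lesion_shape `"sphere"`, `"ellipsoid"` (axes 1 : 0.75 : 0.6) or
#'   `"shell"` (a resection-cavity-like rim whose cavity carries
#'   background uptake).
#' @param confounder_tbr uptake ratio of the scalp/sinus confounder.
#' @param confounder_volume_cm3 confounder volume in cm^3.
#' @param confounder_center_mm confounder centre; `NULL` places it on the
#'   scalp just outside the brain surface, on the lesion side.
#' @param psf_fwhm_mm full width at half maximum of the Gaussian
#'   point-spread blur, in mm.
#' @param noise_sd_suv standard deviation of additive Gaussian noise, in
#'   SUV.
#' @param seed integer RNG seed; identical specs give bit-identical
#'   phantoms.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(96, 96, 48),
                         spacing_mm = c(2.03135, 2.03135, 3),
                         background_mean_suv = 1.0,
                         gm_wm_contrast = 0.15,
                         lesion_center_mm = NULL,
                         lesion_volume_cm3 = 34.13,
                         lesion_tbr = 2.3,
                         lesion_shape = c("sphere", "ellipsoid", "shell"),
                         confounder_tbr = 2.0,
                         confounder_volume_cm3 = 1.5,
                         confounder_center_mm = NULL,
                         psf_fwhm_mm = 4,
                         noise_sd_suv = 0.05,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  spacing_mm <- as.numeric(spacing_mm)
  lesion_shape <- match.arg(lesion_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 8L))
    stop("'grid_shape' must be three integers >= 8")
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("'spacing_mm' must be three strictly positive values")
  for (nm in c("background_mean_suv", "lesion_volume_cm3", "lesion_tbr",
               "confounder_tbr", "confounder_volume_cm3")) {
    v <- get(nm)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      stop("'", nm, "' must be a single strictly positive number")
  }
  if (lesion_tbr <= 1.6)
    stop("'lesion_tbr' must exceed the 1.6 segmentation threshold ",
         "for a segmentable phantom")
  if (gm_wm_contrast < 0 || gm_wm_contrast >= 1)
    stop("'gm_wm_contrast' must be in [0, 1)")
  if (psf_fwhm_mm < 0 || noise_sd_suv < 0)
    stop("'psf_fwhm_mm' and 'noise_sd_suv' must be non-negative")
  extent <- grid_shape * spacing_mm
  center <- extent / 2
  brain_radii <- 0.40 * extent
  if (is.null(lesion_center_mm))
    lesion_center_mm <- center + c(0.45, 0.10, 0.05) * brain_radii
  lesion_center_mm <- as.numeric(lesion_center_mm)
  r_eq <- (3 * lesion_volume_cm3 * 1000 / (4 * pi))^(1 / 3)
  if (any(lesion_center_mm - r_eq < 0) ||
      any(lesion_center_mm + r_eq > extent))
    stop("lesion extends outside the grid")
  if (is.null(confounder_center_mm)) {
    u <- lesion_center_mm - center
    u <- u / sqrt(sum(u^2))
    # distance from centre to ellipsoid surface along u, plus a scalp gap
    t_surf <- 1 / sqrt(sum((u / brain_radii)^2))
    confounder_center_mm <- center + u * (t_surf + 2)
  }
  confounder_center_mm <- as.numeric(confounder_center_mm)
  r_conf <- (3 * confounder_volume_cm3 * 1000 / (4 * pi))^(1 / 3)
  if (any(confounder_center_mm - r_conf < 0) ||
      any(confounder_center_mm + r_conf > extent))
    stop("confounder extends outside the grid")
  structure(
    list(grid_shape = grid_shape, spacing_mm = spacing_mm,
         background_mean_suv = background_mean_suv,
         gm_wm_contrast = gm_wm_contrast,
         lesion_center_mm = lesion_center_mm,
         lesion_volume_cm3 = lesion_volume_cm3,
         lesion_tbr = lesion_tbr, lesion_shape = lesion_shape,
         confounder_tbr = confounder_tbr,
         confounder_volume_cm3 = confounder_volume_cm3,
         confounder_center_mm = confounder_center_mm,
         psf_fwhm_mm = psf_fwhm_mm, noise_sd_suv = noise_sd_suv,
         seed = as.integer(seed),
         brain_center_mm = center, brain_radii_mm = brain_radii),
    class = "phantom_spec"
  )
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("Phantom spec: grid", paste(x$grid_shape, collapse = "x"),
      "@", paste(format(x$spacing_mm, digits = 6), collapse = "x"), "mm\n")
  cat(sprintf("  background %.3g SUV, lesion %.4g cm^3 (%s) at TBR %.3g,\n",
              x$background_mean_suv, x$lesion_volume_cm3, x$lesion_shape,
              x$lesion_tbr))
  cat(sprintf("  confounder TBR %.3g, PSF %.3g mm FWHM, noise sd %.3g SUV, seed %d\n",
              x$confounder_tbr, x$psf_fwhm_mm, x$noise_sd_suv, x$seed))
  invisible(x)
}

# volume-calibrated voxelisation: the n voxels closest to the centre under
# the shape metric, n chosen so that n * voxel volume matches the target
# volume to within half a voxel
lesion_mask_array <- function(spec) {
  d <- spec$grid_shape; sp <- spec$spacing_mm
  ctr <- spec$lesion_center_mm
  vox_vol <- prod(sp) / 1000
  n_target <- max(1L, round(spec$lesion_volume_cm3 / vox_vol))
  # distances on a bounding box around the lesion only, for speed
  r_eq <- (3 * spec$lesion_volume_cm3 * 1000 / (4 * pi))^(1 / 3)
  pad <- 2.5 * r_eq
  rng <- lapply(1:3, function(ax) {
    lo <- max(1L, floor((ctr[ax] - pad) / sp[ax]))
    hi <- min(d[ax], ceiling((ctr[ax] + pad) / sp[ax]))
    lo:hi
  })
  ax_d <- function(ax) (rng[[ax]] - 0.5) * sp[ax] - ctr[ax]
  w <- switch(spec$lesion_shape,
              sphere = c(1, 1, 1),
              ellipsoid = c(1, 0.75, 0.6),
              shell = c(1, 1, 1))
  d2 <- outer(outer((ax_d(1) / w[1])^2, (ax_d(2) / w[2])^2, "+"),
              (ax_d(3) / w[3])^2, "+")
  mask <- array(FALSE, d)
  sub <- array(FALSE, dim(d2))
  if (spec$lesion_shape == "shell") {
    # rim between an inner cavity and the outer surface; same voxel budget
    r_out <- (spec$lesion_volume_cm3 * 1000 * 3 /
                (4 * pi * (1 - 0.6^3)))^(1 / 3)
    r_in <- 0.6 * r_out
    ord <- order(abs(sqrt(d2) - (r_in + r_out) / 2))
    sub[ord[seq_len(min(n_target, length(ord)))]] <- TRUE
  } else {
    ord <- order(d2)
    sub[ord[seq_len(min(n_target, length(ord)))]] <- TRUE
  }
  mask[rng[[1]], rng[[2]], rng[[3]]] <- sub
  mask
}

brain_compartments <- function(spec) {
  d <- spec$grid_shape; sp <- spec$spacing_mm
  ctr <- spec$brain_center_mm; rad <- spec$brain_radii_mm
  nd <- function(ax) ((seq_len(d[ax]) - 0.5) * sp[ax] - ctr[ax]) / rad[ax]
  r2 <- outer(outer(nd(1)^2, nd(2)^2, "+"), nd(3)^2, "+")
  list(brain = array(r2 <= 1, d), white = array(r2 <= 0.65^2, d))
}

#' Generate a static PET phantom with ground truth
#'
#' Builds the piecewise-constant compartment image described by a
#' [phantom_spec()] (brain grey/white background, lesion at
#' `background * lesion_tbr`, scalp/sinus confounder at
#' `background * confounder_tbr`), convolves it with a Gaussian
#' point-spread function, and adds Gaussian noise.  Ground-truth masks
#' are recorded before blurring.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `volume` (a [pet_volume()]) and `truth`
#'   (class `fet_ground_truth`: `lesion_mask`, `confounder_mask`,
#'   `brain_mask`, `true_background_suv`, `true_tbr`, `true_volume_cm3`,
#'   `lesion_center_mm`).
#' @examples
#' ph <- make_static_phantom(phantom_spec(grid_shape = c(48, 48, 24),
#'                                        seed = 7))
#' ph$volume
#' ph$truth$true_volume_cm3
#' @export
make_static_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  comp <- brain_compartments(spec)
  lesion <- lesion_mask_array(spec)
  if (spec$lesion_shape == "shell") {
    # cavity interior keeps background uptake; the rim is the lesion
  }
  conf <- ball_mask_array(spec$grid_shape, spec$spacing_mm, c(0, 0, 0),
                          spec$confounder_center_mm,
                          (3 * spec$confounder_volume_cm3 * 1000 /
                             (4 * pi))^(1 / 3))
  if (any(lesion & conf))
    stop("lesion and confounder overlap; adjust the geometry")
  bg <- spec$background_mean_suv
  img <- array(0, spec$grid_shape)
  img[comp$brain] <- bg * (1 + spec$gm_wm_contrast)       # grey matter
  img[comp$white] <- bg * (1 - spec$gm_wm_contrast)       # white matter
  img[lesion] <- bg * spec$lesion_tbr
  img[conf] <- bg * spec$confounder_tbr
  img <- gaussian_blur_3d(img, spec$psf_fwhm_mm, spec$spacing_mm)
  if (spec$noise_sd_suv > 0) {
    set.seed(spec$seed)
    img <- img + array(stats::rnorm(length(img), 0, spec$noise_sd_suv),
                       dim(img))
  }
  img <- pmax(img, 0)
  vol <- pet_volume(img, spec$spacing_mm)
  truth <- structure(
    list(lesion_mask = voi_mask(lesion, spec$spacing_mm,
                                role = "ground_truth", label = "lesion"),
         confounder_mask = voi_mask(conf, spec$spacing_mm,
                                    role = "ground_truth",
                                    label = "confounder"),
         brain_mask = voi_mask(comp$brain, spec$spacing_mm,
                               role = "ground_truth", label = "brain"),
         true_background_suv = bg,
         true_tbr = spec$lesion_tbr,
         true_volume_cm3 = sum(lesion) * prod(spec$spacing_mm) / 1000,
         lesion_center_mm = spec$lesion_center_mm,
         spec = spec),
    class = "fet_ground_truth")
  list(volume = vol, truth = truth)
}

#' Canonical time-activity curve shapes
#'
#' Relative lesion activity over the acquisition for the three canonical
#' dynamic uptake patterns of amino-acid PET: type I rises monotonically
#' to the end of the acquisition, type II peaks in mid-acquisition and
#' then plateaus (minor descent), type III peaks early and then washes
#' out.  Curves are normalised to peak 1.
#'
#' @param tac_shape `"I"`, `"II"` or `"III"`.
#' @param times_min numeric vector of frame mid-times in minutes.
#' @param t_end_min end of the acquisition window (default 40).
#' @return Numeric vector of relative activities, one per frame.
#' @export
canonical_tac <- function(tac_shape, times_min, t_end_min = 40) {
  tac_shape <- match.arg(as.character(tac_shape), c("I", "II", "III"))
  t <- times_min
  up <- function(t, t_peak) 0.5 + 0.5 * pmin(t, t_peak) / t_peak
  switch(tac_shape,
         I = 0.5 + 0.5 * t / t_end_min,
         II = {
           t_peak <- 25
           y <- up(t, t_peak)
           late <- t > t_peak
           y[late] <- 1 - 0.05 * (t[late] - t_peak) / (t_end_min - t_peak)
           y
         },
         III = {
           t_peak <- 10
           y <- up(t, t_peak)
           late <- t > t_peak
           y[late] <- 1 - 0.40 * (t[late] - t_peak) / (t_end_min - t_peak)
           y
         })
}

#' Generate a dynamic PET phantom
#'
#' Produces one [pet_volume()] per frame.  The lesion compartment is
#' scaled frame-by-frame by the canonical curve of the requested shape
#' ([canonical_tac()]); background and confounder stay constant.  Blur
#' and noise are applied per frame as in [make_static_phantom()].
#'
#' @param spec a [phantom_spec()].
#' @param tac_shape `"I"`, `"II"` or `"III"`.
#' @param frame_mid_times_min strictly increasing frame mid-times within
#'   0-40 min; the default is eight 5-min frames spanning the 40-min
#'   acquisition.
#' @return A list with `frames` (list of [pet_volume()]) and `truth` (as
#'   in [make_static_phantom()], with the true per-frame lesion scaling
#'   recorded as `truth$tac_scaling`).
#' @export
make_dynamic_phantom <- function(spec, tac_shape,
                                 frame_mid_times_min = seq(2.5, 37.5, by = 5)) {
  stopifnot(inherits(spec, "phantom_spec"))
  t <- as.numeric(frame_mid_times_min)
  if (length(t) < 2L || any(diff(t) <= 0) || any(t < 0) || any(t > 40))
    stop("frame mid-times must be strictly increasing within 0-40 min")
  g <- canonical_tac(tac_shape, t)
  comp <- brain_compartments(spec)
  lesion <- lesion_mask_array(spec)
  conf <- ball_mask_array(spec$grid_shape, spec$spacing_mm, c(0, 0, 0),
                          spec$confounder_center_mm,
                          (3 * spec$confounder_volume_cm3 * 1000 /
                             (4 * pi))^(1 / 3))
  bg <- spec$background_mean_suv
  base <- array(0, spec$grid_shape)
  base[comp$brain] <- bg * (1 + spec$gm_wm_contrast)
  base[comp$white] <- bg * (1 - spec$gm_wm_contrast)
  base[conf] <- bg * spec$confounder_tbr
  set.seed(spec$seed)
  frames <- vector("list", length(t))
  for (f in seq_along(t)) {
    img <- base
    img[lesion] <- bg * spec$lesion_tbr * g[f]
    img <- gaussian_blur_3d(img, spec$psf_fwhm_mm, spec$spacing_mm)
    if (spec$noise_sd_suv > 0)
      img <- img + array(stats::rnorm(length(img), 0, spec$noise_sd_suv),
                         dim(img))
    frames[[f]] <- pet_volume(pmax(img, 0), spec$spacing_mm,
                              frame_time_min = t[f])
  }
  truth <- structure(
    list(lesion_mask = voi_mask(lesion, spec$spacing_mm,
                                role = "ground_truth", label = "lesion"),
         confounder_mask = voi_mask(conf, spec$spacing_mm,
                                    role = "ground_truth",
                                    label = "confounder"),
         brain_mask = voi_mask(comp$brain, spec$spacing_mm,
                               role = "ground_truth", label = "brain"),
         true_background_suv = bg, true_tbr = spec$lesion_tbr,
         true_volume_cm3 = sum(lesion) * prod(spec$spacing_mm) / 1000,
         lesion_center_mm = spec$lesion_center_mm,
         tac_shape = match.arg(as.character(tac_shape), c("I", "II", "III")),
         tac_scaling = g, spec = spec),
    class = "fet_ground_truth")
  list(frames = frames, truth = truth)
}
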