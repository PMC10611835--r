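#' Simulated rater model
#'
#' Describes how a cohort of simulated readers perturbs the inputs of
#' the delineation workflow.  Variability is injected where it arises in
#' practice: placement of the initial spherical search volume, choice of
#' the crescent slice, a global under/over-segmentation tendency applied
#' as audited boundary edits, and the decision whether to remove
#' confounding non-tumour uptake after thresholding.
#'
#' @param n_raters number of readers (>= 2, as credentialing requires at
#'   least two readers per site).
#' @param boundary_jitter_mm SD (mm) of the signed boundary offset each
#'   reader applies to the thresholded volume (dilation when positive,
#'   erosion when negative); also drives a one-slice-scale jitter of the
#'   crescent slice.
#' @param sphere_offset_mm SD (mm, per axis) of the search-sphere
#'   placement error.
#' @param p_include_confounder probability that a reader fails to remove
#'   the confounder component after thresholding.
#' @param seed integer; per-reader seeds are derived from it.
#' @return An object of class `rater_model`.
#' @export
rater_model <- function(n_raters = 3L, boundary_jitter_mm = 1,
                        sphere_offset_mm = 2, p_include_confounder = 0,
                        seed = 1L) {
  n_raters <- as.integer(n_raters)
  if (n_raters < 2L) stop("'n_raters' must be at least 2")
  if (boundary_jitter_mm < 0 || sphere_offset_mm < 0)
    stop("jitter SDs must be non-negative")
  if (p_include_confounder < 0 || p_include_confounder > 1)
    stop("'p_include_confounder' must be in [0, 1]")
  structure(list(n_raters = n_raters,
                 boundary_jitter_mm = boundary_jitter_mm,
                 sphere_offset_mm = sphere_offset_mm,
                 p_include_confounder = p_include_confounder,
                 seed = as.integer(seed)),
            class = "rater_model")
}

# components of gtv0 overlapping the confounder but not the lesion;
# returns seed voxels (one per such component) for remove_component edits
confounder_component_seeds <- function(gtv0_array, truth,
                                       connectivity = 26L) {
  if (!any(gtv0_array)) return(list())
  lab <- label_components(gtv0_array, connectivity)
  conf_labs <- setdiff(unique(lab[truth$confounder_mask$data & lab > 0]), 0L)
  lesion_labs <- setdiff(unique(lab[truth$lesion_mask$data & lab > 0]), 0L)
  seeds <- list()
  for (l in setdiff(conf_labs, lesion_labs)) {
    sv <- which(lab == l, arr.ind = TRUE)[1, ]
    seeds[[length(seeds) + 1L]] <- as.integer(sv)
  }
  seeds
}

#' Simulate a cohort of reader contours
#'
#' Runs the full delineation workflow once per simulated reader, with
#' reader-specific perturbations drawn from a [rater_model()]:
#' sphere-placement offsets, crescent-slice jitter, a signed boundary
#' edit, and probabilistic retention of the confounder component.  With
#' all variance parameters at zero every reader produces an identical
#' mask.
#'
#' @param truth ground truth from [make_static_phantom()].
#' @param image the matching [pet_volume()].
#' @param model a [rater_model()].
#' @param sphere_radius_mm radius of the search sphere; the default is
#'   1.5 times the lesion-equivalent radius plus 5 mm.
#' @param tbr_threshold TBR threshold (default 1.6).
#' @return A list of `model$n_raters` BTV [voi_mask()]s; the full
#'   `fet_delineation` of each reader is attached as attribute
#'   `delineations`.
#' @export
make_rater_cohort <- function(truth, image, model,
                              sphere_radius_mm = NULL,
                              tbr_threshold = 1.6) {
  stopifnot(inherits(truth, "fet_ground_truth"),
            inherits(image, "pet_volume"),
            inherits(model, "rater_model"))
  check_same_grid(truth$lesion_mask,
                  list(data = image$data, spacing_mm = image$spacing_mm,
                       origin_mm = image$origin_mm))
  spec <- truth$spec
  if (is.null(sphere_radius_mm)) {
    r_eq <- (3 * spec$lesion_volume_cm3 * 1000 / (4 * pi))^(1 / 3)
    sphere_radius_mm <- 1.5 * r_eq + 5
  }
  d <- dim(image$data)
  lesion_side <- if (truth$lesion_center_mm[1] >=
                     d[1] * image$spacing_mm[1] / 2) "right" else "left"
  base_slice <- ceiling(d[3] / 2)
  masks <- vector("list", model$n_raters)
  delins <- vector("list", model$n_raters)
  for (r in seq_len(model$n_raters)) {
    set.seed(model$seed + r)
    center <- truth$lesion_center_mm +
      stats::rnorm(3, 0, model$sphere_offset_mm)
    slice <- base_slice + round(stats::rnorm(
      1, 0, model$boundary_jitter_mm / image$spacing_mm[3]))
    slice <- min(max(slice, 1L), d[3])
    keep_confounder <- stats::runif(1) < model$p_include_confounder
    boundary_offset <- stats::rnorm(1, 0, model$boundary_jitter_mm)

    bg <- build_crescent_background(image, lesion_side, slice)
    delin <- threshold_gtv0(image, center, sphere_radius_mm, bg,
                            tbr_threshold)
    edits <- list()
    if (!keep_confounder) {
      for (sv in confounder_component_seeds(delin$gtv0$data, truth))
        edits[[length(edits) + 1L]] <-
          list(op = "remove_component", seed_voxel = sv)
    }
    if (abs(boundary_offset) >= min(image$spacing_mm) / 2 &&
        any(delin$gtv0$data)) {
      grown <- mask_grow(delin$gtv0$data, boundary_offset,
                         image$spacing_mm)
      if (boundary_offset > 0) {
        add <- grown & !delin$gtv0$data
        if (any(add))
          edits[[length(edits) + 1L]] <- list(op = "add_region",
                                              mask = add)
      } else {
        rem <- delin$gtv0$data & !grown
        if (any(rem))
          edits[[length(edits) + 1L]] <- list(op = "remove_region",
                                              mask = rem)
      }
    }
    delin <- edit_btv(delin, edits, image = image)
    if (any(delin$btv$data)) {
      tb <- compute_tbr(image, delin$btv, bg)
      delin[names(tb)] <- tb
    }
    delins[[r]] <- delin
    m <- delin$btv
    m$label <- sprintf("rater %d", r)
    masks[[r]] <- m
  }
  attr(masks, "delineations") <- delins
  masks
}
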