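#' Crescent-shaped background region and background SUV
#'
#' Background uptake is assessed from a crescent-shaped region of
#' interest spanning grey and white matter in the hemisphere
#' contralateral to the lesion.  The crescent is a parametric annular
#' arc drawn on a single axial slice and extruded over neighbouring
#' slices into a short tube; the background value is the mean SUV over
#' the resulting mask and is frozen before thresholding.
#'
#' @param image a [pet_volume()].
#' @param lesion_side `"left"` or `"right"`: the hemisphere containing
#'   the suspected lesion (along the first grid axis).  The crescent is
#'   placed on the opposite side; any crescent voxel falling on the
#'   lesion side of the midline is an error.
#' @param slice_index axial slice (1-based, third axis) on which the
#'   crescent is drawn; default the middle slice.
#' @param params list of crescent geometry parameters:
#'   `inner_radius_mm`, `outer_radius_mm` (annulus radii around the
#'   in-plane grid centre; when `NULL` they are sized from the brain
#'   footprint of the drawn slice, at 0.45 and 0.85 of its effective
#'   radius, so that the crescent spans grey and white matter on any
#'   grid), `span_deg` (arc span, centred on the direction pointing
#'   away from the lesion) and `n_slices_extruded` (the tube extends
#'   this many slices each side of `slice_index`).  See
#'   [crescent_params()] for defaults.
#' @return An object of class `fet_background`: `mask` (a [voi_mask()]
#'   with role `background_crescent`), `suv_mean`, `slice_index`,
#'   `n_slices_extruded`.
#' @export
build_crescent_background <- function(image, lesion_side = c("right", "left"),
                                      slice_index = NULL,
                                      params = crescent_params()) {
  stopifnot(inherits(image, "pet_volume"))
  lesion_side <- match.arg(lesion_side)
  d <- dim(image$data); sp <- image$spacing_mm
  if (is.null(slice_index)) slice_index <- ceiling(d[3] / 2)
  slice_index <- as.integer(slice_index)
  if (slice_index < 1L || slice_index > d[3])
    stop("'slice_index' outside the grid")
  p <- utils::modifyList(crescent_params(), as.list(params),
                         keep.null = TRUE)
  if (is.null(p$inner_radius_mm) || is.null(p$outer_radius_mm)) {
    # size the annulus from the brain footprint on the drawn slice so
    # the crescent straddles the grey/white boundary on any grid
    sl <- image$data[, , slice_index]
    fg <- sl > 0.1 * max(sl)
    r_b <- sqrt(sum(fg) * sp[1] * sp[2] / pi)
    if (is.null(p$inner_radius_mm)) p$inner_radius_mm <- 0.45 * r_b
    if (is.null(p$outer_radius_mm)) p$outer_radius_mm <- 0.85 * r_b
  }
  if (p$inner_radius_mm <= 0 || p$outer_radius_mm <= p$inner_radius_mm)
    stop("need 0 < inner_radius_mm < outer_radius_mm")
  cx <- d[1] * sp[1] / 2; cy <- d[2] * sp[2] / 2
  x <- (seq_len(d[1]) - 0.5) * sp[1] - cx
  y <- (seq_len(d[2]) - 0.5) * sp[2] - cy
  r <- sqrt(outer(x^2, y^2, "+"))
  theta <- atan2(matrix(y, d[1], d[2], byrow = TRUE),
                 matrix(x, d[1], d[2]))
  # arc centred on the direction away from the lesion
  theta_c <- if (lesion_side == "right") pi else 0
  dtheta <- atan2(sin(theta - theta_c), cos(theta - theta_c))
  in_slice <- r >= p$inner_radius_mm & r <= p$outer_radius_mm &
    abs(dtheta) <= (p$span_deg / 2) * pi / 180
  if (!any(in_slice)) stop("crescent mask is empty on this grid")
  # contralateral containment: every crescent voxel must lie strictly on
  # the far side of the sagittal midline
  xs <- matrix(x, d[1], d[2])[in_slice]
  if ((lesion_side == "right" && any(xs >= 0)) ||
      (lesion_side == "left" && any(xs <= 0)))
    stop("crescent crosses the midline toward the lesion hemisphere")
  slices <- max(1L, slice_index - p$n_slices_extruded):
    min(d[3], slice_index + p$n_slices_extruded)
  mask <- array(FALSE, d)
  for (s in slices) mask[, , s] <- in_slice
  m <- voi_mask(mask, sp, image$origin_mm, role = "background_crescent",
                label = sprintf("crescent slice %d +/-%d", slice_index,
                                p$n_slices_extruded))
  structure(
    list(mask = m, suv_mean = mean(image$data[mask]),
         slice_index = slice_index,
         n_slices_extruded = p$n_slices_extruded),
    class = "fet_background"
  )
}

#' @rdname build_crescent_background
#' @export
crescent_params <- function() {
  list(inner_radius_mm = NULL, outer_radius_mm = NULL, span_deg = 120,
       n_slices_extruded = 1L)
}

#' @export
print.fet_background <- function(x, ...) {
  cat(sprintf(
    "Crescent background: SUV_mean %.4f over %d voxels (slice %d, +/-%d)\n",
    x$suv_mean, sum(x$mask$data), x$slice_index, x$n_slices_extruded))
  invisible(x)
}

#' TBR thresholding of a spherical search region
#'
#' Applies the tumour-to-background-ratio threshold inside a spherical
#' search volume (the Static VOI) placed around the suspected tumour.
#' A voxel joins the thresholded volume GTV0 when its centre lies inside
#' the sphere and its SUV is at least `tbr_threshold` times the frozen
#' background mean.  An empty GTV0 is not an error: the result is
#' flagged, which is the legitimate outcome for a photopenic case.
#'
#' @param image a [pet_volume()].
#' @param sphere_center_mm,sphere_radius_mm sphere centre (world mm) and
#'   radius.
#' @param bg a `fet_background` from [build_crescent_background()].
#' @param tbr_threshold TBR threshold; 1.6 is the protocol default
#'   (alternatives such as 1.7-1.8 can be configured but are not the
#'   default).
#' @return An object of class `fet_delineation` holding `static_sphere`
#'   and `gtv0` masks, the `background`, `threshold_suv =
#'   tbr_threshold * bg$suv_mean`, and `empty_gtv0` flag.  The BTV slot
#'   is initialised to GTV0 and replaced by [edit_btv()].
#' @export
threshold_gtv0 <- function(image, sphere_center_mm, sphere_radius_mm,
                           bg, tbr_threshold = 1.6) {
  stopifnot(inherits(image, "pet_volume"), inherits(bg, "fet_background"))
  if (bg$suv_mean <= 0) stop("background SUV_mean must be positive")
  if (sphere_radius_mm <= 0) stop("'sphere_radius_mm' must be positive")
  d <- dim(image$data)
  sph <- ball_mask_array(d, image$spacing_mm, image$origin_mm,
                         sphere_center_mm, sphere_radius_mm)
  if (!any(sph)) stop("static sphere does not intersect the grid")
  thr <- tbr_threshold * bg$suv_mean
  g0 <- sph & (image$data >= thr)
  structure(
    list(static_sphere = voi_mask(sph, image$spacing_mm, image$origin_mm,
                                  role = "static_sphere"),
         gtv0 = voi_mask(g0, image$spacing_mm, image$origin_mm,
                         role = "gtv0", allow_empty = TRUE),
         btv = voi_mask(g0, image$spacing_mm, image$origin_mm,
                        role = "btv", allow_empty = TRUE),
         background = bg, threshold_suv = thr,
         tbr_threshold = tbr_threshold,
         sphere_center_mm = as.numeric(sphere_center_mm),
         sphere_radius_mm = sphere_radius_mm,
         empty_gtv0 = !any(g0), edit_log = NULL,
         suv_max = NA_real_, suv_max_location = NULL,
         tbr_max = NA_real_, tbr_mean = NA_real_),
    class = "fet_delineation"
  )
}

#' Audited manual editing of the thresholded volume
#'
#' Applies an ordered list of manual edits to GTV0 to produce the final
#' biological tumour volume (BTV): removing a connected component (for
#' scalp or sinus uptake picked up by the threshold), removing an
#' arbitrary region, or adding a region.  Every edit is recorded in an
#' audit log; adding voxels that fall below the SUV threshold is
#' permitted but logged with a warning flag, because such additions are
#' exactly what drags TBR_mean down in practice.
#'
#' @param gtv0 a [voi_mask()] (role `gtv0`) or a `fet_delineation` from
#'   [threshold_gtv0()].
#' @param edits list of edits; each edit is a list with `op` one of
#'   `"remove_component"` (requires `seed_voxel`, a 1-based voxel index
#'   triple), `"remove_region"` or `"add_region"` (both requiring
#'   `mask`, a [voi_mask()] or logical array on the same grid).
#' @param image the [pet_volume()] being delineated (needed to check
#'   added voxels against the threshold; optional for pure mask edits).
#' @param threshold_suv SUV threshold used for the warning check; taken
#'   from the `fet_delineation` when available.
#' @param connectivity 26 (default) or 6; neighbourhood used by
#'   `remove_component`.
#' @return If `gtv0` was a `fet_delineation`, the same object with `btv`
#'   and `edit_log` updated; otherwise a [voi_mask()] of role `btv` with
#'   the log attached as attribute `edit_log`.
#' @export
edit_btv <- function(gtv0, edits = list(), image = NULL,
                     threshold_suv = NULL, connectivity = 26L) {
  delin <- NULL
  if (inherits(gtv0, "fet_delineation")) {
    delin <- gtv0
    if (is.null(threshold_suv)) threshold_suv <- delin$threshold_suv
    gtv0 <- delin$gtv0
  }
  stopifnot(inherits(gtv0, "voi_mask"))
  cur <- gtv0$data
  log <- list()
  for (i in seq_along(edits)) {
    e <- edits[[i]]
    op <- match.arg(e$op, c("remove_component", "remove_region",
                            "add_region"))
    warn <- NA_character_
    if (op == "remove_component") {
      sv <- as.integer(e$seed_voxel)
      if (length(sv) != 3L) stop("edit ", i, ": 'seed_voxel' must be a ",
                                 "1-based voxel index triple")
      if (!cur[sv[1], sv[2], sv[3]]) {
        warn <- "seed voxel not inside the current mask; no-op"
        removed <- 0L
      } else {
        lab <- label_components(cur, connectivity)
        drop <- lab == lab[sv[1], sv[2], sv[3]]
        removed <- sum(drop)
        cur <- cur & !drop
      }
      log[[i]] <- data.frame(step = i, op = op, voxels_changed = removed,
                             warning = warn, stringsAsFactors = FALSE)
    } else {
      mk <- e$mask
      if (inherits(mk, "voi_mask")) {
        check_same_grid(mk, gtv0)
        mk <- mk$data
      }
      if (!identical(dim(mk), dim(cur)))
        stop("edit ", i, ": region mask grid mismatch")
      if (op == "remove_region") {
        changed <- sum(cur & mk)
        cur <- cur & !mk
      } else {
        added <- mk & !cur
        changed <- sum(added)
        if (!is.null(image) && !is.null(threshold_suv) &&
            is.finite(threshold_suv)) {
          n_below <- sum(image$data[added] < threshold_suv)
          if (n_below > 0)
            warn <- sprintf(
              "%d added voxel(s) below the SUV threshold %.4f", n_below,
              threshold_suv)
        }
        cur <- cur | mk
      }
      log[[i]] <- data.frame(step = i, op = op, voxels_changed = changed,
                             warning = warn, stringsAsFactors = FALSE)
    }
  }
  log <- if (length(log)) do.call(rbind, log) else
    data.frame(step = integer(), op = character(),
               voxels_changed = integer(), warning = character(),
               stringsAsFactors = FALSE)
  btv <- voi_mask(cur, gtv0$spacing_mm, gtv0$origin_mm, role = "btv",
                  allow_empty = TRUE)
  if (!is.null(delin)) {
    delin$btv <- btv
    delin$edit_log <- log
    return(delin)
  }
  attr(btv, "edit_log") <- log
  btv
}

#' Tumour-to-background ratios of a delineated volume
#'
#' `TBR_max` is the maximum SUV within the BTV divided by the background
#' mean; `TBR_mean` is the mean SUV within the BTV divided by the
#' background mean.  Ties in the SUV maximum are broken at the lowest
#' linear voxel index, so the reported location is deterministic.
#'
#' @param image a [pet_volume()].
#' @param btv a non-empty [voi_mask()].
#' @param bg a `fet_background`.
#' @return A list: `tbr_max`, `tbr_mean`, `suv_max`,
#'   `suv_max_location` (1-based voxel index triple).
#' @examples
#' v <- pet_volume(array(c(2, 3, 1, 1), c(2, 2, 1)), c(2, 2, 3))
#' b <- structure(list(suv_mean = 1.25), class = "fet_background")
#' m <- voi_mask(array(c(TRUE, TRUE, FALSE, FALSE), c(2, 2, 1)), c(2, 2, 3))
#' compute_tbr(v, m, b)  # tbr_max 2.4, tbr_mean 2
#' @export
compute_tbr <- function(image, btv, bg) {
  stopifnot(inherits(image, "pet_volume"), inherits(btv, "voi_mask"),
            inherits(bg, "fet_background"))
  if (!any(btv$data)) stop("BTV is empty; TBR undefined")
  if (bg$suv_mean <= 0) stop("background SUV_mean must be positive")
  vals <- image$data[btv$data]
  lin <- which(btv$data)
  i_max <- lin[which.max(vals)]      # which.max takes the first maximum
  loc <- arrayInd(i_max, dim(image$data))[1, ]
  list(tbr_max = max(vals) / bg$suv_mean,
       tbr_mean = mean(vals) / bg$suv_mean,
       suv_max = max(vals),
       suv_max_location = as.integer(loc))
}

#' Full semi-automatic BTV delineation
#'
#' Runs the complete workflow on a static volume: crescent background on
#' a single slice, TBR thresholding within the spherical search region,
#' audited manual edits, and TBR statistics.
#'
#' @inheritParams build_crescent_background
#' @inheritParams threshold_gtv0
#' @param edits edit list for [edit_btv()].
#' @return A `fet_delineation` with all masks, the background, the edit
#'   log and `tbr_max` / `tbr_mean` / `suv_max` filled in (TBR fields
#'   stay `NA` when the BTV comes out empty).
#' @export
delineate <- function(image, sphere_center_mm, sphere_radius_mm,
                      lesion_side = c("right", "left"), slice_index = NULL,
                      params = crescent_params(), tbr_threshold = 1.6,
                      edits = list()) {
  bg <- build_crescent_background(image, lesion_side, slice_index, params)
  delin <- threshold_gtv0(image, sphere_center_mm, sphere_radius_mm, bg,
                          tbr_threshold)
  delin <- edit_btv(delin, edits, image = image)
  if (any(delin$btv$data)) {
    tb <- compute_tbr(image, delin$btv, bg)
    delin[names(tb)] <- tb
  }
  delin
}

#' @export
print.fet_delineation <- function(x, ...) {
  cat("FET delineation\n")
  cat(sprintf("  background SUV_mean %.4f -> threshold %.4f (TBR %.2f)\n",
              x$background$suv_mean, x$threshold_suv, x$tbr_threshold))
  cat(sprintf("  GTV0 %.3f cm^3, BTV %.3f cm^3 (%d edit(s))\n",
              mask_volume_cm3(x$gtv0), mask_volume_cm3(x$btv),
              if (is.null(x$edit_log)) 0L else nrow(x$edit_log)))
  if (isTRUE(x$empty_gtv0))
    cat("  [flag] empty GTV0: no voxel reached the threshold\n")
  if (is.finite(x$tbr_max))
    cat(sprintf("  TBR_max %.3f, TBR_mean %.3f (SUV_max %.3f)\n",
                x$tbr_max, x$tbr_mean, x$suv_max))
  invisible(x)
}
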