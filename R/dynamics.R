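#' 1-mL sphere centred on the SUV maximum of the BTV
#'
#' For dynamic analysis a 1-mL spherical volume of interest is generated
#' automatically, centred on the voxel holding the SUV maximum of the
#' BTV in the static image.  The continuous sphere radius is
#' `(3 * 1000 / (4 * pi))^(1/3)` which is approximately 6.20 mm; on a
#' coarse grid the realised voxel volume is not guaranteed to equal 1 mL
#' and is recorded in attribute `realized_volume_cm3`.
#'
#' @param static a [pet_volume()] (the summed static image).
#' @param btv a non-empty [voi_mask()].
#' @param bg optionally a `fet_background` (only used so that the SUV
#'   maximum search is identical to [compute_tbr()]'s; ratios are not
#'   needed here).
#' @return A [voi_mask()] of role `dyn_sphere_1ml` with attributes
#'   `center_mm` and `realized_volume_cm3`.
#' @export
sphere_1ml_at_suvmax <- function(static, btv, bg = NULL) {
  stopifnot(inherits(static, "pet_volume"), inherits(btv, "voi_mask"))
  if (!any(btv$data)) stop("BTV is empty; cannot place the 1-mL sphere")
  vals <- static$data[btv$data]
  lin <- which(btv$data)
  loc <- arrayInd(lin[which.max(vals)], dim(static$data))[1, ]
  center <- as.numeric(voxel_centers_mm(matrix(loc, ncol = 3),
                                        static$spacing_mm,
                                        static$origin_mm))
  radius <- (3 * 1000 / (4 * pi))^(1 / 3)
  sph <- ball_mask_array(dim(static$data), static$spacing_mm,
                         static$origin_mm, center, radius)
  m <- voi_mask(sph, static$spacing_mm, static$origin_mm,
                role = "dyn_sphere_1ml", label = "1 mL at SUV_max")
  attr(m, "center_mm") <- center
  attr(m, "realized_volume_cm3") <- mask_volume_cm3(m)
  m
}

#' Extract a time-activity curve from dynamic frames
#'
#' The curve value of each frame is the mean SUV over the sphere voxels;
#' the time to peak (TTP) is the frame mid-time of the global maximum,
#' with ties resolved to the earliest frame.
#'
#' @param frames list of [pet_volume()]s, each carrying
#'   `frame_time_min`, or with times supplied via `times_min`.
#' @param sphere a non-empty [voi_mask()] (normally from
#'   [sphere_1ml_at_suvmax()]).
#' @param times_min optional explicit frame mid-times overriding the
#'   frames' own.
#' @return An object of class `fet_tac`: `times_min`, `mean_suv`,
#'   `ttp_min`, and `tac_type` (`NA` until [classify_tac()] is applied).
#' @export
extract_tac <- function(frames, sphere, times_min = NULL) {
  stopifnot(is.list(frames), length(frames) >= 1L,
            inherits(sphere, "voi_mask"))
  if (!any(sphere$data)) stop("sphere mask is empty")
  if (is.null(times_min))
    times_min <- vapply(frames, function(f) {
      if (is.null(f$frame_time_min))
        stop("frames carry no 'frame_time_min'; pass 'times_min'")
      f$frame_time_min
    }, numeric(1))
  if (length(times_min) != length(frames))
    stop("'times_min' length must match the number of frames")
  if (any(diff(times_min) <= 0))
    stop("frame times must be strictly increasing")
  mean_suv <- vapply(frames, function(f) {
    check_same_grid(sphere, list(data = f$data, spacing_mm = f$spacing_mm,
                                 origin_mm = f$origin_mm))
    mean(f$data[sphere$data])
  }, numeric(1))
  structure(list(times_min = as.numeric(times_min), mean_suv = mean_suv,
                 ttp_min = times_min[which.max(mean_suv)],
                 tac_type = NA_character_),
            class = "fet_tac")
}

#' @rdname extract_tac
#' @param tac a `fet_tac`.
#' @export
time_to_peak <- function(tac) {
  stopifnot(inherits(tac, "fet_tac"))
  tac$times_min[which.max(tac$mean_suv)]
}

#' @export
print.fet_tac <- function(x, ...) {
  cat(sprintf("TAC over %d frames (%.1f-%.1f min): peak %.3f SUV at %.1f min",
              length(x$times_min), min(x$times_min), max(x$times_min),
              max(x$mean_suv), x$ttp_min))
  if (!is.na(x$tac_type)) cat(", type ", x$tac_type, sep = "")
  cat("\n")
  invisible(x)
}

#' @export
plot.fet_tac <- function(x, ...) {
  plot(x$times_min, x$mean_suv, type = "b", xlab = "time (min)",
       ylab = "mean SUV (1-mL sphere)",
       main = if (is.na(x$tac_type)) "Time-activity curve" else
         paste("Time-activity curve, type", x$tac_type), ...)
  graphics::abline(v = x$ttp_min, lty = 2)
  invisible(x)
}

#' Classify a time-activity curve into type I, II or III
#'
#' The three canonical uptake patterns are distinguished by the time to
#' peak and the post-peak behaviour: type I keeps rising to the end of
#' the acquisition; type II peaks after `early_peak_cutoff_min` and then
#' plateaus (descent within `plateau_tolerance_frac` of the peak); type
#' III peaks at or before the cutoff and then washes out beyond the
#' tolerance.  A curve with a late peak followed by a descent beyond the
#' tolerance is also reported as type III (washout); the rule trace
#' records every decision.  The exact boundary values are conventions,
#' not universal constants, and are therefore parameters.
#'
#' @param tac a `fet_tac` with at least three frames.
#' @param early_peak_cutoff_min boundary (min) between an "early" and a
#'   "late" peak; default 20.
#' @param plateau_tolerance_frac maximum post-peak fractional descent,
#'   relative to the peak, still counted as a plateau; default 0.10.
#' @return The `fet_tac` with `tac_type` set and a `rule_trace`
#'   character vector attached.
#' @export
classify_tac <- function(tac, early_peak_cutoff_min = 20,
                         plateau_tolerance_frac = 0.10) {
  stopifnot(inherits(tac, "fet_tac"))
  if (length(tac$times_min) < 3L)
    stop("TAC classification needs at least 3 frames")
  peak <- max(tac$mean_suv)
  ttp <- tac$times_min[which.max(tac$mean_suv)]
  final <- tac$mean_suv[length(tac$mean_suv)]
  decline <- (peak - final) / peak
  trace <- sprintf("TTP %.2f min; post-peak decline %.4f (cutoff %.1f min, tolerance %.2f)",
                   ttp, decline, early_peak_cutoff_min,
                   plateau_tolerance_frac)
  if (ttp == tac$times_min[length(tac$times_min)]) {
    type <- "I"
    trace <- c(trace, "peak at final frame -> increasing curve -> type I")
  } else if (decline <= plateau_tolerance_frac) {
    type <- "II"
    trace <- c(trace, "interior peak, descent within tolerance -> plateau -> type II")
  } else if (ttp <= early_peak_cutoff_min) {
    type <- "III"
    trace <- c(trace, "early peak, sustained descent -> type III")
  } else {
    type <- "III"
    trace <- c(trace,
               "late peak but descent beyond tolerance -> washout -> type III")
  }
  tac$tac_type <- type
  attr(tac, "rule_trace") <- trace
  tac
}

#' Default clinical interpretation rule table
#'
#' A transparent, configurable stand-in for the combination of
#' quantitative metrics with qualitative reading: submissions with
#' `TBR_max <= 2.3` are read as treatment-predominant change; above that
#' threshold the TAC type decides between equivocal (type I) and
#' consistent with tumour progression (types II/III).  Rows are matched
#' in order; the first matching row fires.
#'
#' @return A data.frame with columns `name`, `tbr_gt` (exclusive lower
#'   TBR_max bound), `tbr_le` (inclusive upper bound), `tac_types`
#'   (comma-separated list or `"*"`), `category`.
#' @export
default_rule_table <- function() {
  data.frame(
    name = c("low_uptake", "high_uptake_tac_I", "high_uptake_tac_II_III"),
    tbr_gt = c(-Inf, 2.3, 2.3),
    tbr_le = c(2.3, Inf, Inf),
    tac_types = c("*", "I", "II,III"),
    category = c("treatment_predominant_change", "equivocal",
                 "tumour_progression"),
    stringsAsFactors = FALSE)
}

#' Interpret a follow-up case from TBR_max and TAC type
#'
#' Pure function of its inputs: evaluates the rule table rows in order
#' and returns the category of the first matching rule together with a
#' trace of every rule evaluated.
#'
#' @param tbr_max maximum tumour-to-background ratio of the case.
#' @param tac_type `"I"`, `"II"` or `"III"`.
#' @param rules rule table as returned by [default_rule_table()].
#' @return An object of class `fet_interpretation`: `category`,
#'   `tbr_max`, `tac_type`, `rule_trace`.
#' @examples
#' interpret_case(4.67, "III")$category  # tumour_progression
#' interpret_case(2.3, "III")$category   # boundary: not > 2.3
#' @export
interpret_case <- function(tbr_max, tac_type, rules = default_rule_table()) {
  stopifnot(is.numeric(tbr_max), length(tbr_max) == 1L)
  tac_type <- match.arg(as.character(tac_type), c("I", "II", "III"))
  req <- c("name", "tbr_gt", "tbr_le", "tac_types", "category")
  if (!all(req %in% names(rules)))
    stop("rule table must have columns ", paste(req, collapse = ", "))
  trace <- character()
  category <- NA_character_
  for (i in seq_len(nrow(rules))) {
    row <- rules[i, ]
    tac_ok <- row$tac_types == "*" ||
      tac_type %in% strsplit(row$tac_types, ",")[[1]]
    hit <- tbr_max > row$tbr_gt && tbr_max <= row$tbr_le && tac_ok
    trace <- c(trace, sprintf("rule '%s': %s", row$name,
                              if (hit) "fired" else "not matched"))
    if (hit) { category <- row$category; break }
  }
  if (is.na(category))
    stop("no rule matched (tbr_max = ", tbr_max, ", tac_type = ",
         tac_type, "); the rule table must be exhaustive")
  structure(list(category = category, tbr_max = tbr_max,
                 tac_type = tac_type, rule_trace = trace),
            class = "fet_interpretation")
}

#' @export
print.fet_interpretation <- function(x, ...) {
  cat(sprintf("Interpretation: %s (TBR_max %.3f, TAC type %s)\n",
              x$category, x$tbr_max, x$tac_type))
  for (t in x$rule_trace) cat("  ", t, "\n", sep = "")
  invisible(x)
}
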