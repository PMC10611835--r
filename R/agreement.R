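#' Coefficient of variation in percent
#'
#' `100 * sd(x) / mean(x)`, with the sample (n - 1) standard deviation.
#' Used to compare the spread of a measurement (volume, TBR) across
#' readers between cases with different means.
#'
#' @param values numeric vector of at least two values with non-zero
#'   mean.
#' @return The coefficient of variation, in percent.
#' @examples
#' cov_pct(c(1, 3))  # sd sqrt(2), mean 2 -> 70.71
#' @export
cov_pct <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need at least two values")
  if (anyNA(values)) stop("values must not contain NA")
  m <- mean(values)
  if (m == 0) stop("mean is zero; CoV undefined")
  100 * stats::sd(values) / m
}

#' Overlap coefficients between two binary masks
#'
#' `dsc()` is the Dice similarity coefficient `2|A n B| / (|A| + |B|)`;
#' `jaccard()` is `|A n B| / |A u B|`; `dsc_from_jaccard()` converts a
#' Jaccard index J to the equivalent Dice value `2J / (1 + J)`.  Two
#' empty masks are defined to agree perfectly (value 1, with a warning).
#'
#' @param a,b [voi_mask()]s on the same grid (or logical arrays of equal
#'   shape).
#' @return A value in `[0, 1]`.
#' @examples
#' dsc_from_jaccard(0.42)  # 0.5915...
#' @export
dsc <- function(a, b) {
  ab <- mask_pair_arrays(a, b)
  inter <- sum(ab$a & ab$b)
  size <- sum(ab$a) + sum(ab$b)
  if (size == 0L) {
    warning("both masks are empty; DSC defined as 1")
    return(1)
  }
  2 * inter / size
}

#' @rdname dsc
#' @export
jaccard <- function(a, b) {
  ab <- mask_pair_arrays(a, b)
  uni <- sum(ab$a | ab$b)
  if (uni == 0L) {
    warning("both masks are empty; Jaccard defined as 1")
    return(1)
  }
  sum(ab$a & ab$b) / uni
}

#' @rdname dsc
#' @param j Jaccard index in `[0, 1]`.
#' @export
dsc_from_jaccard <- function(j) {
  if (any(j < 0 | j > 1)) stop("Jaccard index must be in [0, 1]")
  2 * j / (1 + j)
}

mask_pair_arrays <- function(a, b) {
  if (inherits(a, "voi_mask") && inherits(b, "voi_mask")) {
    check_same_grid(a, b)
    list(a = a$data, b = b$data)
  } else {
    da <- if (inherits(a, "voi_mask")) a$data else a
    db <- if (inherits(b, "voi_mask")) b$data else b
    if (!identical(dim(da), dim(db))) stop("mask shapes differ")
    list(a = da, b = db)
  }
}

# surface voxels of a mask: member voxels with at least one 6-neighbour
# outside the mask (voxels on the grid boundary count as surface);
# returned as world-mm coordinates of voxel centres
surface_points_mm <- function(m) {
  mask <- m$data
  d <- dim(mask)
  # neighbour-in-mask tests via index shifting along each axis
  nb <- function(off) {
    out <- array(FALSE, d)
    sx <- max(1, 1 - off[1]):min(d[1], d[1] - off[1])
    sy <- max(1, 1 - off[2]):min(d[2], d[2] - off[2])
    sz <- max(1, 1 - off[3]):min(d[3], d[3] - off[3])
    out[sx, sy, sz] <- mask[sx + off[1], sy + off[2], sz + off[3]]
    out
  }
  all_nb <- array(TRUE, d)
  for (off in list(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                   c(0, 0, -1), c(0, 0, 1)))
    all_nb <- all_nb & nb(off)
  surf <- mask & !all_nb
  idx <- which(surf, arr.ind = TRUE)
  voxel_centers_mm(idx, m$spacing_mm, m$origin_mm)
}

# for each row of a (n x 3), distance to the nearest row of b (m x 3);
# chunked so the cross-distance matrix stays within memory.  The
# |a|^2 + |b|^2 - 2ab expansion only screens candidates (it loses
# precision by cancellation); the returned distance is recomputed
# exactly from coordinate differences for the candidate set.
nearest_dists <- function(a, b, chunk = 2000L) {
  nb2 <- rowSums(b^2)
  out <- numeric(nrow(a))
  for (s in seq(1, nrow(a), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(a))
    blk <- a[s:e, , drop = FALSE]
    d2 <- outer(rowSums(blk^2), nb2, "+") - 2 * blk %*% t(b)
    rmin <- apply(d2, 1, min)
    for (r in seq_len(nrow(blk))) {
      cand <- which(d2[r, ] <= rmin[r] + 1e-6 * (1 + abs(rmin[r])))
      diffs <- sweep(b[cand, , drop = FALSE], 2, blk[r, ], "-")
      out[s + r - 1L] <- sqrt(min(rowSums(diffs^2)))
    }
  }
  out
}

#' Surface distances between two masks
#'
#' Surfaces are the border voxels of each mask (member voxels with a
#' 6-neighbour outside), taken at their voxel-centre world coordinates.
#' `hausdorff_mm()` is the exact symmetric Hausdorff distance: the
#' larger of the two directed maximum nearest-surface distances.  A
#' percentile variant (e.g. `percentile = 95`) is available for
#' outlier-robust reporting.  `masd_mm()` is the mean absolute surface
#' distance: the average of the two directed mean nearest-surface
#' distances.
#'
#' @param a,b non-empty [voi_mask()]s on the same grid.
#' @param percentile percentile of the directed nearest-distance
#'   distributions used by `hausdorff_mm()`; 100 (default) gives the
#'   exact Hausdorff distance.
#' @return Distance in mm.
#' @export
hausdorff_mm <- function(a, b, percentile = 100) {
  pts <- surface_pair(a, b)
  dab <- nearest_dists(pts$a, pts$b)
  dba <- nearest_dists(pts$b, pts$a)
  if (percentile >= 100) max(max(dab), max(dba))
  else max(stats::quantile(dab, percentile / 100, names = FALSE),
           stats::quantile(dba, percentile / 100, names = FALSE))
}

#' @rdname hausdorff_mm
#' @export
masd_mm <- function(a, b) {
  pts <- surface_pair(a, b)
  (mean(nearest_dists(pts$a, pts$b)) +
     mean(nearest_dists(pts$b, pts$a))) / 2
}

surface_pair <- function(a, b) {
  stopifnot(inherits(a, "voi_mask"), inherits(b, "voi_mask"))
  check_same_grid(a, b)
  if (!any(a$data) || !any(b$data))
    stop("surface distance undefined for an empty mask")
  list(a = surface_points_mm(a), b = surface_points_mm(b))
}

#' Ratings matrix for reliability analysis
#'
#' A complete n-subjects by k-raters grid of a scalar measurement (for
#' example BTV volume in cm^3), the input of [anova_mean_squares()] and
#' [icc21()].
#'
#' @param values numeric matrix, subjects in rows, raters in columns; no
#'   missing cells.
#' @param subject_ids,rater_ids optional dimension names.
#' @param measure_name label of the measurement.
#' @return An object of class `ratings_matrix`.
#' @export
ratings_matrix <- function(values, subject_ids = NULL, rater_ids = NULL,
                           measure_name = "measurement") {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("'values' must be numeric")
  if (anyNA(values))
    stop("incomplete ratings: the design must be complete (no missing cells)")
  if (nrow(values) < 2L || ncol(values) < 2L)
    stop("need at least 2 subjects and 2 raters")
  if (is.null(subject_ids)) subject_ids <- rownames(values)
  if (is.null(subject_ids)) subject_ids <- paste0("S", seq_len(nrow(values)))
  if (is.null(rater_ids)) rater_ids <- colnames(values)
  if (is.null(rater_ids)) rater_ids <- paste0("R", seq_len(ncol(values)))
  dimnames(values) <- list(subject_ids, rater_ids)
  structure(list(values = values, subject_ids = subject_ids,
                 rater_ids = rater_ids, measure_name = measure_name),
            class = "ratings_matrix")
}

#' Two-way ANOVA mean squares of a ratings matrix
#'
#' Decomposes the ratings into between-subject (rows), between-rater
#' (columns) and residual mean squares via [stats::aov()], the
#' ingredients of the ICC(2,1) formula.
#'
#' @param m a [ratings_matrix()] or a plain numeric matrix.
#' @return A list `ms_rows`, `ms_cols`, `ms_error`, `n`, `k` with the
#'   usual degrees of freedom `n - 1`, `k - 1`, `(n - 1)(k - 1)`.
#' @export
anova_mean_squares <- function(m) {
  x <- if (inherits(m, "ratings_matrix")) m$values else as.matrix(m)
  if (anyNA(x)) stop("incomplete ratings matrix")
  n <- nrow(x); k <- ncol(x)
  if (n < 2L || k < 2L) stop("need at least 2 subjects and 2 raters")
  df <- data.frame(value = as.vector(x),
                   subject = factor(rep(seq_len(n), times = k)),
                   rater = factor(rep(seq_len(k), each = n)))
  fit <- stats::aov(value ~ subject + rater, data = df)
  tab <- summary(fit)[[1]]
  ms <- tab[["Mean Sq"]]
  names(ms) <- trimws(rownames(tab))
  list(ms_rows = unname(ms["subject"]), ms_cols = unname(ms["rater"]),
       ms_error = unname(ms["Residuals"]), n = n, k = k)
}

#' ICC(2,1): two-way absolute-agreement single-rater intraclass
#' correlation
#'
#' Computes the intraclass correlation for a two-way model with absolute
#' agreement and a single rater/measurement,
#' \deqn{ICC(2,1) = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E +
#'   \frac{k}{n}(MS_C - MS_E)},}
#' where \eqn{MS_R}, \eqn{MS_C} and \eqn{MS_E} are the between-subject,
#' between-rater and residual mean squares.  The 95% confidence interval
#' uses the F-distribution method with the Satterthwaite approximation
#' to the denominator degrees of freedom (McGraw & Wong's procedure for
#' this ICC form), and the interval is summarised into a reliability
#' label by where its endpoints fall among the conventional bands
#' (below 0.5 poor, 0.5-0.75 moderate, 0.75-0.9 good, above 0.9
#' excellent), e.g. a CI spanning 0.63-0.97 reads "moderate to
#' excellent".
#'
#' @param m a [ratings_matrix()] or numeric matrix (subjects x raters).
#' @param conf_level confidence level, default 0.95.
#' @return An object of class `fet_icc`: `estimate`, `ci_low`,
#'   `ci_high`, `interpretation`, `mean_squares`, `n`, `k`,
#'   `conf_level`.
#' @export
icc21 <- function(m, conf_level = 0.95) {
  ms <- anova_mean_squares(m)
  n <- ms$n; k <- ms$k
  msr <- ms$ms_rows; msc <- ms$ms_cols; mse <- ms$ms_error
  total_var <- stats::var(as.vector(
    if (inherits(m, "ratings_matrix")) m$values else as.matrix(m)))
  if (total_var == 0) {
    warning("zero total variance; ICC degenerate, reported as 1")
    return(structure(list(estimate = 1, ci_low = 1, ci_high = 1,
                          interpretation = "excellent",
                          mean_squares = ms, n = n, k = k,
                          conf_level = conf_level),
                     class = "fet_icc"))
  }
  est <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  alpha <- 1 - conf_level
  if (mse == 0) {
    ci <- c(est, est)
  } else {
    fj <- msc / mse
    a <- k * est * fj + n * (1 + (k - 1) * est) - k * est
    v <- ((k - 1) * (n - 1) * a^2) /
      ((n - 1) * k^2 * est^2 * fj^2 + (n * (1 + (k - 1) * est) -
                                         k * est)^2)
    f_u <- stats::qf(1 - alpha / 2, n - 1, v)
    f_l <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - f_u * mse) /
      (f_u * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (f_l * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_l * msr)
    ci <- c(lo, hi)
  }
  structure(list(estimate = est, ci_low = ci[1], ci_high = ci[2],
                 interpretation = koo_li_label(ci[1], ci[2]),
                 mean_squares = ms, n = n, k = k,
                 conf_level = conf_level),
            class = "fet_icc")
}

koo_li_band <- function(x) {
  if (x < 0.5) "poor" else if (x < 0.75) "moderate"
  else if (x < 0.9) "good" else "excellent"
}

koo_li_label <- function(ci_low, ci_high) {
  lo <- koo_li_band(ci_low); hi <- koo_li_band(ci_high)
  if (lo == hi) lo else paste(lo, "to", hi)
}

#' @export
print.fet_icc <- function(x, ...) {
  cat(sprintf("ICC(2,1) = %.3f (%d%% CI %.3f-%.3f), n = %d subjects, k = %d raters\n",
              x$estimate, round(100 * x$conf_level), x$ci_low, x$ci_high,
              x$n, x$k))
  cat("  reliability:", x$interpretation, "\n")
  invisible(x)
}

#' Median and range summary
#'
#' Reports the median (mean of the two central order statistics for an
#' even count) and the (min, max) range of per-case values, optionally
#' rounded half-up to a fixed number of decimals as in tabular
#' reporting.
#'
#' @param values numeric vector (e.g. per-case CoVs).
#' @param digits round half-up to this many decimals; `NULL` (default)
#'   leaves values unrounded.
#' @return A list `median`, `range` (length-2).
#' @examples
#' summarize_values(c(23.83, 12.00, 23.87, 19.01, 30.10, 19.23),
#'                  digits = 2)
#' @export
summarize_values <- function(values, digits = NULL) {
  values <- as.numeric(values)
  if (length(values) < 1L || anyNA(values)) stop("invalid values")
  out <- list(median = stats::median(values), range = range(values))
  if (!is.null(digits)) {
    out$median <- round_half_up(out$median, digits)
    out$range <- round_half_up(out$range, digits)
  }
  out
}

#' Pairwise agreement table across rater masks
#'
#' For every case, computes DSC, Jaccard, Hausdorff distance and MASD
#' for each unordered pair of rater masks (`k(k-1)/2` rows per case).
#'
#' @param cases named list; each element is a list of [voi_mask()]s, one
#'   per rater, all on a common grid.
#' @param hd_percentile passed to [hausdorff_mm()].
#' @return A data.frame with columns `case_id`, `rater_a`, `rater_b`,
#'   `dsc`, `jaccard`, `hd_mm`, `masd_mm` and class
#'   `pairwise_agreement`.
#' @export
build_pairwise_table <- function(cases, hd_percentile = 100) {
  stopifnot(is.list(cases), length(cases) >= 1L)
  if (is.null(names(cases)) || any(names(cases) == ""))
    names(cases) <- paste0("case", seq_along(cases))
  rows <- list()
  for (cid in names(cases)) {
    masks <- cases[[cid]]
    k <- length(masks)
    if (k < 2L) stop("case '", cid, "' has fewer than 2 rater masks")
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      rows[[length(rows) + 1L]] <- data.frame(
        case_id = cid, rater_a = i, rater_b = j,
        dsc = dsc(masks[[i]], masks[[j]]),
        jaccard = jaccard(masks[[i]], masks[[j]]),
        hd_mm = hausdorff_mm(masks[[i]], masks[[j]], hd_percentile),
        masd_mm = masd_mm(masks[[i]], masks[[j]]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("pairwise_agreement", class(out))
  out
}

#' Per-case summary of a pairwise agreement table
#'
#' @param table a `pairwise_agreement` data.frame from
#'   [build_pairwise_table()].
#' @return A data.frame with one row per case and metric: mean, sample
#'   SD and CoV (%).
#' @export
summarize_pairwise <- function(table) {
  metrics <- c("dsc", "jaccard", "hd_mm", "masd_mm")
  out <- list()
  for (cid in unique(table$case_id)) {
    sub <- table[table$case_id == cid, ]
    for (met in metrics) {
      v <- sub[[met]]
      out[[length(out) + 1L]] <- data.frame(
        case_id = cid, metric = met, mean = mean(v),
        sd = stats::sd(v),
        cov_pct = if (mean(v) != 0) 100 * stats::sd(v) / mean(v)
                  else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
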