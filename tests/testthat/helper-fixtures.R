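# Shared fixtures and independent brute-force oracles.  Oracles are
# deliberately naive (triple loops, direct set arithmetic) and share no
# code with the package implementation.

test_spacing <- c(2.03135, 2.03135, 3)

# small, fast phantom spec for pipeline tests; unless a test asks
# otherwise the scalp confounder is mirrored away from the lesion so
# that exact-recovery checks are not entangled with confounder removal
small_spec <- function(...) {
  args <- utils::modifyList(
    list(grid_shape = c(48, 48, 24), lesion_volume_cm3 = 10,
         psf_fwhm_mm = 0, noise_sd_suv = 0, gm_wm_contrast = 0,
         lesion_tbr = 2.0, seed = 1L),
    list(...))
  s <- do.call(phantom_spec, args)
  if (is.null(args$confounder_center_mm)) {
    args$confounder_center_mm <- 2 * s$brain_center_mm -
      s$confounder_center_mm
    s <- do.call(phantom_spec, args)
  }
  s
}

# random smooth binary blob on a small grid (nonempty by construction)
random_blob_mask <- function(dim3 = c(9, 10, 8), spacing = test_spacing,
                             n_seeds = 2) {
  ctr <- matrix(runif(n_seeds * 3), ncol = 3) %*% diag(dim3 * spacing)
  rad <- runif(n_seeds, 0.15, 0.35) * min(dim3 * spacing)
  arr <- array(FALSE, dim3)
  idx <- as.matrix(expand.grid(seq_len(dim3[1]), seq_len(dim3[2]),
                               seq_len(dim3[3])))
  pts <- sweep(sweep(idx - 0.5, 2, spacing, "*"), 2, c(0, 0, 0), "+")
  for (s in seq_len(n_seeds)) {
    d2 <- rowSums(sweep(pts, 2, ctr[s, ], "-")^2)
    arr[idx[d2 <= rad[s]^2, , drop = FALSE]] <- TRUE
  }
  if (!any(arr)) arr[ceiling(dim3[1] / 2), ceiling(dim3[2] / 2),
                     ceiling(dim3[3] / 2)] <- TRUE
  voi_mask(arr, spacing, role = "btv", allow_empty = FALSE)
}

# --- naive oracles ------------------------------------------------------

oracle_dsc <- function(a, b) {
  A <- which(a$data); B <- which(b$data)
  2 * length(intersect(A, B)) / (length(A) + length(B))
}

oracle_jaccard <- function(a, b) {
  A <- which(a$data); B <- which(b$data)
  length(intersect(A, B)) / length(union(A, B))
}

# surface voxels by explicit 6-neighbour scan, voxel-centre world coords
oracle_surface <- function(m) {
  d <- dim(m$data)
  pts <- NULL
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!m$data[i, j, k]) next
    border <- FALSE
    for (off in list(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                     c(0, 0, -1), c(0, 0, 1))) {
      p <- c(i, j, k) + off
      if (any(p < 1) || any(p > d) || !m$data[p[1], p[2], p[3]]) {
        border <- TRUE; break
      }
    }
    if (border)
      pts <- rbind(pts, m$origin_mm + (c(i, j, k) - 0.5) * m$spacing_mm)
  }
  pts
}

# exhaustive all-pairs surface distances
oracle_hd_masd <- function(a, b) {
  A <- oracle_surface(a); B <- oracle_surface(b)
  dmat <- matrix(0, nrow(A), nrow(B))
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B)))
    dmat[i, j] <- sqrt(sum((A[i, ] - B[j, ])^2))
  dab <- apply(dmat, 1, min)
  dba <- apply(dmat, 2, min)
  list(hd = max(max(dab), max(dba)),
       masd = (mean(dab) + mean(dba)) / 2)
}

# ICC(2,1) from first-principles sums of squares (no aov)
oracle_icc21 <- function(x) {
  n <- nrow(x); k <- ncol(x)
  g <- mean(x)
  msr <- k * sum((rowMeans(x) - g)^2) / (n - 1)
  msc <- n * sum((colMeans(x) - g)^2) / (k - 1)
  sse <- sum((x - g)^2) - k * sum((rowMeans(x) - g)^2) -
    n * sum((colMeans(x) - g)^2)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# a numeric vector with exact sample mean m and sample sd s
vector_with_moments <- function(m, s, n = 20) {
  set.seed(42)
  z <- rnorm(n)
  z <- (z - mean(z)) / sd(z)
  m + s * z
}

# direct construction of a TAC object for classifier unit tests
make_tac <- function(times, values) {
  structure(list(times_min = times, mean_suv = values,
                 ttp_min = times[which.max(values)],
                 tac_type = NA_character_),
            class = "fet_tac")
}

# printed per-case agreement table of the credentialing benchmark
# (mean, SD, CoV per metric for six cases)
table2 <- list(
  volume = data.frame(
    mean = c(34.13, 64.69, 17.99, 44.17, 68.32, 14.78),
    sd = c(8.13, 7.76, 4.29, 8.40, 20.56, 2.84),
    cov = c(23.83, 12.00, 23.87, 19.01, 30.10, 19.23)),
  tbr_max = data.frame(
    mean = c(4.54, 5.86, 3.15, 3.15, 4.67, 5.43),
    sd = c(0.29, 0.29, 0.21, 0.17, 0.25, 0.35),
    cov = c(6.30, 5.01, 6.68, 5.47, 5.40, 6.36)),
  tbr_mean = data.frame(
    mean = c(2.15, 2.33, 2.04, 2.03, 2.32, 2.56),
    sd = c(0.11, 0.08, 0.10, 0.13, 0.12, 0.09),
    cov = c(5.29, 3.38, 4.73, 6.34, 5.33, 3.37)),
  dsc = data.frame(
    mean = c(0.85, 0.88, 0.85, 0.85, 0.77, 0.84),
    sd = c(0.08, 0.05, 0.09, 0.08, 0.09, 0.08),
    cov = c(9.72, 5.36, 10.29, 9.03, 11.64, 9.70)),
  hd = data.frame(
    mean = c(15.14, 12.78, 10.15, 14.59, 23.37, 18.09),
    sd = c(7.84, 2.74, 5.65, 6.25, 9.40, 8.89),
    cov = c(51.76, 21.45, 55.69, 42.81, 40.22, 49.14)),
  masd = data.frame(
    mean = c(1.24, 0.77, 1.09, 1.10, 3.41, 1.20),
    sd = c(0.82, 0.34, 0.78, 0.68, 1.95, 0.77),
    cov = c(65.62, 44.55, 71.21, 62.01, 57.32, 63.89)))
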