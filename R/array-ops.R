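# Internal array utilities: separable Gaussian smoothing, 3D connected
# components and metric dilation/erosion.  These operate on plain arrays;
# the public API wraps them in pet_volume / voi_mask containers.

gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  k / sum(k)
}

# 1D convolution down the first axis of a 3D array, zero-padded edges
conv_axis1 <- function(a, k) {
  if (length(k) == 1L) return(a * k)
  d <- dim(a)
  r <- (length(k) - 1L) / 2L
  m <- matrix(a, nrow = d[1])
  pad <- matrix(0, r, ncol(m))
  m <- rbind(pad, m, pad)
  out <- stats::filter(m, k, method = "convolution", sides = 2)
  array(out[(r + 1):(r + d[1]), ], d)
}

# separable Gaussian blur; fwhm_mm scalar, sigma set per axis from spacing
gaussian_blur_3d <- function(a, fwhm_mm, spacing_mm) {
  if (fwhm_mm <= 0) return(a)
  sigma_vox <- (fwhm_mm / (2 * sqrt(2 * log(2)))) / spacing_mm
  for (ax in 1:3) {
    k <- gaussian_kernel_1d(sigma_vox[ax])
    perm <- switch(ax, c(1, 2, 3), c(2, 1, 3), c(3, 2, 1))
    a <- aperm(conv_axis1(aperm(a, perm), k), order(perm))
  }
  a
}

# offsets of the 26- or 6-neighbourhood as an m x 3 integer matrix
neighbour_offsets <- function(connectivity = 26L) {
  if (connectivity == 6L) {
    rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
          c(0, 0, -1), c(0, 0, 1))
  } else if (connectivity == 26L) {
    g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    dimnames(g) <- NULL
    g[rowSums(abs(g)) > 0, , drop = FALSE]
  } else stop("connectivity must be 6 or 26")
}

# label connected components of a logical 3D array; returns an integer
# array (0 = background, 1..n = components, labelled in order of their
# smallest linear voxel index)
label_components <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  lab <- array(0L, d)
  idx <- which(mask)
  if (length(idx) == 0L) return(lab)
  coord <- which(mask, arr.ind = TRUE)
  offs <- neighbour_offsets(connectivity)
  vox_id <- seq_along(idx)            # ids within the mask voxel list
  pos <- array(0L, d); pos[idx] <- vox_id
  edges <- NULL
  for (r in seq_len(nrow(offs))) {
    sh <- sweep(coord, 2, offs[r, ], "+")
    ok <- sh[, 1] >= 1 & sh[, 1] <= d[1] &
          sh[, 2] >= 1 & sh[, 2] <= d[2] &
          sh[, 3] >= 1 & sh[, 3] <= d[3]
    if (!any(ok)) next
    lin <- sh[ok, 1] + (sh[ok, 2] - 1L) * d[1] +
      (sh[ok, 3] - 1L) * d[1] * d[2]
    nb <- pos[lin]
    hit <- nb > 0L
    if (any(hit))
      edges <- rbind(edges, cbind(vox_id[ok][hit], nb[hit]))
  }
  if (is.null(edges)) {
    comp <- seq_along(idx)            # all isolated voxels
  } else {
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
    comp <- igraph::components(g)$membership
  }
  # relabel so that component numbering follows first appearance
  first <- tapply(seq_along(idx), comp, min)
  relab <- integer(max(comp))
  relab[as.integer(names(sort(first)))] <- seq_along(first)
  lab[idx] <- relab[comp]
  lab
}

# metric dilation (grow_mm > 0) or erosion (grow_mm < 0) of a logical
# array with a spherical structuring element in world mm
mask_grow <- function(mask, grow_mm, spacing_mm) {
  if (grow_mm == 0 || !any(mask)) return(mask)
  r_vox <- ceiling(abs(grow_mm) / spacing_mm)
  offs <- as.matrix(expand.grid(-r_vox[1]:r_vox[1],
                                -r_vox[2]:r_vox[2],
                                -r_vox[3]:r_vox[3]))
  dist <- sqrt(colSums((t(offs) * spacing_mm)^2))
  offs <- offs[dist <= abs(grow_mm), , drop = FALSE]
  d <- dim(mask)
  target <- if (grow_mm > 0) mask else !mask
  acc <- array(FALSE, d)
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    src_rng <- function(ax) max(1, 1 - o[ax]):min(d[ax], d[ax] - o[ax])
    sx <- src_rng(1); sy <- src_rng(2); sz <- src_rng(3)
    part <- array(FALSE, d)
    part[sx + o[1], sy + o[2], sz + o[3]] <- target[sx, sy, sz]
    acc <- acc | part
  }
  if (grow_mm > 0) acc else mask & !acc
}
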