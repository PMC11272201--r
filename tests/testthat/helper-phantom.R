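# Small phantom/ROI fixtures shared across tests. Everything is generated in
# code; grids are kept small so single tests run in well under a second.

# compact bilateral ROI set on a 40 x 40 x 13 grid (2 mm voxels): same layout
# as the published presets (projection/association pairs mirrored in x),
# scaled down for speed
mini_roi_set <- function() {
  df <- data.frame(
    roi = c("projection", "association", "projection", "association"),
    hemisphere = c("left", "left", "right", "right"),
    x = c(26, 32, 14, 8), y = rep(20, 4), z = rep(6, 4),
    diameter = 5, diameter_unit = "voxel",
    stringsAsFactors = FALSE)
  as_roi_set(df, preset = "mini", grid_dims = c(40L, 40L, 13L),
             voxel_size = c(2, 2, 2))
}

mini_slabs <- function(roi = mini_roi_set(), half_width = 4) {
  lapply(seq_len(nrow(roi)), function(i) {
    ctr <- c(roi$x[i], roi$y[i], roi$z[i])
    list(type = roi$roi[i], box = rbind(ctr - half_width, ctr + half_width))
  })
}

mini_phantom_spec <- function(gain = 1.5, snr = Inf, seed = 1L, ...) {
  phantom_spec(grid_dims = c(40L, 40L, 13L), voxel_size = 2,
               slabs = mini_slabs(), gain = gain, snr = snr, seed = seed,
               preset = "custom", ...)
}

# analytic tensor_volume from an nvox x 6 element matrix (unit test entry
# into simulate_dwi / eigen paths without a phantom spec)
tensor_field_from_matrix <- function(D, dims, voxel_size = c(2, 2, 2), s0 = 1000) {
  stopifnot(nrow(D) == prod(dims))
  structure(list(tensors = array(D, c(dims, 6L)),
                 s0 = array(s0, dims),
                 fit_mask = array(TRUE, dims),
                 clamped = array(FALSE, dims),
                 method = "analytic",
                 voxel_size = voxel_size, origin = c(0L, 0L, 0L),
                 affine = diag(c(voxel_size, 1))),
            class = "tensor_volume")
}

# random symmetric positive-definite tensors with diffusivity-scale
# eigenvalues, as an n x 6 element matrix plus the full 3x3 list
random_pd_tensors <- function(n, seed = 42) {
  withr::with_seed(seed, {
    lam <- matrix(runif(3 * n, 0.2e-3, 2.2e-3), n)
    D <- matrix(0, n, 6)
    full <- vector("list", n)
    for (i in seq_len(n)) {
      Q <- qr.Q(qr(matrix(rnorm(9), 3)))
      T3 <- Q %*% diag(lam[i, ]) %*% t(Q)
      full[[i]] <- T3
      D[i, ] <- c(T3[1, 1], T3[2, 2], T3[3, 3], T3[1, 2], T3[1, 3], T3[2, 3])
    }
    list(elements = D, full = full)
  })
}

# brute-force sphere voxel count: enumerate every voxel, no vectorized mask
brute_force_sphere_count <- function(center, radius_mm, dims, voxel_size) {
  count <- 0L
  for (i in 0:(dims[1] - 1)) for (j in 0:(dims[2] - 1)) for (k in 0:(dims[3] - 1)) {
    d2 <- sum((((c(i, j, k)) - center) * voxel_size)^2)
    if (d2 <= radius_mm^2 + 1e-12) count <- count + 1L
  }
  count
}

# brute-force two-way mean squares by explicit loops (independent of
# anova_decompose's vectorized path)
brute_force_ms <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- sum(m) / (n * k)
  rmean <- sapply(seq_len(n), function(i) sum(m[i, ]) / k)
  cmean <- sapply(seq_len(k), function(j) sum(m[, j]) / n)
  ss_r <- 0; ss_c <- 0; ss_e <- 0
  for (i in seq_len(n)) ss_r <- ss_r + k * (rmean[i] - grand)^2
  for (j in seq_len(k)) ss_c <- ss_c + n * (cmean[j] - grand)^2
  for (i in seq_len(n)) for (j in seq_len(k))
    ss_e <- ss_e + (m[i, j] - rmean[i] - cmean[j] + grand)^2
  list(ms_r = ss_r / (n - 1), ms_c = ss_c / (k - 1),
       ms_e = ss_e / ((n - 1) * (k - 1)))
}
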