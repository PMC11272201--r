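test_that("sphere masks match brute-force voxel enumeration", {
  # diameter of one voxel: exactly the center voxel
  m <- sphere_mask(c(5, 5, 5), 1, "voxel", c(11, 11, 11), c(2, 2, 2))
  expect_equal(sum(m), 1L)
  expect_true(m[6, 6, 6])

  # 5 mm diameter on a 1 mm grid: 81 voxels (integer offsets with
  # dx^2 + dy^2 + dz^2 <= 2.5^2)
  m <- sphere_mask(c(8, 8, 8), 5, "mm", c(17, 17, 17), c(1, 1, 1))
  expect_equal(sum(m), 81L)
  expect_equal(sum(m),
               brute_force_sphere_count(c(8, 8, 8), 2.5, c(17, 17, 17), c(1, 1, 1)))

  # 12-voxel diameter on the DSI template grid
  roi <- alps_roi_preset("DSI_DEFAULT")
  m <- sphere_mask(c(roi$x[1], roi$y[1], roi$z[1]), 12, "voxel",
                   attr(roi, "grid_dims"), attr(roi, "voxel_size"))
  expect_equal(sum(m),
               brute_force_sphere_count(c(roi$x[1], roi$y[1], roi$z[1]),
                                        6 * 2, c(78, 78, 78), c(2, 2, 2)))

  # sphere exceeding the grid is an error
  expect_error(sphere_mask(c(1, 5, 5), 12, "voxel", c(11, 11, 11), c(2, 2, 2)),
               class = "dtialps_roi_error")
})

test_that("preset centers and geometry match the published coordinates", {
  dsi <- alps_roi_preset("DSI_DEFAULT")
  expect_equal(dsi[dsi$roi == "projection", c("x", "y", "z")],
               data.frame(x = c(53, 25), y = c(47, 47), z = c(40, 40)),
               ignore_attr = TRUE)
  expect_equal(dsi[dsi$roi == "association", c("x", "y", "z")],
               data.frame(x = c(59, 19), y = c(47, 47), z = c(40, 40)),
               ignore_attr = TRUE)
  expect_equal(unique(dsi$diameter), 12)
  expect_equal(unique(dsi$diameter_unit), "voxel")

  fsl <- alps_roi_preset("FSL_DEFAULT")
  expect_setequal(fsl$x, c(116, 128, 64, 51))
  expect_equal(unique(fsl$y), 110)
  expect_equal(unique(fsl$z), 99)
  expect_equal(unique(fsl$diameter), 5)
  expect_equal(unique(fsl$diameter_unit), "mm")

  # 1-based interpretation shifts every center down by one voxel
  fsl1 <- alps_roi_preset("FSL_DEFAULT", index_base = 1)
  expect_equal(fsl1$x, fsl$x - 1)

  # an incomplete set is rejected
  expect_error(as_roi_set(fsl[1:3, ]), class = "dtialps_roi_error")
})

test_that("ROI means reduce to map values on constant and phantom fields", {
  roi <- mini_roi_set()
  dims <- c(40L, 40L, 13L)
  # constant Dxx map: means equal the constant regardless of placement
  maps <- scalar_maps(tensor_field_from_matrix(
    matrix(rep(c(1.2e-3, 0.6e-3, 0.9e-3, 0, 0, 0), each = prod(dims)), ncol = 6),
    dims))
  means <- extract_roi_means(maps, roi)
  expect_equal(means$dxx_proj, rep(1.2e-3, 2))
  expect_equal(means$dxx_assoc, rep(1.2e-3, 2))
  expect_equal(means$dyy_proj, rep(0.6e-3, 2))
  expect_equal(means$dzz_assoc, rep(0.9e-3, 2))

  # noise-free phantom: ROI means equal the slab prescriptions exactly
  field <- build_tensor_field(mini_phantom_spec(gain = 1.5), roi)
  pm <- extract_roi_means(scalar_maps(field), roi)
  expect_equal(pm$dxx_proj, rep(0.6e-3, 2), tolerance = 1e-12)
  expect_equal(pm$dxx_assoc, rep(0.6e-3, 2), tolerance = 1e-12)
  expect_equal(pm$dyy_proj, rep(0.4e-3, 2), tolerance = 1e-12)
  expect_equal(pm$dzz_assoc, rep(0.4e-3, 2), tolerance = 1e-12)
  expect_equal(unique(pm$n_proj), sum(sphere_mask(c(26, 20, 6), 5, "voxel",
                                                  dims, c(2, 2, 2))))
})

test_that("an ROI straddling a boundary averages as a voxel-count mixture", {
  dims <- c(20L, 20L, 9L)
  dxx <- array(1e-3, dims)
  dxx[11:20, , ] <- 2e-3                       # step at x = 10 (0-based)
  D <- cbind(as.vector(dxx), 1e-3, 1e-3, 0, 0, 0)
  maps <- scalar_maps(tensor_field_from_matrix(D, dims))
  ctr <- c(10, 10, 4)
  mask <- sphere_mask(ctr, 5, "voxel", dims, c(1, 1, 1))
  # brute-force voxel sum over the mask
  expected <- sum(dxx[mask]) / sum(mask)
  roi <- as_roi_set(data.frame(
    roi = c("projection", "association", "projection", "association"),
    hemisphere = c("left", "left", "right", "right"),
    x = c(10, 15, 4, 2), y = c(10, 10, 10, 10), z = rep(4, 4),
    diameter = c(5, 3, 3, 3), diameter_unit = "voxel"))
  means <- extract_roi_means(maps, roi)
  expect_equal(means$dxx_proj[means$hemisphere == "left"], expected,
               tolerance = 1e-15)
})

test_that("alps_index computes the ratio of means", {
  mk <- function(xp, xa, yp, za)
    structure(data.frame(hemisphere = "left", dxx_proj = xp, dxx_assoc = xa,
                         dyy_proj = yp, dzz_assoc = za,
                         n_proj = 1, n_assoc = 1,
                         flagged_proj = 0, flagged_assoc = 0),
              class = c("roi_means", "data.frame"))
  expect_equal(alps_index(mk(7e-4, 7e-4, 7e-4, 7e-4), "left"), 1.0)
  expect_equal(alps_index(mk(1.2e-3, 1.2e-3, 0.6e-3, 0.6e-3), "left"), 2.0)
  expect_equal(alps_index(mk(1.0e-3, 1.4e-3, 0.5e-3, 0.7e-3), "left"), 2.0)
  expect_error(alps_index(mk(1e-3, 1e-3, 0, 1e-3), "left"),
               class = "dtialps_computation_error")
})

test_that("compute_alps averages independent hemisphere indices", {
  roi <- mini_roi_set()
  # symmetric phantom: left = right = mean
  maps <- scalar_maps(build_tensor_field(mini_phantom_spec(gain = 1.5), roi))
  res <- compute_alps(maps, roi)
  expect_equal(res$alps_left, res$alps_right)
  expect_equal(res$alps_mean, (res$alps_left + res$alps_right) / 2)
  expect_equal(res$alps_mean, 1.5, tolerance = 1e-9)

  # hemisphere-specific gains: splice two fields at the midline (left = +x)
  f_l <- build_tensor_field(mini_phantom_spec(gain = 1.2), roi)
  f_r <- build_tensor_field(mini_phantom_spec(gain = 1.6), roi)
  spliced <- f_l
  spliced$tensors[1:20, , , ] <- f_r$tensors[1:20, , , ]
  res <- compute_alps(scalar_maps(spliced), roi)
  expect_equal(res$alps_left, 1.2, tolerance = 1e-9)
  expect_equal(res$alps_right, 1.6, tolerance = 1e-9)
  expect_equal(res$alps_mean, 1.4, tolerance = 1e-9)
})

test_that("the index is scale-invariant and monotone in Dxx", {
  roi <- mini_roi_set()
  maps <- scalar_maps(build_tensor_field(mini_phantom_spec(gain = 1.5), roi))
  res <- compute_alps(maps, roi)
  scaled <- maps
  for (nm in c("dxx", "dyy", "dzz")) scaled[[nm]] <- 3.7 * scaled[[nm]]
  res2 <- compute_alps(scaled, roi)
  expect_equal(res2$alps_left, res$alps_left, tolerance = 1e-12)
  expect_equal(res2$alps_mean, res$alps_mean, tolerance = 1e-12)

  # increasing Dxx with denominators fixed strictly increases the index
  bumped <- maps
  bumped$dxx <- maps$dxx * 1.05
  expect_gt(compute_alps(bumped, roi)$alps_mean, res$alps_mean)
})

test_that("degenerate-fit fractions surface as provenance warnings", {
  roi <- mini_roi_set()
  maps <- scalar_maps(build_tensor_field(mini_phantom_spec(), roi))
  maps$flagged[] <- TRUE
  means <- extract_roi_means(maps, roi)
  expect_true(length(attr(means, "warnings")) > 0)
  expect_equal(means$flagged_proj, rep(1, 2))
})
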