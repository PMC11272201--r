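#' Published ROI presets for the ALPS index
#'
#' Returns the complete bilateral region-of-interest set of one of the two
#' published ALPS pipelines, as a data frame with one row per sphere.
#'
#' * `DSI_DEFAULT` — manually drawn spheres of 12-voxel diameter at
#'   projection-fiber centers (53,47,40) / (25,47,40) and association-fiber
#'   centers (59,47,40) / (19,47,40) on a 78 x 78 x 78 template grid
#'   (2 mm isotropic phantom grid; the GUI procedure's pixel count is taken
#'   as the operational diameter definition).
#' * `FSL_DEFAULT` — 5 mm diameter spheres at superior-corona-radiata
#'   centers (116,110,99) / (64,110,99) and superior-longitudinal-fasciculus
#'   centers (128,110,99) / (51,110,99) on the 182 x 218 x 182, 1 mm
#'   white-matter atlas template grid.
#'
#' Printed coordinates are interpreted as 0-based voxel indices by default;
#' set `index_base = 1` if your coordinates count from 1.
#'
#' @param preset `"DSI_DEFAULT"` or `"FSL_DEFAULT"`.
#' @param index_base 0 (default) or 1; 1-based centers are shifted down.
#' @return data frame of class `roi_set` with columns `roi`
#'   (projection/association), `hemisphere`, `x`, `y`, `z` (0-based voxel),
#'   `diameter`, `diameter_unit` (`"voxel"`/`"mm"`), and attributes
#'   `preset`, `grid_dims`, `voxel_size`.
#' @export
alps_roi_preset <- function(preset = c("DSI_DEFAULT", "FSL_DEFAULT"),
                            index_base = 0L) {
  preset <- match.arg(preset)
  if (preset == "DSI_DEFAULT") {
    df <- data.frame(
      roi = c("projection", "association", "projection", "association"),
      hemisphere = c("left", "left", "right", "right"),
      x = c(53, 59, 25, 19), y = rep(47, 4), z = rep(40, 4),
      diameter = 12, diameter_unit = "voxel",
      stringsAsFactors = FALSE)
    grid_dims <- c(78L, 78L, 78L); voxel_size <- c(2, 2, 2)
  } else {
    df <- data.frame(
      roi = c("projection", "association", "projection", "association"),
      hemisphere = c("left", "left", "right", "right"),
      x = c(116, 128, 64, 51), y = rep(110, 4), z = rep(99, 4),
      diameter = 5, diameter_unit = "mm",
      stringsAsFactors = FALSE)
    grid_dims <- c(182L, 218L, 182L); voxel_size <- c(1, 1, 1)
  }
  as_roi_set(df, preset = preset, grid_dims = grid_dims,
             voxel_size = voxel_size, index_base = index_base)
}

#' Construct a custom ROI set
#'
#' @param df data frame with columns `roi` (`"projection"`/`"association"`),
#'   `hemisphere` (`"left"`/`"right"`), `x`, `y`, `z` (voxel coordinates),
#'   `diameter`, `diameter_unit` (`"voxel"` or `"mm"`).
#' @param preset identifier recorded in provenance (`"custom"` by default).
#' @param grid_dims,voxel_size geometry of the template grid the coordinates
#'   refer to (used for validation against maps).
#' @param index_base 0 or 1; with 1, coordinates are converted to 0-based.
#' @return `roi_set` data frame.
#' @export
as_roi_set <- function(df, preset = "custom", grid_dims = NULL,
                       voxel_size = NULL, index_base = 0L) {
  need <- c("roi", "hemisphere", "x", "y", "z", "diameter", "diameter_unit")
  if (!all(need %in% names(df)))
    abort_dtialps(paste0("ROI set needs columns: ", paste(need, collapse = ", ")),
                  "dtialps_roi_error")
  if (!index_base %in% c(0L, 1L))
    abort_dtialps("index_base must be 0 or 1", "dtialps_roi_error")
  df$x <- df$x - index_base; df$y <- df$y - index_base; df$z <- df$z - index_base
  tab <- table(df$roi, df$hemisphere)
  ok <- identical(sort(unique(df$roi)), c("association", "projection")) &&
    identical(sort(unique(df$hemisphere)), c("left", "right")) &&
    all(tab == 1L)
  if (!ok)
    abort_dtialps(paste0("a complete ROI set has exactly one projection and one ",
                         "association sphere per hemisphere"), "dtialps_roi_error")
  structure(df, class = c("roi_set", "data.frame"), preset = preset,
            grid_dims = grid_dims, voxel_size = voxel_size)
}

# radius of an ROI sphere in mm on a given grid
roi_radius_mm <- function(diameter, unit, voxel_size) {
  if (unit == "mm") return(diameter / 2)
  if (unit != "voxel")
    abort_dtialps(paste0("unknown diameter unit: ", unit), "dtialps_roi_error")
  if (max(voxel_size) - min(voxel_size) > 1e-9)
    abort_dtialps("voxel-unit diameters require isotropic voxels", "dtialps_roi_error")
  diameter / 2 * voxel_size[1L]
}

#' Spherical ROI mask on a voxel grid
#'
#' A voxel belongs to the sphere iff the Euclidean distance from its center
#' to the ROI center is at most `diameter / 2` in physical mm
#' (center-in-sphere rule, no partial-volume weighting). Voxel-unit
#' diameters are converted through the grid's (isotropic) voxel size.
#' ROI centers are template-grid coordinates; if the target grid is a crop,
#' its `origin` offset is subtracted first.
#'
#' @param center length-3 ROI center, 0-based template voxel coordinates.
#' @param diameter sphere diameter.
#' @param unit `"voxel"` or `"mm"`.
#' @param dims grid dimensions of the mask to produce.
#' @param voxel_size mm per axis.
#' @param origin 0-based voxel offset of the grid within its template.
#' @return logical array of shape `dims`.
#' @export
sphere_mask <- function(center, diameter, unit = "voxel", dims,
                        voxel_size = c(1, 1, 1), origin = c(0L, 0L, 0L)) {
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  r_mm <- roi_radius_mm(diameter, unit, voxel_size)
  ctr <- as.numeric(center) - as.numeric(origin)
  r_vox <- r_mm / voxel_size
  lo <- ctr - r_vox; hi <- ctr + r_vox
  if (any(lo < -0.5) || any(hi > dims - 0.5))
    abort_dtialps(sprintf("ROI sphere at (%s) with radius %.3g mm exceeds the %s grid",
                          paste(center, collapse = ","), r_mm,
                          paste(dims, collapse = "x")), "dtialps_roi_error")
  dx2 <- ((seq_len(dims[1L]) - 1 - ctr[1L]) * voxel_size[1L])^2
  dy2 <- ((seq_len(dims[2L]) - 1 - ctr[2L]) * voxel_size[2L])^2
  dz2 <- ((seq_len(dims[3L]) - 1 - ctr[3L]) * voxel_size[3L])^2
  d2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
  array(d2 <= r_mm^2 + 1e-12, dims)
}

roi_masks <- function(roi_set, dims, voxel_size, origin) {
  masks <- vector("list", nrow(roi_set))
  names(masks) <- paste(roi_set$hemisphere, roi_set$roi, sep = "_")
  for (i in seq_len(nrow(roi_set)))
    masks[[i]] <- sphere_mask(c(roi_set$x[i], roi_set$y[i], roi_set$z[i]),
                              roi_set$diameter[i], roi_set$diameter_unit[i],
                              dims, voxel_size, origin)
  masks
}

#' Extract the four ALPS diffusivity means per hemisphere
#'
#' Arithmetic means of the axis-diffusivity maps over the ROI spheres:
#' Dxx over both the projection and association spheres, Dyy over the
#' projection sphere only, Dzz over the association sphere only.
#'
#' @param maps a `scalar_maps` object.
#' @param roi_set a complete [as_roi_set()] / [alps_roi_preset()] set.
#' @return object of class `roi_means`: data frame with one row per
#'   hemisphere (`dxx_proj`, `dxx_assoc`, `dyy_proj`, `dzz_assoc`,
#'   voxel counts, flagged-voxel fractions); a warning is recorded in the
#'   `warnings` attribute when more than half the voxels of an ROI carry
#'   degenerate fits.
#' @export
extract_roi_means <- function(maps, roi_set) {
  stopifnot(inherits(maps, "scalar_maps"), inherits(roi_set, "roi_set"))
  dims <- dim(maps$dxx)
  gdims <- attr(roi_set, "grid_dims")
  if (!is.null(gdims) && all(maps$origin == 0L) && !is.null(attr(roi_set, "voxel_size"))) {
    # full-grid maps must live on the preset's template grid
    if (!identical(as.integer(gdims), as.integer(dims)))
      abort_dtialps(sprintf("maps grid %s does not match ROI template grid %s",
                            paste(dims, collapse = "x"),
                            paste(gdims, collapse = "x")), "dtialps_roi_error")
  }
  masks <- roi_masks(roi_set, dims, maps$voxel_size, maps$origin)
  warnings <- character()
  rows <- lapply(c("left", "right"), function(h) {
    pm <- masks[[paste0(h, "_projection")]]
    am <- masks[[paste0(h, "_association")]]
    if (!any(pm) || !any(am))
      abort_dtialps(paste0("empty ROI mask in ", h, " hemisphere"), "dtialps_roi_error")
    fl <- c(proj = mean(maps$flagged[pm]), assoc = mean(maps$flagged[am]))
    for (nm in names(fl)) if (fl[[nm]] > 0.5)
      warnings <<- c(warnings, sprintf("%s %s ROI: %.0f%% of voxels have degenerate fits",
                                       h, nm, 100 * fl[[nm]]))
    data.frame(hemisphere = h,
               dxx_proj = mean(maps$dxx[pm]), dxx_assoc = mean(maps$dxx[am]),
               dyy_proj = mean(maps$dyy[pm]), dzz_assoc = mean(maps$dzz[am]),
               n_proj = sum(pm), n_assoc = sum(am),
               flagged_proj = fl[["proj"]], flagged_assoc = fl[["assoc"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("roi_means", "data.frame"),
            preset = attr(roi_set, "preset"), warnings = warnings)
}

#' ALPS index of one hemisphere
#'
#' ALPS = mean(Dxx_proj, Dxx_assoc) / mean(Dyy_proj, Dzz_assoc): the ratio of
#' perivascular-axis (x) diffusivity in the projection- and association-fiber
#' areas to the fiber-perpendicular diffusivities. Values near 1 indicate no
#' preferential diffusion along the perivascular axis.
#'
#' @param means a `roi_means` object.
#' @param hemisphere `"left"` or `"right"`.
#' @return the ALPS index (unitless, positive).
#' @export
alps_index <- function(means, hemisphere = c("left", "right")) {
  hemisphere <- match.arg(hemisphere)
  row <- means[means$hemisphere == hemisphere, , drop = FALSE]
  if (nrow(row) != 1L)
    abort_dtialps(paste0("no ROI means for hemisphere ", hemisphere),
                  "dtialps_roi_error")
  vals <- c(row$dxx_proj, row$dxx_assoc, row$dyy_proj, row$dzz_assoc)
  if (any(vals <= 0))
    abort_dtialps("all four ROI diffusivity means must be positive",
                  "dtialps_computation_error")
  mean(c(row$dxx_proj, row$dxx_assoc)) / mean(c(row$dyy_proj, row$dzz_assoc))
}

#' Compute left, right and mean ALPS indices
#'
#' Convenience wrapper: resolves a preset name or custom ROI set, extracts
#' the ROI means, and computes both hemispheres' indices independently; the
#' reported ALPS index is their average.
#'
#' @param maps a `scalar_maps` object.
#' @param roi preset name (`"DSI_DEFAULT"` / `"FSL_DEFAULT"`) or an
#'   [as_roi_set()] data frame.
#' @param index_base passed to [alps_roi_preset()] when `roi` is a name.
#' @return object of class `alps_result`: list with `alps_left`,
#'   `alps_right`, `alps_mean` (exactly their average), the `roi_means`
#'   table, and a `provenance` list (preset, voxel counts, flagged
#'   fractions, map checksum).
#' @export
compute_alps <- function(maps, roi = "DSI_DEFAULT", index_base = 0L) {
  roi_set <- if (inherits(roi, "roi_set")) roi
             else alps_roi_preset(roi, index_base = index_base)
  means <- extract_roi_means(maps, roi_set)
  left <- alps_index(means, "left")
  right <- alps_index(means, "right")
  checksum <- sprintf("%s|%.10e|%.10e", paste(dim(maps$dxx), collapse = "x"),
                      sum(maps$dxx), sum(maps$dyy) + sum(maps$dzz))
  structure(list(alps_left = left, alps_right = right,
                 alps_mean = (left + right) / 2,
                 roi_means = means,
                 provenance = list(preset = attr(roi_set, "preset"),
                                   voxel_counts = means[, c("hemisphere", "n_proj", "n_assoc")],
                                   flagged = means[, c("hemisphere", "flagged_proj", "flagged_assoc")],
                                   warnings = attr(means, "warnings"),
                                   map_checksum = checksum)),
            class = "alps_result")
}

#' @export
print.alps_result <- function(x, ...) {
  cat(sprintf("<alps_result> preset %s\n  left %.4f | right %.4f | mean %.4f\n",
              x$provenance$preset, x$alps_left, x$alps_right, x$alps_mean))
  if (length(x$provenance$warnings))
    cat("  warnings:", paste(x$provenance$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Export ROI masks for quality-control overlay
#'
#' Writes one NIfTI label map with values 1..4 in ROI-set row order
#' (left projection, left association, right projection, right association
#' for the presets).
#'
#' @param roi_set ROI set.
#' @param maps `scalar_maps` providing the target grid.
#' @param path output NIfTI path.
#' @export
write_roi_masks <- function(roi_set, maps, path) {
  dims <- dim(maps$dxx)
  masks <- roi_masks(roi_set, dims, maps$voxel_size, maps$origin)
  lab <- array(0, dims)
  for (i in seq_along(masks)) lab[masks[[i]]] <- i
  write_map(image_volume(lab, maps$voxel_size, maps$affine, maps$origin), path)
}
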