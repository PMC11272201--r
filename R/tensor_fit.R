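# Design matrix of the log-linear diffusion tensor model, for the b>0 rows:
#   ln(S/S0) = -b g' D g = -X d,  d = (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)
tensor_design <- function(table) {
  dw <- table$bvals > B0_THRESHOLD
  g <- table$bvecs[dw, , drop = FALSE]
  b <- table$bvals[dw]
  X <- b * cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
                 2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3])
  list(X = X, dw = dw)
}

#' Fit the diffusion tensor per voxel
#'
#' Log-linear least-squares estimation of the symmetric diffusion tensor from
#' a single-shell (or multi-shell) acquisition. The non-diffusion signal S0
#' is the geometric mean of the b=0 volumes; each diffusion-weighted sample
#' is clamped to `1e-6 * S0` before the log transform (clamped voxels are
#' flagged). `"ols"` solves the unweighted log-linear system; `"wls"`
#' (default, mirroring common dtifit practice) performs one reweighting pass
#' with weights equal to the squared signals predicted by the OLS fit, which
#' counteracts the log transform's amplification of noise at low signal.
#'
#' @param dwi 4D [image_volume] of diffusion-weighted signals.
#' @param table matching [gradient_table]; the scheme must pass
#'   [validate_scheme()].
#' @param method `"wls"` or `"ols"`.
#' @param s0_threshold voxels with estimated S0 at or below this are excluded
#'   from the fit mask (no other brain masking is applied).
#' @return an object of class `tensor_volume`: arrays `tensors`
#'   (dims x 6: Dxx, Dyy, Dzz, Dxy, Dxz, Dyz in mm^2/s), `s0`, logical
#'   `fit_mask` and `clamped`, plus grid geometry.
#' @export
fit_tensor <- function(dwi, table, method = c("wls", "ols"), s0_threshold = 0) {
  method <- match.arg(method)
  stopifnot(inherits(dwi, "image_volume"), inherits(table, "gradient_table"))
  if (length(dim(dwi$data)) != 4L)
    abort_dtialps("fit_tensor expects a 4D series", "dtialps_format_error")
  if (dim(dwi$data)[4L] != length(table$bvals))
    abort_dtialps("volume count does not match gradient table", "dtialps_scheme_error")
  rep_ <- validate_scheme(table)
  if (!rep_$fittable)
    abort_dtialps(paste0("gradient scheme is not fittable: ",
                         paste(rep_$messages, collapse = "; ")),
                  "dtialps_scheme_error")

  dims <- dim(dwi$data)[1:3]
  nvox <- prod(dims)
  S <- matrix(dwi$data, nvox)
  des <- tensor_design(table)
  X <- des$X
  b0 <- !des$dw

  S0 <- exp(rowMeans(log(pmax(S[, b0, drop = FALSE], .Machine$double.xmin))))
  S0[rowSums(abs(S[, b0, drop = FALSE])) == 0] <- 0
  mask <- S0 > s0_threshold & rowSums(abs(S)) > 0

  Sd <- S[mask, des$dw, drop = FALSE]
  s0m <- S0[mask]
  eps <- 1e-6 * s0m
  clamped_m <- rowSums(Sd < eps) > 0L
  Sd <- pmax(Sd, eps)
  Y <- -log(Sd / s0m)                       # nmask x m, y = X d

  XtX <- crossprod(X)
  B <- Y %*% X %*% solve(XtX)               # OLS, nmask x 6
  if (method == "wls") {
    pred <- s0m * exp(-tcrossprod(B, X))    # predicted signals, nmask x m
    W <- pmax(pred, eps)^2
    B <- t(.wls_batch(X, t(Y), t(W)))
  }

  tensors <- matrix(0, nvox, 6L)
  tensors[mask, ] <- B
  clamped <- rep(FALSE, nvox)
  clamped[mask] <- clamped_m
  structure(list(tensors = array(tensors, c(dims, 6L)),
                 s0 = array(S0, dims),
                 fit_mask = array(mask, dims),
                 clamped = array(clamped, dims),
                 method = method,
                 voxel_size = dwi$voxel_size, origin = dwi$origin,
                 affine = dwi$affine),
            class = "tensor_volume")
}

#' @export
print.tensor_volume <- function(x, ...) {
  dims <- dim(x$s0)
  cat("<tensor_volume> ", paste(dims, collapse = " x "), " | method ",
      x$method, " | ", sum(x$fit_mask), "/", prod(dims), " voxels fit\n", sep = "")
  invisible(x)
}

#' Eigendecomposition of a fitted tensor field
#'
#' Per-voxel symmetric eigendecomposition with eigenvalues sorted in
#' descending order. Eigenvector sign is fixed deterministically (first
#' nonzero component non-negative). Voxels whose smallest eigenvalue is
#' negative — physically impossible diffusivities arising from noise — are
#' flagged but retained.
#'
#' @param tensor a `tensor_volume` from [fit_tensor()].
#' @return an object of class `tensor_eigen`: `values` (dims x 3,
#'   descending), `vectors` (dims x 3 x 3; `[..., k]` is the k-th
#'   eigenvector), logical `negative_eig` flag array.
#' @export
eigen_decompose <- function(tensor) {
  stopifnot(inherits(tensor, "tensor_volume"))
  dims <- dim(tensor$s0)
  nvox <- prod(dims)
  D <- matrix(tensor$tensors, nvox, 6L)
  idx <- which(as.logical(tensor$fit_mask))
  values <- matrix(0, nvox, 3L)
  vectors <- matrix(0, nvox, 9L)
  vectors[, c(1L, 5L, 9L)] <- 1           # identity frame for unfit voxels
  if (length(idx)) {
    e <- .eig3_batch(D[idx, , drop = FALSE])
    values[idx, ] <- e$values
    vectors[idx, ] <- e$vectors
  }
  neg <- rep(FALSE, nvox)
  neg[idx] <- values[idx, 3L] < 0
  structure(list(values = array(values, c(dims, 3L)),
                 vectors = array(vectors, c(dims, 3L, 3L)),
                 negative_eig = array(neg, dims)),
            class = "tensor_eigen")
}

#' Scalar maps for ALPS analysis
#'
#' Derives from a fitted tensor field the maps the ALPS method consumes:
#' fractional anisotropy, the direction-encoded (color) FA map, and the axis
#' diffusivities Dxx, Dyy, Dzz. The axis diffusivities are the diagonal
#' tensor elements in the canonical anatomical frame — deliberately not the
#' eigenvalues — because the ALPS index is defined on fixed anatomical axes.
#'
#' FA = sqrt(3/2) * sqrt(sum((lambda_i - mean)^2)) / sqrt(sum(lambda_i^2)),
#' defined as 0 for a zero tensor; color FA channel c is FA * |e1_c|.
#'
#' @param tensor a `tensor_volume`.
#' @param eig optional precomputed [eigen_decompose()] result.
#' @return an object of class `scalar_maps`: arrays `fa`, `color_fa`
#'   (dims x 3, red = x, green = y, blue = z), `dxx`, `dyy`, `dzz`, logical
#'   `flagged` (clamped or negative-eigenvalue voxels), plus grid geometry.
#' @export
scalar_maps <- function(tensor, eig = eigen_decompose(tensor)) {
  stopifnot(inherits(tensor, "tensor_volume"))
  dims <- dim(tensor$s0)
  nvox <- prod(dims)
  ev <- matrix(eig$values, nvox, 3L)
  mbar <- rowMeans(ev)
  num <- (ev[, 1] - mbar)^2 + (ev[, 2] - mbar)^2 + (ev[, 3] - mbar)^2
  den <- ev[, 1]^2 + ev[, 2]^2 + ev[, 3]^2
  fa <- ifelse(den > 0, sqrt(1.5 * num / den), 0)
  e1 <- matrix(eig$vectors, nvox, 9L)[, 1:3, drop = FALSE]
  color <- fa * abs(e1)
  tens <- matrix(tensor$tensors, nvox, 6L)
  flagged <- as.logical(tensor$clamped) | as.logical(eig$negative_eig)
  structure(list(fa = array(fa, dims),
                 color_fa = array(color, c(dims, 3L)),
                 dxx = array(tens[, 1L], dims),
                 dyy = array(tens[, 2L], dims),
                 dzz = array(tens[, 3L], dims),
                 flagged = array(flagged, dims),
                 fit_mask = tensor$fit_mask,
                 voxel_size = tensor$voxel_size, origin = tensor$origin,
                 affine = tensor$affine),
            class = "scalar_maps")
}

#' Write the scalar maps of a fit to a directory
#'
#' Writes `fa`, `color_fa`, `dxx`, `dyy`, `dzz` (NIfTI, input affine) under
#' `dir`; the color FA map is stored as a 4D volume with three channels.
#'
#' @param maps a `scalar_maps` object.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_scalar_maps <- function(maps, dir) {
  stopifnot(inherits(maps, "scalar_maps"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  geom <- function(d) image_volume(d, maps$voxel_size, maps$affine, maps$origin)
  paths <- character()
  for (nm in c("fa", "dxx", "dyy", "dzz")) {
    p <- file.path(dir, paste0(nm, ".nii.gz"))
    write_map(geom(maps[[nm]]), p)
    paths <- c(paths, p)
  }
  cf <- RNifti::asNifti(maps$color_fa)
  RNifti::pixdim(cf) <- c(maps$voxel_size, 1)
  RNifti::`sform<-`(cf, structure(maps$affine, code = 2L)) -> cf
  p <- file.path(dir, "color_fa.nii.gz")
  RNifti::writeNifti(cf, p, datatype = "double")
  # geometry sidecar so ALPS presets can check the grid and crop offset
  jsonlite::write_json(list(voxel_size = maps$voxel_size, origin = maps$origin,
                            dims = dim(maps$fa)),
                       file.path(dir, "geometry.json"), auto_unbox = FALSE)
  invisible(c(paths, p))
}

#' Read scalar maps previously written by [write_scalar_maps()]
#'
#' @param dir directory holding `dxx.nii.gz`, `dyy.nii.gz`, `dzz.nii.gz`
#'   (and optionally `fa`, `color_fa`, `geometry.json`).
#' @return a `scalar_maps` object (FA zero-filled if absent on disk).
#' @export
read_scalar_maps <- function(dir) {
  need <- file.path(dir, paste0(c("dxx", "dyy", "dzz"), ".nii.gz"))
  if (!all(file.exists(need)))
    abort_dtialps(paste0("missing diffusivity maps under ", dir),
                  "dtialps_format_error")
  rd <- function(p) as.array(RNifti::readNifti(p))
  dxx <- RNifti::readNifti(need[1L])
  vox <- abs(attr(dxx, "pixdim")[1:3])
  origin <- c(0L, 0L, 0L)
  gj <- file.path(dir, "geometry.json")
  if (file.exists(gj)) {
    g <- jsonlite::read_json(gj, simplifyVector = TRUE)
    origin <- as.integer(g$origin)
    vox <- as.numeric(g$voxel_size)
  }
  dims <- dim(as.array(dxx))
  fa_p <- file.path(dir, "fa.nii.gz")
  cf_p <- file.path(dir, "color_fa.nii.gz")
  dxx_a <- as.array(dxx)
  structure(list(fa = if (file.exists(fa_p)) rd(fa_p) else array(0, dims),
                 color_fa = if (file.exists(cf_p)) rd(cf_p) else array(0, c(dims, 3L)),
                 dxx = dxx_a, dyy = rd(need[2L]), dzz = rd(need[3L]),
                 flagged = array(FALSE, dims),
                 fit_mask = array(TRUE, dims),
                 voxel_size = vox, origin = origin,
                 affine = RNifti::xform(dxx)),
            class = "scalar_maps")
}
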