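#' In-memory image volume
#'
#' Light container for a 3D scalar map or a 4D diffusion-weighted series on a
#' regular grid. Voxel indices are 0-based and half-open throughout the
#' package; `origin` records the 0-based voxel offset of the grid within a
#' larger named template when the volume is a crop (phantom slabs use this),
#' so that template-space region-of-interest coordinates stay meaningful.
#'
#' @param data numeric array, 3D or 4D.
#' @param voxel_size length-3 positive numeric, mm per grid axis.
#' @param affine optional 4x4 voxel-to-world matrix; defaults to a diagonal
#'   RAS affine built from `voxel_size` and `origin`.
#' @param origin length-3 integer voxel offset of this grid inside its
#'   template (0-based); `c(0, 0, 0)` for full-grid data.
#' @param axis_labels orientation string of the grid axes, e.g. `"RAS"`
#'   (x = left to right, y = posterior to anterior, z = inferior to superior).
#' @return an object of class `image_volume`.
#' @export
image_volume <- function(data, voxel_size, affine = NULL, origin = c(0L, 0L, 0L),
                         axis_labels = "RAS") {
  data <- as.array(data)
  data <- array(data, dim(data))   # drop any NIfTI header attributes
  nd <- length(dim(data))
  if (!(nd %in% c(3L, 4L)))
    abort_dtialps("image data must be a 3D or 4D array", "dtialps_format_error")
  if (any(dim(data) < 1L))
    abort_dtialps("all grid dimensions must be >= 1", "dtialps_format_error")
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    abort_dtialps("voxel sizes must be positive", "dtialps_format_error")
  origin <- rep_len(as.integer(round(origin)), 3L)
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
    affine[1:3, 4] <- origin * voxel_size
  }
  affine <- matrix(as.numeric(affine), 4L, 4L)
  if (abs(det(affine)) < .Machine$double.eps)
    abort_dtialps("affine must be invertible", "dtialps_format_error")
  structure(list(data = data, voxel_size = voxel_size, affine = affine,
                 origin = origin, axis_labels = axis_labels),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(dim(x$data), collapse = " x "),
      " | voxel ", paste(signif(x$voxel_size, 4), collapse = " x "), " mm",
      " | axes ", x$axis_labels, "\n", sep = "")
  if (any(x$origin != 0L))
    cat("  template origin offset (voxels): ",
        paste(x$origin, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Diffusion gradient table
#'
#' Per-volume b-values and unit gradient directions, FSL dialect: b-vectors
#' are expressed in the image (voxel) coordinate frame, one 3-vector per
#' acquired volume. Vectors for b>0 volumes must be unit length; b=0 volumes
#' may carry the zero vector.
#'
#' @param bvals numeric vector of b-values (s/mm^2).
#' @param bvecs n x 3 numeric matrix of gradient directions (rows), or a
#'   3 x n matrix which is transposed with a message-free heuristic only when
#'   unambiguous.
#' @return an object of class `gradient_table`.
#' @export
gradient_table <- function(bvals, bvecs) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (ncol(bvecs) != 3L && nrow(bvecs) == 3L) bvecs <- t(bvecs)
  if (ncol(bvecs) != 3L)
    abort_dtialps("bvecs must have 3 components per volume", "dtialps_scheme_error")
  if (length(bvals) != nrow(bvecs))
    abort_dtialps(sprintf("bvals (%d) and bvecs (%d) lengths differ",
                          length(bvals), nrow(bvecs)), "dtialps_scheme_error")
  if (any(!is.finite(bvals)) || any(bvals < 0))
    abort_dtialps("b-values must be finite and non-negative", "dtialps_scheme_error")
  norms <- sqrt(rowSums(bvecs^2))
  bad <- bvals > B0_THRESHOLD & abs(norms - 1) > 1e-3
  if (any(bad))
    abort_dtialps(sprintf("%d b>0 gradient vector(s) are not unit length (e.g. norm %.4g)",
                          sum(bad), norms[which(bad)[1]]), "dtialps_scheme_error")
  structure(list(bvals = bvals, bvecs = bvecs), class = "gradient_table")
}

#' @export
print.gradient_table <- function(x, ...) {
  cat("<gradient_table> ", length(x$bvals), " volumes | shells ",
      paste(sort(unique(round(x$bvals / 50) * 50)), collapse = ", "),
      " s/mm^2\n", sep = "")
  invisible(x)
}

#' @export
length.gradient_table <- function(x) length(x$bvals)

#' Single-shell acquisition scheme
#'
#' Builds the acquisition scheme used throughout the package's phantoms:
#' `n_b0` non-diffusion-weighted volumes followed by `n_dir` diffusion
#' directions on one shell. Defaults reproduce the consortium protocol the
#' ALPS validation presets target: six b=0 volumes plus 40 directions at
#' b=1000 s/mm^2. Directions are spread quasi-uniformly over the sphere with
#' a deterministic Fibonacci (golden-angle) lattice.
#'
#' @param n_dir number of diffusion-weighted directions.
#' @param n_b0 number of b=0 volumes (prepended).
#' @param bval shell b-value in s/mm^2.
#' @return a [gradient_table()].
#' @export
single_shell_scheme <- function(n_dir = 40L, n_b0 = 6L, bval = 1000) {
  stopifnot(n_dir >= 6L, n_b0 >= 0L, bval > 0)
  i <- seq_len(n_dir) - 0.5
  z <- 1 - 2 * i / n_dir
  phi <- pi * (3 - sqrt(5)) * (seq_len(n_dir) - 1)
  r <- sqrt(pmax(0, 1 - z^2))
  dirs <- cbind(r * cos(phi), r * sin(phi), z)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  bvecs <- rbind(matrix(0, n_b0, 3), dirs)
  gradient_table(c(rep(0, n_b0), rep(bval, n_dir)), bvecs)
}

read_bvals <- function(path) {
  if (!file.exists(path))
    abort_dtialps(paste0("bval file not found: ", path), "dtialps_format_error")
  scan(path, what = double(), quiet = TRUE)
}

read_bvecs <- function(path) {
  if (!file.exists(path))
    abort_dtialps(paste0("bvec file not found: ", path), "dtialps_format_error")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) != 3L)
    abort_dtialps("bvec file must have exactly three rows (x, y, z components)",
                  "dtialps_format_error")
  rows <- lapply(lines, function(l) scan(text = l, what = double(), quiet = TRUE))
  if (length(unique(lengths(rows))) != 1L)
    abort_dtialps("bvec rows have unequal lengths", "dtialps_format_error")
  t(do.call(rbind, rows))
}

write_gradients <- function(table, bval_path, bvec_path) {
  writeLines(paste(format(table$bvals, trim = TRUE, scientific = FALSE),
                   collapse = " "), bval_path)
  writeLines(apply(t(table$bvecs), 1L, function(r)
    paste(sprintf("%.17g", r), collapse = " ")), bvec_path)
  invisible(NULL)
}

# Axis map from an orientation string like "LPS": for each world axis
# (x, y, z) the source grid axis and its sign.
orientation_map <- function(ostring) {
  chars <- strsplit(ostring, "")[[1]]
  axis_of <- c(R = 1L, L = 1L, A = 2L, P = 2L, S = 3L, I = 3L)
  sign_of <- c(R = 1, L = -1, A = 1, P = -1, S = 1, I = -1)
  if (length(chars) != 3L || !all(chars %in% names(axis_of)))
    abort_dtialps(paste0("unrecognized orientation string: ", ostring),
                  "dtialps_format_error")
  world_axis <- axis_of[chars]           # world axis of each grid axis
  perm <- match(1:3, world_axis)         # grid axis feeding each world axis
  list(perm = perm, sign = sign_of[chars][perm])
}

#' Read a diffusion-weighted dataset
#'
#' Reads a NIfTI volume together with FSL-dialect gradient files (one-row
#' bval, three-row bvec). If the header carries a usable orientation, the
#' volume is reoriented to the package's canonical RAS axes
#' (x = right-left, y = anterior-posterior, z = inferior-superior) before any
#' tensor fitting, and the b-vectors — which live in the voxel frame — are
#' permuted and sign-flipped accordingly.
#'
#' @param image_path path to a `.nii` / `.nii.gz` file.
#' @param bval_path path to the b-value file (single whitespace-separated row).
#' @param bvec_path path to the b-vector file (three rows: x, y, z).
#' @return a list with elements `volume` ([image_volume]) and
#'   `gradients` ([gradient_table]).
#' @export
read_dwi <- function(image_path, bval_path, bvec_path) {
  if (!file.exists(image_path))
    abort_dtialps(paste0("image not found: ", image_path), "dtialps_format_error")
  img <- tryCatch(RNifti::readNifti(image_path),
                  error = function(e) abort_dtialps(
                    paste0("unreadable NIfTI header: ", conditionMessage(e)),
                    "dtialps_format_error"))
  bvals <- read_bvals(bval_path)
  bvecs <- read_bvecs(bvec_path)
  nvol <- if (length(dim(img)) == 4L) dim(img)[4L] else 1L
  if (length(bvals) != nvol)
    abort_dtialps(sprintf("gradient table has %d entries but image has %d volume(s)",
                          length(bvals), nvol), "dtialps_scheme_error")

  ostring <- tryCatch(RNifti::orientation(img), error = function(e) NA_character_)
  if (!is.na(ostring) && nchar(ostring) == 3L && ostring != "RAS") {
    map <- orientation_map(ostring)
    RNifti::orientation(img) <- "RAS"
    bvecs <- sweep(bvecs[, map$perm, drop = FALSE], 2L, map$sign, `*`)
  }
  pix <- attr(img, "pixdim")
  vox <- if (!is.null(pix)) pix[1:3] else RNifti::pixdim(img)[1:3]
  vol <- image_volume(as.array(img), voxel_size = abs(vox),
                      affine = RNifti::xform(img), axis_labels = "RAS")
  list(volume = vol, gradients = gradient_table(bvals, bvecs))
}

#' Write a 3D map as NIfTI
#'
#' @param volume an [image_volume] holding a 3D map.
#' @param path destination `.nii` / `.nii.gz` path.
#' @param datatype NIfTI on-disk datatype; the `"double"` default preserves
#'   diffusivity maps bit-exactly.
#' @export
write_map <- function(volume, path, datatype = "double") {
  stopifnot(inherits(volume, "image_volume"))
  if (length(dim(volume$data)) != 3L)
    abort_dtialps("write_map expects a 3D map; use write_dwi for 4D series",
                  "dtialps_format_error")
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- volume$voxel_size
  RNifti::`sform<-`(img, structure(volume$affine, code = 2L)) -> img
  RNifti::`qform<-`(img, structure(volume$affine, code = 2L)) -> img
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Write a 4D diffusion series with its gradient files
#'
#' @param volume 4D [image_volume].
#' @param table matching [gradient_table].
#' @param prefix output path prefix; writes `<prefix>.nii.gz`,
#'   `<prefix>.bval`, `<prefix>.bvec`.
#' @param datatype NIfTI on-disk datatype.
#' @return invisibly, the three paths written.
#' @export
write_dwi <- function(volume, table, prefix, datatype = "double") {
  stopifnot(inherits(volume, "image_volume"), inherits(table, "gradient_table"))
  if (length(dim(volume$data)) != 4L)
    abort_dtialps("write_dwi expects a 4D series", "dtialps_format_error")
  if (dim(volume$data)[4L] != length(table$bvals))
    abort_dtialps("volume count does not match gradient table", "dtialps_scheme_error")
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- c(volume$voxel_size, 1)
  RNifti::`sform<-`(img, structure(volume$affine, code = 2L)) -> img
  RNifti::`qform<-`(img, structure(volume$affine, code = 2L)) -> img
  paths <- paste0(prefix, c(".nii.gz", ".bval", ".bvec"))
  RNifti::writeNifti(img, paths[1L], datatype = datatype)
  write_gradients(table, paths[2L], paths[3L])
  invisible(paths)
}

#' Validate a gradient scheme for tensor fitting
#'
#' Report-only check of whether a diffusion acquisition supports a tensor
#' fit: at least one b=0 volume and at least six non-collinear gradient
#' directions giving a full-rank 6-parameter design.
#'
#' @param table a [gradient_table].
#' @return an object of class `scheme_report`: a list with `shells`
#'   (rounded b-values found), `n_b0`, `n_directions` (unique up to sign),
#'   `design_rank`, `fittable` and `messages`.
#' @export
validate_scheme <- function(table) {
  stopifnot(inherits(table, "gradient_table"))
  if (length(table$bvals) == 0L)
    abort_dtialps("empty gradient table", "dtialps_scheme_error")
  b0 <- table$bvals <= B0_THRESHOLD
  shells <- sort(unique(round(table$bvals / 50) * 50))
  dirs <- table$bvecs[!b0, , drop = FALSE]
  # unique directions up to antipodal symmetry
  n_unique <- 0L
  if (nrow(dirs) > 0L) {
    canon <- t(apply(dirs, 1L, function(v) {
      nz <- which(abs(v) > 1e-8)
      if (length(nz) && v[nz[1]] < 0) v <- -v
      round(v, 6)
    }))
    n_unique <- nrow(unique(canon))
  }
  rank6 <- if (nrow(dirs) > 0L) qr(tensor_design(table)$X)$rank else 0L
  msgs <- character()
  if (sum(b0) < 1L) msgs <- c(msgs, "no b=0 volume: S0 cannot be estimated")
  if (n_unique < 6L) msgs <- c(msgs, "fewer than 6 unique gradient directions")
  if (rank6 < 6L) msgs <- c(msgs, "rank-deficient 6-parameter tensor design")
  fittable <- sum(b0) >= 1L && n_unique >= 6L && rank6 == 6L
  structure(list(shells = shells, n_b0 = sum(b0), n_directions = n_unique,
                 design_rank = rank6, fittable = fittable, messages = msgs),
            class = "scheme_report")
}

#' @export
print.scheme_report <- function(x, ...) {
  cat("<scheme_report> shells {", paste(x$shells, collapse = ", "), "} | ",
      x$n_b0, " b=0 | ", x$n_directions, " directions | design rank ",
      x$design_rank, "\n", sep = "")
  cat(if (x$fittable) "  PASS: scheme supports tensor fitting\n"
      else paste0("  FAIL: ", paste(x$messages, collapse = "; "), "\n"))
  invisible(x)
}
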