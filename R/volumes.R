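# NIfTI volume I/O and grid geometry.
#
# All volumes are represented as a pair (grid, values): `values` is a 3-D
# numeric array in the grid's axis order and `grid` carries the voxel-to-world
# affine. Volumes are reoriented to the RAS (right-anterior-superior)
# canonical orientation on load, so voxel order is comparable across files.
# Voxel indices are 0-based throughout, matching the NIfTI convention for
# affine transforms.

#' Construct a volume grid
#'
#' A `volume_grid` describes the geometry of a 3-D image: its dimensions,
#' voxel size in millimetres, and the 4x4 affine mapping 0-based voxel
#' indices to world (mm) coordinates.
#'
#' @param dims Integer vector of length 3, voxels per axis (all >= 1).
#' @param voxel_size Numeric vector of length 3, voxel edge lengths in mm
#'   (all > 0). Ignored when `affine` is supplied (derived from it instead).
#' @param affine Optional 4x4 voxel-to-world affine. Defaults to a diagonal
#'   scaling by `voxel_size` with the origin at voxel (0,0,0).
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(dims, voxel_size = c(1, 1, 1), affine = NULL) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 1L))
    stop("`dims` must be three integers, all >= 1")
  if (is.null(affine)) {
    if (length(voxel_size) != 3L || any(voxel_size <= 0))
      stop("`voxel_size` must be three positive numbers")
    affine <- diag(c(voxel_size, 1))
  } else {
    affine <- as.matrix(affine)
    if (!all(dim(affine) == c(4L, 4L)))
      stop("`affine` must be a 4x4 matrix")
    voxel_size <- sqrt(colSums(affine[1:3, 1:3]^2))
  }
  if (abs(det(affine)) < 1e-12)
    stop("degenerate affine: not invertible")
  structure(list(dims = dims, voxel_size = as.numeric(voxel_size),
                 affine = affine),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid %dx%dx%d, voxels %.3gx%.3gx%.3g mm>\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

#' Test whether two grids agree
#'
#' Grids are considered equal when dimensions match and the affines agree
#' element-wise within `tol` (default 1e-4 mm); below this tolerance no
#' resampling is performed by [align_to_grid()].
#'
#' @param a,b `volume_grid` objects.
#' @param tol Element-wise affine tolerance in mm.
#' @return Logical scalar.
#' @export
grids_equal <- function(a, b, tol = 1e-4) {
  all(a$dims == b$dims) && all(abs(a$affine - b$affine) < tol)
}

#' Read a 3-D NIfTI volume
#'
#' Reads a NIfTI-1 file (plain or gzip-compressed), reorients it to the RAS
#' canonical orientation, and returns its grid and values. NaN voxels are
#' preserved as "undefined".
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A list with elements `grid` (a [volume_grid()]) and `values`
#'   (3-D numeric array; `NaN`/`NA` marks undefined voxels).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("not a readable NIfTI file: ", path,
                                           " (", conditionMessage(e), ")"))
  d <- dim(img)
  if (length(d) == 4L) {
    if (d[4] > 1L)
      stop("expected 3-D image, got 4-D with ", d[4], " volumes: ", path)
    img <- RNifti::asNifti(array(as.numeric(img), dim = d[1:3]),
                           reference = img)
  } else if (length(d) != 3L) {
    stop("expected 3-D image, got ", length(d), "-D: ", path)
  }
  RNifti::orientation(img) <- "RAS"
  grid <- volume_grid(dim(img), affine = structure(RNifti::xform(img),
                                                   imagedim = NULL, code = NULL))
  values <- array(as.numeric(img), dim = dim(img))
  list(grid = grid, values = values)
}

#' Write a 3-D volume as NIfTI-1
#'
#' @param volume A list with `grid` and `values`, as returned by
#'   [read_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  grid <- volume$grid
  values <- volume$values
  stopifnot(inherits(grid, "volume_grid"),
            all(dim(values) == grid$dims))
  img <- RNifti::asNifti(values)
  RNifti::pixdim(img) <- grid$voxel_size
  aff <- structure(grid$affine, code = 2L)
  RNifti::qform(img) <- aff
  RNifti::sform(img) <- aff
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Resample a volume onto a target grid
#'
#' Maps each target voxel centre through the target affine into world space,
#' then through the inverse source affine into source voxel coordinates, and
#' samples the source there. Target voxels falling outside the source
#' coverage are undefined (`NA`). When source and target grids agree within
#' the affine tolerance the values pass through unchanged.
#'
#' @param source A list with `grid` and `values`.
#' @param target A [volume_grid()] to resample onto.
#' @param method `"trilinear"` (default; used for beta images) or
#'   `"nearest"` (used for masks).
#' @return A 3-D array of values on `target`.
#' @export
align_to_grid <- function(source, target, method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  sgrid <- source$grid
  if (grids_equal(sgrid, target)) return(source$values)
  if (abs(det(sgrid$affine)) < 1e-12 || abs(det(target$affine)) < 1e-12)
    stop("degenerate affine")

  # 0-based voxel index grid of the target
  idx <- as.matrix(expand.grid(i = seq_len(target$dims[1]) - 1,
                               j = seq_len(target$dims[2]) - 1,
                               k = seq_len(target$dims[3]) - 1))
  world <- target$affine %*% rbind(t(idx), 1)
  src <- solve(sgrid$affine) %*% world   # continuous source voxel coords
  sx <- src[1, ]; sy <- src[2, ]; sz <- src[3, ]
  d <- sgrid$dims
  vals <- source$values
  out <- rep(NA_real_, nrow(idx))

  if (method == "nearest") {
    xi <- round(sx); yi <- round(sy); zi <- round(sz)
    ok <- xi >= 0 & xi <= d[1] - 1 & yi >= 0 & yi <= d[2] - 1 &
      zi >= 0 & zi <= d[3] - 1
    out[ok] <- vals[cbind(xi[ok] + 1, yi[ok] + 1, zi[ok] + 1)]
  } else {
    ok <- sx >= 0 & sx <= d[1] - 1 & sy >= 0 & sy <= d[2] - 1 &
      sz >= 0 & sz <= d[3] - 1
    x0 <- pmin(floor(sx[ok]), d[1] - 2); fx <- sx[ok] - x0
    y0 <- pmin(floor(sy[ok]), d[2] - 2); fy <- sy[ok] - y0
    z0 <- pmin(floor(sz[ok]), d[3] - 2); fz <- sz[ok] - z0
    acc <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
        (if (dz) fz else 1 - fz)
      acc <- acc + w * vals[cbind(x0 + dx + 1, y0 + dy + 1, z0 + dz + 1)]
    }
    out[ok] <- acc
  }
  array(out, dim = target$dims)
}
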