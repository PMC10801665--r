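#' 3D scalar volumes with physical geometry
#'
#' A `volume3d` wraps a numeric 3D array together with its voxel spacing and
#' world-space origin, the common currency for CT-like intensities,
#' probability maps, binary/instance masks and dose grids throughout the
#' package.
#'
#' Coordinate convention (used package-wide): voxel indices are 0-based in
#' world-space formulas; the world coordinate (mm) of voxel index
#' `(i, j, k)` is `origin + c(i, j, k) * spacing`, with the third axis the
#' slice (z) axis. In R code the array is indexed 1-based as usual, so R index
#' `(i, j, k)` sits at `origin + (c(i, j, k) - 1) * spacing`.
#'
#' @param data numeric 3D array (nx, ny, nz).
#' @param spacing numeric length-3 voxel size in mm, all > 0.
#' @param origin numeric length-3 world coordinate (mm) of the first voxel
#'   centre.
#' @return A `volume3d` object.
#' @export
volume3d <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop_cfg("volume3d: data must be a 3D array")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop_cfg("volume3d: spacing must be 3 positive numbers")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop_cfg("volume3d: origin must be 3 finite numbers")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume3d> %d x %d x %d voxels, spacing %.3g/%.3g/%.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%.2f, %.2f, %.2f) mm, range [%.3g, %.3g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.volume3d <- function(x) dim(x$data)

#' World coordinates of voxel indices
#'
#' @param vol a `volume3d`.
#' @param idx integer matrix (n x 3) of 0-based voxel indices.
#' @return numeric matrix (n x 3) of mm coordinates.
#' @export
voxel_to_world <- function(vol, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3L)
  sweep(sweep(idx, 2L, vol$spacing, `*`), 2L, vol$origin, `+`)
}

#' Slice z coordinates (mm) of a volume
#' @param vol a `volume3d`.
#' @return numeric vector of length nz.
#' @export
slice_z <- function(vol) {
  vol$origin[3] + (seq_len(dim(vol$data)[3]) - 1) * vol$spacing[3]
}

same_grid <- function(a, b) {
  identical(dim(a$data), dim(b$data)) &&
    max(abs(a$spacing - b$spacing)) < 1e-9 &&
    max(abs(a$origin - b$origin)) < 1e-9
}

#' Read and write volumes as NIfTI
#'
#' Volumes are stored as NIfTI-1 (`.nii` / `.nii.gz`) through the RNifti
#' library with the affine carrying spacing and origin; a round trip preserves
#' voxel values bitwise and geometry to well below 1e-6 mm.
#'
#' @param path file path ending in `.nii` or `.nii.gz`.
#' @return `read_volume` returns a `volume3d`; `write_volume` returns `path`
#'   invisibly.
#' @export
read_volume <- function(path) {
  if (!grepl("\\.nii(\\.gz)?$", path))
    stop_cfg("read_volume: unsupported extension (want .nii/.nii.gz): %s", path)
  if (!file.exists(path)) stop_cfg("read_volume: no such file: %s", path)
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  arr <- array(as.numeric(img), dim = dim(img)[1:3])
  spacing <- abs(c(aff[1, 1], aff[2, 2], aff[3, 3]))
  # our volumes are written with a diagonal LPS->RAS-free affine; recover the
  # first-voxel origin from the translation column, undoing RNifti's RAS flips
  origin <- c(aff[1, 4] / sign(aff[1, 1] + (aff[1, 1] == 0)),
              aff[2, 4] / sign(aff[2, 2] + (aff[2, 2] == 0)),
              aff[3, 4] / sign(aff[3, 3] + (aff[3, 3] == 0)))
  volume3d(arr, spacing = spacing, origin = origin)
}

#' @param vol a `volume3d` to write.
#' @rdname read_volume
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume3d"))
  if (!grepl("\\.nii(\\.gz)?$", path))
    stop_cfg("write_volume: unsupported extension (want .nii/.nii.gz): %s", path)
  img <- RNifti::asNifti(vol$data)
  aff <- diag(4)
  aff[1, 1] <- vol$spacing[1]; aff[2, 2] <- vol$spacing[2]
  aff[3, 3] <- vol$spacing[3]
  aff[1:3, 4] <- vol$origin
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Central in-plane crop
#'
#' Crops a volume to a target in-plane size, keeping all slices and the
#' central block, and shifts the origin so the world coordinates of retained
#' voxels are unchanged. Mirrors the preprocessing crop used to cut a full
#' scanner matrix down before feeding the network.
#'
#' @param vol a `volume3d`.
#' @param size integer length-1 or length-2 in-plane target (nx, ny).
#' @return the cropped `volume3d`.
#' @export
crop_center <- function(vol, size) {
  stopifnot(inherits(vol, "volume3d"))
  size <- rep(as.integer(size), length.out = 2L)
  d <- dim(vol$data)
  if (any(size > d[1:2]))
    stop_cfg("crop_center: target %dx%d exceeds input %dx%d",
             size[1], size[2], d[1], d[2])
  off <- (d[1:2] - size) %/% 2L
  out <- vol$data[off[1] + seq_len(size[1]), off[2] + seq_len(size[2]), ,
                  drop = FALSE]
  volume3d(out, spacing = vol$spacing,
           origin = vol$origin + c(off * vol$spacing[1:2], 0))
}
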