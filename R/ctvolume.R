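#' CT volume container
#'
#' Bundles a 3D array of Hounsfield-unit (HU) voxels with its geometric
#' metadata. Voxels are stored as `[row, column, slice]`; in-plane pixel
#' spacing and slice thickness are in millimetres. `slice_range` marks the
#' abdominal section (inclusive 1-based slice indices) that downstream
#' segmentation operates on.
#'
#' @param voxels 3D numeric array of HU values, dims `[row, column, slice]`.
#'   A 2D matrix is promoted to a single-slice volume.
#' @param pixel_spacing numeric pair, in-plane spacing in mm (row, column).
#' @param slice_thickness slice spacing in mm.
#' @param slice_range integer pair of inclusive 1-based slice indices
#'   delimiting the abdominal section; defaults to the full volume.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, pixel_spacing = c(1, 1), slice_thickness = 1,
                      slice_range = NULL) {
  if (is.matrix(voxels)) {
    voxels <- array(voxels, dim = c(dim(voxels), 1L))
  }
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    stop("`voxels` must be a 3D array (row x column x slice)")
  }
  if (any(!is.finite(voxels))) {
    stop("HU values must be finite")
  }
  if (length(pixel_spacing) == 1L) pixel_spacing <- rep(pixel_spacing, 2L)
  if (any(pixel_spacing <= 0) || slice_thickness <= 0) {
    stop("pixel spacing and slice thickness must be > 0")
  }
  n_slices <- dim(voxels)[3L]
  if (is.null(slice_range)) slice_range <- c(1L, n_slices)
  slice_range <- as.integer(slice_range)
  if (length(slice_range) != 2L || slice_range[1L] < 1L ||
      slice_range[2L] > n_slices || slice_range[1L] > slice_range[2L]) {
    stop("`slice_range` must be an increasing pair within 1..", n_slices)
  }
  structure(
    list(voxels = voxels,
         pixel_spacing = as.numeric(pixel_spacing),
         slice_thickness = as.numeric(slice_thickness),
         slice_range = slice_range),
    class = "ct_volume"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat("<ct_volume> ", d[1L], "x", d[2L], " px, ", d[3L], " slice(s)\n", sep = "")
  cat("  pixel spacing: ", paste(x$pixel_spacing, collapse = " x "),
      " mm, slice thickness: ", x$slice_thickness, " mm\n", sep = "")
  cat("  HU range: [", round(min(x$voxels)), ", ", round(max(x$voxels)),
      "], slice range: ", x$slice_range[1L], "..", x$slice_range[2L],
      "\n", sep = "")
  invisible(x)
}

#' Number of slices in a CT volume
#' @param volume a [ct_volume()].
#' @return integer slice count.
#' @export
n_slices <- function(volume) {
  stopifnot(inherits(volume, "ct_volume"))
  dim(volume$voxels)[3L]
}

#' Restrict a volume to a manually chosen abdominal slice range
#'
#' The abdominal section is marked by hand (upper bound just below the lungs,
#' lower bound just above the umbilicus); this operation crops the volume to
#' exactly those slices. Indices are 1-based and inclusive at both ends.
#'
#' @param volume a [ct_volume()].
#' @param upper first slice index to keep (1-based).
#' @param lower last slice index to keep (inclusive, `>= upper`).
#' @return A `ct_volume` holding slices `upper..lower`, with metadata
#'   preserved and `slice_range` covering the whole cropped volume.
#' @export
select_slice_range <- function(volume, upper, lower) {
  stopifnot(inherits(volume, "ct_volume"))
  n <- n_slices(volume)
  upper <- as.integer(upper); lower <- as.integer(lower)
  if (upper < 1L || lower > n || upper > lower) {
    stop("invalid slice range [", upper, ", ", lower, "] for a volume of ",
         n, " slices")
  }
  ct_volume(volume$voxels[, , upper:lower, drop = FALSE],
            pixel_spacing = volume$pixel_spacing,
            slice_thickness = volume$slice_thickness)
}
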