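#' Segmentation parameters
#'
#' Operating points of the four-step fat segmentation scheme. The trunk is
#' delimited by line scans stopping at the first pixel strictly above
#' `body_threshold`; fat is the inclusive HU band `[fat_low, fat_high]`
#' (-140 to -40 HU, the standard adipose range); non-fat components smaller
#' than `min_component_size` pixels are treated as specks inside the
#' subcutaneous ring and discarded before the visceral mask is built by
#' dilation, hole filling, and erosion with disk structuring elements.
#'
#' @param body_threshold HU threshold for the trunk line scans.
#' @param fat_low,fat_high inclusive HU bounds of the fat band.
#' @param min_component_size minimum 4-connected non-fat component size, px.
#' @param dilation_radius,erosion_radius disk radii in pixels for the
#'   morphological bracket around hole filling.
#' @return A validated `seg_params` list.
#' @export
seg_params <- function(body_threshold = -140, fat_low = -140, fat_high = -40,
                       min_component_size = 200, dilation_radius = 3,
                       erosion_radius = 3) {
  p <- list(body_threshold = body_threshold, fat_low = fat_low,
            fat_high = fat_high,
            min_component_size = as.integer(min_component_size),
            dilation_radius = as.integer(dilation_radius),
            erosion_radius = as.integer(erosion_radius))
  if (p$fat_low > p$fat_high) stop("`fat_low` must be <= `fat_high`")
  if (p$dilation_radius < 1L || p$erosion_radius < 1L) {
    stop("morphological radii must be >= 1 pixel")
  }
  if (p$min_component_size < 0L) stop("`min_component_size` must be >= 0")
  class(p) <- "seg_params"
  p
}

.disk_brush <- function(radius) {
  EBImage::makeBrush(2L * radius + 1L, shape = "disc")
}

# largest 4-connected component of a logical matrix (empty in, empty out)
.largest_component <- function(mask) {
  if (!any(mask)) return(mask)
  storage.mode(mask) <- "integer"
  lab <- EBImage::bwlabel(mask)
  counts <- tabulate(lab[lab > 0])
  lab == which.max(counts)
}

# fill interior holes: background components not touching the image border
.fill_holes <- function(mask) {
  storage.mode(mask) <- "integer"
  as.matrix(EBImage::fillHull(mask)) > 0
}

#' Detect the body trunk mask on one slice
#'
#' Scans each row left-to-right and right-to-left, and each column
#' top-to-bottom and bottom-to-top, stopping at the first pixel with HU
#' strictly greater than `body_threshold`. Pixels between the two stopping
#' points of a row (column) are row (column) candidates; the trunk is the
#' intersection of the row- and column-candidate sets, restricted to its
#' largest 4-connected component (which drops the CT bed, a separate
#' component), with interior holes filled.
#'
#' @param slice_image 2D HU matrix (>= 2 rows and columns).
#' @param params a [seg_params()].
#' @return Logical matrix: the trunk mask (all `FALSE` when no pixel exceeds
#'   the threshold).
#' @export
detect_trunk_mask <- function(slice_image, params = seg_params()) {
  if (!is.matrix(slice_image) || any(dim(slice_image) < 2L)) {
    stop("`slice_image` must be a matrix with at least 2 rows and columns")
  }
  above <- slice_image > params$body_threshold
  if (!any(above)) return(matrix(FALSE, nrow(slice_image), ncol(slice_image)))

  span_mask <- function(hits) {
    # hits: logical matrix; returns mask of pixels between the first and the
    # last hit of each row (rows with no hit stay empty)
    out <- matrix(FALSE, nrow(hits), ncol(hits))
    for (i in seq_len(nrow(hits))) {
      w <- which(hits[i, ])
      if (length(w) > 0L) out[i, w[1L]:w[length(w)]] <- TRUE
    }
    out
  }
  rows_cand <- span_mask(above)
  cols_cand <- t(span_mask(t(above)))
  .fill_holes(.largest_component(rows_cand & cols_cand))
}

#' Split the trunk into fat and non-fat masks
#'
#' Fat pixels are trunk pixels whose HU lies in the inclusive band
#' `[fat_low, fat_high]`; everything else in the trunk is non-fat. Trunk
#' pixels below -140 HU (bowel gas) therefore land in the non-fat mask and
#' are later covered by the visceral mask rather than counted as fat.
#'
#' @param slice_image 2D HU matrix.
#' @param trunk logical trunk mask of the same shape.
#' @param params a [seg_params()].
#' @return List of logical matrices `fat` and `nonfat`; they are disjoint and
#'   their union is the trunk.
#' @export
segment_fat_nonfat <- function(slice_image, trunk, params = seg_params()) {
  if (!identical(dim(slice_image), dim(trunk))) {
    stop("`trunk` must have the same shape as `slice_image`")
  }
  fat <- trunk & slice_image >= params$fat_low & slice_image <= params$fat_high
  list(fat = fat, nonfat = trunk & !fat)
}

#' Build the visceral region mask from the non-fat mask
#'
#' Pipeline: (1) label 4-connected components of the non-fat mask;
#' (2) delete components smaller than `min_component_size` pixels;
#' (3) dilate with a disk of `dilation_radius`, closing gaps between the
#' muscle wall and interior structures; (4) fill interior holes;
#' (5) erode with a disk of `erosion_radius`. The result covers the whole
#' visceral region (muscle wall and everything inside it).
#'
#' @param nonfat logical non-fat mask.
#' @param params a [seg_params()].
#' @return Logical visceral region mask.
#' @export
build_visceral_mask <- function(nonfat, params = seg_params()) {
  stopifnot(is.matrix(nonfat))
  if (!any(nonfat)) return(nonfat & FALSE)
  nonfat_int <- nonfat
  storage.mode(nonfat_int) <- "integer"
  lab <- EBImage::bwlabel(nonfat_int)
  counts <- tabulate(lab[lab > 0])
  keep <- which(counts >= params$min_component_size)
  mask <- matrix(lab %in% keep, nrow(nonfat), ncol(nonfat))
  if (!any(mask)) return(mask)
  storage.mode(mask) <- "integer"
  mask <- EBImage::dilate(mask, .disk_brush(params$dilation_radius))
  mask <- EBImage::fillHull(mask)
  mask <- EBImage::erode(mask, .disk_brush(params$erosion_radius))
  as.matrix(mask) > 0
}

#' Split the fat mask into visceral and subcutaneous compartments
#'
#' AND-logic split: VFA is fat inside the visceral region mask; SFA is fat in
#' the trunk outside it. The two compartments are disjoint and their union is
#' the fat mask.
#'
#' @param fat,visceral,trunk logical masks of identical shape.
#' @return List of logical matrices `vfa` and `sfa`.
#' @export
split_fat_compartments <- function(fat, visceral, trunk) {
  if (!identical(dim(fat), dim(visceral)) || !identical(dim(fat), dim(trunk))) {
    stop("`fat`, `visceral` and `trunk` must share the same shape")
  }
  list(vfa = fat & visceral, sfa = fat & trunk & !visceral)
}

#' Segment a CT volume into adiposity compartments
#'
#' Applies the four per-slice steps (trunk detection, fat/non-fat
#' thresholding, visceral mask construction, AND-logic compartment split)
#' independently to every slice in the volume's `slice_range` and collects
#' per-slice masks and pixel counts.
#'
#' @param volume a [ct_volume()] with its abdominal `slice_range` set.
#' @param params a [seg_params()].
#' @return A `segmentation_result`: list with `masks` (logical arrays
#'   `trunk`, `fat`, `nonfat`, `visceral`, `vfa`, `sfa` over the selected
#'   slices), `counts` (per-slice pixel counts data.frame), `voxels` (HU of
#'   the selected slices), `pixel_spacing`, `slice_thickness`, and `params`.
#' @export
segment_case <- function(volume, params = seg_params()) {
  stopifnot(inherits(volume, "ct_volume"))
  idx <- volume$slice_range[1L]:volume$slice_range[2L]
  if (length(idx) == 0L) stop("empty slice range")
  d <- dim(volume$voxels)[1:2]
  nm <- c("trunk", "fat", "nonfat", "visceral", "vfa", "sfa")
  masks <- stats::setNames(
    lapply(nm, function(.) array(FALSE, dim = c(d, length(idx)))), nm)
  for (j in seq_along(idx)) {
    sl <- volume$voxels[, , idx[j]]
    trunk <- detect_trunk_mask(sl, params)
    fn <- segment_fat_nonfat(sl, trunk, params)
    visceral <- build_visceral_mask(fn$nonfat, params)
    comp <- split_fat_compartments(fn$fat, visceral, trunk)
    masks$trunk[, , j] <- trunk
    masks$fat[, , j] <- fn$fat
    masks$nonfat[, , j] <- fn$nonfat
    masks$visceral[, , j] <- visceral
    masks$vfa[, , j] <- comp$vfa
    masks$sfa[, , j] <- comp$sfa
  }
  counts <- data.frame(
    slice = idx,
    trunk = apply(masks$trunk, 3L, sum), fat = apply(masks$fat, 3L, sum),
    nonfat = apply(masks$nonfat, 3L, sum),
    visceral = apply(masks$visceral, 3L, sum),
    vfa = apply(masks$vfa, 3L, sum), sfa = apply(masks$sfa, 3L, sum))
  structure(
    list(masks = masks, counts = counts,
         voxels = volume$voxels[, , idx, drop = FALSE],
         pixel_spacing = volume$pixel_spacing,
         slice_thickness = volume$slice_thickness, params = params),
    class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat("<segmentation_result> ", nrow(x$counts), " slice(s)\n", sep = "")
  cat("  total pixels: trunk ", sum(x$counts$trunk), ", SFA ",
      sum(x$counts$sfa), ", VFA ", sum(x$counts$vfa), "\n", sep = "")
  invisible(x)
}

#' Dice similarity coefficient between two binary masks
#'
#' `2|A n B| / (|A| + |B|)`, computed by direct pixel counting. Two empty
#' masks have Dice 1 by convention.
#'
#' @param a,b logical arrays of identical shape.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
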