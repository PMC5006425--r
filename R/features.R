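#' Compute the adiposity feature vector for one case
#'
#' Seven descriptors summarizing body composition over the selected
#' abdominal slices:
#' \describe{
#'   \item{f1}{body mass index, kg/m^2 (supplied, not derived from the image)}
#'   \item{f2}{SFA/body ratio: total subcutaneous fat pixels over total trunk
#'     pixels}
#'   \item{f3}{VFA/body ratio, analogous}
#'   \item{f4, f5}{mean and SD of the HU of all SFA pixels, pooled across
#'     slices}
#'   \item{f6, f7}{mean and SD of the HU of all VFA pixels, pooled across
#'     slices}
#'   \item{f8}{optional SFA/VFA pixel-count ratio, off by default}
#' }
#' SDs use the population divisor (N). An empty SFA (VFA) compartment leaves
#' f4/f5 (f6/f7) as `NA`; f8 with an empty VFA is an error.
#'
#' @param seg a `segmentation_result` from [segment_case()].
#' @param bmi body mass index, kg/m^2.
#' @param include_ratio also compute f8 (SFA/VFA ratio).
#' @return Named numeric vector `f1..f7` (and `f8` when requested).
#' @export
compute_features <- function(seg, bmi, include_ratio = FALSE) {
  stopifnot(inherits(seg, "segmentation_result"))
  trunk_px <- sum(seg$counts$trunk)
  if (trunk_px == 0) stop("segmentation contains no trunk pixels")
  sfa_px <- sum(seg$counts$sfa)
  vfa_px <- sum(seg$counts$vfa)
  sfa_hu <- seg$voxels[seg$masks$sfa]
  vfa_hu <- seg$voxels[seg$masks$vfa]
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  fv <- c(
    f1 = as.numeric(bmi),
    f2 = sfa_px / trunk_px,
    f3 = vfa_px / trunk_px,
    f4 = if (sfa_px > 0) mean(sfa_hu) else NA_real_,
    f5 = if (sfa_px > 0) pop_sd(sfa_hu) else NA_real_,
    f6 = if (vfa_px > 0) mean(vfa_hu) else NA_real_,
    f7 = if (vfa_px > 0) pop_sd(vfa_hu) else NA_real_)
  if (include_ratio) {
    if (vfa_px == 0) stop("cannot compute SFA/VFA ratio: no VFA pixels")
    fv <- c(fv, f8 = sfa_px / vfa_px)
  }
  fv
}

#' Convert a mask pixel count to an area in cm^2
#'
#' @param count number of pixels (>= 0).
#' @param spacing in-plane pixel spacing in mm; a single value is treated as
#'   isotropic.
#' @return Area in cm^2: `count * spacing_x * spacing_y / 100`.
#' @export
area_cm2 <- function(count, spacing) {
  if (any(count < 0)) stop("pixel count must be >= 0")
  if (length(spacing) == 1L) spacing <- rep(spacing, 2L)
  if (any(spacing <= 0)) stop("pixel spacing must be > 0")
  count * spacing[1L] * spacing[2L] / 100
}
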