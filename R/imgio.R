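#' Read a CT volume from NIfTI or a DICOM series directory
#'
#' A path ending in `.nii`/`.nii.gz` is read with RNifti; a directory is
#' treated as a single DICOM series (one file per slice, uncompressed
#' little-endian). DICOM stored values are converted to Hounsfield units with
#' the per-file rescale slope/intercept, slices are ordered by their spatial
#' position along the scanner axis, and spacing is taken from the header.
#'
#' @param path NIfTI file or DICOM series directory.
#' @return A [ct_volume()].
#' @export
read_volume <- function(path) {
  if (dir.exists(path)) {
    return(read_dicom_series(path))
  }
  if (!file.exists(path)) {
    stop("no such file or directory: ", path)
  }
  if (!grepl("\\.nii(\\.gz)?$", path)) {
    stop("not a recognized volume format (expect .nii, .nii.gz or a DICOM directory): ", path)
  }
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  arr <- as.array(img)
  if (length(dim(arr)) == 2L) arr <- array(arr, dim = c(dim(arr), 1L))
  ct_volume(arr,
            pixel_spacing = pd[1:2],
            slice_thickness = if (length(pd) >= 3L) pd[3L] else 1)
}

#' Write a CT volume to NIfTI
#'
#' HU values are stored as float64 so integer HU round-trip exactly.
#'
#' @param volume a [ct_volume()].
#' @param path output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "ct_volume"))
  img <- RNifti::asNifti(volume$voxels)
  RNifti::pixdim(img) <- c(volume$pixel_spacing, volume$slice_thickness)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Write a segmentation label map to NIfTI
#'
#' Encodes a segmentation as a single label volume: 0 outside the trunk,
#' 1 trunk non-fat ("other"), 2 subcutaneous fat (SFA), 3 visceral fat (VFA).
#'
#' @param seg a `segmentation_result` from [segment_case()], or a list with
#'   binary mask arrays `trunk`, `sfa`, `vfa` of identical dimension.
#' @param path output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_label_map <- function(seg, path) {
  masks <- if (inherits(seg, "segmentation_result")) seg$masks else seg
  lab <- array(0L, dim = dim(masks$trunk))
  lab[masks$trunk > 0] <- 1L
  lab[masks$sfa > 0] <- 2L
  lab[masks$vfa > 0] <- 3L
  img <- RNifti::asNifti(lab)
  if (inherits(seg, "segmentation_result")) {
    RNifti::pixdim(img) <- c(seg$pixel_spacing, seg$slice_thickness)
  }
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Read a label map written by [write_label_map()]
#'
#' @param path NIfTI label map path.
#' @return List of logical arrays `trunk`, `sfa`, `vfa`, `other` (trunk
#'   non-fat).
#' @export
read_label_map <- function(path) {
  lab <- as.array(RNifti::readNifti(path))
  if (!all(lab %in% 0:3)) {
    stop("label map contains values outside the declared set {0,1,2,3}")
  }
  list(trunk = lab >= 1L, sfa = lab == 2L, vfa = lab == 3L, other = lab == 1L)
}

#' Read a per-case metadata table
#'
#' Expects a CSV with columns `case_id`, `bmi`, `pfs_months`, `os_months`;
#' optional columns `upper_slice`, `lower_slice` (manual abdominal slice
#' range, 1-based inclusive) and `manual_sfa_cm2`, `manual_vfa_cm2`
#' (radiologist single-slice areas).
#'
#' @param path CSV file path.
#' @return A data.frame, one row per case, with the optional columns present
#'   only when found in the file.
#' @export
read_case_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("case_id", "bmi", "pfs_months", "os_months")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("case table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df$case_id <- as.character(df$case_id)
  numeric_cols <- intersect(
    c("bmi", "pfs_months", "os_months", "upper_slice", "lower_slice",
      "manual_sfa_cm2", "manual_vfa_cm2"),
    names(df))
  for (col in numeric_cols) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.na(df[[col]]) & df[[col]] != "" & is.na(vals))
    if (length(bad) > 0L) {
      stop("non-numeric value in column '", col, "' at row ", bad[1L],
           ": '", df[[col]][bad[1L]], "'")
    }
    df[[col]] <- vals
  }
  bad_bmi <- which(!is.na(df$bmi) & df$bmi <= 0)
  if (length(bad_bmi) > 0L) {
    stop("BMI must be > 0 (row ", bad_bmi[1L], ")")
  }
  for (col in c("pfs_months", "os_months")) {
    bad <- which(!is.na(df[[col]]) & df[[col]] < 0)
    if (length(bad) > 0L) stop(col, " must be >= 0 (row ", bad[1L], ")")
  }
  df
}
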