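# Minimal DICOM reader: uncompressed little-endian single-frame CT series.
# Supports explicit-VR (1.2.840.10008.1.2.1) and implicit-VR (1.2.840.10008.1.2)
# transfer syntaxes, which covers what CT scanners export for axial series.

TS_IMPLICIT_LE <- "1.2.840.10008.1.2"
TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

# VRs whose explicit encoding carries a 2-byte reserved field + 4-byte length
.long_vrs <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")

read_uint16 <- function(raw, at) {
  readBin(raw[at:(at + 1L)], "integer", n = 1L, size = 2L,
          signed = FALSE, endian = "little")
}

read_uint32 <- function(raw, at) {
  # avoid readBin size-4 sign issues for lengths >= 2^31 (undefined length)
  sum(as.integer(raw[at:(at + 3L)]) * c(1, 256, 65536, 16777216))
}

# Parses one data element at `at`; returns list(group, element, vr, value_at,
# length, next_at). `explicit` selects the VR encoding.
.dicom_element <- function(raw, at, explicit) {
  group <- read_uint16(raw, at)
  element <- read_uint16(raw, at + 2L)
  if (explicit) {
    vr <- rawToChar(raw[(at + 4L):(at + 5L)])
    if (vr %in% .long_vrs) {
      len <- read_uint32(raw, at + 8L)
      value_at <- at + 12L
    } else {
      len <- read_uint16(raw, at + 6L)
      value_at <- at + 8L
    }
  } else {
    vr <- NA_character_
    len <- read_uint32(raw, at + 4L)
    value_at <- at + 8L
  }
  if (len == 4294967295) {
    stop("undefined-length DICOM element (",
         sprintf("%04x,%04x", group, element),
         "): compressed or sequence data is not supported")
  }
  list(group = group, element = element, vr = vr,
       value_at = value_at, length = len, next_at = value_at + len)
}

.dicom_string <- function(raw, el) {
  if (el$length == 0L) return("")
  bytes <- raw[el$value_at:(el$value_at + el$length - 1L)]
  bytes <- bytes[bytes != as.raw(0L)]  # strip UI padding nulls
  trimws(rawToChar(bytes))
}

.dicom_numeric <- function(raw, el) {
  as.numeric(strsplit(.dicom_string(raw, el), "\\\\")[[1L]])
}

.dicom_uint16_value <- function(raw, el) read_uint16(raw, el$value_at)

# Reads the tags needed to reconstruct HU slices from one DICOM file.
parse_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 140L || rawToChar(raw[129:132]) != "DICM") {
    stop("not a DICOM file (missing DICM magic): ", path)
  }
  at <- 133L
  transfer_syntax <- TS_EXPLICIT_LE
  # file meta group (0002,xxxx) is always explicit little-endian
  repeat {
    if (at + 7L > length(raw)) stop("truncated DICOM file: ", path)
    if (read_uint16(raw, at) != 2L) break
    el <- .dicom_element(raw, at, explicit = TRUE)
    if (el$element == 0x0010) transfer_syntax <- .dicom_string(raw, el)
    at <- el$next_at
  }
  explicit <- switch(transfer_syntax,
    "1.2.840.10008.1.2.1" = TRUE,
    "1.2.840.10008.1.2" = FALSE,
    stop("unsupported DICOM transfer syntax '", transfer_syntax, "' in ", path)
  )
  out <- list(path = path)
  while (at + 7L <= length(raw)) {
    el <- .dicom_element(raw, at, explicit)
    key <- sprintf("%04x%04x", el$group, el$element)
    if (key == "7fe00010") {
      out$pixel_data <- raw[el$value_at:(el$value_at + el$length - 1L)]
    } else if (key == "00280010") {
      out$rows <- .dicom_uint16_value(raw, el)
    } else if (key == "00280011") {
      out$cols <- .dicom_uint16_value(raw, el)
    } else if (key == "00280100") {
      out$bits_allocated <- .dicom_uint16_value(raw, el)
    } else if (key == "00280103") {
      out$pixel_representation <- .dicom_uint16_value(raw, el)
    } else if (key == "00280030") {
      out$pixel_spacing <- .dicom_numeric(raw, el)
    } else if (key == "00180050") {
      out$slice_thickness <- .dicom_numeric(raw, el)[1L]
    } else if (key == "00281052") {
      out$rescale_intercept <- .dicom_numeric(raw, el)[1L]
    } else if (key == "00281053") {
      out$rescale_slope <- .dicom_numeric(raw, el)[1L]
    } else if (key == "00200032") {
      out$image_position <- .dicom_numeric(raw, el)
    } else if (key == "00200013") {
      out$instance_number <- as.integer(.dicom_numeric(raw, el)[1L])
    } else if (key == "0020000e") {
      out$series_uid <- .dicom_string(raw, el)
    }
    at <- el$next_at
  }
  for (field in c("rows", "cols", "pixel_data")) {
    if (is.null(out[[field]])) {
      stop("DICOM file lacks required tag (", field, "): ", path)
    }
  }
  if (is.null(out$rescale_slope) || is.null(out$rescale_intercept)) {
    stop("DICOM file lacks rescale slope/intercept tags, cannot convert to HU: ",
         path)
  }
  out
}

# Decodes the stored pixel array of a parsed file and applies the HU rescale.
.dicom_hu_matrix <- function(info) {
  bits <- if (is.null(info$bits_allocated)) 16L else info$bits_allocated
  if (bits != 16L) {
    stop("only 16-bit DICOM pixel data is supported: ", info$path)
  }
  signed <- !is.null(info$pixel_representation) && info$pixel_representation == 1L
  n <- info$rows * info$cols
  stored <- readBin(info$pixel_data, "integer", n = n, size = 2L,
                    signed = signed, endian = "little")
  if (length(stored) < n) stop("truncated pixel data: ", info$path)
  # DICOM pixel order is row-major (first row left-to-right, then next row)
  hu <- stored * info$rescale_slope + info$rescale_intercept
  matrix(hu, nrow = info$rows, ncol = info$cols, byrow = TRUE)
}

#' Read a directory holding one DICOM series
#'
#' All files in the directory must belong to the same series; slices are
#' ordered by the z component of Image Position (Patient), falling back to
#' Instance Number. Stored values are converted to HU via each file's rescale
#' slope and intercept.
#'
#' @param dir directory containing one `.dcm` file per slice.
#' @return A [ct_volume()].
#' @export
read_dicom_series <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) stop("no files in DICOM directory: ", dir)
  infos <- lapply(files, parse_dicom_file)
  uids <- unique(vapply(infos, function(i) i$series_uid %||% "", ""))
  if (length(uids) > 1L) {
    stop("directory mixes multiple DICOM series: ", paste(uids, collapse = ", "))
  }
  z <- vapply(infos, function(i) {
    if (!is.null(i$image_position)) i$image_position[3L]
    else if (!is.null(i$instance_number)) as.numeric(i$instance_number)
    else NA_real_
  }, 0)
  if (anyNA(z)) {
    stop("DICOM series lacks Image Position (Patient) and Instance Number; ",
         "cannot order slices")
  }
  infos <- infos[order(z)]
  slices <- lapply(infos, .dicom_hu_matrix)
  dims <- unique(t(vapply(slices, dim, integer(2L))))
  if (nrow(dims) > 1L) stop("DICOM series has inconsistent slice dimensions")
  vol <- array(unlist(slices), dim = c(dim(slices[[1L]]), length(slices)))
  spacing <- infos[[1L]]$pixel_spacing %||% c(1, 1)
  zs <- sort(z)
  thickness <- if (length(zs) > 1L && !is.null(infos[[1L]]$image_position)) {
    stats::median(diff(zs))
  } else {
    infos[[1L]]$slice_thickness %||% 1
  }
  ct_volume(vol, pixel_spacing = spacing, slice_thickness = thickness)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
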