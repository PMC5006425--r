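# Small phantom for fast unit tests: 96^2 px at 2.5 mm, 2 slices.
tiny_phantom_cfg <- function(...) {
  defaults <- list(image_size = 96, n_slices = 2, pixel_spacing = 2.5,
                   body_semiaxes = c(90, 70), sfa_thickness = 15,
                   muscle_wall_thickness = 8)
  do.call(phantom_config, utils::modifyList(defaults, list(...)))
}

# The ground-truth visceral region: everything inside the subcutaneous ring
# (visceral fat plus all interior non-fat structures: muscle wall, organs,
# gas), which is what the constructed visceral mask is meant to cover.
truth_visceral <- function(truth) truth$vfa | truth$nonfat

# Writes a tiny CT DICOM series with pydicom (independent writer oracle).
# `slices` is a list of lists: stored (matrix), slope, intercept, z.
write_dicom_fixture <- function(dir, slices, series = "1.2.3.4",
                                spacing = c(0.8, 0.7)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spec <- list(dir = dir, series = series, spacing = spacing,
               slices = lapply(slices, function(s) {
                 list(stored = as.vector(t(s$stored)), rows = nrow(s$stored),
                      cols = ncol(s$stored), slope = s$slope,
                      intercept = s$intercept, z = s$z)
               }))
  spec_json <- jsonlite::toJSON(spec, auto_unbox = TRUE, digits = NA)
  script <- '
import json, sys
import numpy as np
import pydicom
from pydicom.dataset import Dataset, FileMetaDataset
from pydicom.uid import ExplicitVRLittleEndian, generate_uid

spec = json.loads(sys.stdin.read())
outdir = spec["dir"]
for i, sl in enumerate(spec["slices"]):
    fm = FileMetaDataset()
    fm.MediaStorageSOPClassUID = pydicom.uid.CTImageStorage
    fm.MediaStorageSOPInstanceUID = generate_uid()
    fm.TransferSyntaxUID = ExplicitVRLittleEndian
    ds = Dataset()
    ds.file_meta = fm
    ds.SOPClassUID = fm.MediaStorageSOPClassUID
    ds.SOPInstanceUID = fm.MediaStorageSOPInstanceUID
    ds.SeriesInstanceUID = spec["series"]
    ds.Rows, ds.Columns = sl["rows"], sl["cols"]
    ds.BitsAllocated = ds.BitsStored = 16
    ds.HighBit = 15
    ds.PixelRepresentation = 0
    ds.SamplesPerPixel = 1
    ds.PhotometricInterpretation = "MONOCHROME2"
    ds.PixelSpacing = [str(x) for x in spec["spacing"]]
    ds.SliceThickness = "5.0"
    ds.RescaleSlope = str(sl["slope"])
    ds.RescaleIntercept = str(sl["intercept"])
    ds.ImagePositionPatient = ["0", "0", str(sl["z"])]
    ds.InstanceNumber = i + 1
    arr = np.array(sl["stored"], dtype=np.uint16).reshape(sl["rows"], sl["cols"])
    ds.PixelData = arr.tobytes()
    ds.save_as(f"{outdir}/sl{i}.dcm", enforce_file_format=True)
print("ok")
'
  out <- suppressWarnings(system2("python", c("-c", shQuote(script)),
                                  input = spec_json,
                                  stdout = TRUE, stderr = TRUE))
  if (!any(grepl("^ok$", out))) {
    stop("pydicom fixture writer failed: ", paste(out, collapse = "\n"))
  }
  invisible(dir)
}
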