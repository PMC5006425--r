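test_that("NIfTI volume write/read round-trips HU values and spacing", {
  ph <- generate_phantom(tiny_phantom_cfg())
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(ph$volume, path)
  v2 <- read_volume(path)
  expect_equal(as.array(v2$voxels), ph$volume$voxels, ignore_attr = TRUE)
  expect_equal(v2$pixel_spacing, ph$volume$pixel_spacing)
  expect_equal(v2$slice_thickness, ph$volume$slice_thickness)
})

test_that("label maps carry only the declared labels and round-trip masks", {
  ph <- generate_phantom(tiny_phantom_cfg())
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_label_map(list(trunk = ph$truth$trunk, sfa = ph$truth$sfa,
                       vfa = ph$truth$vfa), path)
  raw <- as.array(RNifti::readNifti(path))
  expect_true(all(raw %in% 0:3))
  lm <- read_label_map(path)
  expect_identical(lm$sfa, ph$truth$sfa)
  expect_identical(lm$vfa, ph$truth$vfa)
  expect_identical(lm$trunk, ph$truth$trunk)
})

test_that("slice-range selection keeps exactly the requested slices", {
  vol <- ct_volume(array(seq_len(4 * 4 * 10), dim = c(4, 4, 10)))
  expect_equal(n_slices(select_slice_range(vol, 1, 10)), 10)
  expect_equal(select_slice_range(vol, 1, 10)$voxels, vol$voxels)

  sub <- select_slice_range(vol, 3, 5)
  expect_equal(n_slices(sub), 3)
  expect_equal(sub$voxels[, , 1], vol$voxels[, , 3])

  expect_error(select_slice_range(vol, 5, 3), "invalid slice range")
  expect_error(select_slice_range(vol, 0, 3), "invalid slice range")
  expect_error(select_slice_range(vol, 8, 11), "invalid slice range")
})

test_that("case tables are validated row by row", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(case_id = sprintf("c%02d", 1:32), bmi = runif(32, 18, 40),
                   pfs_months = runif(32, 1, 60), os_months = runif(32, 1, 80))
  write.csv(df, path, row.names = FALSE)
  tab <- read_case_table(path)
  expect_equal(nrow(tab), 32)
  expect_false("manual_sfa_cm2" %in% names(tab))

  df_bad <- df; df_bad$bmi <- as.character(df_bad$bmi); df_bad$bmi[7] <- "abc"
  write.csv(df_bad, path, row.names = FALSE)
  expect_error(read_case_table(path), "row 7")

  write.csv(df[, -2], path, row.names = FALSE)
  expect_error(read_case_table(path), "bmi")
})

test_that("DICOM series read applies the rescale and orders slices spatially", {
  dir <- withr::local_tempdir()
  slices <- list(
    list(stored = matrix(924, 4, 4), slope = 1, intercept = -1024, z = 10),
    list(stored = matrix(430, 4, 4), slope = 2, intercept = -1000, z = 0))
  write_dicom_fixture(dir, slices)
  vol <- read_volume(dir)
  expect_equal(dim(vol$voxels), c(4, 4, 2))
  # z = 0 slice comes first despite being written second
  expect_equal(vol$voxels[1, 1, 1], 430 * 2 - 1000)  # -140 HU
  expect_equal(vol$voxels[1, 1, 2], 924 * 1 - 1024)  # -100 HU
  expect_equal(vol$pixel_spacing, c(0.8, 0.7))
})

test_that("mixed DICOM series in one directory is a format error", {
  dir <- withr::local_tempdir()
  write_dicom_fixture(file.path(dir, "a"),
                      list(list(stored = matrix(0, 2, 2), slope = 1,
                                intercept = 0, z = 0)),
                      series = "1.2.3.4")
  write_dicom_fixture(file.path(dir, "b"),
                      list(list(stored = matrix(0, 2, 2), slope = 1,
                                intercept = 0, z = 5)),
                      series = "9.8.7.6")
  file.copy(file.path(dir, "a", "sl0.dcm"), file.path(dir, "s1.dcm"))
  file.copy(file.path(dir, "b", "sl0.dcm"), file.path(dir, "s2.dcm"))
  expect_error(read_dicom_series(dir), "multiple DICOM series")
})

test_that("non-image files are rejected with a format error", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines("not an image", path)
  expect_error(read_volume(path), "not a recognized volume format")
  dir <- withr::local_tempdir()
  writeLines("junk", file.path(dir, "x.dcm"))
  expect_error(read_volume(dir), "DICOM")
})
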