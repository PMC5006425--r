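test_that("trunk detection handles uniform slices", {
  expect_equal(detect_trunk_mask(matrix(-1000, 32, 32)),
               matrix(FALSE, 32, 32))
  expect_equal(detect_trunk_mask(matrix(0, 32, 32)), matrix(TRUE, 32, 32))
})

test_that("trunk detection recovers the phantom body and excludes the bed", {
  ph <- generate_phantom(tiny_phantom_cfg(include_bed = TRUE))
  sl <- ph$volume$voxels[, , 1]
  trunk <- detect_trunk_mask(sl)
  truth <- ph$truth$trunk[, , 1]
  # agreement within a 1-pixel boundary band
  disagree <- xor(trunk, truth)
  grown <- as.matrix(EBImage::dilate(truth + 0L, EBImage::makeBrush(3, "box"))) > 0
  shrunk <- as.matrix(EBImage::erode(truth + 0L, EBImage::makeBrush(3, "box"))) > 0
  expect_true(all(!disagree | (grown & !shrunk)))
  # the CT bed (HU 0 outside the body) is a separate component and is dropped
  bed <- sl > -140 & !truth
  expect_gt(sum(bed), 0)
  expect_false(any(trunk & bed))
})

test_that("trunk detection is idempotent after masking the background", {
  ph <- generate_phantom(tiny_phantom_cfg())
  sl <- ph$volume$voxels[, , 1]
  trunk <- detect_trunk_mask(sl)
  sl2 <- sl
  sl2[!trunk] <- -1000
  expect_identical(detect_trunk_mask(sl2), trunk)
})

test_that("fat band is inclusive at both ends and partitions the trunk", {
  sl <- matrix(-1000, 8, 8)
  sl[3:6, 3:6] <- 0
  sl[4, 4] <- -140; sl[4, 5] <- -40; sl[5, 4] <- -39; sl[5, 5] <- -90
  sl[6, 6] <- -141
  trunk <- matrix(FALSE, 8, 8); trunk[3:6, 3:6] <- TRUE
  fn <- segment_fat_nonfat(sl, trunk)
  expect_true(fn$fat[4, 4])    # exactly -140 HU is fat
  expect_true(fn$fat[4, 5])    # exactly -40 HU is fat
  expect_true(fn$fat[5, 5])    # interior of the band
  expect_false(fn$fat[5, 4])   # -39 HU just above the band
  expect_true(fn$nonfat[6, 6]) # sub--140 interior pixel (bowel gas) is non-fat
  expect_identical(fn$fat | fn$nonfat, trunk)
  expect_false(any(fn$fat & fn$nonfat))
  expect_error(segment_fat_nonfat(sl, trunk[1:4, ]), "shape")
})

test_that("small non-fat components are filtered before the visceral mask", {
  empty <- matrix(FALSE, 64, 64)
  expect_equal(build_visceral_mask(empty), empty)

  block <- matrix(FALSE, 64, 64)
  block[20:31, 20:31] <- TRUE  # 144 px < 200
  expect_equal(sum(build_visceral_mask(block)), 0)

  big <- matrix(FALSE, 64, 64)
  big[10:40, 10:40] <- TRUE    # 961 px >= 200 survives
  expect_gt(sum(build_visceral_mask(big)), 0)
})

test_that("raising the component-size filter is monotone", {
  set.seed(99)
  mask <- matrix(runif(96 * 96) < 0.35, 96, 96)
  surviving <- function(min_size) {
    m <- mask; storage.mode(m) <- "integer"
    lab <- EBImage::bwlabel(m)
    counts <- tabulate(lab[lab > 0])
    sum(counts >= min_size)
  }
  sizes <- c(0, 5, 20, 50, 200, 1000)
  n_comp <- vapply(sizes, surviving, 0)
  expect_true(all(diff(n_comp) <= 0))
})

test_that("compartment split obeys AND logic in degenerate cases", {
  ph <- generate_phantom(tiny_phantom_cfg())
  sl <- ph$volume$voxels[, , 1]
  trunk <- detect_trunk_mask(sl)
  fn <- segment_fat_nonfat(sl, trunk)
  none <- matrix(FALSE, nrow(sl), ncol(sl))
  comp <- split_fat_compartments(fn$fat, none, trunk)
  expect_identical(comp$sfa, fn$fat)
  expect_equal(sum(comp$vfa), 0)
  comp2 <- split_fat_compartments(fn$fat, trunk, trunk)
  expect_identical(comp2$vfa, fn$fat)
  expect_equal(sum(comp2$sfa), 0)
  expect_error(split_fat_compartments(fn$fat, none[1:4, ], trunk), "shape")
})

test_that("full pipeline reproduces phantom ground truth", {
  ph <- generate_phantom(tiny_phantom_cfg(include_gas_pockets = TRUE))
  seg <- segment_case(ph$volume)
  tr <- ph$truth
  expect_gte(dice_coefficient(seg$masks$sfa, tr$sfa), 0.95)
  expect_gte(dice_coefficient(seg$masks$vfa, tr$vfa), 0.95)
  expect_gte(dice_coefficient(seg$masks$visceral, truth_visceral(tr)), 0.90)
  # identical slices give identical per-slice counts
  expect_equal(length(unique(seg$counts$vfa)), 1L)
  # mask partition invariants on every slice
  expect_identical(seg$masks$fat | seg$masks$nonfat, seg$masks$trunk)
  expect_false(any(seg$masks$fat & seg$masks$nonfat))
  expect_identical(seg$masks$vfa | seg$masks$sfa, seg$masks$fat)
  expect_false(any(seg$masks$vfa & seg$masks$sfa))
  expect_false(any(seg$masks$vfa & !seg$masks$visceral))
})

test_that("segment_case composes the four single-slice operations", {
  ph <- generate_phantom(tiny_phantom_cfg(n_slices = 1, hu_noise_sd = 5))
  seg <- segment_case(ph$volume)
  sl <- ph$volume$voxels[, , 1]
  trunk <- detect_trunk_mask(sl)
  fn <- segment_fat_nonfat(sl, trunk)
  visceral <- build_visceral_mask(fn$nonfat)
  comp <- split_fat_compartments(fn$fat, visceral, trunk)
  expect_equal(seg$masks$trunk[, , 1], trunk)
  expect_equal(seg$masks$vfa[, , 1], comp$vfa)
  expect_equal(seg$masks$sfa[, , 1], comp$sfa)
})

test_that("truncated noise does not move fat pixels across the thresholds", {
  ph <- generate_phantom(tiny_phantom_cfg(hu_noise_sd = 5, seed = 8))
  seg <- segment_case(ph$volume)
  truth_fat <- sum(ph$truth$sfa) + sum(ph$truth$vfa)
  got_fat <- sum(seg$counts$vfa) + sum(seg$counts$sfa)
  expect_lt(abs(got_fat - truth_fat) / truth_fat, 0.02)
})
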