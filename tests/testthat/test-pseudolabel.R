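test_that("pseudo-label thresholding follows the HU interval and lung gate", {
  vox <- array(0, c(4, 4, 1))
  vox[1, 1, 1] <- -500    # inside interval, inside lung
  vox[2, 1, 1] <- -800    # below interval
  vox[3, 1, 1] <- -300    # inside interval but outside lung
  vox[4, 1, 1] <- 50      # inclusive upper bound
  vox[1, 2, 1] <- -750    # inclusive lower bound
  vox[2, 2, 1] <- 51      # just above
  lung <- array(1L, c(4, 4, 1)); lung[3, 1, 1] <- 0L
  pl <- generate_pseudolabel(hu_volume(vox), label_mask(lung, role = "lung"))
  expect_equal(pl$voxels[1, 1, 1], 1L)
  expect_equal(pl$voxels[2, 1, 1], 0L)
  expect_equal(pl$voxels[3, 1, 1], 0L)   # lung gating
  expect_equal(pl$voxels[4, 1, 1], 1L)
  expect_equal(pl$voxels[1, 2, 1], 1L)
  expect_equal(pl$voxels[2, 2, 1], 0L)
  expect_equal(pl$role, "pseudo")
})

test_that("toy volume with 5 in-interval in-lung voxels yields count 5", {
  set.seed(2)
  vox <- array(-1000, c(4, 4, 1))
  vox[c(1, 3, 6, 7, 12)] <- c(-700, -100, 0, -400, 42)
  lung <- label_mask(array(1L, c(4, 4, 1)), role = "lung")
  pl <- generate_pseudolabel(hu_volume(vox), lung)
  expect_equal(sum(pl$voxels), 5)
})

test_that("pseudo-label is always a subset of the lung mask", {
  for (s in 1:5) {
    ph <- test_phantom(seed = s)
    pl <- generate_pseudolabel(ph$volume, ph$lung)
    expect_true(all(pl$voxels <= ph$lung$voxels))
  }
})

test_that("widening the HU interval never shrinks the pseudo-label", {
  ph <- test_phantom(seed = 9)
  widths <- list(c(-500, 0), c(-650, 25), c(-750, 50), c(-900, 100))
  counts <- vapply(widths, function(w) {
    sum(generate_pseudolabel(ph$volume, ph$lung,
                             hu_interval(w[1], w[2]))$voxels)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("subtype classification splits GGO and consolidation at -300 HU", {
  vox <- array(-1000, c(5, 2, 1))
  les <- array(0L, c(5, 2, 1))
  vox[1:5, 1, 1] <- c(-500, -100, -300, -750, 50)
  les[1:5, 1, 1] <- 1L
  st <- classify_lesion_subtypes(hu_volume(vox), label_mask(les))
  expect_equal(st$voxels[1, 1, 1], 1L)  # GGO
  expect_equal(st$voxels[2, 1, 1], 2L)  # consolidation
  expect_equal(st$voxels[3, 1, 1], 2L)  # boundary -300 -> consolidation
  expect_equal(st$voxels[4, 1, 1], 1L)  # GGO lower bound
  expect_equal(st$voxels[5, 1, 1], 2L)  # consolidation upper bound
  expect_equal(st$n_outside, 0L)
})

test_that("subtype counts partition the lesion when HU lies in [-750, 50]", {
  vox <- array(-1000, c(10, 1, 1))
  les <- array(1L, c(10, 1, 1))
  vox[1:10] <- c(rep(-500, 4), rep(-100, 6))   # 4 GGO, 6 consolidation
  st <- classify_lesion_subtypes(hu_volume(vox), label_mask(les))
  expect_equal(sum(st$voxels == 1L), 4)
  expect_equal(sum(st$voxels == 2L), 6)
  expect_equal(sum(st$voxels > 0L), sum(les))

  empty <- classify_lesion_subtypes(hu_volume(vox),
                                    label_mask(array(0L, c(10, 1, 1))))
  expect_true(all(empty$voxels == 0L))
})

test_that("simple_lung_mask recovers phantom lungs and respects borders", {
  ph <- test_phantom(seed = 5, distractors = 0)
  lm <- simple_lung_mask(ph$volume)
  inter <- sum(lm$voxels & ph$lung$voxels)
  uni <- sum(lm$voxels | ph$lung$voxels)
  expect_gte(inter / uni, 0.9)
  # exterior air (connected to the in-plane border) must be excluded
  expect_equal(sum(lm$voxels[1, , ]), 0)
  expect_equal(sum(lm$voxels[, 1, ]), 0)

  solid <- hu_volume(array(40, c(16, 16, 4)))
  empty <- simple_lung_mask(solid)
  expect_equal(sum(empty$voxels), 0)
  expect_true(isTRUE(attr(empty, "warning")))
})

test_that("infection quantification uses voxel volume and flags edge cases", {
  lung <- array(0L, c(20, 10, 10)); lung[1:10, , ] <- 1L   # 1000 voxels
  les <- array(0L, c(20, 10, 10)); les[1:10, 1, 1:10] <- 1L # 100 voxels
  rep <- quantify_infection(label_mask(lung, role = "lung"),
                            label_mask(les), spacing = c(1, 1, 1))
  expect_equal(rep$infection_ratio, 0.1)
  expect_equal(rep$lesion_volume_ml, 0.1)
  expect_equal(rep$lung_volume_ml, 1)

  # single lesion voxel at anisotropic spacing: 0.7 * 0.7 * 5 = 2.45 mm^3
  l1 <- array(0L, c(4, 4, 2)); l1[1, 1, 1] <- 1L
  lung1 <- array(1L, c(4, 4, 2))
  r1 <- quantify_infection(label_mask(lung1, role = "lung"), label_mask(l1),
                           spacing = c(0.7, 0.7, 5))
  expect_equal(r1$lesion_volume_ml * 1000, 2.45, tolerance = 1e-9)

  r0 <- quantify_infection(label_mask(lung1, role = "lung"),
                           label_mask(array(0L, c(4, 4, 2))))
  expect_equal(r0$infection_ratio, 0)
  expect_equal(r0$lesion_volume_ml, 0)

  re <- quantify_infection(label_mask(array(0L, c(4, 4, 2)), role = "lung"),
                           label_mask(l1))
  expect_true(is.na(re$infection_ratio))
  expect_true(re$empty_lung)
  expect_equal(re$n_outside_lung, 1)
})

test_that("GGO and consolidation volumes sum to the lesion volume", {
  ph <- test_phantom(seed = 12)
  st <- classify_lesion_subtypes(ph$volume, ph$lesion)
  rep <- quantify_infection(ph$lung, ph$lesion, st,
                            spacing = ph$volume$spacing)
  vox_ml <- prod(ph$volume$spacing) / 1000
  expect_lte(abs(rep$ggo_volume_ml + rep$consolidation_volume_ml -
                 rep$lesion_volume_ml),
             rep$n_outside_lung * vox_ml + sum(st$n_outside) * vox_ml +
               vox_ml)
})
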