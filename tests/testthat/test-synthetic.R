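test_that("phantom generation is deterministic under its seed", {
  a <- generate_phantom(phantom_spec(seed = 3))
  b <- generate_phantom(phantom_spec(seed = 3))
  expect_identical(a$volume$voxels, b$volume$voxels)
  expect_identical(a$lesion$voxels, b$lesion$voxels)
  c2 <- generate_phantom(phantom_spec(seed = 4))
  expect_false(identical(a$volume$voxels, c2$volume$voxels))
})

test_that("noiseless lesion HU values respect the truncation intervals", {
  sp <- phantom_spec(seed = 8, noise_sd = 0)
  ph <- generate_phantom(sp)
  les_hu <- ph$volume$voxels[ph$lesion$voxels == 1L]
  expect_true(all(les_hu >= -750 & les_hu <= 50))
  st <- ph$subtypes$voxels[ph$lesion$voxels == 1L]
  hu_ggo <- ph$volume$voxels[ph$subtypes$voxels == 1L]
  hu_con <- ph$volume$voxels[ph$subtypes$voxels == 2L]
  expect_true(all(hu_ggo >= -750 & hu_ggo <= -301))
  expect_true(all(hu_con >= -300 & hu_con <= 50))
  expect_true(all(st > 0L))  # every lesion voxel carries a subtype
})

test_that("lesions lie strictly inside the lungs", {
  for (s in 1:5) {
    ph <- test_phantom(seed = s)
    expect_true(all(ph$lesion$voxels <= ph$lung$voxels))
  }
})

test_that("pseudo-label from a noiseless phantom covers the true lesion and
           distractors make it strictly larger", {
  sp <- phantom_spec(seed = 21, noise_sd = 0, distractor_count = 4L)
  ph <- generate_phantom(sp)
  pl <- generate_pseudolabel(ph$volume, ph$lung)
  expect_true(all(pl$voxels >= ph$lesion$voxels))      # superset
  expect_gt(sum(pl$voxels), sum(ph$lesion$voxels))     # strictly larger
  rates <- pseudo_label_noise_rate(ph$lesion, pl)
  expect_gt(rates[["fp"]], 0)
  expect_equal(rates[["fn"]], 0)

  clean_sp <- phantom_spec(seed = 21, noise_sd = 0, distractor_count = 0L)
  clean <- generate_phantom(clean_sp)
  pl0 <- generate_pseudolabel(clean$volume, clean$lung)
  r0 <- pseudo_label_noise_rate(clean$lesion, pl0)
  expect_lte(r0[["fp"]], rates[["fp"]])
})

test_that("more distractors raise the pseudo-label false-positive fraction", {
  fp_at <- function(k) {
    mean(vapply(1:6, function(s) {
      ph <- generate_phantom(phantom_spec(seed = 100 + s,
                                          distractor_count = k))
      pl <- generate_pseudolabel(ph$volume, ph$lung)
      pseudo_label_noise_rate(ph$lesion, pl)[["fp"]]
    }, numeric(1)))
  }
  expect_lt(fp_at(0L), fp_at(6L))
})

test_that("healthy lung parenchyma stays below the pseudo-label interval", {
  sp <- phantom_spec(seed = 31)
  ph <- generate_phantom(sp)
  healthy <- ph$volume$voxels[ph$lung$voxels == 1L & ph$lesion$voxels == 0L]
  # all but a small tail concentrates below -750 + 3 * noise_sd
  expect_gt(mean(healthy < -750 + 3 * sp$noise_sd), 0.95)
})

test_that("pseudo_label_noise_rate matches direct counts", {
  t0 <- array(0L, c(10, 11, 1)); t0[1:100] <- 1L
  p0 <- t0; p0[101:110] <- 1L           # 10 extra -> FP = 10/110
  r <- pseudo_label_noise_rate(label_mask(t0), label_mask(p0))
  expect_equal(r[["fp"]], 10 / 110)
  expect_equal(r[["fn"]], 0)
  expect_equal(pseudo_label_noise_rate(label_mask(t0), label_mask(t0)),
               c(fp = 0, fn = 0))
  d1 <- array(0L, c(4, 4, 1)); d1[1] <- 1L
  d2 <- array(0L, c(4, 4, 1)); d2[2] <- 1L
  expect_equal(pseudo_label_noise_rate(label_mask(d1), label_mask(d2)),
               c(fp = 1, fn = 1))
  rna <- pseudo_label_noise_rate(label_mask(d1),
                                 label_mask(array(0L, c(4, 4, 1))))
  expect_true(is.na(rna[["fp"]]))
})

test_that("generate_dataset writes volumes, masks and a seed manifest", {
  tmp <- withr::local_tempdir()
  mf <- generate_dataset(6, phantom_spec(seed = 40,
                                         shape = c(32L, 32L, 4L)), tmp)
  files <- list.files(tmp)
  expect_equal(sum(grepl("_ct\\.nii\\.gz$", files)), 6)
  expect_equal(sum(grepl("_lung\\.nii\\.gz$", files)), 6)
  expect_equal(sum(grepl("_lesion\\.nii\\.gz$", files)), 6)
  expect_true("manifest.json" %in% files)
  expect_equal(sort(unique(mf$subset)), c("labeled", "pseudo", "test"))
  expect_equal(mf$seed, 40 + 1:6)   # provenance: every case seed recorded
  # pseudo subset ships HU-derived labels
  pseudo_ids <- mf$case[mf$subset == "pseudo"]
  expect_true(all(file.exists(
    file.path(tmp, paste0(pseudo_ids, "_pseudo.nii.gz")))))
  labeled_ids <- mf$case[mf$subset == "labeled"]
  expect_false(any(file.exists(
    file.path(tmp, paste0(labeled_ids, "_pseudo.nii.gz")))))
})
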