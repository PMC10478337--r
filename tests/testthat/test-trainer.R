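make_sets <- function(n_lab = 2, n_pse = 2, seed0 = 300) {
  mk <- function(s, label) {
    ph <- generate_phantom(phantom_spec(seed = s))
    lab <- if (label == "gt") ph$lesion
           else generate_pseudolabel(ph$volume, ph$lung)
    list(volume = ph$volume, label = lab, lung = ph$lung)
  }
  list(labeled = slice_dataset(lapply(seed0 + seq_len(n_lab), mk, "gt")),
       pseudo = slice_dataset(lapply(seed0 + 100 + seq_len(n_pse), mk,
                                     "pseudo")))
}

test_that("augmentation is deterministic, binary-preserving and involutive", {
  set.seed(5)
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  msk <- array(rbinom(64 * 64 * 3, 1, 0.2), c(64, 64, 3))
  a1 <- augment(img, msk, seed = 9)
  a2 <- augment(img, msk, seed = 9)
  expect_identical(a1, a2)
  expect_true(all(a1$masks %in% c(0, 1)))
  # flipping twice restores the original slice
  flip <- function(m) m[rev(seq_len(nrow(m))), ]
  expect_identical(flip(flip(img[, , 1])), img[, , 1])
  a3 <- augment(img, msk, seed = 10)
  expect_false(identical(a1$images, a3$images))
})

test_that("short training runs are reproducible and fully logged", {
  sets <- make_sets()
  cfg <- train_config(iters = 8, seed = 21, atst = list(window_len = 5L))
  f1 <- train(cfg, sets$labeled, sets$pseudo)
  f2 <- train(cfg, sets$labeled, sets$pseudo)
  expect_identical(f1$clean, f2$clean)
  expect_identical(f1$noisy, f2$noisy)
  expect_identical(f1$log, f2$log)
  expect_equal(nrow(f1$log), 8)                  # one row per iteration
  expect_equal(f1$log$iteration, 1:8)
  expect_false(any(is.na(f1$log$l_mseg)))
  expect_equal(f1$log$eps, adaptive_coef(0:7, ema_schedule(8)))
  expect_equal(f1$log$lr, 0.01 * 0.1^((0:7) / 8))
  expect_error(train(cfg, list()), "empty")
})

test_that("weak targets come from pseudo-labels until the tau window fills", {
  sets <- make_sets()
  cfg <- train_config(iters = 6, seed = 3, atst = list(window_len = 100L))
  fit <- train(cfg, sets$labeled, sets$pseudo)
  expect_true(all(fit$log$switch_fraction == 0))
  expect_true(all(is.na(fit$log$tau)))
})

test_that("with lambda 0, EMA off and an unfilled window, dual-branch training
           reduces bitwise to the supervised single branch", {
  sets <- make_sets()
  base <- list(iters = 10L, seed = 77)
  dual <- train_config(iters = base$iters, seed = base$seed, lambda_max = 0,
                       ema = list(mode = "off"),
                       atst = list(window_len = 10000L))
  ref <- train_config(iters = base$iters, seed = base$seed,
                      supervised_only = TRUE)
  fit_d <- train(dual, sets$labeled, sets$pseudo)
  fit_r <- train(ref, sets$labeled)
  expect_identical(fit_d$clean, fit_r$clean)
  expect_identical(fit_d$log$l_mseg, fit_r$log$l_mseg)
})

test_that("the noisy branch follows the clean branch under the EMA blend", {
  sets <- make_sets()
  cfg <- train_config(iters = 5, seed = 13, noisy_grad = FALSE,
                      lambda_max = 0)
  fit <- train(cfg, sets$labeled, sets$pseudo)
  # with no gradient on the noisy branch, it must be an EMA trace of clean:
  # different from initialization but not equal to clean
  init <- build_backbone(cfg$backbone, seed = 13)
  expect_false(identical(fit$noisy, init))
  expect_false(identical(fit$noisy, fit$clean))
})

test_that("the optional consistency term couples the branches", {
  sets <- make_sets()
  base <- train_config(iters = 6, seed = 31)
  cons <- train_config(iters = 6, seed = 31, consistency_weight = 5)
  f0 <- train(base, sets$labeled, sets$pseudo)
  f1 <- train(cons, sets$labeled, sets$pseudo)
  expect_false(identical(f0$clean, f1$clean))   # the clean branch now sees p_noisy
  expect_true(all(is.finite(f1$log$l_mseg)))
})

test_that("prediction respects geometry, range and the lung gate", {
  ph <- generate_phantom(phantom_spec(seed = 401))
  sets <- make_sets(1, 1)
  cfg <- train_config(iters = 3, seed = 5)
  fit <- train(cfg, sets$labeled, sets$pseudo)
  pr <- predict_volume(fit, ph$volume, ph$lung)
  expect_equal(dim(pr), dim(ph$volume$voxels))
  expect_true(all(pr >= 0 & pr <= 1))
  expect_true(all(pr[ph$lung$voxels == 0L] == 0))  # gated outside the lung
  pr_free <- predict_volume(fit, ph$volume)
  expect_gte(sum(pr_free > 0), sum(pr > 0))
})

test_that("binarize thresholds inclusively and is idempotent and monotone", {
  p <- array(c(0.2, 0.5, 0.7, 0.49), c(2, 2, 1))
  m <- binarize(p, 0.5)
  expect_equal(as.vector(m$voxels), c(0L, 1L, 1L, 0L))  # 0.5 -> foreground
  expect_identical(binarize(m$voxels * 1, 0.5)$voxels, m$voxels)
  set.seed(6)
  pr <- array(runif(100), c(10, 10, 1))
  counts <- vapply(c(0.2, 0.4, 0.6, 0.8),
                   function(t) sum(binarize(pr, t)$voxels), numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(binarize(pr, 0), "thr")
  expect_error(binarize(pr, 1), "thr")
})

test_that("checkpoints carry both branches, the config and the seed", {
  tmp <- withr::local_tempdir()
  sets <- make_sets(1, 1)
  cfg <- train_config(iters = 4, seed = 9, checkpoint_every = 2L)
  fit <- train(cfg, sets$labeled, sets$pseudo, out_dir = tmp)
  cks <- list.files(tmp, pattern = "^checkpoint_")
  expect_equal(length(cks), 2)
  ck <- readRDS(file.path(tmp, cks[length(cks)]))
  expect_identical(ck$clean, fit$clean)
  expect_identical(ck$noisy, fit$noisy)
  expect_equal(ck$seed, 9L)
})

test_that("tidy and glance expose the training log", {
  sets <- make_sets(1, 1)
  fit <- train(train_config(iters = 3, seed = 2), sets$labeled, sets$pseudo)
  td <- generics::tidy(fit)
  expect_s3_class(td, "data.frame")
  expect_equal(nrow(td), 3)
  gl <- generics::glance(fit)
  expect_equal(gl$iters, 3)
  expect_equal(gl$seed, 2L)
})
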