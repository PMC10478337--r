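mask_of <- function(coords, dims = c(12, 12, 1)) {
  m <- array(0L, dims)
  for (i in seq_len(nrow(coords))) m[coords[i, 1], coords[i, 2], 1] <- 1L
  label_mask(m)
}

test_that("DSC matches hand-counted overlaps and handles degenerate masks", {
  set.seed(4)
  a <- label_mask(array(rbinom(64, 1, 0.4), c(4, 4, 4)))
  expect_equal(as.numeric(dsc(a, a)), 100)

  # |A| = 4, |B| = 6, |A n B| = 3 -> 2*3/10 * 100 = 60
  A <- array(0L, c(4, 4, 1)); A[1:4] <- 1L
  B <- array(0L, c(4, 4, 1)); B[2:7] <- 1L
  expect_equal(as.numeric(dsc(label_mask(A), label_mask(B))), 60)

  C <- array(0L, c(4, 4, 1)); C[9:12] <- 1L
  expect_equal(as.numeric(dsc(label_mask(A), label_mask(C))), 0)

  e <- label_mask(array(0L, c(4, 4, 1)))
  both <- dsc(e, e)
  expect_equal(as.numeric(both), 100)
  expect_true(isTRUE(attr(both, "degenerate")))
  expect_equal(as.numeric(dsc(e, label_mask(A))), 0)
  expect_error(dsc(label_mask(A), label_mask(array(0L, c(5, 5, 1)))),
               "shapes")
})

test_that("DSC is symmetric and permutation-invariant", {
  set.seed(7)
  for (k in 1:10) {
    a <- array(rbinom(60, 1, 0.3), c(5, 4, 3))
    b <- array(rbinom(60, 1, 0.3), c(5, 4, 3))
    expect_equal(as.numeric(dsc(a, b)), as.numeric(dsc(b, a)))
    perm <- sample(60)
    ap <- array(a[perm], dim(a)); bp <- array(b[perm], dim(b))
    expect_equal(as.numeric(dsc(ap, bp)), as.numeric(dsc(a, b)))
  }
})

test_that("directed Hausdorff distance matches hand-derived cases", {
  a <- mask_of(rbind(c(1, 1)))
  b <- mask_of(rbind(c(4, 5)))     # offset (3, 4) -> distance 5
  expect_equal(directed_hd(a, b), 5)
  expect_equal(directed_hd(a, a), 0)

  c2 <- mask_of(rbind(c(1, 1), c(11, 1)))
  d2 <- mask_of(rbind(c(1, 1)))
  expect_equal(directed_hd(c2, d2), 10)  # farthest point governs
  expect_equal(directed_hd(d2, c2), 0)   # nested: inner to outer is 0
  expect_equal(hd(c2, d2), 10)
  expect_error(directed_hd(a, label_mask(array(0L, c(12, 12, 1)))),
               "nonempty")
})

test_that("directed_hd equals an exhaustive all-pairs brute force", {
  brute <- function(a, b) {
    A <- which(a$voxels == 1L, arr.ind = TRUE)
    B <- which(b$voxels == 1L, arr.ind = TRUE)
    max(apply(A, 1, function(p)
      min(sqrt(colSums((t(B) - as.numeric(p))^2)))))
  }
  set.seed(21)
  for (k in 1:20) {
    dims <- c(9, 8, 4)
    a <- array(0L, dims); b <- array(0L, dims)
    a[sample(prod(dims), sample(1:50, 1))] <- 1L
    b[sample(prod(dims), sample(1:50, 1))] <- 1L
    ma <- label_mask(a); mb <- label_mask(b)
    expect_equal(directed_hd(ma, mb), brute(ma, mb))
    expect_equal(hd(ma, mb), hd(mb, ma))
  }
})

test_that("hd95 is a pooled percentile bounded by the maximum distance", {
  set.seed(31)
  for (k in 1:10) {
    a <- array(rbinom(128, 1, 0.2), c(8, 8, 2))
    b <- array(rbinom(128, 1, 0.2), c(8, 8, 2))
    if (sum(a) == 0 || sum(b) == 0) next
    expect_lte(hd95(label_mask(a), label_mask(b)),
               hd(label_mask(a), label_mask(b)) + 1e-12)
  }
  a <- label_mask(array(rbinom(64, 1, 0.5), c(8, 8, 1)))
  expect_equal(hd95(a, a), 0)
})

test_that("hd95 suppresses a single outlier above the 95th percentile", {
  # 100 points at distance 1 plus one outlier at distance 50:
  # pooled distances B->A are 0, so the pooled list has 101 nonzero entries
  # out of 202; the 95th percentile of {A->B distances} alone is 1.
  dims <- c(120, 60, 1)
  A <- array(0L, dims); B <- array(0L, dims)
  for (i in 1:100) { A[i, 10, 1] <- 1L; B[i, 11, 1] <- 1L }
  A[110, 10, 1] <- 1L; B[110, 60, 1] <- 1L  # outlier pair at distance 50
  dab <- c(rep(1, 100), 50)
  pooled <- c(dab, rep(0, 101))
  expected <- unname(quantile(pooled, 0.95, type = 7))
  expect_equal(hd95(label_mask(A), label_mask(B)), expected)
  expect_lt(hd95(label_mask(A), label_mask(B)), 50)
  # per-direction variant: 95th percentile of dab list is 1
  expect_equal(hd95(label_mask(A), label_mask(B), pooled = FALSE),
               unname(quantile(dab, 0.95, type = 7)))
})

test_that("hd95 on an empty mask returns the flagged volume diagonal", {
  a <- label_mask(array(0L, c(3, 4, 5)))
  b <- label_mask(array(c(1L, rep(0L, 59)), c(3, 4, 5)))
  v <- hd95(a, b)
  expect_true(isTRUE(attr(v, "degenerate")))
  expect_equal(as.numeric(v), sqrt(2^2 + 3^2 + 4^2))
})

test_that("benchmark evaluation aggregates per-case metrics", {
  set.seed(12)
  masks <- lapply(1:4, function(i)
    label_mask(array(rbinom(100, 1, 0.3), c(10, 10, 1))))
  rep <- evaluate_benchmark(masks, masks)
  expect_equal(nrow(rep), 4)
  agg <- attr(rep, "aggregate")
  expect_equal(agg$mean[agg$metric == "dsc"], 100)
  expect_equal(agg$sd[agg$metric == "dsc"], 0)

  # two cases with DSC 60 and 80 -> mean 70
  A <- array(0L, c(4, 4, 1)); A[1:4] <- 1L
  B <- array(0L, c(4, 4, 1)); B[2:7] <- 1L   # DSC 60 with A
  C <- array(0L, c(4, 4, 1)); C[1:3] <- 1L   # DSC 2*3/7*100 with A
  r2 <- evaluate_benchmark(list(label_mask(A), label_mask(A)),
                           list(label_mask(B), label_mask(C)))
  expect_equal(attr(r2, "aggregate")$mean[1],
               mean(c(60, 2 * 3 / 7 * 100)))
  expect_error(evaluate_benchmark(list(), list()), "empty")
})
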