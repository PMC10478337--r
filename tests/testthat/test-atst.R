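# independent brute-force evaluation of the Lovász extension from its
# definition: sort errors descending, accumulate Jaccard-loss differences
lev_brute <- function(g, p) {
  m <- ifelse(g == 1, 1 - p, p)
  ord <- order(m, decreasing = TRUE)
  gs <- g[ord]
  jacc <- numeric(length(m))
  for (k in seq_along(m)) {
    sel <- seq_len(k)            # the k largest errors treated as mispredicted
    inter <- sum(g) - sum(gs[sel] == 1)
    uni <- sum(g) + sum(gs[sel] == 0)
    jacc[k] <- 1 - inter / uni
  }
  grad <- diff(c(0, jacc))
  sum(m[ord] * grad)
}

iou_loss <- function(g, p) {
  1 - sum(p & g) / sum(p | g)
}

test_that("Lovász extension equals 1 - IoU on binary vertices", {
  # g = [1,0,0,1], p = [1,0,1,1]: IoU = 2/3 -> LEV = 1/3
  expect_equal(lovasz_extension_value(c(1, 0, 0, 1), c(1, 0, 1, 1)), 1 / 3)
  expect_equal(lovasz_extension_value(c(1, 1, 0), c(1, 1, 0)), 0)
  set.seed(14)
  for (len in 2:8) {
    for (rep in 1:20) {
      g <- rbinom(len, 1, 0.5)
      p <- rbinom(len, 1, 0.5)
      if (sum(g) == 0 || sum(p | g) == 0) next
      expect_equal(as.numeric(lovasz_extension_value(g, p)), iou_loss(g, p),
                   tolerance = 1e-12)
    }
  }
})

test_that("Lovász extension matches the brute-force oracle on soft inputs", {
  expect_equal(lovasz_extension_value(c(1, 0), c(0.7, 0.2)),
               lev_brute(c(1, 0), c(0.7, 0.2)))
  set.seed(15)
  for (rep in 1:50) {
    len <- sample(2:12, 1)
    g <- rbinom(len, 1, 0.5)
    if (sum(g) == 0) g[sample(len, 1)] <- 1
    p <- runif(len)
    expect_equal(as.numeric(lovasz_extension_value(g, p)), lev_brute(g, p),
                 tolerance = 1e-12)
  }
})

test_that("Lovász extension stays in [0, 1] and flags all-background targets", {
  set.seed(16)
  for (rep in 1:30) {
    len <- sample(2:20, 1)
    g <- rbinom(len, 1, 0.5); if (sum(g) == 0) g[1] <- 1
    p <- runif(len)
    v <- as.numeric(lovasz_extension_value(g, p))
    expect_gte(v, 0); expect_lte(v, 1)
  }
  v0 <- lovasz_extension_value(c(0, 0, 0), c(0.2, 0.4, 0.1))
  expect_true(isTRUE(attr(v0, "degenerate")))
  expect_equal(as.numeric(v0), mean(c(0.2, 0.4, 0.1)))
})

test_that("symmetric divergence matches the Bernoulli closed form", {
  # p = 0.9, q = 0.1: 0.5*[KL(p||q) + KL(q||p)] = 0.8 * ln 9
  expect_equal(sym_divergence(0.9, 0.1), 0.8 * log(9), tolerance = 1e-9)
  set.seed(17)
  p <- runif(30); q <- runif(30)
  expect_equal(sym_divergence(p, q), sym_divergence(q, p))
  expect_equal(sym_divergence(p, p), 0)
  expect_gte(sym_divergence(p, q), 0)
  expect_gte(sym_divergence(p, q, method = "js"), 0)
  expect_equal(sym_divergence(p, p, method = "js"), 0)
})

test_that("the Lovász score composes LEV and the divergence discount", {
  g <- c(1, 0, 1, 0)
  expect_equal(s_lovasz(g, g, c(0.5, 0.5, 0.5, 0.5)), 0)  # perfect clean
  # div = 0 (noisy equals the lifted label) -> S = LEV
  p_clean <- c(0.7, 0.2, 0.9, 0.1)
  lifted <- pmin(pmax(g, 1e-6), 1 - 1e-6)
  expect_equal(s_lovasz(g, p_clean, lifted),
               as.numeric(lovasz_extension_value(g, p_clean)),
               tolerance = 1e-9)
  # LEV = 0.4, div = ln 2 -> S = 0.2 (composition checked numerically)
  lev <- as.numeric(lovasz_extension_value(g, p_clean))
  pn <- runif(4)
  dv <- sym_divergence(lifted, pn)
  expect_equal(s_lovasz(g, p_clean, pn), lev / exp(dv), tolerance = 1e-12)
})

test_that("the score decreases as the noisy branch diverges further", {
  g <- c(1, 0, 1, 0, 0, 1)
  p_clean <- c(0.9, 0.2, 0.6, 0.3, 0.1, 0.8)
  drift <- seq(0, 0.45, by = 0.05)
  svals <- vapply(drift, function(d) {
    pn <- abs(g - d)
    s_lovasz(g, p_clean, pn)
  }, numeric(1))
  expect_true(all(diff(svals) <= 1e-12))
})

test_that("tau stays unset until the window fills, then is the percentile", {
  st <- atst_state(window_len = 100L, h_percentile = 50)
  for (i in 1:99) {
    st <- update_tau(st, i)
    expect_true(is.na(st$tau))
  }
  st <- update_tau(st, 100)
  expect_equal(st$tau, 50.5)   # median of 1..100 by linear interpolation
  # constant window -> tau equals the constant
  st2 <- atst_state(window_len = 10L)
  for (i in 1:10) st2 <- update_tau(st2, 3.3)
  expect_equal(st2$tau, 3.3)
  # eviction keeps the window length exact
  st <- update_tau(st, 1000)
  expect_equal(length(st$s_history), 100L)
  expect_error(update_tau(st, NaN), "finite")
})

test_that("target selection switches exactly at s - tau >= 0", {
  st <- atst_state(window_len = 3L)
  p_clean <- matrix(c(0.9, 0.4, 0.6, 0.1), 2, 2)
  gt <- matrix(c(1, 0, 0, 0), 2, 2)
  # unset tau: always the pseudo-label
  tg <- select_target(10, st, p_clean, gt)
  expect_equal(tg$source, "pseudo_label")
  expect_equal(tg$mask, gt * 1L)
  for (s in c(0.5, 0.5, 0.5)) st <- update_tau(st, s)
  expect_equal(st$tau, 0.5)
  expect_equal(select_target(0.4, st, p_clean, gt)$source, "pseudo_label")
  sw <- select_target(0.6, st, p_clean, gt)
  expect_equal(sw$source, "clean_prediction")
  expect_equal(sw$mask, (p_clean >= 0.5) * 1L)
  # tie: s == tau selects the clean prediction (inclusive rule)
  expect_equal(select_target(0.5, st, p_clean, gt)$source, "clean_prediction")
})
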