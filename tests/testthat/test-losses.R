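# Loss suite: hand-derived cases, independent straight-line oracles,
# invariants, and optimization behaviour.

test_that("3D Dice loss matches hand arithmetic and the oracle", {
  t <- array(0, c(10, 10, 10)); t[2:9, 2:9, 2:9] <- 1   # >= 10^3 foreground
  expect_lt(diceLoss3D(t, t), 1e-6)                      # perfect overlap
  p <- array(0, c(4, 4, 4)); p[1, 1, 1] <- 1
  q <- array(0, c(4, 4, 4)); q[4, 4, 4] <- 1
  expect_gt(diceLoss3D(p, q), 0.999)                     # disjoint
  # |pred| = 2, |target| = 2, intersection 1 -> 0.5 as eps -> 0
  p2 <- array(0, c(2, 2, 1)); p2[1:2, 1, 1] <- 1
  t2 <- array(0, c(2, 2, 1)); t2[2, 1:2, 1] <- 1
  expect_equal(diceLoss3D(p2, t2, smoothEps = 1e-12), 0.5, tolerance = 1e-9)
  expect_error(diceLoss3D(array(0.5, c(2, 2, 2)), array(0, c(2, 2, 3))),
               "shapes differ")
  expect_error(diceLoss3D(array(2, c(2, 2, 2)), array(1, c(2, 2, 2))),
               "probabilities")
  set.seed(52)
  for (i in 1:10) {
    pr <- array(runif(8^3), c(8, 8, 8))
    tr <- array(rbinom(8^3, 1, 0.3), c(8, 8, 8))
    expect_equal(diceLoss3D(pr, tr), oDice3d(pr, tr), tolerance = 1e-10)
  }
})

test_that("2D slice Dice handles vacuous and partial slices", {
  s <- matrix(0, 4, 4); s[2:3, 2:3] <- 1
  expect_lt(diceLoss2DSlice(s, s), 1e-4)
  expect_equal(diceLoss2DSlice(matrix(0, 4, 4), matrix(0, 4, 4)), 0)
  # enumerated 2x2 half-overlap: soft pred of mass 0.5 on a unit target
  p <- matrix(c(0.5, 0, 0, 0), 2, 2)
  t <- matrix(c(1, 0, 0, 0), 2, 2)
  num <- 0; den <- 0
  for (i in 1:4) { num <- num + p[i] * t[i]; den <- den + p[i] + t[i] }
  expect_equal(1 - 2 * num / den, 1 / 3, tolerance = 1e-12)
  expect_equal(diceLoss2DSlice(p, t, 1e-12), 1 / 3, tolerance = 1e-9)
})

test_that("adaptive slice weight is 1 - dice^2", {
  s <- matrix(0, 4, 4); s[2:3, 2:3] <- 1
  expect_lt(adaptiveSliceWeight(s, s), 1e-4)             # d = 1 -> 0
  d0p <- matrix(c(1, rep(0, 15)), 4, 4)
  d0t <- matrix(c(rep(0, 15), 1), 4, 4)
  expect_gt(adaptiveSliceWeight(d0p, d0t), 0.999)        # d = 0 -> 1
  # d = 0.5: |p| = 1, |t| = 3, intersection 1
  p <- matrix(0, 4, 4); p[1, 1] <- 1
  t <- matrix(0, 4, 4); t[1, 1:3] <- 1
  expect_equal(adaptiveSliceWeight(p, t, 1e-12), 0.75, tolerance = 1e-6)
})

test_that("adaptive loss composes its terms as published (0.3016 case)", {
  # slice with dice exactly 0.8: |p| = |t| = 5, intersection 4
  p <- matrix(0, 5, 5); p[1, 1:5] <- 1
  t <- matrix(0, 5, 5); t[1, 2:5] <- 1; t[2, 1] <- 1
  d <- 1 - diceLoss2DSlice(p, t, 1e-12)
  expect_equal(d, 0.8, tolerance = 1e-9)
  w <- adaptiveSliceWeight(p, t, 1e-12)
  l2 <- diceLoss2DSlice(p, t, 1e-12)
  composed <- 0.7 * 0.4 + 0.3 * w * l2
  expect_equal(composed, 0.3016, tolerance = 1e-6)
})

test_that("adaptive loss equals the independent oracle on random inputs", {
  set.seed(61)
  cfg <- LossConfig()
  for (i in 1:15) {
    p <- array(runif(8^3), c(8, 8, 8))
    t <- array(rbinom(8^3, 1, 0.25), c(8, 8, 8))
    expect_equal(adaptiveLoss(p, t, cfg), oAdaptive(p, t), tolerance = 1e-6)
  }
  # perfect prediction: only the smoothing constant remains
  t <- array(0, c(6, 6, 6)); t[2:5, 2:5, 2:5] <- 1
  expect_lt(adaptiveLoss(t, t, cfg), 1e-3)
  # slice axis configurability
  cfg2 <- LossConfig(sliceAxis = 1)
  p <- array(runif(4^3), c(4, 4, 4)); t <- array(rbinom(64, 1, 0.4), c(4, 4, 4))
  expect_equal(adaptiveLoss(p, t, cfg2), oAdaptive(p, t, axis = 1),
               tolerance = 1e-6)
})

test_that("adaptive loss invariants hold", {
  set.seed(71)
  cfg <- LossConfig()
  for (i in 1:8) {
    p <- array(runif(6 * 6 * 5), c(6, 6, 5))
    t <- array(rbinom(180, 1, 0.3), c(6, 6, 5))
    la <- adaptiveLoss(p, t, cfg)
    expect_gte(la, cfg@lambda1 * diceLoss3D(p, t, cfg@smoothEps) - 1e-12)
    # joint slice permutation leaves the loss unchanged
    perm <- sample(5)
    expect_equal(adaptiveLoss(p[, , perm], t[, , perm], cfg), la,
                 tolerance = 1e-10)
  }
})

test_that("boundary Dice ignores interior errors and matches set arithmetic", {
  cfg <- LossConfig(boundaryWidthVox = 2L)
  t <- array(0, c(16, 16, 16)); t[4:13, 4:13, 4:13] <- 1   # 10^3 cube
  expect_lt(boundaryDiceLoss(t, t, cfg), 1e-4)
  # error strictly inside the eroded target does not register
  p <- t; p[8, 8, 8] <- 0
  expect_lt(boundaryDiceLoss(p, t, cfg), 1e-4)
  # one-voxel shift: compare against an independent masked-Dice oracle
  ps <- array(0, c(16, 16, 16)); ps[5:14, 4:13, 4:13] <- 1
  band <- t > 0
  for (w in 1:2) band <- oDilate(band)
  ero <- t > 0
  for (w in 1:2) ero <- oErode(ero)
  band <- band & !ero
  expect_equal(boundaryDiceLoss(ps, t, cfg),
               oDice3d(ps * band, t * band), tolerance = 1e-9)
  # no-boundary degenerate cases
  expect_warning(z <- boundaryDiceLoss(array(0, c(4, 4, 4)),
                                       array(0, c(4, 4, 4)), cfg), "boundary")
  expect_equal(z, 0)
})

test_that("focal loss reduces to cross-entropy and matches hand arithmetic", {
  set.seed(81)
  p <- array(runif(5^3, 0.05, 0.95), c(5, 5, 5))
  t <- array(rbinom(125, 1, 0.4), c(5, 5, 5))
  bce <- -mean(t * log(p) + (1 - t) * log(1 - p))
  expect_equal(focalLoss(p, t, gamma = 0, alpha = 1), bce, tolerance = 1e-7)
  expect_lt(focalLoss(t * 0.999999 + 0.0000005, t, gamma = 2), 1e-4)
  # single voxel with p_t = 0.5, gamma = 2: 0.25 * log 2
  expect_equal(focalLoss(array(0.5, c(1, 1, 1)), array(1, c(1, 1, 1)),
                         gamma = 2, alpha = 1), 0.25 * log(2),
               tolerance = 1e-9)
})

test_that("all losses are non-negative and vanish at perfect prediction", {
  set.seed(91)
  cfg <- LossConfig()
  for (i in 1:6) {
    t <- array(rbinom(6^3, 1, runif(1, 0.1, 0.6)), c(6, 6, 6))
    p <- array(runif(6^3), c(6, 6, 6))
    for (f in list(function(a, b) diceLoss3D(a, b),
                   function(a, b) adaptiveLoss(a, b, cfg),
                   function(a, b) suppressWarnings(boundaryDiceLoss(a, b, cfg)),
                   function(a, b) focalLoss(a, b))) {
      expect_gte(f(p, t), 0)
      expect_lt(f(t, t), 2e-3)
    }
  }
})

test_that("gradient descent on the adaptive loss recovers the target", {
  set.seed(101)
  t <- array(0, c(8, 8, 6)); t[3:6, 3:6, 2:5] <- 1
  p <- array(runif(length(t), 0.3, 0.7), dim(t))
  cfg <- LossConfig()
  for (step in 1:500) {
    g <- adaptiveLossGrad(p, t, cfg)
    p <- pmin(pmax(p - 0.5 * g, 0), 1)
    if (step %% 100 == 0 &&
        diceCoefficient(p > 0.5, t > 0) > 0.99) break
  }
  expect_gt(diceCoefficient(p > 0.5, t > 0), 0.99)
})
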