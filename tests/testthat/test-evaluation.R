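test_that("confusion counts follow the 0 = object convention", {
  tmpl <- matrix(1, 10, 10); tmpl[3:4, 3:4] <- 0          # 4-px object
  mask <- matrix(1, 10, 10); mask[3:4, 3] <- 0; mask[3, 4] <- 0
  mask[8, 8] <- 0                                          # stray detection
  cc <- confusionCounts(mask, tmpl)
  expect_equal(unname(cc), c(3, 95, 1, 1))  # TP TN FP FN
  # identity and all-background extremes
  expect_equal(unname(confusionCounts(tmpl, tmpl)), c(4, 96, 0, 0))
  none <- matrix(1, 10, 10)
  expect_equal(unname(confusionCounts(none, tmpl)["FN"]), 4)
  expect_error(confusionCounts(matrix(1, 2, 2), tmpl), "shapes")
})

test_that("agreement metrics reproduce hand-computed coefficients", {
  m <- agreementMetrics(c(TP = 3, TN = 95, FP = 1, FN = 1))
  expect_equal(unname(m["S"]), 0.75)
  expect_equal(unname(m["P"]), 95 / 96, tolerance = 1e-9)
  expect_equal(unname(m["rD"]), 0.75)
  expect_equal(unname(m["rJ"]), 0.6)
  expect_equal(unname(m["rSS"]), 3 / 7, tolerance = 1e-9)
  expect_equal(unname(m["rRT"]), 98 / 102, tolerance = 1e-9)
  perfect <- agreementMetrics(c(TP = 10, TN = 90, FP = 0, FN = 0))
  expect_true(all(perfect == 1))
})

test_that("metric identities hold on 1000 random confusion quadruples", {
  set.seed(99)
  for (i in 1:1000) {
    q <- c(TP = sample(1:500, 1), TN = sample(1:500, 1),
           FP = sample(0:100, 1), FN = sample(0:100, 1))
    m <- agreementMetrics(q)
    expect_equal(unname(m["rD"]), unname(2 * m["rJ"] / (1 + m["rJ"])),
                 tolerance = 1e-12)
    expect_true(m["rSS"] <= m["rJ"] + 1e-12 && m["rJ"] <= m["rD"] + 1e-12)
    expect_lte(m["rRT"], 1)
    allOne <- all(abs(m[c("S", "P", "rD", "rJ", "rSS", "rRT")] - 1) < 1e-12)
    expect_equal(allOne, q[["FP"]] == 0 && q[["FN"]] == 0)
  }
})

test_that("object matching is one-to-one with a majority-overlap criterion", {
  tmpl <- matrix(1, 30, 30); tmpl[5:14, 5:14] <- 0
  tl <- labelObjects(tmpl)
  # identical maps: all matched
  ms <- matchObjects(tl, tl)
  expect_equal(nrow(ms$pairs), 1)
  expect_length(ms$fpObjects, 0)
  expect_length(ms$fnObjects, 0)
  # a far-away extra blob is a FP object
  det <- tmpl; det[22:28, 22:28] <- 0
  ms <- matchObjects(labelObjects(det), tl)
  expect_equal(nrow(ms$pairs), 1)
  expect_length(ms$fpObjects, 1)
  # 30% erosion still matches (70% > 50%)...
  det2 <- matrix(1, 30, 30); det2[5:14, 5:11] <- 0   # 70 of 100 px
  ms2 <- matchObjects(labelObjects(det2), tl)
  expect_equal(nrow(ms2$pairs), 1)
  # ...but a 60% erosion does not
  det3 <- matrix(1, 30, 30); det3[5:14, 5:8] <- 0    # 40 of 100 px
  ms3 <- matchObjects(labelObjects(det3), tl)
  expect_equal(nrow(ms3$pairs), 0)
  expect_length(ms3$fnObjects, 1)
})

test_that("object count metrics reproduce the 70-of-72 precision example", {
  fake <- list(pairs = data.frame(template = 1:70, detected = 1:70,
                                  intersection = 100),
               nTemplate = 70, nDetected = 72)
  m <- objectCountMetrics(fake)
  expect_equal(unname(m["accuracy"]), 1)
  expect_equal(unname(m["precision"]), 70 / 72, tolerance = 1e-9)
  expect_equal(unname(m["countError"]), 2)
  m2 <- objectCountMetrics(fake, nTemplate = 8, nDetected = 5)
  expect_equal(unname(m2["countError"]), -3)
})

test_that("shape features behave on canonical objects", {
  # disc: roundness near 1, high solidity, low eccentricity
  disc <- discMask(60, 60, 30, 30, 20)
  f <- objectFeatures(labelObjects(disc))
  expect_gt(f$roundness, 0.85); expect_lt(f$roundness, 1.1)
  expect_gte(f$solidity, 0.95)
  expect_lte(f$eccentricity, 0.15)
  expect_equal(f$area, sum(disc == 0))
  # 10 x 40 rectangle: moment-ellipse axis ratio 4 (with the 1/12 term)
  rect <- matrix(1, 60, 20); rect[11:50, 6:15] <- 0
  fr <- objectFeatures(labelObjects(rect))
  expect_equal(fr$axisRatio, 4, tolerance = 0.05)
  # square: eccentricity 0 by symmetry
  sq <- matrix(1, 30, 30); sq[6:25, 6:25] <- 0
  expect_equal(objectFeatures(labelObjects(sq))$eccentricity, 0)
  # single pixel: documented conventions
  one <- matrix(1, 5, 5); one[3, 3] <- 0
  f1 <- objectFeatures(labelObjects(one))
  expect_equal(f1$eccentricity, 0)
  expect_equal(f1$perimeter, 1)
})

test_that("Bland-Altman bias and limits follow their definitions", {
  ba <- blandAltman(c(100, 200), c(90, 190))
  expect_equal(ba$bias, -10)
  expect_equal(ba$sdDiff, 0)
  expect_equal(ba$loa, c(-10, -10))
  ident <- blandAltman(c(5, 7, 9), c(5, 7, 9))
  expect_true(all(ident$table$difference == 0))
  expect_equal(ident$bias, 0)
  # constant offset: bias = c, zero-width limits
  x <- c(10, 50, 90)
  off <- blandAltman(x, x + 13)
  expect_equal(off$bias, 13)
  expect_equal(diff(off$loa), 0)
  expect_error(blandAltman(numeric(0), numeric(0)), "empty")
})

test_that("quasi-Bland-Altman points capture co-localisation errors", {
  tmpl <- discMask(80, 80, 40, 40, 15)
  tl <- labelObjects(tmpl)
  # identity: the point is exactly (0, 0)
  q0 <- quasiBA(matchObjects(tl, tl), tl, tl)
  expect_equal(q0$centroidDistance, 0)
  expect_equal(q0$errorRatio, 0)
  # uniform erosion: centroid fixed, ratio = lost area / template area
  er <- discMask(80, 80, 40, 40, 14)
  el <- labelObjects(er)
  qe <- quasiBA(matchObjects(el, tl), el, tl)
  lost <- sum(tmpl == 0) - sum(er == 0)
  expect_lt(qe$centroidDistance, 0.05)
  expect_equal(qe$errorRatio, lost / sum(tmpl == 0), tolerance = 1e-9)
  # translation by (3, 0): distance 3, ratio from the pixel-set oracle
  tr <- discMask(80, 80, 43, 40, 15)
  rl <- labelObjects(tr)
  qt <- quasiBA(matchObjects(rl, tl), rl, tl)
  expect_equal(qt$centroidDistance, 3, tolerance = 1e-6)
  tset <- which(tmpl == 0); dset <- which(tr == 0)
  oracle <- (length(setdiff(dset, tset)) + length(setdiff(tset, dset))) /
    length(tset)
  expect_equal(qt$errorRatio, oracle, tolerance = 1e-12)
})

test_that("homogeneous erosion leaves shape features unbiased but area reduced", {
  tmpl <- discMask(90, 90, 45, 45, 20)
  det <- discMask(90, 90, 45, 45, 18)   # 2-px homogeneous boundary erosion
  ft <- objectFeatures(labelObjects(tmpl))
  fd <- objectFeatures(labelObjects(det))
  expect_lt(blandAltman(ft$area, fd$area)$bias, 0)
  expect_equal(fd$solidity - ft$solidity, 0, tolerance = 0.02)
  expect_equal(fd$roundness - ft$roundness, 0, tolerance = 0.05)
})
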