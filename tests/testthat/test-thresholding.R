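# Direct checks of each binarisation rule on hand-constructed window
# statistics, plus property tests on random images.

mkStats <- function(img, mean, sd, min, max, w = 51L) {
  d <- dim(img)
  cm <- function(v) matrix(v, d[1], d[2])
  new("WindowStats", mean = cm(mean), sd = cm(sd), min = cm(min),
      max = cm(max), contrast = cm(max) - cm(min), w = w)
}

test_that("Niblack rule: strict inequality about m + k*sigma", {
  img <- matrix(c(120, 90, 98), 1, 3)
  s <- mkStats(img, mean = 100, sd = 10, min = 40, max = 200)
  out <- pixels(thresholdNiblack(img, thresholdParams(), s))
  # T = 100 - 2 = 98; ties fall to the object branch
  expect_equal(as.numeric(out), c(1, 0, 0))
})

test_that("Sauvola rule collapses to m when sigma = R and respects printed k", {
  img <- matrix(c(101, 110), 1, 2)
  sEq <- mkStats(img, mean = 100, sd = 128, min = 0, max = 255)
  out <- pixels(thresholdSauvola(img, thresholdParams(), sEq))
  expect_equal(out[1, 1], 1)  # T = m = 100 < 101
  # printed parameterisation: k = -0.2, sigma = 0 -> T = 1.2 m = 120
  s0 <- mkStats(img, mean = 100, sd = 0, min = 100, max = 100)
  out <- pixels(thresholdSauvola(img, thresholdParams(sauvolaK = -0.2), s0))
  expect_equal(out[1, 2], 0)  # 110 < 120: flat surround becomes object
  # default positive k: T = 0.8 m = 80 < 110 -> background
  out <- pixels(thresholdSauvola(img, thresholdParams(), s0))
  expect_equal(out[1, 2], 1)
  expect_error(thresholdSauvola(img, thresholdParams(R = -1), s0), "R")
})

test_that("White rule compares the local mean with bias * I", {
  img <- matrix(c(49, 51), 1, 2)
  s <- mkStats(img, mean = 100, sd = 0, min = 100, max = 100)
  out <- pixels(thresholdWhite(img, thresholdParams(), s))
  expect_equal(as.numeric(out), c(0, 1))  # 100 < 98 false; 100 < 102 true
  # bias = 1 reduces to "darker than the local mean is object"
  img2 <- matrix(c(99, 101), 1, 2)
  s2 <- mkStats(img2, mean = 100, sd = 1, min = 99, max = 101)
  out2 <- pixels(thresholdWhite(img2, thresholdParams(bias = 1), s2))
  expect_equal(as.numeric(out2), c(0, 1))
})

test_that("Bernsen rule thresholds at the mid-range under the contrast gate", {
  img <- matrix(c(100, 121, 100), 1, 3)
  sHi <- mkStats(img, mean = 120, sd = 50, min = 40, max = 200)  # C = 160
  out <- pixels(thresholdBernsen(img, thresholdParams(), sHi))
  expect_equal(as.numeric(out)[1:2], c(0, 1))  # T = 120
  sLo <- mkStats(img, mean = 110, sd = 5, min = 100, max = 120)  # C = 20
  out <- pixels(thresholdBernsen(img, thresholdParams(), sLo))
  expect_equal(as.numeric(out), c(1, 1, 1))  # low contrast -> background
  # literal piecewise mode: threshold 0 in low-contrast windows
  img0 <- matrix(c(0, 100), 1, 2)
  s0 <- mkStats(img0, mean = 50, sd = 5, min = 45, max = 55)
  out <- pixels(thresholdBernsen(
    img0, thresholdParams(bernsenLowContrast = "equation"), s0))
  expect_equal(as.numeric(out), c(0, 1))  # only I = 0 fails I > 0
})

test_that("hybrids equal their base method under the gate and background elsewhere", {
  p <- thresholdParams(w = 9L)
  for (seed in c(1, 2)) {
    m <- randIntensity(40, 40, seed)
    s <- windowStats(m, p@w)
    gate <- s@contrast >= p@Tc
    hn <- pixels(hybridNiblack(m, p, s))
    hs <- pixels(hybridSauvola(m, p, s))
    bn <- pixels(thresholdNiblack(m, p, s))
    bs <- pixels(thresholdSauvola(m, p, s))
    expect_identical(hn[gate], bn[gate])
    expect_identical(hs[gate], bs[gate])
    expect_true(all(hn[!gate] == 1))
    expect_true(all(hs[!gate] == 1))
  }
  # an all-high-contrast image makes the hybrids equal their base methods
  chk <- matrix(c(0, 255), 30, 30)
  s <- windowStats(chk, p@w)
  expect_true(all(s@contrast >= p@Tc))
  expect_identical(pixels(hybridNiblack(chk, p, s)),
                   pixels(thresholdNiblack(chk, p, s)))
})

test_that("Yasuda matches a literal four-step reference implementation", {
  p <- thresholdParams(w = 9L)
  for (seed in c(4, 8)) {
    m <- randIntensity(24, 24, seed)
    expect_equal(pixels(thresholdYasuda(m, p)), bruteYasuda(m, p),
                 tolerance = 1e-9)
  }
})

test_that("Yasuda handles degenerate and full-range inputs", {
  p <- thresholdParams(w = 9L)
  expect_true(all(pixels(thresholdYasuda(matrix(77, 20, 20), p)) == 1))
  # an image already spanning 0..255 passes step 1 unchanged
  m <- randIntensity(20, 20, 3); m[1, 1] <- 0; m[20, 20] <- 255
  i1 <- 255 * (m - min(m)) / (max(m) - min(m))
  expect_equal(i1, m)
})

test_that("Palumbo matches the brute-force centre-surround oracle", {
  p <- thresholdParams(w = 9L)
  for (seed in c(5, 13)) {
    m <- randIntensity(26, 21, seed)
    expect_equal(pixels(thresholdPalumbo(m, p)), brutePalumbo(m, p),
                 tolerance = 1e-9)
  }
  expect_error(thresholdPalumbo(randIntensity(20, 20, 1),
                                thresholdParams(w = 11L)), "divisible")
})

test_that("Palumbo clause arithmetic", {
  p <- thresholdParams(w = 9L)
  # very dark pixels are objects regardless of the surround
  m <- matrix(200, 21, 21); m[11, 11] <- 10
  expect_equal(pixels(thresholdPalumbo(m, p))[11, 11], 0)
  # flat image: 0.85 * 200 > 200 is false -> background
  expect_true(all(pixels(thresholdPalumbo(matrix(200, 21, 21), p)) == 1))
})

test_that("darkening a pixel can only turn it into an object (global window)", {
  p <- thresholdParams(w = 15L)
  runs <- list(
    list(fn = thresholdNiblack), list(fn = thresholdSauvola),
    list(fn = thresholdWhite), list(fn = thresholdBernsen))
  set.seed(77)
  for (rep in 1:6) {
    m <- matrix(sample(0:255, 225, replace = TRUE), 15, 15)
    x <- sample(15, 1); y <- sample(15, 1)
    if (m[x, y] == 0) next
    m2 <- m; m2[x, y] <- sample(0:(m[x, y] - 1), 1)
    for (r in runs) {
      before <- pixels(r$fn(m, p))[x, y]
      after <- pixels(r$fn(m2, p))[x, y]
      # never object -> background
      expect_false(before == 0 && after == 1)
    }
  }
})

test_that("all methods are deterministic and binary", {
  m <- randIntensity(40, 40, 10)
  p <- thresholdParams(w = 9L)
  for (met in allMethods()) {
    a <- pixels(segmentImage(m, met, p))
    b <- pixels(segmentImage(m, met, p))
    expect_identical(a, b)
    expect_true(all(a %in% c(0, 1)))
  }
})
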