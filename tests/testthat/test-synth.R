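test_that("nucleus sampling is deterministic and respects empty cases", {
  cfg <- smallScene(seed = 5L)
  n1 <- sampleNuclei(cfg)
  n2 <- sampleNuclei(cfg)
  expect_identical(n1, n2)
  cfg0 <- smallScene(seed = 5L, nBrown = 0L)
  expect_equal(sum(sampleNuclei(cfg0)$class == "brown"), 0)
  tmpl <- renderTemplate(sampleNuclei(cfg0), 320, 320, "brown")
  expect_true(all(pixels(tmpl) == 1))
})

test_that("overly dense scenes fail with an informative packing error", {
  cfg <- sceneConfig(width = 120L, height = 120L, nBrown = 2L,
                     areaMean = 2000, areaSd = 10, seed = 1L)
  expect_error(generateTemplatePair(
    sceneConfig(width = 100L, height = 100L, nBrown = 20L, areaMean = 150,
                areaSd = 5, seed = 1L)), "overlap|density|packing")
})

test_that("rasterised discs recover their analytic area within 2%", {
  for (r in c(15, 20, 25)) {
    nuc <- data.frame(class = "brown", cx = 40.3, cy = 41.7, a = r, b = r,
                      theta = 0, e2 = 0, e3 = 0, e4 = 0,
                      f2 = 0, f3 = 0, f4 = 0, area = pi * r^2)
    tmpl <- renderTemplate(nuc, 81, 81, "brown")
    expect_equal(sum(pixels(tmpl) == 0), pi * r^2, tolerance = 0.02)
  }
})

test_that("rendered nucleus areas track the sampled target areas", {
  cfg <- smallScene(seed = 9L)
  nuc <- sampleNuclei(cfg)
  brown <- nuc[nuc$class == "brown", ]
  tmpl <- renderTemplate(nuc, cfg@height, cfg@width, "brown")
  lab <- labelObjects(tmpl)
  expect_equal(lab$n, nrow(brown))
  expect_equal(sum(lab$areas), sum(round(brown$area)), tolerance = 0.02)
})

test_that("two near-tangent ellipses stay separate 8-connected objects", {
  nuc <- data.frame(class = "brown", cx = c(30, 72), cy = c(50, 50),
                    a = 20, b = 20, theta = 0, e2 = 0, e3 = 0, e4 = 0,
                    f2 = 0, f3 = 0, f4 = 0, area = pi * 400)
  tmpl <- renderTemplate(nuc, 100, 100, "brown")
  expect_equal(labelObjects(tmpl)$n, 2L)
})

test_that("Perlin textures are deterministic, centred and seed-decorrelated", {
  a <- perlinTexture(100, 120, scale = 10, seed = 4L)
  b <- perlinTexture(100, 120, scale = 10, seed = 4L)
  expect_identical(a, b)
  expect_true(all(a >= 0 & a <= 1))
  big1 <- perlinTexture(1000, 1000, scale = 12, seed = 1L)
  big2 <- perlinTexture(1000, 1000, scale = 12, seed = 2L)
  expect_gt(mean(big1), 0.4)
  expect_lt(mean(big1), 0.6)
  expect_lt(abs(cor(as.numeric(big1), as.numeric(big2))), 0.2)
})

test_that("rendering honours the palette contract", {
  # zero jitter/texture/rim amplitudes: brown nuclei are exactly the mean colour
  cfg <- smallScene(seed = 2L, palette = list(
    brownJitter = 0, brownTexAmp = 0, brownRim = 0, backgroundGradAmp = 0))
  nuc <- sampleNuclei(cfg)
  img <- renderScene(nuc, cfg)
  brown <- pixels(renderTemplate(nuc, cfg@height, cfg@width, "brown")) == 0
  for (ch in 1:3)
    expect_true(all(img[, , ch][brown] == cfg@palette$brown[ch]))
  # default palette: blue nuclei are bluer than brown ones, background bright
  cfg2 <- smallScene(seed = 2L)
  nuc2 <- sampleNuclei(cfg2)
  img2 <- renderScene(nuc2, cfg2)
  brown2 <- pixels(renderTemplate(nuc2, cfg2@height, cfg2@width, "brown")) == 0
  blue2 <- pixels(renderTemplate(nuc2, cfg2@height, cfg2@width, "blue")) == 0 &
    !brown2
  bg <- !brown2 & !blue2
  expect_gt(mean(img2[, , 3][blue2]), mean(img2[, , 3][brown2]))
  expect_true(all(img2[, , 1][bg] >= 200))
  expect_true(all(img2[, , 2][bg] >= 200))
  expect_true(all(img2[, , 3][bg] >= 200))
})

test_that("the degradation chain follows its closed forms", {
  flat <- array(200, c(101, 101, 3))
  cfg0 <- smallScene(seed = 1L, blur = 0, vignette = 0, noiseSd = 0,
                     aberration = 0)
  expect_equal(degrade(flat, cfg0), flat)  # identity up to quantisation
  # vignette: corner/centre ratio is exactly 1 - v on a flat field
  cfgV <- smallScene(seed = 1L, blur = 0, vignette = 0.1, noiseSd = 0,
                     aberration = 0)
  outV <- degrade(flat, cfgV)
  expect_equal(outV[51, 51, 1], 200)
  expect_equal(outV[1, 1, 1] / 200, 0.9)
  # noise: sample sd of (degraded - clean) within 10% of the nominal sigma
  cfgN <- smallScene(seed = 1L, blur = 0, vignette = 0, noiseSd = 5,
                     aberration = 0)
  outN <- degrade(flat, cfgN)
  expect_equal(sd(outN - flat), 5, tolerance = 0.1)
})

test_that("degradation never touches the templates", {
  cfg <- smallScene(seed = 6L)
  pair <- generateTemplatePair(cfg)
  expect_identical(pixels(pair@template),
                   pixels(renderTemplate(sampleNuclei(cfg), cfg@height,
                                         cfg@width, "brown")))
  # and the whole pair is bit-identical across regenerations
  pair2 <- generateTemplatePair(cfg)
  expect_identical(pair@rgb, pair2@rgb)
  expect_identical(pixels(pair@template), pixels(pair2@template))
})

test_that("the five presets realise their configured counts", {
  set <- generateSet(masterSeed = 11L)
  counts <- vapply(set, function(p) labelObjects(p@template)$n, 1L)
  expect_equal(unname(counts), c(8L, 34L, 15L, 13L, 21L))
})

test_that("preset A areas track the configured distribution", {
  areas <- unlist(lapply(1:40, function(i) {
    cfg <- scenePreset("A", seed = 1000L + i)
    nuc <- sampleNuclei(cfg)
    nuc$area[nuc$class == "brown"]
  }))
  se <- sd(areas) / sqrt(length(areas))
  expect_lt(abs(mean(areas) - 1681), 2 * se + 1e-9)
})
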