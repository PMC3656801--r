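# Synthetic DAB&H scene generator. A scene is sampled as a list of nucleus
# shapes (perturbed ellipses), rasterised once into exact binary templates,
# rendered into a clean RGB image (background + Perlin-textured blue nuclei
# + almost homogeneous brown nuclei) and finally pushed through a
# microscope/camera degradation chain that never touches the templates.

#' Construct a synthetic scene configuration
#'
#' See [SceneConfig-class] for slot semantics. The palette is a named list;
#' any entry supplied here overrides the default:
#' `brown` fill RGB mean, `brownJitter` per-nucleus RGB jitter sd,
#' `brownTexAmp`/`brownTexScale` amplitude and cell size of the weak brown
#' texture, `brownRim` width (px) of the stain falloff at the nuclear
#' border, `blueLight`/`blueDark` endpoints of the blue fill ramp,
#' `blueTexScale` cell size of the curly blue texture, `blueRim` falloff
#' width of blue nuclei, `background` RGB,
#' `backgroundGradAmp`/`backgroundGradScale` amplitude and cell size of the
#' illumination gradient.
#'
#' @param name scene label.
#' @param width,height canvas size (px).
#' @param nBrown,nBlue nucleus counts.
#' @param areaMean,areaSd brown nucleus area statistics (px^2).
#' @param rmaxMean,rmaxSd,rminMean,rminSd brown radius statistics (px).
#' @param blueAreaMean,blueAreaSd blue nucleus area statistics (px^2).
#' @param perturb harmonic boundary perturbation amplitude, in `[0, 0.3]`.
#' @param palette named list of palette overrides (see above).
#' @param blur,vignette,noiseSd,aberration degradation chain parameters
#'   (Gaussian blur sigma in px, fractional corner attenuation, additive
#'   noise sd in intensity units, per-channel radial magnification offset).
#' @param seed integer RNG seed.
#' @return a [SceneConfig].
#' @export
sceneConfig <- function(name = "custom", width = 1000L, height = 1000L,
                        nBrown = 10L, nBlue = 180L,
                        areaMean = 1800, areaSd = 300,
                        rmaxMean = 28, rmaxSd = 1.2,
                        rminMean = 20, rminSd = 2.5,
                        blueAreaMean = 1400, blueAreaSd = 600,
                        perturb = 0.05, palette = list(),
                        blur = 1.0, vignette = 0.1, noiseSd = 3,
                        aberration = 0.001, seed = 1L) {
  defPal <- list(brown = c(120, 72, 45), brownJitter = 8,
                 brownTexAmp = 6, brownTexScale = 12, brownRim = 2,
                 blueLight = c(165, 170, 205), blueDark = c(70, 80, 150),
                 blueTexScale = 6, blueRim = 2,
                 background = c(235, 232, 228),
                 backgroundGradAmp = 6, backgroundGradScale = 500)
  bad <- setdiff(names(palette), names(defPal))
  if (length(bad)) stop("unknown palette entries: ", paste(bad, collapse = ", "))
  defPal[names(palette)] <- palette
  cfg <- new("SceneConfig", name = name, width = as.integer(width),
             height = as.integer(height), nBrown = as.integer(nBrown),
             nBlue = as.integer(nBlue), areaMean = areaMean, areaSd = areaSd,
             rmaxMean = rmaxMean, rmaxSd = rmaxSd, rminMean = rminMean,
             rminSd = rminSd, blueAreaMean = blueAreaMean,
             blueAreaSd = blueAreaSd, perturb = perturb, palette = defPal,
             blur = blur, vignette = vignette, noiseSd = noiseSd,
             aberration = aberration, seed = as.integer(seed))
  validObject(cfg)
  cfg
}

# Object statistics of the five benchmark images: counts and the mean +/- sd
# of nucleus area (px^2) and of the maximal/minimal radius (px).
presetTable <- function() {
  data.frame(
    name = c("A", "B", "C", "D", "E"),
    nBrown = c(8L, 34L, 15L, 13L, 21L),
    areaMean = c(1681, 1922, 1867, 2047, 1892),
    areaSd = c(426, 166, 256, 150, 211),
    rmaxMean = c(27.4, 27.9, 28.0, 29.0, 27.8),
    rmaxSd = c(1.4, 1.3, 1.2, 1.0, 1.0),
    rminMean = c(17.4, 20.7, 20.2, 21.2, 20.7),
    rminSd = c(3.9, 1.8, 2.8, 1.4, 2.5))
}

#' Scene presets of the five benchmark images
#'
#' Returns the configuration of one of the artificial images A-E: a
#' 1000 x 1000 px canvas (consistent with the reported per-area object
#' fractions), the per-image immunopositive nucleus counts
#' (8, 34, 15, 13, 21) and the per-image area/radius statistics.
#'
#' @param name `"A"` to `"E"`.
#' @param seed integer RNG seed.
#' @param ... further overrides passed to [sceneConfig()].
#' @return a [SceneConfig].
#' @export
scenePreset <- function(name, seed = 1L, ...) {
  tab <- presetTable()
  if (!name %in% tab$name) stop("unknown preset '", name, "'")
  r <- tab[tab$name == name, ]
  args <- list(name = name, nBrown = r$nBrown, areaMean = r$areaMean,
               areaSd = r$areaSd, rmaxMean = r$rmaxMean, rmaxSd = r$rmaxSd,
               rminMean = r$rminMean, rminSd = r$rminSd, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(sceneConfig, args)
}

# Truncated normal draw (mean, sd; rejected outside mean +/- cc * sd' and at
# <= lower). The pre-truncation sd is inflated so the *realised* sd matches
# the requested one; plain +/-2.5 sd truncation would shave ~4.5% off it.
rtruncAdj <- function(n, mean, sd, cc = 2.5, lower = 0) {
  if (n == 0L) return(numeric(0))
  if (sd <= 0) return(rep(mean, n))
  retain <- sqrt(1 - 2 * cc * stats::dnorm(cc) / (2 * stats::pnorm(cc) - 1))
  s <- sd / retain
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(max(2L * n, 16L), mean, s)
    x <- x[abs(x - mean) <= cc * s & x > lower]
    out <- c(out, x)
  }
  out[seq_len(n)]
}

# Radius of the (a, b)-ellipse at polar angle phi in its own frame.
ellipseRadius <- function(a, b, phi) {
  a * b / sqrt((b * cos(phi))^2 + (a * sin(phi))^2)
}

# Draw shape parameters for one nucleus class and rescale each shape so its
# analytic area equals the sampled target area exactly.
sampleShapes <- function(n, areaMean, areaSd, qMean, qSd, perturb, class) {
  if (n == 0L)
    return(data.frame(class = character(0), cx = numeric(0), cy = numeric(0),
                      a = numeric(0), b = numeric(0), theta = numeric(0),
                      e2 = numeric(0), e3 = numeric(0), e4 = numeric(0),
                      f2 = numeric(0), f3 = numeric(0), f4 = numeric(0),
                      area = numeric(0)))
  areas <- rtruncAdj(n, areaMean, areaSd)
  q <- pmin(3, pmax(1.05, rnorm(n, qMean, qSd)))
  theta <- runif(n, 0, 2 * pi)
  e <- cbind(runif(n, 0, perturb), runif(n, 0, 0.7 * perturb),
             runif(n, 0, 0.5 * perturb))
  f <- matrix(runif(3L * n, 0, 2 * pi), n, 3L)
  phi <- seq(0, 2 * pi, length.out = 721L)[-721L]
  a <- sqrt(areas * q / pi)
  b <- sqrt(areas / (pi * q))
  for (i in seq_len(n)) {
    rho <- ellipseRadius(a[i], b[i], phi) *
      (1 + e[i, 1] * cos(2 * phi + f[i, 1]) +
           e[i, 2] * cos(3 * phi + f[i, 2]) +
           e[i, 3] * cos(4 * phi + f[i, 3]))
    s <- sqrt(areas[i] / (pi * mean(rho^2)))
    a[i] <- a[i] * s
    b[i] <- b[i] * s
  }
  data.frame(class = class, cx = NA_real_, cy = NA_real_, a = a, b = b,
             theta = theta, e2 = e[, 1], e3 = e[, 2], e4 = e[, 3],
             f2 = f[, 1], f3 = f[, 2], f4 = f[, 3], area = areas)
}

nucleusReach <- function(nuc) nuc$a * (1 + nuc$e2 + nuc$e3 + nuc$e4)

#' Sample the nucleus population of a scene
#'
#' Brown (immunopositive) nuclei have areas drawn from a truncated normal
#' matching the configured mean/sd, aspect ratios consistent with the
#' configured radius statistics, uniform orientations and a low-order
#' harmonic boundary perturbation. They are placed fully inside the frame by
#' rejection sampling so that no two brown nuclei overlap (a 2-px clearance
#' keeps near-touching nuclei separate 8-connected template objects, so the
#' template count always equals `nBrown`). Blue (immunonegative) nuclei may
#' overlap anything and may be clipped by the frame. Deterministic for a
#' fixed seed.
#'
#' @param cfg a [SceneConfig].
#' @return data frame with one row per nucleus: `class`, centroid
#'   `cx`/`cy` (px), semi-axes `a`/`b` (px), orientation `theta` (rad),
#'   harmonic amplitudes `e2`-`e4` and phases `f2`-`f4`, and the sampled
#'   target `area` (px^2).
#' @export
sampleNuclei <- function(cfg) withSeed(cfg@seed, {
  W <- cfg@width; H <- cfg@height
  if (cfg@nBrown * cfg@areaMean >= 0.2 * W * H)
    stop(sprintf(
      "infeasible packing: %d brown nuclei of mean area %.0f exceed 20%% of a %dx%d canvas",
      cfg@nBrown, cfg@areaMean, W, H))
  qMean <- cfg@rmaxMean / cfg@rminMean
  qSd <- qMean * sqrt((cfg@rmaxSd / cfg@rmaxMean)^2 +
                      (cfg@rminSd / cfg@rminMean)^2)
  brown <- sampleShapes(cfg@nBrown, cfg@areaMean, cfg@areaSd, qMean, qSd,
                        cfg@perturb, "brown")
  reach <- nucleusReach(brown)
  clearance <- 2
  placedX <- numeric(0); placedY <- numeric(0); placedR <- numeric(0)
  for (i in seq_len(cfg@nBrown)) {
    margin <- reach[i] + 1
    if (2 * margin >= min(W, H))
      stop("nucleus too large for the canvas")
    ok <- FALSE
    for (try in seq_len(2000L)) {
      x <- runif(1, 1 + margin, W - margin)
      y <- runif(1, 1 + margin, H - margin)
      if (!length(placedX) ||
          all(sqrt((placedX - x)^2 + (placedY - y)^2) >
              placedR + reach[i] + clearance)) {
        ok <- TRUE; break
      }
    }
    if (!ok)
      stop(sprintf(
        "could not place brown nucleus %d of %d without overlap: density too high",
        i, cfg@nBrown))
    placedX <- c(placedX, x); placedY <- c(placedY, y)
    placedR <- c(placedR, reach[i])
  }
  brown$cx <- placedX; brown$cy <- placedY
  blue <- sampleShapes(cfg@nBlue, cfg@blueAreaMean, cfg@blueAreaSd,
                       1.4, 0.25, cfg@perturb * 1.5, "blue")
  blue$cx <- runif(cfg@nBlue, 1, W)
  blue$cy <- runif(cfg@nBlue, 1, H)
  rbind(brown, blue)
})

# Rasterise a set of nuclei into an integer id map (0 = none); later rows
# overwrite earlier ones where they overlap. Inclusive boundary test at
# pixel centres: pixel (row, col) belongs to nucleus i when its centre lies
# on or inside the perturbed ellipse boundary. With depth = TRUE also
# returns the radial distance (px) from each inside pixel to the boundary,
# used by the renderer to fade the stain out towards the nuclear rim.
rasterizeNuclei <- function(nuc, H, W, depth = FALSE) {
  ids <- matrix(0L, H, W)
  dep <- if (depth) matrix(0, H, W) else NULL
  for (i in seq_len(nrow(nuc))) {
    n <- nuc[i, ]
    reach <- nucleusReach(n) + 1
    r0 <- max(1L, floor(n$cy - reach)); r1 <- min(H, ceiling(n$cy + reach))
    c0 <- max(1L, floor(n$cx - reach)); c1 <- min(W, ceiling(n$cx + reach))
    if (r0 > r1 || c0 > c1) next
    rows <- r0:r1; cols <- c0:c1
    dy <- matrix(rows - n$cy, length(rows), length(cols))
    dx <- matrix(cols - n$cx, length(rows), length(cols), byrow = TRUE)
    u <- dx * cos(n$theta) + dy * sin(n$theta)
    v <- -dx * sin(n$theta) + dy * cos(n$theta)
    r <- sqrt(u^2 + v^2)
    phi <- atan2(v, u)
    bound <- ellipseRadius(n$a, n$b, phi) *
      (1 + n$e2 * cos(2 * phi + n$f2) + n$e3 * cos(3 * phi + n$f3) +
           n$e4 * cos(4 * phi + n$f4))
    inside <- r <= bound
    sub <- ids[rows, cols, drop = FALSE]
    sub[inside] <- i
    ids[rows, cols] <- sub
    if (depth) {
      dsub <- dep[rows, cols, drop = FALSE]
      dsub[inside] <- (bound - r)[inside]
      dep[rows, cols] <- dsub
    }
  }
  if (depth) list(ids = ids, depth = dep) else ids
}

#' Rasterise nucleus templates
#'
#' Renders the exact binary ground truth of one nucleus class: a pixel is an
#' object (0) iff its centre lies inside (or on) a nucleus boundary.
#'
#' @param nuclei nucleus data frame from [sampleNuclei()].
#' @param H,W canvas size (px).
#' @param class `"brown"` (default) or `"blue"`.
#' @return a [BinaryMask].
#' @export
renderTemplate <- function(nuclei, H, W, class = "brown") {
  sub <- nuclei[nuclei$class == class, , drop = FALSE]
  ids <- rasterizeNuclei(sub, H, W)
  new("BinaryMask", pixels = ifelse(ids > 0L, 0, 1))
}

#' Render the clean RGB scene
#'
#' Composites three layers: an off-white background with a gentle
#' low-frequency illumination gradient, blue nuclei filled by mapping a
#' fine Perlin field through the blue palette ramp (curly chromatin
#' texture), and brown nuclei drawn on top, filled almost homogeneously
#' (per-nucleus colour jitter plus a weak smooth texture). Stain density
#' falls off linearly over the outermost `brownRim`/`blueRim` pixels of
#' each nucleus, emulating the gradual, partly blurred nuclear border of
#' stained tissue; the geometric templates are unaffected. No degradation
#' is applied; values are continuous.
#'
#' @param nuclei nucleus data frame from [sampleNuclei()].
#' @param cfg the [SceneConfig] (canvas, palette, seed).
#' @return H x W x 3 numeric array in `[0, 255]`.
#' @export
renderScene <- function(nuclei, cfg) {
  H <- cfg@height; W <- cfg@width
  pal <- cfg@palette
  grad <- perlinTexture(H, W, pal$backgroundGradScale, octaves = 2L,
                        seed = cfg@seed + 101L)
  blueTex <- perlinTexture(H, W, pal$blueTexScale, octaves = 3L,
                           seed = cfg@seed + 202L)
  brownTex <- perlinTexture(H, W, pal$brownTexScale, octaves = 2L,
                            seed = cfg@seed + 303L)
  blueR <- rasterizeNuclei(nuclei[nuclei$class == "blue", , drop = FALSE],
                           H, W, depth = TRUE)
  brownR <- rasterizeNuclei(nuclei[nuclei$class == "brown", , drop = FALSE],
                            H, W, depth = TRUE)
  nB <- sum(nuclei$class == "brown")
  jit <- withSeed(cfg@seed + 404L, {
    matrix(rnorm(3L * max(nB, 1L), 0, pal$brownJitter), max(nB, 1L), 3L)
  })
  img <- array(0, c(H, W, 3L))
  isBlue <- blueR$ids > 0L
  isBrown <- brownR$ids > 0L
  # stain weight ramps 0 -> 1 over the outermost rim pixels
  rampW <- function(dep, sel, rim) {
    if (rim > 0) pmin(dep[sel] / rim, 1) else 1
  }
  wBlue <- rampW(blueR$depth, isBlue, pal$blueRim)
  wBrown <- rampW(brownR$depth, isBrown, pal$brownRim)
  for (ch in 1:3) {
    plane <- pal$background[ch] + (grad - 0.5) * 2 * pal$backgroundGradAmp
    blueFill <- pal$blueLight[ch] +
      blueTex[isBlue] * (pal$blueDark[ch] - pal$blueLight[ch])
    plane[isBlue] <- plane[isBlue] * (1 - wBlue) + blueFill * wBlue
    if (nB > 0L) {
      brownFill <- pal$brown[ch] + jit[brownR$ids[isBrown], ch] +
        (brownTex[isBrown] - 0.5) * 2 * pal$brownTexAmp
      plane[isBrown] <- plane[isBrown] * (1 - wBrown) + brownFill * wBrown
    }
    img[, , ch] <- pmin(pmax(plane, 0), 255)
  }
  img
}

# Clamped bilinear sampling of a matrix at fractional coordinates.
bilinearSample <- function(m, ys, xs) {
  H <- nrow(m); W <- ncol(m)
  ys <- pmin(H, pmax(1, ys)); xs <- pmin(W, pmax(1, xs))
  y0 <- pmin(H - 1L, floor(ys)); x0 <- pmin(W - 1L, floor(xs))
  fy <- ys - y0; fx <- xs - x0
  i00 <- (x0 - 1) * H + y0
  v <- m[i00] * (1 - fy) * (1 - fx) + m[i00 + 1] * fy * (1 - fx) +
       m[i00 + H] * (1 - fy) * fx + m[i00 + H + 1] * fy * fx
  matrix(v, H, W)
}

#' Microscope/camera degradation chain
#'
#' Applies, in order: Gaussian blur (`blur` sigma), a radial vignette
#' `1 - vignette * (d / d_max)^2` (centre brighter than the periphery,
#' `d_max` = centre-to-corner distance), chromatic aberration as per-channel
#' radial magnification about the centre (R scaled by `1 + aberration`, B by
#' `1 - aberration`, producing colour rims at object edges), additive
#' Gaussian noise (`noiseSd`), and clipping/quantisation to 8 bits.
#' Deterministic for a fixed `cfg@seed`; with all factors zero it is the
#' identity up to quantisation.
#'
#' @param rgb H x W x 3 numeric array in `[0, 255]` (clean rendering).
#' @param cfg the [SceneConfig] carrying the degradation parameters.
#' @return H x W x 3 numeric array of 8-bit values.
#' @export
degrade <- function(rgb, cfg) {
  d <- dim(rgb)
  H <- d[1]; W <- d[2]
  out <- rgb
  if (cfg@blur > 0)
    for (ch in 1:3) out[, , ch] <- gaussianBlur(out[, , ch], cfg@blur)
  if (cfg@vignette > 0) {
    cy <- (H + 1) / 2; cx <- (W + 1) / 2
    dy <- matrix(seq_len(H) - cy, H, W)
    dx <- matrix(seq_len(W) - cx, H, W, byrow = TRUE)
    d2 <- (dy^2 + dx^2) / ((1 - cy)^2 + (1 - cx)^2)
    fac <- 1 - cfg@vignette * d2
    for (ch in 1:3) out[, , ch] <- out[, , ch] * fac
  }
  if (cfg@aberration != 0) {
    cy <- (H + 1) / 2; cx <- (W + 1) / 2
    ys <- matrix(seq_len(H), H, W)
    xs <- matrix(seq_len(W), H, W, byrow = TRUE)
    scales <- c(1 + cfg@aberration, 1, 1 - cfg@aberration)
    for (ch in 1:3) {
      s <- scales[ch]
      if (s == 1) next
      out[, , ch] <- bilinearSample(out[, , ch],
                                    cy + (ys - cy) / s, cx + (xs - cx) / s)
    }
  }
  if (cfg@noiseSd > 0)
    out <- out + withSeed(cfg@seed + 505L,
                          array(rnorm(length(out), 0, cfg@noiseSd), d))
  array(pmin(pmax(round(out), 0), 255), d)
}

#' Generate a complete synthetic image with ground truth
#'
#' Samples the nucleus population, rasterises the brown and blue templates,
#' renders the clean scene and applies the degradation chain. The templates
#' are computed from the geometry alone, before any degradation.
#'
#' @param cfg a [SceneConfig].
#' @return a [TemplatePair].
#' @export
generateTemplatePair <- function(cfg) {
  nuclei <- sampleNuclei(cfg)
  tmpl <- renderTemplate(nuclei, cfg@height, cfg@width, "brown")
  blueT <- renderTemplate(nuclei, cfg@height, cfg@width, "blue")
  rgb <- degrade(renderScene(nuclei, cfg), cfg)
  new("TemplatePair", rgb = rgb, template = tmpl, blueTemplate = blueT,
      nuclei = nuclei, scene = cfg)
}

# Per-image seed derived from a master seed; kept below 2^31.
deriveSeed <- function(masterSeed, i) {
  as.integer((as.numeric(masterSeed) * 97 + i * 1009) %% 2147483647)
}

#' Generate the five benchmark images
#'
#' Instantiates presets A-E with per-image seeds derived from `masterSeed`.
#' The realised templates contain exactly 8, 34, 15, 13 and 21
#' immunopositive nuclei.
#'
#' @param masterSeed integer master seed.
#' @param presets subset of `c("A","B","C","D","E")`.
#' @param ... overrides forwarded to [scenePreset()].
#' @return named list of [TemplatePair] objects.
#' @export
generateSet <- function(masterSeed = 1L, presets = c("A", "B", "C", "D", "E"),
                        ...) {
  out <- lapply(seq_along(presets), function(i) {
    generateTemplatePair(scenePreset(presets[i],
                                     seed = deriveSeed(masterSeed, i), ...))
  })
  names(out) <- presets
  out
}
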