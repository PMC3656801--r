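#' @title Core data containers
#' @name ihcthresh-classes
#' @description S4 containers used throughout the package: monochrome
#'   intensity images, binary masks, sliding-window statistics, stain bases
#'   for colour deconvolution, threshold parameter sets and synthetic-scene
#'   descriptions.
NULL

#' Monochrome 8-bit intensity image
#'
#' A single-channel image with values in `[0, 255]` under the fixed polarity
#' contract of this package: candidate objects (stained nuclei) are *dark*,
#' background is *bright*. Every threshold method consumes this type.
#'
#' @slot pixels numeric matrix, values in `[0, 255]` (rows = y, cols = x).
#' @slot channel character tag recording the colour separation that produced
#'   the image, e.g. `"blue"`, `"brown_axis"` or `"dab_deconv"`.
#' @exportClass IntensityImage
setClass("IntensityImage",
  representation(pixels = "matrix", channel = "character"),
  prototype(channel = "grey"))

setValidity("IntensityImage", function(object) {
  p <- object@pixels
  if (!is.numeric(p)) return("pixels must be a numeric matrix")
  if (nrow(p) < 1L || ncol(p) < 1L) return("image must be at least 1x1")
  if (anyNA(p) || any(p < 0) || any(p > 255))
    return("pixel values must lie in [0, 255]")
  if (length(object@channel) != 1L) return("channel must be a single string")
  TRUE
})

#' Binary segmentation mask
#'
#' `0` marks object pixels and `1` marks background, the convention used by
#' all threshold methods here (dark objects fall in the 0 branch of each
#' binarisation rule).
#'
#' @slot pixels numeric matrix containing only 0 (object) and 1 (background).
#' @exportClass BinaryMask
setClass("BinaryMask", representation(pixels = "matrix"))

setValidity("BinaryMask", function(object) {
  p <- object@pixels
  if (!is.numeric(p)) return("pixels must be a numeric matrix")
  if (anyNA(p) || !all(p == 0 | p == 1))
    return("mask values must be exactly 0 (object) or 1 (background)")
  TRUE
})

#' Sliding-window statistics of an intensity image
#'
#' Per-pixel mean, population standard deviation, minimum, maximum and
#' contrast (max - min) of the `w x w` neighbourhood centred on each pixel,
#' with mirror padding at the borders. The variance can be obtained as
#' `sd^2`.
#'
#' @slot mean,sd,min,max,contrast numeric matrices, one value per pixel.
#' @slot w odd integer window side length in pixels.
#' @exportClass WindowStats
setClass("WindowStats",
  representation(mean = "matrix", sd = "matrix", min = "matrix",
                 max = "matrix", contrast = "matrix", w = "integer"))

setValidity("WindowStats", function(object) {
  d <- dim(object@mean)
  for (s in c("sd", "min", "max", "contrast"))
    if (!identical(dim(slot(object, s)), d))
      return("all statistic maps must share the same dimensions")
  if (any(object@sd < 0)) return("sd must be non-negative")
  if (any(object@contrast < 0)) return("contrast must be non-negative")
  if (any(object@min > object@mean + 1e-9) ||
      any(object@mean > object@max + 1e-9))
    return("min <= mean <= max must hold everywhere")
  TRUE
})

#' Stain basis for colour deconvolution
#'
#' Three unit-length absorption vectors in optical-density space, stored as
#' the columns of a 3x3 matrix (haematoxylin, DAB, residual). The residual
#' axis is usually the normalised cross product of the first two.
#'
#' @slot M 3x3 numeric matrix; columns named `h`, `dab`, `residual`, each of
#'   Euclidean norm 1; must be invertible.
#' @exportClass StainBasis
setClass("StainBasis", representation(M = "matrix"))

setValidity("StainBasis", function(object) {
  M <- object@M
  if (!is.numeric(M) || !identical(dim(M), c(3L, 3L)))
    return("M must be a numeric 3x3 matrix")
  n <- sqrt(colSums(M^2))
  if (any(abs(n - 1) > 1e-9)) return("stain vectors must have unit norm")
  if (abs(det(M)) < 1e-12)
    return("stain vectors are collinear: basis is not invertible")
  TRUE
})

#' Parameters of the adaptive threshold methods
#'
#' All tunables of the six threshold methods and the two hybrids, with the
#' benchmark defaults `w = 51`, `k = -0.2`, `R = 128`, `bias = 2`,
#' `Tc = 150`, Palumbo `T1 = 20`, `T2 = 0.85`, Yasuda `T1 = 50`, `T2 = 100`,
#' `T3 = 128`, `T4 = 15`. Construct with [thresholdParams()].
#'
#' @slot w odd integer window side length (pixels).
#' @slot k numeric variance bias of Niblack (dimensionless).
#' @slot sauvolaK numeric variance bias of the Sauvola rule. The default is
#'   +0.2, the sign of the original Sauvola formulation for dark objects;
#'   with the multiplicative rule a negative value raises the threshold
#'   above the local mean in flat windows and surrounds every object with a
#'   false-positive ring. Set to -0.2 to reproduce the printed benchmark
#'   parameter table literally.
#' @slot R numeric variance normaliser of Sauvola (intensity units, > 0).
#' @slot bias numeric multiplier of the White rule (dimensionless).
#' @slot Tc numeric minimum local contrast of Bernsen and the hybrids
#'   (intensity units, in `[0, 255]`).
#' @slot T1,T2,T3,T4 numeric method-specific thresholds. For Palumbo `T1` is
#'   an intensity and `T2` a ratio; for Yasuda `T1` is a local range, `T2` a
#'   contrast, `T3` an intensity and `T4` a deviation (all on the 8-bit
#'   scale).
#' @slot palumboT1,palumboT2 numeric, the Palumbo pair kept separately so a
#'   single object can drive every method.
#' @slot bernsenLowContrast `"background"` (default: low-contrast windows
#'   are classified background) or `"equation"` (threshold 0 in low-contrast
#'   windows, as the piecewise formula reads literally).
#' @slot yasudaStep4 `"equation"` (default: the final condition marks
#'   *object*) or `"prose"` (inverted: the condition marks background).
#' @slot yasudaStep4Window `"local"` (default: 3x3 statistics in step 4) or
#'   `"window"` (the full `w x w` statistics).
#' @exportClass ThresholdParams
setClass("ThresholdParams",
  representation(w = "integer", k = "numeric", sauvolaK = "numeric",
                 R = "numeric",
                 bias = "numeric", Tc = "numeric",
                 T1 = "numeric", T2 = "numeric", T3 = "numeric",
                 T4 = "numeric", palumboT1 = "numeric", palumboT2 = "numeric",
                 bernsenLowContrast = "character", yasudaStep4 = "character",
                 yasudaStep4Window = "character"))

setValidity("ThresholdParams", function(object) {
  if (object@w < 3L || object@w %% 2L == 0L)
    return("w must be odd and >= 3")
  if (object@R <= 0) return("R must be > 0")
  if (object@Tc < 0 || object@Tc > 255) return("Tc must lie in [0, 255]")
  if (!object@bernsenLowContrast %in% c("background", "equation"))
    return("bernsenLowContrast must be 'background' or 'equation'")
  if (!object@yasudaStep4 %in% c("equation", "prose"))
    return("yasudaStep4 must be 'equation' or 'prose'")
  if (!object@yasudaStep4Window %in% c("local", "window"))
    return("yasudaStep4Window must be 'local' or 'window'")
  TRUE
})

#' Configuration of a synthetic DAB&H scene
#'
#' Describes one artificial image: canvas size, counts and shape statistics
#' of immunopositive (brown) and immunonegative (blue) nuclei, the colour
#' palette, the degradation chain and the RNG seed. Presets `"A"`-`"E"`
#' reproduce the object statistics of the five benchmark images
#' (see [scenePreset()]).
#'
#' @slot name scene label.
#' @slot width,height canvas size in pixels.
#' @slot nBrown,nBlue nucleus counts.
#' @slot areaMean,areaSd brown nucleus area statistics (px^2).
#' @slot rmaxMean,rmaxSd,rminMean,rminSd brown nucleus radius statistics
#'   (px); only their ratio shapes the ellipses, area has priority.
#' @slot blueAreaMean,blueAreaSd blue nucleus area statistics (px^2).
#' @slot perturb maximal relative amplitude of the harmonic boundary
#'   perturbation, in `[0, 0.3]`.
#' @slot palette named list of rendering colours and texture amplitudes, see
#'   [sceneConfig()].
#' @slot blur Gaussian blur sigma (px).
#' @slot vignette fractional corner attenuation of the radial vignette.
#' @slot noiseSd additive Gaussian noise sigma (intensity units).
#' @slot aberration per-channel radial magnification offset of the chromatic
#'   aberration model (R scaled by `1 + a`, B by `1 - a`).
#' @slot seed integer RNG seed; the whole scene is deterministic given it.
#' @exportClass SceneConfig
setClass("SceneConfig",
  representation(name = "character", width = "integer", height = "integer",
                 nBrown = "integer", nBlue = "integer",
                 areaMean = "numeric", areaSd = "numeric",
                 rmaxMean = "numeric", rmaxSd = "numeric",
                 rminMean = "numeric", rminSd = "numeric",
                 blueAreaMean = "numeric", blueAreaSd = "numeric",
                 perturb = "numeric", palette = "list",
                 blur = "numeric", vignette = "numeric",
                 noiseSd = "numeric", aberration = "numeric",
                 seed = "integer"))

setValidity("SceneConfig", function(object) {
  if (object@width < 1L || object@height < 1L) return("canvas must be >= 1x1")
  if (object@nBrown < 0L || object@nBlue < 0L)
    return("nucleus counts must be >= 0")
  if (object@areaMean <= 0) return("areaMean must be > 0")
  if (object@areaSd < 0 || object@blueAreaSd < 0)
    return("standard deviations must be >= 0")
  if (object@perturb < 0 || object@perturb > 0.3)
    return("perturb must lie in [0, 0.3]")
  TRUE
})

#' A synthetic image with its ground truth
#'
#' The realised scene: the degraded RGB rendering, the binary template of
#' brown (immunopositive) nuclei, the template of blue nuclei, the sampled
#' nucleus list and the configuration that produced them. Degradations touch
#' only the RGB rendering; the templates are computed from the geometry
#' alone.
#'
#' @slot rgb H x W x 3 numeric array of 8-bit values.
#' @slot template [BinaryMask] of brown nuclei (0 = nucleus).
#' @slot blueTemplate [BinaryMask] of blue nuclei.
#' @slot nuclei data frame of sampled nucleus shapes (see [sampleNuclei()]).
#' @slot scene the [SceneConfig] actually realised.
#' @exportClass TemplatePair
setClass("TemplatePair",
  representation(rgb = "array", template = "BinaryMask",
                 blueTemplate = "BinaryMask", nuclei = "data.frame",
                 scene = "SceneConfig"))

setValidity("TemplatePair", function(object) {
  d <- dim(object@rgb)
  if (length(d) != 3L || d[3] != 3L) return("rgb must be an H x W x 3 array")
  if (!identical(dim(object@template@pixels), d[1:2]))
    return("template dimensions must match the image")
  TRUE
})
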