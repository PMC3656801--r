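# The six locally adaptive threshold methods and the two Bernsen-contrast
# hybrids. All share the binarisation convention B = 0 object / 1 background
# and strict inequalities exactly as each rule is usually printed, so ties
# fall to the 0 (object) branch.

#' Threshold parameter set with the benchmark defaults
#'
#' @param w odd window side length in pixels (default 51).
#' @param k variance bias of Niblack (default -0.2).
#' @param sauvolaK variance bias of the Sauvola rule (default +0.2; see
#'   [ThresholdParams-class] for why the sign differs from `k`).
#' @param R variance normaliser of Sauvola (default 128).
#' @param bias multiplier of the White rule (default 2).
#' @param Tc minimum local contrast of Bernsen and the hybrids (default 150).
#' @param palumboT1,palumboT2 Palumbo intensity threshold (default 20) and
#'   centre/surround ratio (default 0.85).
#' @param T1,T2,T3,T4 Yasuda local-range, contrast, intensity and deviation
#'   thresholds (defaults 50, 100, 128, 15).
#' @param bernsenLowContrast,yasudaStep4,yasudaStep4Window resolution of the
#'   ambiguous corners of the printed rules; see
#'   [ThresholdParams-class] for the choices.
#' @return a [ThresholdParams] object.
#' @export
thresholdParams <- function(w = 51L, k = -0.2, sauvolaK = 0.2, R = 128,
                            bias = 2, Tc = 150,
                            palumboT1 = 20, palumboT2 = 0.85,
                            T1 = 50, T2 = 100, T3 = 128, T4 = 15,
                            bernsenLowContrast = c("background", "equation"),
                            yasudaStep4 = c("equation", "prose"),
                            yasudaStep4Window = c("local", "window")) {
  p <- new("ThresholdParams", w = as.integer(w), k = k,
           sauvolaK = sauvolaK, R = R, bias = bias,
           Tc = Tc, T1 = T1, T2 = T2, T3 = T3, T4 = T4,
           palumboT1 = palumboT1, palumboT2 = palumboT2,
           bernsenLowContrast = match.arg(bernsenLowContrast),
           yasudaStep4 = match.arg(yasudaStep4),
           yasudaStep4Window = match.arg(yasudaStep4Window))
  validObject(p)
  p
}

#' Read threshold parameters from a YAML or JSON file
#'
#' Unknown keys are rejected; missing keys keep their defaults.
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return a [ThresholdParams] object.
#' @export
readThresholdParams <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(thresholdParams))
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  do.call(thresholdParams, cfg)
}

newMask <- function(m) new("BinaryMask", pixels = m)

# Shared preamble: intensity matrix plus (possibly precomputed) window stats.
prepStats <- function(img, params, stats) {
  m <- asIntensityMatrix(img)
  if (is.null(stats)) stats <- windowStats(m, params@w)
  else {
    stopifnot(is(stats, "WindowStats"))
    if (stats@w != params@w || !identical(dim(stats@mean), dim(m)))
      stop("precomputed stats do not match the image/params")
  }
  list(m = m, s = stats)
}

#' Niblack local-variance threshold
#'
#' `T = m_w + k * sigma_w`; a pixel is background when `I > T`, object
#' otherwise.
#'
#' @param img an [IntensityImage] or numeric matrix (dark objects).
#' @param params a [ThresholdParams]; defaults are the benchmark values.
#' @param stats optional precomputed [windowStats()] for `params@w`,
#'   shared across methods for speed.
#' @return a [BinaryMask].
#' @export
thresholdNiblack <- function(img, params = thresholdParams(), stats = NULL) {
  x <- prepStats(img, params, stats)
  thr <- x$s@mean + params@k * x$s@sd
  newMask((x$m > thr) + 0)
}

#' Sauvola local-variance threshold
#'
#' The standard multiplicative Sauvola rule
#' `T = m_w * (1 + k * (sigma_w / R - 1))` with `k = params@sauvolaK`;
#' background where `I > T`. With the default `k = +0.2` the threshold
#' drops below the local mean in flat windows (suppressing noise) and
#' approaches it near high-variance edges; a negative `k` inverts this and
#' over-detects around objects, which is why the method is normally run
#' inside a Bernsen contrast gate (see [hybridSauvola()]).
#'
#' @inheritParams thresholdNiblack
#' @return a [BinaryMask].
#' @export
thresholdSauvola <- function(img, params = thresholdParams(), stats = NULL) {
  if (params@R <= 0) stop("R must be > 0")
  x <- prepStats(img, params, stats)
  thr <- x$s@mean * (1 + params@sauvolaK * (x$s@sd / params@R - 1))
  newMask((x$m > thr) + 0)
}

#' White centre-surround threshold
#'
#' A pixel is background when `m_w < I * bias`, i.e. it is an object only
#' when it is considerably darker than its surround (for `bias = 2`, darker
#' than half the local mean).
#'
#' @inheritParams thresholdNiblack
#' @return a [BinaryMask].
#' @export
thresholdWhite <- function(img, params = thresholdParams(), stats = NULL) {
  x <- prepStats(img, params, stats)
  newMask((x$s@mean < x$m * params@bias) + 0)
}

#' Bernsen local-contrast threshold
#'
#' Where the window contrast `C_w = max_w - min_w` reaches `Tc`, the
#' threshold is the mid-range `(max_w + min_w) / 2`; where contrast is too
#' low the window is classified as background (default), or thresholded at 0
#' when `params@bernsenLowContrast = "equation"`.
#'
#' @inheritParams thresholdNiblack
#' @return a [BinaryMask].
#' @export
thresholdBernsen <- function(img, params = thresholdParams(), stats = NULL) {
  x <- prepStats(img, params, stats)
  gate <- x$s@contrast >= params@Tc
  thr <- (x$s@max + x$s@min) / 2
  if (params@bernsenLowContrast == "equation") thr[!gate] <- 0
  b <- (x$m > thr) + 0
  if (params@bernsenLowContrast == "background") b[!gate] <- 1
  newMask(b)
}

#' Yasuda four-step local-contrast threshold
#'
#' Step 1 stretches the image to the full 8-bit range; step 2 smooths
#' low-range 3x3 neighbourhoods with their mean; step 3 coarsely flags
#' background (value 255) wherever the `w x w` mean falls below the pixel or
#' the window contrast is below `T2`, and otherwise rescales the pixel
#' within its window range; step 4 classifies a pixel as object when the
#' local 3x3 minimum of the step-3 image falls below `T3` or its local
#' deviation exceeds `T4`. All intermediate images live on the 8-bit scale.
#' A constant input yields an all-background mask.
#'
#' @inheritParams thresholdNiblack
#' @return a [BinaryMask].
#' @export
thresholdYasuda <- function(img, params = thresholdParams(), stats = NULL) {
  m <- asIntensityMatrix(img)
  rng <- range(m)
  if (rng[2] <= rng[1]) return(newMask(array(1, dim(m))))
  i1 <- 255 * (m - rng[1]) / (rng[2] - rng[1])
  s3 <- windowStats(i1, 3L)
  i2 <- ifelse(s3@contrast < params@T1, s3@mean, i1)
  sw <- windowStats(i2, params@w)
  cw <- sw@contrast
  flag <- sw@mean < i2 | cw < params@T2
  i3 <- ifelse(flag, 255, 255 * (i2 - sw@min) / pmax(cw, .Machine$double.eps))
  s4 <- if (params@yasudaStep4Window == "local") windowStats(i3, 3L)
        else windowStats(i3, params@w)
  mn3 <- boxExtPadded(mirrorPad(i3, 1L), 3L, FALSE)
  cond <- mn3 < params@T3 | s4@sd > params@T4
  b <- if (params@yasudaStep4 == "equation") ifelse(cond, 0, 1)
       else ifelse(cond, 1, 0)
  newMask(b)
}

#' Palumbo centre-surround threshold
#'
#' The `w x w` window is divided into a 3x3 grid of `(w/3) x (w/3)` tiles;
#' the central tile is the near neighbourhood and the four corner tiles the
#' far neighbourhood. A pixel is an object when it is very dark
#' (`I < T1`) or when the centre tile mean is sufficiently below the
#' surround: `T2 * mean(A_neigh) > mean(A_center)`.
#'
#' @inheritParams thresholdNiblack
#' @return a [BinaryMask].
#' @export
thresholdPalumbo <- function(img, params = thresholdParams(), stats = NULL) {
  m <- asIntensityMatrix(img)
  tm <- palumboTileMeans(m, params@w)
  obj <- (m < params@palumboT1) | (params@palumboT2 * tm$neigh > tm$center)
  newMask(ifelse(obj, 0, 1))
}

#' Hybrid Niblack-Bernsen threshold
#'
#' Applies the Niblack rule only where the Bernsen contrast condition
#' `C_w >= Tc` holds; low-contrast windows are classified background.
#'
#' @inheritParams thresholdNiblack
#' @return a [BinaryMask].
#' @export
hybridNiblack <- function(img, params = thresholdParams(), stats = NULL) {
  x <- prepStats(img, params, stats)
  base <- thresholdNiblack(x$m, params, x$s)@pixels
  base[x$s@contrast < params@Tc] <- 1
  newMask(base)
}

#' Hybrid Sauvola-Bernsen threshold
#'
#' Applies the Sauvola rule only where the Bernsen contrast condition
#' `C_w >= Tc` holds; low-contrast windows are classified background.
#'
#' @inheritParams thresholdNiblack
#' @return a [BinaryMask].
#' @export
hybridSauvola <- function(img, params = thresholdParams(), stats = NULL) {
  x <- prepStats(img, params, stats)
  base <- thresholdSauvola(x$m, params, x$s)@pixels
  base[x$s@contrast < params@Tc] <- 1
  newMask(base)
}

#' Names of the available threshold methods
#'
#' `benchmarkMethods()` lists the six methods of the comparison study (where
#' "Niblack" and "Sauvola" mean their Bernsen hybrids);
#' `allMethods()` adds the plain Niblack and Sauvola variants.
#'
#' @return character vector of method names accepted by [segmentImage()].
#' @export
benchmarkMethods <- function() {
  c("hybrid_niblack", "hybrid_sauvola", "white", "bernsen", "palumbo",
    "yasuda")
}

#' @rdname benchmarkMethods
#' @export
allMethods <- function() c(benchmarkMethods(), "niblack", "sauvola")

#' Segment an intensity image with a named method
#'
#' Dispatches to the corresponding threshold function and optionally applies
#' the size filter.
#'
#' @param img an [IntensityImage] or numeric matrix (dark objects).
#' @param method one of [allMethods()].
#' @param params a [ThresholdParams].
#' @param stats optional precomputed [windowStats()] at `params@w`.
#' @param minArea if positive, remove objects smaller than this many pixels
#'   (see [sizeFilter()]); the benchmark uses 900.
#' @return a [BinaryMask].
#' @export
segmentImage <- function(img, method, params = thresholdParams(),
                         stats = NULL, minArea = 0) {
  method <- match.arg(method, allMethods())
  fn <- switch(method,
               niblack = thresholdNiblack, sauvola = thresholdSauvola,
               white = thresholdWhite, bernsen = thresholdBernsen,
               yasuda = thresholdYasuda, palumbo = thresholdPalumbo,
               hybrid_niblack = hybridNiblack, hybrid_sauvola = hybridSauvola)
  mask <- fn(img, params, stats)
  if (minArea > 0) mask <- sizeFilter(mask, minArea)
  mask
}
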