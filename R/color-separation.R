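# Colour separation: turn an RGB IHC image into the monochrome maps the
# threshold methods consume. All three outputs follow the same polarity
# contract: stained (brown) nuclei dark, background bright.

# Validate and return an H x W x 3 array of 8-bit-scale values.
asRGBArray <- function(rgb) {
  if (is(rgb, "TemplatePair")) rgb <- rgb@rgb
  d <- dim(rgb)
  if (is.null(d) || length(d) != 3L || d[3] != 3L)
    stop("expected an H x W x 3 RGB array")
  if (anyNA(rgb) || any(rgb < 0) || any(rgb > 255))
    stop("RGB values must lie in [0, 255]")
  rgb
}

newIntensity <- function(m, channel) {
  new("IntensityImage", pixels = m, channel = channel)
}

# Extract one colour plane as a matrix (never dropped to a vector).
rgbPlane <- function(rgb, ch) {
  matrix(rgb[, , ch], dim(rgb)[1], dim(rgb)[2])
}

# Accept an IntensityImage or bare matrix wherever a monochrome map is needed.
asIntensityMatrix <- function(img) {
  if (is(img, "IntensityImage")) return(img@pixels)
  if (is.matrix(img) && is.numeric(img)) return(img)
  stop("expected an IntensityImage or a numeric matrix")
}

#' Blue channel extraction
#'
#' Returns the B plane of an RGB image unchanged. In DAB&H staining the blue
#' channel gives the greatest brown/blue contrast, so brown (DAB-positive)
#' nuclei appear dark in it.
#'
#' @param rgb H x W x 3 numeric array with values in `[0, 255]`, or a
#'   [TemplatePair].
#' @return an [IntensityImage] with channel tag `"blue"`.
#' @examples
#' rgb <- array(c(100, 80, 60), c(1, 1, 3))
#' pixels(extractBlueChannel(rgb))  # 60
#' @export
extractBlueChannel <- function(rgb) {
  rgb <- asRGBArray(rgb)
  newIntensity(rgbPlane(rgb, 3), "blue")
}

#' Brown-axis colour combination
#'
#' Computes the per-pixel combination `B - 0.3 * (R + G)`, a one-dimensional
#' "brown axis" on which DAB-stained pixels take low values. Because the raw
#' axis of an 8-bit image can only span about `[-153, 255]` and in practice
#' stays well below the nominal 8-bit range (a neutral white background maps
#' to 0.4 * B at most), the default output is linearly rescaled so that the
#' image minimum maps to 0 and the maximum to 255, which restores enough
#' global contrast for contrast-gated threshold methods. Set
#' `rescale = FALSE` to clip the raw axis to `[0, 255]` instead and keep an
#' absolute scale.
#'
#' @param rgb H x W x 3 numeric array with values in `[0, 255]`, or a
#'   [TemplatePair].
#' @param rescale logical; rescale the raw axis to the full 8-bit range
#'   (default) rather than clipping it.
#' @return an [IntensityImage] with channel tag `"brown_axis"`.
#' @export
brownAxis <- function(rgb, rescale = TRUE) {
  rgb <- asRGBArray(rgb)
  a <- rgbPlane(rgb, 3) - 0.3 * (rgbPlane(rgb, 1) + rgbPlane(rgb, 2))
  if (rescale) {
    rng <- range(a)
    a <- if (rng[2] > rng[1]) (a - rng[1]) / (rng[2] - rng[1]) * 255
         else a * 0
  }
  newIntensity(pmin(pmax(round(a), 0), 255), "brown_axis")
}

#' Optical-density transform
#'
#' Converts 8-bit transmitted intensities to optical densities by the
#' Beer-Lambert relation `OD = -log10((I + 1) / 256)`. The `+1` offset makes
#' the map bijective on `[0, 255]` and avoids `log(0)`; a fully transparent
#' pixel (`I = 255`) has OD 0.
#'
#' @param rgb H x W x 3 numeric array with values in `[0, 255]`, or a
#'   [TemplatePair].
#' @return H x W x 3 numeric array of non-negative optical densities.
#' @export
odTransform <- function(rgb) {
  rgb <- asRGBArray(rgb)
  -log10((rgb + 1) / 256)
}

#' Construct a stain basis
#'
#' Builds the 3x3 matrix of unit absorption vectors used by
#' [colorDeconvolution()]. Vectors are normalised to unit length; when
#' `residual` is omitted it is completed as the normalised cross product of
#' the first two, giving an orthogonal third axis.
#'
#' @param h,dab numeric length-3 absorption vectors of haematoxylin and DAB.
#' @param residual optional third vector; defaults to `h x dab` normalised.
#' @return a [StainBasis].
#' @export
stainBasis <- function(h, dab, residual = NULL) {
  unit <- function(v) {
    n <- sqrt(sum(v^2))
    if (n < 1e-12) stop("stain vector has zero norm")
    v / n
  }
  h <- unit(as.numeric(h)); dab <- unit(as.numeric(dab))
  if (is.null(residual)) {
    residual <- c(h[2] * dab[3] - h[3] * dab[2],
                  h[3] * dab[1] - h[1] * dab[3],
                  h[1] * dab[2] - h[2] * dab[1])
    if (sqrt(sum(residual^2)) < 1e-9)
      stop("h and dab vectors are collinear: invalid stain vectors")
  }
  residual <- unit(as.numeric(residual))
  M <- cbind(h = h, dab = dab, residual = residual)
  rownames(M) <- c("R", "G", "B")
  b <- new("StainBasis", M = M)
  validObject(b)
  b
}

#' Default haematoxylin-DAB stain basis
#'
#' The standard Ruifrok-Johnston H-DAB absorption vectors,
#' H = (0.650, 0.704, 0.286) and DAB = (0.269, 0.568, 0.778), with the
#' residual axis completed as their normalised cross product.
#'
#' @return a [StainBasis].
#' @export
defaultStainBasis <- function() {
  stainBasis(c(0.650, 0.704, 0.286), c(0.269, 0.568, 0.778))
}

#' Read a stain basis from a YAML or JSON config file
#'
#' The file must provide numeric length-3 entries `h` and `dab` and may
#' provide `residual`.
#'
#' @param path file path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return a [StainBasis].
#' @export
readStainBasis <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$h) || is.null(cfg$dab))
    stop("config must contain 'h' and 'dab' vectors")
  stainBasis(cfg$h, cfg$dab, cfg$residual)
}

#' Per-pixel stain concentrations
#'
#' Solves the linear system `OD = M c` for every pixel, where the columns of
#' `M` are the stain vectors, and clips negative concentrations to zero.
#'
#' @param rgb H x W x 3 numeric array with values in `[0, 255]`, or a
#'   [TemplatePair].
#' @param basis a [StainBasis]; default [defaultStainBasis()].
#' @return H x W x 3 array of concentrations (h, dab, residual).
#' @export
stainConcentrations <- function(rgb, basis = defaultStainBasis()) {
  rgb <- asRGBArray(rgb)
  stopifnot(is(basis, "StainBasis"))
  od <- odTransform(rgb)
  d <- dim(od)
  odm <- matrix(od, ncol = 3L)           # pixels x channels
  Minv <- solve(basis@M)
  conc <- odm %*% t(Minv)                # pixels x stains
  conc[conc < 0] <- 0
  array(conc, c(d[1], d[2], 3L),
        dimnames = list(NULL, NULL, c("h", "dab", "residual")))
}

#' Colour deconvolution into stain maps
#'
#' Unmixes the image into haematoxylin, DAB and residual concentration maps
#' and re-renders each as a pseudo-brightfield 8-bit intensity
#' `round(255 * 10^(-c))`, so that strongly stained pixels are dark. The DAB
#' map (channel tag `"dab_deconv"`) is the monochrome input the benchmark
#' uses for the deconvolution channel.
#'
#' @param rgb H x W x 3 numeric array with values in `[0, 255]`, or a
#'   [TemplatePair].
#' @param basis a [StainBasis]; default [defaultStainBasis()].
#' @return named list of three [IntensityImage]s: `h`, `dab`, `residual`.
#' @export
colorDeconvolution <- function(rgb, basis = defaultStainBasis()) {
  conc <- stainConcentrations(rgb, basis)
  d <- dim(conc)
  render <- function(i, tag) {
    cm <- matrix(conc[, , i], d[1], d[2])
    newIntensity(pmin(pmax(round(255 * 10^(-cm)), 0), 255), tag)
  }
  list(h = render(1, "h_deconv"),
       dab = render(2, "dab_deconv"),
       residual = render(3, "residual_deconv"))
}

#' Derive a named monochrome channel from an RGB image
#'
#' Convenience dispatcher used by the benchmark and the command-line tool.
#'
#' @param rgb H x W x 3 numeric array or [TemplatePair].
#' @param channel one of `"blue"`, `"brown_axis"`, `"dab_deconv"`.
#' @param basis [StainBasis] used when `channel = "dab_deconv"`.
#' @return an [IntensityImage].
#' @export
extractChannel <- function(rgb,
                           channel = c("blue", "brown_axis", "dab_deconv"),
                           basis = defaultStainBasis()) {
  channel <- match.arg(channel)
  switch(channel,
         blue = extractBlueChannel(rgb),
         brown_axis = brownAxis(rgb),
         dab_deconv = colorDeconvolution(rgb, basis)$dab)
}
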