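#' Extract the pixel matrix of an image-like object
#'
#' @param x an [IntensityImage] or [BinaryMask].
#' @return the underlying numeric matrix (rows = y, cols = x).
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname pixels
#' @export
setMethod("pixels", "IntensityImage", function(x) x@pixels)

#' @rdname pixels
#' @export
setMethod("pixels", "BinaryMask", function(x) x@pixels)

#' Channel tag of an intensity image
#'
#' @param x an [IntensityImage].
#' @return the character tag of the colour separation that produced `x`.
#' @export
setGeneric("channelTag", function(x) standardGeneric("channelTag"))

#' @rdname channelTag
#' @export
setMethod("channelTag", "IntensityImage", function(x) x@channel)

#' Stain matrix of a basis
#'
#' @param x a [StainBasis].
#' @return the 3x3 matrix whose columns are the unit stain vectors.
#' @export
setGeneric("stainMatrix", function(x) standardGeneric("stainMatrix"))

#' @rdname stainMatrix
#' @export
setMethod("stainMatrix", "StainBasis", function(x) x@M)

setMethod("show", "IntensityImage", function(object) {
  p <- object@pixels
  cat(sprintf("IntensityImage %dx%d, channel '%s', range [%g, %g]\n",
              nrow(p), ncol(p), object@channel, min(p), max(p)))
})

setMethod("show", "BinaryMask", function(object) {
  p <- object@pixels
  cat(sprintf("BinaryMask %dx%d, %d object pixels (%.2f%%)\n",
              nrow(p), ncol(p), sum(p == 0), 100 * mean(p == 0)))
})

setMethod("show", "WindowStats", function(object) {
  cat(sprintf("WindowStats %dx%d, window %dx%d\n",
              nrow(object@mean), ncol(object@mean), object@w, object@w))
})

setMethod("show", "StainBasis", function(object) {
  cat("StainBasis (columns = unit OD vectors):\n")
  print(round(object@M, 4))
})

setMethod("show", "ThresholdParams", function(object) {
  cat(sprintf(
    "ThresholdParams: w=%d k=%g R=%g bias=%g Tc=%g\n  Palumbo T1=%g T2=%g; Yasuda T1=%g T2=%g T3=%g T4=%g\n",
    object@w, object@k, object@R, object@bias, object@Tc,
    object@palumboT1, object@palumboT2,
    object@T1, object@T2, object@T3, object@T4))
})

setMethod("show", "SceneConfig", function(object) {
  cat(sprintf(
    "SceneConfig '%s': %dx%d px, %d brown + %d blue nuclei, area %g+/-%g, seed %d\n",
    object@name, object@width, object@height, object@nBrown, object@nBlue,
    object@areaMean, object@areaSd, object@seed))
})

setMethod("show", "TemplatePair", function(object) {
  d <- dim(object@rgb)
  cat(sprintf(
    "TemplatePair '%s': %dx%d RGB, %d template objects\n",
    object@scene@name, d[1], d[2], sum(object@nuclei$class == "brown")))
})
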