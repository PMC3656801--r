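# Sliding-window statistics engine. All maps are computed on a mirror-padded
# copy of the image (reflection about the edge pixel, no duplication), so a
# pixel at the border sees a plausible neighbourhood instead of an artificial
# intensity step. Sums use running-window accumulation, extrema the van
# Herk-Gil-Werman algorithm; both are O(N) per image independent of w.

# Reflect-pad a matrix by p pixels on every side.
mirrorPad <- function(m, p) {
  if (p == 0L) return(m)
  H <- nrow(m); W <- ncol(m)
  if (p >= H || p >= W)
    stop("padding (", p, " px) must be smaller than the image")
  ri <- c(seq(p + 1L, 2L), seq_len(H), seq(H - 1L, H - p))
  ci <- c(seq(p + 1L, 2L), seq_len(W), seq(W - 1L, W - p))
  m[ri, ci]
}

# w x w box sum / extremum of a mirror-padded image, evaluated at every
# original pixel. `pad` may exceed (w-1)/2; `shift` moves the window centre.
boxSumPadded <- function(padded, w) {
  t(cpp_runsum_cols(t(cpp_runsum_cols(padded, w)), w))
}

boxExtPadded <- function(padded, w, maximum) {
  t(cpp_runext_cols(t(cpp_runext_cols(padded, w, maximum)), w, maximum))
}

#' Sliding-window statistics
#'
#' Computes per-pixel mean, population standard deviation (divide by `w^2`),
#' minimum, maximum and contrast (max - min) of the `w x w` neighbourhood
#' centred on each pixel. Borders are mirror padded.
#'
#' @param img an [IntensityImage] or numeric matrix.
#' @param w odd window side length in pixels.
#' @return a [WindowStats] object.
#' @examples
#' s <- windowStats(matrix(100, 8, 8), 3)
#' stopifnot(all(s@sd == 0), all(s@mean == 100))
#' @export
windowStats <- function(img, w) {
  m <- asIntensityMatrix(img)
  w <- as.integer(w)
  if (w %% 2L == 0L || w < 3L) stop("w must be odd and >= 3")
  p <- (w - 1L) %/% 2L
  P <- mirrorPad(m, p)
  n <- as.numeric(w)^2
  mu <- boxSumPadded(P, w) / n
  musq <- boxSumPadded(P * P, w) / n
  sdm <- sqrt(pmax(musq - mu * mu, 0))
  mn <- boxExtPadded(P, w, FALSE)
  mx <- boxExtPadded(P, w, TRUE)
  new("WindowStats", mean = mu, sd = sdm, min = mn, max = mx,
      contrast = mx - mn, w = w)
}

# Tile means for the Palumbo centre-surround scheme: the w x w window is cut
# into a 3 x 3 grid of s x s tiles (s = w / 3). Returns the mean of the
# central tile and the mean over the union of the four corner tiles (equal
# tile sizes, so the union mean is the average of the four tile means), both
# computed on the mirror-padded image.
palumboTileMeans <- function(m, w) {
  w <- as.integer(w)
  if (w %% 3L != 0L) stop("Palumbo requires w divisible by 3")
  s <- w %/% 3L
  if (s %% 2L == 0L) stop("Palumbo tile size w/3 must be odd")
  H <- nrow(m); W <- ncol(m)
  ptot <- s + (s - 1L) %/% 2L
  P <- mirrorPad(m, ptot)
  B <- boxSumPadded(P, s) / as.numeric(s)^2   # (H + 2s) x (W + 2s)
  tile <- function(dr, dc) B[(seq_len(H)) + dr + s, (seq_len(W)) + dc + s]
  center <- tile(0L, 0L)
  neigh <- (tile(-s, -s) + tile(-s, s) + tile(s, -s) + tile(s, s)) / 4
  list(center = center, neigh = neigh)
}

# Separable Gaussian blur with mirror padding (kernel truncated at 3 sigma).
gaussianBlur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  P <- mirrorPad(m, r)
  t(cpp_conv_cols(t(cpp_conv_cols(P, k)), k))
}
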