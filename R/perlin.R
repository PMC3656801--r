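# Gradient (Perlin) noise, used to texture immunonegative nuclei ("curly"
# chromatin), to modulate the brown fill weakly and to bend the background
# illumination. Classic lattice-gradient construction with a seeded
# permutation table; fully vectorised over the pixel grid.

perlinOctave <- function(xs, ys, perm, grad) {
  xi <- floor(xs); yi <- floor(ys)
  xf <- xs - xi; yf <- ys - yi
  fade <- function(t) t * t * t * (t * (t * 6 - 15) + 10)
  u <- fade(xf); v <- fade(yf)
  hash <- function(ix, iy) {
    # perm is a 0..255 permutation, 1-indexed lookup
    perm[(ix + perm[(iy %% 256L) + 1L]) %% 256L + 1L]
  }
  corner <- function(ix, iy, dx, dy) {
    g <- hash(ix, iy) %% 8L + 1L
    grad[g, 1L] * dx + grad[g, 2L] * dy
  }
  xi <- as.integer(xi %% 256L); yi <- as.integer(yi %% 256L)
  n00 <- corner(xi, yi, xf, yf)
  n10 <- corner((xi + 1L) %% 256L, yi, xf - 1, yf)
  n01 <- corner(xi, (yi + 1L) %% 256L, xf, yf - 1)
  n11 <- corner((xi + 1L) %% 256L, (yi + 1L) %% 256L, xf - 1, yf - 1)
  nx0 <- n00 + u * (n10 - n00)
  nx1 <- n01 + u * (n11 - n01)
  nx0 + v * (nx1 - nx0)
}

#' Perlin gradient-noise texture
#'
#' Smooth pseudo-random field on a pixel grid, deterministic for a fixed
#' seed, normalised to `[0, 1]` (field minimum maps to 0, maximum to 1).
#' `scale` is the side length in pixels of one lattice cell of the base
#' octave; successive octaves double the frequency and halve the amplitude.
#'
#' @param H,W output size in pixels.
#' @param scale base lattice cell size in px (> 0); small values give a
#'   fine, curly texture.
#' @param octaves number of octaves to sum (default 3).
#' @param seed integer RNG seed for the gradient permutation.
#' @return H x W numeric matrix in `[0, 1]`.
#' @export
perlinTexture <- function(H, W, scale, octaves = 3L, seed = 1L) {
  if (scale <= 0) stop("scale must be > 0")
  s2 <- 1 / sqrt(2)
  grad <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                c(s2, s2), c(-s2, s2), c(s2, -s2), c(-s2, -s2))
  out <- withSeed(seed, {
    perm <- sample.int(256L) - 1L
    # random lattice offset so fields with different seeds are uncorrelated
    # even on the integer grid
    off <- runif(2L, 0, 256)
    ys <- matrix((seq_len(H) - 1), H, W) # rows
    xs <- matrix((seq_len(W) - 1), H, W, byrow = TRUE)
    acc <- matrix(0, H, W)
    amp <- 1
    for (o in seq_len(octaves)) {
      f <- 2^(o - 1) / scale
      acc <- acc + amp * perlinOctave(xs * f + off[1], ys * f + off[2],
                                      perm, grad)
      amp <- amp / 2
    }
    acc
  })
  rng <- range(out)
  if (rng[2] > rng[1]) (out - rng[1]) / (rng[2] - rng[1])
  else out * 0 + 0.5
}
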