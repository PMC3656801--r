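# Brute-force reference implementations, deliberately written as literal
# per-pixel loops so they stay independent of the package's incremental
# algorithms.

# reflect an out-of-range index about the edges (mirror without edge
# duplication), matching np.pad-style "reflect"
reflectIdx <- function(i, n) {
  while (i < 1L || i > n) {
    if (i < 1L) i <- 2L - i
    if (i > n) i <- 2L * n - i
  }
  i
}

windowPixels <- function(m, x, y, w) {
  p <- (w - 1L) %/% 2L
  vals <- numeric(w * w)
  q <- 1L
  for (dc in -p:p) for (dr in -p:p) {
    vals[q] <- m[reflectIdx(x + dr, nrow(m)), reflectIdx(y + dc, ncol(m))]
    q <- q + 1L
  }
  vals
}

bruteWindowStats <- function(m, w) {
  H <- nrow(m); W <- ncol(m)
  mu <- sdv <- mn <- mx <- matrix(0, H, W)
  for (x in seq_len(H)) for (y in seq_len(W)) {
    v <- windowPixels(m, x, y, w)
    mu[x, y] <- sum(v) / length(v)
    sdv[x, y] <- sqrt(sum((v - mu[x, y])^2) / length(v))
    mn[x, y] <- min(v)
    mx[x, y] <- max(v)
  }
  list(mean = mu, sd = sdv, min = mn, max = mx, contrast = mx - mn)
}

# mean of the s x s tile centred at (x + dr, y + dc), reflect-padded
bruteTileMean <- function(m, x, y, dr, dc, s) {
  p <- (s - 1L) %/% 2L
  tot <- 0
  for (a in -p:p) for (b in -p:p)
    tot <- tot + m[reflectIdx(x + dr + a, nrow(m)),
                   reflectIdx(y + dc + b, ncol(m))]
  tot / (s * s)
}

brutePalumbo <- function(m, params) {
  s <- params@w %/% 3L
  H <- nrow(m); W <- ncol(m)
  out <- matrix(1, H, W)
  for (x in seq_len(H)) for (y in seq_len(W)) {
    ac <- bruteTileMean(m, x, y, 0L, 0L, s)
    an <- (bruteTileMean(m, x, y, -s, -s, s) +
           bruteTileMean(m, x, y, -s, s, s) +
           bruteTileMean(m, x, y, s, -s, s) +
           bruteTileMean(m, x, y, s, s, s)) / 4
    if (m[x, y] < params@palumboT1 || params@palumboT2 * an > ac)
      out[x, y] <- 0
  }
  out
}

# the four Yasuda steps written out literally
bruteYasuda <- function(m, params) {
  rng <- range(m)
  if (rng[2] <= rng[1]) return(matrix(1, nrow(m), ncol(m)))
  i1 <- 255 * (m - rng[1]) / (rng[2] - rng[1])
  H <- nrow(m); W <- ncol(m)
  i2 <- i1
  for (x in seq_len(H)) for (y in seq_len(W)) {
    v <- windowPixels(i1, x, y, 3L)
    if (max(v) - min(v) < params@T1) i2[x, y] <- sum(v) / length(v)
  }
  i3 <- matrix(0, H, W)
  for (x in seq_len(H)) for (y in seq_len(W)) {
    v <- windowPixels(i2, x, y, params@w)
    mw <- sum(v) / length(v)
    cw <- max(v) - min(v)
    i3[x, y] <- if (mw < i2[x, y] || cw < params@T2) 255
                else 255 * (i2[x, y] - min(v)) / cw
  }
  out <- matrix(1, H, W)
  for (x in seq_len(H)) for (y in seq_len(W)) {
    v <- windowPixels(i3, x, y, 3L)
    mu <- sum(v) / length(v)
    sdv <- sqrt(sum((v - mu)^2) / length(v))
    if (min(v) < params@T3 || sdv > params@T4) out[x, y] <- 0
  }
  out
}

# 8-connected labelling by BFS flood fill, scanning in raster order
bruteLabel8 <- function(mask01) {
  obj <- mask01 == 0
  H <- nrow(obj); W <- ncol(obj)
  lab <- matrix(0L, H, W)
  nxt <- 0L
  for (r in seq_len(H)) for (cc in seq_len(W)) {
    if (!obj[r, cc] || lab[r, cc] > 0L) next
    nxt <- nxt + 1L
    queue <- list(c(r, cc))
    lab[r, cc] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dr in -1:1) for (dc in -1:1) {
        nr <- p[1] + dr; nc <- p[2] + dc
        if (nr >= 1 && nr <= H && nc >= 1 && nc <= W &&
            obj[nr, nc] && lab[nr, nc] == 0L) {
          lab[nr, nc] <- nxt
          queue[[length(queue) + 1L]] <- c(nr, nc)
        }
      }
    }
  }
  lab
}

randIntensity <- function(H, W, seed) {
  set.seed(seed)
  matrix(sample(0:255, H * W, replace = TRUE), H, W)
}

# a filled disc mask (0 = object) at integer centre
discMask <- function(H, W, cx, cy, r) {
  m <- matrix(1, H, W)
  for (x in seq_len(H)) for (y in seq_len(W))
    if ((x - cy)^2 + (y - cx)^2 <= r^2) m[x, y] <- 0
  m
}

# small scene used by the benchmark tests (fast to render and segment)
smallScene <- function(seed = 3L, ...) {
  args <- list(name = "small", width = 320L, height = 320L, nBrown = 5L,
               nBlue = 25L, areaMean = 1200, areaSd = 150, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(sceneConfig, args)
}
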