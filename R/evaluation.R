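# Agreement between a segmentation mask and the ground-truth template:
# pixel-level confusion counts and similarity coefficients, object-level
# matching and counting, per-object shape features, Bland-Altman agreement
# tables and the quasi-Bland-Altman co-localisation statistic.

asMaskMatrix <- function(x) {
  m <- if (is(x, "BinaryMask")) x@pixels else x
  if (!is.matrix(m) || !all(m == 0 | m == 1))
    stop("expected a BinaryMask or a {0,1} matrix")
  m
}

#' Pixel confusion counts
#'
#' Counts agreement between a segmentation and the template under the
#' 0 = object convention: TP = both object, TN = both background, FP =
#' detected object where the template has background, FN = missed object.
#'
#' @param mask,template [BinaryMask]s or `{0,1}` matrices of identical
#'   shape (0 = object).
#' @return named numeric vector `c(TP, TN, FP, FN)`.
#' @export
confusionCounts <- function(mask, template) {
  m <- asMaskMatrix(mask); t <- asMaskMatrix(template)
  if (!identical(dim(m), dim(t))) stop("mask and template shapes differ")
  c(TP = sum(m == 0 & t == 0), TN = sum(m == 1 & t == 1),
    FP = sum(m == 0 & t == 1), FN = sum(m == 1 & t == 0))
}

#' Pixel-level agreement metrics
#'
#' Sensitivity `S = TP/(TP+FN)`, specificity `P = TN/(TN+FP)`, Dice
#' `r_D = 2TP/(2TP+FN+FP)`, Jaccard `r_J = TP/(TP+FN+FP)`, Sokal-Sneath
#' `r_SS = TP/(TP+2FN+2FP)`, Rogers-Tanimoto
#' `r_RT = (TP+TN)/(TP+TN+2FN+2FP)`, plus overall pixel accuracy
#' `(TP+TN)/total` and pixel precision `TP/(TP+FP)`. Ratios with a zero
#' denominator are reported as `NA`.
#'
#' @param counts named vector from [confusionCounts()].
#' @return named numeric vector
#'   `c(S, P, rD, rJ, rSS, rRT, accuracy, precision)`.
#' @export
agreementMetrics <- function(counts) {
  TP <- counts[["TP"]]; TN <- counts[["TN"]]
  FP <- counts[["FP"]]; FN <- counts[["FN"]]
  total <- TP + TN + FP + FN
  if (total == 0) stop("all confusion counts are zero")
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  c(S = ratio(TP, TP + FN),
    P = ratio(TN, TN + FP),
    rD = ratio(2 * TP, 2 * TP + FN + FP),
    rJ = ratio(TP, TP + FN + FP),
    rSS = ratio(TP, TP + 2 * FN + 2 * FP),
    rRT = ratio(TP + TN, TP + TN + 2 * FN + 2 * FP),
    accuracy = ratio(TP + TN, total),
    precision = ratio(TP, TP + FP))
}

#' Match detected objects to template objects
#'
#' A detected object matches a template object when their pixel
#' intersection exceeds 50% of the template object's area. Matches are
#' one-to-one, resolved greedily by descending intersection (ties broken by
#' lower template, then lower detected label). Unmatched detected objects
#' are false-positive objects, unmatched template objects false negatives.
#'
#' @param detected,template label matrices (or lists from
#'   [labelObjects()]) of identical shape.
#' @return list with `pairs` (data frame `template`, `detected`,
#'   `intersection`), `fpObjects` and `fnObjects` (integer label vectors),
#'   and `nDetected`/`nTemplate`.
#' @export
matchObjects <- function(detected, template) {
  dl <- if (is.list(detected)) detected$labels else detected
  tl <- if (is.list(template)) template$labels else template
  if (!identical(dim(dl), dim(tl))) stop("label map shapes differ")
  nd <- max(dl); nt <- max(tl)
  tArea <- if (nt > 0) tabulate(tl[tl > 0L], nt) else integer(0)
  both <- dl > 0L & tl > 0L
  pairs <- data.frame(template = integer(0), detected = integer(0),
                      intersection = integer(0))
  if (any(both)) {
    key <- paste(tl[both], dl[both])
    cnt <- table(key)
    parts <- do.call(rbind, strsplit(names(cnt), " ", fixed = TRUE))
    cand <- data.frame(template = as.integer(parts[, 1]),
                       detected = as.integer(parts[, 2]),
                       intersection = as.integer(cnt))
    cand <- cand[order(-cand$intersection, cand$template, cand$detected), ]
    usedT <- logical(nt); usedD <- logical(nd)
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      ti <- cand$template[i]; di <- cand$detected[i]
      if (usedT[ti] || usedD[di]) next
      if (cand$intersection[i] > 0.5 * tArea[ti]) {
        keep[i] <- TRUE; usedT[ti] <- TRUE; usedD[di] <- TRUE
      }
    }
    pairs <- cand[keep, , drop = FALSE]
    pairs <- pairs[order(pairs$template), , drop = FALSE]
    rownames(pairs) <- NULL
  }
  list(pairs = pairs,
       fpObjects = setdiff(seq_len(nd), pairs$detected),
       fnObjects = setdiff(seq_len(nt), pairs$template),
       nDetected = nd, nTemplate = nt)
}

#' Object-count accuracy and precision
#'
#' `object_accuracy = matched / n_template`, `object_precision = matched /
#' n_detected` and `count_error = n_detected - n_template`. Precision is
#' `NA` when nothing was detected.
#'
#' @param match result of [matchObjects()].
#' @param nTemplate,nDetected optional overrides of the object counts
#'   (default: taken from `match`).
#' @return named numeric vector.
#' @export
objectCountMetrics <- function(match, nTemplate = match$nTemplate,
                               nDetected = match$nDetected) {
  m <- nrow(match$pairs)
  c(accuracy = if (nTemplate > 0) m / nTemplate else NA_real_,
    precision = if (nDetected > 0) m / nDetected else NA_real_,
    countError = nDetected - nTemplate)
}

# Moore 8-neighbour contour tracing; returns the boundary length with
# unit steps for orthogonal moves and sqrt(2) for diagonal ones. A single
# pixel has perimeter 1 by convention.
tracePerimeter <- function(obj) {
  H <- nrow(obj); W <- ncol(obj)
  if (sum(obj) == 1L) return(1)
  # pad so tracing never leaves the matrix
  P <- matrix(FALSE, H + 2L, W + 2L)
  P[2:(H + 1L), 2:(W + 1L)] <- obj
  idx <- which(P)
  start <- idx[1]
  sr <- (start - 1L) %% nrow(P) + 1L
  sc <- (start - 1L) %/% nrow(P) + 1L
  # neighbour offsets clockwise starting west
  dr <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  steps <- sqrt(dr^2 + dc^2)
  per <- 0
  r <- sr; cc <- sc; dir <- 1L  # came from the west
  repeat {
    found <- FALSE
    for (q in 0:7) {
      d <- (dir + 4L + 1L + q) %% 8L + 1L  # start after backtrack direction
      nr <- r + dr[d]; nc <- cc + dc[d]
      if (P[nr, nc]) {
        per <- per + steps[d]
        r <- nr; cc <- nc; dir <- d
        found <- TRUE
        break
      }
    }
    if (!found) return(1)  # isolated pixel
    if (r == sr && cc == sc) break
  }
  per
}

#' Shape features of labelled objects
#'
#' For each object: pixel `area`; `perimeter` by 8-neighbour contour
#' tracing (orthogonal steps count 1, diagonal steps `sqrt(2)`; a 1-px
#' object has perimeter 1 by convention); `roundness = 4*pi*area /
#' perimeter^2`; `solidity` = area / convex hull area (hull taken over
#' pixel corners, so solidity <= 1); `eccentricity` and `axisRatio` of the
#' ellipse with the same second moments as the object (pixel-centre moments
#' plus the 1/12 single-pixel term, so a 1-px object has eccentricity 0);
#' and the centroid `cx`/`cy` in px.
#'
#' @param labels label matrix (or [labelObjects()] list).
#' @param ids which labels to measure (default all).
#' @return data frame, one row per object.
#' @export
objectFeatures <- function(labels, ids = NULL) {
  lab <- if (is.list(labels)) labels$labels else labels
  n <- max(lab)
  if (is.null(ids)) ids <- seq_len(n)
  H <- nrow(lab)
  res <- lapply(ids, function(id) {
    idx <- which(lab == id)
    if (!length(idx)) stop("label ", id, " not present")
    r <- (idx - 1L) %% H + 1L
    cc <- (idx - 1L) %/% H + 1L
    area <- length(idx)
    cx <- mean(cc); cy <- mean(r)
    # second central moments with the single-pixel (1/12) term
    mxx <- mean((cc - cx)^2) + 1 / 12
    myy <- mean((r - cy)^2) + 1 / 12
    mxy <- mean((cc - cx) * (r - cy))
    common <- sqrt((mxx - myy)^2 + 4 * mxy^2)
    l1 <- (mxx + myy + common) / 2
    l2 <- (mxx + myy - common) / 2
    ecc <- if (l1 > 0) sqrt(pmax(0, 1 - l2 / l1)) else 0
    axisRatio <- if (l2 > 0) sqrt(l1 / l2) else Inf
    # local window for perimeter tracing
    r0 <- min(r); c0 <- min(cc)
    obj <- matrix(FALSE, max(r) - r0 + 1L, max(cc) - c0 + 1L)
    obj[cbind(r - r0 + 1L, cc - c0 + 1L)] <- TRUE
    per <- tracePerimeter(obj)
    # convex hull over the 4 corners of every pixel
    px <- c(cc - 0.5, cc - 0.5, cc + 0.5, cc + 0.5)
    py <- c(r - 0.5, r + 0.5, r - 0.5, r + 0.5)
    h <- grDevices::chull(px, py)
    hx <- px[h]; hy <- py[h]
    hullArea <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
    data.frame(label = id, area = area, perimeter = per,
               roundness = 4 * pi * area / per^2,
               solidity = area / hullArea,
               eccentricity = ecc, axisRatio = axisRatio,
               cx = cx, cy = cy)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Bland-Altman agreement table
#'
#' For paired measurements of the same objects (template value vs detected
#' value) returns the per-pair mean and difference (detected - template),
#' the bias (mean difference) and the 1.96-sd limits of agreement.
#'
#' @param template,detected numeric vectors of equal length.
#' @return list with `table` (data frame `mean`, `difference`), `bias`,
#'   `sdDiff`, `loa` (length-2 vector).
#' @export
blandAltman <- function(template, detected) {
  if (length(template) != length(detected)) stop("lengths differ")
  if (!length(template)) stop("empty input")
  diff <- detected - template
  bias <- mean(diff)
  s <- if (length(diff) > 1) sd(diff) else 0
  list(table = data.frame(mean = (template + detected) / 2,
                          difference = diff),
       bias = bias, sdDiff = s, loa = bias + c(-1.96, 1.96) * s)
}

#' Quasi-Bland-Altman co-localisation statistic
#'
#' For every matched (template, detected) object pair, the erroneously
#' detected area relative to the true object,
#' `error_ratio = (FP_area + FN_area) / template_area`, is paired with the
#' Euclidean distance between the two objects' centroids. Small distance
#' with a large ratio indicates errors distributed homogeneously around the
#' object boundary; a large distance indicates a directional bias.
#'
#' @param match result of [matchObjects()].
#' @param detected,template the label matrices used for the matching.
#' @return data frame with one row per matched pair: `template`,
#'   `detected`, `centroidDistance`, `errorRatio`, `fpArea`, `fnArea`,
#'   `templateArea`.
#' @export
quasiBA <- function(match, detected, template) {
  dl <- if (is.list(detected)) detected$labels else detected
  tl <- if (is.list(template)) template$labels else template
  H <- nrow(tl)
  res <- lapply(seq_len(nrow(match$pairs)), function(i) {
    ti <- match$pairs$template[i]; di <- match$pairs$detected[i]
    tIdx <- which(tl == ti); dIdx <- which(dl == di)
    inter <- match$pairs$intersection[i]
    fp <- length(dIdx) - inter
    fn <- length(tIdx) - inter
    cen <- function(idx) c(mean((idx - 1L) %/% H + 1L),
                           mean((idx - 1L) %% H + 1L))
    ct <- cen(tIdx); cd <- cen(dIdx)
    data.frame(template = ti, detected = di,
               centroidDistance = sqrt(sum((ct - cd)^2)),
               errorRatio = (fp + fn) / length(tIdx),
               fpArea = fp, fnArea = fn, templateArea = length(tIdx))
  })
  out <- if (length(res)) do.call(rbind, res)
         else data.frame(template = integer(0), detected = integer(0),
                         centroidDistance = numeric(0),
                         errorRatio = numeric(0), fpArea = integer(0),
                         fnArea = integer(0), templateArea = integer(0))
  rownames(out) <- NULL
  out
}
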