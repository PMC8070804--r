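## Single-cell segmentation from NAD(P)H intensity images, following the
## classic CellProfiler recipe: mid-band threshold for (darker) nuclei,
## seeded propagation for whole cells, cytoplasm = cell minus nucleus.

#' Otsu thresholds for 2 or 3 intensity classes
#'
#' Exhaustive search over a histogram for the threshold set maximizing
#' between-class variance. With \code{nClasses = 3} the two thresholds
#' separate background / mid-band / bright pixels.
#'
#' @param x numeric matrix or vector of intensities.
#' @param nClasses 2 or 3.
#' @param nBins histogram resolution (default 128).
#' @return numeric vector of nClasses - 1 thresholds (intensity units).
#' @export
otsuThresholds <- function(x, nClasses = 2L, nBins = 128L) {
  x <- as.numeric(x)
  rng <- range(x, finite = TRUE)
  if (diff(rng) == 0) stop("constant image has no Otsu threshold")
  br <- seq(rng[1L], rng[2L], length.out = nBins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nBins)
  w <- h / sum(h)
  mids <- (br[-1L] + br[-(nBins + 1L)]) / 2
  cw <- cumsum(w)
  cm <- cumsum(w * mids)
  muT <- cm[nBins]
  classVar <- function(i0, i1) {  # bins i0..i1 (1-based, inclusive)
    wk <- cw[i1] - if (i0 > 1L) cw[i0 - 1L] else 0
    if (wk <= 0) return(0)
    mk <- (cm[i1] - if (i0 > 1L) cm[i0 - 1L] else 0) / wk
    wk * (mk - muT)^2
  }
  if (nClasses == 2L) {
    best <- -Inf; bi <- 1L
    for (i in seq_len(nBins - 1L)) {
      v <- classVar(1L, i) + classVar(i + 1L, nBins)
      if (v > best) { best <- v; bi <- i }
    }
    return(br[bi + 1L])
  }
  if (nClasses != 3L) stop("nClasses must be 2 or 3")
  best <- -Inf; bi <- c(1L, 2L)
  for (i in seq_len(nBins - 2L)) {
    vi <- classVar(1L, i)
    for (j in (i + 1L):(nBins - 1L)) {
      v <- vi + classVar(i + 1L, j) + classVar(j + 1L, nBins)
      if (v > best) { best <- v; bi <- c(i, j) }
    }
  }
  br[bi + 1L]
}

## solidity = pixel count / lattice-point estimate of the convex-hull area
## (shoelace area + boundary/2 + 1, Pick-style, over pixel centers)
.solidity <- function(rows, cols) {
  n <- length(rows)
  if (n < 4L) return(1)
  pts <- cbind(rows, cols)
  hull <- grDevices::chull(pts)
  if (length(hull) < 3L) return(1)  # collinear object: treat as solid
  hp <- pts[hull, , drop = FALSE]
  m <- nrow(hp)
  nxt <- c(2:m, 1L)
  area <- abs(sum(hp[, 1L] * hp[nxt, 2L] - hp[nxt, 1L] * hp[, 2L])) / 2
  perim <- sum(sqrt(rowSums((hp[nxt, , drop = FALSE] - hp)^2)))
  min(n / (area + perim / 2 + 1), 1)
}

## eccentricity from second-order pixel moments (0 = circle, -> 1 = line)
.eccentricity <- function(rows, cols) {
  n <- length(rows)
  if (n < 3L) return(0)
  cv <- stats::cov(cbind(rows, cols)) * (n - 1) / n + diag(2) / 12
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  if (ev[1L] <= 0) return(0)
  sqrt(max(0, 1 - ev[2L] / ev[1L]))
}

#' Detect nuclei in an NAD(P)H intensity image
#'
#' Nuclei appear as a mid-intensity band between dark background and bright
#' cytoplasm in NAD(P)H images. A three-class Otsu threshold extracts that
#' band, touching nuclei are split by a distance-transform watershed, and
#' the resulting objects are filtered for area and roundness (eccentricity
#' and solidity).
#'
#' @param nadhIntensity 2-d non-negative intensity matrix.
#' @param config a \linkS4class{FlimConfig} (area range, eccentricity and
#'   solidity filters).
#' @return integer label matrix; 0 labels on a blank image.
#' @export
detectNuclei <- function(nadhIntensity, config = flimConfig()) {
  stopifnot(is.matrix(nadhIntensity), all(nadhIntensity >= 0))
  empty <- matrix(0L, nrow(nadhIntensity), ncol(nadhIntensity))
  if (diff(range(nadhIntensity)) == 0) return(empty)
  thr <- otsuThresholds(nadhIntensity, 3L)
  band <- nadhIntensity > thr[1L] & nadhIntensity <= thr[2L]
  if (!any(band)) return(empty)
  band <- EBImage::fillHull(band * 1) > 0
  dm <- EBImage::distmap(band * 1)
  labs <- EBImage::imageData(EBImage::watershed(dm, tolerance = 1))
  keep <- integer(0)
  px <- which(labs > 0, arr.ind = TRUE)
  byLab <- split(seq_len(nrow(px)), labs[labs > 0])
  for (lb in names(byLab)) {
    ii <- byLab[[lb]]
    a <- length(ii)
    if (a < config@nucleusAreaRange[1L] || a > config@nucleusAreaRange[2L])
      next
    if (.eccentricity(px[ii, 1L], px[ii, 2L]) > config@maxEccentricity)
      next
    if (.solidity(px[ii, 1L], px[ii, 2L]) < config@minSolidity) next
    keep <- c(keep, as.integer(lb))
  }
  out <- empty
  for (k in seq_along(keep)) out[labs == keep[k]] <- k
  out
}

#' Propagate cell bodies out from nuclear seeds
#'
#' Intensity-guided geodesic propagation (the CellProfiler secondary-object
#' algorithm) from each nucleus, restricted to foreground pixels above a
#' global two-class Otsu threshold so propagation cannot continue into
#' background. Every nucleus pixel keeps its seed label.
#'
#' @param nuclei integer label matrix of seeds.
#' @param nadhIntensity intensity matrix guiding the propagation cost.
#' @param config a \linkS4class{FlimConfig}.
#' @param lambda regularization balancing intensity versus Euclidean
#'   distance in the propagation cost (default 1e-4).
#' @return integer cell label matrix (label i grown from nucleus i).
#' @export
propagateCells <- function(nuclei, nadhIntensity, config = flimConfig(),
                           lambda = 1e-4) {
  stopifnot(is.matrix(nuclei), identical(dim(nuclei), dim(nadhIntensity)))
  if (all(nuclei == 0L)) return(nuclei)
  fg <- if (diff(range(nadhIntensity)) == 0) nuclei > 0
        else nadhIntensity > otsuThresholds(nadhIntensity, 2L)
  fg <- fg | nuclei > 0  # seeds are always claimable
  cells <- EBImage::imageData(
    EBImage::propagate(nadhIntensity, nuclei, mask = fg, lambda = lambda))
  storage.mode(cells) <- "integer"
  cells
}

#' Cytoplasm labels: cell minus nucleus
#'
#' @param cells,nuclei integer label matrices; each nucleus pixel must carry
#'   its cell's label (violations are an error).
#' @return integer cytoplasm label matrix.
#' @export
cytoplasmMask <- function(cells, nuclei) {
  stopifnot(identical(dim(cells), dim(nuclei)))
  nz <- nuclei > 0
  if (any(cells[nz] != nuclei[nz]))
    stop("nuclei must lie inside cells of the same label")
  cyto <- cells
  cyto[nz] <- 0L
  storage.mode(cyto) <- "integer"
  cyto
}

#' Segment cells from an NAD(P)H intensity image
#'
#' Convenience pipeline: \code{\link{detectNuclei}},
#' \code{\link{propagateCells}}, \code{\link{cytoplasmMask}}, returned as a
#' validated \linkS4class{LabelMasks} (label-consistency invariants are
#' checked on construction).
#'
#' @param nadhIntensity intensity matrix.
#' @param config a \linkS4class{FlimConfig}.
#' @return a \linkS4class{LabelMasks}.
#' @export
segmentCells <- function(nadhIntensity, config = flimConfig()) {
  nuc <- detectNuclei(nadhIntensity, config)
  cells <- propagateCells(nuc, nadhIntensity, config)
  labelMasks(nuc, cells)
}

#' Percent of objects positive for a marker
#'
#' The colocalization counter used for immunofluorescence scoring: an object
#' (e.g., a DAPI nucleus) is positive when the marker mask covers at least
#' \code{minOverlapFrac} of its area; the result is 100 x positive / total.
#'
#' @param primaryLabels integer label matrix of counted objects.
#' @param markerMask logical (or 0/1) matrix of marker-positive pixels.
#' @param minOverlapFrac minimum overlap fraction (default 0.25).
#' @return percent of objects positive, in [0, 100].
#' @export
percentPositive <- function(primaryLabels, markerMask,
                            minOverlapFrac = 0.25) {
  stopifnot(identical(dim(primaryLabels), dim(markerMask)))
  marker <- markerMask > 0
  labs <- primaryLabels[primaryLabels > 0]
  if (length(labs) == 0L) stop("no objects in primaryLabels")
  area <- table(labs)
  hit <- table(factor(primaryLabels[primaryLabels > 0 & marker],
                      levels = names(area)))
  100 * mean(as.numeric(hit) / as.numeric(area) >= minOverlapFrac)
}
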