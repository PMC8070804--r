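## Decay model, IRF reconvolution, and per-pixel fitting.

#' Amplitude-weighted mean lifetime
#'
#' tau_m = alpha1 * tau1 + alpha2 * tau2, the standard summary of a
#' two-component fluorescence decay.
#'
#' @param x a \linkS4class{BiExpParams}, or a numeric vector of alpha1 values
#'   (the numeric method vectorizes over pixels/cells).
#' @param ... for the numeric method: \code{tau1}, \code{tau2} and optionally
#'   \code{alpha2} (default \code{1 - alpha1}).
#' @return mean lifetime in nanoseconds.
#' @examples
#' meanLifetime(biExpParams(0.7, 0.4, 2.5))   # 1.03 ns
#' meanLifetime(c(0.5, 0.7), tau1 = 0.4, tau2 = 2.5)
#' @export
setGeneric("meanLifetime", function(x, ...) standardGeneric("meanLifetime"))

#' @rdname meanLifetime
#' @export
setMethod("meanLifetime", "BiExpParams", function(x, ...) {
  x@alpha1 * x@tau1 + x@alpha2 * x@tau2
})

#' @rdname meanLifetime
#' @export
setMethod("meanLifetime", "numeric", function(x, tau1, tau2,
                                              alpha2 = 1 - x, ...) {
  x * tau1 + alpha2 * tau2
})

## linear (open) convolution of a decay curve with an IRF kernel on the same
## grid, truncated to the first n bins
.convolveIrf <- function(decay, kernel) {
  n <- length(decay)
  full <- stats::convolve(decay, rev(kernel), type = "open")
  full[seq_len(n)]
}

#' Expected decay curve under the bi-exponential model
#'
#' Samples I(t) = alpha1 exp(-t/tau1) + alpha2 exp(-t/tau2) at the time-bin
#' centers, convolves it with the normalized IRF kernel (the forward model of
#' iterative reconvolution), scales by \code{ampl}, and adds the background
#' offset C after the convolution.
#'
#' @param params a \linkS4class{BiExpParams}.
#' @param irf an \linkS4class{InstrumentResponse} on the same time grid.
#' @param nBins number of time bins.
#' @param binWidthNs bin width in nanoseconds; must match the IRF grid.
#' @param ampl amplitude at t = 0 in counts (default 1).
#' @return numeric vector of expected counts per bin (non-negative).
#' @examples
#' irf <- instrumentResponse(c(1, numeric(63)), 0.2)
#' modelDecay(biExpParams(0.7, 0.4, 2.5), irf, 64, 0.2)
#' @export
modelDecay <- function(params, irf, nBins, binWidthNs, ampl = 1) {
  stopifnot(is(params, "BiExpParams"), is(irf, "InstrumentResponse"))
  if (abs(irf@binWidthNs - binWidthNs) > 1e-9 * binWidthNs)
    stop("time-grid mismatch: IRF bin width differs from requested grid")
  if (length(irf@kernel) != nBins)
    stop("time-grid mismatch: IRF kernel length differs from nBins")
  tt <- (seq_len(nBins) - 0.5) * binWidthNs
  d <- params@alpha1 * exp(-tt / params@tau1) +
       params@alpha2 * exp(-tt / params@tau2)
  m <- ampl * .convolveIrf(d, irf@kernel) + params@offsetC
  pmax(m, 0)
}

## raw model evaluation used inside the optimizer (no S4 dispatch per call)
.decayModelRaw <- function(tt, kernel, ampl, alpha1, tau1, tau2, C) {
  d <- alpha1 * exp(-tt / tau1) + (1 - alpha1) * exp(-tt / tau2)
  ampl * .convolveIrf(d, kernel) + C
}

## core weighted LM fit; mono = TRUE pins alpha1 = 1 and fits (ampl, tau1, C).
## "mle": Poisson deviance residuals, so least squares == Poisson maximum
## likelihood — unbiased in the low-counts-per-bin regime. "neyman":
## classical chi-square with counts clipped at 1.
.fitDecayCore <- function(counts, binWidthNs, kernel, init, lower, upper,
                          mono = FALSE, weighting = c("mle", "neyman")) {
  weighting <- match.arg(weighting)
  n <- length(counts)
  tt <- (seq_len(n) - 0.5) * binWidthNs
  evalModel <- if (mono) {
    function(p) .decayModelRaw(tt, kernel, p[1L], 1, p[2L], p[2L] + 1, p[3L])
  } else {
    function(p) .decayModelRaw(tt, kernel, p[1L], p[2L], p[3L], p[4L], p[5L])
  }
  if (weighting == "mle") {
    pos <- counts > 0
    resid <- function(p) {
      m <- pmax(evalModel(p), 1e-12)
      dev <- m - counts
      dev[pos] <- dev[pos] + counts[pos] * log(counts[pos] / m[pos])
      sign(counts - m) * sqrt(pmax(2 * dev, 0))
    }
  } else {
    w <- 1 / sqrt(pmax(counts, 1))
    resid <- function(p) (evalModel(p) - counts) * w
  }
  ctl <- minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-10,
                                    ptol = 1e-10)
  fit <- minpack.lm::nls.lm(par = init, lower = lower, upper = upper,
                            fn = resid, control = ctl)
  p <- fit$par
  chi2 <- sum(fit$fvec^2) / max(n - length(init), 1L)
  list(par = p, chi2 = chi2, converged = fit$info %in% 1:4)
}

#' Fit a two-component decay by iterative reconvolution
#'
#' Least-squares fit of \code{\link{modelDecay}} against a photon histogram,
#' with free parameters amplitude, alpha1, tau1, tau2 and background C.
#' The default "mle" weighting minimizes Poisson deviance residuals
#' (equivalent to Poisson maximum likelihood, unbiased at low counts per
#' bin); "neyman" gives the classical chi-square with counts clipped at 1. If the optimizer returns
#' tau1 >= tau2 the component pairs are swapped so the short-lifetime
#' component is always first.
#'
#' @param decay a \linkS4class{DecayHistogram}.
#' @param irf an \linkS4class{InstrumentResponse} on the same grid.
#' @param init a \linkS4class{BiExpParams} of starting values (default: the
#'   NAD(P)H initials of \code{\link{flimConfig}}).
#' @param tauBounds named numeric (tau1Lo, tau1Hi, tau2Lo, tau2Hi) in ns.
#' @param photonThreshold minimum total photons; below it the fit refuses
#'   with an "insufficient photons" error.
#' @param weighting "mle" (Poisson deviance, default) or "neyman".
#' @return a \linkS4class{FitResult}; \code{chi2Reduced} is the reduced
#'   deviance under "mle" weighting.
#' @examples
#' irf <- instrumentResponse(c(1, numeric(255)), 0.0122)
#' truth <- biExpParams(0.7, 0.4, 2.5)
#' y <- modelDecay(truth, irf, 256, 0.0122, ampl = 5000)
#' fitBiexponential(decayHistogram(y, 0.0122), irf)
#' @export
fitBiexponential <- function(decay, irf,
                             init = biExpParams(0.7, 0.4, 2.5),
                             tauBounds = c(tau1Lo = 0.05, tau1Hi = 1.5,
                                           tau2Lo = 0.8, tau2Hi = 8),
                             photonThreshold = 500,
                             weighting = c("mle", "neyman")) {
  stopifnot(is(decay, "DecayHistogram"), is(irf, "InstrumentResponse"))
  counts <- decay@counts
  photons <- sum(counts)
  if (photons < photonThreshold)
    stop(sprintf("insufficient photons: %g < threshold %g",
                 photons, photonThreshold))
  if (length(irf@kernel) != length(counts))
    stop("time-grid mismatch between decay and IRF")
  ampl0 <- max(counts)
  p0 <- c(ampl0, init@alpha1, init@tau1, init@tau2, init@offsetC)
  lower <- c(0, 0, tauBounds[["tau1Lo"]], tauBounds[["tau2Lo"]], 0)
  upper <- c(Inf, 1, tauBounds[["tau1Hi"]], tauBounds[["tau2Hi"]], Inf)
  f <- .fitDecayCore(counts, decay@binWidthNs, irf@kernel, p0, lower, upper,
                     weighting = match.arg(weighting))
  ampl <- f$par[1L]; a1 <- f$par[2L]
  t1 <- f$par[3L]; t2 <- f$par[4L]; C <- f$par[5L]
  if (t1 >= t2) {  # swap so tau1 < tau2 always
    tmp <- t1; t1 <- t2; t2 <- tmp
    a1 <- 1 - a1
  }
  if (t2 <= t1) t2 <- t1 * (1 + 1e-9)  # degenerate equal-lifetime fit
  new("FitResult",
      params = biExpParams(alpha1 = a1, tau1 = t1, tau2 = t2, offsetC = C),
      ampl = ampl, chi2Reduced = f$chi2, photons = photons,
      converged = f$converged)
}

#' Fit a single-exponential decay
#'
#' Same reconvolution machinery as \code{\link{fitBiexponential}} with the
#' second component's amplitude pinned to zero; used for lifetime standards
#' such as daily fluorescent-microsphere measurements.
#'
#' @param decay a \linkS4class{DecayHistogram}.
#' @param irf an \linkS4class{InstrumentResponse} on the same grid.
#' @param tauInit starting lifetime in ns (default 2).
#' @param tauBounds lifetime search interval in ns.
#' @param photonThreshold minimum total photons.
#' @param weighting "mle" (Poisson deviance, default) or "neyman".
#' @return fitted lifetime in nanoseconds (scalar), with attributes
#'   \code{converged}, \code{chi2Reduced} and \code{ampl}.
#' @export
fitMonoexponential <- function(decay, irf, tauInit = 2,
                               tauBounds = c(0.05, 10),
                               photonThreshold = 500,
                               weighting = c("mle", "neyman")) {
  stopifnot(is(decay, "DecayHistogram"), is(irf, "InstrumentResponse"))
  counts <- decay@counts
  photons <- sum(counts)
  if (photons < photonThreshold)
    stop(sprintf("insufficient photons: %g < threshold %g",
                 photons, photonThreshold))
  if (length(irf@kernel) != length(counts))
    stop("time-grid mismatch between decay and IRF")
  p0 <- c(max(counts), tauInit, 0)
  f <- .fitDecayCore(counts, decay@binWidthNs, irf@kernel, p0,
                     lower = c(0, tauBounds[1L], 0),
                     upper = c(Inf, tauBounds[2L], Inf), mono = TRUE,
                     weighting = match.arg(weighting))
  structure(f$par[2L], converged = f$converged, chi2Reduced = f$chi2,
            ampl = f$par[1L])
}

#' Full width at half maximum of an IRF
#'
#' Locates the half-maximum crossings on either side of the kernel peak by
#' linear interpolation between bins and returns their distance in
#' picoseconds.
#'
#' @param irf an \linkS4class{InstrumentResponse}.
#' @return FWHM in picoseconds.
#' @examples
#' irfFwhm(defaultIrf())   # ~220 ps
#' @export
irfFwhm <- function(irf) {
  stopifnot(is(irf, "InstrumentResponse"))
  k <- irf@kernel
  tt <- (seq_along(k) - 0.5) * irf@binWidthNs
  ip <- which.max(k)
  half <- k[ip] / 2
  iL <- which(k[seq_len(ip)] < half)
  iR <- which(k[ip:length(k)] < half) + ip - 1L
  if (length(iL) == 0L || length(iR) == 0L)
    stop("IRF kernel does not fall below half maximum on both sides")
  iL <- max(iL)  # last bin below half on the rising edge
  tL <- tt[iL] + (half - k[iL]) / (k[iL + 1L] - k[iL]) * irf@binWidthNs
  iR <- min(iR)  # first bin below half on the falling edge
  tR <- tt[iR - 1L] + (k[iR - 1L] - half) / (k[iR - 1L] - k[iR]) *
    irf@binWidthNs
  (tR - tL) * 1000
}

#' Spatially bin a FLIM stack
#'
#' Replaces each pixel's decay with the sum over its (2r+1) x (2r+1)
#' neighborhood, clipped at the image edge — the standard TCSPC move to
#' reach fittable photon counts per pixel.
#'
#' @param stack a \linkS4class{FlimStack}.
#' @param radius neighborhood radius r >= 0 (0 is the identity).
#' @return a \linkS4class{FlimStack} of the same shape.
#' @export
binPixels <- function(stack, radius) {
  stopifnot(is(stack, "FlimStack"), radius >= 0)
  radius <- as.integer(radius)
  if (radius == 0L) return(stack)
  a <- stack@counts
  d <- dim(a)
  out <- array(0, d)
  ## box filter via padded cumulative sums, per time bin
  for (tb in seq_len(d[1L])) {
    m <- a[tb, , ]
    cs <- matrix(0, d[2L] + 1L, d[3L] + 1L)
    cs[-1L, -1L] <- t(apply(apply(m, 2L, cumsum), 1L, cumsum))
    r1 <- pmax(seq_len(d[2L]) - radius, 1L); r2 <- pmin(seq_len(d[2L]) + radius, d[2L])
    c1 <- pmax(seq_len(d[3L]) - radius, 1L); c2 <- pmin(seq_len(d[3L]) + radius, d[3L])
    out[tb, , ] <- cs[r2 + 1L, c2 + 1L, drop = FALSE] -
      cs[r1, c2 + 1L, drop = FALSE] -
      cs[r2 + 1L, c1, drop = FALSE] + cs[r1, c1, drop = FALSE]
  }
  flimStack(out, stack@binWidthNs, stack@channel, stack@pixelSizeUm)
}

#' Photon-sum intensity image
#'
#' Total fluorescence intensity per pixel, computed by summing the photons
#' detected in every time bin.
#'
#' @param stack a \linkS4class{FlimStack}.
#' @return numeric matrix (row, col) of photon sums.
#' @export
intensityImage <- function(stack) {
  stopifnot(is(stack, "FlimStack"))
  colSums(stack@counts, dims = 1L)
}

#' Fit every pixel of a FLIM stack
#'
#' Applies \code{\link{binPixels}}, then fits each pixel whose binned decay
#' clears the photon threshold with \code{\link{fitBiexponential}} (initials
#' chosen by channel). Pixels below threshold, or whose fit fails to
#' converge, are marked invalid. The intensity map is the unbinned photon
#' sum.
#'
#' @param stack a \linkS4class{FlimStack}.
#' @param irf an \linkS4class{InstrumentResponse} on the stack's grid.
#' @param config a \linkS4class{FlimConfig}.
#' @return a \linkS4class{LifetimeImageSet}.
#' @export
fitImage <- function(stack, irf, config = flimConfig()) {
  stopifnot(is(stack, "FlimStack"), is(irf, "InstrumentResponse"))
  init <- if (stack@channel == "NADH") config@nadhInit else config@fadInit
  initP <- biExpParams(init[["alpha1"]], init[["tau1"]], init[["tau2"]])
  intens <- intensityImage(stack)
  binned <- binPixels(stack, config@binRadius)
  binnedSum <- colSums(binned@counts, dims = 1L)
  d <- dim(intens)
  tau1 <- tau2 <- alpha1 <- tauM <- matrix(NA_real_, d[1L], d[2L])
  valid <- matrix(FALSE, d[1L], d[2L])
  idx <- which(binnedSum >= config@photonThreshold, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1L]; j <- idx[k, 2L]
    fr <- tryCatch(
      fitBiexponential(
        decayHistogram(binned@counts[, i, j], stack@binWidthNs), irf,
        init = initP, tauBounds = config@tauBounds,
        photonThreshold = config@photonThreshold,
        weighting = config@weighting),
      error = function(e) NULL)
    if (is.null(fr) || !fr@converged) next
    p <- fr@params
    tau1[i, j] <- p@tau1; tau2[i, j] <- p@tau2; alpha1[i, j] <- p@alpha1
    tauM[i, j] <- meanLifetime(p)
    valid[i, j] <- TRUE
  }
  new("LifetimeImageSet", tau1 = tau1, tau2 = tau2, alpha1 = alpha1,
      tauM = tauM, intensity = intens, validMask = valid,
      channel = stack@channel)
}
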