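#' @import methods
NULL

#' DecayHistogram: a TCSPC photon-arrival histogram
#'
#' Photon counts per time bin for one pixel or region, on a uniform time grid.
#' This is the object that decay fitting consumes.
#'
#' @slot counts non-negative numeric vector, photons per time bin.
#' @slot binWidthNs positive scalar, width of one time bin in nanoseconds.
#' @exportClass DecayHistogram
setClass("DecayHistogram",
  representation(counts = "numeric", binWidthNs = "numeric"),
  validity = function(object) {
    if (length(object@counts) < 2L) return("need at least 2 time bins")
    if (any(object@counts < 0) || anyNA(object@counts))
      return("counts must be non-negative and finite")
    if (length(object@binWidthNs) != 1L || object@binWidthNs <= 0)
      return("binWidthNs must be a positive scalar")
    TRUE
  })

#' Construct a DecayHistogram
#'
#' @param counts non-negative photon counts per time bin.
#' @param binWidthNs time-bin width in nanoseconds.
#' @return a \linkS4class{DecayHistogram}.
#' @examples
#' decayHistogram(rpois(256, 10), 0.0122)
#' @export
decayHistogram <- function(counts, binWidthNs) {
  new("DecayHistogram", counts = as.numeric(counts),
      binWidthNs = as.numeric(binWidthNs))
}

#' InstrumentResponse: the system's temporal blur kernel
#'
#' The instrument response function (IRF) of a TCSPC system, stored as a
#' non-negative kernel on the same time grid as the decays it blurs. The
#' kernel is normalized to unit sum on construction; decay models are
#' convolved with it during fitting ("iterative reconvolution").
#'
#' @slot kernel non-negative numeric vector summing to 1.
#' @slot binWidthNs positive scalar, nanoseconds per bin.
#' @exportClass InstrumentResponse
setClass("InstrumentResponse",
  representation(kernel = "numeric", binWidthNs = "numeric"),
  validity = function(object) {
    if (any(object@kernel < 0) || anyNA(object@kernel))
      return("kernel must be non-negative and finite")
    if (sum(object@kernel) <= 0) return("kernel must have positive mass")
    if (abs(sum(object@kernel) - 1) > 1e-8)
      return("kernel must be normalized to unit sum")
    if (length(object@binWidthNs) != 1L || object@binWidthNs <= 0)
      return("binWidthNs must be a positive scalar")
    TRUE
  })

#' Construct an InstrumentResponse
#'
#' The kernel is renormalized to unit sum.
#'
#' @param kernel non-negative weights per time bin.
#' @param binWidthNs time-bin width in nanoseconds.
#' @return an \linkS4class{InstrumentResponse}.
#' @examples
#' ## an ideal (delta) IRF on a 256-bin grid
#' instrumentResponse(c(1, numeric(255)), 0.0122)
#' @export
instrumentResponse <- function(kernel, binWidthNs) {
  kernel <- as.numeric(kernel)
  s <- sum(kernel)
  if (!is.finite(s) || s <= 0) stop("IRF kernel must have positive mass")
  new("InstrumentResponse", kernel = kernel / s,
      binWidthNs = as.numeric(binWidthNs))
}

#' BiExpParams: parameters of the two-component decay model
#'
#' The fluorescence decay model I(t) = a1*exp(-t/tau1) + a2*exp(-t/tau2) + C,
#' with fractional amplitudes a1 + a2 = 1 and lifetimes in nanoseconds. The
#' two components correspond to the short-lived (free) and long-lived
#' (protein-bound) conformations of NAD(P)H, and the reverse for FAD. C
#' accounts for background light.
#'
#' @slot alpha1,alpha2 fractional contributions, summing to 1.
#' @slot tau1,tau2 lifetimes in nanoseconds, 0 < tau1 < tau2.
#' @slot offsetC non-negative background counts per bin.
#' @exportClass BiExpParams
setClass("BiExpParams",
  representation(alpha1 = "numeric", alpha2 = "numeric",
                 tau1 = "numeric", tau2 = "numeric", offsetC = "numeric"),
  validity = function(object) {
    with_slots <- c(object@alpha1, object@alpha2, object@tau1, object@tau2,
                    object@offsetC)
    if (anyNA(with_slots) || any(!is.finite(with_slots)))
      return("all parameters must be finite")
    if (abs(object@alpha1 + object@alpha2 - 1) > 1e-9)
      return("alpha1 + alpha2 must equal 1")
    if (object@alpha1 < 0 || object@alpha2 < 0)
      return("fractional amplitudes must be non-negative")
    if (object@tau1 <= 0 || object@tau2 <= object@tau1)
      return("lifetimes must satisfy 0 < tau1 < tau2")
    if (object@offsetC < 0) return("offsetC must be non-negative")
    TRUE
  })

#' Construct BiExpParams
#'
#' @param alpha1 fractional contribution of the short component; alpha2 is
#'   1 - alpha1 unless given explicitly.
#' @param tau1,tau2 short and long lifetimes in nanoseconds (tau1 < tau2).
#' @param alpha2 fractional contribution of the long component.
#' @param offsetC background counts per bin (default 0).
#' @return a \linkS4class{BiExpParams}.
#' @examples
#' biExpParams(alpha1 = 0.7, tau1 = 0.4, tau2 = 2.5)
#' @export
biExpParams <- function(alpha1, tau1, tau2, alpha2 = 1 - alpha1, offsetC = 0) {
  new("BiExpParams", alpha1 = as.numeric(alpha1), alpha2 = as.numeric(alpha2),
      tau1 = as.numeric(tau1), tau2 = as.numeric(tau2),
      offsetC = as.numeric(offsetC))
}

#' FitResult: a fitted decay with diagnostics
#'
#' @slot params fitted \linkS4class{BiExpParams}.
#' @slot ampl total model amplitude at t = 0 (counts), scaling the unit-sum
#'   fractional model to the data.
#' @slot chi2Reduced reduced chi-square of the weighted fit.
#' @slot photons total photons in the fitted histogram.
#' @slot converged logical; optimizer convergence flag.
#' @exportClass FitResult
setClass("FitResult",
  representation(params = "BiExpParams", ampl = "numeric",
                 chi2Reduced = "numeric", photons = "numeric",
                 converged = "logical"),
  validity = function(object) {
    if (object@chi2Reduced < 0) return("chi2Reduced must be >= 0")
    if (object@photons < 0) return("photons must be >= 0")
    TRUE
  })

#' FlimStack: a time-resolved photon-count image stack
#'
#' One FLIM acquisition channel: an integer photon-count array indexed
#' (time_bin, row, col) with its time-bin width and channel identity.
#'
#' @slot counts non-negative array, dim (n_bins, n_rows, n_cols).
#' @slot binWidthNs positive scalar, nanoseconds per time bin.
#' @slot channel "NADH" or "FAD".
#' @slot pixelSizeUm pixel pitch in micrometers (NA if unknown).
#' @exportClass FlimStack
setClass("FlimStack",
  representation(counts = "array", binWidthNs = "numeric",
                 channel = "character", pixelSizeUm = "numeric"),
  validity = function(object) {
    d <- dim(object@counts)
    if (length(d) != 3L) return("counts must be a 3-d (time, row, col) array")
    if (d[1L] < 16L) return("need at least 16 time bins")
    if (any(object@counts < 0) || anyNA(object@counts))
      return("counts must be non-negative")
    if (length(object@binWidthNs) != 1L || object@binWidthNs <= 0)
      return("binWidthNs must be a positive scalar")
    if (!object@channel %in% c("NADH", "FAD"))
      return('channel must be "NADH" or "FAD"')
    TRUE
  })

#' Construct a FlimStack
#'
#' @param counts 3-d non-negative array (time_bin, row, col).
#' @param binWidthNs time-bin width in nanoseconds.
#' @param channel "NADH" or "FAD".
#' @param pixelSizeUm optional pixel pitch in micrometers.
#' @return a \linkS4class{FlimStack}.
#' @export
flimStack <- function(counts, binWidthNs, channel = c("NADH", "FAD"),
                      pixelSizeUm = NA_real_) {
  channel <- match.arg(channel)
  new("FlimStack", counts = counts, binWidthNs = as.numeric(binWidthNs),
      channel = channel, pixelSizeUm = as.numeric(pixelSizeUm))
}

#' LifetimeImageSet: per-pixel decay-fit maps for one channel
#'
#' Per-pixel maps of the fitted short and long lifetimes, the short-component
#' fraction, the amplitude-weighted mean lifetime, the photon-sum intensity,
#' and a validity mask marking pixels whose decays met the photon threshold
#' and converged.
#'
#' @slot tau1,tau2,alpha1,tauM numeric matrices (NA where invalid).
#' @slot intensity photon-sum matrix.
#' @slot validMask logical matrix.
#' @slot channel "NADH" or "FAD".
#' @exportClass LifetimeImageSet
setClass("LifetimeImageSet",
  representation(tau1 = "matrix", tau2 = "matrix", alpha1 = "matrix",
                 tauM = "matrix", intensity = "matrix", validMask = "matrix",
                 channel = "character"),
  validity = function(object) {
    d <- dim(object@tauM)
    for (s in c("tau1", "tau2", "alpha1", "intensity", "validMask"))
      if (!identical(dim(slot(object, s)), d))
        return("all maps must share one shape")
    if (!is.logical(object@validMask)) return("validMask must be logical")
    v <- object@validMask
    if (any(is.na(object@tauM[v]))) return("tauM must be defined where valid")
    if (any(object@tau1[v] >= object@tau2[v]))
      return("tau1 < tau2 must hold wherever valid")
    TRUE
  })

#' LabelMasks: nuclei, cell, and cytoplasm label images
#'
#' Integer label images sharing one coordinate frame; label i in
#' \code{nuclei} seeds label i in \code{cells}, and \code{cytoplasm} is the
#' cell minus its nucleus. Background is 0.
#'
#' @slot nuclei,cells,cytoplasm integer matrices of the same shape.
#' @exportClass LabelMasks
setClass("LabelMasks",
  representation(nuclei = "matrix", cells = "matrix", cytoplasm = "matrix"),
  validity = function(object) {
    if (!identical(dim(object@nuclei), dim(object@cells)) ||
        !identical(dim(object@nuclei), dim(object@cytoplasm)))
      return("masks must share one shape")
    if (any(object@nuclei < 0) || any(object@cells < 0) ||
        any(object@cytoplasm < 0))
      return("labels must be non-negative")
    nz <- object@nuclei > 0
    if (any(object@cells[nz] != object@nuclei[nz]))
      return("each nucleus must lie inside the cell of the same label")
    expected <- object@cells
    expected[nz] <- 0L
    if (any(object@cytoplasm != expected))
      return("cytoplasm must equal cells minus nuclei")
    TRUE
  })

#' Construct LabelMasks
#'
#' \code{cytoplasm} is derived from \code{cells} and \code{nuclei} when not
#' supplied.
#'
#' @param nuclei,cells integer label matrices (same shape; nucleus label i
#'   inside cell label i).
#' @param cytoplasm optional; defaults to cells with nucleus pixels zeroed.
#' @return a \linkS4class{LabelMasks}.
#' @export
labelMasks <- function(nuclei, cells, cytoplasm = NULL) {
  storage.mode(nuclei) <- "integer"
  storage.mode(cells) <- "integer"
  if (is.null(cytoplasm)) {
    cytoplasm <- cells
    cytoplasm[nuclei > 0L] <- 0L
  }
  storage.mode(cytoplasm) <- "integer"
  new("LabelMasks", nuclei = nuclei, cells = cells, cytoplasm = cytoplasm)
}

#' MixtureModel: a univariate Gaussian mixture fitted by EM
#'
#' Components are sorted by mean. AIC is 2k - 2 logLik with k = 3K - 1 free
#' parameters (K means, K standard deviations, K - 1 independent weights).
#'
#' @slot p component proportions, summing to 1.
#' @slot mu component means (sorted ascending).
#' @slot sigma component standard deviations.
#' @slot logLik maximized log-likelihood.
#' @slot aic Akaike information criterion.
#' @slot nCells number of observations fitted.
#' @slot seed RNG seed used for the restarts.
#' @exportClass MixtureModel
setClass("MixtureModel",
  representation(p = "numeric", mu = "numeric", sigma = "numeric",
                 logLik = "numeric", aic = "numeric", nCells = "integer",
                 seed = "integer"),
  validity = function(object) {
    k <- length(object@mu)
    if (length(object@p) != k || length(object@sigma) != k)
      return("p, mu, sigma must have one entry per component")
    if (abs(sum(object@p) - 1) > 1e-8) return("proportions must sum to 1")
    if (any(object@sigma <= 0)) return("sigma must be positive")
    if (is.unsorted(object@mu)) return("components must be sorted by mean")
    if (abs(object@aic - (2 * (3 * k - 1) - 2 * object@logLik)) > 1e-6)
      return("aic must equal 2(3K-1) - 2 logLik")
    TRUE
  })

#' FlimConfig: run configuration for the pipeline
#'
#' Collects the tunable parameters of every stage with their defaults:
#' pixel binning and photon threshold for fitting, initial values and bounds
#' for the decay model per channel, segmentation filters, the response-call
#' gates, and the mixture-model search settings.
#'
#' @slot binRadius pixel-binning radius r; each decay is summed over a
#'   (2r+1)^2 neighborhood before fitting.
#' @slot photonThreshold minimum photons (post-binning) for a decay fit.
#' @slot weighting decay-fit weighting, "mle" or "neyman".
#' @slot nadhInit,fadInit named numeric (alpha1, tau1, tau2): fit initials.
#' @slot tauBounds named numeric (tau1Lo, tau1Hi, tau2Lo, tau2Hi) in ns.
#' @slot nucleusAreaRange min/max nucleus area in pixels.
#' @slot maxEccentricity,minSolidity roundness filters for nuclei.
#' @slot minOverlapFrac object/marker overlap fraction for percentPositive.
#' @slot minValidPixels minimum valid cytoplasm pixels per retained cell.
#' @slot alpha ANOVA significance level.
#' @slot deltaCutoff Glass's delta cutoff for a meaningful effect.
#' @slot kMax largest number of mixture components considered.
#' @slot nRestarts EM restarts per K.
#' @slot minCells strict lower bound: groups need more than this many cells
#'   for subpopulation analysis.
#' @slot seed RNG seed recorded in outputs.
#' @exportClass FlimConfig
setClass("FlimConfig",
  representation(binRadius = "integer", photonThreshold = "numeric",
                 weighting = "character",
                 nadhInit = "numeric", fadInit = "numeric",
                 tauBounds = "numeric", nucleusAreaRange = "numeric",
                 maxEccentricity = "numeric", minSolidity = "numeric",
                 minOverlapFrac = "numeric", minValidPixels = "integer",
                 alpha = "numeric", deltaCutoff = "numeric",
                 kMax = "integer", nRestarts = "integer",
                 minCells = "integer", seed = "integer"),
  validity = function(object) {
    if (object@binRadius < 0L) return("binRadius must be >= 0")
    if (object@photonThreshold < 0) return("photonThreshold must be >= 0")
    if (!object@weighting %in% c("mle", "neyman"))
      return('weighting must be "mle" or "neyman"')
    for (s in c("nadhInit", "fadInit")) {
      v <- slot(object, s)
      if (!all(c("alpha1", "tau1", "tau2") %in% names(v)))
        return(sprintf("%s needs alpha1, tau1, tau2", s))
      if (v["alpha1"] < 0 || v["alpha1"] > 1) return("alpha1 init in [0,1]")
      if (v["tau1"] <= 0 || v["tau2"] <= v["tau1"])
        return("inits must satisfy 0 < tau1 < tau2")
    }
    b <- object@tauBounds
    if (!all(c("tau1Lo", "tau1Hi", "tau2Lo", "tau2Hi") %in% names(b)))
      return("tauBounds needs tau1Lo, tau1Hi, tau2Lo, tau2Hi")
    if (b["tau1Lo"] <= 0 || b["tau1Hi"] <= b["tau1Lo"] ||
        b["tau2Hi"] <= b["tau2Lo"])
      return("tauBounds must be positive and ordered")
    if (object@alpha <= 0 || object@alpha >= 1) return("alpha in (0,1)")
    if (object@deltaCutoff < 0) return("deltaCutoff must be >= 0")
    if (object@kMax < 1L) return("kMax must be >= 1")
    if (object@nRestarts < 1L) return("nRestarts must be >= 1")
    if (object@minCells < 1L) return("minCells must be >= 1")
    if (object@minOverlapFrac < 0 || object@minOverlapFrac > 1)
      return("minOverlapFrac in [0,1]")
    TRUE
  })

#' Build a run configuration
#'
#' Defaults follow standard TCSPC/OMI practice: 3x3 pixel binning with a
#' 500-photon fit threshold; NAD(P)H initials (alpha1 = 0.7, tau1 = 0.4 ns,
#' tau2 = 2.5 ns) and FAD initials (0.7, 0.3 ns, 2.0 ns) inside bounds
#' tau1 in [0.05, 1.5], tau2 in [0.8, 8] ns; ANOVA alpha 0.05 and a Glass's
#' delta cutoff of 0.75; mixture search over K = 1..3 with 100 EM restarts
#' and a strict >100-cell gate per (patient, condition) group.
#'
#' @param binRadius pixel-binning radius (default 1).
#' @param photonThreshold minimum photons per fitted decay (default 500).
#' @param weighting decay-fit weighting: "mle" (Poisson deviance, default)
#'   or "neyman" (chi-square, counts clipped at 1).
#' @param nadhInit,fadInit named numeric (alpha1, tau1, tau2) initials.
#' @param tauBounds named numeric (tau1Lo, tau1Hi, tau2Lo, tau2Hi), ns.
#' @param nucleusAreaRange nucleus area window in pixels, c(min, max).
#' @param maxEccentricity,minSolidity nucleus roundness filters.
#' @param minOverlapFrac overlap fraction for marker positivity (default 0.25).
#' @param minValidPixels minimum valid cytoplasm pixels per cell (default 10).
#' @param alpha significance level for the response ANOVA (default 0.05).
#' @param deltaCutoff Glass's delta cutoff (default 0.75).
#' @param kMax maximum mixture components (default 3).
#' @param nRestarts EM restarts per K (default 100).
#' @param minCells strict minimum group size for subpopulation analysis
#'   (default 100; groups need more than this).
#' @param seed RNG seed recorded in outputs.
#' @return a \linkS4class{FlimConfig}.
#' @examples
#' cfg <- flimConfig(binRadius = 0L, photonThreshold = 100)
#' @export
flimConfig <- function(binRadius = 1L, photonThreshold = 500,
                       weighting = c("mle", "neyman"),
                       nadhInit = c(alpha1 = 0.7, tau1 = 0.4, tau2 = 2.5),
                       fadInit = c(alpha1 = 0.7, tau1 = 0.3, tau2 = 2.0),
                       tauBounds = c(tau1Lo = 0.05, tau1Hi = 1.5,
                                     tau2Lo = 0.8, tau2Hi = 8),
                       nucleusAreaRange = c(15, 500),
                       maxEccentricity = 0.9, minSolidity = 0.8,
                       minOverlapFrac = 0.25, minValidPixels = 10L,
                       alpha = 0.05, deltaCutoff = 0.75,
                       kMax = 3L, nRestarts = 100L, minCells = 100L,
                       seed = NA_integer_) {
  new("FlimConfig", binRadius = as.integer(binRadius),
      photonThreshold = as.numeric(photonThreshold),
      weighting = match.arg(weighting),
      nadhInit = nadhInit, fadInit = fadInit, tauBounds = tauBounds,
      nucleusAreaRange = as.numeric(nucleusAreaRange),
      maxEccentricity = as.numeric(maxEccentricity),
      minSolidity = as.numeric(minSolidity),
      minOverlapFrac = as.numeric(minOverlapFrac),
      minValidPixels = as.integer(minValidPixels),
      alpha = as.numeric(alpha), deltaCutoff = as.numeric(deltaCutoff),
      kMax = as.integer(kMax), nRestarts = as.integer(nRestarts),
      minCells = as.integer(minCells), seed = as.integer(seed))
}
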