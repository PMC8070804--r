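#' Photon counts of an object
#'
#' @param x a \linkS4class{DecayHistogram} or \linkS4class{FlimStack}.
#' @return numeric vector (histogram) or 3-d array (stack).
#' @export
setGeneric("photonCounts", function(x) standardGeneric("photonCounts"))

#' @rdname photonCounts
#' @export
setMethod("photonCounts", "DecayHistogram", function(x) x@counts)

#' @rdname photonCounts
#' @export
setMethod("photonCounts", "FlimStack", function(x) x@counts)

#' Time-bin width in nanoseconds
#'
#' @param x a DecayHistogram, FlimStack or InstrumentResponse.
#' @return positive scalar (ns per bin).
#' @export
setGeneric("binWidthNs", function(x) standardGeneric("binWidthNs"))

#' @rdname binWidthNs
#' @export
setMethod("binWidthNs", "DecayHistogram", function(x) x@binWidthNs)

#' @rdname binWidthNs
#' @export
setMethod("binWidthNs", "FlimStack", function(x) x@binWidthNs)

#' @rdname binWidthNs
#' @export
setMethod("binWidthNs", "InstrumentResponse", function(x) x@binWidthNs)

#' Channel identity of a FLIM object
#'
#' @param x a FlimStack or LifetimeImageSet.
#' @return "NADH" or "FAD".
#' @export
setGeneric("flimChannel", function(x) standardGeneric("flimChannel"))

#' @rdname flimChannel
#' @export
setMethod("flimChannel", "FlimStack", function(x) x@channel)

#' @rdname flimChannel
#' @export
setMethod("flimChannel", "LifetimeImageSet", function(x) x@channel)

#' IRF kernel weights
#'
#' @param x an \linkS4class{InstrumentResponse}.
#' @return numeric vector summing to 1.
#' @export
irfKernel <- function(x) x@kernel

#' Fitted decay-model parameters
#'
#' @param x a \linkS4class{FitResult}.
#' @return a \linkS4class{BiExpParams}.
#' @export
fitParams <- function(x) x@params

#' Mixture-model component table
#'
#' @param x a \linkS4class{MixtureModel}.
#' @return data.frame with columns p, mu, sigma, one row per component.
#' @export
mixtureComponents <- function(x) data.frame(p = x@p, mu = x@mu, sigma = x@sigma)

#' Number of mixture components
#'
#' @param x a \linkS4class{MixtureModel}.
#' @return integer K.
#' @export
nComponents <- function(x) length(x@mu)

#' AIC of a fitted mixture
#'
#' @param x a \linkS4class{MixtureModel}.
#' @return 2(3K - 1) - 2 logLik.
#' @export
modelAIC <- function(x) x@aic

setMethod("show", "DecayHistogram", function(object) {
  cat(sprintf("DecayHistogram: %d bins x %.4g ns, %g photons\n",
              length(object@counts), object@binWidthNs, sum(object@counts)))
})

setMethod("show", "InstrumentResponse", function(object) {
  cat(sprintf("InstrumentResponse: %d bins x %.4g ns, FWHM %.0f ps\n",
              length(object@kernel), object@binWidthNs,
              irfFwhm(object)))
})

setMethod("show", "BiExpParams", function(object) {
  cat(sprintf(
    "BiExpParams: a1=%.3f t1=%.3f ns, a2=%.3f t2=%.3f ns, C=%.3g (tm=%.3f ns)\n",
    object@alpha1, object@tau1, object@alpha2, object@tau2, object@offsetC,
    meanLifetime(object)))
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult (%s, %g photons, chi2_r=%.3f):\n",
              if (object@converged) "converged" else "NOT converged",
              object@photons, object@chi2Reduced))
  show(object@params)
})

setMethod("show", "FlimStack", function(object) {
  d <- dim(object@counts)
  cat(sprintf("FlimStack [%s]: %d bins x %d x %d px, %.4g ns/bin, %g photons\n",
              object@channel, d[1L], d[2L], d[3L], object@binWidthNs,
              sum(object@counts)))
})

setMethod("show", "LifetimeImageSet", function(object) {
  cat(sprintf("LifetimeImageSet [%s]: %d x %d px, %d valid (%.0f%%)\n",
              object@channel, nrow(object@tauM), ncol(object@tauM),
              sum(object@validMask),
              100 * mean(object@validMask)))
})

setMethod("show", "LabelMasks", function(object) {
  cat(sprintf("LabelMasks: %d x %d px, %d cells\n",
              nrow(object@cells), ncol(object@cells),
              length(setdiff(unique(as.vector(object@cells)), 0L))))
})

setMethod("show", "MixtureModel", function(object) {
  cat(sprintf("MixtureModel: K=%d, n=%d, logLik=%.2f, AIC=%.2f\n",
              length(object@mu), object@nCells, object@logLik, object@aic))
  print(mixtureComponents(object), digits = 4)
})
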