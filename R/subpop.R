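## Single-cell subpopulation analysis: univariate Gaussian mixtures fitted
## by random-restart EM, AIC model selection, equal-area density curves,
## the >100-cell eligibility gate, and the weighted heterogeneity index.

## one EM run from a given start; returns parameters and log-likelihood
.emRun <- function(x, mu, sigma, p, tol = 1e-6, maxIter = 500L,
                   sigmaFloor = 0) {
  n <- length(x)
  K <- length(mu)
  llOld <- -Inf
  ll <- -Inf
  for (it in seq_len(maxIter)) {
    dens <- vapply(seq_len(K),
                   function(k) p[k] * stats::dnorm(x, mu[k], sigma[k]),
                   numeric(n))
    dim(dens) <- c(n, K)
    rs <- .rowSums(dens, n, K)
    rs[rs < 1e-300] <- 1e-300
    ll <- sum(log(rs))
    r <- dens / rs
    nk <- .colSums(r, n, K)
    nk[nk < 1e-12] <- 1e-12
    p <- nk / n
    mu <- .colSums(r * x, n, K) / nk
    dev <- (matrix(x, n, K) - matrix(mu, n, K, byrow = TRUE))^2
    sigma <- pmax(sqrt(.colSums(r * dev, n, K) / nk), sigmaFloor)
    if (is.finite(llOld) && abs(ll - llOld) < tol) break
    llOld <- ll
  }
  list(p = p, mu = mu, sigma = sigma, logLik = ll)
}

## a restart solution is degenerate when a "subpopulation" owns fewer than
## 5 cells or its SD collapsed onto the floor — not a population
.degenerateFit <- function(fit, n, sigmaFloor) {
  any(fit$p * n < 5) || any(fit$sigma <= sigmaFloor * 1.0001)
}

.asMixtureModel <- function(fit, n, seed) {
  ord <- order(fit$mu)
  k <- length(fit$mu)
  aic <- 2 * (3 * k - 1) - 2 * fit$logLik
  new("MixtureModel", p = fit$p[ord], mu = fit$mu[ord],
      sigma = fit$sigma[ord], logLik = fit$logLik, aic = aic,
      nCells = as.integer(n),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Fit a K-component Gaussian mixture by random-restart EM
#'
#' Expectation-maximization from \code{nRestarts} random initializations
#' (means drawn from the data, SDs at the data SD, uniform weights); the
#' restart with the best log-likelihood wins. Component SDs are floored at
#' 1e-4 of the data SD to prevent singular collapse. Degenerate data (all
#' values equal) with K > 1 returns a single-component-equivalent model
#' with a warning.
#'
#' @param values numeric vector, length >= 5 K.
#' @param K number of components.
#' @param nRestarts EM restarts (default 100).
#' @param seed RNG seed for the restarts (reproducible when set).
#' @param tol log-likelihood convergence tolerance (default 1e-6).
#' @param maxIter EM iteration cap per restart (default 500).
#' @return a \linkS4class{MixtureModel} (components sorted by mean).
#' @export
fitGmm <- function(values, K, nRestarts = 100L, seed = NULL, tol = 1e-6,
                   maxIter = 500L) {
  x <- as.numeric(values)
  n <- length(x)
  K <- as.integer(K)
  if (n < 5L * K)
    stop("need at least 5 observations per component")
  sdx <- stats::sd(x)
  if (sdx == 0) {
    if (K > 1L)
      warning("degenerate data (all values equal); collapsing to K = 1")
    eps <- max(abs(x[1L]) * 1e-8, .Machine$double.eps^0.5)
    ll <- sum(stats::dnorm(x, x[1L], eps, log = TRUE))
    return(.asMixtureModel(list(p = 1, mu = x[1L], sigma = eps,
                                logLik = ll), n, seed))
  }
  floor <- 1e-4 * sdx
  runAll <- function() {
    best <- bestAny <- NULL
    if (K == 1L) nRestarts <- 1L  # EM optimum is unique for one component
    for (r in seq_len(nRestarts)) {
      mu0 <- sample(x, K)
      fit <- .emRun(x, mu0, rep(sdx, K), rep(1 / K, K), tol = tol,
                    maxIter = maxIter, sigmaFloor = floor)
      if (is.null(bestAny) || fit$logLik > bestAny$logLik) bestAny <- fit
      if (.degenerateFit(fit, n, floor)) next
      if (is.null(best) || fit$logLik > best$logLik) best <- fit
    }
    if (is.null(best)) {
      warning("all ", nRestarts, " restarts degenerate; returning the ",
              "best collapsed solution")
      best <- bestAny
    }
    best
  }
  best <- if (is.null(seed) || is.na(seed)) runAll()
          else withr::with_seed(as.integer(seed), runAll())
  .asMixtureModel(best, n, seed)
}

#' Select the number of subpopulations by repeated AIC comparison
#'
#' The fit-and-select process is repeated \code{nRestarts} times: each
#' repeat runs one randomly initialized EM per candidate K = 1..\code{kMax}
#' and picks the minimum-AIC K (degenerate solutions — a component owning
#' fewer than 5 cells or a collapsed SD — are ineligible). The K chosen by
#' the majority of repeats wins (ties resolve to the smaller K), and the
#' best-log-likelihood fit at that K is returned. The consensus over
#' repeats makes the selection robust to the overfit local optima that a
#' single best-likelihood search hands to AIC; the cap of three components
#' further guards against over-fitting single-cell distributions.
#'
#' @param values numeric vector of per-cell OMI-index values.
#' @param kMax largest K considered (default 3).
#' @param nRestarts fit-and-select repeats (default 100).
#' @param seed RNG seed.
#' @return the selected \linkS4class{MixtureModel}; \code{attr(, "votes")}
#'   holds the per-K vote counts.
#' @export
selectModel <- function(values, kMax = 3L, nRestarts = 100L, seed = NULL) {
  x <- as.numeric(values)
  n <- length(x)
  kMax <- max(1L, min(as.integer(kMax), n %/% 5L))
  sdx <- stats::sd(x)
  if (kMax == 1L || sdx == 0)
    return(fitGmm(x, 1L, nRestarts = nRestarts, seed = seed))
  floor <- 1e-4 * sdx
  run <- function() {
    votes <- integer(kMax)
    best <- vector("list", kMax)
    for (r in seq_len(nRestarts)) {
      aics <- rep(Inf, kMax)
      for (k in seq_len(kMax)) {
        f <- .emRun(x, sample(x, k), rep(sdx, k), rep(1 / k, k),
                    sigmaFloor = floor)
        if (.degenerateFit(f, n, floor)) next
        aics[k] <- 2 * (3 * k - 1) - 2 * f$logLik
        if (is.null(best[[k]]) || f$logLik > best[[k]]$logLik)
          best[[k]] <- f
      }
      if (any(is.finite(aics)))
        votes[which.min(aics)] <- votes[which.min(aics)] + 1L
    }
    if (all(votes == 0L))
      return(fitGmm(x, 1L, nRestarts = 1L))
    kSel <- which.max(votes)
    out <- .asMixtureModel(best[[kSel]], n, seed)
    attr(out, "votes") <- votes
    out
  }
  if (is.null(seed) || is.na(seed)) run()
  else withr::with_seed(as.integer(seed), run())
}

#' Weighted heterogeneity index of a fitted mixture
#'
#' wH-index = sum_i (1 - p_i ln(p_i + 1)) (sigma_i + d_i), where p_i,
#' sigma_i are the proportion and SD of subpopulation i and d_i is the
#' distance between the subpopulation median (its mean, by Gaussian
#' symmetry) and the median of the entire cell distribution. Higher values
#' mean more cell-level metabolic heterogeneity.
#'
#' @param model a \linkS4class{MixtureModel}.
#' @param values the raw per-cell values the model was fitted to (the
#'   overall median is taken from these).
#' @return list with \code{wh_index}, per-component \code{terms} and
#'   \code{d}, and \code{overall_median}.
#' @examples
#' ## a single tight population: (1 - ln 2) * sigma
#' m <- fitGmm(rnorm(200, 0, 0.3), 1, seed = 1)
#' whIndex(m, rnorm(200, 0, 0.3))$wh_index
#' @export
whIndex <- function(model, values) {
  stopifnot(is(model, "MixtureModel"))
  med <- stats::median(values)
  d <- abs(model@mu - med)
  terms <- (1 - model@p * log(model@p + 1)) * (model@sigma + d)
  list(wh_index = sum(terms), terms = terms, d = d, overall_median = med)
}

#' Eligible groups for subpopulation analysis
#'
#' Robust mixture estimation needs more than \code{minN} cells per patient
#' per treatment condition; the gate is strict (a group of exactly
#' \code{minN} is excluded).
#'
#' @param table cell-record data.frame with patient_id and condition.
#' @param minN strict lower bound (default 100).
#' @return data.frame (patient_id, condition, n) of eligible groups.
#' @export
gateMinCells <- function(table, minN = 100L) {
  counts <- as.data.frame(table(patient_id = table$patient_id,
                                condition = table$condition),
                          stringsAsFactors = FALSE)
  names(counts)[3L] <- "n"
  counts <- counts[counts$n > minN, , drop = FALSE]
  counts <- counts[order(counts$patient_id, counts$condition), ,
                   drop = FALSE]
  rownames(counts) <- NULL
  counts
}

#' Mixture density curve, normalized to unit area
#'
#' The fitted mixture probability density evaluated on a grid — by
#' construction every curve has equal (unit) area, so distributions from
#' groups of different sizes are directly comparable.
#'
#' @param model a \linkS4class{MixtureModel}.
#' @param grid evaluation points; default covers all components to +/- 8 SD
#'   with 1024 points.
#' @return data.frame (x, density).
#' @export
normalizedDensity <- function(model, grid = NULL) {
  stopifnot(is(model, "MixtureModel"))
  if (is.null(grid)) {
    lo <- min(model@mu - 8 * model@sigma)
    hi <- max(model@mu + 8 * model@sigma)
    grid <- seq(lo, hi, length.out = 1024L)
  }
  dens <- rep(0, length(grid))
  for (k in seq_along(model@mu))
    dens <- dens + model@p[k] * stats::dnorm(grid, model@mu[k],
                                             model@sigma[k])
  data.frame(x = grid, density = dens)
}
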