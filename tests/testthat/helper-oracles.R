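## Independent oracles used across the suite. These deliberately avoid the
## package's own code paths: direct sums, loops, and closed forms only.

## brute-force discrete convolution truncated to length(d)
refConvolve <- function(d, k) {
  n <- length(d)
  vapply(seq_len(n), function(j) sum(k[seq_len(j)] * d[j:1]), numeric(1))
}

## bi-exponential curve sampled at bin centers
refBiexp <- function(alpha1, tau1, tau2, n, dt, ampl = 1, C = 0) {
  tt <- (seq_len(n) - 0.5) * dt
  ampl * (alpha1 * exp(-tt / tau1) + (1 - alpha1) * exp(-tt / tau2)) + C
}

## object-level F1 between two label images at an IoU threshold
refObjectF1 <- function(truth, pred, iouMin = 0.5) {
  tl <- setdiff(unique(as.vector(truth)), 0L)
  pl <- setdiff(unique(as.vector(pred)), 0L)
  if (length(tl) == 0L && length(pl) == 0L) return(1)
  matched <- 0L
  for (a in tl) {
    ai <- truth == a
    best <- 0
    for (b in pl) {
      bi <- pred == b
      best <- max(best, sum(ai & bi) / sum(ai | bi))
    }
    if (best >= iouMin) matched <- matched + 1L
  }
  2 * matched / (length(tl) + length(pl))
}

## term-by-term weighted heterogeneity index
refWhIndex <- function(p, mu, sigma, values) {
  med <- median(values)
  s <- 0
  for (i in seq_along(p))
    s <- s + (1 - p[i] * log(p[i] + 1)) * (sigma[i] + abs(mu[i] - med))
  s
}

## textbook two-group one-way ANOVA from sums of squares
refAnovaF <- function(a, b) {
  g <- c(rep(1, length(a)), rep(2, length(b)))
  v <- c(a, b)
  gm <- mean(v)
  ssb <- length(a) * (mean(a) - gm)^2 + length(b) * (mean(b) - gm)^2
  ssw <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
  dfb <- 1L
  dfw <- length(v) - 2L
  F <- (ssb / dfb) / (ssw / dfw)
  list(F = F, p = pf(F, dfb, dfw, lower.tail = FALSE))
}

## a tiny uniform-intensity LifetimeImageSet for feature tests
makeUniformMaps <- function(dim, tau1, tau2, alpha1, intensity,
                            channel = "NADH", valid = NULL) {
  if (is.null(valid)) valid <- matrix(TRUE, dim[1], dim[2])
  mk <- function(v) {
    m <- matrix(v, dim[1], dim[2])
    m[!valid] <- NA_real_
    m
  }
  new("LifetimeImageSet", tau1 = mk(tau1), tau2 = mk(tau2),
      alpha1 = mk(alpha1), tauM = mk(alpha1 * tau1 + (1 - alpha1) * tau2),
      intensity = matrix(intensity, dim[1], dim[2]), validMask = valid,
      channel = channel)
}

## a MixtureModel with a consistent AIC slot, for formula tests
makeMixture <- function(p, mu, sigma, logLik = 0, n = 10L) {
  k <- length(p)
  new("MixtureModel", p = p, mu = mu, sigma = sigma, logLik = logLik,
      aic = 2 * (3 * k - 1) - 2 * logLik, nCells = as.integer(n),
      seed = NA_integer_)
}

## small intensity image with disk "nuclei" and annulus "cytoplasm"
makeDiskImage <- function(size, centers, rNuc, rCell, bg = 10, nuc = 60,
                          cyto = 150) {
  img <- matrix(bg, size, size)
  xg <- matrix(seq_len(size), size, size)
  yg <- t(xg)
  for (i in seq_len(nrow(centers))) {
    d2 <- (xg - centers[i, 1])^2 + (yg - centers[i, 2])^2
    img[d2 <= rCell^2] <- cyto
    img[d2 <= rNuc^2] <- nuc
  }
  img
}
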