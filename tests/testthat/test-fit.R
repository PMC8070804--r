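test_that("modelDecay with a delta IRF reproduces the pure bi-exponential", {
  n <- 128L; dt <- 0.05
  irf <- instrumentResponse(c(1, numeric(n - 1L)), dt)
  p <- biExpParams(0.7, 0.4, 2.5)
  expect_equal(modelDecay(p, irf, n, dt, ampl = 100),
               refBiexp(0.7, 0.4, 2.5, n, dt, ampl = 100), tolerance = 1e-12)
  ## alpha2 = 0 gives a mono-exponential shape
  pm <- biExpParams(1, 1.2, 3)
  m <- modelDecay(pm, irf, n, dt)
  tt <- (seq_len(n) - 0.5) * dt
  expect_equal(m, exp(-tt / 1.2), tolerance = 1e-12)
})

test_that("modelDecay matches a direct-sum convolution oracle", {
  n <- 200L; dt <- 0.05
  tt <- (seq_len(n) - 0.5) * dt
  k <- dnorm(tt, 0.6, 0.1); k <- k / sum(k)
  irf <- instrumentResponse(k, dt)
  for (par in list(c(0.7, 0.4, 2.5, 0), c(0.3, 0.2, 1.1, 5),
                   c(0.95, 0.08, 4, 0.2))) {
    p <- biExpParams(par[1], par[2], par[3], offsetC = par[4])
    d <- refBiexp(par[1], par[2], par[3], n, dt)
    expect_equal(modelDecay(p, irf, n, dt, ampl = 50),
                 50 * refConvolve(d, k) + par[4], tolerance = 1e-10)
  }
  expect_error(modelDecay(biExpParams(0.7, 0.4, 2.5), irf, 100L, dt),
               "grid")
})

test_that("photon conservation: default-window truncation loses < 1%", {
  dt <- 0.0122
  irf <- instrumentResponse(c(1, numeric(1023L)), dt)
  p <- biExpParams(0.7, 0.4, 2.5)
  onWindow <- sum(modelDecay(p, irf, 1024L, dt, ampl = 1))
  irfLong <- instrumentResponse(c(1, numeric(8191L)), dt)
  unbounded <- sum(modelDecay(p, irfLong, 8192L, dt, ampl = 1))
  expect_lt((unbounded - onWindow) / unbounded, 0.01)
})

test_that("meanLifetime equals the amplitude-weighted average", {
  expect_equal(meanLifetime(biExpParams(0.7, 0.4, 2.5)), 1.03)
  expect_equal(meanLifetime(biExpParams(1, 0.9, 2)), 0.9)  # alpha1 = 1
  set.seed(11)
  for (i in 1:1000) {
    a1 <- runif(1); t1 <- runif(1, 0.05, 1.5); t2 <- t1 + runif(1, 0.1, 5)
    expect_equal(meanLifetime(biExpParams(a1, t1, t2)),
                 a1 * t1 + (1 - a1) * t2, tolerance = 1e-12)
  }
})

test_that("irfFwhm is exact on rectangles and Gaussian-consistent", {
  dt <- 0.01
  ## rectangular kernel of width w has FWHM w
  for (w in c(5L, 11L, 30L)) {
    k <- numeric(200L); k[50:(49L + w)] <- 1
    expect_equal(irfFwhm(instrumentResponse(k, dt)), w * dt * 1000,
                 tolerance = dt * 1000)
  }
  ## sampled Gaussians match 2.3548 sigma within one bin
  tt <- (seq_len(512L) - 0.5) * dt
  for (sg in c(0.05, 0.0934, 0.2)) {
    k <- dnorm(tt, 1.5, sg)
    expect_equal(irfFwhm(instrumentResponse(k, dt)),
                 2 * sqrt(2 * log(2)) * sg * 1000, tolerance = dt * 1000)
  }
})

test_that("binPixels sums clipped neighborhoods", {
  a <- array(1, c(16L, 6L, 9L))
  st <- flimStack(a, 0.05, "NADH")
  expect_identical(photonCounts(binPixels(st, 0L)), a)
  b9 <- binPixels(st, 1L)
  expect_equal(photonCounts(b9)[1, 3, 5], 9)   # interior
  expect_equal(photonCounts(b9)[1, 1, 1], 4)   # corner, edge-clipped
  ## random stack against a sliding-window oracle
  set.seed(4)
  a <- array(rpois(16 * 5 * 7, 3), c(16L, 5L, 7L))
  got <- photonCounts(binPixels(flimStack(a, 0.05, "FAD"), 1L))
  for (i in 1:5) for (j in 1:7) {
    ri <- max(1, i - 1):min(5, i + 1)
    rj <- max(1, j - 1):min(7, j + 1)
    expect_equal(got[, i, j],
                 apply(a[, ri, rj, drop = FALSE], 1, sum))
  }
})

test_that("intensityImage sums photons over time", {
  z <- flimStack(array(0, c(16L, 4L, 4L)), 0.05, "NADH")
  expect_equal(intensityImage(z), matrix(0, 4, 4))
  a <- array(0, c(16L, 4L, 4L)); a[5, 2, 3] <- 1
  expect_equal(intensityImage(flimStack(a, 0.05, "NADH"))[2, 3], 1)
  set.seed(2)
  a <- array(rpois(16 * 4 * 4, 5), c(16L, 4L, 4L))
  expect_equal(intensityImage(flimStack(a, 0.05, "NADH")),
               apply(a, c(2, 3), sum))
})

test_that("noiseless bi-exponential fits recover the truth to 1e-3", {
  irf <- defaultIrf(0.0488, 256L)
  truth <- biExpParams(0.7, 0.4, 2.5)
  y <- modelDecay(truth, irf, 256L, 0.0488, ampl = 2e4)
  fr <- fitBiexponential(decayHistogram(y, 0.0488), irf)
  p <- fitParams(fr)
  expect_true(fr@converged)
  expect_equal(p@alpha1, 0.7, tolerance = 1e-3)
  expect_equal(p@tau1, 0.4, tolerance = 1e-3)
  expect_equal(p@tau2, 2.5, tolerance = 1e-3)
  expect_equal(fr@photons, sum(y))
})

test_that("fits enforce tau1 < tau2 and refuse starved decays", {
  irf <- defaultIrf(0.0488, 256L)
  expect_error(
    fitBiexponential(decayHistogram(numeric(256L), 0.0488), irf),
    "insufficient photons")
  ## start the optimizer upside down: ordering must still come out right
  truth <- biExpParams(0.35, 0.5, 2.2)
  y <- photonCounts(simulateDecay(truth, irf, 2e4, seed = 9))
  fr <- fitBiexponential(decayHistogram(y, 0.0488), irf,
                         init = biExpParams(0.2, 1.2, 1.4))
  expect_lt(fitParams(fr)@tau1, fitParams(fr)@tau2)
})

test_that("mono-exponential fits recover known lifetimes", {
  n <- 256L; dt <- 0.0488
  delta <- instrumentResponse(c(1, numeric(n - 1L)), dt)
  tt <- (seq_len(n) - 0.5) * dt
  y <- 5e3 * exp(-tt / 1.0)
  expect_equal(as.numeric(fitMonoexponential(decayHistogram(y, dt), delta)),
               1.0, tolerance = 1e-4)
  ## Poisson noise at 1e5 photons: mean of 20 seeds within 1%
  irf <- defaultIrf()
  p3 <- biExpParams(1, 3, 4)
  taus <- vapply(1:20, function(s)
    as.numeric(fitMonoexponential(
      simulateDecay(p3, irf, 1e5, seed = s), irf)), numeric(1))
  expect_equal(mean(taus), 3, tolerance = 0.01)
})

test_that("parameter recovery improves with photon count", {
  irf <- defaultIrf(0.0488, 256L)
  truth <- biExpParams(0.7, 0.4, 2.5)
  med <- vapply(c(1e3, 1e4, 1e5), function(ph) {
    errs <- vapply(1:25, function(s) {
      fr <- fitBiexponential(simulateDecay(truth, irf, ph, seed = s), irf,
                             photonThreshold = 200)
      abs(meanLifetime(fitParams(fr)) - 1.03) / 1.03
    }, numeric(1))
    median(errs)
  }, numeric(1))
  expect_true(all(diff(med) < 0))
})

test_that("fitImage marks starved pixels invalid and fits the rest", {
  irf <- defaultIrf(0.0488, 256L)
  empty <- flimStack(array(0, c(256L, 8L, 8L)), 0.0488, "NADH")
  lis <- fitImage(empty, irf, flimConfig(binRadius = 0L))
  expect_false(any(lis@validMask))
  ## single bright uniform region recovers its tau_m
  truth <- biExpParams(0.7, 0.4, 2.5)
  curve <- modelDecay(truth, irf, 256L, 0.0488)
  curve <- curve / sum(curve) * 4000
  a <- array(0, c(256L, 6L, 6L))
  set.seed(3)
  for (i in 3:4) for (j in 3:4) a[, i, j] <- rpois(256L, curve)
  lis <- fitImage(flimStack(a, 0.0488, "NADH"), irf,
                  flimConfig(binRadius = 0L, photonThreshold = 500))
  expect_true(all(lis@validMask[3:4, 3:4]))
  expect_false(lis@validMask[1, 1])
  expect_equal(mean(lis@tauM[3:4, 3:4]), 1.03, tolerance = 0.05)
})
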