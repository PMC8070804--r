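test_that("single-component EM recovers mean and SD", {
  x <- withr::with_seed(31, rnorm(500))
  m <- fitGmm(x, 1, seed = 1)
  expect_equal(nComponents(m), 1L)
  expect_lt(abs(m@mu), 0.15)
  expect_lt(abs(m@sigma - 1), 0.1)
  expect_equal(m@nCells, 500L)
})

test_that("well-separated clusters are pinned to within 0.05", {
  x <- withr::with_seed(32, c(rnorm(100, 0, 0.1), rnorm(100, 5, 0.1)))
  m <- fitGmm(x, 2, nRestarts = 50, seed = 2)
  expect_equal(m@mu, c(0, 5), tolerance = 0.05)
  expect_equal(m@p, c(0.5, 0.5), tolerance = 0.05)
  ## components come out sorted by mean
  expect_true(!is.unsorted(m@mu))
})

test_that("degenerate all-equal data collapses to one component", {
  expect_warning(m <- fitGmm(rep(2.5, 40), 2, seed = 1), "degenerate")
  expect_equal(nComponents(m), 1L)
  expect_equal(m@mu, 2.5)
  expect_error(fitGmm(rnorm(8), 2), "at least 5")
})

test_that("AIC identity 2(3K-1) - 2 logLik holds for every fitted model", {
  set.seed(17)
  for (i in 1:12) {
    x <- rnorm(60 + i * 10, sd = runif(1, 0.5, 2))
    k <- sample(1:3, 1)
    m <- fitGmm(x, k, nRestarts = 10, seed = i)
    expect_equal(modelAIC(m),
                 2 * (3 * nComponents(m) - 1) - 2 * m@logLik,
                 tolerance = 1e-10)
  }
})

test_that("EM log-likelihood matches an independent mixture fitter", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))
  x <- withr::with_seed(9, c(rnorm(200, 0, 1), rnorm(100, 4, 0.5)))
  f <- fitGmm(x, 2, seed = 3)
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(f@logLik, mc$loglik, tolerance = 1e-3)
  expect_equal(f@mu, sort(unname(mc$parameters$mean)), tolerance = 1e-2)
})

test_that("consensus selection separates bimodal from unimodal presets", {
  tb <- normalizeToControl(cohort(seed = 11))
  x6 <- tb$omi_index[tb$patient_id == "P6" & tb$condition == "ABT263"]
  x7 <- tb$omi_index[tb$patient_id == "P7" & tb$condition == "control"]
  ## the bimodal patient shows metabolic substructure (AIC occasionally
  ## splits a 4-SD mode further; >= 2 is the heterogeneity call), the
  ## narrow unimodal patient never does
  expect_gte(nComponents(selectModel(x6, seed = 1)), 2L)
  expect_equal(nComponents(selectModel(x7, seed = 1)), 1L)
})

test_that("small unimodal samples select one component in most replicates", {
  ## n = 50 standard normal: the AIC penalty dominates in the majority of
  ## replicates (selection is genuinely marginal at this sample size)
  ks <- vapply(1:12, function(s)
    nComponents(selectModel(withr::with_seed(s, rnorm(50)),
                            nRestarts = 50, seed = 500 + s)), integer(1))
  expect_gt(mean(ks == 1L), 0.5)
})

test_that("4-SD-separated mixtures are recovered in most replicates", {
  ks <- vapply(1:12, function(s) {
    x <- withr::with_seed(s, c(rnorm(150, -0.31, 0.155),
                               rnorm(150, 0.31, 0.155)))
    nComponents(selectModel(x, nRestarts = 50, seed = 700 + s))
  }, integer(1))
  expect_gte(mean(ks == 2L), 0.75)
})

test_that("the wH-index matches its closed forms and term sums", {
  ## single tight population: d = 0, wh = (1 - ln 2) sigma
  m1 <- makeMixture(1, 0.5, 0.3)
  r1 <- whIndex(m1, rep(0.5, 11))
  expect_equal(r1$wh_index, (1 - log(2)) * 0.3, tolerance = 1e-12)
  expect_equal(round(r1$wh_index, 4), 0.0921)
  ## two balanced components at +/-1 around a median of 0
  m2 <- makeMixture(c(0.5, 0.5), c(-1, 1), c(0.2, 0.2))
  r2 <- whIndex(m2, c(-1, -1, 0, 1, 1))
  expect_equal(r2$wh_index, 2 * (1 - 0.5 * log(1.5)) * 1.2,
               tolerance = 1e-12)
  expect_equal(round(r2$wh_index, 4), 1.9134)
  ## random mixtures against a term-by-term oracle
  set.seed(23)
  for (i in 1:200) {
    k <- sample(1:3, 1)
    p <- runif(k); p <- p / sum(p)
    mu <- sort(rnorm(k)); sigma <- runif(k, 0.05, 1)
    vals <- rnorm(50)
    m <- makeMixture(p, mu, sigma)
    expect_equal(whIndex(m, vals)$wh_index,
                 refWhIndex(p, mu, sigma, vals), tolerance = 1e-12)
  }
})

test_that("the wH-index is non-negative and grows with spread", {
  set.seed(41)
  for (i in 1:50) {
    k <- sample(1:3, 1)
    p <- runif(k); p <- p / sum(p)
    mu <- sort(rnorm(k)); sigma <- runif(k, 0.05, 1)
    vals <- rnorm(40)
    base <- whIndex(makeMixture(p, mu, sigma), vals)$wh_index
    expect_gte(base, 0)
    ## widening any single component strictly increases the index
    j <- sample(k, 1)
    sigma2 <- sigma; sigma2[j] <- sigma2[j] + 0.1
    expect_gt(whIndex(makeMixture(p, mu, sigma2), vals)$wh_index, base)
    ## doubling every component's distance from the overall median
    ## increases the index (order-preserving)
    med <- median(vals)
    mu2 <- med + (mu - med) * 2
    expect_gt(whIndex(makeMixture(p, mu2, sigma), vals)$wh_index,
              base - 1e-12)
  }
})

test_that("the >100-cell gate is strict and counts correctly", {
  tb <- data.frame(
    patient_id = rep(c("A", "B", "C"), c(100, 101, 250)),
    condition = "control")
  g <- gateMinCells(tb)
  expect_setequal(g$patient_id, c("B", "C"))
  expect_equal(g$n[g$patient_id == "B"], 101)
  ## oracle: table counts
  tb2 <- cohort(seed = 2)
  g2 <- gateMinCells(tb2)
  tab <- table(tb2$patient_id, tb2$condition)
  for (r in seq_len(nrow(g2)))
    expect_equal(g2$n[r], unname(tab[g2$patient_id[r], g2$condition[r]]))
  expect_true(all(g2$n > 100))
})

test_that("normalized densities integrate to one and sum components", {
  m <- makeMixture(c(0.3, 0.7), c(0, 3), c(0.5, 1))
  d <- normalizedDensity(m)
  area <- sum(diff(d$x) * (head(d$density, -1) + tail(d$density, -1)) / 2)
  expect_equal(area, 1, tolerance = 1e-6)
  ## K = 1 equals the plain Gaussian pdf
  m1 <- makeMixture(1, 2, 0.4)
  g <- seq(0, 4, length.out = 101)
  expect_equal(normalizedDensity(m1, g)$density, dnorm(g, 2, 0.4),
               tolerance = 1e-12)
  ## mixture equals the componentwise sum
  expect_equal(normalizedDensity(m, g)$density,
               0.3 * dnorm(g, 0, 0.5) + 0.7 * dnorm(g, 3, 1),
               tolerance = 1e-12)
})
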