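test_that("redox ratio map is the elementwise NAD(P)H / FAD ratio", {
  a <- matrix(5, 4, 4)
  expect_equal(redoxRatioMap(a, a), matrix(1, 4, 4))
  expect_equal(redoxRatioMap(2 * a, a), matrix(2, 4, 4))
  f <- matrix(c(0, 1, 2, 4), 2, 2)
  r <- redoxRatioMap(matrix(2, 2, 2), f)
  expect_true(is.na(r[1, 1]))
  set.seed(3)
  n <- matrix(runif(36, 1, 100), 6, 6)
  f <- matrix(runif(36, 1, 100), 6, 6)
  expect_equal(redoxRatioMap(n, f), n / f, tolerance = 1e-15)
})

test_that("aggregateCells averages valid cytoplasm pixels per cell", {
  cyto <- matrix(0L, 6, 6); cyto[2:5, 2:5] <- 1L
  nadh <- makeUniformMaps(c(6, 6), 0.4, 2.5, 0.7, 1000)
  fad <- makeUniformMaps(c(6, 6), 0.3, 2.0, 0.6, 500, channel = "FAD")
  rec <- aggregateCells(nadh, fad, cyto, "P1", "control")
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$nadh_tau_m, 0.7 * 0.4 + 0.3 * 2.5)
  expect_equal(rec$fad_tau_m, 0.6 * 0.3 + 0.4 * 2.0)
  expect_equal(rec$redox_ratio, 2)
  expect_equal(rec$n_pixels, 16L)

  ## two cells against a masked-mean oracle with a partially invalid map
  valid <- matrix(TRUE, 8, 8); valid[, 1:2] <- FALSE
  set.seed(7)
  n2 <- makeUniformMaps(c(8, 8), 0.4, 2.5, 0.7, 100, valid = valid)
  n2@tauM[valid] <- runif(sum(valid), 0.8, 1.2)
  f2 <- makeUniformMaps(c(8, 8), 0.3, 2.0, 0.6, 50, valid = valid)
  cyto2 <- matrix(0L, 8, 8); cyto2[1:4, ] <- 1L; cyto2[5:8, ] <- 2L
  rec2 <- aggregateCells(n2, f2, cyto2, "P1", "control",
                         minValidPixels = 5L)
  for (i in 1:2) {
    idx <- which(cyto2 == i & valid)
    expect_equal(rec2$nadh_tau_m[rec2$cell_id == i], mean(n2@tauM[idx]))
  }

  ## a cell with no valid pixels is dropped
  allBad <- makeUniformMaps(c(6, 6), 0.4, 2.5, 0.7, 10,
                            valid = matrix(FALSE, 6, 6))
  expect_message(
    recNone <- aggregateCells(allBad, fad, cyto, "P1", "control"),
    "dropped")
  expect_equal(nrow(recNone), 0L)
})

test_that("control normalization makes control means exactly 1", {
  tb <- cohort(seed = 3)
  norm <- normalizeToControl(tb)
  for (pid in unique(norm$patient_id)) {
    ctrl <- norm$patient_id == pid & norm$condition == "control"
    expect_equal(mean(norm$norm_redox_ratio[ctrl]), 1, tolerance = 1e-12)
    expect_equal(mean(norm$norm_nadh_tau_m[ctrl]), 1, tolerance = 1e-12)
    expect_equal(mean(norm$norm_fad_tau_m[ctrl]), 1, tolerance = 1e-12)
  }
  ## normalization is per-group mean division
  pid <- "P2"
  sel <- tb$patient_id == pid & tb$condition == "ABT263"
  ctrl <- tb$patient_id == pid & tb$condition == "control"
  expect_equal(norm$norm_redox_ratio[sel],
               tb$redox_ratio[sel] / mean(tb$redox_ratio[ctrl]),
               tolerance = 1e-12)
  ## doubling a treated group's redox ratio doubles its normalized value
  tb2 <- tb
  tb2$redox_ratio[sel] <- 2 * tb2$redox_ratio[sel]
  norm2 <- normalizeToControl(tb2)
  expect_equal(norm2$norm_redox_ratio[sel], 2 * norm$norm_redox_ratio[sel],
               tolerance = 1e-12)
  ## control group is mandatory
  expect_error(normalizeToControl(tb[tb$condition != "control", ]),
               "control")
})

test_that("the OMI index is the (1, 1, -1) combination and is linear", {
  expect_equal(omiIndex(1, 1, 1), 1)
  expect_equal(omiIndex(0.8, 0.9, 1.1), 0.6)
  set.seed(5)
  for (i in 1:1000) {
    v <- runif(3, 0.2, 2)
    expect_equal(omiIndex(v[1], v[2], v[3]), sum(v * c(1, 1, -1)),
                 tolerance = 1e-12)
  }
  d <- runif(1)
  expect_identical(omiIndex(1.1 + d, 0.9, 1.2) - omiIndex(1.1, 0.9, 1.2), d)
})

test_that("control-mean OMI index is ~1 and responders decrease it", {
  tb <- normalizeToControl(cohort(seed = 19))
  ctrl <- tb$condition == "control" & tb$patient_id == "P1"
  expect_lt(abs(mean(tb$omi_index[ctrl]) - 1), 0.02)
  ## the response direction: lower redox ratio and NAD(P)H tau_m, higher
  ## FAD tau_m strictly decreases the mean OMI index
  trt <- tb$patient_id == "P3" & tb$condition == "combination"
  c3 <- tb$patient_id == "P3" & tb$condition == "control"
  expect_lt(mean(tb$omi_index[trt]), mean(tb$omi_index[c3]))
})

test_that("Z-scores are control-referenced per patient and variable", {
  set.seed(13)
  tb <- data.frame(
    patient_id = "P1",
    condition = rep(c("control", "drug"), each = 200),
    cell_id = 1:400,
    redox_ratio = c(rnorm(200, 1, 0.1), rnorm(200, 1, 0.1)),
    nadh_tau_m = c(rnorm(200, 1, 0.1), rnorm(200, 1, 0.1) + 0.1),
    fad_tau_m = rnorm(400, 0.8, 0.05))
  z <- zscoreTable(tb)
  zr <- z$z[z$variable == "redox_ratio"]
  expect_lt(abs(zr), 0.25)  # same distribution: Z ~ 0
  zn <- z$z[z$variable == "nadh_tau_m"]  # shifted by ~+1 control SD
  expect_equal(zn, 1, tolerance = 0.35)
  ## direct formula oracle
  ctrl <- tb$condition == "control"
  expect_equal(zn, (mean(tb$nadh_tau_m[!ctrl]) - mean(tb$nadh_tau_m[ctrl])) /
                 sd(tb$nadh_tau_m[ctrl]), tolerance = 1e-12)
})
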