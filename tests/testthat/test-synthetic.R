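test_that("the default IRF has 220 ps FWHM, unit area, and a delta limit", {
  irf <- defaultIrf()
  expect_equal(sum(irfKernel(irf)), 1, tolerance = 1e-12)
  expect_equal(irfFwhm(irf), 220, tolerance = 12.2)  # one time bin
  narrow <- defaultIrf(sigmaPs = 2)
  expect_gt(max(irfKernel(narrow)), 0.9)  # sigma -> 0 approaches a delta
})

test_that("simulateDecay is seeded, Poisson, and respects zero photons", {
  irf <- defaultIrf(0.0488, 256L)
  p <- biExpParams(0.7, 0.4, 2.5)
  a <- simulateDecay(p, irf, 1e4, seed = 7)
  b <- simulateDecay(p, irf, 1e4, seed = 7)
  expect_identical(photonCounts(a), photonCounts(b))
  expect_false(identical(photonCounts(a),
                         photonCounts(simulateDecay(p, irf, 1e4, seed = 8))))
  expect_equal(sum(photonCounts(simulateDecay(p, irf, 0, seed = 1))), 0)
  ## mean of replicates tracks the expected curve; dispersion index ~ 1
  m <- modelDecay(p, irf, 256L, 0.0488)
  m <- m / sum(m) * 1e4
  reps <- withr::with_seed(42, {
    t(vapply(1:1000, function(i)
      photonCounts(simulateDecay(p, irf, 1e4)), numeric(256L)))
  })
  bins <- which(m > 20)[1:30]
  se <- sqrt(m[bins] / 1000)
  expect_true(all(abs(colMeans(reps[, bins]) - m[bins]) < 4 * se))
  disp <- apply(reps[, bins], 2, var) / m[bins]
  expect_true(all(disp > 0.8 & disp < 1.2))
})

test_that("microsphere standards carry ~2e5 photons and tight lifetimes", {
  irf <- defaultIrf()
  ms <- microsphereStandard(seed = 3)
  expect_length(ms, 7L)
  expect_true(all(vapply(ms, function(d) sum(photonCounts(d)), numeric(1)) >
                    1e5))
  taus <- vapply(ms, function(d) as.numeric(fitMonoexponential(d, irf)),
                 numeric(1))
  expect_lt(sd(taus), 0.05)
  expect_equal(round(mean(taus), 1), 2.1)
})

test_that("renderScene returns as many labelled cells as requested", {
  irf <- defaultIrf(0.0488, 64L)
  pre <- scenePreset(imageSize = 96L, nCells = 12L)
  sc <- renderScene(pre, seed = 4, irf = irf)
  expect_equal(length(setdiff(unique(as.vector(sc$masks@cells)), 0L)), 12L)
  expect_equal(nrow(sc$truth), 12L)
  ## seed reproducibility, bit-exact counts
  sc2 <- renderScene(pre, seed = 4, irf = irf)
  expect_identical(photonCounts(sc$nadh), photonCounts(sc2$nadh))
  ## NAD(P)H contrast ordering: background < nucleus < cytoplasm
  ii <- intensityImage(sc$nadh)
  bg <- mean(ii[sc$masks@cells == 0])
  nuc <- mean(ii[sc$masks@nuclei > 0])
  cyt <- mean(ii[sc$masks@cytoplasm > 0])
  expect_lt(bg, nuc); expect_lt(nuc, cyt)
  expect_true(validObject(sc$masks))
})

test_that("the cohort matches its design: sizes, gate, response pattern", {
  tb <- cohort(seed = 11)
  design <- attr(tb, "design")
  counts <- table(tb$patient_id, tb$condition)
  for (r in seq_len(nrow(design)))
    expect_equal(unname(counts[design$patient_id[r], design$condition[r]]),
                 design$n_cells[r])
  ## only patients 1, 6, 7 clear the strict >100-cell gate
  g <- gateMinCells(tb)
  expect_setequal(unique(g$patient_id), c("P1", "P6", "P7"))
  expect_equal(nrow(g), 12L)  # 3 patients x 4 conditions
  ## reproducible
  expect_identical(cohort(seed = 11)$nadh_tau_m, tb$nadh_tau_m)
  ## gate boundary: exactly 100 is excluded, 101 included
  fake <- data.frame(patient_id = rep(c("A", "B"), c(100, 101)),
                     condition = "control")
  gg <- gateMinCells(fake)
  expect_equal(gg$patient_id, "B")
})

test_that("cohort responder calls reproduce the designed counts", {
  tb <- normalizeToControl(cohort(seed = 11))
  calls <- callResponse(tb)
  expect_equal(countResponders(calls, "combination"), 5L)
  expect_equal(countResponders(calls, "everolimus"), 4L)
  expect_equal(countResponders(calls, "ABT263"), 4L)
  ## the patient-level pattern: combo-only responders and a combo
  ## non-responder among single-agent responders
  comboResp <- calls$patient_id[calls$condition == "combination" &
                                  calls$responder == "responder"]
  expect_setequal(comboResp, c("P1", "P2", "P3", "P5", "P7"))
  everResp <- calls$patient_id[calls$condition == "everolimus" &
                                 calls$responder == "responder"]
  expect_setequal(everResp, c("P1", "P3", "P4", "P7"))
})

test_that("growth tables separate slow and fast-growing lines", {
  g <- growthGenerator("gepnet", n = 100L, seed = 21)
  expect_lt(abs(median(g$growth_percent)), 1.5)
  expect_equal(growthPercent(g$day1_diameter, g$day7_diameter),
               g$growth_percent, tolerance = 1e-12)
  crc <- growthGenerator("crc", n = 100L, seed = 21)
  expect_gt(median(crc$growth_percent), median(g$growth_percent))
  wt <- wilcox.test(crc$growth_percent, g$growth_percent,
                    alternative = "greater")
  expect_lt(wt$p.value, 0.01)
  expect_identical(growthGenerator("crc", n = 100L, seed = 21), crc)
})

test_that("the cell-line preset responds to ABT263 but not everolimus", {
  tb <- normalizeToControl(stc1Preset(seed = 6))
  calls <- callResponse(tb)
  expect_equal(calls$responder[calls$condition == "combination"],
               "responder")
  expect_equal(calls$responder[calls$condition == "ABT263"], "responder")
  expect_equal(calls$responder[calls$condition == "everolimus"],
               "na_increase")
  expect_identical(stc1Preset(seed = 6)$redox_ratio, tb$redox_ratio)
})
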