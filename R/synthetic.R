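## Synthetic ground-truth generators: the default IRF, Poisson decay
## simulation, microsphere lifetime standards, two-channel organoid FLIM
## scenes, the 7-patient treatment cohort, growth tables, and a
## neuroendocrine-cell-line preset. Every generator is a pure function of
## (preset, seed).

## ground-truth control parameters of the cell population emulated by the
## generators: literature-standard free/bound lifetimes and fractions for
## the two co-enzyme channels, 8% cell-to-cell variation, and matched
## channel intensities (redox ratio ~ 1)
.omiBase <- list(
  nadh = c(alpha1 = 0.7, tau1 = 0.4, tau2 = 2.5),
  fad = c(alpha1 = 0.7, tau1 = 0.3, tau2 = 2.0),
  intensity = 1000, relTau = 0.08, relInt = 0.08, sdAlpha = 0.02)

## delta-method CV of tau_m = a1 t1 + (1-a1) t2 under the base noise model
.cvTauM <- function(ch) {
  b <- .omiBase[[ch]]
  a1 <- b[["alpha1"]]; t1 <- b[["tau1"]]; t2 <- b[["tau2"]]
  v <- a1^2 * (.omiBase$relTau * t1)^2 +
    (1 - a1)^2 * (.omiBase$relTau * t2)^2 +
    (t2 - t1)^2 * .omiBase$sdAlpha^2
  sqrt(v) / (a1 * t1 + (1 - a1) * t2)
}

## SD of the control OMI index in normalized (control-mean = 1) units
.sigmaOmiControl <- function() {
  sqrt(2 * .omiBase$relInt^2 + .cvTauM("nadh")^2 + .cvTauM("fad")^2)
}

#' Default synthetic instrument response function
#'
#' A Gaussian kernel with sigma = 93.4 ps (FWHM 220 ps, the measured width
#' of a second-harmonic-generation IRF on a standard two-photon TCSPC
#' system), centered at 10% of the time range, on the default 12.2 ps grid
#' spanning the ~12.5 ns pulse period of an 80 MHz acquisition (1024 bins).
#'
#' @param binWidthNs bin width in ns (default 0.0122).
#' @param nBins number of bins (default 1024).
#' @param sigmaPs Gaussian sigma in picoseconds (default 93.4).
#' @return an \linkS4class{InstrumentResponse}.
#' @examples
#' irfFwhm(defaultIrf())  # ~220 ps
#' @export
defaultIrf <- function(binWidthNs = 0.0122, nBins = 1024L, sigmaPs = 93.4) {
  tt <- (seq_len(nBins) - 0.5) * binWidthNs
  center <- 0.1 * nBins * binWidthNs
  k <- stats::dnorm(tt, center, sigmaPs / 1000)
  instrumentResponse(k, binWidthNs)
}

#' Simulate a Poisson photon-count decay histogram
#'
#' Evaluates the expected reconvolved decay curve, scales it to the
#' requested total photons, and draws independent Poisson counts per bin.
#'
#' @param params ground-truth \linkS4class{BiExpParams}.
#' @param irf an \linkS4class{InstrumentResponse}.
#' @param totalPhotons expected total photon count (>= 0).
#' @param seed RNG seed (bit-reproducible when set).
#' @param nBins,binWidthNs time grid; defaults follow the IRF.
#' @return a \linkS4class{DecayHistogram}.
#' @export
simulateDecay <- function(params, irf, totalPhotons, seed = NULL,
                          nBins = length(irf@kernel),
                          binWidthNs = irf@binWidthNs) {
  stopifnot(totalPhotons >= 0)
  if (totalPhotons == 0)
    return(decayHistogram(numeric(nBins), binWidthNs))
  m <- modelDecay(params, irf, nBins, binWidthNs)
  m <- m / sum(m) * totalPhotons
  draw <- function() stats::rpois(nBins, m)
  counts <- if (is.null(seed)) draw()
            else withr::with_seed(as.integer(seed), draw())
  decayHistogram(counts, binWidthNs)
}

#' Daily-standard microsphere decays
#'
#' Replicate mono-exponential decays at the 2.1 ns lifetime of the
#' fluorescent-microsphere standard imaged daily to validate a FLIM system,
#' each with ~2e5 photons under the default IRF.
#'
#' @param seed RNG seed.
#' @param nReplicates number of daily measurements (default 7).
#' @param tauNs nominal standard lifetime (default 2.1 ns).
#' @param totalPhotons photons per replicate (default 2e5).
#' @param irf the \linkS4class{InstrumentResponse} to blur with.
#' @return list of \linkS4class{DecayHistogram}s.
#' @export
microsphereStandard <- function(seed = NULL, nReplicates = 7L, tauNs = 2.1,
                                totalPhotons = 2e5, irf = defaultIrf()) {
  ## alpha2 = 0: the second component never contributes
  params <- biExpParams(alpha1 = 1, tau1 = tauNs, tau2 = tauNs + 1)
  seeds <- if (is.null(seed)) rep(list(NULL), nReplicates)
           else as.list(as.integer(seed) + seq_len(nReplicates) - 1L)
  lapply(seeds, function(s) simulateDecay(params, irf, totalPhotons, s))
}

#' Scene preset for synthetic organoid FLIM images
#'
#' @param imageSize image side in pixels (default 64).
#' @param nCells number of cells (default 8).
#' @param morphology "solid" (cells packed in a disk) or "hollow" (cells on
#'   an annulus, the cross-section of a hollow organoid).
#' @param nucleusRadius,cellRadius radii in pixels.
#' @param photonsPerPixel expected photons in a cytoplasm pixel (default
#'   5000).
#' @param backgroundLevel background intensity as a fraction of
#'   photonsPerPixel (default 0.05).
#' @return a list of class "scenePreset".
#' @export
scenePreset <- function(imageSize = 64L, nCells = 8L,
                        morphology = c("solid", "hollow"),
                        nucleusRadius = 3, cellRadius = 6.5,
                        photonsPerPixel = 5000, backgroundLevel = 0.05) {
  morphology <- match.arg(morphology)
  stopifnot(imageSize >= 16L, nCells >= 1L, nucleusRadius < cellRadius,
            photonsPerPixel > 0, backgroundLevel >= 0, backgroundLevel < 0.3)
  structure(list(imageSize = as.integer(imageSize),
                 nCells = as.integer(nCells), morphology = morphology,
                 nucleusRadius = nucleusRadius, cellRadius = cellRadius,
                 photonsPerPixel = photonsPerPixel,
                 backgroundLevel = backgroundLevel),
            class = "scenePreset")
}

## non-overlapping cell centers for a preset
.placeCells <- function(preset) {
  n <- preset$nCells
  sz <- preset$imageSize
  rc <- preset$cellRadius
  minSep <- 2 * rc + 1
  if (preset$morphology == "hollow") {
    ring <- sz / 2 - rc - 1.5
    if (ring <= 0) stop("image too small for hollow morphology")
    ang <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)] +
      stats::runif(n, -0.1, 0.1)
    ctr <- cbind(sz / 2 + ring * cos(ang), sz / 2 + ring * sin(ang))
    if (n > 1L && min(stats::dist(ctr)) < minSep)
      stop("too many cells for the hollow ring; reduce nCells")
    return(ctr)
  }
  ctr <- matrix(NA_real_, n, 2L)
  placed <- 0L
  for (try in seq_len(20000L)) {
    cand <- stats::runif(2L, rc + 1.5, sz - rc - 0.5)
    if (placed == 0L ||
        min(sqrt(.rowSums((ctr[seq_len(placed), , drop = FALSE] -
                           matrix(cand, placed, 2L, byrow = TRUE))^2,
                          placed, 2L))) >= minSep) {
      placed <- placed + 1L
      ctr[placed, ] <- cand
      if (placed == n) break
    }
  }
  if (placed < n)
    stop("could not place ", n, " non-overlapping cells; reduce nCells")
  ctr
}

## draw per-cell ground-truth decay parameters from the control population
.drawCellParams <- function(n, shifts = c(rr = 1, tn = 1, tf = 1),
                            sdFactor = 1) {
  b <- .omiBase
  draw1 <- function(base, scaleMean, relSd)
    stats::rnorm(n, base * scaleMean, base * relSd * sdFactor)
  clampTau <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  df <- data.frame(
    nadh_alpha1 = clampTau(stats::rnorm(n, b$nadh[["alpha1"]],
                                        b$sdAlpha * sdFactor), 0.05, 0.95),
    nadh_tau1 = clampTau(draw1(b$nadh[["tau1"]], shifts[["tn"]], b$relTau),
                         0.06, 1.4),
    nadh_tau2 = clampTau(draw1(b$nadh[["tau2"]], shifts[["tn"]], b$relTau),
                         0.9, 7.5),
    fad_alpha1 = clampTau(stats::rnorm(n, b$fad[["alpha1"]],
                                       b$sdAlpha * sdFactor), 0.05, 0.95),
    fad_tau1 = clampTau(draw1(b$fad[["tau1"]], shifts[["tf"]], b$relTau),
                        0.06, 1.4),
    fad_tau2 = clampTau(draw1(b$fad[["tau2"]], shifts[["tf"]], b$relTau),
                        0.9, 7.5),
    fad_intensity = pmax(draw1(b$intensity, 1, b$relInt), 50))
  ## the per-cell redox ratio is itself Gaussian across cells; NAD(P)H
  ## intensity is derived so the ratio carries the treatment shift exactly
  rr <- pmax(stats::rnorm(n, shifts[["rr"]],
                          sqrt(2) * b$relInt * sdFactor), 0.05)
  df$nadh_intensity <- df$fad_intensity * rr
  df$nadh_tau_m <- meanLifetime(df$nadh_alpha1, df$nadh_tau1, df$nadh_tau2)
  df$fad_tau_m <- meanLifetime(df$fad_alpha1, df$fad_tau1, df$fad_tau2)
  df$redox_ratio <- df$nadh_intensity / df$fad_intensity
  df
}

#' Render a synthetic two-channel organoid FLIM scene
#'
#' Places non-overlapping cells (disk nuclei inside circular cell bodies;
#' ring layout for hollow organoids), assigns each cell ground-truth decay
#' parameters, and simulates per-pixel Poisson photon histograms for both
#' channels. NAD(P)H intensity reproduces the contrast ordering real images
#' show — dark background, mid-intensity nuclei, bright cytoplasm — which
#' the segmentation stage relies on.
#'
#' @param preset a \code{\link{scenePreset}}.
#' @param cellParams optional data.frame of per-cell ground-truth
#'   parameters (as produced internally; one row per cell). Drawn from the
#'   control population when NULL.
#' @param seed RNG seed.
#' @param irf \linkS4class{InstrumentResponse} used for the forward model.
#' @return list with \code{nadh} and \code{fad} \linkS4class{FlimStack}s,
#'   ground-truth \code{masks} (\linkS4class{LabelMasks}) and \code{truth}
#'   (per-cell parameter table).
#' @export
renderScene <- function(preset = scenePreset(), cellParams = NULL,
                        seed = NULL, irf = defaultIrf()) {
  run <- function() {
    sz <- preset$imageSize
    ctr <- .placeCells(preset)
    n <- preset$nCells
    if (is.null(cellParams)) cellParams <- .drawCellParams(n)
    stopifnot(nrow(cellParams) == n)
    xg <- matrix(seq_len(sz), sz, sz)
    yg <- t(xg)
    nuclei <- cells <- matrix(0L, sz, sz)
    for (i in seq_len(n)) {
      d2 <- (xg - ctr[i, 1L])^2 + (yg - ctr[i, 2L])^2
      cells[d2 <= preset$cellRadius^2] <- i
      nuclei[d2 <= preset$nucleusRadius^2] <- i
    }
    nBins <- length(irf@kernel)
    dt <- irf@binWidthNs
    mkStack <- function(ch) {
      pref <- if (ch == "NADH") "nadh_" else "fad_"
      ## expected unit-sum decay curve per cell
      curves <- lapply(seq_len(n), function(i) {
        p <- biExpParams(cellParams[[paste0(pref, "alpha1")]][i],
                         cellParams[[paste0(pref, "tau1")]][i],
                         cellParams[[paste0(pref, "tau2")]][i])
        m <- modelDecay(p, irf, nBins, dt)
        m / sum(m)
      })
      ## background: dim, free-co-enzyme-like decay
      bgCurve <- modelDecay(biExpParams(0.9, 0.5, 2.5), irf, nBins, dt)
      bgCurve <- bgCurve / sum(bgCurve)
      ## per-pixel photon budget; NADH carries the cell's intensity so the
      ## per-pixel redox ratio matches the cell's ground truth
      base <- preset$photonsPerPixel
      relInt <- cellParams[[paste0(pref, "intensity")]] /
        .omiBase$intensity
      budget <- matrix(base * preset$backgroundLevel, sz, sz)
      for (i in seq_len(n)) {
        budget[cells == i] <- base * relInt[i]
        budget[nuclei == i] <- 0.45 * base * relInt[i]
      }
      a <- array(0L, c(nBins, sz, sz))
      regions <- c(list(`0` = which(cells == 0L)),
                   lapply(seq_len(n), function(i) which(cells == i)))
      for (ri in seq_along(regions)) {
        idx <- regions[[ri]]
        if (length(idx) == 0L) next
        curve <- if (ri == 1L) bgCurve else curves[[ri - 1L]]
        lam <- outer(curve, budget[idx])  # nBins x nPix
        a[rep(idx - 1L, each = nBins) * nBins + seq_len(nBins)] <-
          stats::rpois(length(lam), lam)
      }
      flimStack(a, dt, ch)
    }
    nadhStack <- mkStack("NADH")
    fadStack <- mkStack("FAD")
    truth <- cbind(cell_id = seq_len(n), cellParams)
    list(nadh = nadhStack, fad = fadStack,
         masks = labelMasks(nuclei, cells), truth = truth, preset = preset)
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

## the 7-patient cohort design: response pattern, variance features and
## group sizes. effect is in units of the patient's control OMI-index SD
## (positive = OMI decrease = response direction).
.patientPresets <- function() {
  resp <- list(P1 = c("everolimus", "ABT263", "combination"),
               P2 = "combination",
               P3 = c("everolimus", "ABT263", "combination"),
               P4 = c("everolimus", "ABT263"),
               P5 = "combination",
               P6 = character(0),
               P7 = c("everolimus", "ABT263", "combination"))
  out <- list()
  for (pid in names(resp)) {
    sdAll <- if (pid == "P7") 0.6 else 1   # narrow single-cell variance
    nGrp <- if (pid %in% c("P1", "P6", "P7")) 300L else 100L
    for (cond in c("control", "everolimus", "ABT263", "combination")) {
      e <- if (cond == "control") 0
           else if (cond %in% resp[[pid]]) 1.2 else -0.2
      sdFac <- sdAll * if (pid == "P1" && cond == "everolimus") 2 else 1
      out[[length(out) + 1L]] <- data.frame(
        patient_id = pid, condition = cond, n_cells = nGrp, effect = e,
        sd_factor = sdFac, bimodal = pid == "P6")
    }
  }
  do.call(rbind, out)
}

## generate one (patient, condition) group of cell records
.generateGroup <- function(pid, cond, n, effect, sdFactor, bimodal,
                           sdFactorControl) {
  sigmaOmi <- .sigmaOmiControl() * sdFactorControl
  comp <- if (bimodal) stats::rbinom(n, 1L, 0.5) else rep(0L, n)
  ## per-cell total OMI shift (in normalized units): treatment effect plus,
  ## for bimodal lines, a +/- 2 SD component offset (4 SD separation)
  shiftOmi <- -effect * sigmaOmi + (comp * 2L - as.integer(bimodal)) *
    2 * sigmaOmi
  rows <- lapply(seq_len(n), function(i) {
    s <- shiftOmi[i] / 3  # spread equally over the three OMI variables
    .drawCellParams(1L, shifts = c(rr = 1 + s, tn = 1 + s, tf = 1 - s),
                    sdFactor = sdFactor)
  })
  df <- do.call(rbind, rows)
  cbind(data.frame(patient_id = pid, condition = cond, cell_id = seq_len(n)),
        df)
}

#' Synthetic 7-patient treatment cohort (table level)
#'
#' Generates per-cell ground-truth OMI variables for seven patient organoid
#' lines under control, everolimus, ABT263 and combination treatment.
#' Responder groups carry a 1.2-control-SD OMI-index decrease (realized as
#' lower redox ratio, lower NAD(P)H tau_m and higher FAD tau_m), and
#' non-responder groups a 0.2-SD increase. Patients 1, 6 and 7 have 300
#' cells per condition (eligible for subpopulation analysis); the others
#' have exactly 100, the largest group size the strict >100-cell gate
#' excludes. Patient 6 is a 50/50 two-subtype mixture separated by 4 SD in
#' every condition, patient 1's everolimus group has twice the control
#' variance, and patient 7 has 0.6x variance throughout. Responder counts
#' by design: 4 everolimus, 4 ABT263, 5 combination.
#'
#' @param seed RNG seed.
#' @param presets design table (default \code{.patientPresets()}); columns
#'   patient_id, condition, n_cells, effect, sd_factor, bimodal.
#' @return data.frame of cell records; attribute \code{"design"} holds the
#'   preset table with the intended response direction.
#' @export
cohort <- function(seed = NULL, presets = NULL) {
  if (is.null(presets)) presets <- .patientPresets()
  run <- function() {
    rows <- lapply(seq_len(nrow(presets)), function(r) {
      p <- presets[r, ]
      ctrlFac <- presets$sd_factor[presets$patient_id == p$patient_id &
                                     presets$condition == "control"][1L]
      .generateGroup(p$patient_id, p$condition, p$n_cells, p$effect,
                     p$sd_factor, p$bimodal, ctrlFac)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "design") <- presets
    out
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

#' Synthetic neuroendocrine cell-line preset
#'
#' A single 2-D-culture "patient" whose OMI index decreases under ABT263
#' (1.2 control SD) and the combination (1.5 SD) but increases under
#' everolimus alone (0.3 SD), the pattern seen in mouse neuroendocrine
#' cells: response to Bcl-2 inhibition, none to mTOR inhibition alone.
#'
#' @param seed RNG seed.
#' @param nPerGroup cells per condition (default 200).
#' @return data.frame of cell records with a \code{"design"} attribute.
#' @export
stc1Preset <- function(seed = NULL, nPerGroup = 200L) {
  presets <- data.frame(
    patient_id = "STC1",
    condition = c("control", "everolimus", "ABT263", "combination"),
    n_cells = as.integer(nPerGroup),
    effect = c(0, -0.3, 1.2, 1.5),
    sd_factor = 1, bimodal = FALSE)
  cohort(seed = seed, presets = presets)
}

#' Synthetic organoid growth tables
#'
#' 48-h diameter changes for untreated organoid lines: slow-growing
#' neuroendocrine lines ("gepnet") have percent-change distributions
#' centered at zero (Normal(0, 5)); a fast-growing colorectal line ("crc")
#' grows Normal(40, 15), truncated above -100%.
#'
#' @param kind "gepnet" or "crc".
#' @param n number of organoids (default 100).
#' @param seed RNG seed.
#' @return data.frame (day1_diameter, day7_diameter, growth_percent).
#' @export
growthGenerator <- function(kind = c("gepnet", "crc"), n = 100L,
                            seed = NULL) {
  kind <- match.arg(kind)
  run <- function() {
    d1 <- pmax(stats::rnorm(n, 120, 25), 30)
    pct <- if (kind == "gepnet") stats::rnorm(n, 0, 5)
           else pmax(stats::rnorm(n, 40, 15), -99.9)
    data.frame(day1_diameter = d1, day7_diameter = d1 * (1 + pct / 100),
               growth_percent = pct)
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}
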