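## Per-cell OMI variables: cytoplasm aggregation, the optical redox ratio,
## control normalization, the OMI index, and cohort Z-score tables.

#' Per-pixel optical redox ratio
#'
#' NAD(P)H intensity divided by FAD intensity, elementwise. Pixels where the
#' FAD intensity is zero are NA (undefined ratio).
#'
#' @param nadhIntensity,fadIntensity same-shape non-negative matrices.
#' @return numeric matrix of ratios.
#' @export
redoxRatioMap <- function(nadhIntensity, fadIntensity) {
  stopifnot(identical(dim(nadhIntensity), dim(fadIntensity)))
  out <- nadhIntensity / fadIntensity
  out[fadIntensity == 0] <- NA_real_
  out
}

## mean of map values over one cell's valid pixels
.cellMean <- function(map, idx) mean(map[idx])

#' Aggregate pixel maps into per-cell records
#'
#' For each cytoplasm label, averages every lifetime/intensity map and the
#' redox-ratio map over the pixels that are valid in both channels. Cells
#' with fewer than \code{minValidPixels} valid cytoplasm pixels are dropped
#' (with a message).
#'
#' @param nadh,fad \linkS4class{LifetimeImageSet}s for the two channels.
#' @param cytoplasm integer cytoplasm label matrix.
#' @param patientId,condition identifiers stamped on every record.
#' @param minValidPixels minimum valid pixels per retained cell (default 10).
#' @return data.frame of cell records (one row per retained cell) with
#'   snake_case OMI columns.
#' @export
aggregateCells <- function(nadh, fad, cytoplasm, patientId, condition,
                           minValidPixels = 10L) {
  stopifnot(is(nadh, "LifetimeImageSet"), is(fad, "LifetimeImageSet"),
            identical(dim(cytoplasm), dim(nadh@tauM)),
            identical(dim(cytoplasm), dim(fad@tauM)))
  ratio <- redoxRatioMap(nadh@intensity, fad@intensity)
  valid <- nadh@validMask & fad@validMask & !is.na(ratio)
  labs <- sort(setdiff(unique(as.vector(cytoplasm)), 0L))
  rows <- vector("list", length(labs))
  dropped <- 0L
  for (k in seq_along(labs)) {
    idx <- which(cytoplasm == labs[k] & valid)
    if (length(idx) < minValidPixels) { dropped <- dropped + 1L; next }
    rows[[k]] <- data.frame(
      patient_id = patientId, condition = condition, cell_id = labs[k],
      nadh_tau1 = .cellMean(nadh@tau1, idx),
      nadh_tau2 = .cellMean(nadh@tau2, idx),
      nadh_alpha1 = .cellMean(nadh@alpha1, idx),
      nadh_tau_m = .cellMean(nadh@tauM, idx),
      nadh_intensity = .cellMean(nadh@intensity, idx),
      fad_tau1 = .cellMean(fad@tau1, idx),
      fad_tau2 = .cellMean(fad@tau2, idx),
      fad_alpha1 = .cellMean(fad@alpha1, idx),
      fad_tau_m = .cellMean(fad@tauM, idx),
      fad_intensity = .cellMean(fad@intensity, idx),
      redox_ratio = .cellMean(ratio, idx),
      n_pixels = length(idx))
  }
  if (dropped > 0L)
    message(dropped, " cell(s) dropped: fewer than ", minValidPixels,
            " valid cytoplasm pixels")
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  if (is.null(out))
    out <- data.frame(patient_id = character(0), condition = character(0),
                      cell_id = integer(0))
  rownames(out) <- NULL
  out
}

#' Normalize OMI variables to the patient-matched control mean
#'
#' Divides each cell's redox ratio, NAD(P)H tau_m and FAD tau_m by the mean
#' of that variable over the same patient's control cells, producing
#' unitless, commensurate variables whose control-group means are exactly 1.
#' By default the composite OMI index (normalized redox ratio + NAD(P)H
#' tau_m - FAD tau_m) is appended.
#'
#' @param table cell-record data.frame with columns patient_id, condition,
#'   redox_ratio, nadh_tau_m, fad_tau_m.
#' @param controlCondition label of the control group (default "control").
#' @param addIndex append the omi_index column (default TRUE).
#' @return the table with norm_redox_ratio, norm_nadh_tau_m,
#'   norm_fad_tau_m (and omi_index) columns added.
#' @export
normalizeToControl <- function(table, controlCondition = "control",
                               addIndex = TRUE) {
  need <- c("patient_id", "condition", "redox_ratio", "nadh_tau_m",
            "fad_tau_m")
  stopifnot(all(need %in% names(table)))
  vars <- c(redox_ratio = "norm_redox_ratio", nadh_tau_m = "norm_nadh_tau_m",
            fad_tau_m = "norm_fad_tau_m")
  for (v in names(vars)) table[[vars[[v]]]] <- NA_real_
  for (pid in unique(table$patient_id)) {
    sel <- table$patient_id == pid
    ctrl <- sel & table$condition == controlCondition
    if (!any(ctrl))
      stop("missing control group for patient ", pid)
    for (v in names(vars)) {
      m <- mean(table[[v]][ctrl])
      if (!is.finite(m) || m == 0)
        stop("degenerate control mean for ", v, ", patient ", pid)
      table[[vars[[v]]]][sel] <- table[[v]][sel] / m
    }
  }
  if (addIndex)
    table$omi_index <- omiIndex(table$norm_redox_ratio,
                                table$norm_nadh_tau_m,
                                table$norm_fad_tau_m)
  table
}

#' The composite OMI index
#'
#' Linear combination of the normalized OMI variables with coefficients
#' (1, 1, -1): normalized redox ratio + NAD(P)H tau_m - FAD tau_m. A
#' decrease with treatment indicates metabolic drug response.
#'
#' @param normRedoxRatio,normNadhTauM,normFadTauM numeric vectors of
#'   control-normalized variables.
#' @return numeric vector of OMI-index values.
#' @examples
#' omiIndex(1, 1, 1)         # 1
#' omiIndex(0.8, 0.9, 1.1)   # 0.6
#' @export
omiIndex <- function(normRedoxRatio, normNadhTauM, normFadTauM) {
  normRedoxRatio + normNadhTauM - normFadTauM
}

#' Control-referenced Z-scores per patient, condition and variable
#'
#' For each patient and treated condition, Z = (treated mean - control mean)
#' / control SD, computed for every OMI variable present in the table — the
#' summary behind cohort-wide heatmaps of treatment effects.
#'
#' @param table cell-record data.frame.
#' @param controlCondition control group label (default "control").
#' @param variables columns to score; defaults to all numeric OMI variables
#'   present.
#' @return long data.frame (patient_id, condition, variable, z).
#' @export
zscoreTable <- function(table, controlCondition = "control",
                        variables = NULL) {
  if (is.null(variables)) {
    cand <- c("nadh_tau1", "nadh_tau2", "nadh_alpha1", "nadh_tau_m",
              "nadh_intensity", "fad_tau1", "fad_tau2", "fad_alpha1",
              "fad_tau_m", "fad_intensity", "redox_ratio", "omi_index")
    variables <- intersect(cand, names(table))
  }
  out <- list()
  for (pid in unique(table$patient_id)) {
    sel <- table$patient_id == pid
    ctrl <- sel & table$condition == controlCondition
    if (!any(ctrl)) stop("missing control group for patient ", pid)
    for (cond in setdiff(unique(table$condition[sel]), controlCondition)) {
      trt <- sel & table$condition == cond
      z <- vapply(variables, function(v) {
        s <- stats::sd(table[[v]][ctrl])
        (mean(table[[v]][trt]) - mean(table[[v]][ctrl])) / s
      }, numeric(1L))
      out[[length(out) + 1L]] <- data.frame(
        patient_id = pid, condition = cond, variable = variables,
        z = unname(z))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
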