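## Response calling: control-vs-treatment one-way ANOVA, Glass's delta with
## the 0.75 cutoff and the n.a.-on-increase rule, and organoid growth %.

#' One-way ANOVA of control versus one treatment
#'
#' Two-group one-way ANOVA (equal-variance), for which F equals the square
#' of the unpaired t statistic and both tests share one p-value; both are
#' reported.
#'
#' @param control,treated numeric vectors (each length >= 2).
#' @return list with \code{F}, \code{p}, \code{t}, \code{df}.
#' @export
anovaControlVsTreatment <- function(control, treated) {
  stopifnot(length(control) >= 2L, length(treated) >= 2L)
  g <- factor(rep(c("control", "treated"),
                  c(length(control), length(treated))))
  v <- c(control, treated)
  if (stats::var(v) == 0)  # identical groups: no effect by definition
    return(list(F = 0, p = 1, t = 0, df = length(v) - 2L))
  df <- length(v) - 2L
  if (stats::var(control) == 0 && stats::var(treated) == 0) {
    ## zero within-group variance, different means: unbounded statistic
    return(list(F = Inf, p = 0,
                t = Inf * sign(mean(control) - mean(treated)), df = df))
  }
  aovr <- stats::oneway.test(v ~ g, var.equal = TRUE)
  tt <- stats::t.test(control, treated, var.equal = TRUE)
  list(F = unname(aovr$statistic), p = unname(aovr$p.value),
       t = unname(tt$statistic), df = unname(tt$parameter))
}

#' Glass's delta effect size (control-SD denominator)
#'
#' Delta = (mean(control) - mean(treated)) / sd(control), with the sample
#' (n - 1) standard deviation, signed so that a decrease in the treated
#' group gives a positive delta. When the treated mean is greater than or
#' equal to the control mean — an increase, i.e., non-response — the effect
#' size is not applicable and NA is returned.
#'
#' @param control,treated numeric vectors; control needs length >= 2.
#' @return positive delta, or NA_real_ when the treated mean increased.
#' @examples
#' glassDelta(c(0.8, 1.0, 1.2), c(0.56, 0.76, 0.96))  # 1.2
#' @export
glassDelta <- function(control, treated) {
  stopifnot(length(control) >= 2L, length(treated) >= 1L)
  mc <- mean(control); mt <- mean(treated)
  if (mt >= mc) return(NA_real_)
  (mc - mt) / stats::sd(control)
}

#' Call metabolic drug response per patient and condition
#'
#' For every (patient, treated-condition) group, tests the OMI index against
#' the patient's control cells and classifies:
#' \itemize{
#'   \item \code{na_increase} — treated mean >= control mean (effect size
#'     not applicable; indicates non-response),
#'   \item \code{responder} — p < alpha AND Glass's delta > cutoff,
#'   \item \code{non_responder} — otherwise.
#' }
#'
#' @param table cell-record data.frame with an \code{omi_index} column (see
#'   \code{\link{normalizeToControl}}).
#' @param alpha ANOVA significance level (default 0.05).
#' @param deltaCutoff Glass's delta cutoff (default 0.75).
#' @param controlCondition control group label (default "control").
#' @param pGate,deltaGate switch either gate off to report the other alone.
#' @return data.frame with one row per (patient_id, condition): means, p,
#'   glass_delta (NA when not applicable) and the responder call.
#' @export
callResponse <- function(table, alpha = 0.05, deltaCutoff = 0.75,
                         controlCondition = "control", pGate = TRUE,
                         deltaGate = TRUE) {
  stopifnot("omi_index" %in% names(table))
  out <- list()
  for (pid in unique(table$patient_id)) {
    sel <- table$patient_id == pid
    ctrl <- table$omi_index[sel & table$condition == controlCondition]
    if (length(ctrl) < 2L) stop("need >= 2 control cells for patient ", pid)
    for (cond in setdiff(unique(table$condition[sel]), controlCondition)) {
      trt <- table$omi_index[sel & table$condition == cond]
      st <- anovaControlVsTreatment(ctrl, trt)
      gd <- glassDelta(ctrl, trt)
      call <- if (is.na(gd)) "na_increase"
        else if ((!pGate || st$p < alpha) &&
                 (!deltaGate || gd > deltaCutoff)) "responder"
        else "non_responder"
      out[[length(out) + 1L]] <- data.frame(
        patient_id = pid, condition = cond,
        mean_control = mean(ctrl), mean_treated = mean(trt),
        f_statistic = st$F, p_value = st$p, glass_delta = gd,
        responder = call)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Count responder patients for one condition
#'
#' @param calls data.frame from \code{\link{callResponse}}.
#' @param condition treatment condition to count.
#' @return integer number of patients called \code{responder}.
#' @export
countResponders <- function(calls, condition) {
  if (is.null(calls) || nrow(calls) == 0L) return(0L)
  sum(calls$responder == "responder" & calls$condition == condition)
}

#' Organoid growth percent
#'
#' Growth % = (day-7 diameter - day-1 diameter) / day-1 diameter x 100,
#' vectorized over organoids.
#'
#' @param day1Diameter,day7Diameter positive numeric vectors.
#' @return percent change per organoid.
#' @examples
#' growthPercent(100, 115)  # 15
#' @export
growthPercent <- function(day1Diameter, day7Diameter) {
  stopifnot(all(day1Diameter > 0))
  (day7Diameter - day1Diameter) / day1Diameter * 100
}
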