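# Cycle normalization and curve-comparison metrics used to validate
# predicted tibiofemoral contact force curves: RMSE, coefficient of
# determination, and the Sprague-Geers magnitude/phase/combined error.

#' Resample a time series onto the 0-100% normalized cycle
#'
#' Linear interpolation onto 101 evenly spaced points between the event
#' bounds; endpoints are preserved exactly.
#'
#' @param time sample times (s).
#' @param value sample values.
#' @param bounds length-2 event window (defaults to the full record).
#' @param activity optional activity label carried on the curve.
#' @return a `Curve`: list with `percent` (0..100), `value` (length 101)
#'   and `activity`.
#' @export
normalize_cycle <- function(time, value, bounds = range(time), activity = NA) {
  sel <- time >= bounds[1] - 1e-12 & time <= bounds[2] + 1e-12
  if (sum(sel) < 2) knee_stop("fewer than 2 samples inside bounds", "knee_domain_error")
  tt <- time[sel]; vv <- value[sel]
  tq <- seq(bounds[1], bounds[2], length.out = 101)
  out <- approx(tt, vv, tq, rule = 2)$y
  structure(list(percent = seq(0, 100, length.out = 101), value = out,
                 activity = activity), class = "Curve")
}

curve_values <- function(x) if (inherits(x, "Curve")) x$value else as.numeric(x)

#' Root-mean-square error between two curves
#' @param c predicted curve (`Curve` or numeric).
#' @param m reference curve, same length.
#' @return RMSE in the curves' units (BW for contact force curves).
#' @export
rmse <- function(c, m) {
  cv <- curve_values(c); mv <- curve_values(m)
  if (length(cv) != length(mv)) knee_stop("curve lengths differ", "knee_domain_error")
  sqrt(mean((cv - mv)^2))
}

#' Coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot` with the total sum of squares about the mean
#' of the reference curve `m`.
#'
#' @inheritParams rmse
#' @return R-squared (1 iff the curves agree pointwise).
#' @export
r_squared <- function(c, m) {
  cv <- curve_values(c); mv <- curve_values(m)
  if (length(cv) != length(mv)) knee_stop("curve lengths differ", "knee_domain_error")
  ss_tot <- sum((mv - mean(mv))^2)
  ss_res <- sum((cv - mv)^2)
  if (ss_tot == 0) {
    if (ss_res == 0) return(1)
    knee_stop("reference curve is constant: R^2 denominator undefined",
              "knee_domain_error")
  }
  1 - ss_res / ss_tot
}

#' Sprague-Geers magnitude, phase and combined error
#'
#' With inner products `psi_ab = mean(a * b)`:
#' `M = sqrt(psi_cc / psi_mm) - 1`,
#' `P = acos(psi_cm / sqrt(psi_cc * psi_mm)) / pi`,
#' `C_E = sqrt(M^2 + P^2)`.
#' Amplitude-only distortion gives `P = 0`; a pure time shift of a periodic
#' curve gives `M = 0`.
#'
#' @inheritParams rmse
#' @return list with `M`, `P`, `C_E`.
#' @export
sprague_geers <- function(c, m) {
  cv <- curve_values(c); mv <- curve_values(m)
  if (length(cv) != length(mv)) knee_stop("curve lengths differ", "knee_domain_error")
  pmm <- mean(mv^2)
  pcc <- mean(cv^2)
  if (pmm == 0) knee_stop("reference curve has zero energy", "knee_domain_error")
  M <- sqrt(pcc / pmm) - 1
  P <- if (pcc == 0) 0.5 else acos(max(-1, min(1, mean(cv * mv) / sqrt(pcc * pmm)))) / pi
  list(M = M, P = P, C_E = sqrt(M^2 + P^2))
}

#' Peak summary of an activity curve
#'
#' Double-peak activities (walking, stair ascent/descent) report the maxima
#' over the early ([0, 50)%) and late ([50, 100]%) windows; the sit/stand
#' transfers report the single global maximum. The medial share is the
#' cycle-mean ratio of the medial to the total curve, in percent.
#'
#' @param curve total-force `Curve` (or numeric length 101).
#' @param activity one of `"walk"`, `"stair_ascent"`, `"stair_descent"`,
#'   `"sit_to_stand"`, `"stand_to_sit"`.
#' @param medial optional medial-compartment curve for the share.
#' @param split window split (% cycle) for double-peak activities.
#' @return a `PeakSummary` list.
#' @export
extract_peaks <- function(curve, activity, medial = NULL, split = 50) {
  v <- curve_values(curve)
  pc <- seq(0, 100, length.out = length(v))
  acts <- c("walk", "stair_ascent", "stair_descent", "sit_to_stand", "stand_to_sit")
  if (!activity %in% acts)
    knee_stop(paste("unknown activity:", activity), "knee_domain_error")
  double <- activity %in% c("walk", "stair_ascent", "stair_descent")
  out <- list(activity = activity)
  if (double) {
    e <- pc < split
    i1 <- which.max(v[e]); i2 <- which.max(v[!e])
    out$first_peak <- v[e][i1]; out$first_peak_pct <- pc[e][i1]
    out$second_peak <- v[!e][i2]; out$second_peak_pct <- pc[!e][i2]
  } else {
    i <- which.max(v)
    out$peak <- v[i]; out$peak_pct <- pc[i]
  }
  if (!is.null(medial)) {
    mv <- curve_values(medial)
    out$medial_share <- 100 * mean(mv) / mean(v)
  }
  structure(out, class = "PeakSummary")
}

#' Full comparison metrics between predicted and reference curves
#' @inheritParams rmse
#' @return a `ComparisonMetrics` list: `rmse`, `r_squared`, `sg_magnitude`,
#'   `sg_phase`, `c_e`.
#' @export
compare_curves <- function(c, m) {
  sg <- sprague_geers(c, m)
  structure(list(rmse = rmse(c, m), r_squared = r_squared(c, m),
                 sg_magnitude = sg$M, sg_phase = sg$P, c_e = sg$C_E),
            class = "ComparisonMetrics")
}
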