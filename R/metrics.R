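# Objective functions and post-hoc AP/CaT metrics.

waveform_rmse <- function(a, b) sqrt(mean((a - b)^2))

#' Normalized RMSE objectives and the acceptance rule
#'
#' Scores a treated HF cardiomyocyte against the healthy target:
#' `rmse_ap = RMSE(treated.AP, healthy.AP) / RMSE(untreated.AP, healthy.AP)`
#' and analogously for the calcium transient, over the shared 501-sample 1 ms
#' grid. A candidate is accepted when both normalized RMSEs are strictly
#' below 0.5 (ties at exactly 0.5 reject). The untreated waveform scores
#' exactly (1, 1) by construction.
#'
#' @param treated,healthy,untreated `cellforge_beat` waveforms on the
#'   identical grid.
#' @return Object of class `objective_scores`: list with `rmse_ap`,
#'   `rmse_cat` (dimensionless fractions), `n_pass` (0-2), `accepted`.
#' @export
normalized_rmse <- function(treated, healthy, untreated) {
  for (w in list(treated, healthy, untreated))
    stopifnot(inherits(w, "cellforge_beat"))
  if (!isTRUE(all.equal(treated$time_ms, healthy$time_ms)) ||
      !isTRUE(all.equal(treated$time_ms, untreated$time_ms)))
    stop("waveform grids do not match")
  den_ap <- waveform_rmse(untreated$ap, healthy$ap)
  den_cat <- waveform_rmse(untreated$cat, healthy$cat)
  if (den_ap == 0 || den_cat == 0)
    stop("untreated and healthy waveforms are identical: normalization undefined")
  objective_scores(waveform_rmse(treated$ap, healthy$ap) / den_ap,
                   waveform_rmse(treated$cat, healthy$cat) / den_cat)
}

objective_scores <- function(rmse_ap, rmse_cat) {
  n_pass <- sum(c(rmse_ap, rmse_cat) < 0.5)
  structure(list(rmse_ap = rmse_ap, rmse_cat = rmse_cat,
                 n_pass = as.integer(n_pass), accepted = n_pass == 2L),
            class = "objective_scores")
}

#' @export
print.objective_scores <- function(x, ...) {
  cat(sprintf("<objective_scores> RMSE_AP = %.3f, RMSE_CaT = %.3f (%d/2 < 0.5) -> %s\n",
              x$rmse_ap, x$rmse_cat, x$n_pass,
              if (x$accepted) "ACCEPTED" else "rejected"))
  invisible(x)
}

# first downward crossing of `level` after index `from`; linear interpolation
cross_down <- function(t, y, level, from) {
  n <- length(y)
  if (from >= n) return(NA_real_)
  below <- which(y[(from + 1):n] < level)
  if (!length(below)) return(NA_real_)
  i <- below[1] + from                 # first sample below level
  t[i - 1] + (y[i - 1] - level) / (y[i - 1] - y[i]) * (t[i] - t[i - 1])
}

#' Action-potential metrics
#'
#' Metrics of one paced beat: resting membrane potential (Vm at stimulus
#' onset, the first sample), peak Vm, maximum upstroke velocity (finite
#' differences on the stored 1 ms grid), and APD50/APD90 measured from the
#' maximum-upstroke instant to the downstroke crossing of
#' `peak - x% * (peak - RMP)`. A beat whose amplitude is below 10 mV carries
#' no action potential and yields `no_ap = TRUE` with NA durations.
#'
#' @param beat A `cellforge_beat`.
#' @return List: `rmp`, `peak_vm` (mV), `upstroke_vmax` (mV/ms), `apd50`,
#'   `apd90` (ms), `no_ap`.
#' @export
ap_metrics <- function(beat) {
  stopifnot(inherits(beat, "cellforge_beat"))
  t <- beat$time_ms; v <- beat$ap
  rmp <- v[1]
  peak <- max(v)
  dv <- diff(v) / diff(t)
  iup <- which.max(dv)                 # steepest interval starts at t[iup]
  vmax <- dv[iup]
  if (peak - rmp < 10) {
    return(list(rmp = rmp, peak_vm = peak, upstroke_vmax = vmax,
                apd50 = NA_real_, apd90 = NA_real_, no_ap = TRUE))
  }
  t_up <- t[iup]
  ipk <- which.max(v)
  apd <- function(frac) {
    lev <- peak - frac * (peak - rmp)
    tc <- cross_down(t, v, lev, ipk)
    if (is.na(tc)) NA_real_ else tc - t_up
  }
  list(rmp = rmp, peak_vm = peak, upstroke_vmax = vmax,
       apd50 = apd(0.5), apd90 = apd(0.9), no_ap = FALSE)
}

#' Calcium-transient metrics
#'
#' Diastolic level is the pre-stimulus sample, amplitude is peak minus
#' diastolic, and the relaxation times tau50/tau90 are the threshold-crossing
#' times from the CaT peak to 50% / 90% decay of the amplitude (crossing
#' times, not fitted exponential constants).
#'
#' @param beat A `cellforge_beat`.
#' @return List: `peak`, `diastolic`, `amplitude` (mM), `tau50`, `tau90` (ms).
#' @export
cat_metrics <- function(beat) {
  stopifnot(inherits(beat, "cellforge_beat"))
  t <- beat$time_ms; ca <- beat$cat
  dia <- ca[1]
  ipk <- which.max(ca)
  peak <- ca[ipk]
  amp <- peak - dia
  tau <- function(frac) {
    tc <- cross_down(t, ca, peak - frac * amp, ipk)
    if (is.na(tc)) NA_real_ else tc - t[ipk]
  }
  list(peak = peak, diastolic = dia, amplitude = amp,
       tau50 = tau(0.5), tau90 = tau(0.9))
}
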