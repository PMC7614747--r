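# IEC-style limit logic: allowed drive power, thermal limit crossings and
# h-sensitivity sweeps.

#' Construct a limit set
#'
#' Defaults are the operative values for head-coil exposure: head-average
#' SAR 3.2 W/kg, psSAR10g 10 W/kg, whole-body SAR 4 W/kg, core-temperature
#' rise 0.5 C, absolute local temperature 39 C.  Limits are plain numbers:
#' the operating-mode taxonomy is not encoded.
#'
#' @param headAvg,psSAR10g,wholeBody SAR limits (W/kg).
#' @param coreRise core-temperature rise limit (C).
#' @param absoluteT absolute local temperature limit (C).
#' @return A \linkS4class{LimitSet}.
#' @export
limitSet <- function(headAvg = 3.2, psSAR10g = 10, wholeBody = 4,
                     coreRise = 0.5, absoluteT = 39) {
  new("LimitSet", headAvg = headAvg, psSAR10g = psSAR10g,
      wholeBody = wholeBody, coreRise = coreRise, absoluteT = absoluteT)
}

#' Allowed drive power for the SAR limits
#'
#' Given SAR summaries normalized per watt of input power, the allowed
#' power is the minimum over limits of limit / (SAR per watt); the binding
#' limit is reported.  Whole-body is only enforced when a whole-body value
#' is supplied and finite.
#'
#' @param sarPerW named numeric with elements \code{head_avg},
#'   \code{psSAR10g} and optionally \code{whole_body_avg} (W/kg/W), e.g.
#'   from \code{\link{normalizeSAR}} with mode \code{input_power}.
#' @param limits A \linkS4class{LimitSet}.
#' @return list(power, binding, margins) where margins are the per-limit
#'   allowed powers (W).
#' @export
powerForLimit <- function(sarPerW, limits = limitSet()) {
  cand <- c(head_avg = limits@headAvg / sarPerW[["head_avg"]],
            psSAR10g = limits@psSAR10g / sarPerW[["psSAR10g"]])
  if ("whole_body_avg" %in% names(sarPerW) &&
      is.finite(sarPerW[["whole_body_avg"]]) && sarPerW[["whole_body_avg"]] > 0)
    cand <- c(cand, whole_body = limits@wholeBody / sarPerW[["whole_body_avg"]])
  if (any(!is.finite(cand)))
    stop("zero or non-finite normalized SAR; cannot compute allowed power")
  i <- which.min(cand)
  list(power = unname(cand[i]), binding = names(cand)[i], margins = cand)
}

#' First crossing times of the thermal limits
#'
#' Finds, with linear interpolation between samples, the first time at
#' which the core temperature rise above \code{T_core_baseline} exceeds the
#' core-rise limit, and the first time the maximum temperature exceeds the
#' absolute limit.  \code{Inf} means no crossing within the series.
#'
#' @param series data.frame with columns \code{t_s}, \code{T_core_C},
#'   \code{T_max_C} (as emitted by \code{\link{runExposure}}).
#' @param limits A \linkS4class{LimitSet}.
#' @param T_core_baseline baseline core temperature (C); defaults to the
#'   first sample (RF onset).
#' @return list(core_rise_s, absolute_s) first-crossing times in seconds.
#' @export
checkThermal <- function(series, limits = limitSet(), T_core_baseline = NULL) {
  if (is.null(series) || !nrow(series)) stop("empty thermal series")
  if (is.unsorted(series$t_s)) stop("series must be ordered in time")
  if (is.null(T_core_baseline)) T_core_baseline <- series$T_core_C[1]
  firstCrossing <- function(t, v, thr) {
    above <- !is.na(v) & v > thr
    if (!any(above)) return(Inf)
    i <- which(above)[1]
    if (i == 1) return(t[1])
    # linear interpolation between the bracketing samples
    t[i - 1] + (thr - v[i - 1]) / (v[i] - v[i - 1]) * (t[i] - t[i - 1])
  }
  list(core_rise_s = firstCrossing(series$t_s,
                                   series$T_core_C - T_core_baseline,
                                   limits@coreRise),
       absolute_s = firstCrossing(series$t_s, series$T_max_C,
                                  limits@absoluteT))
}

#' Heat-transfer-coefficient sensitivity sweep
#'
#' Repeats the exposure run for h scaled by the requested deltas and
#' tabulates limit-crossing times and final temperatures.  Deterministic:
#' the same state and SAR grid are reused for every h.
#'
#' @param state0 equilibrated \linkS4class{ThermalState}.
#' @param system ThermalSystem.
#' @param sar SAR grid (W/kg) at the exposure drive.
#' @param h0 baseline h; defaults to the system config value.
#' @param deltas relative changes (default +/-10 and +/-20 percent).
#' @param duration exposure duration (s).
#' @param limits A \linkS4class{LimitSet}.
#' @param file optional CSV path.
#' @return data.frame, one row per h.
#' @export
hSensitivity <- function(state0, system, sar, h0 = NULL,
                         deltas = c(-0.2, -0.1, 0, 0.1, 0.2),
                         duration = 3600, limits = limitSet(), file = NULL) {
  if (is.null(h0)) h0 <- system$config@h
  rows <- lapply(deltas, function(dl) {
    h <- h0 * (1 + dl)
    run <- runExposure(state0, system, sar = sar, duration = duration, h = h)
    cr <- checkThermal(run$series, limits)
    n <- nrow(run$series)
    data.frame(delta = dl, h_W_m2_K = h,
               core_rise_crossing_s = cr$core_rise_s,
               absolute_crossing_s = cr$absolute_s,
               T_core_final_C = run$series$T_core_C[n],
               T_max_final_C = run$series$T_max_C[n],
               T_blood_final_C = run$series$T_blood_C[n])
  })
  out <- do.call(rbind, rows)
  if (!is.null(file)) write.csv(out, file, row.names = FALSE)
  out
}
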