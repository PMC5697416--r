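#' Construct a full cardiovascular parameter set
#'
#' Bundles the five tunable inputs of the model (maximal left-ventricular
#' elastance, systemic vascular resistance, total arterial compliance,
#' circulating blood volume and cardiac cycle period) with the fixed internal
#' constants of the closed loop (diastolic elastances, atrial elastance
#' bounds, valve and venous resistances, venous compliance, unstressed
#' volumes and activation timing fractions).  The defaults for the fixed
#' constants are the frozen result of the one-time baseline calibration (see
#' [calibrateBaseline()]); the defaults for the five tunable inputs are the
#' normal-physiology preset.
#'
#' Units are mmHg, ml and s throughout: elastances in mmHg/ml, resistances in
#' mmHg·s/ml, compliances in ml/mmHg, volumes in ml, times in s.
#'
#' @param E_lv_max Maximal (end-systolic) left-ventricular elastance, mmHg/ml.
#' @param R_sys Systemic vascular resistance, mmHg·s/ml.
#' @param C_art Total arterial compliance, ml/mmHg.
#' @param V_total Circulating blood volume, ml.
#' @param T Cardiac cycle period, s (60/heart rate).
#' @param E_lv_min Minimal (diastolic) left-ventricular elastance, mmHg/ml.
#' @param E_la_min,E_la_max Atrial elastance bounds, mmHg/ml.
#' @param R_mi,R_ao Open-valve resistances of the mitral and aortic valves,
#'   mmHg·s/ml.
#' @param R_ven Venous-return resistance, mmHg·s/ml.
#' @param C_ven Venous (capacitance-bed) compliance, ml/mmHg.
#' @param V0_la,V0_lv,V0_art,V0_ven Unstressed volumes, ml.
#' @param f_peak,f_end Ventricular activation timing, as fractions of `T`:
#'   time of peak elastance and end of systole.
#' @param f_atrial_onset,f_atrial_end Atrial activation timing fractions of
#'   `T`; the atrial beat may wrap across the cycle end.
#' @return An object of class `cardio_params` (a validated named list).
#' @seealso [loadPreset()], [applyOverrides()], [runToSteadyState()]
#' @examples
#' p <- cardioParams()                    # calibrated normal physiology
#' p2 <- cardioParams(R_sys = 1.374, C_art = 1.165, E_lv_max = 2.7)
#' @export
cardioParams <- function(E_lv_max = 2.5,
                         R_sys = 0.994,
                         C_art = 1.75,
                         V_total = 5700,
                         T = 1,
                         E_lv_min = 0.039867,
                         E_la_min = 0.221524,
                         E_la_max = 0.282894,
                         R_mi = 0.01,
                         R_ao = 0.01,
                         R_ven = 0.115502,
                         C_ven = 171.21,
                         V0_la = 5,
                         V0_lv = 10,
                         V0_art = 600,
                         V0_ven = 1872.6,
                         f_peak = 0.218808,
                         f_end = 0.495060,
                         f_atrial_onset = 0.85,
                         f_atrial_end = 1.0) {
  p <- list(E_lv_max = E_lv_max, R_sys = R_sys, C_art = C_art,
            V_total = V_total, T = T,
            E_lv_min = E_lv_min, E_la_min = E_la_min, E_la_max = E_la_max,
            R_mi = R_mi, R_ao = R_ao, R_ven = R_ven, C_ven = C_ven,
            V0_la = V0_la, V0_lv = V0_lv, V0_art = V0_art, V0_ven = V0_ven,
            f_peak = f_peak, f_end = f_end,
            f_atrial_onset = f_atrial_onset, f_atrial_end = f_atrial_end)
  class(p) <- "cardio_params"
  validateParams(p)
  p
}

#' Validate a cardiovascular parameter set
#'
#' Checks positivity of all elastances, resistances, compliances, volumes and
#' the period; the elastance orderings `E_lv_min < E_lv_max` and
#' `E_la_min <= E_la_max`; the ventricular timing ordering
#' `0 < f_peak < f_end < 1`; atrial timing fractions in `[0, 1)` (the atrial
#' end fraction 1.0 is permitted, meaning the beat ends exactly at the cycle
#' boundary); and that some stressed volume exists
#' (`V_total > V0_la + V0_lv + V0_art + V0_ven`).
#'
#' @param p A `cardio_params` object or a named list with the same fields.
#' @return `p`, invisibly, if valid; otherwise an error describing the first
#'   violated constraint.
#' @export
validateParams <- function(p) {
  fields <- names(formals(cardioParams))
  missing <- setdiff(fields, names(p))
  if (length(missing))
    stop("parameter set is missing fields: ", paste(missing, collapse = ", "))
  num <- vapply(p[fields], function(x)
    is.numeric(x) && length(x) == 1L && is.finite(x), logical(1))
  if (!all(num))
    stop("non-numeric or non-finite parameter: ",
         paste(fields[!num], collapse = ", "))
  positive <- c("E_lv_max", "R_sys", "C_art", "V_total", "T", "E_lv_min",
                "E_la_min", "E_la_max", "R_mi", "R_ao", "R_ven", "C_ven",
                "V0_la", "V0_lv", "V0_art", "V0_ven")
  bad <- positive[vapply(p[positive], function(x) x <= 0, logical(1))]
  if (length(bad))
    stop("parameters must be strictly positive: ", paste(bad, collapse = ", "))
  if (p$E_lv_min >= p$E_lv_max)
    stop("E_lv_min (", p$E_lv_min, ") must be < E_lv_max (", p$E_lv_max, ")")
  if (p$E_la_min > p$E_la_max)
    stop("E_la_min must be <= E_la_max")
  if (!(p$f_peak > 0 && p$f_peak < p$f_end && p$f_end < 1))
    stop("ventricular timing must satisfy 0 < f_peak < f_end < 1")
  if (p$f_atrial_onset < 0 || p$f_atrial_onset >= 1 ||
      p$f_atrial_end < 0 || p$f_atrial_end > 1)
    stop("atrial timing fractions must lie in [0, 1]")
  v0 <- p$V0_la + p$V0_lv + p$V0_art + p$V0_ven
  if (p$V_total <= v0)
    stop("V_total (", p$V_total, ") must exceed total unstressed volume (",
         v0, "): no stressed volume would remain")
  invisible(p)
}

#' Apply named overrides to a parameter set
#'
#' Returns a new parameter set with the given fields replaced; the base set
#' is not modified and the full validation is re-run on the result.
#'
#' @param base A `cardio_params` object.
#' @param overrides A named list (or named numeric vector) of replacement
#'   values; names must be `cardio_params` fields.
#' @return A new validated `cardio_params` object.
#' @examples
#' htn <- applyOverrides(cardioParams(), list(R_sys = 1.614, C_art = 1.165))
#' @export
applyOverrides <- function(base, overrides = list()) {
  stopifnot(inherits(base, "cardio_params"))
  overrides <- as.list(overrides)
  if (length(overrides) == 0L) return(base)
  if (is.null(names(overrides)) || any(!nzchar(names(overrides))))
    stop("overrides must be named")
  unknown <- setdiff(names(overrides), names(base))
  if (length(unknown))
    stop("unknown parameter field(s): ", paste(unknown, collapse = ", "))
  out <- base
  out[names(overrides)] <- overrides
  validateParams(out)
  out
}

#' @export
print.cardio_params <- function(x, ...) {
  cat("<cardio_params>  (mmHg, ml, s)\n")
  cat(sprintf("  inputs:   E_lv_max %.3f  R_sys %.3f  C_art %.3f  V_total %g  T %.3f (HR %.0f)\n",
              x$E_lv_max, x$R_sys, x$C_art, x$V_total, x$T, 60 / x$T))
  cat(sprintf("  chambers: E_lv_min %.4f  E_la [%.3f, %.3f]  timing f_peak %.3f f_end %.3f\n",
              x$E_lv_min, x$E_la_min, x$E_la_max, x$f_peak, x$f_end))
  cat(sprintf("  vessels:  R_mi %.3f  R_ao %.3f  R_ven %.3f  C_ven %.1f\n",
              x$R_mi, x$R_ao, x$R_ven, x$C_ven))
  cat(sprintf("  V0:       la %g  lv %g  art %g  ven %g\n",
              x$V0_la, x$V0_lv, x$V0_art, x$V0_ven))
  invisible(x)
}
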