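#' Simulation configuration
#'
#' Controls for the periodic-steady-state run: output sampling interval,
#' cycle cap, the relative steady-state tolerance applied to both stroke
#' volume and mean arterial pressure between consecutive cycles, and the
#' integrator tolerances passed to [deSolve::ode()].
#'
#' @param dt_output Sampling interval of the recorded final cycle, s.
#' @param max_cycles Maximum number of cycles to integrate before flagging
#'   non-convergence; at least 2.
#' @param ss_rel_tol Relative steady-state tolerance (dimensionless).
#' @param solver_rel_tol,solver_abs_tol Integrator tolerances.
#' @return An object of class `sim_config`.
#' @export
simConfig <- function(dt_output = 1e-3, max_cycles = 50, ss_rel_tol = 1e-3,
                      solver_rel_tol = 1e-8, solver_abs_tol = 1e-8) {
  if (dt_output <= 0) stop("dt_output must be positive")
  if (max_cycles < 2) stop("max_cycles must be at least 2")
  if (ss_rel_tol <= 0 || solver_rel_tol <= 0 || solver_abs_tol <= 0)
    stop("tolerances must be positive")
  structure(list(dt_output = dt_output, max_cycles = as.integer(max_cycles),
                 ss_rel_tol = ss_rel_tol, solver_rel_tol = solver_rel_tol,
                 solver_abs_tol = solver_abs_tol),
            class = "sim_config")
}

#' Deterministic warm-start state
#'
#' Distributes the stressed volume `V_total - sum(V0)` across the four
#' compartments in proportion to their diastolic compliances (chambers taken
#' at `1/E_min`), so every compartment starts at the same transmural
#' pressure.
#'
#' @param params A `cardio_params` object.
#' @return Named numeric vector `V_la, V_lv, V_art, V_ven`, ml, summing
#'   exactly to `V_total`.
#' @export
initialState <- function(params) {
  v0 <- c(V_la = params$V0_la, V_lv = params$V0_lv,
          V_art = params$V0_art, V_ven = params$V0_ven)
  stressed <- params$V_total - sum(v0)
  cw <- c(1 / params$E_la_min, 1 / params$E_lv_min, params$C_art, params$C_ven)
  v0 + stressed * cw / sum(cw)
}

# integrate exactly one cycle from y0, sampled at `times`
.integrate_cycle <- function(y0, times, params, config) {
  out <- deSolve::ode(y = y0, times = times, func = circulationRHS,
                      parms = params, method = "lsoda",
                      rtol = config$solver_rel_tol,
                      atol = config$solver_abs_tol)
  if (attr(out, "istate")[1L] < 0 || any(!is.finite(out)))
    stop("integrator failure within cycle")
  out
}

#' Run the closed loop to periodic steady state
#'
#' Integrates the circulation cycle by cycle from the deterministic warm
#' start ([initialState()]) until the relative change in both stroke volume
#' and mean arterial pressure between consecutive cycles drops below
#' `ss_rel_tol`, or `max_cycles` is reached (the result is then flagged
#' non-converged rather than raising an error).  The final converged cycle
#' is re-sampled at `dt_output` and returned with pressures and flows.
#'
#' @param params A `cardio_params` object.
#' @param config A `sim_config` object.
#' @return A `cycle_series` data frame with columns `t`, the four pressures
#'   `P_la, P_lv, P_art, P_ven` (mmHg), the four volumes
#'   `V_la, V_lv, V_art, V_ven` (ml), the four flows
#'   `Q_mi, Q_ao, Q_sys, Q_ven` (ml/s) and `cycle`; attributes carry the
#'   parameters and convergence metadata (`converged`, `cycles`,
#'   `conservation`, the largest relative total-volume drift over the
#'   recorded cycle).
#' @examples
#' \donttest{
#' series <- runToSteadyState(loadPreset("normal"))
#' attr(series, "converged"); attr(series, "cycles")
#' }
#' @export
runToSteadyState <- function(params, config = simConfig()) {
  validateParams(params)
  y <- initialState(params)
  coarse <- seq(0, params$T, length.out = 201L)
  prev <- NULL
  converged <- FALSE
  cycles <- 0L
  for (k in seq_len(config$max_cycles)) {
    cycles <- k
    out <- tryCatch(.integrate_cycle(y, coarse, params, config),
                    error = function(e)
                      stop("simulation failed in cycle ", k, ": ",
                           conditionMessage(e)))
    y <- out[nrow(out), c("V_la", "V_lv", "V_art", "V_ven")]
    sv <- max(out[, "V_lv"]) - min(out[, "V_lv"])
    map <- .cycle_mean(out[, "time"], out[, "P_art"])
    if (!is.null(prev) &&
        abs(sv - prev[1L]) <= config$ss_rel_tol * abs(prev[1L]) &&
        abs(map - prev[2L]) <= config$ss_rel_tol * abs(prev[2L])) {
      converged <- TRUE
      break
    }
    prev <- c(sv, map)
  }
  times <- seq(0, params$T, by = config$dt_output)
  if (times[length(times)] < params$T) times <- c(times, params$T)
  out <- .integrate_cycle(y, times, params, config)
  series <- as.data.frame(out)
  names(series)[1L] <- "t"
  series <- series[, c("t", "P_la", "P_lv", "P_art", "P_ven",
                       "V_la", "V_lv", "V_art", "V_ven",
                       "Q_mi", "Q_ao", "Q_sys", "Q_ven")]
  series$cycle <- cycles
  total <- series$V_la + series$V_lv + series$V_art + series$V_ven
  structure(series,
            class = c("cycle_series", "data.frame"),
            params = params,
            converged = converged,
            cycles = cycles,
            conservation = max(abs(total - params$V_total)) / params$V_total)
}

# time-average of x(t) over one cycle by the trapezoidal rule
.cycle_mean <- function(t, x) {
  n <- length(t)
  sum(diff(t) * (x[-1L] + x[-n]) / 2) / (t[n] - t[1L])
}

.assert_one_cycle <- function(series) {
  if (!inherits(series, "cycle_series") || nrow(series) < 3L)
    stop("expected a non-empty cycle_series covering one cycle")
  p <- attr(series, "params")
  span <- max(series$t) - min(series$t)
  if (length(unique(series$cycle)) != 1L || span > 1.5 * p$T)
    stop("series must cover exactly one cycle")
  invisible(p)
}

#' Extract haemodynamic indices from a converged cycle
#'
#' Computes the standard summary of one periodic cycle: systolic, diastolic
#' and (time-averaged) mean arterial pressure; end-diastolic, end-systolic
#' and stroke volume of the left ventricle; heart rate; cardiac output and
#' ejection fraction.  Heart rate is reported rounded to the nearest beat
#' per minute while cardiac output is computed from the unrounded rate
#' (`CO = SV * (60/T) / 1000` l/min).
#'
#' @param series A `cycle_series` covering exactly one converged cycle.
#' @param T Cycle period, s; defaults to the period stored with the series.
#' @return An object of class `haemodynamics`: a list with fields `SBP`,
#'   `DBP`, `MAP` (mmHg), `HR` (bpm, integer-rounded), `HR_exact` (bpm),
#'   `SV`, `EDV`, `ESV` (ml), `CO` (l/min) and `LVEF` (fraction).
#' @export
extractMetrics <- function(series, T = NULL) {
  p <- .assert_one_cycle(series)
  if (is.null(T)) T <- p$T
  sbp <- max(series$P_art)
  dbp <- min(series$P_art)
  map <- .cycle_mean(series$t, series$P_art)
  edv <- max(series$V_lv)
  esv <- min(series$V_lv)
  sv <- edv - esv
  hr <- 60 / T
  out <- list(SBP = sbp, DBP = dbp, MAP = map,
              HR = round(hr), HR_exact = hr,
              SV = sv, EDV = edv, ESV = esv,
              CO = sv * hr / 1000, LVEF = sv / edv)
  class(out) <- "haemodynamics"
  out
}

#' @export
print.haemodynamics <- function(x, ...) {
  cat("<haemodynamics>\n")
  cat(sprintf("  BP %.0f/%.0f mmHg  (MAP %.0f)   HR %d bpm\n",
              x$SBP, x$DBP, x$MAP, x$HR))
  cat(sprintf("  SV %.1f ml  EDV %.1f  ESV %.1f  CO %.1f l/min  LVEF %.2f\n",
              x$SV, x$EDV, x$ESV, x$CO, x$LVEF))
  invisible(x)
}

#' @export
print.cycle_series <- function(x, ...) {
  cat(sprintf("<cycle_series> %d samples over one cycle (T = %g s)\n",
              nrow(x), attr(x, "params")$T))
  cat(sprintf("  converged: %s after %d cycles; volume drift %.2e relative\n",
              attr(x, "converged"), attr(x, "cycles"),
              attr(x, "conservation")))
  invisible(x)
}

#' Pressure-volume loop of the left ventricle
#'
#' Orders the `(V_lv, P_lv)` samples of one converged cycle into a closed
#' loop (the first point is appended at the end) and computes the enclosed
#' area by the shoelace formula.  With ejection occurring at high pressure
#' the loop is traversed counter-clockwise in the (V, P) plane and the area
#' equals the net stroke work in mmHg·ml.
#'
#' @param series A `cycle_series` covering exactly one converged cycle.
#' @return A data frame of class `pv_loop` with columns `V_lv` (ml) and
#'   `P_lv` (mmHg), first row duplicated as the last; attribute `area` holds
#'   the stroke work (mmHg·ml).
#' @export
pvLoop <- function(series) {
  .assert_one_cycle(series)
  n <- nrow(series)
  # drop the duplicated cycle endpoint if present, then close the loop
  if (isTRUE(all.equal(series$V_lv[1L], series$V_lv[n], tolerance = 1e-6)) &&
      isTRUE(all.equal(series$P_lv[1L], series$P_lv[n], tolerance = 1e-6)))
    series <- series[-n, , drop = FALSE]
  loop <- data.frame(V_lv = c(series$V_lv, series$V_lv[1L]),
                     P_lv = c(series$P_lv, series$P_lv[1L]))
  structure(loop, class = c("pv_loop", "data.frame"),
            area = loopArea(loop$V_lv, loop$P_lv))
}

#' Shoelace area of a closed loop
#'
#' Signed polygon area of the closed `(V, P)` trajectory, with the sign
#' chosen so that a counter-clockwise loop (ejection at high pressure,
#' filling at low pressure) has positive area.
#'
#' @param V,P Coordinates of the loop; the last point should repeat the
#'   first (it is closed automatically otherwise).
#' @return Area in mmHg·ml.
#' @export
loopArea <- function(V, P) {
  n <- length(V)
  if (V[1L] != V[n] || P[1L] != P[n]) {
    V <- c(V, V[1L]); P <- c(P, P[1L]); n <- n + 1L
  }
  i <- seq_len(n - 1L)
  sum(V[i] * P[i + 1L] - V[i + 1L] * P[i]) / 2
}
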