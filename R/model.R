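#' Ventricular activation waveform
#'
#' Normalised activation e(t) driving the time-varying elastance of the left
#' ventricle: a piecewise-cosine pulse that rises smoothly from 0 to 1 over
#' `[0, f_peak*T]`, falls back to 0 over `[f_peak*T, f_end*T]` and is 0 for
#' the remainder of the cycle.  The instantaneous elastance is then
#' `E(t) = E_min + (E_max - E_min) * e(t)`.
#'
#' @param t_in_cycle Time since the start of the current cycle, s; must lie
#'   in `[0, T)`.
#' @param T Cardiac cycle period, s.
#' @param f_peak Fraction of `T` at which elastance peaks.
#' @param f_end Fraction of `T` at which systole ends.
#' @return Activation value(s) in `[0, 1]`.
#' @examples
#' activation(0, 1, 0.3, 0.45)        # 0 at cycle start
#' activation(0.3, 1, 0.3, 0.45)      # 1 at peak
#' activation(0.15, 1, 0.3, 0.45)     # 0.5 halfway up the cosine ramp
#' @export
activation <- function(t_in_cycle, T, f_peak, f_end) {
  if (any(t_in_cycle < 0 | t_in_cycle >= T))
    stop("t_in_cycle must lie in [0, T)")
  .activation(t_in_cycle, T, f_peak, f_end)
}

# unchecked core, accepts any t and wraps it into the cycle
.activation <- function(t, T, f_peak, f_end) {
  tt <- t %% T
  tp <- f_peak * T
  te <- f_end * T
  ifelse(tt < tp,
         (1 - cos(pi * tt / tp)) / 2,
         ifelse(tt < te,
                (1 + cos(pi * (tt - tp) / (te - tp))) / 2,
                0))
}

#' Atrial activation waveform
#'
#' A single raised-cosine pulse placed in late diastole, expressed in cycle
#' fractions and allowed to wrap across the cycle end (onset fraction larger
#' than end fraction means the beat straddles `t = T`).
#'
#' @inheritParams activation
#' @param f_onset,f_end Onset and end of the atrial beat as fractions of `T`.
#' @return Activation value(s) in `[0, 1]`.
#' @export
atrialActivation <- function(t_in_cycle, T, f_onset, f_end) {
  if (any(t_in_cycle < 0 | t_in_cycle >= T))
    stop("t_in_cycle must lie in [0, T)")
  .atrial_activation(t_in_cycle, T, f_onset, f_end)
}

.atrial_activation <- function(t, T, f_onset, f_end) {
  d <- (f_end - f_onset) %% 1
  if (d == 0) return(rep(0, length(t)))
  ph <- ((t / T) - f_onset) %% 1
  ifelse(ph < d, (1 - cos(2 * pi * ph / d)) / 2, 0)
}

#' Elastance-chamber pressure law
#'
#' Pressure generated by a heart chamber of elastance `E` holding volume `V`
#' above its unstressed volume `V0`: `P = E * (V - V0)`.  Transiently
#' negative pressures (`V < V0`) are permitted.
#'
#' @param V Chamber volume, ml.
#' @param E Chamber elastance, mmHg/ml; must be positive.
#' @param V0 Unstressed volume, ml.
#' @return Pressure, mmHg.
#' @export
chamberPressure <- function(V, E, V0) {
  if (any(E <= 0)) stop("elastance E must be positive")
  E * (V - V0)
}

#' Flow through an ideal-diode valve
#'
#' Pressure-gradient flow through an open valve of resistance `R_valve`,
#' blocked completely when the gradient reverses:
#' `Q = max(P_up - P_down, 0) / R_valve`.
#'
#' @param P_up,P_down Upstream and downstream pressures, mmHg.
#' @param R_valve Open-valve resistance, mmHg·s/ml; must be positive.
#' @return Flow, ml/s; never negative.
#' @export
valveFlow <- function(P_up, P_down, R_valve) {
  if (any(R_valve <= 0)) stop("R_valve must be positive")
  pmax(P_up - P_down, 0) / R_valve
}

#' Flow through a linear resistance
#'
#' Ohmic flow `Q = (P_up - P_down) / R`; the sign follows the gradient.
#'
#' @param P_up,P_down Upstream and downstream pressures, mmHg.
#' @param R Resistance, mmHg·s/ml; must be positive.
#' @return Flow, ml/s.
#' @export
resistiveFlow <- function(P_up, P_down, R) {
  if (any(R <= 0)) stop("R must be positive")
  (P_up - P_down) / R
}

#' Instantaneous pressures and flows of the closed loop
#'
#' Evaluates the four compartment pressures (left atrium, left ventricle,
#' arteries, veins) and the four flows (mitral, aortic, systemic, venous
#' return) at a given time and state.
#'
#' @param t Time, s (wrapped into the cycle internally).
#' @param state Named numeric vector with `V_la`, `V_lv`, `V_art`, `V_ven`
#'   in ml.
#' @param params A `cardio_params` object.
#' @return Named numeric vector `P_la, P_lv, P_art, P_ven` (mmHg) and
#'   `Q_mi, Q_ao, Q_sys, Q_ven` (ml/s).
#' @export
circulationPressures <- function(t, state, params) {
  e_v <- .activation(t, params$T, params$f_peak, params$f_end)
  e_a <- .atrial_activation(t, params$T, params$f_atrial_onset,
                            params$f_atrial_end)
  E_lv <- params$E_lv_min + (params$E_lv_max - params$E_lv_min) * e_v
  E_la <- params$E_la_min + (params$E_la_max - params$E_la_min) * e_a
  P_la <- E_la * (state[["V_la"]] - params$V0_la)
  P_lv <- E_lv * (state[["V_lv"]] - params$V0_lv)
  P_art <- (state[["V_art"]] - params$V0_art) / params$C_art
  P_ven <- (state[["V_ven"]] - params$V0_ven) / params$C_ven
  c(P_la = P_la, P_lv = P_lv, P_art = P_art, P_ven = P_ven,
    Q_mi = max(P_la - P_lv, 0) / params$R_mi,
    Q_ao = max(P_lv - P_art, 0) / params$R_ao,
    Q_sys = (P_art - P_ven) / params$R_sys,
    Q_ven = (P_ven - P_la) / params$R_ven)
}

#' Right-hand side of the circulation ODE system
#'
#' State derivative of the closed loop: each compartment volume changes by
#' inflow minus outflow, so the four derivatives sum to zero exactly and
#' total blood volume is conserved.  Suitable for [deSolve::ode()].
#'
#' @param t Time, s.
#' @param state Named numeric vector `V_la, V_lv, V_art, V_ven`, ml.
#' @param params A `cardio_params` object.
#' @return A list as required by deSolve: first the derivative vector
#'   (ml/s), then the instantaneous pressures and flows as auxiliary
#'   outputs.
#' @export
circulationRHS <- function(t, state, params) {
  if (any(!is.finite(state))) {
    bad <- names(state)[!is.finite(state)]
    stop("non-finite state component: ", paste(bad, collapse = ", "))
  }
  pq <- circulationPressures(t, state, params)
  d <- c(pq[["Q_ven"]] - pq[["Q_mi"]],
         pq[["Q_mi"]] - pq[["Q_ao"]],
         pq[["Q_ao"]] - pq[["Q_sys"]],
         pq[["Q_sys"]] - pq[["Q_ven"]])
  list(d, pq)
}
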