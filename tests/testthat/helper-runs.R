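# Memoised steady-state runs so expensive simulations happen once per suite.
.run_cache <- new.env(parent = emptyenv())

cached_run <- function(preset, config = simConfig()) {
  key <- preset
  if (is.null(.run_cache[[key]]))
    .run_cache[[key]] <- runToSteadyState(loadPreset(preset), config)
  .run_cache[[key]]
}

cached_metrics <- function(preset) extractMetrics(cached_run(preset))

# synthetic one-cycle series with prescribed P_art / V_lv trajectories,
# carrying just enough structure for extractMetrics / pvLoop
synthetic_series <- function(t, P_art, V_lv, P_lv = P_art, T = max(t)) {
  n <- length(t)
  df <- data.frame(t = t, P_la = 0, P_lv = P_lv, P_art = P_art, P_ven = 0,
                   V_la = 0, V_lv = V_lv, V_art = 0, V_ven = 0,
                   Q_mi = 0, Q_ao = 0, Q_sys = 0, Q_ven = 0, cycle = 1L)
  structure(df, class = c("cycle_series", "data.frame"),
            params = cardioParams(T = T), converged = TRUE, cycles = 1L,
            conservation = 0)
}

table2 <- data.frame(
  preset = c("normal", "htn_stage1", "htn_stage2", "htn_accelerated",
             "hf_mild", "hf_moderate", "hf_severe",
             "haem_I", "haem_II", "haem_III", "haem_IV"),
  SBP = c(120, 140, 160, 180, 120, 110, 100, 120, 100, 80, 60),
  DBP = c(80, 80, 90, 100, 80, 70, 60, 80, 70, 60, 50),
  CO  = c(5, 5, 5, 5, 4.5, 4, 3.5, 5, 4, 3.5, 3),
  HR  = c(60, 60, 60, 60, 60, 70, 80, 100, 120, 140, 160))
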