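test_that("the normal preset reaches a conserved periodic steady state", {
  s <- cached_run("normal")
  expect_true(attr(s, "converged"))
  expect_lt(attr(s, "cycles"), 50)
  expect_lt(attr(s, "conservation"), 1e-6)

  # periodicity: cycle start and end states agree compartment by compartment
  first <- as.numeric(s[1, c("V_la", "V_lv", "V_art", "V_ven")])
  last <- as.numeric(s[nrow(s), c("V_la", "V_lv", "V_art", "V_ven")])
  expect_equal(last, first, tolerance = 1e-3)

  # per-sample volume conservation
  total <- s$V_la + s$V_lv + s$V_art + s$V_ven
  p <- attr(s, "params")
  expect_lt(max(abs(total - p$V_total)) / p$V_total, 1e-5)
})

test_that("a tiny cycle cap on a cold start is flagged, not thrown", {
  s <- runToSteadyState(loadPreset("normal"), simConfig(max_cycles = 2))
  expect_false(attr(s, "converged"))
  expect_equal(attr(s, "cycles"), 2L)
})

test_that("metric extraction matches its definitions on synthetic input", {
  # constant arterial pressure collapses SBP, DBP and MAP to one value
  t <- seq(0, 1, by = 0.01)
  s <- synthetic_series(t, P_art = rep(100, length(t)),
                        V_lv = 60 + 40 * (1 - cos(2 * pi * t)) / 2)
  m <- extractMetrics(s)
  expect_equal(m$SBP, 100)
  expect_equal(m$DBP, 100)
  expect_equal(m$MAP, 100)
  expect_equal(m$EDV, 100)
  expect_equal(m$ESV, 60)
  expect_equal(m$SV, 40)
  expect_equal(m$LVEF, 0.4)
  expect_equal(m$HR, 60)
  expect_equal(m$CO, 40 * 60 / 1000)
})

test_that("heart rate reporting rounds 60/T to the nearest beat", {
  t <- seq(0, 0.375, by = 0.0075)
  s <- synthetic_series(t, P_art = 50 + t, V_lv = 30 + t, T = 0.375)
  m <- extractMetrics(s)
  expect_equal(m$HR, 160)
  t2 <- seq(0, 0.429, length.out = 51)
  s2 <- synthetic_series(t2, P_art = 50 + t2, V_lv = 30 + t2, T = 0.429)
  expect_equal(extractMetrics(s2)$HR, 140)  # 60/0.429 = 139.86
})

test_that("haemodynamic invariants hold on a real converged run", {
  m <- cached_metrics("normal")
  expect_true(m$SBP >= m$MAP && m$MAP >= m$DBP)
  expect_gte(m$EDV, m$ESV)
  expect_equal(m$SV, m$EDV - m$ESV)
  expect_equal(m$CO, m$SV * m$HR_exact / 1000)
  expect_equal(m$LVEF, m$SV / m$EDV)
  expect_true(m$LVEF > 0 && m$LVEF < 1)
})

test_that("the PV loop closes and a synthetic rectangle has the hand area", {
  loop <- pvLoop(cached_run("normal"))
  n <- nrow(loop)
  expect_equal(loop$V_lv[1], loop$V_lv[n])
  expect_equal(loop$P_lv[1], loop$P_lv[n])
  expect_gt(attr(loop, "area"), 0)

  # rectangle V: 60<->130, P: 10<->100, traversed with ejection at high P
  V <- c(60, 130, 130, 60)
  P <- c(10, 10, 100, 100)
  expect_equal(loopArea(V, P), 70 * 90)
})

test_that("metric extraction rejects series not covering exactly one cycle", {
  expect_error(extractMetrics(data.frame(t = 1)), "cycle_series")
  s <- cached_run("normal")
  two <- rbind(as.data.frame(s), transform(as.data.frame(s), t = t + 1))
  attributes(two)$params <- attr(s, "params")
  class(two) <- c("cycle_series", "data.frame")
  attr(two, "params") <- attr(s, "params")
  expect_error(extractMetrics(two), "one cycle")
})

test_that("halving the solver tolerances barely moves the reported metrics", {
  cfg1 <- simConfig()
  cfg2 <- simConfig(solver_rel_tol = cfg1$solver_rel_tol / 2,
                    solver_abs_tol = cfg1$solver_abs_tol / 2)
  m1 <- extractMetrics(runToSteadyState(loadPreset("hf_moderate"), cfg1))
  m2 <- extractMetrics(runToSteadyState(loadPreset("hf_moderate"), cfg2))
  for (q in c("SBP", "DBP", "CO"))
    expect_lt(abs(m1[[q]] - m2[[q]]) / m1[[q]], 0.005)
})

test_that("output grids honour dt_output", {
  s <- runToSteadyState(loadPreset("haem_I"),
                        simConfig(dt_output = 5e-3, ss_rel_tol = 5e-3))
  expect_equal(diff(s$t)[1], 5e-3)
  expect_equal(max(s$t), 0.6)
})
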