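params <- kinetic_preset()
osat <- rig_preset("osat")
tele <- rig_preset("telescoped")

test_that("step-1 limits behave physically", {
  # vanishing residence time: outlet equals feed
  out <- simulate_step1(c(T1 = 150, Q1 = 1e9, C1 = 0.05), params = params)
  expect_lt(out$conc[["c2"]], 1e-9)
  expect_equal(out$conc[["c1"]], 0.05, tolerance = 1e-9)
  # dead catalyst: no conversion
  dead <- catalyst_state(activity = 1e-12)
  out2 <- simulate_step1(c(T1 = 150, Q1 = 0.1, C1 = 0.025), state = dead,
                         params = params)
  expect_lt(out2$conc[["c2"]] / 0.025, 1e-6)
  expect_error(simulate_step1(c(T1 = 100, Q1 = 0, C1 = 0.05)), "Q1")
})

test_that("calibrated step-1 grid maximum is 65% at min flow, max temperature", {
  g <- rig_grid_max("step1", params = params, preset = osat)
  expect_equal(g$max, 0.65, tolerance = 0.005)
  expect_equal(unname(g$argmax[["Q1"]]), 0.1)
  expect_equal(unname(g$argmax[["T1"]]), 150)
  expect_equal(unname(g$argmax[["C1"]]), 0.025)
})

test_that("step-2 degenerate inputs pass through", {
  feed <- stream_composition(c2 = 0.02, water = 0.1, liquid_flow = 0.5)
  # no acylating agent
  out <- simulate_step2(feed, c(T2 = 80, tau2 = 5, equiv3 = 0),
                        params = params)
  expect_equal(out$conc[["c4"]], 0)
  expect_equal(out$conc[["c2"]], 0.02, tolerance = 1e-9)
  # zero residence time
  out0 <- simulate_step2(feed, c(T2 = 80, tau2 = 0, equiv3 = 2),
                         params = params)
  expect_equal(out0$conc[["c2"]], 0.02, tolerance = 1e-12)
  expect_equal(out0$conc[["c3"]], 0.04, tolerance = 1e-12)
})

test_that("integrator matches the analytic second-order solution without side reactions", {
  # pure A + B -> P kinetics: a(t) = a0 (b0 - a0) / (b0 exp((b0-a0) k t) - a0)
  set.seed(7)
  for (i in 1:20) {
    a0 <- runif(1, 0.005, 0.05)
    b0 <- a0 * runif(1, 1.2, 3)
    T2 <- runif(1, 30, 100)
    tau <- runif(1, 0.5, 5)
    p <- kinetic_params(A1 = params$A1, Ea1 = params$Ea1, K_inh = params$K_inh,
                        A2 = params$A2, Ea2 = params$Ea2, k_h = 0, k_da = 0,
                        C_w0 = 0.1)
    k2 <- p$A2 * exp(-p$Ea2 / (8.314462618 * (T2 + 273.15)))
    feed <- stream_composition(c2 = a0, water = 0.1, liquid_flow = 0.5)
    out <- simulate_step2(feed, c(T2 = T2, tau2 = tau, equiv3 = b0 / a0), p)
    a_exact <- a0 * (b0 - a0) / (b0 * exp((b0 - a0) * k2 * tau) - a0)
    expect_lt(abs(out$conc[["c2"]] - a_exact), 1e-6)
  }
})

test_that("ODE path agrees with a 10x-finer fixed-step RK4 reference", {
  set.seed(11)
  for (i in 1:5) {
    y0 <- c(runif(1, 0.01, 0.06), runif(1, 0.02, 0.25), 0, 0, 0.1, 0)
    k2 <- runif(1, 50, 500)
    tau <- runif(1, 1, 8)
    ours <- flowbo:::integrate_step2(y0, k2, params$k_h, params$k_da, tau)
    ref <- rk4_step2(y0, k2, params$k_h, params$k_da, tau, n_steps = 20000)
    expect_equal(unname(ours), unname(ref), tolerance = 1e-5)
  }
})

test_that("phenolic-core mass balance is conserved through both steps", {
  sp <- design_space_preset("telescoped")
  set.seed(3)
  for (i in 1:100) {
    cond <- from_unit(sp, runif(4))
    res <- simulate_telescoped(cond, params = params, preset = tele)
    # step 1 conserves nitrophenol + aminophenol
    core1 <- res$step1$conc[["c1"]] + res$step1$conc[["c2"]]
    expect_equal(core1, tele$stock_conc_1, tolerance = 1e-6)
    # step 2 conserves the phenolic core across all four species, allowing
    # for the flow-weighted dilution at the mixing tee
    w1 <- cond[["Q1"]] / (cond[["Q1"]] + cond[["Q1"]] / cond[["ratio"]])
    core2 <- sum(res$step2$conc[c("c1", "c2", "c4", "c5")])
    expect_equal(core2, core1 * w1, tolerance = 1e-6 * core1)
    expect_true(all(res$step2$conc >= 0))
  }
})

test_that("telescoped limiting-reagent behaviour: huge ratio starves step two", {
  cond <- c(T1 = 150, T2 = 100, Q1 = 0.1, ratio = 1e6)
  res <- simulate_telescoped(cond, params = params, preset = tele)
  expect_lt(res$yield_overall, 0.01)
  expect_gt(res$yield_step1, 0.9)  # step 1 unaffected by the starved coil
})

test_that("yield responds monotonically to the driving variables", {
  # step 1: up in T1 and residence time, down in C1
  base <- c(T1 = 100, Q1 = 0.5, C1 = 0.05)
  y1 <- function(cond) simulate_step1(cond, params = params,
                                      preset = osat)$conc[["c2"]] / cond[["C1"]]
  Ts <- sapply(seq(60, 150, length.out = 10),
               function(v) { b <- base; b[["T1"]] <- v; y1(b) })
  Qs <- sapply(seq(0.1, 1, length.out = 10),
               function(v) { b <- base; b[["Q1"]] <- v; y1(b) })
  Cs <- sapply(seq(0.025, 0.1, length.out = 10),
               function(v) { b <- base; b[["C1"]] <- v; y1(b) })
  expect_true(all(diff(Ts) > 0))
  expect_true(all(diff(Qs) < 0))  # higher flow = shorter residence time
  expect_true(all(diff(Cs) < 0))
  # step 2: up in anhydride equivalents
  feed <- intermediate_mixture(params = params, preset = osat)
  y2 <- sapply(seq(1, 3, length.out = 9), function(eq) {
    out <- simulate_step2(feed, c(T2 = 70, tau2 = 2, equiv3 = eq), params)
    out$conc[["c4"]] / feed$conc[["c2"]]
  })
  expect_true(all(diff(y2) > 0))
})

test_that("measurement layer reproduces truth, faults and the noise law", {
  truth <- list(yield_step1 = 0.6, yield_step2 = 0.4)
  set.seed(1)
  m <- measure(truth, noise_model(sigma_abs = 0, p_fault = 0))
  expect_equal(m$yield_step1, 0.6)
  expect_equal(m$yield_step2, 0.4)
  expect_false(m$blank_flag)
  m2 <- measure(truth, noise_model(sigma_abs = 0, p_fault = 1 - 1e-12))
  expect_true(m2$blank_flag)
  expect_lte(m2$yield_step2, 0.02)
  set.seed(42)
  ys <- replicate(10000,
                  measure(list(yield_step2 = 0.5),
                          noise_model(sigma_abs = 0.01, p_fault = 0))$yield_step2)
  expect_gte(sd(ys), 0.009)
  expect_lte(sd(ys), 0.011)
})

test_that("catalyst deactivation: slow decay stays under 5% over 28 h, shutdown recovers 5%", {
  st <- catalyst_state()
  expect_equal(advance_catalyst(st, 0)$activity, 1)
  aged <- advance_catalyst(st, 28)
  expect_lt(1 - aged$activity, 0.05)
  expect_gt(1 - aged$activity, 0.02)  # decay is real, not negligible
  rec <- advance_catalyst(catalyst_state(activity = 0.90), 0,
                          shutdown = TRUE)
  expect_equal(rec$activity, 0.945)
  dropped <- advance_catalyst(st, 0, failure = TRUE)
  expect_equal(dropped$activity, 0.70)
})

test_that("shipped calibration pins the three corner optima", {
  # corner values equal the calibration targets (full grid checks are run
  # in the acceptance suite)
  c1 <- c(T1 = 150, Q1 = 0.1, C1 = 0.025)
  expect_equal(simulate_step1(c1, params = params,
                              preset = osat)$conc[["c2"]] / 0.025,
               0.65, tolerance = 1e-6)
  im <- intermediate_mixture(params = params, preset = osat)
  out2 <- simulate_step2(im, c(T2 = 100, tau2 = 5, equiv3 = 3), params)
  expect_equal(out2$conc[["c4"]] / im$conc[["c2"]], 0.97, tolerance = 1e-6)
  res <- simulate_telescoped(c(T1 = 150, T2 = 100, Q1 = 0.1, ratio = 2),
                             params = params, preset = tele)
  expect_equal(res$yield_overall, 0.85, tolerance = 1e-3)
  # step-2 on a pure aminophenol reservoir still clears 97%
  pure <- stream_composition(c2 = 0.025, water = 0.1, liquid_flow = 0.5)
  outp <- simulate_step2(pure, c(T2 = 100, tau2 = 5, equiv3 = 3), params)
  expect_gte(outp$conc[["c4"]] / 0.025, 0.97)
  # the double-acylation byproduct stays below 0.5% of the phenolic core
  expect_lt(res$step2$conc[["c5"]] / sum(res$step2$conc[c("c1", "c2", "c4", "c5")]),
            0.005)
})

test_that("unreacted nitrophenol in the reservoir does not change the yield", {
  cond <- c(T2 = 100, tau2 = 5, equiv3 = 3)
  mixed <- stream_composition(c1 = 0.0125, c2 = 0.0125, water = 0.1,
                              liquid_flow = 0.5)
  pure <- stream_composition(c2 = 0.0125, water = 0.1, liquid_flow = 0.5)
  y_mixed <- simulate_step2(mixed, cond, params)$conc[["c4"]] / 0.0125
  y_pure <- simulate_step2(pure, cond, params)$conc[["c4"]] / 0.0125
  expect_equal(y_mixed, y_pure, tolerance = 0.005)
})
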