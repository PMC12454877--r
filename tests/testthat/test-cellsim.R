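test_that("passive RC charging matches the closed form within 0.5%", {
  mod <- passive_model(g_pas = 5e-5)
  A <- pi * 20e-4 * 31.83e-4          # cm^2
  I <- 0.05                            # nA
  tr <- integrate_cell(mod, stimulus(0, 500, I), dt = 0.025, t_stop = 500)
  tau <- 1 / (1e3 * 5e-5)              # cm / g_pas, ms
  dv_inf <- I * 1e-9 / (5e-5 * A) * 1000
  v_pred <- -70 + dv_inf * (1 - exp(-tr$t / tau))
  i_tau <- which.min(abs(tr$t - tau))
  expect_lt(abs(tr$v[i_tau] - v_pred[i_tau]) / dv_inf, 0.005)
  # steady state satisfies the charge balance to 0.1%
  v_end <- tail(tr$v, 1)
  I_balance <- 5e-5 * A * (v_end + 70) * 1e6  # nA
  expect_lt(abs(I_balance - I) / I, 0.001)
})

test_that("rest is a fixed point of the passive system", {
  mod <- passive_model()
  tr <- integrate_cell(mod, NULL, dt = 0.05, t_stop = 300, v_init = -70)
  expect_lt(max(abs(tr$v + 70)), 1e-9)
})

test_that("a multi-compartment passive cable settles to uniform rest", {
  m <- synth_basal_tree(n_stems = 2, total_length = 400, branch_orders = 1,
                        rng_seed = 2)
  p <- trn_default_params() * 0
  p[["g_pas"]] <- 1e-4
  mod <- cell_model(m, p)
  tr <- integrate_cell(mod, NULL, dt = 0.05, t_stop = 200, v_init = -60)
  expect_equal(tail(tr$v, 1), -70, tolerance = 1e-6)
})

test_that("holding-current search honors its contracts", {
  mod <- passive_model(g_pas = 5e-5)
  # rest needs no current
  expect_equal(find_holding_current(mod, -70), 0, tolerance = 1e-3)
  # Ohmic prediction for a passive cell: I = dV * g * A
  A <- pi * 20e-4 * 31.83e-4
  i_pred <- -10 * 5e-5 * A * 1e6  # nA for -10 mV
  i_got <- find_holding_current(mod, -80)
  v_err <- abs((i_got - i_pred) / (5e-5 * A * 1e6))  # back to mV
  expect_lt(v_err, 0.5)
  # unreachable target fails
  expect_error(find_holding_current(mod, -80, bracket = c(0.5, 2)),
               class = "trnlab_search_failure")
})

test_that("stimulus segments are validated", {
  expect_error(stimulus(10, 5, 1), class = "trnlab_invalid_argument")
  expect_error(stimulus(c(0, -5), c(5, 2), c(1, 1)),
               class = "trnlab_invalid_argument")
  expect_error(integrate_cell(passive_model(), NULL, dt = -1),
               class = "trnlab_invalid_argument")
})

test_that("protocol traces carry their analysis metadata", {
  mod <- trn_reference_model("Spp1")
  tr <- run_burst_protocol(mod, -65, post_duration = 500, hold_duration = 300,
                           settle = 100, dt = 0.1,
                           holding = list(hold = -0.05, hyp = -0.4))
  md <- trace_metadata(tr)
  expect_equal(md$protocol, "burst")
  expect_equal(md$steady_v, -65)
  expect_equal(md$step_end - md$step_start, 500)
  expect_equal(max(tr$t), 300 + 500 + 500, tolerance = 1)
  expect_error(run_burst_protocol(mod, -30), class = "trnlab_invalid_argument")
  # the injected current column reflects the step
  during <- tr$i_inj[tr$t > md$step_start + 1 & tr$t < md$step_end - 1]
  expect_true(all(during == -0.4))
})

test_that("spike times converge under dt refinement", {
  mod <- trn_reference_model("Spp1")
  i_hold <- find_holding_current(mod, -60)
  t1 <- run_tonic_protocol(mod, dt = 0.05, pre = 100, post = 50, settle = 200,
                           holding = i_hold, record_every = 1L)
  t2 <- run_tonic_protocol(mod, dt = 0.025, pre = 100, post = 50, settle = 200,
                           holding = i_hold, record_every = 1L)
  s1 <- detect_spikes(t1)
  s2 <- detect_spikes(t2)
  expect_equal(nrow(s1), nrow(s2))
  # early spike times converge; later ones accumulate phase drift
  n <- min(nrow(s1), 3)
  expect_lt(max(abs(s1$time[1:n] - s2$time[1:n])), 0.5)
})

test_that("tonic firing at 0.15 nA sits in the physiological envelope", {
  mod <- trn_reference_model("Spp1")
  i_hold <- find_holding_current(mod, -60)
  f0 <- tonic_frequency(run_tonic_protocol(mod, amplitude = 0, dt = 0.05,
                                           holding = i_hold))
  f15 <- tonic_frequency(run_tonic_protocol(mod, amplitude = 0.15, dt = 0.05,
                                            holding = i_hold))
  f25 <- tonic_frequency(run_tonic_protocol(mod, amplitude = 0.25, dt = 0.05,
                                            holding = i_hold))
  expect_equal(f0, 0)
  expect_gte(f15, 10)
  expect_lte(f15, 60)
  expect_gte(f25, f15)  # IF curve non-decreasing
})
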