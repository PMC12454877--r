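test_that("q10 scaling matches the closed form and is multiplicative", {
  expect_equal(q10_scale(25, 25, 3), 1)
  expect_equal(q10_scale(40, 25, 1), 1)
  expect_equal(q10_scale(34, 25, 3), 3^0.9, tolerance = 1e-9)
  # chain rule across temperatures
  expect_equal(q10_scale(34, 25, 2.5),
               q10_scale(30, 25, 2.5) * q10_scale(34, 30, 2.5),
               tolerance = 1e-12)
  expect_error(q10_scale(30, 25, -1), class = "trnlab_invalid_argument")
})

test_that("calcium Nernst potential matches the closed form", {
  expect_equal(nernst_eca(2, 2, 25), 0)
  expect_equal(nernst_eca(2.4e-4, 2, 25), 115.9765, tolerance = 1e-3)
  # ratio invariance
  expect_equal(nernst_eca(1e-4, 2, 30), nernst_eca(2e-4, 4, 30),
               tolerance = 1e-12)
  expect_error(nernst_eca(0, 2), class = "trnlab_invalid_argument")
})

test_that("the dendritic IT gradient is linear and floored at zero", {
  d <- it_distribution(1e-4, 0.01)
  expect_equal(it_density(d, 0), 1e-4)
  expect_equal(it_density(d, 100), 2e-4)
  expect_equal(it_density(it_distribution(1e-4, 0), c(0, 50, 500)),
               rep(1e-4, 3))
  neg <- it_distribution(1e-4, -0.02)
  expect_equal(it_density(neg, 100), 0)  # floored
  expect_error(it_density(d, -5), class = "trnlab_invalid_argument")
})

test_that("gate steady states stay in [0,1] and time constants positive", {
  mech <- trn_mechanisms()
  v <- seq(-120, 60, by = 0.5)
  for (name in c("hh2_Na", "hh2_K", "IT", "IA")) {
    for (g in gate_specs(name, mech)) {
      ss <- g$steady_state(v)
      expect_true(all(ss >= 0 & ss <= 1), info = name)
      expect_true(all(g$time_constant(v) > 0), info = name)
    }
  }
  ca <- 10^seq(-5, -0.5, by = 0.1)
  for (name in c("IAHP", "ICAN")) {
    g <- gate_specs(name, mech)$m
    expect_true(all(g$steady_state(ca) >= 0 & g$steady_state(ca) <= 1))
    expect_true(all(g$time_constant(ca) > 0))
  }
})

test_that("gate_step relaxes to the fixed point and stays bounded", {
  spec <- gate_specs("IT")$m
  v <- -60
  # equilibrium is a fixed point
  g_eq <- spec$steady_state(v)
  expect_equal(gate_step(g_eq, v, spec, dt = 0.1), g_eq, tolerance = 1e-12)
  # long steps converge to the steady state
  expect_equal(gate_step(0, v, spec, dt = 1e6), spec$steady_state(v),
               tolerance = 1e-9)
  # one full step vs two half steps agree with the exact exponential
  g0 <- 0.2
  dt <- 0.5
  one <- gate_step(g0, v, spec, dt)
  two <- gate_step(gate_step(g0, v, spec, dt / 2), v, spec, dt / 2)
  expect_equal(one, two, tolerance = 1e-12)  # exact for frozen voltage
  # random voltage trajectories keep gates in [0,1]
  set.seed(42)
  for (name in c("hh2_Na", "IT", "IA")) {
    for (spec_i in gate_specs(name)) {
      g <- runif(1)
      for (vv in runif(300, -120, 60)) {
        g <- gate_step(g, vv, spec_i, dt = 0.1, tadj = 2.7)
        expect_true(g >= 0 && g <= 1)
      }
    }
  }
})

test_that("mechanism currents vanish at reversal and scale with gbar", {
  mech <- trn_mechanisms()
  # passive: Ohmic example
  expect_equal(mechanism_current(list(name = "pas", gbar = 1e-5), NULL, -60,
                                 mech = mech), 1e-4)
  # reversal potentials zero the current
  expect_equal(mechanism_current(list(name = "hh2_Na", gbar = 0.1),
                                 c(m = 0.5, h = 0.5), mech$hh2$ena, mech = mech), 0)
  eca <- nernst_eca(1e-3, 2, 25)
  expect_equal(mechanism_current(list(name = "IT", gbar = 1e-3),
                                 c(m = 0.3, h = 0.4), eca, cai = 1e-3,
                                 mech = mech), 0)
  # zero conductance
  expect_equal(mechanism_current(list(name = "ICAN", gbar = 0),
                                 c(m = 0.8), -50, mech = mech), 0)
  # IAHP reverses at ek + configured shift
  e_ahp <- mech$hh2$ek + mech$ahp_rev_shift
  expect_equal(mechanism_current(list(name = "IAHP", gbar = 0.02),
                                 c(m = 0.6), e_ahp, mech = mech), 0)
})

test_that("IT window has one interior maximum that tracks vshift exactly", {
  v <- seq(-110, -40, by = 0.01)
  w0 <- it_window(v, vshift = 0)
  # single interior maximum: open rises then falls
  i_max <- which.max(w0$open)
  expect_gt(i_max, 1)
  expect_lt(i_max, length(v))
  d <- diff(w0$open)
  expect_true(all(d[seq_len(i_max - 1)] > 0))
  expect_true(all(d[i_max:length(d)] < 0))
  # a vshift translates the maximizer by exactly -vshift on the voltage axis
  w4 <- it_window(v, vshift = 4)
  expect_equal(w0$v[which.max(w0$open)] - w4$v[which.max(w4$open)], 4,
               tolerance = 0.02)
})

test_that("isoform split conserves total conductance for any fraction", {
  it <- list(gbar = 2e-3, vshift = 1.5)
  for (f in c(0, 0.25, 0.5, 0.77, 1)) {
    sp <- split_it_isoforms(it, delta_v = 3, fraction_up = f)
    expect_equal(sp$up$gbar + sp$down$gbar, it$gbar, tolerance = 1e-15)
    expect_equal(sp$up$vshift, it$vshift + 3)
    expect_equal(sp$down$vshift, it$vshift - 3)
  }
  sp0 <- split_it_isoforms(it, delta_v = 0, fraction_up = 0.3)
  expect_equal(sp0$up$vshift, sp0$down$vshift)
  expect_error(split_it_isoforms(it, 3, fraction_up = 1.2),
               class = "trnlab_invalid_argument")
})
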