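test_that("Tsodyks-Markram recursion matches its closed form", {
  st <- list(u = 0.4, r = 1, U = 0.4, tau_rec = 300, tau_facil = 0, gmax = 5)
  # first spike after a long rest releases U * gmax
  out <- tm_update(st, 1e9)
  expect_equal(out$release, 0.4 * 5)
  expect_equal(out$state$r, 1)
  # two-spike hand iteration under pure depression
  dt <- 50
  s1 <- tm_update(st, 1e9)
  s2 <- tm_update(s1$state, dt)
  r2 <- 1 - (1 - 1 * (1 - 0.4)) * exp(-dt / 300)
  expect_equal(s2$release, 0.4 * r2 * 5, tolerance = 1e-12)
  expect_lt(s2$release, s1$release)  # depression
  # infinite rest restores (U, 1)
  s3 <- tm_update(s2$state, 1e9)
  expect_equal(s3$state$r, 1, tolerance = 1e-9)
  expect_equal(s3$release, 0.4 * 5, tolerance = 1e-9)
  # facilitation raises u above U
  stf <- list(u = 0.2, r = 1, U = 0.2, tau_rec = 100, tau_facil = 500, gmax = 1)
  f1 <- tm_update(stf, 1e9)
  f2 <- tm_update(f1$state, 20)
  expect_gt(f2$state$u, 0.2)
})

test_that("TM state stays in [0,1] for arbitrary spike trains", {
  set.seed(31)
  for (rep in 1:20) {
    st <- list(u = runif(1), r = runif(1), U = runif(1, 0.05, 0.95),
               tau_rec = runif(1, 50, 800), tau_facil = sample(c(0, 300), 1),
               gmax = 1)
    for (dt in rexp(200, 1 / 50)) {
      st <- tm_update(st, dt)$state
      expect_true(st$u >= 0 && st$u <= 1 && st$r >= 0 && st$r <= 1)
    }
  }
})

test_that("gap junctions are ohmic and conserve charge pairwise", {
  expect_equal(gap_junction_current(-60, -60, 1), 0)
  expect_equal(gap_junction_current(-70, -60, 0), 0)
  expect_equal(gap_junction_current(-70, -60, 1), 10)  # 1 nS * 10 mV = 10 pA
  set.seed(2)
  vi <- runif(50, -90, -40); vj <- runif(50, -90, -40); g <- runif(50, 0, 3)
  expect_equal(gap_junction_current(vi, vj, g) + gap_junction_current(vj, vi, g),
               rep(0, 50))
  expect_error(gap_junction_current(-60, -60, -1),
               class = "trnlab_invalid_argument")
})

test_that("the PETH normalizes counts to per-neuron rates", {
  # one spike per neuron exactly at each event onset
  n <- 20
  onsets <- c(1000, 4000)
  raster <- tibble::tibble(cell = rep(1:n, 2),
                           t = rep(onsets, each = n) + 0.1)
  pm <- peth(raster, onsets, window = 500, bin = 25, n_neurons = n)
  expect_equal(dim(pm), c(2, 20))
  expect_equal(pm[, 1], rep(n / (n * 0.025), 2))  # 40 Hz bin
  expect_true(all(pm[, -1] == 0))
  # empty raster gives zeros; bin must divide window
  empty <- peth(raster[0, ], onsets, 500, 25, n)
  expect_true(all(empty == 0))
  expect_error(peth(raster, onsets, 500, 33, n), class = "trnlab_invalid_argument")
})

test_that("PETH of a homogeneous Poisson raster is flat at its rate", {
  set.seed(77)
  n <- 50; rate <- 20; t_stop <- 20000
  ts <- sort(runif(rpois(1, n * rate * t_stop / 1000), 0, t_stop))
  raster <- tibble::tibble(cell = sample.int(n, length(ts), TRUE), t = ts)
  pm <- peth(raster, c(0, 5000, 10000), window = 4000, bin = 100, n_neurons = n)
  # each bin estimate ~ rate with SE = sqrt(rate / (n * bin_s * n_events))
  se <- sqrt(rate / (n * 0.1 * 3))
  expect_true(all(abs(colMeans(pm) - rate) < 3.5 * se))
})

test_that("mean peak firing averages cycle peaks and handles flat PETHs", {
  # constructed PETH with peaks of 50 Hz between troughs
  row <- rep(c(0, 50, 0, 0), 5)
  pm <- rbind(row, row)
  res <- mean_peak_firing(pm)
  expect_equal(res$mean_peak_firing, 50)
  # two events with different peaks average arithmetically
  pm2 <- rbind(rep(c(0, 30, 0, 0), 5), rep(c(0, 50, 0, 0), 5))
  expect_equal(mean_peak_firing(pm2)$mean_peak_firing, 40)
  # flat rows contribute their mean rate
  flat <- matrix(7, nrow = 1, ncol = 12)
  expect_equal(mean_peak_firing(flat)$mean_peak_firing, 7)
})

test_that("sigmoid turning-point fitting is exact, equivariant, and robust", {
  shape <- list(L = 40, k = 12)
  x <- seq(0.4, 1, by = 0.1)
  y <- shape$L / (1 + exp(-shape$k * (x - 0.8)))
  pts <- tibble::tibble(ct_fraction = x, mean_peak_firing = y)
  expect_equal(fit_ct_sigmoid(pts, shape), 0.8, tolerance = 0.005)
  # translation equivariance
  pts2 <- pts; pts2$ct_fraction <- x + 0.1
  expect_equal(fit_ct_sigmoid(pts2, shape), 0.9, tolerance = 0.005)
  # 5% multiplicative noise: recovery within 0.02 in >= 90% of 100 seeds
  hits <- 0
  for (seed in 1:100) {
    set.seed(seed)
    noisy <- pts
    noisy$mean_peak_firing <- y * (1 + rnorm(length(y), 0, 0.05))
    if (abs(fit_ct_sigmoid(noisy, shape) - 0.8) <= 0.02) hits <- hits + 1
  }
  expect_gte(hits, 90)
  # degenerate input
  flat <- tibble::tibble(ct_fraction = x, mean_peak_firing = 1)
  expect_error(fit_ct_sigmoid(flat, shape), class = "trnlab_fit_failure")
  expect_error(fit_ct_sigmoid(pts[1:3, ], shape),
               class = "trnlab_insufficient_data")
})

test_that("shared-shape joint fits recover per-scan centers", {
  L <- 35; k <- 10
  centers <- c(a = 0.6, b = 0.75, c = 0.9)
  x <- seq(0.3, 1.1, by = 0.1)
  scans <- purrr::map_dfr(names(centers), function(id) {
    tibble::tibble(scan = id, ct_fraction = x,
                   mean_peak_firing = L / (1 + exp(-k * (x - centers[[id]]))))
  })
  fit <- fit_shared_sigmoid(scans)
  expect_equal(fit$L, L, tolerance = 0.05 * L)
  expect_equal(sort(fit$centers$x0), sort(unname(centers)), tolerance = 0.02)
})

test_that("effective IT is the weighted harmonic mean", {
  expect_equal(effective_it(c(1), c(2e-4)), 2e-4)
  expect_equal(effective_it(c(0.5, 0.5), c(1e-4, 3e-4)), 1.5e-4)
  # harmonic <= arithmetic, always
  set.seed(4)
  for (i in 1:50) {
    w <- runif(3); w <- w / sum(w)
    g <- runif(3, 1e-4, 3e-3)
    expect_lte(effective_it(w, g), sum(w * g) + 1e-15)
  }
  expect_error(effective_it(c(0.5, 0.5), c(0, 1e-4)),
               class = "trnlab_invalid_argument")
  expect_error(effective_it(c(0.6, 0.6), c(1e-4, 1e-4)),
               class = "trnlab_invalid_argument")
})

test_that("turning-point versus effective-IT regression is OLS", {
  pts <- tibble::tibble(effective_it = c(1, 2, 3, 4) * 1e-3,
                        turning_point = c(0.9, 0.8, 0.7, 0.6))
  fit <- center_vs_git_fit(pts)
  expect_equal(fit$slope, -100, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_error(center_vs_git_fit(pts[1:2, ]),
               class = "trnlab_insufficient_data")
})

test_that("network wiring and drive are reproducible per seed", {
  cfg <- network_config(n_trn = 4, n_tc = 6,
                        ct = list(n_cycles = 1, up_duration = 300,
                                  down_duration = 300))
  a <- trnlab:::build_network(cfg)
  b <- trnlab:::build_network(cfg)
  expect_identical(a$net, b$net)
  expect_identical(a$trn_types, b$trn_types)
  cfg2 <- cfg; cfg2$seed <- 99
  expect_false(identical(trnlab:::build_network(cfg2)$net$ext_t, a$net$ext_t))
})

test_that("a driveless network stays silent and the sim is deterministic", {
  cfg <- network_config(n_trn = 4, n_tc = 6,
                        trn_composition = c(Ecel1 = 0, Spp1 = 1, Runaway = 0),
                        ct = list(n_cycles = 2, up_duration = 300,
                                  down_duration = 400, fraction_active = 0),
                        seed = 7)
  sim <- simulate_network(cfg, dt = 0.1)
  # no afferent drive, no spikes during down states (or at all)
  expect_equal(nrow(sim$raster), 0)
  cfg$ct$fraction_active <- 1
  s1 <- simulate_network(cfg, dt = 0.1)
  s2 <- simulate_network(cfg, dt = 0.1)
  expect_identical(s1$raster, s2$raster)
  expect_gt(nrow(s1$raster), 0)
})
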