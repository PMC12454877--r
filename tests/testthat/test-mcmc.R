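test_that("Z-score cost is the maximum absolute score", {
  spec <- cost_spec(tibble::tibble(steady_v = c(-65, -65), feature = c("a", "b"),
                                   mean = c(10, 0), sd = c(2, 1)))
  feats <- tibble::tibble(steady_v = -65, a = 10, b = 0)
  expect_equal(zscore_cost(feats, spec)$cost, 0)
  feats$a <- 14  # +2 SD
  expect_equal(zscore_cost(feats, spec)$cost, 2)
  feats$b <- -3  # -3 SD beats it
  expect_equal(zscore_cost(feats, spec)$cost, 3)
  # missing features take the worst-case score
  expect_equal(zscore_cost(tibble::tibble(steady_v = -65, a = 10), spec)$cost, 20)
  expect_error(cost_spec(tibble::tibble(steady_v = 1, feature = "a",
                                        mean = 0, sd = 0)),
               class = "trnlab_invalid_argument")
})

test_that("the sampler is seed-reproducible and respects bounds", {
  space <- parameter_space(c("x", "y"), c(-1, 0), c(1, 2))
  cost <- function(th) sum(th^2)
  a <- mcmc_sample(space, cost, n_steps = 300, n_chains = 2, seed = 5)
  b <- mcmc_sample(space, cost, n_steps = 300, n_chains = 2, seed = 5)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- mcmc_sample(space, cost, n_steps = 300, n_chains = 2, seed = 6)
  expect_false(identical(a$x, c$x))
  expect_true(all(a$x >= -1 & a$x <= 1))
  expect_true(all(a$y >= 0 & a$y <= 2))
})

test_that("a quadratic surrogate posterior concentrates at its optimum", {
  space <- parameter_space(c("x", "y"), c(0, 0), c(1, 1))
  opt <- c(0.63, 0.41)
  cost <- function(th) 50 * sum((th - opt)^2)
  pop <- mcmc_sample(space, cost, n_steps = 10000, n_chains = 1, seed = 2,
                     beta = 2, proposal_sd = 0.08)
  keep <- pop[pop$step > 2000, ]
  expect_equal(mean(keep$x), opt[1], tolerance = 0.02 * 1 / 0.63 * opt[1])
  expect_equal(mean(keep$y), opt[2], tolerance = 0.02 * 1 / 0.41 * opt[2])
  # mode via histogram peak
  hx <- hist(keep$x, breaks = 40, plot = FALSE)
  expect_equal(hx$mids[which.max(hx$counts)], opt[1], tolerance = 0.05)
})

test_that("beta -> 0 recovers a uniform marginal over the bounds", {
  space <- parameter_space("x", 0, 1)
  pop <- mcmc_sample(space, function(th) th[["x"]], n_steps = 50000,
                     n_chains = 1, seed = 9, beta = 0, proposal_sd = 0.1)
  ks <- suppressWarnings(ks.test(pop$x[seq(1, 50000, by = 10)], "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("cost_fn errors mark samples invalid without killing the chain", {
  space <- parameter_space("x", 0, 1)
  cost <- function(th) if (th[["x"]] > 0.5) stop("boom") else th[["x"]]
  pop <- mcmc_sample(space, cost, n_steps = 200, n_chains = 1, seed = 3,
                     init = matrix(0.2, 1, 1))
  expect_equal(nrow(pop), 200)
  expect_true(all(is.finite(pop$cost)))   # rejected proposals keep last state
  expect_true(all(pop$x <= 0.5))
})

test_that("valid_models filters strictly below the threshold", {
  space <- parameter_space("x", 0, 1)
  pop <- mcmc_sample(space, function(th) 4 * th[["x"]], n_steps = 500,
                     n_chains = 1, seed = 4)
  val <- valid_models(pop, threshold = 2)
  expect_true(all(val$cost < 2))
  expect_equal(nrow(valid_models(pop, threshold = Inf)), nrow(pop))
  # costs exactly at the threshold are excluded
  fake <- pop
  fake$cost <- rep(c(1.9, 2.0, 2.1), length.out = nrow(fake))
  expect_true(all(valid_models(fake, 2)$cost == 1.9))
})

test_that("detailed balance holds on a discrete-like toy target", {
  # three wells at x = 0.2, 0.5, 0.8 with known relative weights under
  # exp(-beta*cost); empirical occupancies must match the Gibbs ratios
  space <- parameter_space("x", 0, 1)
  wells <- c(0.2, 0.5, 0.8)
  depth <- c(0, 1, 2)  # cost of each well
  cost <- function(th) {
    k <- which.min(abs(th[["x"]] - wells))
    depth[k]
  }
  beta <- 1.2
  pop <- mcmc_sample(space, cost, n_steps = 200000, n_chains = 1, seed = 8,
                     beta = beta, proposal_sd = 0.25)
  x <- pop$x[pop$step > 5000]
  occ <- table(vapply(x, function(v) which.min(abs(v - wells)), integer(1)))
  occ <- as.numeric(occ) / sum(occ)
  # stationary mass of each well: its basin width times exp(-beta * depth)
  widths <- c(0.35, 0.30, 0.35)
  want <- widths * exp(-beta * depth)
  want <- want / sum(want)
  expect_lt(max(abs(occ - want)), 0.02)  # total-variation-style bound
})

test_that("parameter-feature correlations follow Pearson", {
  space <- parameter_space(c("x", "y"), c(0, 0), c(1, 1))
  pop <- mcmc_sample(space, function(th) 0, n_steps = 1000, n_chains = 1,
                     seed = 12, beta = 0, proposal_sd = 0.2)
  pop$copy_x <- pop$x
  pop$anti_x <- -pop$x
  res <- param_feature_correlations(pop, params = c("x", "y"),
                                    features = c("copy_x", "anti_x"))
  expect_equal(res$r[res$param == "x" & res$feature == "copy_x"], 1)
  expect_equal(res$r[res$param == "x" & res$feature == "anti_x"], -1)
  # independent columns decorrelate
  r_xy <- res$r[res$param == "x" & res$feature == "y"]
  expect_lt(abs(r_xy), 0.2)
  # zero-variance column gives NA
  pop$flat <- 1
  res2 <- param_feature_correlations(pop, params = "x", features = "flat")
  expect_true(is.na(res2$r[res2$feature == "flat"]))
})
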