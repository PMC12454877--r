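test_that("spike detection finds injected waveforms and respects thresholds", {
  tr <- make_burst_trace(burst_trace_spec(n_bursts = 1, spikes_per_burst = 7,
                                          intra_isi = 12))
  sp <- detect_spikes(tr)
  truth <- trace_metadata(tr)$ground_truth$spike_times
  expect_equal(nrow(sp), 7)
  expect_true(all(abs(sp$time - truth) <= 2 * attr(tr, "dt")))
  # flat trace and too-high threshold give empty trains
  flat <- make_burst_trace(burst_trace_spec(n_bursts = 0))
  expect_equal(nrow(detect_spikes(flat)), 0)
  expect_equal(nrow(detect_spikes(tr, threshold = 50)), 0)
  # times strictly increasing
  expect_true(all(diff(sp$time) > 0))
})

test_that("burst segmentation handles the canonical edge cases", {
  mk <- function(isis) {
    tibble::tibble(time = cumsum(c(100, isis)), peak_v = 20)
  }
  # [5,5,300,5,5] -> two bursts of three
  seg <- segment_bursts(mk(c(5, 5, 300, 5, 5)))
  expect_equal(lengths(seg$bursts), c(3, 3))
  # all ISIs below 50 ms -> one burst
  seg2 <- segment_bursts(mk(rep(10, 9)))
  expect_equal(length(seg2$bursts), 1)
  expect_equal(seg2$bursts[[1]], 1:10)
  # regular widely spaced spikes -> not bursting
  seg3 <- segment_bursts(mk(rep(200, 9)))
  expect_equal(length(seg3$bursts), 0)
  # single-spike bursts allowed once bimodality is established
  seg4 <- segment_bursts(mk(c(5, 5, 300, 5, 5, 300, 300)))
  expect_equal(lengths(seg4$bursts), c(3, 3, 1, 1))
})

test_that("segmentation equals the brute-force threshold-enumeration oracle", {
  set.seed(101)
  for (rep in 1:60) {
    n_b <- sample(1:6, 1)
    sizes <- sample(1:5, n_b, replace = TRUE)
    intra <- runif(1, 4, 15)
    inter <- runif(1, 80, 400)
    times <- c()
    t <- 0
    for (b in seq_len(n_b)) {
      times <- c(times, t + cumsum(c(0, rep(intra, sizes[b] - 1))) +
                   runif(sizes[b], 0, 0.5))
      t <- max(times) + inter * runif(1, 0.8, 1.2)
    }
    times <- sort(times)[seq_len(min(30, length(times)))]
    spikes <- tibble::tibble(time = times, peak_v = 20)
    got <- segment_bursts(spikes)
    want <- oracle_segment_bursts(spikes)
    expect_equal(length(got$bursts), want$n_bursts)
    if (want$n_bursts > 0) {
      expect_equal(lengths(got$bursts), unname(want$sizes))
    }
  }
})

test_that("burst number excludes the tonic tail and runaway slope is recovered", {
  tr <- make_burst_trace(burst_trace_spec(n_bursts = 12, ahp_drift_slope = 0))
  expect_equal(burst_number(tr), 12)
  expect_equal(runaway_metric(tr), 0, tolerance = 1e-6)
  expect_equal(post_burst_tonic_count(tr), 0)

  tr2 <- make_burst_trace(burst_trace_spec(n_bursts = 3, tonic_tail_spikes = 5))
  expect_equal(burst_number(tr2), 3)
  expect_equal(post_burst_tonic_count(tr2), 5)  # 4 tonic ISIs + 1

  # prescribed drift is recovered by the least-squares slope
  tr3 <- make_burst_trace(burst_trace_spec(n_bursts = 10, ahp_drift_slope = 0.005,
                                           inter_burst_interval = 150))
  expect_equal(runaway_metric(tr3), 0.005, tolerance = 0.005 * 0.05)
  # two bursts cannot support the drift fit: sentinel
  tr4 <- make_burst_trace(burst_trace_spec(n_bursts = 2))
  expect_equal(runaway_metric(tr4), 2)
  # empty trace
  expect_equal(burst_number(make_burst_trace(burst_trace_spec(n_bursts = 0))), 0)
})

test_that("time reversal leaves the burst count unchanged", {
  for (nb in c(3, 8)) {
    tr <- make_burst_trace(burst_trace_spec(n_bursts = nb, spikes_per_burst = 4))
    rev_tr <- tr
    rev_tr$v <- rev(tr$v)
    attr(rev_tr, "metadata") <- list(protocol = "synthetic", step_end = 0)
    expect_equal(burst_number(rev_tr), burst_number(tr))
  }
})

test_that("feature vector fields follow their definitions", {
  tr <- make_burst_trace(burst_trace_spec(n_bursts = 4, spikes_per_burst = 3,
                                          intra_isi = 10))
  fv <- extract_features(tr)
  truth <- trace_metadata(tr)$ground_truth
  expect_equal(fv$burst_number, 4)
  expect_equal(fv$spikes_per_burst, 3)
  # spikes at 0,10,20 within each burst: (3-1)/20 ms = 100 Hz
  expect_equal(fv$burst_mean_frequency, 100, tolerance = 0.05)
  expect_equal(fv$first_isi, diff(truth$spike_times[1:2]), tolerance = 0.5)
  expect_equal(fv$ap2_ap1_peak_difference, 0, tolerance = 0.5)
  expect_equal(fv$time_to_first_spike, truth$spike_times[1],
               tolerance = 2 * attr(tr, "dt"))
  # reproducibility: identical trace, identical features
  expect_identical(extract_features(tr), fv)
})

test_that("e-type classification applies the thresholds in order", {
  fv <- function(b, run, pbt) {
    tibble::tibble(burst_number = b, runaway_metric = run, post_burst_tonic = pbt)
  }
  expect_equal(classify_etype(fv(3, 2, 0)), "Ecel1")
  expect_equal(classify_etype(fv(20, 0.2, 0)), "Spp1")
  expect_equal(classify_etype(fv(60, 0.01, 0)), "Runaway")
  expect_equal(classify_etype(fv(60, 0.01, 4)), "PostBurstTonic")
  expect_equal(classify_etype(fv(5, 2, 0)), "Spp1")   # threshold inclusive
  expect_equal(classify_etype(fv(4, 2, 0)), "Ecel1")
})
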