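# Synthetic voltage traces, burst curves and labelled cohorts with known
# ground truth. These generators emulate the phenomenology of rebound-burst
# recordings (stereotyped action potentials riding a low-threshold envelope,
# slow-AHP minima drifting linearly between bursts, optional post-burst tonic
# tails) so the whole feature pipeline is testable without any simulation.

#' Specification of a synthetic rebound-burst trace
#'
#' @param n_bursts number of bursts.
#' @param spikes_per_burst spikes in each burst.
#' @param intra_isi within-burst inter-spike interval (ms).
#' @param inter_burst_interval gap between the last spike of a burst and the
#'   first spike of the next (ms).
#' @param ahp_drift_slope linear drift of the slow-AHP minima (mV/ms); 0
#'   produces stable (runaway-like) bursting.
#' @param tonic_tail_spikes number of regular tonic spikes after the bursts.
#' @param tonic_isi inter-spike interval of the tonic tail (ms).
#' @param noise_sd additive Gaussian noise on the subthreshold voltage (mV).
#' @param seed integer seed (only used when `noise_sd > 0`).
#' @param baseline resting voltage (mV).
#' @param spike_peak action-potential peak (mV).
#' @param fast_ahp fast AHP floor between spikes within a burst (mV).
#' @param slow_ahp_start depth of the first usable slow-AHP minimum (mV).
#' @return a `burst_trace_spec` list.
#' @export
burst_trace_spec <- function(n_bursts = 10, spikes_per_burst = 4,
                             intra_isi = 10, inter_burst_interval = 250,
                             ahp_drift_slope = 0, tonic_tail_spikes = 0,
                             tonic_isi = 120, noise_sd = 0, seed = 1,
                             baseline = -70, spike_peak = 20,
                             fast_ahp = -52, slow_ahp_start = -82) {
  if (n_bursts < 0 || spikes_per_burst < 0 || tonic_tail_spikes < 0) {
    stop_invalid("counts must be non-negative")
  }
  if (n_bursts > 0 && spikes_per_burst > 1 && intra_isi >= inter_burst_interval) {
    stop_invalid("intra_isi must be smaller than inter_burst_interval")
  }
  structure(as.list(environment()), class = "burst_trace_spec")
}

# triangular-exponential AP waveform sampled on the trace grid
ap_waveform <- function(tt, t_spike, peak, base_v, floor_v, rise = 0.4,
                        fall = 0.8, recover = 6) {
  w <- numeric(length(tt))
  rel <- tt - t_spike
  up <- rel >= -rise & rel < 0
  w[up] <- base_v[up] + (peak - base_v[up]) * (rel[up] + rise) / rise
  down <- rel >= 0 & rel < fall
  w[down] <- peak + (floor_v - peak) * rel[down] / fall
  rec <- rel >= fall & rel < fall + recover
  w[rec] <- floor_v + (base_v[rec] - floor_v) *
    (1 - exp(-(rel[rec] - fall) / (recover / 4)))
  sel <- up | down | rec
  list(sel = sel, w = w)
}

#' Generate a synthetic rebound-burst trace
#'
#' Builds a stylized trace following a [burst_trace_spec()]: bursts of
#' stereotyped spikes, inter-burst slow-AHP minima on an exact linear drift
#' (the minimum sits at the center of each gap), and an optional tonic tail
#' whose inter-spike minima match the fast AHP depth. The generating truth
#' (spike times, burst count, drift slope, tonic count) is attached as
#' metadata.
#'
#' @param spec a [burst_trace_spec()].
#' @param dt sample interval (ms).
#' @return a `trn_trace` with `ground_truth` in its metadata.
#' @export
make_burst_trace <- function(spec, dt = 0.2) {
  stopifnot(inherits(spec, "burst_trace_spec"))
  # spike times
  spike_times <- list()
  t <- 200
  burst_bounds <- list()
  for (b in seq_len(spec$n_bursts)) {
    st <- t + (seq_len(spec$spikes_per_burst) - 1) * spec$intra_isi
    spike_times[[length(spike_times) + 1]] <- st
    burst_bounds[[b]] <- range(st)
    t <- max(st) + spec$inter_burst_interval
  }
  tonic_times <- numeric(0)
  if (spec$tonic_tail_spikes > 0) {
    start <- if (spec$n_bursts > 0) t else 200
    tonic_times <- start + (seq_len(spec$tonic_tail_spikes) - 1) * spec$tonic_isi
  }
  all_spikes <- c(unlist(spike_times), tonic_times)
  t_end <- if (length(all_spikes) > 0) max(all_spikes) + 500 else 1000
  tt <- seq(0, t_end, by = dt)
  v <- rep(spec$baseline, length(tt))

  # slow-AHP envelope between bursts: minimum at gap center, on the drift line
  if (spec$n_bursts >= 2) {
    gap_mid <- numeric(spec$n_bursts - 1)
    for (k in seq_len(spec$n_bursts - 1)) {
      gap_mid[k] <- (burst_bounds[[k]][2] + burst_bounds[[k + 1]][1]) / 2
    }
    min_v <- spec$slow_ahp_start + spec$ahp_drift_slope * (gap_mid - gap_mid[1])
    if (any(min_v > spec$baseline - 2)) {
      stop_invalid(paste("inconsistent spec: the slow-AHP drift line crosses the",
                         "baseline before the last burst"))
    }
    for (k in seq_len(spec$n_bursts - 1)) {
      t0 <- burst_bounds[[k]][2] + 2
      t1 <- burst_bounds[[k + 1]][1] - 2
      i <- which(tt > t0 & tt < t1)
      if (length(i) == 0) next
      # V-shaped dip with vertex at the gap center
      half <- (t1 - t0) / 2
      frac <- abs(tt[i] - (t0 + half)) / half
      v[i] <- min_v[k] + (spec$baseline - min_v[k]) * frac^2
    }
  }
  # deep dip after the last burst when a tonic tail follows, so the
  # burst-to-tail gap is not classified tonic
  if (spec$n_bursts >= 1 && spec$tonic_tail_spikes > 0) {
    t0 <- burst_bounds[[spec$n_bursts]][2] + 2
    t1 <- tonic_times[1] - 2
    i <- which(tt > t0 & tt < t1)
    if (length(i) > 0) {
      half <- (t1 - t0) / 2
      frac <- abs(tt[i] - (t0 + half)) / half
      deep <- spec$slow_ahp_start
      v[i] <- deep + (spec$baseline - deep) * frac^2
    }
  }
  # tonic inter-spike troughs at (just above) the fast AHP depth
  if (spec$tonic_tail_spikes > 1) {
    for (k in seq_len(spec$tonic_tail_spikes - 1)) {
      t0 <- tonic_times[k] + 2
      t1 <- tonic_times[k + 1] - 2
      i <- which(tt > t0 & tt < t1)
      if (length(i) == 0) next
      half <- (t1 - t0) / 2
      frac <- abs(tt[i] - (t0 + half)) / half
      trough <- spec$fast_ahp + 1
      v[i] <- trough + (spec$baseline - trough) * frac^2
    }
  }
  # overlay spikes
  base_v <- v
  for (ts in all_spikes) {
    wf <- ap_waveform(tt, ts, spec$spike_peak, base_v, spec$fast_ahp)
    v[wf$sel] <- wf$w[wf$sel]
  }
  if (spec$noise_sd > 0) {
    noise <- local_seed(spec$seed, rnorm(length(v), 0, spec$noise_sd))
    sub <- v < -30  # do not perturb spike peaks
    v[sub] <- v[sub] + noise[sub]
  }
  truth <- list(n_bursts = spec$n_bursts,
                spike_times = all_spikes,
                ahp_drift_slope = spec$ahp_drift_slope,
                tonic_tail_spikes = spec$tonic_tail_spikes,
                post_burst_tonic = if (spec$tonic_tail_spikes > 1)
                  spec$tonic_tail_spikes else 0)
  new_trace(tibble::tibble(t = tt, v = v, i_inj = 0), dt = dt,
            metadata = list(protocol = "synthetic", step_end = 0,
                            ground_truth = truth))
}

#' Synthetic burst-curve data
#'
#' Evaluates the skewed-Gaussian burst-curve model on a voltage grid and
#' rounds (optionally Poisson-samples) the counts, attaching the generating
#' parameters as ground truth.
#'
#' @param params skewed-Gaussian parameters, see [skewed_gaussian_params()].
#' @param voltages steady-state voltages (mV).
#' @param noise `"none"` or `"poisson"`.
#' @param seed integer seed for the Poisson noise.
#' @return a `trn_burst_curve` tibble (`steady_v`, `burst_number`,
#'   `runaway`).
#' @export
make_burst_curve_data <- function(params, voltages = seq(-85, -50, length.out = 10),
                                  noise = c("none", "poisson"), seed = 1) {
  noise <- match.arg(noise)
  mu <- eval_burst_curve(params, voltages)
  counts <- switch(noise,
    none = round(mu),
    poisson = local_seed(seed, rpois(length(mu), mu)))
  new_burst_curve(tibble::tibble(steady_v = voltages,
                                 burst_number = as.numeric(counts),
                                 runaway = FALSE),
                  window = NA_real_, ground_truth = params)
}

#' Generate a labelled synthetic cohort
#'
#' Draws per-cell trace specifications from type-specific distributions
#' (low-burst Ecel1-like with a ceasing drift, high-burst Spp1-like with a
#' clear drift, drift-free Runaway-like) and renders the traces.
#'
#' @param n_cells number of cells.
#' @param type_fractions named fractions over `c("Ecel1", "Spp1", "Runaway")`,
#'   summing to 1.
#' @param seed integer seed.
#' @return tibble with `cell`, `label`, and a `trace` list-column.
#' @export
make_cohort <- function(n_cells,
                        type_fractions = c(Ecel1 = 0.4, Spp1 = 0.3, Runaway = 0.3),
                        seed = 1) {
  if (abs(sum(type_fractions) - 1) > 1e-9) {
    stop_invalid("type_fractions must sum to 1")
  }
  if (n_cells == 0) {
    return(tibble::tibble(cell = integer(0), label = character(0),
                          trace = list()))
  }
  specs <- local_seed(seed, {
    labels <- sample(names(type_fractions), n_cells, replace = TRUE,
                     prob = type_fractions)
    lapply(seq_len(n_cells), function(i) {
      lab <- labels[i]
      sd_i <- sample.int(1e6, 1)
      spec <- switch(lab,
        Ecel1 = burst_trace_spec(
          n_bursts = sample(1:4, 1), spikes_per_burst = sample(2:4, 1),
          intra_isi = runif(1, 8, 14), inter_burst_interval = runif(1, 150, 250),
          ahp_drift_slope = runif(1, 0.005, 0.015),
          noise_sd = 0.05, seed = sd_i),
        Spp1 = burst_trace_spec(
          n_bursts = sample(5:6, 1), spikes_per_burst = sample(4:7, 1),
          intra_isi = runif(1, 6, 10), inter_burst_interval = runif(1, 60, 90),
          ahp_drift_slope = runif(1, 0.012, 0.02),
          slow_ahp_start = -88, noise_sd = 0.05, seed = sd_i),
        Runaway = burst_trace_spec(
          n_bursts = sample(15:25, 1), spikes_per_burst = sample(5:8, 1),
          intra_isi = runif(1, 5, 9), inter_burst_interval = runif(1, 100, 140),
          ahp_drift_slope = runif(1, 0, 0.002),
          noise_sd = 0.05, seed = sd_i))
      list(label = lab, spec = spec)
    })
  })
  tibble::tibble(
    cell = seq_len(n_cells),
    label = vapply(specs, function(s) s$label, character(1)),
    trace = lapply(specs, function(s) make_burst_trace(s$spec)))
}
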