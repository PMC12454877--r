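# Electrical feature extraction from voltage traces: spike detection, burst
# segmentation by a bimodal split of the log inter-spike intervals, the
# runaway drift metric, the post-burst tonic count, and e-type classification.

#' Detect action potentials in a voltage trace
#'
#' One event per contiguous supra-threshold excursion, timed at the voltage
#' maximum; events closer than `merge_window` are merged.
#'
#' @param trace a `trn_trace` (or any tibble with `t` and `v`).
#' @param threshold detection threshold (mV), default -20.
#' @param merge_window refractory merge window (ms).
#' @return tibble with `time` (ms) and `peak_v` (mV), strictly increasing.
#' @export
detect_spikes <- function(trace, threshold = -20, merge_window = 1) {
  v <- trace$v
  t <- trace$t
  above <- v >= threshold
  if (!any(above)) {
    return(tibble::new_tibble(list(time = numeric(0), peak_v = numeric(0)),
                              nrow = 0L))
  }
  d <- diff(c(FALSE, above, FALSE))
  starts <- which(d == 1)
  ends <- which(d == -1) - 1L
  peak_i <- vapply(seq_along(starts), function(k) {
    i <- starts[k]:ends[k]
    i[which.max(v[i])]
  }, integer(1))
  times <- t[peak_i]
  peaks <- v[peak_i]
  # merge events closer than merge_window, keeping the higher peak
  keep <- rep(TRUE, length(times))
  if (length(times) > 1) {
    for (k in 2:length(times)) {
      prev <- max(which(keep[1:(k - 1)]))
      if (times[k] - times[prev] < merge_window) {
        if (peaks[k] > peaks[prev]) keep[prev] <- FALSE else keep[k] <- FALSE
      }
    }
  }
  tibble::new_tibble(list(time = times[keep], peak_v = peaks[keep]),
                     nrow = sum(keep))
}

# two-class variance-maximizing split of log-ISIs; returns the threshold (ms)
# or NA when no acceptable bimodal split exists
isi_split_threshold <- function(isis, separation = 3, all_intra_ms = 50) {
  n <- length(isis)
  if (n < 2) return(NA_real_)
  x <- sort(log(isis))
  best <- -Inf; best_k <- NA_integer_
  for (k in 1:(n - 1)) {
    if (x[k + 1] - x[k] < 1e-9) next  # no threshold separates (near-)ties
    lo <- x[1:k]; hi <- x[(k + 1):n]
    w1 <- k / n; w2 <- 1 - w1
    between <- w1 * w2 * (mean(hi) - mean(lo))^2
    if (between > best) { best <- between; best_k <- k }
  }
  if (is.na(best_k)) return(NA_real_)
  lo <- x[1:best_k]; hi <- x[(best_k + 1):n]
  # geometric separation of class means must reach the acceptance factor
  if (exp(mean(hi) - mean(lo)) < separation) return(NA_real_)
  exp((x[best_k] + x[best_k + 1]) / 2)
}

#' Segment a spike train into bursts
#'
#' Inter-spike intervals are split into intra- and inter-burst classes by a
#' two-class variance-maximizing split on the log ISI (a bimodality
#' acceptance requires the class geometric means to differ by at least
#' `separation`-fold). Edge cases follow the burst-number conventions: if
#' every ISI is below `all_intra_ms` the train is a single burst; once
#' bimodality is established single-spike bursts are allowed; if *all*
#' resulting bursts are single spikes the train is not bursting.
#'
#' @param spikes spike table from [detect_spikes()].
#' @param separation geometric separation factor to accept bimodality.
#' @param all_intra_ms the single-burst ISI ceiling (ms).
#' @return list with `bursts` (list of spike index vectors; empty if not
#'   bursting), `threshold` (ms or `NA`), `intra_isis`, `inter_isis`.
#' @export
segment_bursts <- function(spikes, separation = 3, all_intra_ms = 50) {
  ns <- nrow(spikes)
  empty <- list(bursts = list(), threshold = NA_real_,
                intra_isis = numeric(0), inter_isis = numeric(0))
  if (ns == 0) return(empty)
  if (ns == 1) return(empty)  # a lone spike is not a burst
  isis <- diff(spikes$time)
  if (all(isis < all_intra_ms)) {
    return(list(bursts = list(seq_len(ns)), threshold = NA_real_,
                intra_isis = isis, inter_isis = numeric(0)))
  }
  thr <- isi_split_threshold(isis, separation, all_intra_ms)
  if (is.na(thr)) {
    # no bimodal structure and intervals are long: regular (tonic) spiking
    return(empty)
  }
  inter <- which(isis > thr)
  breaks <- c(0L, inter, ns)
  bursts <- lapply(seq_len(length(breaks) - 1L), function(k) {
    (breaks[k] + 1L):breaks[k + 1L]
  })
  if (all(lengths(bursts) == 1L)) return(empty)
  list(bursts = bursts, threshold = thr,
       intra_isis = isis[-inter], inter_isis = isis[inter])
}

# index range of [t0, t1] on the (uniform) trace grid
grid_range <- function(trace, t0, t1) {
  tt <- trace$t
  n <- length(tt)
  dt <- if (n > 1) tt[2] - tt[1] else 1
  i0 <- max(1L, as.integer(ceiling((t0 - tt[1]) / dt)) + 1L)
  i1 <- min(n, as.integer(floor((t1 - tt[1]) / dt)) + 1L)
  if (i0 > i1) return(integer(0))
  i0:i1
}

# minimum voltage between two times, excluding the first `guard` ms
slow_ahp_minima <- function(trace, spikes, bursts, guard = 5) {
  nb <- length(bursts)
  if (nb < 2) {
    return(tibble::new_tibble(list(time = numeric(0), v = numeric(0)),
                              nrow = 0L))
  }
  out_t <- numeric(nb - 1); out_v <- numeric(nb - 1)
  for (k in seq_len(nb - 1)) {
    t0 <- spikes$time[max(bursts[[k]])] + guard
    t1 <- spikes$time[min(bursts[[k + 1]])]
    i <- grid_range(trace, t0, t1)
    if (length(i) == 0) { out_t[k] <- NA; out_v[k] <- NA; next }
    j <- i[which.min(trace$v[i])]
    out_t[k] <- trace$t[j]; out_v[k] <- trace$v[j]
  }
  tibble::new_tibble(list(time = out_t, v = out_v), nrow = nb - 1L)
}

# fast AHP reference: median of within-burst inter-spike minima
fast_ahp_reference <- function(trace, spikes, bursts) {
  mins <- numeric(0)
  for (b in bursts) {
    if (length(b) < 2) next
    for (k in seq_len(length(b) - 1)) {
      i <- grid_range(trace, spikes$time[b[k]], spikes$time[b[k + 1]])
      if (length(i) > 2) mins <- c(mins, min(trace$v[i[-c(1, length(i))]]))
    }
  }
  if (length(mins) == 0) return(NA_real_)
  median(mins)
}

# identify tonic inter-burst ISIs: slow minimum not deeper than the fast AHP
# reference (within tolerance). Returns logical per inter-burst gap.
tonic_gaps <- function(trace, spikes, bursts, tol = 1) {
  nb <- length(bursts)
  if (nb < 2) return(logical(0))
  ref <- fast_ahp_reference(trace, spikes, bursts)
  if (is.na(ref)) return(rep(FALSE, nb - 1))
  minima <- slow_ahp_minima(trace, spikes, bursts, guard = 0)
  !is.na(minima$v) & minima$v > ref - tol
}

#' Post-burst tonic spike count
#'
#' Counts the inter-burst gaps whose slow AHP minimum is *higher* (more
#' depolarized) than the trace's fast AHP reference (the median within-burst
#' inter-spike minimum); returns that count plus one if positive, else zero.
#' In the bursting regime the slow AHP is always deeper than the fast AHP;
#' comparable depths mark the transition to regular post-burst firing.
#'
#' @param trace a `trn_trace`.
#' @param threshold spike threshold (mV).
#' @return non-negative count.
#' @export
post_burst_tonic_count <- function(trace, threshold = -20) {
  trace <- analysis_window(trace)
  spikes <- detect_spikes(trace, threshold)
  seg <- segment_bursts(spikes)
  pbt_core(trace, spikes, seg$bursts)
}

pbt_core <- function(trace, spikes, bursts) {
  gaps <- tonic_gaps(trace, spikes, bursts)
  n <- sum(gaps)
  if (n > 0) n + 1L else 0L
}

# restrict a protocol trace to its analysis window (after the end of the
# hyperpolarizing step, when known); features and burst counts are defined
# on the post-step window
analysis_window <- function(trace) {
  md <- attr(trace, "metadata") %||% list()
  t0 <- md$step_end %||% 0
  if (t0 > 0) trace[trace$t >= t0, ] else trace
}

# bursts after removing the tonic tail; internal core shared by burst_number
counted_bursts <- function(trace, threshold = -20) {
  trace <- analysis_window(trace)
  spikes <- detect_spikes(trace, threshold)
  seg <- segment_bursts(spikes)
  bursts <- seg$bursts
  if (length(bursts) >= 2) {
    gaps <- tonic_gaps(trace, spikes, seg$bursts)
    # spikes flanking tonic gaps are tonic; drop bursts made only of them
    tonic_spk <- logical(nrow(spikes))
    for (k in which(gaps)) {
      tonic_spk[max(bursts[[k]])] <- TRUE
      tonic_spk[bursts[[k + 1]]] <- TRUE
    }
    bursts <- Filter(function(b) !all(tonic_spk[b]), bursts)
  }
  list(spikes = spikes, bursts = bursts, seg = seg)
}

#' Burst number
#'
#' The number of bursts in a trace (see [segment_bursts()]), excluding
#' spikes classified as post-burst tonic for consistency with
#' [post_burst_tonic_count()].
#'
#' @param trace a `trn_trace`.
#' @param threshold spike threshold (mV).
#' @return non-negative count.
#' @export
burst_number <- function(trace, threshold = -20) {
  length(counted_bursts(trace, threshold)$bursts)
}

#' Burst runaway metric
#'
#' The slope (mV/ms) of a least-squares line through the slow-AHP minima
#' between bursts. Minima within 5 ms of the last spike of a burst are
#' discarded; the first and last bursts are discarded; the line runs through
#' the minima from the second to the one before the last. If fewer than
#' `min_minima` usable minima remain (or the slope is not computable) the
#' sentinel value 2 is returned. Slopes below `0.05` mV/ms indicate stable
#' (runaway) bursting.
#'
#' @param trace a `trn_trace`.
#' @param threshold spike threshold (mV).
#' @param min_minima minimum usable minima (default 4).
#' @return slope in mV/ms, or the sentinel 2.
#' @export
runaway_metric <- function(trace, threshold = -20, min_minima = 4) {
  runaway_metric_core(analysis_window(trace), counted_bursts(trace, threshold),
                      min_minima)
}

runaway_metric_core <- function(trace, cb, min_minima = 4) {
  bursts <- cb$bursts
  nb <- length(bursts)
  if (nb < 4) return(2)
  # discard first and last burst; minima between remaining consecutive bursts
  inner <- bursts[2:(nb - 1)]
  minima <- slow_ahp_minima(trace, cb$spikes, inner, guard = 5)
  # (trace already restricted to the analysis window by the caller)
  minima <- minima[stats::complete.cases(minima), ]
  if (nrow(minima) < min_minima) return(2)
  fit <- lm(v ~ time, data = minima)
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope)) return(2)
  slope
}

#' Extract the electrical feature vector of a trace
#'
#' All features used to constrain and classify models, as one tibble row:
#' burst number, mean spikes per burst, burst mean frequency (mean over
#' multi-spike bursts of `(n_spikes - 1) / duration`), mean spike peak
#' voltage, the drop between the first two spike peaks, time to first/last
#' spike (relative to the end of the hyperpolarizing step when the protocol
#' window is known), first ISI, fast AHP depth, mean slow AHP depth between
#' bursts, voltage SD over the post-step window, the runaway metric, and the
#' post-burst tonic count.
#'
#' @param trace a `trn_trace`.
#' @param threshold spike threshold (mV).
#' @return one-row tibble.
#' @export
extract_features <- function(trace, threshold = -20) {
  md <- attr(trace, "metadata") %||% list()
  t0 <- md$step_end %||% 0
  win <- analysis_window(trace)
  cb <- counted_bursts(trace, threshold)
  spikes <- cb$spikes
  bursts <- cb$bursts
  nb <- length(bursts)
  ns <- nrow(spikes)
  multi <- bursts[lengths(bursts) > 1]
  bmf <- if (length(multi) > 0) {
    mean(vapply(multi, function(b) {
      1000 * (length(b) - 1) / (spikes$time[max(b)] - spikes$time[min(b)])
    }, numeric(1)))
  } else NA_real_
  minima <- if (nb >= 2) slow_ahp_minima(win, spikes, bursts) else
    list(time = numeric(0), v = numeric(0))
  out <- list(
    burst_number = nb,
    spikes_per_burst = if (nb > 0) mean(lengths(bursts)) else 0,
    burst_mean_frequency = bmf,
    peak_voltage = if (ns > 0) mean(spikes$peak_v) else NA_real_,
    ap2_ap1_peak_difference = if (ns >= 2) spikes$peak_v[2] - spikes$peak_v[1] else NA_real_,
    time_to_first_spike = if (ns > 0) spikes$time[1] - t0 else NA_real_,
    time_to_last_spike = if (ns > 0) spikes$time[ns] - t0 else NA_real_,
    first_isi = if (ns >= 2) spikes$time[2] - spikes$time[1] else NA_real_,
    ahp_depth = fast_ahp_reference(win, spikes, bursts),
    postburst_minima = if (length(minima$v) > 0) mean(minima$v, na.rm = TRUE) else NA_real_,
    voltage_std = if (nrow(win) > 1) sd(win$v) else NA_real_,
    runaway_metric = runaway_metric_core(win, cb),
    post_burst_tonic = pbt_core(win, cb$spikes, cb$seg$bursts))
  tibble::new_tibble(out, nrow = 1L)
}

#' Classify a feature vector into an electrical type
#'
#' Post-burst tonic firing takes precedence; then a runaway drift metric
#' below `runaway_threshold` (0.05 mV/ms) marks stable runaway bursting; then
#' a burst number of at least `burst_threshold` (5) separates the high-burst
#' (Spp1-like) from the low-burst (Ecel1-like) type.
#'
#' @param fv one-row feature tibble from [extract_features()].
#' @param burst_threshold burst-number cut between Ecel1 and Spp1 (default 5).
#' @param runaway_threshold drift cut in mV/ms (default 0.05).
#' @return one of `"PostBurstTonic"`, `"Runaway"`, `"Spp1"`, `"Ecel1"`.
#' @export
classify_etype <- function(fv, burst_threshold = 5, runaway_threshold = 0.05) {
  if (fv$post_burst_tonic > 0) return("PostBurstTonic")
  if (fv$runaway_metric < runaway_threshold) return("Runaway")
  if (fv$burst_number >= burst_threshold) return("Spp1")
  "Ecel1"
}
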