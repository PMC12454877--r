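# shared fixtures: cheap models and traces built once per test run

# a tiny passive single-compartment model (soma only)
passive_model <- function(g_pas = 5e-5, radius = 10, length = 31.83) {
  p <- trn_default_params() * 0
  p[["g_pas"]] <- g_pas
  cell_model(morphology(soma_cylinder(radius, length), label = "passive"), p)
}

# small deterministic burst trace for feature tests
quick_burst_trace <- function(n_bursts = 5, ...) {
  make_burst_trace(burst_trace_spec(n_bursts = n_bursts, ...))
}

# brute-force oracle for the ISI split: enumerate every threshold between
# consecutive sorted ISIs, pick the between-class-variance maximizer on the
# log scale, apply the same bimodality acceptance and edge rules
oracle_segment_bursts <- function(spikes, separation = 3, all_intra_ms = 50) {
  ns <- nrow(spikes)
  empty <- list(n_bursts = 0L, sizes = integer(0))
  if (ns <= 1) return(empty)
  isis <- diff(spikes$time)
  if (all(isis < all_intra_ms)) return(list(n_bursts = 1L, sizes = ns))
  x <- sort(log(isis))
  n <- length(x)
  best_var <- -Inf; best_thr <- NA_real_
  for (k in seq_len(n - 1)) {
    if (x[k + 1] - x[k] < 1e-9) next  # no threshold separates (near-)ties
    thr <- (x[k] + x[k + 1]) / 2
    lo <- x[1:k]; hi <- x[(k + 1):n]
    w <- k / n
    bv <- w * (1 - w) * (mean(hi) - mean(lo))^2
    if (bv > best_var) { best_var <- bv; best_thr <- thr }
  }
  if (is.na(best_thr)) return(if (all(isis < all_intra_ms))
    list(n_bursts = 1L, sizes = ns) else empty)
  lo <- x[x <= best_thr]; hi <- x[x > best_thr]
  if (exp(mean(hi) - mean(lo)) < separation) return(empty)
  inter <- which(log(isis) > best_thr)
  sizes <- diff(c(0L, inter, ns))
  if (all(sizes == 1L)) return(empty)
  list(n_bursts = length(sizes), sizes = sizes)
}
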