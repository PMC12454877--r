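# MCMC sampling of cell-model populations: Metropolis-Hastings chains
# targeting exp(-beta * cost), where the cost is the maximum |Z| of model
# electrical features against target means and SDs across the three
# burst-protocol steady-state voltages (-80, -65, -55 mV).

#' Parameter space for model sampling
#'
#' @param names parameter identifiers (must match the names understood by
#'   [cell_model()] parameters).
#' @param lower,upper per-parameter bounds (named or positional).
#' @return a `trn_parameter_space`.
#' @export
parameter_space <- function(names, lower, upper) {
  lower <- setNames(as.numeric(lower), names)
  upper <- setNames(as.numeric(upper), names)
  if (any(lower >= upper)) stop_invalid("need lower < upper for every parameter")
  structure(list(names = names, lower = lower, upper = upper),
            class = "trn_parameter_space")
}

#' Default parameter space of the TRN model family
#'
#' Bounds span roughly a factor of ten around the reference conductances;
#' the T-type voltage shift spans 0-8 mV and the dendritic gradient slope
#' 0-6e-3 per um.
#'
#' @return a `trn_parameter_space`.
#' @export
trn_parameter_space <- function() {
  ref <- trn_default_params()
  nm <- names(ref)
  lower <- ref / 3
  upper <- ref * 3
  lower[["vshift_it2"]] <- 0; upper[["vshift_it2"]] <- 8
  lower[["it2_slope"]] <- 0; upper[["it2_slope"]] <- 6e-3
  parameter_space(nm, lower[nm], upper[nm])
}

#' Feature cost specification
#'
#' A table of target means and SDs per (protocol steady-state voltage,
#' feature). These package defaults mimic the spread of the experimental
#' feature distributions used as sampling constraints; they are package
#' fixtures, not measured values.
#'
#' @param table tibble with columns `steady_v`, `feature`, `mean`, `sd`.
#' @return a `trn_cost_spec`.
#' @export
cost_spec <- function(table) {
  stopifnot(all(c("steady_v", "feature", "mean", "sd") %in% names(table)))
  if (any(table$sd <= 0)) stop_invalid("target SDs must be positive")
  structure(tibble::as_tibble(table), class = c("trn_cost_spec",
                                                class(tibble::tibble())))
}

#' Default cost specification of the TRN sampling problem
#'
#' No bursts at -80 mV; broad burst-number targets at -65 and -55 mV (wide
#' SDs deliberately span the Ecel1-to-Runaway continuum); spike shape and
#' timing targets at -65 mV.
#'
#' @return a `trn_cost_spec`.
#' @export
trn_cost_spec <- function() {
  cost_spec(tibble::tribble(
    ~steady_v, ~feature, ~mean, ~sd,
    -80, "burst_number", 0, 0.5,
    -65, "burst_number", 8, 4,
    -65, "spikes_per_burst", 5, 3,
    -65, "peak_voltage", 2, 8,
    -65, "ap2_ap1_peak_difference", -2, 5,
    -65, "postburst_minima", -82, 4,
    -65, "first_isi", 8, 6,
    -65, "time_to_first_spike", 120, 100,
    -55, "burst_number", 6, 4))
}

#' Z-score cost of a feature set
#'
#' `score = |feature - mean| / sd` per target; the scalar cost is the maximum
#' score. Targets whose feature is missing (`NA`) receive the worst-case
#' score `na_score`.
#'
#' @param features tibble with a `steady_v` column and feature columns, one
#'   row per protocol.
#' @param spec a [cost_spec()].
#' @param na_score score assigned to missing features.
#' @return list with `scores` (tibble) and `cost` (scalar max).
#' @export
zscore_cost <- function(features, spec, na_score = 20) {
  scores <- vapply(seq_len(nrow(spec)), function(i) {
    row <- features[features$steady_v == spec$steady_v[i], , drop = FALSE]
    if (nrow(row) == 0 || !(spec$feature[i] %in% names(row))) return(na_score)
    val <- row[[spec$feature[i]]][1]
    if (is.na(val)) return(na_score)
    abs(val - spec$mean[i]) / spec$sd[i]
  }, numeric(1))
  out <- tibble::as_tibble(spec[, c("steady_v", "feature")])
  out$score <- scores
  list(scores = out, cost = max(scores))
}

#' Metropolis-Hastings sampling of a bounded parameter space
#'
#' Samples from a density proportional to `exp(-beta * cost(theta))` with
#' Gaussian proposals reflected at the bounds. Bit-reproducible for a given
#' seed. A `cost_fn` error marks the sample invalid (infinite cost) and the
#' chain continues.
#'
#' @param space a [parameter_space()].
#' @param cost_fn function of a named parameter vector returning either a
#'   scalar cost or a list with elements `cost` and (optionally) `features`
#'   (a one-row tibble collected into the population).
#' @param n_steps steps per chain.
#' @param n_chains independent chains.
#' @param seed integer seed.
#' @param beta inverse-temperature of the target density.
#' @param proposal_sd proposal SD as a fraction of each parameter range.
#' @param init optional matrix (n_chains x n_params) of starting points;
#'   default: uniform draws within bounds.
#' @param progress print a line per chain.
#' @return a `trn_population` tibble: one row per step with `chain`, `step`,
#'   parameters, `cost`, `accepted`, and any feature columns.
#' @export
mcmc_sample <- function(space, cost_fn, n_steps = 1000, n_chains = 2,
                        seed = 1, beta = 2, proposal_sd = 0.05,
                        init = NULL, progress = FALSE) {
  if (n_steps < 1) stop_invalid("n_steps must be >= 1")
  np <- length(space$names)
  lo <- space$lower; hi <- space$upper
  rng <- hi - lo
  step_sd <- proposal_sd * rng

  eval_cost <- function(theta) {
    res <- tryCatch(cost_fn(theta), error = function(e) list(cost = Inf))
    if (!is.list(res)) res <- list(cost = res)
    res$cost <- if (is.finite(res$cost %||% Inf)) res$cost else Inf
    res
  }
  reflect <- function(x) {
    # reflect into [lo, hi]
    for (k in seq_len(np)) {
      while (x[k] < lo[k] || x[k] > hi[k]) {
        if (x[k] < lo[k]) x[k] <- 2 * lo[k] - x[k]
        if (x[k] > hi[k]) x[k] <- 2 * hi[k] - x[k]
      }
    }
    x
  }

  local_seed(seed, {
    chains <- vector("list", n_chains)
    for (ch in seq_len(n_chains)) {
      theta <- if (!is.null(init)) setNames(as.numeric(init[ch, ]), space$names) else
        setNames(lo + runif(np) * rng, space$names)
      cur <- eval_cost(theta)
      rows <- vector("list", n_steps)
      for (s in seq_len(n_steps)) {
        prop <- reflect(theta + rnorm(np, 0, step_sd))
        names(prop) <- space$names
        cand <- eval_cost(prop)
        logr <- -beta * (cand$cost - cur$cost)
        accept <- is.finite(cand$cost) && log(runif(1)) < logr
        if (accept) { theta <- prop; cur <- cand }
        feats <- cur$features
        rows[[s]] <- c(list(chain = ch, step = s),
                       as.list(theta),
                       list(cost = cur$cost, accepted = accept),
                       if (!is.null(feats)) lapply(feats, `[[`, 1))
      }
      chains[[ch]] <- dplyr::bind_rows(rows)
      if (progress) message(sprintf("chain %d/%d done", ch, n_chains))
    }
    pop <- dplyr::bind_rows(chains)
    structure(pop, class = c("trn_population", class(tibble::tibble())),
              space = space, seed = seed, beta = beta)
  })
}

#' Valid models of a sampled population
#'
#' Subset with cost strictly below `threshold` (default 2 SDs), optionally
#' after discarding a burn-in fraction of each chain.
#'
#' @param pop a `trn_population`.
#' @param threshold maximal Z-score cost (default 2).
#' @param burn_in fraction of each chain discarded from the start.
#' @return filtered `trn_population`.
#' @export
valid_models <- function(pop, threshold = 2, burn_in = 0) {
  keep <- pop$cost < threshold
  if (burn_in > 0) {
    nmax <- max(pop$step)
    keep <- keep & pop$step > burn_in * nmax
  }
  out <- pop[keep, ]
  attributes(out)[c("space", "seed", "beta")] <-
    attributes(pop)[c("space", "seed", "beta")]
  out
}

#' Pearson correlations between parameters and features
#'
#' @param pop a `trn_population` (usually after [valid_models()]).
#' @param params,features column names; defaults: the sampled parameter
#'   names and every other numeric column except bookkeeping.
#' @return tibble in long form: `param`, `feature`, `r`. Zero-variance
#'   columns give `NA`.
#' @export
param_feature_correlations <- function(pop, params = NULL, features = NULL) {
  space <- attr(pop, "space")
  params <- params %||% space$names
  drop <- c("chain", "step", "cost", "accepted")
  features <- features %||% setdiff(names(pop)[vapply(pop, is.numeric, logical(1))],
                                    c(params, drop))
  if (nrow(pop) < 3) stop_insufficient("need at least 3 samples for correlations")
  grid <- expand.grid(param = c(params), feature = c(params, features),
                      stringsAsFactors = FALSE)
  grid <- grid[grid$param != grid$feature, ]
  grid$r <- vapply(seq_len(nrow(grid)), function(i) {
    x <- pop[[grid$param[i]]]; y <- pop[[grid$feature[i]]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) return(NA_real_)
    cor(x[ok], y[ok])
  }, numeric(1))
  tibble::as_tibble(grid)
}

#' Burst-protocol cost function for a cell model family
#'
#' Builds the standard cost function used for sampling: simulate the rebound
#' burst protocol at each target steady-state voltage, extract features, and
#' return the maximum |Z| against the cost specification, along with a
#' feature row collected into the population.
#'
#' @param base_model a [cell_model()] whose parameters are overridden by the
#'   sampled vector.
#' @param spec a [cost_spec()].
#' @param dt integration step (ms); the default favors throughput.
#' @param hold_duration,post_duration protocol periods (ms); shorter windows
#'   than the full protocol keep sampling affordable.
#' @param etype_label also classify each sample's -65 mV trace.
#' @param hold_tol holding-current acceptance tolerance (mV).
#' @return function suitable for [mcmc_sample()].
#' @export
burst_cost_fn <- function(base_model, spec = trn_cost_spec(), dt = 0.2,
                          hold_duration = 700, post_duration = 3500,
                          etype_label = TRUE, hold_tol = 1) {
  voltages <- sort(unique(spec$steady_v), decreasing = TRUE)
  # holding currents vary smoothly across proposals: verify the previous
  # current with a single test step first, then bisect in a narrow bracket,
  # then fall back to the full search
  hold_cache <- new.env(parent = emptyenv())
  hold_step <- 600
  cached_hold <- function(m, sys, target_v) {
    key <- sprintf("v%g", target_v)
    prev <- hold_cache[[key]]
    i <- NULL
    if (!is.null(prev)) {
      tr <- integrate_cell(m, stimulus(0, hold_step, prev), dt = dt,
                           t_stop = hold_step, v_init = m$v_init,
                           record_every = 10L, sys = sys)
      vend <- mean(tail(tr$v, max(2L, floor(nrow(tr) * 0.1))))
      if (abs(vend - target_v) <= hold_tol) {
        i <- prev
      } else {
        i <- tryCatch(
          find_holding_current(m, target_v, step_duration = hold_step,
                               dt = dt, tol = hold_tol,
                               bracket = prev + c(-0.25, 0.25), sys = sys),
          trnlab_search_failure = function(e) NULL)
      }
    }
    if (is.null(i)) {
      i <- find_holding_current(m, target_v, step_duration = hold_step,
                                dt = dt, tol = hold_tol, sys = sys)
    }
    hold_cache[[key]] <- i
    i
  }
  function(theta) {
    m <- base_model
    m$params[names(theta)] <- theta
    sys <- build_system(m)
    i_hyp <- cached_hold(m, sys, -100)
    rows <- lapply(voltages, function(sv) {
      tr <- run_burst_protocol(
        m, sv, post_duration = post_duration, hold_duration = hold_duration,
        settle = 300, dt = dt, record_every = 2L,
        holding = list(hold = cached_hold(m, sys, sv), hyp = i_hyp),
        sys = sys)
      fv <- extract_features(tr)
      fv$steady_v <- sv
      fv$etype <- if (etype_label) classify_etype(fv) else NA_character_
      fv
    })
    features <- dplyr::bind_rows(rows)
    z <- zscore_cost(features, spec)
    main <- features[features$steady_v == -65, , drop = FALSE]
    keep <- main[, c("burst_number", "spikes_per_burst", "burst_mean_frequency",
                     "peak_voltage", "first_isi", "time_to_first_spike",
                     "runaway_metric", "post_burst_tonic", "etype")]
    list(cost = z$cost, features = keep)
  }
}
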