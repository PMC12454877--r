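# Reduced thalamoreticular network demonstrator: two-compartment TRN cells
# (three base electrical types differing in dendritic T-type conductance),
# single-compartment TC relay cells, Tsodyks-Markram chemical synapses,
# gap junctions among TRN dendrites, and corticothalamic (CT) up/down drive.
# Spindle readouts: peri-event time histograms, mean peak firing, sigmoid
# turning points versus CT input, and the effective-IT prediction.

#' Tsodyks-Markram synapse state update
#'
#' The standard release recursion applied at a presynaptic spike arriving
#' `dt` ms after the previous one: facilitation
#' `u <- U + u (1 - U) exp(-dt / tau_facil)` (or `u = U` with no
#' facilitation), recovery
#' `r <- 1 - (1 - r (1 - u_prev)) exp(-dt / tau_rec)`, release `u * r * gmax`.
#'
#' @param state list with `u`, `r` and parameters `U`, `tau_rec`,
#'   `tau_facil` (0 disables facilitation), `gmax`.
#' @param dt_since_last_spike time since the previous spike (ms); `Inf` for
#'   the first spike.
#' @return list with `release` (conductance increment) and `state` (updated).
#' @export
tm_update <- function(state, dt_since_last_spike) {
  if (dt_since_last_spike < 0) stop_invalid("dt must be >= 0")
  u_prev <- state$u
  u <- if (state$tau_facil > 0) {
    state$U + u_prev * (1 - state$U) * exp(-dt_since_last_spike / state$tau_facil)
  } else state$U
  r <- 1 - (1 - state$r * (1 - u_prev)) * exp(-dt_since_last_spike / state$tau_rec)
  state$u <- min(1, max(0, u))
  state$r <- min(1, max(0, r))
  list(release = state$u * state$r * state$gmax, state = state)
}

#' Gap-junction current
#'
#' Ohmic electrical coupling: the current into cell i is `g * (v_j - v_i)`;
#' the pair conserves charge exactly.
#'
#' @param v_i,v_j membrane voltages (mV).
#' @param g coupling conductance (nS).
#' @return current into cell i, in pA.
#' @export
gap_junction_current <- function(v_i, v_j, g) {
  if (any(g < 0)) stop_invalid("gap-junction conductance must be >= 0")
  g * (v_j - v_i)
}

#' Base TRN parameter sets for the network
#'
#' Three electrical types share every parameter except the dendritic T-type
#' conductance, which spans the Ecel1-to-Runaway range.
#'
#' @param type `"Ecel1"`, `"Spp1"` or `"Runaway"`.
#' @param gbar_iahp SK conductance override (S/cm^2).
#' @return named parameter vector for [cell_model()].
#' @export
trn_base_params <- function(type = c("Ecel1", "Spp1", "Runaway"),
                            gbar_iahp = NULL) {
  type <- match.arg(type)
  p <- trn_default_params()
  p[["gbar_IT_basal"]] <- switch(type, Ecel1 = 6e-4, Spp1 = 1.1e-3,
                                 Runaway = 2.4e-3)
  if (!is.null(gbar_iahp)) p[["gbar_IAHP"]] <- gbar_iahp
  p
}

#' Network configuration
#'
#' @param n_trn,n_tc cell counts.
#' @param trn_composition named fractions over the three TRN base types,
#'   summing to 1.
#' @param ct list: `n_cycles`, `up_duration` (ms), `down_duration` (ms),
#'   `fraction_active` in `[0,1]`, `rate` (Hz), `n_afferents`,
#'   `per_cell` afferents contacted per cell.
#' @param syn synaptic parameters per pathway (`tc_trn`, `trn_tc`, `ct`):
#'   each a list with `p` (connection probability; `ct` uses `per_cell`),
#'   `gmax` (nS), `e` (mV), `tau` (ms), `U`, `tau_rec`, `tau_facil`,
#'   `delay` (ms).
#' @param gj list with `p` (TRN pair probability) and `g` (nS).
#' @param tc_params named overrides of the TC cell conductances.
#' @param gbar_iahp optional IAHP override applied to every TRN cell.
#' @param temperature simulation temperature (deg C).
#' @param seed integer seed for wiring and drive.
#' @return a `trn_network_config`.
#' @export
network_config <- function(n_trn = 40, n_tc = 80,
                           trn_composition = c(Ecel1 = 1, Spp1 = 0, Runaway = 0),
                           ct = list(), syn = list(), gj = list(),
                           tc_params = NULL,
                           gbar_iahp = NULL, temperature = 34, seed = 1) {
  if (n_trn < 1 || n_tc < 1) stop_invalid("cell counts must be >= 1")
  if (abs(sum(trn_composition) - 1) > 1e-9) {
    stop_invalid("trn_composition must sum to 1")
  }
  ct_def <- list(n_cycles = 16, up_duration = 1000, down_duration = 2000,
                 fraction_active = 1, rate = 30, n_afferents = 60,
                 per_cell = 10)
  syn_def <- list(
    tc_trn = list(p = 0.2, gmax = 18, e = 0, tau = 2, U = 0.5,
                  tau_rec = 300, tau_facil = 0, delay = 1),
    trn_tc = list(p = 0.2, gmax = 30, e = -85, tau = 10, U = 0.4,
                  tau_rec = 400, tau_facil = 0, delay = 1),
    ct = list(gmax = 6, e = 0, tau = 2, U = 0.3, tau_rec = 200,
              tau_facil = 200, delay = 1),
    ct_tc = list(gmax = 0.6, e = 0, tau = 2, U = 0.3, tau_rec = 200,
                 tau_facil = 200, delay = 1))
  gj_def <- list(p = 0.1, g = 0.8)
  structure(list(n_trn = n_trn, n_tc = n_tc,
                 trn_composition = trn_composition,
                 ct = modifyList(ct_def, ct),
                 syn = modifyList(syn_def, syn, keep.null = TRUE),
                 gj = modifyList(gj_def, gj),
                 tc_params = tc_params,
                 gbar_iahp = gbar_iahp,
                 temperature = temperature, seed = seed),
            class = "trn_network_config")
}

# two-compartment TRN geometry shared by the network and the reduced
# single-cell model: soma cylinder + one lumped basal cable
reduced_morphology <- function(dend_area = 14000, dend_length = 500,
                               soma_radius = 10, soma_length = 20,
                               dend_n_comp = 4L) {
  dend_diam <- dend_area / (pi * dend_length)
  morphology(dplyr::bind_rows(
    soma_cylinder(soma_radius, soma_length),
    tibble::tibble(id = 2L, parent_id = 1L, kind = "basal",
                   length = dend_length, diam = dend_diam,
                   n_comp = as.integer(dend_n_comp))),
    label = "reduced")
}

#' Two-compartment reduction of a TRN cell model
#'
#' Soma plus one lumped basal cable preserving the full model's dendritic
#' surface area; the lumped T-type density is the area-weighted mean of the
#' linear gradient over the tree (the gradient's mean density), so
#' `gbar_IT_basal` and `it2_slope` collapse into a single effective density.
#'
#' @param model a [cell_model()] with a detailed morphology.
#' @param dend_length lumped cable length (um); the electrotonic coupling
#'   was fixed once so the reduction tracks the full model's burst number.
#' @param dend_n_comp compartments for the lumped cable.
#' @return a [cell_model()] on the reduced morphology.
#' @export
reduce_two_compartment <- function(model, dend_length = 500, dend_n_comp = 4L) {
  m <- model$morphology
  comp <- discretize(model)
  basal <- comp[comp$kind == "basal", ]
  area <- sum(basal$area) / 1e-8  # cm^2 -> um^2
  g_eff <- if (nrow(basal) > 0) sum(basal$git * basal$area) / sum(basal$area) else 0
  soma <- m[m$kind == "soma", ]
  red <- reduced_morphology(dend_area = area, dend_length = dend_length,
                            soma_radius = soma$diam / 2, soma_length = soma$length,
                            dend_n_comp = dend_n_comp)
  p <- model$params
  p[["gbar_IT_basal"]] <- g_eff
  p[["it2_slope"]] <- 0
  cell_model(red, p, mechanisms = model$mechanisms, cm = model$cm,
             Ra = model$Ra, temperature = model$temperature,
             v_init = model$v_init, it_split = model$it_split,
             label = paste0(model$label, "_reduced"))
}

# TC relay cell: single compartment with rebound-burst machinery
tc_cell_params <- function() {
  c(gbar_Na = 0.09, gbar_K = 0.01, gbar_IT_soma = 4e-4,
    gbar_IT_basal = 0, it2_slope = 0, vshift_it2 = 0,
    gbar_IAHP = 2e-4, gbar_ICAN = 0, gbar_IA = 0, g_pas = 3e-5)
}

tc_morphology <- function() {
  morphology(soma_cylinder(10, 20), label = "tc_soma")
}

# assemble the flattened multi-cell system + wiring; all randomness under the
# config seed via R's RNG
build_network <- function(cfg) {
  types <- names(cfg$trn_composition)
  local_seed(cfg$seed, {
    trn_types <- sample(types, cfg$n_trn, replace = TRUE,
                        prob = cfg$trn_composition)
    ncell <- cfg$n_trn + cfg$n_tc
    # compartments: TRN i -> soma 2i-1, dend 2i (1-based); TC appended
    parent <- c(); area <- c(); gax <- c(); cmv <- c()
    gna <- gk <- git <- git2 <- gahp <- gican <- gia <- gpas <- c()
    vshift <- vshift2 <- c()
    soma_comp <- integer(ncell)
    dend_comp <- integer(ncell)  # TC: soma itself
    mech <- trn_mechanisms()
    for (i in seq_len(cfg$n_trn)) {
      p <- trn_base_params(trn_types[i], gbar_iahp = cfg$gbar_iahp)
      mdl <- cell_model(reduced_morphology(), p, mechanisms = mech,
                        temperature = cfg$temperature)
      comp <- discretize(mdl)
      base <- length(parent)
      parent <- c(parent, ifelse(comp$parent < 0, -1L, comp$parent - 1L + base))
      area <- c(area, comp$area); gax <- c(gax, comp$gax); cmv <- c(cmv, comp$cm)
      gna <- c(gna, comp$gna); gk <- c(gk, comp$gk); git <- c(git, comp$git)
      git2 <- c(git2, comp$git2); gahp <- c(gahp, comp$gahp)
      gican <- c(gican, comp$gican); gia <- c(gia, comp$gia)
      gpas <- c(gpas, comp$gpas)
      vshift <- c(vshift, comp$vshift); vshift2 <- c(vshift2, comp$vshift2)
      soma_comp[i] <- base
      dend_comp[i] <- base + 1L
    }
    tc_p <- tc_cell_params()
    if (!is.null(cfg$tc_params)) tc_p[names(cfg$tc_params)] <- cfg$tc_params
    for (i in seq_len(cfg$n_tc)) {
      mdl <- cell_model(tc_morphology(), tc_p, mechanisms = mech,
                        temperature = cfg$temperature)
      comp <- discretize(mdl)
      base <- length(parent)
      parent <- c(parent, -1L)
      area <- c(area, comp$area); gax <- c(gax, 0); cmv <- c(cmv, comp$cm)
      gna <- c(gna, comp$gna); gk <- c(gk, comp$gk); git <- c(git, comp$git)
      git2 <- c(git2, 0); gahp <- c(gahp, comp$gahp)
      gican <- c(gican, 0); gia <- c(gia, 0); gpas <- c(gpas, comp$gpas)
      vshift <- c(vshift, comp$vshift); vshift2 <- c(vshift2, 0)
      soma_comp[cfg$n_trn + i] <- base
      dend_comp[cfg$n_trn + i] <- base
    }
    sys <- list(parent = as.integer(parent), area = area, gax = gax, cm = cmv,
                gna = gna, gk = gk, git = git, git2 = git2, gahp = gahp,
                gican = gican, gia = gia, gpas = gpas,
                vshift = vshift, vshift2 = vshift2,
                kin = kin_vector(mech, cfg$temperature),
                cell_of = as.integer(rep(seq_len(ncell) - 1L,
                                         times = c(rep(2, cfg$n_trn),
                                                   rep(1, cfg$n_tc)))),
                soma_comp = as.integer(soma_comp))

    # chemical synapses
    syn <- list()
    add_syn <- function(pre, ext, post_comp, pars) {
      syn[[length(syn) + 1L]] <<- tibble::tibble(
        pre = pre, ext = ext, post = post_comp,
        e = pars$e, tau = pars$tau, gmax = pars$gmax * 1e-9,
        U = pars$U, trec = pars$tau_rec, tfac = pars$tau_facil,
        delay = pars$delay)
    }
    for (tc in seq_len(cfg$n_tc)) {
      for (trn in seq_len(cfg$n_trn)) {
        if (runif(1) < cfg$syn$tc_trn$p) {
          add_syn(cfg$n_trn + tc - 1L, -1L, dend_comp[trn], cfg$syn$tc_trn)
        }
        if (runif(1) < cfg$syn$trn_tc$p) {
          add_syn(trn - 1L, -1L, soma_comp[cfg$n_trn + tc], cfg$syn$trn_tc)
        }
      }
    }
    # CT afferents: each cell contacts `per_cell` distinct afferents
    for (c_i in seq_len(ncell)) {
      aff <- sample.int(cfg$ct$n_afferents, cfg$ct$per_cell)
      pars <- if (c_i <= cfg$n_trn) cfg$syn$ct else cfg$syn$ct_tc
      for (a in aff) add_syn(-1L, a - 1L, dend_comp[c_i], pars)
    }
    syn <- if (length(syn) > 0) dplyr::bind_rows(syn) else
      tibble::tibble(pre = integer(0), ext = integer(0), post = integer(0),
                     e = numeric(0), tau = numeric(0), gmax = numeric(0),
                     U = numeric(0), trec = numeric(0), tfac = numeric(0),
                     delay = numeric(0))
    # gap junctions between TRN dendrites
    gj_a <- integer(0); gj_b <- integer(0)
    if (cfg$n_trn >= 2) {
      for (i in seq_len(cfg$n_trn - 1)) {
        for (j in (i + 1):cfg$n_trn) {
          if (runif(1) < cfg$gj$p) {
            gj_a <- c(gj_a, dend_comp[i]); gj_b <- c(gj_b, dend_comp[j])
          }
        }
      }
    }
    # CT drive: Poisson trains for the active afferents of each up state
    onsets <- cfg$ct$down_duration +
      (seq_len(cfg$ct$n_cycles) - 1) * (cfg$ct$up_duration + cfg$ct$down_duration)
    ev_id <- integer(0); ev_t <- numeric(0)
    for (k in seq_len(cfg$ct$n_cycles)) {
      active <- which(runif(cfg$ct$n_afferents) < cfg$ct$fraction_active)
      for (a in active) {
        n_sp <- rpois(1, cfg$ct$rate * cfg$ct$up_duration / 1000)
        if (n_sp == 0) next
        tt <- sort(runif(n_sp, onsets[k], onsets[k] + cfg$ct$up_duration))
        ev_id <- c(ev_id, rep(a - 1L, n_sp)); ev_t <- c(ev_t, tt)
      }
    }
    ord <- order(ev_t)
    net <- list(syn_pre = as.integer(syn$pre),
                syn_ext = as.integer(syn$ext), syn_post = as.integer(syn$post),
                syn_e = syn$e, syn_tau = syn$tau, syn_gmax = syn$gmax,
                syn_U = syn$U, syn_trec = syn$trec, syn_tfac = syn$tfac,
                syn_delay = syn$delay,
                gj_a = as.integer(gj_a), gj_b = as.integer(gj_b),
                gj_g = rep(cfg$gj$g * 1e-9, length(gj_a)),
                ext_id = as.integer(ev_id[ord]), ext_t = ev_t[ord])
    list(sys = sys, net = net, trn_types = trn_types, onsets = onsets,
         soma_comp = soma_comp, dend_comp = dend_comp)
  })
}

#' Simulate the reduced thalamoreticular network
#'
#' Integrates every cell under the corticothalamic up/down drive of the
#' configuration and returns the spike raster, up-state onsets, and sample
#' voltage traces. Fully reproducible for a given config seed.
#'
#' @param cfg a [network_config()].
#' @param t_stop simulation end (ms); default covers all CT cycles plus one
#'   trailing down state.
#' @param dt integration step (ms).
#' @param n_sample_voltages somatic voltages to record per population.
#' @return a `trn_network_sim` list: `raster` (tibble `cell`, `t`, `pop`,
#'   `etype`), `onsets`, `voltages`, `config`.
#' @export
simulate_network <- function(cfg, t_stop = NULL, dt = 0.05,
                             n_sample_voltages = 3) {
  bn <- build_network(cfg)
  t_stop <- t_stop %||%
    (cfg$ct$down_duration +
       cfg$ct$n_cycles * (cfg$ct$up_duration + cfg$ct$down_duration))
  rec <- c(bn$soma_comp[seq_len(min(n_sample_voltages, cfg$n_trn))],
           bn$soma_comp[cfg$n_trn + seq_len(min(n_sample_voltages, cfg$n_tc))])
  res <- cpp_simulate_network(bn$sys, bn$net, dt, t_stop,
                              trn_mechanisms()$pas$e_pas,
                              as.integer(rec), as.integer(max(1, 0.5 / dt)))
  if (res$fail_step >= 0) {
    stop_numerical(sprintf("network integration failed at step %d", res$fail_step))
  }
  cells <- res$raster_cell + 1L
  pop <- ifelse(cells <= cfg$n_trn, "TRN", "TC")
  etype <- ifelse(cells <= cfg$n_trn, bn$trn_types[pmin(cells, cfg$n_trn)],
                  NA_character_)
  vdf <- tibble::as_tibble(as.data.frame(res$v))
  names(vdf) <- c(paste0("trn_", seq_len(min(n_sample_voltages, cfg$n_trn))),
                  paste0("tc_", seq_len(min(n_sample_voltages, cfg$n_tc))))
  vdf$t <- res$t
  structure(list(raster = tibble::tibble(cell = cells, t = res$raster_t,
                                         pop = pop, etype = etype),
                 onsets = bn$onsets, voltages = vdf, config = cfg,
                 trn_types = bn$trn_types),
            class = "trn_network_sim")
}

#' @export
print.trn_network_sim <- function(x, ...) {
  cat(sprintf("<trn_network_sim: %d TRN + %d TC, %d cycles, %d spikes>\n",
              x$config$n_trn, x$config$n_tc, x$config$ct$n_cycles,
              nrow(x$raster)))
  invisible(x)
}

#' Peri-event time histogram
#'
#' Spike rate per bin per event, normalized per neuron.
#'
#' @param raster tibble with `cell` and `t` (spike times, ms).
#' @param event_onsets event times (ms).
#' @param window histogram length after each onset (ms).
#' @param bin bin width (ms); must divide `window`.
#' @param n_neurons number of neurons contributing to `raster`.
#' @return matrix (events x bins) of rates in Hz per neuron; bin centers in
#'   `attr(, "bin_centers")`.
#' @export
peth <- function(raster, event_onsets, window, bin, n_neurons) {
  nb <- window / bin
  if (abs(nb - round(nb)) > 1e-9) stop_invalid("bin must divide window")
  nb <- as.integer(round(nb))
  out <- matrix(0, nrow = length(event_onsets), ncol = nb)
  for (e in seq_along(event_onsets)) {
    rel <- raster$t - event_onsets[e]
    rel <- rel[rel >= 0 & rel < window]
    if (length(rel) > 0) {
      idx <- pmin(nb, floor(rel / bin) + 1L)
      tab <- tabulate(idx, nbins = nb)
      out[e, ] <- tab / n_neurons / (bin / 1000)
    }
  }
  attr(out, "bin_centers") <- (seq_len(nb) - 0.5) * bin
  out
}

# local maxima of one PETH row with a minimum separation (in bins)
peth_row_peaks <- function(row, min_sep = 2, min_height_frac = 0.25) {
  n <- length(row)
  if (n < 3 || max(row) <= 0) return(numeric(0))
  cand <- which(vapply(seq_len(n), function(i) {
    lo <- max(1, i - min_sep); hi <- min(n, i + min_sep)
    row[i] == max(row[lo:hi]) && row[i] > 0
  }, logical(1)))
  cand <- cand[row[cand] >= min_height_frac * max(row)]
  if (length(cand) == 0) return(numeric(0))
  # collapse plateaus
  keep <- c(TRUE, diff(cand) > min_sep)
  row[cand[keep]]
}

#' Mean peak firing of spindle events
#'
#' For each event (CT cycle), detect the oscillation-cycle peaks of its PETH
#' row and average their heights; then average over events. A flat PETH has
#' no cycle structure and contributes its mean rate.
#'
#' @param peth_matrix events x bins rate matrix from [peth()].
#' @param min_sep_bins minimum separation between peaks (bins).
#' @return list with `mean_peak_firing` (Hz) and `per_event` (Hz vector).
#' @export
mean_peak_firing <- function(peth_matrix, min_sep_bins = 2) {
  per_event <- apply(peth_matrix, 1, function(row) {
    pk <- peth_row_peaks(row, min_sep = min_sep_bins)
    if (length(pk) == 0) mean(row) else mean(pk)
  })
  list(mean_peak_firing = mean(per_event), per_event = per_event)
}

#' Spindle metrics of a network simulation
#'
#' TRN-population PETH over the CT cycles and the mean peak firing.
#'
#' @param sim a `trn_network_sim`.
#' @param bin PETH bin (ms).
#' @param window window after each up-state onset (ms); default the up-state
#'   duration.
#' @param skip initial portion of each up state excluded from the peak
#'   analysis (ms); removes the stereotyped CT-onset volley so the metric
#'   reflects the oscillation cycles.
#' @return list with `peth`, `mean_peak_firing`, `per_event`.
#' @export
spindle_metrics <- function(sim, bin = 25, window = NULL, skip = 150) {
  cfg <- sim$config
  window <- window %||% (cfg$ct$up_duration - skip)
  window <- floor(window / bin) * bin
  trn <- sim$raster[sim$raster$pop == "TRN", ]
  pm <- peth(trn, sim$onsets + skip, window, bin, cfg$n_trn)
  mpf <- mean_peak_firing(pm)
  list(peth = pm, mean_peak_firing = mpf$mean_peak_firing,
       per_event = mpf$per_event)
}

#' Fit a shared-shape sigmoid's turning point
#'
#' Least-squares fit of `L / (1 + exp(-k (x - x0)))` with `L` and `k` fixed
#' by `shared_shape`; only the turning point `x0` is free.
#'
#' @param points tibble with `ct_fraction` and `mean_peak_firing` (>= 4
#'   points).
#' @param shared_shape list with `L` (plateau, Hz) and `k` (steepness).
#' @return fitted turning point (CT fraction units).
#' @export
fit_ct_sigmoid <- function(points, shared_shape) {
  if (nrow(points) < 4) stop_insufficient("need at least 4 points")
  y <- points$mean_peak_firing
  x <- points$ct_fraction
  if (max(y) - min(y) < 1e-12) abort("degenerate sigmoid data (all-equal y)",
                                     class = "trnlab_fit_failure")
  L <- shared_shape$L; k <- shared_shape$k
  obj <- function(x0) sum((L / (1 + exp(-k * (x - x0))) - y)^2)
  opt <- optimize(obj, interval = c(min(x) - 1, max(x) + 1), tol = 1e-8)
  opt$minimum
}

#' Joint sigmoid shape over several CT scans
#'
#' Fits one shared plateau `L` and steepness `k` plus a per-scan turning
#' point to several (CT fraction, mean peak firing) scans; the shared shape
#' is then frozen for [fit_ct_sigmoid()].
#'
#' @param scans tibble with `scan` (id), `ct_fraction`, `mean_peak_firing`.
#' @return list with `L`, `k`, and `centers` (tibble `scan`, `x0`).
#' @export
fit_shared_sigmoid <- function(scans) {
  ids <- unique(scans$scan)
  obj <- function(par) {
    L <- par[1]; k <- par[2]
    x0 <- par[-(1:2)]
    s <- 0
    for (i in seq_along(ids)) {
      d <- scans[scans$scan == ids[i], ]
      s <- s + sum((L / (1 + exp(-k * (d$ct_fraction - x0[i]))) -
                      d$mean_peak_firing)^2)
    }
    s
  }
  L0 <- max(scans$mean_peak_firing)
  x00 <- vapply(ids, function(id) {
    d <- scans[scans$scan == id, ]
    d$ct_fraction[which.min(abs(d$mean_peak_firing - L0 / 2))]
  }, numeric(1))
  opt <- optim(c(L0, 10, x00), obj, method = "L-BFGS-B",
               lower = c(1e-3, 0.5, rep(-2, length(ids))),
               upper = c(500, 100, rep(3, length(ids))),
               control = list(maxit = 1000))
  list(L = unname(opt$par[1]), k = unname(opt$par[2]),
       centers = tibble::tibble(scan = ids,
                                x0 = unname(opt$par[-(1:2)])))
}

#' Effective T-type conductance of a mixed circuit
#'
#' The weighted harmonic mean of the per-type dendritic IT conductance
#' densities: `(sum_i w_i / g_i)^-1`.
#'
#' @param fractions per-type weights summing to 1.
#' @param g_it_basal per-type conductances (S/cm^2, > 0).
#' @return effective conductance (S/cm^2).
#' @export
effective_it <- function(fractions, g_it_basal) {
  if (abs(sum(fractions) - 1) > 1e-9) stop_invalid("weights must sum to 1")
  if (any(g_it_basal <= 0 & fractions > 0)) {
    stop_invalid("zero conductance with nonzero weight")
  }
  use <- fractions > 0
  1 / sum(fractions[use] / g_it_basal[use])
}

#' Linear fit of sigmoid turning points against effective IT
#'
#' Ordinary least squares of the CT turning point on the effective circuit
#' IT conductance; used to predict mixed-circuit turning points.
#'
#' @param points tibble with `effective_it` and `turning_point` (>= 3 rows).
#' @return list with `slope`, `intercept`, `r_squared`, `fit` (the `lm`).
#' @export
center_vs_git_fit <- function(points) {
  if (nrow(points) < 3) stop_insufficient("need at least 3 points")
  fit <- lm(turning_point ~ effective_it, data = points)
  # collinear-degenerate (exact-fit) inputs are legitimate here
  ss <- suppressWarnings(summary(fit))
  r2 <- if (is.nan(ss$r.squared)) 1 else ss$r.squared
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = r2, fit = fit)
}

#' Corticothalamic input study: sigmoids, turning points, effective IT
#'
#' Runs the reduced network over a grid of CT activation fractions for each
#' circuit composition, computes spindle mean peak firing, fits one shared
#' sigmoid shape over the uniform circuits, extracts per-circuit turning
#' points, and regresses them on the effective (harmonic-mean) dendritic IT
#' conductance.
#'
#' @param compositions named list of composition vectors over
#'   `c(Ecel1, Spp1, Runaway)`.
#' @param ct_fractions CT activation grid.
#' @param n_trn,n_tc cell counts.
#' @param n_cycles CT cycles per simulation.
#' @param seed base seed (one simulation per composition x fraction).
#' @param dt integration step (ms).
#' @param uniform names of `compositions` treated as uniform circuits for
#'   the shared-shape fit; defaults to single-type compositions.
#' @return list: `scans` (tibble of mean peak firing), `shape` (shared L, k),
#'   `centers` (turning point + effective IT per composition), `fit`
#'   (linear turning-point vs effective-IT model).
#' @export
ct_sigmoid_study <- function(compositions, ct_fractions = seq(0.4, 1, by = 0.15),
                             n_trn = 20, n_tc = 40, n_cycles = 4, seed = 1,
                             dt = 0.05, uniform = NULL) {
  g_by_type <- c(Ecel1 = trn_base_params("Ecel1")[["gbar_IT_basal"]],
                 Spp1 = trn_base_params("Spp1")[["gbar_IT_basal"]],
                 Runaway = trn_base_params("Runaway")[["gbar_IT_basal"]])
  scans <- purrr::map_dfr(names(compositions), function(nm) {
    comp <- compositions[[nm]]
    purrr::map_dfr(ct_fractions, function(f) {
      cfg <- network_config(n_trn = n_trn, n_tc = n_tc,
                            trn_composition = comp,
                            ct = list(n_cycles = n_cycles, fraction_active = f),
                            seed = seed)
      sm <- spindle_metrics(simulate_network(cfg, dt = dt))
      tibble::tibble(scan = nm, ct_fraction = f,
                     mean_peak_firing = sm$mean_peak_firing)
    })
  })
  uniform <- uniform %||%
    names(compositions)[vapply(compositions, function(x) any(x == 1), logical(1))]
  shape_fit <- fit_shared_sigmoid(scans[scans$scan %in% uniform, ])
  shape <- list(L = shape_fit$L, k = shape_fit$k)
  centers <- purrr::map_dfr(names(compositions), function(nm) {
    pts <- scans[scans$scan == nm, ]
    x0 <- fit_ct_sigmoid(pts, shape)
    comp <- compositions[[nm]]
    tibble::tibble(scan = nm, turning_point = x0,
                   effective_it = effective_it(comp, g_by_type[names(comp)]),
                   uniform = nm %in% uniform)
  })
  fit <- center_vs_git_fit(centers[centers$uniform, ])
  list(scans = scans, shape = shape, centers = centers, fit = fit)
}

#' @export
autoplot.trn_network_sim <- function(object, ...) {
  ggplot2::ggplot(object$raster,
                  ggplot2::aes(x = .data$t, y = .data$cell, color = .data$pop)) +
    ggplot2::geom_point(size = 0.3) +
    ggplot2::geom_vline(xintercept = object$onsets, linetype = 3,
                        color = "grey60") +
    ggplot2::labs(x = "time (ms)", y = "cell", color = NULL)
}
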