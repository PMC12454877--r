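# Shipped reference models: a synthetic average-like morphology (soma
# cylinder matched to a typical TRN soma area plus a branched basal tree)
# and the three electrical-type parameterizations used throughout the
# examples and scans.

#' Reference TRN morphology
#'
#' Synthetic soma + basal tree standing in for an average reconstruction:
#' four stems, two bifurcation levels, tapering diameters.
#'
#' @param total_length total basal length (um).
#' @param rng_seed seed of the deterministic generator.
#' @return a `trn_morphology`.
#' @export
trn_reference_morphology <- function(total_length = 2400, rng_seed = 42) {
  synth_basal_tree(n_stems = 4, total_length = total_length,
                   taper_profile = function(d) 2.2 * exp(-d / 300) + 0.5,
                   branch_orders = 2, rng_seed = rng_seed,
                   soma_radius = 10, soma_length = 20,
                   label = "trn_reference")
}

#' Reference TRN cell models
#'
#' The three shipped electrical types on the reference morphology. They share
#' all parameters except the dendritic T-type conductance (see
#' [trn_base_params()]), the knob that spans the Ecel1-to-Runaway burst
#' range.
#'
#' @param type `"Ecel1"`, `"Spp1"` or `"Runaway"`.
#' @param temperature simulation temperature (deg C).
#' @param reduced return the two-compartment reduction instead of the full
#'   tree (default TRUE: the reduction tracks the full model's burst
#'   behavior at a fraction of the cost).
#' @return a [cell_model()].
#' @export
trn_reference_model <- function(type = c("Spp1", "Ecel1", "Runaway"),
                                temperature = 25, reduced = TRUE) {
  type <- match.arg(type)
  full <- cell_model(trn_reference_morphology(), trn_base_params(type),
                     temperature = temperature, label = paste0("ref_", type))
  if (reduced) reduce_two_compartment(full) else full
}

#' Spike frequency of a tonic protocol trace
#'
#' Mean firing rate during the depolarizing step window.
#'
#' @param trace a `trn_trace` from [run_tonic_protocol()].
#' @return rate in Hz.
#' @export
tonic_frequency <- function(trace) {
  md <- attr(trace, "metadata")
  sp <- detect_spikes(trace)
  n <- sum(sp$time >= md$step_start & sp$time <= md$step_end)
  1000 * n / (md$step_end - md$step_start)
}

#' Current-frequency curve of the tonic protocol
#'
#' @param model a [cell_model()].
#' @param amplitudes step amplitudes (nA).
#' @param ... passed to [run_tonic_protocol()].
#' @return tibble with `amplitude` and `frequency` (Hz).
#' @export
if_curve <- function(model, amplitudes = seq(0, 0.3, by = 0.05), ...) {
  i_hold <- find_holding_current(model, -60)
  purrr::map_dfr(amplitudes, function(a) {
    tr <- run_tonic_protocol(model, amplitude = a, holding = i_hold, ...)
    tibble::tibble(amplitude = a, frequency = tonic_frequency(tr))
  })
}

#' @export
autoplot.trn_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = .data$v)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (ms)", y = "membrane voltage (mV)")
}
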