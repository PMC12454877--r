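# Burst curves: rebound burst number as a function of the pre-hyperpolarization
# steady-state voltage, and their skewed-Gaussian parametrization
#   f(v) = a * exp(-(v - c)^2 / w) * (1 + erf(s * (v - c))) + d
# fitted by bounded least squares with a deterministic multi-start grid.

new_burst_curve <- function(df, window = NA_real_, ground_truth = NULL) {
  structure(df, class = c("trn_burst_curve", class(tibble::tibble())),
            window = window, ground_truth = ground_truth)
}

#' Skewed-Gaussian burst-curve parameters
#'
#' @param a amplitude (bursts), in `[0, 100]`.
#' @param w width-like parameter (mV^2 scale, plays the role of `2 sigma^2`),
#'   in `[20, 180]`.
#' @param c center (mV), in `[-100, -40]`.
#' @param s skewness (dimensionless), in `[-2, 2]`.
#' @param d baseline shift (bursts), in `[0, 1]`.
#' @return named list of class `skewed_gaussian_params`.
#' @export
skewed_gaussian_params <- function(a, w, c, s, d = 0) {
  structure(list(a = a, w = w, c = c, s = s, d = d),
            class = "skewed_gaussian_params")
}

curve_bounds <- function() {
  list(lower = c(a = 0, w = 20, c = -100, s = -2, d = 0),
       upper = c(a = 100, w = 180, c = -40, s = 2, d = 1))
}

#' Evaluate the skewed-Gaussian burst-curve model
#'
#' @param params a [skewed_gaussian_params()].
#' @param v steady-state voltage(s), mV.
#' @return expected burst number(s).
#' @export
eval_burst_curve <- function(params, v) {
  params$a * exp(-(v - params$c)^2 / params$w) *
    (1 + erf(params$s * (v - params$c))) + params$d
}

#' Fit the skewed-Gaussian model to a burst curve
#'
#' Bounded nonlinear least squares (`a` in `[0,100]`, `w` in `[20,180]`, `c`
#' in `[-100,-40]`, `s` in `[-2,2]`, `d` in `[0,1]`) with a fixed 3x3x3
#' multi-start grid over `(c, w, s)`; deterministic given the data.
#'
#' @param curve a burst-curve tibble with `steady_v` and `burst_number`
#'   (at least 5 points).
#' @return object of class `trn_curve_fit` with elements `params`,
#'   `residual_norm`, `fitted`, `data`, `convergence`.
#' @export
fit_burst_curve <- function(curve) {
  if (nrow(curve) < 5) stop_insufficient("need at least 5 points to fit a burst curve")
  v <- curve$steady_v
  y <- curve$burst_number
  b <- curve_bounds()
  rss <- function(p) {
    pred <- skewed_gaussian_params(p[1], p[2], p[3], p[4], p[5])
    sum((eval_burst_curve(pred, v) - y)^2)
  }
  a0 <- min(max(max(y) - min(y), 1e-3), 100)
  d0 <- min(max(min(y), 0), 1)
  starts <- expand.grid(c = c(-80, -65, -50), w = c(30, 90, 160),
                        s = c(-1, 0, 1))
  # include the empirical peak location as an extra deterministic start
  starts <- rbind(starts,
                  data.frame(c = max(min(v[which.max(y)], -40), -100),
                             w = 90, s = 0))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    p0 <- c(a0, starts$w[i], starts$c[i], starts$s[i], d0)
    fit <- tryCatch(
      optim(p0, rss, method = "L-BFGS-B",
            lower = b$lower, upper = b$upper,
            control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value - 1e-12) best <- fit
  }
  if (is.null(best)) stop_numerical("burst-curve fit failed from every start")
  p <- skewed_gaussian_params(best$par[1], best$par[2], best$par[3],
                              best$par[4], best$par[5])
  structure(list(params = p,
                 residual_norm = sqrt(best$value),
                 fitted = eval_burst_curve(p, v),
                 data = tibble::as_tibble(curve[, c("steady_v", "burst_number")]),
                 convergence = best$convergence),
            class = "trn_curve_fit")
}

#' @export
print.trn_curve_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf(paste0("<trn_curve_fit: a = %.2f, w = %.1f, c = %.2f mV, ",
                     "s = %.2f, d = %.3f; ||r|| = %.3f>\n"),
              p$a, p$w, p$c, p$s, p$d, x$residual_norm))
  invisible(x)
}

#' @export
tidy.trn_curve_fit <- function(x, ...) {
  tibble::tibble(term = c("a", "w", "c", "s", "d"),
                 estimate = unlist(x$params, use.names = FALSE))
}

#' @export
glance.trn_curve_fit <- function(x, ...) {
  tibble::tibble(residual_norm = x$residual_norm,
                 n = nrow(x$data),
                 converged = x$convergence == 0)
}

#' Scan a model's burst curve
#'
#' Runs the rebound-burst protocol at each steady-state voltage and collects
#' burst number and the runaway flag (drift metric below the runaway
#' threshold).
#'
#' @param model a [cell_model()].
#' @param voltages steady-state voltages (mV), increasing.
#' @param window post-step analysis window (ms); 14000 matches the
#'   experimental sampling, 25000 the full model protocol.
#' @param dt integration step (ms).
#' @param hyp_holding optional precomputed -100 mV holding current (nA).
#' @param ... further arguments to [run_burst_protocol()].
#' @return a `trn_burst_curve` tibble (`steady_v`, `burst_number`, `runaway`).
#' @export
scan_burst_curve <- function(model, voltages = seq(-85, -50, length.out = 10),
                             window = 14000, dt = 0.025, hyp_holding = NULL,
                             ...) {
  i_hyp <- hyp_holding %||% find_holding_current(model, -100)
  rows <- purrr::map_dfr(voltages, function(sv) {
    tr <- run_burst_protocol(model, sv, post_duration = window, dt = dt,
                             holding = list(hold = find_holding_current(model, sv),
                                            hyp = i_hyp), ...)
    tibble::tibble(steady_v = sv,
                   burst_number = burst_number(tr),
                   runaway = runaway_metric(tr) < 0.05)
  })
  new_burst_curve(rows, window = window)
}

#' Burst curves of a split-isoform model family
#'
#' Replaces the single generic IT by two voltage-shifted copies (see
#' [split_it_isoforms()]) and scans the burst curve for each conductance
#' fraction. At equal fractions the curve should stay close to the
#' single-channel model; the extreme fractions reproduce the single-channel
#' model shifted by -/+ `delta_v`.
#'
#' @param model a [cell_model()].
#' @param delta_v isoform shift magnitude (mV), default 3.
#' @param fractions conductance fractions of the up-shifted copy.
#' @param ... arguments passed to [scan_burst_curve()].
#' @return tibble with `fraction` and a `curve` list-column.
#' @export
isoform_curve_comparison <- function(model, delta_v = 3,
                                     fractions = c(0, 0.5, 1), ...) {
  it0 <- list(gbar = model$params[["gbar_IT_basal"]],
              vshift = model$params[["vshift_it2"]])
  tibble::tibble(
    fraction = fractions,
    curve = lapply(fractions, function(f) {
      sp <- split_it_isoforms(it0, delta_v, f)
      m2 <- model
      m2$it_split <- sp
      scan_burst_curve(m2, ...)
    }))
}

#' @export
autoplot.trn_burst_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$steady_v, y = .data$burst_number)) +
    ggplot2::geom_line(color = "grey50") +
    ggplot2::geom_point(ggplot2::aes(color = .data$runaway)) +
    ggplot2::labs(x = "steady-state voltage (mV)", y = "burst number")
}

#' @export
autoplot.trn_curve_fit <- function(object, ...) {
  grid <- tibble::tibble(steady_v = seq(min(object$data$steady_v),
                                        max(object$data$steady_v),
                                        length.out = 200))
  grid$fit <- eval_burst_curve(object$params, grid$steady_v)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$steady_v, y = .data$burst_number)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fit), color = "red") +
    ggplot2::labs(x = "steady-state voltage (mV)", y = "burst number")
}
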