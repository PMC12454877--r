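# shared internal helpers

stop_invalid <- function(msg) abort(msg, class = "trnlab_invalid_argument")
stop_not_found <- function(msg) abort(msg, class = "trnlab_not_found")
stop_format <- function(msg) abort(msg, class = "trnlab_format_error")
stop_search <- function(msg) abort(msg, class = "trnlab_search_failure")
stop_numerical <- function(msg) abort(msg, class = "trnlab_numerical_failure")
stop_config <- function(msg) abort(msg, class = "trnlab_config_error")
stop_insufficient <- function(msg) abort(msg, class = "trnlab_insufficient_data")

# run code with a local RNG seed, restoring global RNG state afterwards
local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Error function
#'
#' `erf(x) = 2/sqrt(pi) * integral_0^x exp(-t^2) dt`, evaluated through the
#' normal CDF. Used by the skewed-Gaussian burst-curve model.
#'
#' @param x numeric vector.
#' @return numeric vector of the same length.
#' @export
erf <- function(x) 2 * pnorm(sqrt(2) * x) - 1

`%||%` <- function(a, b) if (is.null(a)) b else a
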