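`%||%` <- function(x, y) if (is.null(x)) y else x

cfg_stop <- function(fmt, ...) {
  stop(sprintf(paste0("configuration error: ", fmt), ...), call. = FALSE)
}

usage_stop <- function(fmt, ...) {
  stop(sprintf(paste0("usage error: ", fmt), ...), call. = FALSE)
}

#' Sigmoid activation probability
#'
#' Probability that a stochastic binary unit fires given its summed input,
#' `1 / (1 + exp(-beta * (x - theta)))`. Both simulators in this package use
#' this form; `beta` sets the noise amplitude (larger `beta`, sharper
#' threshold) and `theta` the firing threshold, so `x = theta` always gives
#' probability 0.5.
#'
#' @param x summed input (activation units); may be a vector.
#' @param beta sigmoid steepness (inverse activation units).
#' @param theta firing threshold (activation units).
#' @return firing probabilities in (0, 1), same length as `x`.
#' @export
activation_probability <- function(x, beta, theta) {
  1 / (1 + exp(-beta * (x - theta)))
}

#' Derive a per-trial seed from a master seed
#'
#' All multi-trial experiment functions draw one pseudo-random stream per
#' trial, seeded deterministically from `(master, cell, replicate)` so that
#' grid cells are independent of enumeration order and any single trial can be
#' re-run bit-identically.
#'
#' @param master master seed (integer).
#' @param cell 0-based cell index within a grid (0 for plain sweeps).
#' @param replicate 1-based replicate number.
#' @return a positive integer seed below 2^31.
#' @export
derive_seed <- function(master, cell = 0L, replicate = 1L) {
  # exact in doubles: master < 2^31 so master*1000003 < 2^51 < 2^53
  v <- (as.numeric(master) %% 2147483647) * 1000003 +
    as.numeric(cell) * 10007 + as.numeric(replicate) * 101
  as.integer(v %% 2147483399) + 1L
}

# deep copy of an environment-backed state object
clone_state <- function(state) {
  new <- list2env(as.list.environment(state, all.names = TRUE),
                  parent = emptyenv())
  class(new) <- class(state)
  new
}

# snapshot / restore the global RNG state (for paired branching of runs)
get_rng_state <- function() {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  get(".Random.seed", envir = globalenv(), inherits = FALSE)
}

set_rng_state <- function(seed_state) {
  assign(".Random.seed", seed_state, envir = globalenv())
}
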