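ring_distance_matrix <- function(N) {
  idx <- 0:(N - 1L)
  d <- abs(outer(idx, idx, "-"))
  pmin(d, N - d)
}

neighborhood_mask <- function(N, n) {
  ring_distance_matrix(N) <= n %/% 2L
}

#' Build a three-layer network state
#'
#' Initializes the full mutable state of the three-layer model: the two
#' masked weight matrices (input to middle, middle to output), the alive
#' mask of the middle layer, and one random input/desired-output pattern
#' pair with `active_fraction` of nodes active. Weight `W[i, j]` connects
#' presynaptic node `j` to postsynaptic node `i`; entries are nonzero only
#' inside the inclusive modular neighborhood `[j - floor(n/2), j + floor(n/2)]`
#' and are drawn uniformly on `[w_min, init_weight_max]` (see
#' [three_layer_params()] for the default scale).
#'
#' The returned state is an environment: simulation functions update it in
#' place. Use identical `(params, seed)` to reproduce a state bit-exactly.
#'
#' @param params a [three_layer_params()] object.
#' @param seed integer seed for the R random stream.
#' @return an environment of class `three_layer_state` with fields `W_im`,
#'   `W_mo`, `mask`, `alive`, `input_pattern`, `desired_output`, `t`.
#' @export
build_network <- function(params, seed) {
  set.seed(as.integer(seed))
  build_network_impl(params)
}

# builds from the current RNG stream (callers that manage their own seed)
build_network_impl <- function(params) {
  N <- params$N
  mask <- neighborhood_mask(N, params$n)
  iw <- init_weight_bounds(params)
  W_im <- matrix(stats::runif(N * N, params$w_min, iw$im), N, N)
  W_im[!mask] <- 0
  W_mo <- matrix(stats::runif(N * N, params$w_min, iw$mo), N, N)
  W_mo[!mask] <- 0
  state <- list2env(list(
    W_im = W_im, W_mo = W_mo, mask = mask,
    alive = rep(TRUE, N),
    input_pattern = random_binary_pattern(N, params$active_fraction),
    desired_output = random_binary_pattern(N, params$active_fraction),
    t = 0L
  ), parent = emptyenv())
  class(state) <- "three_layer_state"
  state
}

# binary vector with exactly round(fraction * N) active nodes
random_binary_pattern <- function(N, fraction) {
  v <- integer(N)
  k <- round(fraction * N)
  if (k > 0L) v[sample.int(N, k)] <- 1L
  v
}

#' One stochastic middle-layer update
#'
#' Computes each alive middle node's summed input
#' `X_i = sum_j W_im[i, j] * input_j` and fires it (state 1) with probability
#' `1 / (1 + exp(-beta * (X_i - theta_ml)))`; dead nodes always return 0.
#' Consumes `N` uniform draws from the R random stream regardless of how many
#' nodes are alive, so paired runs stay stream-aligned.
#'
#' @param state a `three_layer_state`.
#' @param params the matching [three_layer_params()].
#' @return integer vector of middle-layer states (0/1), length `N`.
#' @export
middle_step <- function(state, params) {
  X <- drop(state$W_im %*% state$input_pattern)
  p <- activation_probability(X, params$beta, params$theta_ml)
  u <- stats::runif(length(X))
  as.integer(state$alive & (u < p))
}

#' Deterministic output-layer update
#'
#' Output nodes are binary threshold (Heaviside) units: node `i` fires iff
#' `sum_j W_mo[i, j] * middle_j >= theta_output` (a sum exactly at threshold
#' counts as firing).
#'
#' @param state a `three_layer_state`.
#' @param middle_states integer vector of middle-layer states, length `N`.
#' @param params the matching [three_layer_params()].
#' @return integer vector of output states (0/1), length `N`.
#' @export
output_step <- function(state, middle_states, params) {
  if (length(middle_states) != params$N) {
    usage_stop("middle_states must have length N=%d (got %d)", params$N, length(middle_states))
  }
  X <- drop(state$W_mo %*% middle_states)
  as.integer(X >= params$theta_output)
}

#' Hamming distance between binary patterns
#'
#' Counts positions where two equal-length binary vectors differ; the
#' three-layer model's disability measure (actual vs. desired output).
#'
#' @param actual,desired binary vectors of equal length.
#' @return nonnegative integer count of mismatches.
#' @export
hamming <- function(actual, desired) {
  if (length(actual) != length(desired)) {
    usage_stop("hamming requires equal lengths (got %d and %d)",
               length(actual), length(desired))
  }
  sum(actual != desired)
}

#' Disability-dependent learning rate
#'
#' Evaluates the learning-rate law of an [eta_policy()] at disability `H`.
#' Fixed mode always returns `eta0`. Modified mode returns `eta0` for
#' `H < H0`, the quarter-ellipse `eta0 * sqrt(1 - ((H - H0)/(Hc - H0))^2)`
#' for `H0 <= H < Hc` (decreasing slowly at first, rapidly later), and 0 for
#' `H >= Hc`; the law is continuous and nonincreasing.
#'
#' @param H disability (Hamming units), scalar or vector, `>= 0`.
#' @param policy an [eta_policy()].
#' @return learning rate(s), same length as `H`.
#' @export
eta_of_H <- function(H, policy) {
  if (any(H < 0)) usage_stop("H must be >= 0")
  if (policy$mode == "fixed") return(rep_len(policy$eta0, length(H)))
  out <- numeric(length(H))
  out[H < policy$H0] <- policy$eta0
  mid <- H >= policy$H0 & H < policy$Hc
  if (any(mid)) {
    r <- (H[mid] - policy$H0) / (policy$Hc - policy$H0)
    out[mid] <- policy$eta0 * sqrt(pmax(1 - r^2, 0))
  }
  out
}

#' Hebbian-like weight change for one connection
#'
#' `delta_w = eta * (a * s_post * s_pre - b * s_post - c * s_pre)`. With the
#' default constants (`a = 1.5`, `b = c = 0.5`) the change is `+eta/2` when
#' both units are active, `-eta/2` when exactly one is, and 0 when neither is.
#'
#' @param s_pre,s_post binary states (0/1) of the pre- and postsynaptic node;
#'   vectorized.
#' @param eta learning rate.
#' @param params a [three_layer_params()] (supplies `a`, `b`, `c`).
#' @return the weight change(s).
#' @export
hebbian_delta <- function(s_pre, s_post, eta, params) {
  eta * (params$a * s_post * s_pre - params$b * s_post - params$c * s_pre)
}

# vectorized Hebbian update of a whole masked weight matrix; rows are
# postsynaptic, columns presynaptic. Dead rows/cols are frozen at 0.
apply_hebbian <- function(W, pre, post, eta, params, mask,
                          dead_rows = NULL, dead_cols = NULL, row_gate = NULL) {
  np <- length(post)
  dW <- eta * (params$a * tcrossprod(post, pre) - params$b * post) -
    eta * params$c * tcrossprod(rep(1, np), pre)
  dW[!mask] <- 0
  if (!is.null(row_gate)) dW[!row_gate, ] <- 0
  if (!is.null(dead_rows)) dW[dead_rows, ] <- 0
  if (!is.null(dead_cols)) dW[, dead_cols] <- 0
  W <- pmin(pmax(W + dW, params$w_min), params$w_max)
  W[!mask] <- 0
  if (!is.null(dead_rows)) W[dead_rows, ] <- 0
  if (!is.null(dead_cols)) W[, dead_cols] <- 0
  W
}

#' One full training/recovery time step
#'
#' Runs one forward pass (stochastic middle layer, then deterministic output
#' layer), measures the disability `H` against the desired output, and - only
#' if `H > 0` - applies the Hebbian-like rule at rate `eta_of_H(H, policy)`
#' to every masked, alive-incident connection in both layers, clipping to
#' `[w_min, w_max]`. For the middle-to-output update the postsynaptic state
#' is the *desired* output bit (teacher clamping); the input-to-middle update
#' uses the actual input and middle activities. Increments the step counter.
#'
#' @param state a `three_layer_state` (updated in place).
#' @param params the matching [three_layer_params()].
#' @param policy an [eta_policy()].
#' @param gating `"per_bit"` (default: middle-to-output rows update only for
#'   output bits currently in error, so corrected outputs freeze at
#'   just-trained margins) or `"global"` (both layers update in full whenever
#'   total `H > 0`; margins then inflate for as long as any error persists
#'   anywhere, which makes the trained network insensitive to lesions of
#'   `m <= n` - see the package vignette).
#' @return a list with `state`, `H`, `eta` (rate in effect this step),
#'   `output`, and `middle`.
#' @export
train_step <- function(state, params, policy, gating = c("per_bit", "global")) {
  gating <- match.arg(gating)
  M <- middle_step(state, params)
  O <- output_step(state, M, params)
  H <- hamming(O, state$desired_output)
  eta <- eta_of_H(H, policy)
  if (H > 0L && eta > 0) {
    dead <- !state$alive
    state$W_im <- apply_hebbian(state$W_im, pre = state$input_pattern,
                                post = M, eta, params, state$mask,
                                dead_rows = dead)
    row_gate <- if (gating == "per_bit") O != state$desired_output else NULL
    state$W_mo <- apply_hebbian(state$W_mo, pre = M,
                                post = state$desired_output, eta, params,
                                state$mask, dead_cols = dead,
                                row_gate = row_gate)
  }
  state$t <- state$t + 1L
  list(state = state, H = H, eta = eta, output = O, middle = M)
}

#' Pre-lesion training phase
#'
#' Runs [train_step()] for `duration` steps (1000 by default, the injury
#' start time used throughout the package) so the network learns its
#' input/desired pattern pair before any damage is applied.
#'
#' @param state a `three_layer_state` (updated in place).
#' @param params the matching [three_layer_params()].
#' @param policy an [eta_policy()]; experiment drivers pass the fixed base
#'   rate here and engage a modified policy only from damage onset.
#' @param duration number of training steps (`>= 0`).
#' @return the trained state (invisibly the same environment), with an
#'   attribute-free history left to the caller.
#' @export
pre_lesion_train <- function(state, params, policy, duration = 1000L) {
  if (duration < 0L) usage_stop("duration must be >= 0")
  if (duration > 0L) {
    for (k in seq_len(duration)) train_step(state, params, policy)
  }
  state
}
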