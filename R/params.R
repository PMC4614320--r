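#' Parameters of the three-ring feed-forward lesion model
#'
#' Constructs and validates the parameter set of the stochastic binary
#' three-layer model: three rings of `N` nodes (input, middle/processing,
#' output) with locally dense feed-forward connectivity, a noisy sigmoid
#' middle layer, a Heaviside output layer, and a bounded Hebbian-like
#' learning rule. Defaults are the reference simulation values used
#' throughout this package.
#'
#' Each node feeds the inclusive modular neighborhood from `-floor(n/2)` to
#' `+floor(n/2)` in the next ring, i.e. `n + 1` connections for even `n`
#' (recorded as `n_effective`).
#'
#' @param N nodes per ring.
#' @param n fan-out neighborhood width; a node connects to the inclusive
#'   range `[-n/2, +n/2]` around its index in the next layer.
#' @param theta_ml middle-layer firing threshold.
#' @param theta_output output-layer threshold (Heaviside units; a summed
#'   input exactly at threshold counts as firing).
#' @param beta middle-layer sigmoid noise amplitude.
#' @param a,b,c Hebb-rule constants; with the defaults, coactive pre/post
#'   give `+eta/2`, exactly one active gives `-eta/2`, neither gives 0.
#' @param w_max,w_min weight bounds; `w_min >= 0` keeps every connection
#'   excitatory.
#' @param eta0 base learning rate.
#' @param H0 disability (Hamming) level where the modified learning rate
#'   starts dropping.
#' @param Hc critical disability where the modified learning rate reaches 0;
#'   case-dependent, so `NA` unless a modified-eta policy is used.
#' @param active_fraction fraction of active nodes in generated input/desired
#'   patterns.
#' @param init_weight_max upper bound of the uniform initial-weight
#'   distribution. `NULL` (default) chooses a scale such that the expected
#'   summed drive of a unit equals its threshold
#'   (`2*theta / (n_effective * presynaptic rate)`), the regime in which
#'   pre-lesion training converges and lesions of size `m <= n` produce
#'   measurable disability; see the package vignette.
#' @return an object of class `three_layer_params`.
#' @seealso [build_network()], [eta_policy()]
#' @export
three_layer_params <- function(N = 500L, n = 100L,
                               theta_ml = 5.54, theta_output = 5.54,
                               beta = 0.25,
                               a = 1.5, b = 0.5, c = 0.5,
                               w_max = 10.3, w_min = 0.0,
                               eta0 = 0.01, H0 = 5, Hc = NA_real_,
                               active_fraction = 0.5,
                               init_weight_max = NULL) {
  N <- as.integer(N); n <- as.integer(n)
  if (is.na(N) || N <= 0L) cfg_stop("N must be a positive integer (got %s)", N)
  if (is.na(n) || n <= 0L || n >= N) cfg_stop("n must satisfy 0 < n < N (got n=%s, N=%s)", n, N)
  if (w_min < 0) cfg_stop("w_min must be >= 0 (got %s)", w_min)
  if (w_min > w_max) cfg_stop("w_min must be <= w_max (got w_min=%s, w_max=%s)", w_min, w_max)
  if (eta0 <= 0) cfg_stop("eta0 must be > 0 (got %s)", eta0)
  if (H0 < 0) cfg_stop("H0 must be >= 0 (got %s)", H0)
  if (!is.na(Hc) && !(H0 < Hc && Hc <= N)) {
    cfg_stop("Hc must satisfy H0 < Hc <= N (got H0=%s, Hc=%s, N=%s)", H0, Hc, N)
  }
  if (active_fraction < 0 || active_fraction > 1) {
    cfg_stop("active_fraction must lie in [0, 1] (got %s)", active_fraction)
  }
  if (!is.null(init_weight_max)) {
    if (init_weight_max < w_min || init_weight_max > w_max) {
      cfg_stop("init_weight_max must lie in [w_min, w_max] (got %s)", init_weight_max)
    }
  }
  structure(
    list(N = N, n = n, n_effective = 2L * (n %/% 2L) + 1L,
         theta_ml = theta_ml, theta_output = theta_output, beta = beta,
         a = a, b = b, c = c, w_max = w_max, w_min = w_min,
         eta0 = eta0, H0 = H0, Hc = Hc,
         active_fraction = active_fraction,
         init_weight_max = init_weight_max),
    class = "three_layer_params"
  )
}

# initial-weight upper bounds for the two connection layers; `rate` is the
# expected presynaptic activity (active_fraction for inputs, ~0.5 for the
# stochastic middle layer at threshold)
init_weight_bounds <- function(params) {
  scale_for <- function(theta, rate) {
    s <- 2 * theta / (params$n_effective * rate)
    if (!is.finite(s)) s <- params$w_max
    min(max(s, params$w_min), params$w_max)
  }
  if (!is.null(params$init_weight_max)) {
    return(list(im = params$init_weight_max, mo = params$init_weight_max))
  }
  list(im = scale_for(params$theta_ml, params$active_fraction),
       mo = scale_for(params$theta_output, 0.5))
}

#' Learning-rate policy for the three-layer model
#'
#' The learning rate eta is either a constant (`mode = "fixed"`) or a
#' smoothly decreasing function of the current network disability H
#' (`mode = "modified"`): eta equals `eta0` for `H < H0`, follows the
#' quarter-ellipse `eta0 * sqrt(1 - ((H - H0)/(Hc - H0))^2)` for
#' `H0 <= H < Hc`, and is 0 for `H >= Hc`. A network whose disability
#' exceeds the critical size `Hc` therefore cannot relearn.
#'
#' @param mode `"fixed"` or `"modified"`.
#' @param eta0 base learning rate.
#' @param H0 disability level below which eta is constant (ignored for
#'   `mode = "fixed"`).
#' @param Hc critical disability; required for `mode = "modified"`.
#' @return an object of class `eta_policy`.
#' @seealso [eta_of_H()]
#' @export
eta_policy <- function(mode = c("fixed", "modified"), eta0 = 0.01,
                       H0 = 5, Hc = NA_real_) {
  mode <- match.arg(mode)
  if (eta0 <= 0) cfg_stop("eta0 must be > 0 (got %s)", eta0)
  if (mode == "modified") {
    if (is.null(Hc) || is.na(Hc)) cfg_stop("Hc is required when eta mode is 'modified'")
    if (!(H0 >= 0 && H0 < Hc)) cfg_stop("modified eta requires 0 <= H0 < Hc (got H0=%s, Hc=%s)", H0, Hc)
  }
  structure(list(mode = mode, eta0 = eta0, H0 = H0, Hc = Hc),
            class = "eta_policy")
}

#' Parameters of the homeostatic recurrent ring model
#'
#' Constructs and validates the parameter set of the recurrent ring model:
#' `n_nodes` stochastic binary neurons (a fraction `frac_excit` excitatory)
#' on a ring, each synapse contributing +1 (excitatory) or -1 (inhibitory)
#' per presynaptic spike, plus Poisson external drive. Activity runs in unit
#' time steps; every `morph_period` steps a morphological update moves each
#' neuron's synapse counts toward the homeostatic target firing probability
#' 0.5 at relative rate `nu` per unit deviation.
#'
#' @param n_nodes number of neurons on the ring.
#' @param morph_period activity steps between morphological updates.
#' @param theta firing threshold.
#' @param beta sigmoid steepness (noise amplitude).
#' @param p_del per-morphological-step realization probability of a synapse
#'   deletion that the homeostatic rule has marked; `p_del = 1` makes
#'   structural decay deterministic.
#' @param nu homeostatic convergence rate.
#' @param lambda_ext rate of the Poisson external input.
#' @param frac_excit fraction of excitatory neurons.
#' @param window number of recent activity steps over which per-neuron firing
#'   probabilities are averaged (for both the homeostatic drive and the
#'   disability measure); shorter histories early in a run are averaged as-is.
#' @param init_indegree initial synapses per neuron.
#' @param kernel_sigma ring-distance scale of the Gaussian kernel
#'   `exp(-d^2 / (2 sigma^2))` used to pick partners for new synapses
#'   (nearer neighbors are favored); `Inf` gives uniform choice.
#' @return an object of class `homeo_params`.
#' @seealso [build_ring()], [run_homeostasis_trial()]
#' @export
homeo_params <- function(n_nodes = 100L, morph_period = 100L,
                         theta = 500, beta = 0.002, p_del = 0.1,
                         nu = 0.005, lambda_ext = 30,
                         frac_excit = 0.8, window = 1000L,
                         init_indegree = 940L, kernel_sigma = 10) {
  n_nodes <- as.integer(n_nodes)
  morph_period <- as.integer(morph_period)
  window <- as.integer(window)
  init_indegree <- as.integer(init_indegree)
  if (is.na(n_nodes) || n_nodes < 2L) cfg_stop("n_nodes must be an integer >= 2 (got %s)", n_nodes)
  if (is.na(morph_period) || morph_period < 1L) cfg_stop("morph_period must be >= 1 (got %s)", morph_period)
  if (p_del < 0 || p_del > 1) cfg_stop("p_del must lie in [0, 1] (got %s)", p_del)
  if (nu < 0) cfg_stop("nu must be >= 0 (got %s)", nu)
  if (lambda_ext < 0) cfg_stop("lambda_ext must be >= 0 (got %s)", lambda_ext)
  if (frac_excit < 0 || frac_excit > 1) cfg_stop("frac_excit must lie in [0, 1] (got %s)", frac_excit)
  if (is.na(window) || window < 1L) cfg_stop("window must be >= 1 (got %s)", window)
  if (is.na(init_indegree) || init_indegree < 0L) cfg_stop("init_indegree must be >= 0 (got %s)", init_indegree)
  if (kernel_sigma <= 0) cfg_stop("kernel_sigma must be > 0 (got %s)", kernel_sigma)
  structure(
    list(n_nodes = n_nodes, morph_period = morph_period, theta = theta,
         beta = beta, p_del = p_del, nu = nu, lambda_ext = lambda_ext,
         frac_excit = frac_excit, window = window,
         init_indegree = init_indegree, kernel_sigma = kernel_sigma),
    class = "homeo_params"
  )
}
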