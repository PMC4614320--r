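# small, fast parameter sets used across unit tests

tiny_tl_params <- function(...) {
  three_layer_params(N = 40L, n = 8L, ...)
}

tiny_tl_config <- function(kind = "immediate", m = 10L, irt = 0, seed = 1L,
                           eta = list(mode = "fixed"), ...) {
  run_config(
    model = "three_layer",
    three_layer = list(N = 40L, n = 8L),
    eta = eta,
    lesion = list(kind = kind, m = m, irt = irt, ...),
    run = list(seed = seed, pre_duration = 200L, recovery_steps = 400L)
  )
}

# a small but dynamically sensible homeostasis model: at the target rate 0.5
# the expected synaptic drive plus external input sits near theta
tiny_homeo_params <- function(...) {
  defaults <- list(n_nodes = 30L, morph_period = 20L, theta = 50, beta = 0.02,
                   lambda_ext = 5, window = 60L, init_indegree = 120L,
                   kernel_sigma = 4)
  do.call(homeo_params, utils::modifyList(defaults, list(...)))
}

# three-layer state components that define equality between runs
tl_state_fields <- function(state) {
  list(W_im = state$W_im, W_mo = state$W_mo, alive = state$alive,
       input = state$input_pattern, desired = state$desired_output,
       t = state$t)
}

# hand-built homeostasis state with a prescribed firing-probability history,
# for exact tests of the morphological rule and the disability measure
fabricated_homeo_state <- function(fbar, params, indegree = 0) {
  n <- length(fbar)
  st <- build_ring(params, 1L)
  stopifnot(length(st$alive) == n)
  st$C <- matrix(0, n, n)
  if (indegree > 0) {
    for (i in seq_len(n)) {
      st$C[i, i %% n + 1L] <- indegree  # ring successor: in- and out-degree equal
    }
  }
  st$fbuf <- matrix(rep(fbar, each = params$window), params$window, n)
  st$fsum <- fbar * params$window
  st$fcount <- params$window
  st$fidx <- params$window
  st$resid_in <- numeric(n)
  st$resid_out <- numeric(n)
  st$pending_in <- numeric(n)
  st$pending_out <- numeric(n)
  st
}

# memoised store for expensive acceptance computations shared across blocks
.acceptance_cache <- new.env(parent = emptyenv())

acceptance_homeo_sweep <- function() {
  if (is.null(.acceptance_cache$homeo)) {
    .acceptance_cache$homeo <- homeostasis_irt_sweep(
      homeostasis_config(seed = 20260927L, m = 10L),
      irt_values = c(0, 20), n_seeds = 30L, n_branches = 2L
    )
  }
  .acceptance_cache$homeo
}
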