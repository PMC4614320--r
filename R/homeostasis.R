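ring_kernel <- function(n, sigma) {
  d <- ring_distance_matrix(n)
  K <- exp(-(d^2) / (2 * sigma^2))
  diag(K) <- 0
  K
}

#' Build a homeostatic ring-network state
#'
#' Initializes the recurrent model: a random `frac_excit` share of neurons is
#' flagged excitatory; each neuron receives `init_indegree` synapses whose
#' presynaptic partners are sampled (with replacement, self-synapses
#' excluded) proportionally to the Gaussian ring-distance kernel
#' `exp(-d^2 / (2 kernel_sigma^2))`, so nearer neighbors are favored.
#' `C[i, j]` counts synapses from neuron `j` to neuron `i`.
#'
#' The returned state is an environment updated in place by the simulation
#' functions; identical `(params, seed)` reproduce it bit-exactly.
#'
#' @param params a [homeo_params()] object.
#' @param seed integer seed for the R random stream.
#' @return an environment of class `homeostasis_state` with fields `C`
#'   (synapse-count matrix), `excit`, `sign`, `alive`, `s` (current 0/1
#'   states), the rolling firing-probability window (`fbuf`, `fsum`,
#'   `fcount`, `fidx`), fractional-change accumulators (`resid_in`,
#'   `resid_out`, `pending_in`, `pending_out`), and `t_act`.
#' @export
build_ring <- function(params, seed) {
  set.seed(as.integer(seed))
  build_ring_impl(params)
}

build_ring_impl <- function(params) {
  n <- params$n_nodes
  perm <- sample.int(n)
  excit <- logical(n)
  n_exc <- as.integer(ceiling(params$frac_excit * n))
  if (n_exc > 0L) excit[perm[seq_len(n_exc)]] <- TRUE
  K <- ring_kernel(n, params$kernel_sigma)
  C <- matrix(0, n, n)
  if (params$init_indegree > 0L) {
    for (i in seq_len(n)) {
      picks <- sample.int(n, params$init_indegree, replace = TRUE, prob = K[i, ])
      C[i, ] <- tabulate(picks, nbins = n)
    }
  }
  state <- list2env(list(
    C = C, excit = excit, sign = ifelse(excit, 1, -1),
    alive = rep(TRUE, n),
    s = as.integer(stats::runif(n) < 0.5),
    kernel = K,
    fbuf = matrix(0, params$window, n),
    fsum = numeric(n), fcount = 0L, fidx = 0L,
    resid_in = numeric(n), resid_out = numeric(n),
    pending_in = numeric(n), pending_out = numeric(n),
    t_act = 0L
  ), parent = emptyenv())
  class(state) <- "homeostasis_state"
  state
}

#' One activity time step of the homeostasis model
#'
#' Each alive neuron `i` receives
#' `X_i = sum_j sign_j * C[i, j] * s_j + Poisson(lambda_ext)` (excitatory
#' presynaptic neurons contribute +1 per synapse per spike, inhibitory -1),
#' gets firing probability `F_i = 1 / (1 + exp(-beta * (X_i - theta)))`, and
#' draws its new binary state Bernoulli(`F_i`). `F_i` is appended to the
#' rolling window of length `window`. Dead neurons have state 0 and `F = 0`.
#' Poisson and uniform draws are made for all neurons each step so paired
#' runs stay stream-aligned.
#'
#' @param state a `homeostasis_state` (updated in place).
#' @param params the matching [homeo_params()].
#' @return the state, invisibly.
#' @export
activity_step <- function(state, params) {
  n <- length(state$s)
  X <- drop(state$C %*% (state$s * state$sign)) +
    stats::rpois(n, params$lambda_ext)
  p <- activation_probability(X, params$beta, params$theta)
  p[!state$alive] <- 0
  u <- stats::runif(n)
  state$s <- as.integer(state$alive & (u < p))
  w <- params$window
  state$fidx <- if (state$fidx >= w) 1L else state$fidx + 1L
  if (state$fcount >= w) {
    state$fsum <- state$fsum - state$fbuf[state$fidx, ]
  } else {
    state$fcount <- state$fcount + 1L
  }
  state$fbuf[state$fidx, ] <- p
  state$fsum <- state$fsum + p
  state$t_act <- state$t_act + 1L
  invisible(state)
}

#' Per-neuron mean firing probability over the rolling window
#'
#' Mean of each neuron's firing probability over the last `window` activity
#' steps (or over however many steps exist early in a run).
#'
#' @param state a `homeostasis_state`.
#' @return numeric vector, one value per neuron.
#' @export
mean_firing_probability <- function(state) {
  state$fsum / max(state$fcount, 1L)
}

#' Network disability of the homeostasis model
#'
#' Population variance, across alive neurons, of the per-neuron mean firing
#' probability over the rolling window: how far the network as a whole is
#' from its homeostatic state (all neurons at rate 0.5). Bounded by 0.25.
#'
#' @param state a `homeostasis_state` with at least one alive neuron and a
#'   nonempty firing history.
#' @return nonnegative scalar in `[0, 0.25]`.
#' @export
disability <- function(state) {
  if (!any(state$alive)) usage_stop("disability is undefined with no alive neurons")
  if (state$fcount == 0L) usage_stop("disability is undefined before any activity step")
  f <- mean_firing_probability(state)[state$alive]
  mean((f - mean(f))^2)
}

# sample `k` existing synapse instances from a count vector and decrement
delete_synapses <- function(counts, k) {
  for (d in seq_len(k)) {
    tot <- sum(counts)
    if (tot <= 0) break
    j <- sample.int(length(counts), 1L, prob = counts)
    counts[j] <- counts[j] - 1
  }
  counts
}

#' One morphological (structural) update
#'
#' Moves each alive neuron's synapse counts toward the homeostatic target
#' rate 0.5. For neuron `i` with windowed mean firing probability `Fbar_i`,
#' the signed drive is `delta = nu * (Fbar_i - 0.5) * I_i` on the input side
#' (`I_i` = in-degree) and analogously on the output side. Signed drives
#' accumulate in per-neuron fractional residuals; only integer parts are
#' realized. Above-target neurons have synapses marked for removal, and each
#' pending mark is realized with probability `p_del` per morphological step
#' (victim synapse drawn proportionally to current counts). Below-target
#' neurons immediately form new synapses with partners drawn from the
#' ring-distance kernel among alive neurons. Counts never go negative; dead
#' neurons neither gain nor lose synapses.
#'
#' @param state a `homeostasis_state` (updated in place).
#' @param params the matching [homeo_params()].
#' @return the state, invisibly.
#' @export
morphological_step <- function(state, params) {
  n <- length(state$alive)
  alive <- state$alive
  fbar <- mean_firing_probability(state)
  dF <- fbar - 0.5
  I_in <- rowSums(state$C)
  I_out <- colSums(state$C)
  state$resid_in[alive] <- state$resid_in[alive] +
    params$nu * dF[alive] * I_in[alive]
  state$resid_out[alive] <- state$resid_out[alive] +
    params$nu * dF[alive] * I_out[alive]

  for (i in which(alive)) {
    # input side: rows of C
    r <- state$resid_in[i]
    if (r >= 1) {                          # above target: mark deletions
      k <- floor(r)
      state$pending_in[i] <- state$pending_in[i] + k
      state$resid_in[i] <- r - k
    } else if (r <= -1) {                  # below target: form synapses
      k <- floor(-r)
      state$resid_in[i] <- r + k
      partners <- partner_probs(state, i)
      if (any(partners > 0)) {
        picks <- sample.int(n, k, replace = TRUE, prob = partners)
        state$C[i, ] <- state$C[i, ] + tabulate(picks, nbins = n)
      }
    }
    if (state$pending_in[i] >= 1) {
      avail <- sum(state$C[i, ])
      if (avail <= 0) {
        state$pending_in[i] <- 0            # nothing left to delete
      } else {
        ndel <- stats::rbinom(1L, state$pending_in[i], params$p_del)
        ndel <- min(ndel, avail)
        if (ndel > 0L) {
          state$C[i, ] <- delete_synapses(state$C[i, ], ndel)
          state$pending_in[i] <- state$pending_in[i] - ndel
        }
      }
    }
    # output side: columns of C
    r <- state$resid_out[i]
    if (r >= 1) {
      k <- floor(r)
      state$pending_out[i] <- state$pending_out[i] + k
      state$resid_out[i] <- r - k
    } else if (r <= -1) {
      k <- floor(-r)
      state$resid_out[i] <- r + k
      partners <- partner_probs(state, i)
      if (any(partners > 0)) {
        picks <- sample.int(n, k, replace = TRUE, prob = partners)
        state$C[, i] <- state$C[, i] + tabulate(picks, nbins = n)
      }
    }
    if (state$pending_out[i] >= 1) {
      avail <- sum(state$C[, i])
      if (avail <= 0) {
        state$pending_out[i] <- 0
      } else {
        ndel <- stats::rbinom(1L, state$pending_out[i], params$p_del)
        ndel <- min(ndel, avail)
        if (ndel > 0L) {
          state$C[, i] <- delete_synapses(state$C[, i], ndel)
          state$pending_out[i] <- state$pending_out[i] - ndel
        }
      }
    }
  }
  invisible(state)
}

# kernel weights over admissible partners (alive, not self)
partner_probs <- function(state, i) {
  p <- state$kernel[i, ]
  p[!state$alive] <- 0
  p
}

#' Run one homeostasis-model trial
#'
#' Alternates `morph_period` activity steps with one morphological step for
#' `total_morph_steps` morphological steps, applying the removal events of a
#' lesion schedule at their morphological times (the network is given
#' `start_time` morphological steps to reach homeostasis before the first
#' removal). Records the disability trace once per morphological step.
#'
#' @param params a [homeo_params()].
#' @param schedule a [lesion_schedule()]; `irt` counts morphological steps.
#'   If its `start_index` is `NULL` it is drawn from the run seed.
#' @param total_morph_steps run length in morphological steps; must reach
#'   `schedule$start_time`.
#' @param seed integer seed; identical `(params, schedule, seed)` reproduce
#'   the trace bit-exactly.
#' @return a `data.frame` trace of class `disability_trace` with columns
#'   `time` (morphological step), `disability`, `alive_count`, `mean_F`,
#'   `total_synapses`, and attributes `events`, `damage_start`, `seed`,
#'   `model`.
#' @export
run_homeostasis_trial <- function(params, schedule, total_morph_steps, seed) {
  if (schedule$start_time > total_morph_steps) {
    usage_stop("schedule start_time (%g) exceeds total_morph_steps (%g)",
               schedule$start_time, total_morph_steps)
  }
  set.seed(as.integer(seed))
  state <- build_ring_impl(params)
  si <- sample.int(params$n_nodes, 1L) - 1L
  if (!is.null(schedule$start_index)) si <- schedule$start_index
  schedule$start_index <- si
  events <- removal_events(schedule, params$n_nodes)
  rec <- homeo_segment(state, params, events, 1L, as.integer(total_morph_steps))
  trace <- as.data.frame(rec)
  attr(trace, "events") <- events
  attr(trace, "damage_start") <- schedule$start_time
  attr(trace, "seed") <- as.integer(seed)
  attr(trace, "schedule") <- schedule
  attr(trace, "model") <- "homeostasis"
  attr(trace, "params") <- unclass(params)
  class(trace) <- c("disability_trace", class(trace))
  trace
}

# one morphological period of activity, computed on local variables with the
# period's external-input and firing draws batched (one rpois and one runif
# call per period); same per-step dynamics as activity_step()
homeo_run_period <- function(state, params) {
  n <- length(state$s)
  Tm <- params$morph_period
  w <- params$window
  C <- state$C; sgn <- state$sign; alive <- state$alive; s <- state$s
  fbuf <- state$fbuf; fsum <- state$fsum
  fcount <- state$fcount; fidx <- state$fidx
  ext <- matrix(stats::rpois(n * Tm, params$lambda_ext), n, Tm)
  U <- matrix(stats::runif(n * Tm), n, Tm)
  beta <- params$beta; theta <- params$theta
  for (k in seq_len(Tm)) {
    X <- drop(C %*% (s * sgn)) + ext[, k]
    p <- 1 / (1 + exp(-beta * (X - theta)))
    p[!alive] <- 0
    s <- as.integer(alive & (U[, k] < p))
    fidx <- if (fidx >= w) 1L else fidx + 1L
    if (fcount >= w) fsum <- fsum - fbuf[fidx, ] else fcount <- fcount + 1L
    fbuf[fidx, ] <- p
    fsum <- fsum + p
  }
  state$s <- s
  state$fbuf <- fbuf
  state$fsum <- fsum
  state$fcount <- fcount
  state$fidx <- fidx
  state$t_act <- state$t_act + Tm
  invisible(state)
}

# run morphological steps `from..to` (inclusive) on a live state, applying
# events at their times; returns the recorded trace columns for the segment
homeo_segment <- function(state, params, events, from, to) {
  ev_times <- vapply(events, function(e) e$time, numeric(1))
  nsteps <- to - from + 1L
  time <- integer(nsteps); dis <- numeric(nsteps)
  alive_count <- integer(nsteps); meanF <- numeric(nsteps)
  total_syn <- numeric(nsteps)
  for (k in seq_len(nsteps)) {
    mt <- from + k - 1L
    hit <- which(ev_times == mt)
    for (e in hit) apply_removal(state, events[[e]]$nodes)
    homeo_run_period(state, params)
    morphological_step(state, params)
    time[k] <- mt
    dis[k] <- disability(state)
    alive_count[k] <- sum(state$alive)
    meanF[k] <- mean(mean_firing_probability(state)[state$alive])
    total_syn[k] <- sum(state$C)
  }
  list(time = time, disability = dis, alive_count = alive_count,
       mean_F = meanF, total_synapses = total_syn)
}
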