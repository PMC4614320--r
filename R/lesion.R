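#' Declarative lesion schedule
#'
#' Describes when which contiguous block of nodes dies. Three kinds:
#' `"immediate"` removes all `m` nodes at `start_time`; `"gradual"` removes
#' one node every `irt` time units; `"resection"` removes `n_p` packages of
#' `m / n_p` contiguous nodes every `irt` time units (a non-divisible `m`
#' gives the earliest packages one extra node each). Immediate injury is
#' equivalent to either other kind with `irt = 0`. Time units are simulation
#' steps for the three-layer model and morphological steps for the
#' homeostasis model.
#'
#' @param kind `"immediate"`, `"gradual"`, or `"resection"`.
#' @param m defect size: total number of nodes removed (`>= 0`; 0 means no
#'   lesion).
#' @param irt inter-removal time (`>= 0`).
#' @param n_p number of packages (resection only; `1 <= n_p <= m`).
#' @param start_time time of the first removal.
#' @param start_index ring index (0-based) of the first node removed; the
#'   removed nodes are `start_index .. start_index + m - 1` modulo `N`. If
#'   `NULL`, experiment drivers draw it from the run seed.
#' @return an object of class `lesion_schedule`.
#' @seealso [removal_events()], [apply_removal()]
#' @export
lesion_schedule <- function(kind = c("immediate", "gradual", "resection"),
                            m, irt = 0, n_p = NULL,
                            start_time = 1000, start_index = NULL) {
  kind <- match.arg(kind)
  m <- as.integer(m)
  if (is.na(m) || m < 0L) cfg_stop("defect size m must be >= 0 (got %s)", m)
  if (irt < 0) cfg_stop("IRT must be >= 0 (got %s)", irt)
  if (kind == "resection") {
    if (is.null(n_p)) cfg_stop("resection requires n_p")
    n_p <- as.integer(n_p)
    if (is.na(n_p) || n_p < 1L || (m > 0L && n_p > m)) {
      cfg_stop("resection requires 1 <= n_p <= m (got n_p=%s, m=%s)", n_p, m)
    }
  } else {
    n_p <- NULL
  }
  if (!is.null(start_index)) start_index <- as.integer(start_index)
  structure(list(kind = kind, m = m, irt = irt, n_p = n_p,
                 start_time = start_time, start_index = start_index),
            class = "lesion_schedule")
}

#' @export
print.lesion_schedule <- function(x, ...) {
  cat(sprintf("<lesion_schedule> kind=%s m=%d irt=%g%s start_time=%g start_index=%s\n",
              x$kind, x$m, x$irt,
              if (!is.null(x$n_p)) sprintf(" n_p=%d", x$n_p) else "",
              x$start_time,
              if (is.null(x$start_index)) "<from seed>" else x$start_index))
  invisible(x)
}

#' Expand a lesion schedule into removal events
#'
#' Turns a [lesion_schedule()] into the ordered list of `(time, nodes)`
#' events it implies on a ring of `N` nodes. The union over events is exactly
#' the contiguous modular block of `m` distinct nodes starting at
#' `start_index`; event node sets are disjoint and removed in ring order.
#'
#' @param schedule a [lesion_schedule()]; `start_index` must be set.
#' @param N ring size.
#' @return a list of events, each `list(time=, nodes=)` with 0-based node
#'   indices; empty for `m = 0`.
#' @export
removal_events <- function(schedule, N) {
  if (schedule$m > N) cfg_stop("defect size m=%d exceeds N=%d", schedule$m, N)
  if (schedule$m == 0L) return(list())
  s0 <- schedule$start_index
  if (is.null(s0)) cfg_stop("start_index is unset; draw or configure it before expanding events")
  nodes <- (s0 + 0:(schedule$m - 1L)) %% N
  if (schedule$kind == "immediate") {
    return(list(list(time = schedule$start_time, nodes = nodes)))
  }
  if (schedule$kind == "gradual") {
    return(lapply(seq_along(nodes), function(k) {
      list(time = schedule$start_time + (k - 1L) * schedule$irt,
           nodes = nodes[k])
    }))
  }
  # resection: n_p packages; the earliest packages absorb any remainder
  n_p <- schedule$n_p
  sizes <- rep(schedule$m %/% n_p, n_p) + (seq_len(n_p) <= schedule$m %% n_p)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  lapply(seq_len(n_p), function(k) {
    list(time = schedule$start_time + (k - 1L) * schedule$irt,
         nodes = nodes[starts[k]:ends[k]])
  })
}

#' Kill a set of nodes in a model state
#'
#' Marks the given nodes dead and disconnects them. In the three-layer model
#' the middle-layer alive mask is cleared and all incident weights are zeroed
#' (the node can never fire again and its weights are never updated). In the
#' homeostasis model all synapses to and from the neuron are deleted and the
#' neuron is barred from future synapse formation and excluded from the
#' disability statistic. Removing an already-dead node is a no-op with a
#' warning; removal is idempotent.
#'
#' @param state a `three_layer_state` or `homeostasis_state` (updated in
#'   place).
#' @param nodes integer vector of 0-based node indices.
#' @return the state, invisibly.
#' @export
apply_removal <- function(state, nodes) UseMethod("apply_removal")

check_removal_nodes <- function(nodes, N, alive) {
  nodes <- as.integer(nodes)
  if (any(nodes < 0L | nodes >= N)) usage_stop("node indices must lie in [0, N)")
  idx <- nodes + 1L
  dead <- !alive[idx]
  if (any(dead)) {
    warning(sprintf("removing already-dead node(s): %s",
                    paste(nodes[dead], collapse = ", ")), call. = FALSE)
  }
  idx[!dead]
}

#' @export
apply_removal.three_layer_state <- function(state, nodes) {
  idx <- check_removal_nodes(nodes, length(state$alive), state$alive)
  if (length(idx)) {
    state$alive[idx] <- FALSE
    state$W_im[idx, ] <- 0
    state$W_mo[, idx] <- 0
  }
  invisible(state)
}

#' @export
apply_removal.homeostasis_state <- function(state, nodes) {
  idx <- check_removal_nodes(nodes, length(state$alive), state$alive)
  if (length(idx)) {
    state$alive[idx] <- FALSE
    state$C[idx, ] <- 0
    state$C[, idx] <- 0
    state$s[idx] <- 0L
    state$resid_in[idx] <- 0
    state$resid_out[idx] <- 0
    state$pending_in[idx] <- 0
    state$pending_out[idx] <- 0
  }
  invisible(state)
}
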