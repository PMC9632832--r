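#' STDP parameters
#'
#' Additive pair-based STDP with hard bounds. A pairing with lag
#' `dt` (postsynaptic minus presynaptic arrival time at the synapse) changes
#' the weight by `eta * exp(-dt / tau_plus)` for `dt > 0` (potentiation) and
#' by `-eta * (beta / tau_R) * exp(dt / tau_minus)` for `dt < 0`
#' (depression), with `tau_minus = tau_plus * tau_R`. The depression
#' amplitude `beta / tau_R` makes `beta` exactly the ratio of the total LTD
#' integral to the total LTP integral:
#' `eta * (beta / tau_R) * tau_minus = beta * eta * tau_plus`.
#'
#' These defaults place the unstimulated network in a bistable regime with a
#' strongly connected synchronised state and a weakly connected asynchronous
#' state.
#'
#' @param eta Update scale per pairing (weight units).
#' @param beta LTD:LTP integral ratio (dimensionless).
#' @param tau_R Decay-time asymmetry `tau_minus / tau_plus` (dimensionless).
#' @param tau_plus Potentiation time constant (ms).
#' @return An object of class `stdp_parameters` (with derived `tau_minus`).
#' @export
stdp_parameters <- function(eta = 0.02, beta = 1.4, tau_R = 4,
                            tau_plus = 10) {
  if (eta < 0) stop("'eta' must be non-negative")
  if (beta <= 0 || tau_R <= 0 || tau_plus <= 0) {
    stop("'beta', 'tau_R' and 'tau_plus' must be positive")
  }
  structure(list(eta = eta, beta = beta, tau_R = tau_R, tau_plus = tau_plus,
                 tau_minus = tau_plus * tau_R), class = "stdp_parameters")
}

#' The STDP function W(dt)
#'
#' @param delta_t Numeric vector of lags (ms): postsynaptic minus
#'   presynaptic arrival time at the synapse.
#' @param params A [stdp_parameters()] object.
#' @return Weight increments; `W(0) = 0`.
#' @export
stdp_function <- function(delta_t, params = stdp_parameters()) {
  stopifnot(inherits(params, "stdp_parameters"))
  out <- numeric(length(delta_t))
  pos <- delta_t > 0
  neg <- delta_t < 0
  out[pos] <- params$eta * exp(-delta_t[pos] / params$tau_plus)
  out[neg] <- -params$eta * (params$beta / params$tau_R) *
    exp(delta_t[neg] / params$tau_minus)
  out
}

#' Event-driven nearest-neighbour STDP update
#'
#' Reference implementation of the per-synapse bookkeeping used inside the
#' simulator: each spike arrival at a synapse is paired only with the most
#' recent opposite-side arrival. A presynaptic arrival at time
#' `t_i + t_a` pairs with the latest postsynaptic arrival (non-positive
#' lag); a postsynaptic arrival at `t_j + t_d` pairs with the latest
#' presynaptic arrival (non-negative lag). The weight is clipped to
#' `[0, 1]` after every update, and the arrival then becomes the new latest
#' arrival of its kind. No update occurs if no opposite-side arrival has
#' been seen yet.
#'
#' @param state A `network_state` (arrival registers `last_pre`,
#'   `last_post` and weights `w` are read and updated).
#' @param synapse Either a single edge index into the state's edge arrays or
#'   a length-2 vector `c(i, j)` naming the pre- and postsynaptic neurons.
#' @param arrival_kind `"pre"` or `"post"`.
#' @param arrival_time Arrival time at the synapse (ms), already including
#'   the respective delay; must be non-decreasing per synapse.
#' @param params A [stdp_parameters()] object.
#' @return The updated `network_state`.
#' @export
process_arrival <- function(state, synapse, arrival_kind = c("pre", "post"),
                            arrival_time, params = stdp_parameters()) {
  arrival_kind <- match.arg(arrival_kind)
  if (length(synapse) == 2L) {
    e <- which(state$edge_pre == synapse[1] & state$edge_post == synapse[2])
    if (length(e) != 1L) stop("unknown synapse")
  } else {
    e <- as.integer(synapse)
    if (e < 1L || e > length(state$w)) stop("unknown synapse")
  }
  if (arrival_kind == "pre") {
    if (is.finite(state$last_post[e])) {
      dw <- stdp_function(state$last_post[e] - arrival_time, params)
      state$w[e] <- min(1, max(0, state$w[e] + dw))
    }
    state$last_pre[e] <- arrival_time
  } else {
    if (is.finite(state$last_pre[e])) {
      dw <- stdp_function(arrival_time - state$last_pre[e], params)
      state$w[e] <- min(1, max(0, state$w[e] + dw))
    }
    state$last_post[e] <- arrival_time
  }
  state
}
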