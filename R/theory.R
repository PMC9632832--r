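#' Expected per-cycle STDP updates and the mean rate of weight change
#'
#' The analytical core: given the stimulus-locked spike statistics of the
#' pre- and postsynaptic populations (assumed identical and
#' stimulation-controlled), the expected total potentiation `W+` and
#' depression `W-` accumulated by one synapse per stimulation cycle are
#' computed by quadrature over the discrete spike-time grid, and the mean
#' rate of weight change is `J = f * (W+ + W-)` (weight units per second).
#'
#' `phi` is the phase lag between the stimulus trains delivered to the
#' postsynaptic and the presynaptic population; `xi = t_a - t_d` is the
#' difference between axonal and dendritic delays. The post-triggered
#' (positive-lag) contribution of the mth postsynaptic spike pairs it with
#' the presynaptic arrival immediately before it, summing over the
#' presynaptic spike order `n`, the cycle offset `k` (truncated to
#' `k_range`), and the gap to the next presynaptic arrival — including the
#' boundary gap between a cycle's last spike and the first spike of the
#' next cycle. The pre-triggered (negative-lag) contribution mirrors this
#' with the roles of pre and post exchanged. Spike times are evaluated at
#' bin centres; the STDP kernel is evaluated analytically.
#'
#' @param m Spike order (for the per-order components).
#' @param phi Phase lag in `[0, 1)` (post relative to pre).
#' @param f Stimulation frequency (Hz). Must match the grid frequency of
#'   `densities`.
#' @param xi Delay difference `t_a - t_d` (ms).
#' @param densities An `isi_densities` object (the spike-time distributions
#'   are derived internally), or a list with elements `isi` and `std` as
#'   returned by [spike_time_densities()] if precomputed.
#' @param stdp A [stdp_parameters()] object.
#' @param k_range Integer vector `c(kmin, kmax)`: cycle offsets retained in
#'   the lag sum.
#' @return `per_cycle_update_positive` / `negative` return the expected
#'   update (weight units per cycle) contributed by the mth post-/presynaptic
#'   spike, with the mth-spike distribution conditioned on its existence.
#'   `mean_rate_of_weight_change` returns an object of class
#'   `rate_of_change` with fields `phi`, `f`, `xi`, `J` (per second),
#'   `W_plus`, `W_minus` (per cycle), and the per-order components.
#' @export
mean_rate_of_weight_change <- function(phi, f, xi, densities,
                                       stdp = stdp_parameters(),
                                       k_range = c(-5L, 5L)) {
  pc <- theory_components(phi, f, xi, densities, stdp, k_range)
  kmax <- length(pc$P_k)
  # spike-count weighting of the per-order components (existence-conditioned
  # components times P(k) summed over m <= k)
  Wp <- 0; Wm <- 0
  for (k in seq_len(kmax)) {
    if (pc$P_k[k] <= 0) next
    Wp <- Wp + pc$P_k[k] * sum(pc$Wm_plus[seq_len(k)])
    Wm <- Wm + pc$P_k[k] * sum(pc$Wm_minus[seq_len(k)])
  }
  structure(list(phi = phi, f = f, xi = xi,
                 J = f * (Wp + Wm), W_plus = Wp, W_minus = Wm,
                 Wm_plus = pc$Wm_plus, Wm_minus = pc$Wm_minus,
                 P_k = pc$P_k), class = "rate_of_change")
}

#' @rdname mean_rate_of_weight_change
#' @export
per_cycle_update_positive <- function(m, phi, f, xi, densities,
                                      stdp = stdp_parameters(),
                                      k_range = c(-5L, 5L)) {
  pc <- theory_components(phi, f, xi, densities, stdp, k_range)
  if (m > length(pc$Wm_plus)) return(0)
  pc$Wm_plus[m]
}

#' @rdname mean_rate_of_weight_change
#' @export
per_cycle_update_negative <- function(m, phi, f, xi, densities,
                                      stdp = stdp_parameters(),
                                      k_range = c(-5L, 5L)) {
  pc <- theory_components(phi, f, xi, densities, stdp, k_range)
  if (m > length(pc$Wm_minus)) return(0)
  pc$Wm_minus[m]
}

theory_components <- function(phi, f, xi, densities, stdp, k_range) {
  stopifnot(inherits(stdp, "stdp_parameters"))
  if (inherits(densities, "isi_densities")) {
    isi <- densities
    std <- spike_time_densities(isi)
  } else {
    isi <- densities$isi
    std <- densities$std
    stopifnot(inherits(isi, "isi_densities"),
              inherits(std, "spike_time_densities"))
  }
  if (abs(isi$f - f) > 1e-9) {
    stop("'f' does not match the grid frequency of the densities")
  }
  T_ms <- 1000 / f
  kmax_order <- ncol(std$Lambda)
  lamc <- vector("list", max(kmax_order, 1L))
  for (l in seq_along(lamc)) {
    ll <- l + 1L
    lamc[[l]] <- if (ll <= length(isi$lam)) isi$lam[[ll]] else NULL
  }
  out <- theory_percycle_cpp(std$Lambda, isi$lam1, lamc, std$Lambda_last,
                             std$P_k, phi, T_ms, xi, isi$bin,
                             as.integer(k_range[1]), as.integer(k_range[2]),
                             stdp$eta, stdp$beta, stdp$tau_R, stdp$tau_plus)
  list(Wm_plus = out$Wm_plus, Wm_minus = out$Wm_minus, P_k = std$P_k)
}

#' Linear bounded growth of a block-mean weight
#'
#' Rate of change of the mean weight of a synapse group whose individual
#' weights sit near the hard bounds: a negative mean rate `J` empties the
#' fraction `w` of strong synapses (`S = w * J`), a positive one fills the
#' fraction `1 - w` of weak synapses (`S = (1 - w) * J`).
#'
#' @param J Mean rate of weight change (per second); number or
#'   `rate_of_change` object.
#' @param w Current block-mean weight in `[0, 1]`.
#' @return The growth rate `S` (per second).
#' @export
linear_growth <- function(J, w) {
  if (inherits(J, "rate_of_change")) J <- J$J
  if (any(w < 0 | w > 1)) stop("'w' must lie in [0, 1]")
  ifelse(J <= 0, w * J, (1 - w) * J)
}

#' Forecast the block structure of the weight matrix under a PMCS pattern
#'
#' Combines the phase-shift matrix of the delivery pattern with the
#' theoretical mean rate of weight change to forecast every
#' subpopulation-to-subpopulation block mean `<w_xy(t)>`: each block grows
#' or decays linearly at rate `S(J_xy, w0_xy)` and is clipped to `[0, 1]`.
#' The network mean weight is the unweighted average over the `M^2` blocks
#' (homogeneous network, equally sized subpopulations). The `t -> Inf`
#' limit sends each block to 0 (negative rate), 1 (positive rate) or leaves
#' it at `w0` (zero rate).
#'
#' @param delta_alpha The `M - 1` phase lags of the PMCS pattern.
#' @param f Stimulation frequency (Hz).
#' @param xi Delay difference (ms).
#' @param densities An `isi_densities` object.
#' @param stdp A [stdp_parameters()] object.
#' @param w0 Pre-stimulation block means: scalar or `M x M` matrix.
#' @param t Forecast horizon(s) in seconds after stimulation onset.
#' @param t0 Stimulation onset (s).
#' @param k_range Cycle-offset truncation, as in
#'   [mean_rate_of_weight_change()].
#' @return An object of class `weight_forecast`: `J_matrix` (`M x M`),
#'   `Dphi`, `w0`, `block_weights` (list of `M x M` matrices, one per `t`),
#'   `mean_weight` (per `t`), `block_weights_inf` and `mean_weight_inf`.
#' @export
forecast_blocks <- function(delta_alpha, f, xi, densities,
                            stdp = stdp_parameters(), w0, t, t0 = 0,
                            k_range = c(-5L, 5L)) {
  M <- length(delta_alpha) + 1L
  if (length(w0) == 1L) w0 <- matrix(w0, M, M)
  if (any(w0 < 0 | w0 > 1)) stop("'w0' entries must lie in [0, 1]")
  if (any(t < t0)) stop("forecast times must not precede 't0'")
  Dphi <- phase_shift_matrix(delta_alpha)
  # J depends on the phase shift only; evaluate once per distinct value
  vals <- sort(unique(as.vector(Dphi)))
  Jv <- vapply(vals, function(p) {
    mean_rate_of_weight_change(p, f, xi, densities, stdp, k_range)$J
  }, numeric(1))
  J <- matrix(Jv[match(as.vector(Dphi), vals)], M, M)
  S <- matrix(linear_growth(as.vector(J), as.vector(w0)), M, M)
  blocks <- lapply(t, function(tt) {
    b <- w0 + S * (tt - t0)
    b[b < 0] <- 0
    b[b > 1] <- 1
    b
  })
  winf <- ifelse(J > 0, 1, ifelse(J < 0, 0, w0))
  structure(list(delta_alpha = delta_alpha, f = f, xi = xi,
                 Dphi = Dphi, J_matrix = J, w0 = w0, t = t, t0 = t0,
                 block_weights = blocks,
                 mean_weight = vapply(blocks, mean, numeric(1)),
                 block_weights_inf = winf,
                 mean_weight_inf = mean(winf)),
            class = "weight_forecast")
}

#' @export
print.weight_forecast <- function(x, ...) {
  cat(sprintf("<weight_forecast> M = %d, f = %g Hz, xi = %g ms\n",
              nrow(x$J_matrix), x$f, x$xi))
  cat("J matrix (per s):\n"); print(round(x$J_matrix, 5))
  cat(sprintf("mean weight at t = %s s: %s\n",
              paste(x$t, collapse = ", "),
              paste(round(x$mean_weight, 4), collapse = ", ")))
  invisible(x)
}

#' Monte-Carlo pairing oracle for the mean rate of weight change
#'
#' Direct simulation of the pairing sum that defines the rate of weight
#' change: one presynaptic and one independent postsynaptic spike train are
#' sampled from the same stimulus-locked densities (the postsynaptic
#' stimulus train shifted by `phi` cycles), the nearest-neighbour
#' arrival scheme is replayed event by event without clipping, and the
#' total update is divided by the total time. Used as an independent check
#' of [mean_rate_of_weight_change()].
#'
#' @inheritParams mean_rate_of_weight_change
#' @param n_cycles Number of stimulation cycles sampled.
#' @param seed Integer seed.
#' @return List with `J` (per second), `total` (weight units),
#'   `n_pairings`, and `duration_s`.
#' @export
bruteforce_rate_oracle <- function(densities, phi, f, xi,
                                   stdp = stdp_parameters(), n_cycles, seed) {
  isi <- if (inherits(densities, "isi_densities")) densities else densities$isi
  T_ms <- 1000 / f
  pre <- generate_locked_trains(isi, 1L, n_cycles, seed)
  post <- generate_locked_trains(isi, 1L, n_cycles, seed + 1L,
                                 t_offset = phi * T_ms)
  # arrival times at the synapse: only the delay difference matters
  ev_t <- c(pre$time + xi, post$time)
  ev_kind <- c(rep(1L, nrow(pre)), rep(0L, nrow(post)))  # post (0) before pre
  o <- order(ev_t, ev_kind)
  ev_t <- ev_t[o]; ev_kind <- ev_kind[o]
  last_pre <- -Inf; last_post <- -Inf
  total <- 0; n_pair <- 0L
  for (q in seq_along(ev_t)) {
    if (ev_kind[q] == 1L) {                  # presynaptic arrival
      if (is.finite(last_post)) {
        total <- total + stdp_function(last_post - ev_t[q], stdp)
        n_pair <- n_pair + 1L
      }
      last_pre <- ev_t[q]
    } else {                                 # postsynaptic arrival
      if (is.finite(last_pre)) {
        total <- total + stdp_function(ev_t[q] - last_pre, stdp)
        n_pair <- n_pair + 1L
      }
      last_post <- ev_t[q]
    }
  }
  dur_s <- n_cycles * T_ms / 1000
  list(J = total / dur_s, total = total, n_pairings = n_pair,
       duration_s = dur_s)
}
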