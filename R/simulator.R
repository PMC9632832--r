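#' Simulation configuration
#'
#' @param h Integration step (ms) of the forward-Euler scheme.
#' @param duration_s Simulated time (seconds).
#' @param seed Integer seed for the run's random number stream (Poisson
#'   background input and any stochastic schedule).
#' @param record_block_means_every Interval (ms) at which block-mean weights
#'   and the mean weight are recorded; must be a multiple of `h`. Set to
#'   `NA` to disable.
#' @param record_spikes Record spike times?
#' @param record_spikes_from Absolute time (ms) from which spikes are kept
#'   (limits memory in long runs).
#' @param snapshot_times_ms Absolute times (ms) at which full weight-vector
#'   snapshots are taken.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(h = 0.1, duration_s, seed = 1L,
                              record_block_means_every = 50,
                              record_spikes = TRUE,
                              record_spikes_from = -Inf,
                              snapshot_times_ms = numeric(0)) {
  if (h <= 0) stop("'h' must be positive")
  if (duration_s < 0) stop("'duration_s' must be non-negative")
  if (!is.na(record_block_means_every)) {
    r <- record_block_means_every / h
    if (abs(r - round(r)) > 1e-6) {
      stop("'record_block_means_every' must be a multiple of 'h'")
    }
  }
  structure(list(h = h, duration_s = duration_s, seed = as.integer(seed),
                 record_block_means_every = record_block_means_every,
                 record_spikes = record_spikes,
                 record_spikes_from = record_spikes_from,
                 snapshot_times_ms = snapshot_times_ms),
            class = "simulation_config")
}

#' Stimulation schedule for a simulation run
#'
#' Pairs a stimulus waveform with per-subpopulation onset times. All
#' neurons of a target subpopulation receive the identical stimulation
#' current; neurons outside receive none. If consecutive stimuli overlap in
#' time (e.g. a burst longer than the cycle), their currents sum and a
#' warning is issued.
#'
#' @param shape A [stimulus_shape()] object.
#' @param onsets List of per-subpopulation onset time vectors (ms), as from
#'   [pmcs_onsets()] or [crs_rvs_onsets()]; use an empty vector for an
#'   unstimulated subpopulation.
#' @return An object of class `stim_schedule`.
#' @export
stim_schedule <- function(shape, onsets) {
  stopifnot(inherits(shape, "stimulus_shape"))
  onsets <- lapply(onsets, function(o) sort(as.numeric(o)))
  gaps <- unlist(lapply(onsets, function(o) if (length(o) > 1) diff(o)))
  if (length(gaps) && any(gaps < shape$duration - 1e-9)) {
    warning("consecutive stimuli overlap; their currents are summed")
  }
  structure(list(shape = shape, onsets = onsets), class = "stim_schedule")
}

null_schedule <- function(M) {
  # zero-amplitude placeholder: no subpopulation receives current
  structure(list(
    shape = list(A_e = 0, A_i = 0, nu_e = 0.1, nu_i = 0.1, T_intra = 1,
                 n_pulses = 1L, duration = 0.2),
    onsets = rep(list(numeric(0)), M)), class = "stim_schedule")
}

#' Advance a plastic LIF network
#'
#' Integrates the network with the forward-Euler method: the membrane
#' potential follows the leak, synaptic, noise and stimulation currents;
#' the adaptive threshold relaxes towards its resting value; synaptic and
#' noise conductances decay exponentially and jump on (delayed) spike
#' arrivals (`kappa * w / N` per presynaptic spike, `kappa_noise` per
#' Poisson noise event). A threshold crossing emits a spike: the membrane
#' is held at `V_spike` for `tau_spike`, then reset to `V_reset` with the
#' threshold lifted to `V_th_spike`. Emitted spikes are delivered to the
#' synapses one axonal delay later, where the event-driven
#' nearest-neighbour STDP scheme updates the weights (hard bounds at 0 and
#' 1). Spike times are recorded on the integration grid; spikes still in
#' flight at the end of a run are carried in the returned state, so a run
#' can be split into consecutive segments.
#'
#' @param network A `network_state` from [build_network()] (or a previous
#'   run's `state`).
#' @param schedule A [stim_schedule()], or `NULL` for no stimulation.
#' @param config A [simulation_config()].
#' @param stdp A [stdp_parameters()] object; use `eta = 0` to freeze all
#'   weights.
#' @return An object of class `simulation_record`: `spikes` (data.frame
#'   `neuron`, `time` ms), `block_trace` (data.frame `time`, one column per
#'   directed block `x -> y`), `mean_weight_trace` (data.frame `time`,
#'   `mean_w`), `snapshots` (list of weight vectors) with
#'   `snapshot_times`, the advanced `state`, and the resolved `config`.
#' @export
simulate_network <- function(network, schedule = NULL, config,
                             stdp = stdp_parameters()) {
  stopifnot(inherits(network, "network_state"),
            inherits(config, "simulation_config"))
  np <- network$neuron_params
  nc <- network$net_config
  N <- nc$N
  M <- length(network$partition)
  if (is.null(schedule)) schedule <- null_schedule(M)
  stopifnot(inherits(schedule, "stim_schedule"))
  if (length(schedule$onsets) != M) {
    stop("schedule must provide onsets for each of the M subpopulations")
  }

  h <- config$h
  n_steps <- round(config$duration_s * 1000 / h)
  membership <- integer(N)
  membership[] <- -1L
  for (s in seq_len(M)) membership[network$partition[[s]]] <- s - 1L

  stim <- list(membership = membership,
               onsets = schedule$onsets,
               A_e = schedule$shape$A_e, A_i = schedule$shape$A_i,
               nu_e = schedule$shape$nu_e, nu_i = schedule$shape$nu_i,
               T_intra = schedule$shape$T_intra,
               n_pulses = as.integer(schedule$shape$n_pulses),
               duration = schedule$shape$duration)

  block_every <- if (is.na(config$record_block_means_every)) -1L else
    as.integer(round(config$record_block_means_every / h))
  snap_steps <- sort(round((config$snapshot_times_ms - network$time) / h))
  snap_steps <- snap_steps[snap_steps >= 1 & snap_steps <= n_steps]

  pending <- network$pending
  if (is.null(pending)) pending <- list(es = numeric(0), neuron = integer(0))

  set.seed(config$seed)
  res <- lif_run_cpp(network$V, network$V_th, network$g_syn, network$g_noise,
                     network$C, network$plateau,
                     network$edge_pre - 1L, network$edge_post - 1L,
                     network$w, network$last_pre, network$last_post,
                     unclass(np), unclass(nc), unclass(stdp), stim,
                     h, n_steps, network$time,
                     config$record_spikes, config$record_spikes_from,
                     block_every,
                     lapply(network$partition, function(p) p - 1L),
                     as.numeric(snap_steps),
                     pending$es, as.integer(pending$neuron))

  state <- network
  state$V <- res$V; state$V_th <- res$V_th
  state$g_syn <- res$g_syn; state$g_noise <- res$g_noise
  state$plateau <- res$plateau
  state$w <- res$w
  state$last_pre <- res$last_pre; state$last_post <- res$last_post
  state$time <- res$time
  state$pending <- list(es = res$pending_es, neuron = res$pending_neuron)

  nb <- M * M
  bt <- if (length(res$block_times)) {
    bm <- matrix(res$block_vals, ncol = nb, byrow = TRUE)
    colnames(bm) <- paste0("w_", rep(seq_len(M), each = M), "_",
                           rep(seq_len(M), times = M))
    # C++ stores blocks as x * M + y (row-major); columns above follow suit
    data.frame(time = res$block_times, bm, check.names = FALSE)
  } else {
    data.frame(time = numeric(0))
  }

  structure(list(
    spikes = data.frame(neuron = res$spike_neuron, time = res$spike_time),
    block_trace = bt,
    mean_weight_trace = data.frame(time = res$block_times,
                                   mean_w = res$mean_w),
    snapshots = res$snapshots,
    snapshot_times = res$snapshot_times,
    state = state,
    config = config,
    stdp = stdp,
    schedule_shape = schedule$shape
  ), class = "simulation_record")
}

#' @export
print.simulation_record <- function(x, ...) {
  cat(sprintf("<simulation_record> %d spikes, t = %.1f ms, mean w = %.4f\n",
              nrow(x$spikes), x$state$time,
              if (length(x$state$w)) mean(x$state$w) else NA_real_))
  invisible(x)
}

#' Relax a network to its stationary state
#'
#' Runs the network without stimulation until STDP has driven the weight
#' distribution to its stationary bimodal form — the strongly connected
#' synchronised state that serves as the pre-stimulation condition. Logs
#' the final mean weight, the fraction of weights at the hard bounds, and
#' the collective-event rate over the final part of the run.
#'
#' @param network A `network_state`.
#' @param duration_s Relaxation time (seconds).
#' @param seed Seed for the run.
#' @param stdp STDP parameters.
#' @param h Integration step (ms).
#' @param qc_window_s Trailing window (seconds) used for the logged
#'   collective-event rate.
#' @param quiet Suppress the log message?
#' @return The relaxed `network_state`, with attributes `mean_w`,
#'   `bound_fraction` and `event_rate`.
#' @export
relax_to_stationary <- function(network, duration_s, seed,
                                stdp = stdp_parameters(), h = 0.1,
                                qc_window_s = 100, quiet = FALSE) {
  t_end <- network$time + duration_s * 1000
  cfg <- simulation_config(h = h, duration_s = duration_s, seed = seed,
                           record_spikes_from = t_end - qc_window_s * 1000)
  rec <- simulate_network(network, NULL, cfg, stdp)
  st <- rec$state
  mw <- if (length(st$w)) mean(st$w) else NA_real_
  bf <- if (length(st$w)) mean(st$w < 0.05 | st$w > 0.95) else NA_real_
  ev <- detect_collective_events(rec$spikes, st$net_config$N,
                                 t_start = t_end - qc_window_s * 1000,
                                 t_end = t_end)
  if (!quiet) {
    message(sprintf(
      "relaxed %g s: mean weight %.4f, %.1f%% of weights at bounds, %.2f collective events/s",
      duration_s, mw, 100 * bf, ev$rate))
  }
  attr(st, "mean_w") <- mw
  attr(st, "bound_fraction") <- bf
  attr(st, "event_rate") <- ev$rate
  st
}
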