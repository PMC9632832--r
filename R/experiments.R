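#' Build and relax a network at a given scale
#'
#' Convenience constructor for the pre-stimulation condition used by the
#' experiment drivers: a network with the default tonically spiking neuron
#' profile is built and relaxed without stimulation until its weight
#' distribution is stationary and bimodal. The default desk scale (300
#' neurons, 600 s of relaxation) reproduces the stationary statistics of
#' the full-scale system (1000 neurons, 3000 s) within sampling tolerance
#' at a fraction of the cost; pass `N = 1000, relax_s = 3000` for the
#' full-scale protocol.
#'
#' @param N Network size.
#' @param M Number of subpopulations.
#' @param relax_s Relaxation duration (seconds).
#' @param seed Integer seed (network construction uses `seed`, the
#'   relaxation run `seed + 1`).
#' @param stdp STDP parameters.
#' @param quiet Suppress the relaxation log line?
#' @return The relaxed `network_state` (with QC attributes, see
#'   [relax_to_stationary()]).
#' @export
prepare_relaxed_network <- function(N = 300, M = 3, relax_s = 600, seed = 1,
                                    stdp = stdp_parameters(), quiet = FALSE) {
  net <- build_network(neuron_parameters(),
                       network_config(N = N, M = M), seed)
  relax_to_stationary(net, relax_s, seed + 1, stdp = stdp, quiet = quiet)
}

#' Relaxation protocol: stationary state statistics
#'
#' Builds and relaxes one network per seed and reports the stationary
#' mean weight, the fraction of weights at the hard bounds (bimodality),
#' and the collective-event rate.
#'
#' @param N,M,relax_s Scale parameters, as in [prepare_relaxed_network()].
#' @param seeds Integer vector of seeds.
#' @param outdir Optional output directory for tabular results.
#' @param quiet Passed through to the relaxation.
#' @return A data.frame with one row per seed (`seed`, `mean_w`,
#'   `bound_fraction`, `event_rate`) plus the relaxed states as attribute
#'   `states`.
#' @export
run_relax <- function(N = 300, M = 3, relax_s = 600, seeds = 1:3,
                      outdir = NULL, quiet = FALSE) {
  states <- lapply(seeds, function(s) {
    prepare_relaxed_network(N = N, M = M, relax_s = relax_s, seed = s,
                            quiet = quiet)
  })
  out <- data.frame(
    seed = seeds,
    mean_w = vapply(states, attr, numeric(1), "mean_w"),
    bound_fraction = vapply(states, attr, numeric(1), "bound_fraction"),
    event_rate = vapply(states, attr, numeric(1), "event_rate"))
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(out, file.path(outdir, "relax_summary.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  attr(out, "states") <- states
  out
}

#' Spiking-response statistics under periodic stimulation
#'
#' Delivers periodic stimulation to the first subpopulation of a relaxed
#' network for each stimulus in a parameter grid and records the mean
#' number of spikes per inter-stimulus interval and neuron, together with
#' the estimated stimulus-locked densities.
#'
#' @param state A relaxed `network_state`.
#' @param grid Data.frame of stimulus parameters with columns `kind`
#'   (`"single_pulse"`/`"burst"`), `A_stim`, `d_e` and optionally `pulses`
#'   and `f_intra`.
#' @param f Stimulation frequency (Hz).
#' @param stim_s Stimulation duration per grid point (seconds).
#' @param seed Seed for the stimulation runs.
#' @param outdir Optional output directory.
#' @return The grid with an added `mean_spikes` column; the per-point
#'   `isi_densities` objects are attached as attribute `densities`.
#' @export
run_isi_stats <- function(state, grid, f = 5, stim_s = 100, seed = 1,
                          outdir = NULL) {
  stopifnot(inherits(state, "network_state"))
  dens <- vector("list", nrow(grid))
  mean_spikes <- numeric(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    shape <- stimulus_shape(
      kind = as.character(grid$kind[r]), A_stim = grid$A_stim[r],
      d_e = grid$d_e[r],
      pulses_per_burst = if ("pulses" %in% names(grid)) grid$pulses[r] else 1,
      f_intra = if ("f_intra" %in% names(grid)) grid$f_intra[r] else 120,
      neuron_params = state$neuron_params)
    est <- stimulate_and_estimate(state, shape, f, stim_s, seed)
    dens[[r]] <- est
    mean_spikes[r] <- est$mean_spikes_per_cycle
  }
  out <- cbind(grid, mean_spikes = mean_spikes)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(out, file.path(outdir, "isi_stats.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  attr(out, "densities") <- dens
  out
}

# Stimulate subpopulation 1 of `state` periodically and estimate the
# stimulus-locked conditional ISI densities from its spikes.
stimulate_and_estimate <- function(state, shape, f, stim_s, seed,
                                   bin = 0.2) {
  M <- length(state$partition)
  pat <- pmcs_pattern(f = f, M = 1)
  onsets1 <- pmcs_onsets(pat, state$time, state$time + stim_s * 1000)[[1]]
  sched <- stim_schedule(shape, c(list(onsets1),
                                  rep(list(numeric(0)), M - 1L)))
  cfg <- simulation_config(duration_s = stim_s, seed = seed,
                           record_block_means_every = NA)
  rec <- simulate_network(state, sched, cfg)
  estimate_isi_densities(rec$spikes, onsets1, f, bin = bin,
                         neurons = state$partition[[1]])
}

#' Theory versus simulation: rate of weight change for two subpopulations
#'
#' For each phase lag in `dalpha_grid`, delivers PMCS with `M = 2` to a
#' relaxed two-subpopulation network, estimates the rate of change of the
#' mean weight of synapses from subpopulation 1 to subpopulation 2
#' ([estimate_J()]), and compares it with the theoretical mean rate of
#' weight change evaluated from stimulus-locked densities estimated in a
#' separate single-population run.
#'
#' @param state A relaxed `network_state` with `M = 2`.
#' @param shape A [stimulus_shape()].
#' @param f Stimulation frequency (Hz).
#' @param dalpha_grid Phase lags to evaluate.
#' @param stim_s Stimulation duration per phase lag (seconds).
#' @param density_s Duration of the density-estimation run (seconds).
#' @param seed Base seed.
#' @param outdir Optional output directory.
#' @return Data.frame with columns `dalpha`, `J_est`, `J_theory`, plus
#'   attributes `sign_agreement` (fraction of grid points with matching
#'   sign) and `rank_correlation` (Spearman).
#' @export
run_two_pop_rate <- function(state, shape, f = 10,
                             dalpha_grid = seq(0, 0.9, by = 0.1),
                             stim_s = 40, density_s = 100, seed = 1,
                             outdir = NULL) {
  stopifnot(inherits(state, "network_state"))
  if (length(state$partition) != 2L) {
    stop("'state' must be partitioned into M = 2 subpopulations")
  }
  isi <- stimulate_and_estimate(state, shape, f, density_s, seed)
  xi <- state$net_config$t_a - state$net_config$t_d
  w0_all <- mean(state$w)

  res <- lapply(seq_along(dalpha_grid), function(q) {
    da <- dalpha_grid[q]
    pat <- pmcs_pattern(f = f, M = 2, delta_alpha = da)
    ons <- pmcs_onsets(pat, state$time, state$time + stim_s * 1000)
    sched <- stim_schedule(shape, ons)
    cfg <- simulation_config(duration_s = stim_s, seed = seed + q,
                             record_spikes = FALSE)
    rec <- simulate_network(state, sched, cfg)
    tr <- data.frame(time = rec$block_trace$time,
                     value = rec$block_trace$w_1_2)
    w0 <- tr$value[1]
    J_est <- tryCatch(estimate_J(tr, w0)$J_est,
                      error = function(e) NA_real_)
    J_th <- mean_rate_of_weight_change(da, f, xi, isi)$J
    c(J_est = J_est, J_theory = J_th)
  })
  out <- data.frame(dalpha = dalpha_grid, do.call(rbind, res))
  ok <- is.finite(out$J_est)
  attr(out, "sign_agreement") <-
    mean(sign(out$J_est[ok]) == sign(out$J_theory[ok]))
  attr(out, "rank_correlation") <-
    if (sum(ok) >= 3) stats::cor(out$J_est[ok], out$J_theory[ok],
                                 method = "spearman") else NA_real_
  attr(out, "densities") <- isi
  attr(out, "w0") <- w0_all
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(out, file.path(outdir, "two_pop_rate.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  out
}

#' Phase-lag maps of the forecast mean weight
#'
#' Sweeps the two phase lags of a three-subpopulation PMCS pattern and
#' tabulates the theoretical forecast of the mean weight at the requested
#' times, optionally alongside simulated values on a (coarser) subgrid.
#'
#' @param state A relaxed `network_state` with `M = 3`.
#' @param shape Stimulus waveform.
#' @param f Stimulation frequency (Hz).
#' @param dalpha1,dalpha2 Grids for the two phase lags.
#' @param t_eval Times (s) after onset at which the forecast is evaluated.
#' @param simulate_at Optional data.frame with columns `dalpha1`,
#'   `dalpha2`: grid points at which a simulation is also run (duration
#'   `max(t_eval)`).
#' @param seed Base seed.
#' @param density_s Density-estimation duration (s).
#' @param outdir Optional output directory.
#' @return Long data.frame: `dalpha1`, `dalpha2`, `t`, `mean_w_theory`,
#'   and `mean_w_sim` where simulated.
#' @export
run_phase_map <- function(state, shape, f = 10,
                          dalpha1 = seq(0, 0.9, by = 0.1),
                          dalpha2 = seq(0, 0.9, by = 0.1),
                          t_eval = c(20, 1000), simulate_at = NULL,
                          seed = 1, density_s = 100, outdir = NULL) {
  stopifnot(length(state$partition) == 3L)
  isi <- stimulate_and_estimate(state, shape, f, density_s, seed)
  xi <- state$net_config$t_a - state$net_config$t_d
  w0 <- block_means(state)
  rows <- list()
  for (a1 in dalpha1) for (a2 in dalpha2) {
    fc <- forecast_blocks(c(a1, a2), f, xi, isi, w0 = w0, t = t_eval)
    rows[[length(rows) + 1L]] <-
      data.frame(dalpha1 = a1, dalpha2 = a2, t = t_eval,
                 mean_w_theory = fc$mean_weight)
  }
  out <- do.call(rbind, rows)
  out$mean_w_sim <- NA_real_
  if (!is.null(simulate_at)) {
    for (r in seq_len(nrow(simulate_at))) {
      a1 <- simulate_at$dalpha1[r]; a2 <- simulate_at$dalpha2[r]
      pat <- pmcs_pattern(f = f, M = 3, delta_alpha = c(a1, a2))
      dur <- max(t_eval)
      ons <- pmcs_onsets(pat, state$time, state$time + dur * 1000)
      cfg <- simulation_config(duration_s = dur, seed = seed + r,
                               record_spikes = FALSE)
      rec <- simulate_network(state, stim_schedule(shape, ons), cfg)
      tr <- rec$mean_weight_trace
      for (tt in t_eval) {
        i <- which.min(abs(tr$time - (state$time + tt * 1000)))
        sel <- out$dalpha1 == a1 & out$dalpha2 == a2 & out$t == tt
        out$mean_w_sim[sel] <- tr$mean_w[i]
      }
    }
  }
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(out, file.path(outdir, "phase_map.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  out
}

#' Decoupling curve: mean weight versus stimulation frequency
#'
#' For a fixed PMCS pattern, sweeps the stimulation frequency and records
#' the simulated mean weight after the requested stimulation times.
#'
#' @param state A relaxed `network_state`.
#' @param shape Stimulus waveform.
#' @param f_grid Stimulation frequencies (Hz).
#' @param delta_alpha Phase lags (length `M - 1`).
#' @param t_eval Times (s) after onset at which the mean weight is read.
#' @param seed Base seed.
#' @param outdir Optional output directory.
#' @return Data.frame `f`, `t`, `mean_w`.
#' @export
run_decoupling_curve <- function(state, shape, f_grid,
                                 delta_alpha = NULL, t_eval = c(20, 100),
                                 seed = 1, outdir = NULL) {
  M <- length(state$partition)
  if (is.null(delta_alpha)) delta_alpha <- numeric(M - 1)
  rows <- list()
  for (q in seq_along(f_grid)) {
    f <- f_grid[q]
    pat <- pmcs_pattern(f = f, M = M, delta_alpha = delta_alpha)
    dur <- max(t_eval)
    ons <- pmcs_onsets(pat, state$time, state$time + dur * 1000)
    cfg <- simulation_config(duration_s = dur, seed = seed + q,
                             record_spikes = FALSE)
    rec <- simulate_network(state, stim_schedule(shape, ons), cfg)
    tr <- rec$mean_weight_trace
    for (tt in t_eval) {
      i <- which.min(abs(tr$time - (state$time + tt * 1000)))
      rows[[length(rows) + 1L]] <-
        data.frame(f = f, t = tt, mean_w = tr$mean_w[i])
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(out, file.path(outdir, "decoupling_curve.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  out
}

#' Motif induction: drive the network towards a target block structure
#'
#' Delivers a PMCS pattern and classifies every block of the final weight
#' matrix as up-regulated (block mean above `w0 + margin`), down-regulated
#' (below `w0 - margin`) or unchanged, optionally comparing against a
#' target motif matrix.
#'
#' @param state A relaxed `network_state`.
#' @param shape Stimulus waveform.
#' @param f Stimulation frequency (Hz).
#' @param delta_alpha Phase lags (length `M - 1`).
#' @param stim_s Stimulation duration (seconds).
#' @param margin Classification margin around the pre-stimulation mean.
#' @param target Optional `M x M` matrix with entries `"up"`, `"down"` or
#'   `"none"`.
#' @param seed Seed.
#' @param outdir Optional output directory.
#' @return List with `blocks` (final block means), `w0`, `classes`
#'   (character matrix), `match` (logical, if `target` given) and the
#'   final `state`.
#' @export
run_motif <- function(state, shape, f, delta_alpha, stim_s = 150,
                      margin = 0.2, target = NULL, seed = 1,
                      outdir = NULL) {
  M <- length(state$partition)
  pat <- pmcs_pattern(f = f, M = M, delta_alpha = delta_alpha)
  ons <- pmcs_onsets(pat, state$time, state$time + stim_s * 1000)
  cfg <- simulation_config(duration_s = stim_s, seed = seed,
                           record_spikes = FALSE)
  rec <- simulate_network(state, stim_schedule(shape, ons), cfg)
  w0 <- mean(state$w)
  blocks <- block_means(rec$state)
  classes <- matrix("none", M, M)
  classes[blocks > w0 + margin] <- "up"
  classes[blocks < w0 - margin] <- "down"
  res <- list(blocks = blocks, w0 = w0, classes = classes,
              state = rec$state)
  if (!is.null(target)) res$match <- all(classes == target)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    df <- data.frame(x = rep(seq_len(M), M), y = rep(seq_len(M), each = M),
                     block_mean = as.vector(blocks),
                     class = as.vector(classes))
    utils::write.table(df, file.path(outdir, "motif_blocks.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  res
}
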