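#' Neuron parameters for the excitatory LIF model
#'
#' Bundles the single-neuron constants of the conductance-based leaky
#' integrate-and-fire model: a leak current towards `V_rest`, excitatory
#' synaptic and noise conductances reversing at `V_syn`, an adaptive spike
#' threshold relaxing towards `V_th_rest` with time constant `tau_th`, and a
#' spike plateau at `V_spike` of duration `tau_spike` followed by a reset to
#' `V_reset` with the threshold lifted to `V_th_spike`.
#'
#' The defaults are the tonically spiking parameter profile used throughout
#' the package: with `V_rest` above `V_th_rest`, an isolated neuron drifts
#' through its resting threshold and fires periodically, as observed for
#' neurons of the rat subthalamic nucleus. `V_spike` and `tau_spike` describe
#' the spike plateau; they only shape the emitted waveform and the absolute
#' refractory period.
#'
#' @param g_leak Leak conductance density (mS/cm^2).
#' @param V_rest Resting potential (mV).
#' @param V_reset Post-spike reset potential (mV).
#' @param V_syn Excitatory reversal potential (mV), shared by synaptic and
#'   noise conductances.
#' @param V_th_spike Threshold value immediately after a spike (mV).
#' @param V_th_rest Resting threshold (mV).
#' @param V_spike Spike plateau potential (mV).
#' @param tau_th Threshold relaxation time constant (ms).
#' @param tau_syn Synaptic (and noise) conductance decay time constant (ms).
#' @param tau_spike Spike plateau duration (ms); also the absolute refractory
#'   period.
#' @param mu_C Mean membrane capacitance (uF/cm^2).
#' @param sigma_C_rel Relative standard deviation of the capacitance
#'   (dimensionless); capacitances are Gaussian with sd `sigma_C_rel * mu_C`,
#'   truncated at `0.1 * mu_C` to guarantee positivity.
#' @return An object of class `neuron_parameters`.
#' @export
neuron_parameters <- function(g_leak = 0.02, V_rest = -38, V_reset = -67,
                              V_syn = 0, V_th_spike = 0, V_th_rest = -40,
                              V_spike = 20, tau_th = 5, tau_syn = 1,
                              tau_spike = 1, mu_C = 3, sigma_C_rel = 0.05) {
  p <- list(g_leak = g_leak, V_rest = V_rest, V_reset = V_reset, V_syn = V_syn,
            V_th_spike = V_th_spike, V_th_rest = V_th_rest, V_spike = V_spike,
            tau_th = tau_th, tau_syn = tau_syn, tau_spike = tau_spike,
            mu_C = mu_C, sigma_C_rel = sigma_C_rel)
  for (nm in c("g_leak", "tau_th", "tau_syn", "tau_spike", "mu_C")) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || p[[nm]] <= 0) {
      stop(sprintf("'%s' must be a single positive number", nm))
    }
  }
  if (sigma_C_rel < 0) stop("'sigma_C_rel' must be non-negative")
  if (!(V_reset < V_th_rest && V_th_rest < V_th_spike)) {
    stop("require V_reset < V_th_rest < V_th_spike")
  }
  structure(p, class = "neuron_parameters")
}

#' Network construction parameters
#'
#' @param N Number of neurons.
#' @param p_conn Probability of a directed synaptic connection between any
#'   ordered pair of distinct neurons.
#' @param kappa Maximal coupling strength (mS/cm^2); a presynaptic spike at a
#'   synapse of weight `w` raises the postsynaptic conductance by
#'   `kappa * w / N`.
#' @param t_a Axonal delay (ms): time for a presynaptic spike to reach the
#'   synapse.
#' @param t_d Dendritic delay (ms): time for the backpropagating postsynaptic
#'   spike to reach the synapse. The simulator supports any non-negative
#'   multiple of the integration step; the default is 0.
#' @param kappa_noise Conductance jump per noise event (mS/cm^2).
#' @param f_noise Per-neuron Poisson noise rate (Hz).
#' @param M Number of stimulated subpopulations the network is partitioned
#'   into.
#' @return An object of class `network_config`.
#' @export
network_config <- function(N = 1000, p_conn = 0.07, kappa = 8, t_a = 3,
                           t_d = 0, kappa_noise = 0.026, f_noise = 20, M = 3) {
  if (N < 1 || N != round(N)) stop("'N' must be a positive integer")
  if (p_conn < 0 || p_conn > 1) stop("'p_conn' must lie in [0, 1]")
  if (kappa < 0 || kappa_noise < 0 || f_noise < 0) {
    stop("'kappa', 'kappa_noise' and 'f_noise' must be non-negative")
  }
  if (t_a < 0 || t_d < 0) stop("delays must be non-negative")
  if (M < 1 || M != round(M)) stop("'M' must be a positive integer")
  if (N <= M) stop("'N' must exceed the number of subpopulations 'M'")
  structure(list(N = as.integer(N), p_conn = p_conn, kappa = kappa,
                 t_a = t_a, t_d = t_d, kappa_noise = kappa_noise,
                 f_noise = f_noise, M = as.integer(M)),
            class = "network_config")
}

#' Partition neurons into stimulation subpopulations
#'
#' Splits indices `1..N` into `M` contiguous, disjoint blocks of maximally
#' balanced sizes (larger blocks first when `N` is not divisible by `M`).
#' Because connectivity is homogeneous, spatial adjacency is induced purely
#' by this index grouping.
#'
#' @param N Number of neurons.
#' @param M Number of subpopulations.
#' @return A list of `M` integer vectors of neuron indices.
#' @export
assign_subpopulations <- function(N, M) {
  if (M > N) stop("'M' must not exceed 'N'")
  if (M < 1) stop("'M' must be at least 1")
  sizes <- rep(N %/% M, M)
  extra <- N %% M
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  lapply(seq_len(M), function(k) seq.int(starts[k], ends[k]))
}

#' Build a random network state
#'
#' Constructs the directed synaptic graph and the initial dynamical state.
#' Every ordered pair (i, j), i != j, is connected independently with
#' probability `p_conn`. Initial weights are bimodal: each synapse starts at
#' 0 or 1 with probability one half, giving mean initial weight 0.5; this
#' initial distribution speeds up relaxation but is otherwise immaterial, as
#' networks are relaxed to a stationary state before stimulation.
#' Capacitances are Gaussian around `mu_C` (sd `sigma_C_rel * mu_C`),
#' truncated below at `0.1 * mu_C`. Membrane potentials start uniformly in
#' `[V_reset, V_th_rest]` and thresholds at `V_th_rest` — an arbitrary but
#' fixed convention, washed out during relaxation.
#'
#' @param neuron_params A [neuron_parameters()] object.
#' @param net_config A [network_config()] object.
#' @param seed Integer seed; identical seeds give bit-identical states.
#' @return An object of class `network_state` with fields `V`, `V_th`,
#'   `g_syn`, `g_noise`, `C`, `plateau` (remaining plateau time, ms),
#'   `edge_pre`, `edge_post` (1-based endpoints of every synapse), `w`
#'   (weights in `[0, 1]`), `last_pre`, `last_post` (most recent STDP arrival
#'   times at each synapse, ms; `-Inf` when none), `time` (state time, ms),
#'   plus the parameter objects and the subpopulation partition.
#' @export
build_network <- function(neuron_params, net_config, seed) {
  stopifnot(inherits(neuron_params, "neuron_parameters"),
            inherits(net_config, "network_config"))
  if (length(seed) != 1L || seed < 0 || seed != round(seed)) {
    stop("'seed' must be a single non-negative integer")
  }
  N <- net_config$N
  set.seed(as.integer(seed))

  # adjacency: sample the N*(N-1) ordered off-diagonal pairs
  pre <- rep.int(seq_len(N), N)
  post <- rep(seq_len(N), each = N)
  keep <- pre != post
  pre <- pre[keep]; post <- post[keep]
  if (net_config$p_conn > 0) {
    sel <- stats::runif(length(pre)) < net_config$p_conn
  } else {
    sel <- rep(FALSE, length(pre))
  }
  edge_pre <- pre[sel]
  edge_post <- post[sel]
  n_syn <- length(edge_pre)

  w <- as.numeric(stats::runif(n_syn) < 0.5)

  C <- stats::rnorm(N, neuron_params$mu_C,
                    neuron_params$sigma_C_rel * neuron_params$mu_C)
  lo <- 0.1 * neuron_params$mu_C
  while (any(C < lo)) {
    bad <- C < lo
    C[bad] <- stats::rnorm(sum(bad), neuron_params$mu_C,
                           neuron_params$sigma_C_rel * neuron_params$mu_C)
  }

  V <- stats::runif(N, neuron_params$V_reset, neuron_params$V_th_rest)

  structure(list(
    V = V,
    V_th = rep(neuron_params$V_th_rest, N),
    g_syn = rep(0, N),
    g_noise = rep(0, N),
    C = C,
    plateau = rep(0, N),
    edge_pre = as.integer(edge_pre),
    edge_post = as.integer(edge_post),
    w = w,
    last_pre = rep(-Inf, n_syn),
    last_post = rep(-Inf, n_syn),
    time = 0,
    neuron_params = neuron_params,
    net_config = net_config,
    partition = assign_subpopulations(N, net_config$M),
    seed = as.integer(seed)
  ), class = "network_state")
}

#' @export
print.network_state <- function(x, ...) {
  cat(sprintf("<network_state> N = %d, synapses = %d, M = %d, time = %.1f ms\n",
              x$net_config$N, length(x$w), x$net_config$M, x$time))
  if (length(x$w)) {
    cat(sprintf("  mean weight = %.4f, weights near bounds = %.1f%%\n",
                mean(x$w), 100 * mean(x$w < 0.05 | x$w > 0.95)))
  }
  invisible(x)
}

#' Read and write resolved parameter configurations
#'
#' Model, stimulation and run parameters are serialised as sectioned YAML so
#' every run can dump the fully resolved parameter set next to its outputs
#' for provenance, and a run can be rebuilt from that file.
#'
#' @param neuron_params,net_config,stdp_params,extra Parameter objects (and
#'   an optional named list of additional entries) to serialise.
#' @param path File path of the YAML configuration.
#' @return `write_config` returns `path` invisibly; `read_config` returns a
#'   list with elements `neuron_params`, `net_config`, `stdp_params` and
#'   `extra`.
#' @export
write_config <- function(path, neuron_params, net_config,
                         stdp_params = NULL, extra = NULL) {
  cfg <- list(neuron = unclass(neuron_params), network = unclass(net_config))
  if (!is.null(stdp_params)) cfg$stdp <- unclass(stdp_params)
  if (!is.null(extra)) cfg$extra <- extra
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  keep_formals <- function(x, fun) x[names(x) %in% names(formals(fun))]
  out <- list(
    neuron_params = do.call(neuron_parameters,
                            keep_formals(cfg$neuron, neuron_parameters)),
    net_config = do.call(network_config,
                         keep_formals(cfg$network, network_config))
  )
  out$stdp_params <- if (!is.null(cfg$stdp)) {
    do.call(stdp_parameters, keep_formals(cfg$stdp, stdp_parameters))
  }
  out$extra <- cfg$extra
  out
}
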