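#' Charge-balanced stimulus waveforms
#'
#' A stimulus is either a single charge-balanced pulse or a burst of such
#' pulses at a fixed intraburst frequency. Each pulse consists of an
#' excitatory rectangular lobe of duration `nu_e = 0.4 * d_e` ms immediately
#' followed by an inhibitory rectangular lobe of duration `nu_i = 0.8 * d_e`
#' ms (no gap). Amplitudes are set so that each pulse is exactly
#' charge-balanced and so that one excitatory lobe delivers the charge
#' needed to depolarise the average neuron by `A_stim` times the
#' reset-to-threshold voltage distance:
#' `A_e = A_stim * mu / nu_e`, `A_i = -A_stim * mu / nu_i`, with
#' `mu = (V_th_spike - V_reset) * mean(C)` the charge density (per cm^2)
#' separating reset from the spiking threshold. `A_stim` is therefore
#' dimensionless: `A_stim = 1` lifts the mean neuron from `V_reset` to
#' `V_th_spike` within one excitatory lobe.
#'
#' @param kind `"single_pulse"` or `"burst"`.
#' @param A_stim Dimensionless stimulation strength.
#' @param d_e Dimensionless pulse-width factor.
#' @param pulses_per_burst Number of pulses per burst (>= 1; forced to 1 for
#'   single pulses).
#' @param f_intra Intraburst pulse repetition frequency (Hz; bursts only).
#' @param neuron_params A [neuron_parameters()] object supplying
#'   `V_th_spike`, `V_reset` and `mu_C` for the amplitude normalisation.
#' @return An object of class `stimulus_shape` with derived fields `nu_e`,
#'   `nu_i` (ms), `A_e`, `A_i` (uA/cm^2), `n_pulses`, `T_intra` (ms) and
#'   `duration` (ms, total stimulus support).
#' @export
stimulus_shape <- function(kind = c("single_pulse", "burst"), A_stim, d_e,
                           pulses_per_burst = 1, f_intra = 120,
                           neuron_params = neuron_parameters()) {
  kind <- match.arg(kind)
  if (A_stim < 0) stop("'A_stim' must be non-negative")
  if (d_e <= 0) stop("'d_e' must be positive")
  n_pulses <- if (kind == "single_pulse") 1L else as.integer(pulses_per_burst)
  if (n_pulses < 1L) stop("'pulses_per_burst' must be >= 1")
  nu_e <- 0.4 * d_e
  nu_i <- 0.8 * d_e
  T_intra <- if (n_pulses > 1L) 1000 / f_intra else nu_e + nu_i
  if (n_pulses > 1L) {
    if (f_intra <= 0) stop("'f_intra' must be positive for bursts")
    if (T_intra < nu_e + nu_i) {
      stop(sprintf(paste0("intraburst period %.3f ms is shorter than the ",
                          "pulse duration %.3f ms: pulses overlap"),
                   T_intra, nu_e + nu_i))
    }
  }
  mu <- (neuron_params$V_th_spike - neuron_params$V_reset) * neuron_params$mu_C
  structure(list(kind = kind, A_stim = A_stim, d_e = d_e,
                 n_pulses = n_pulses, f_intra = f_intra,
                 nu_e = nu_e, nu_i = nu_i, T_intra = T_intra,
                 A_e = A_stim * mu / nu_e, A_i = -A_stim * mu / nu_i,
                 duration = (n_pulses - 1L) * T_intra + nu_e + nu_i),
            class = "stimulus_shape")
}

#' Stimulation current of a single stimulus
#'
#' Evaluates the stimulus current density at times after stimulus onset.
#' Pulse `p` (0-based) starts at `p * 1000 / f_intra` ms; within a pulse the
#' current is `A_e` during the excitatory lobe, `A_i` during the inhibitory
#' lobe, and 0 elsewhere. The time integral over the full stimulus is zero
#' (charge balance).
#'
#' @param shape A [stimulus_shape()] object.
#' @param t_since_onset Numeric vector of times since stimulus onset (ms);
#'   must be non-negative.
#' @return Current density (uA/cm^2), same length as `t_since_onset`.
#' @export
stimulus_current <- function(shape, t_since_onset) {
  stopifnot(inherits(shape, "stimulus_shape"))
  if (any(t_since_onset < 0)) stop("'t_since_onset' must be non-negative")
  p <- floor(t_since_onset / shape$T_intra)
  tau <- t_since_onset - p * shape$T_intra
  out <- numeric(length(t_since_onset))
  in_pulse <- p < shape$n_pulses
  out[in_pulse & tau < shape$nu_e] <- shape$A_e
  out[in_pulse & tau >= shape$nu_e & tau < shape$nu_e + shape$nu_i] <- shape$A_i
  out
}

#' PMCS delivery pattern
#'
#' Periodic multichannel stimulation delivers one stimulus per cycle of
#' duration `1/f` to each of `M` subpopulations. Onset phases are
#' `alpha_1 = 0` and `alpha_{k+1} = alpha_k + delta_alpha_k`; results depend
#' on the phase lags only modulo one, so phases are reduced to `[0, 1)`
#' before scheduling.
#'
#' @param f Stimulation frequency (Hz).
#' @param M Number of subpopulations.
#' @param delta_alpha Numeric vector of the `M - 1` phase lags between
#'   stimulus trains delivered to subpopulations with adjacent indices
#'   (cycle fractions).
#' @return An object of class `pmcs_pattern` with the onset phases `alpha`
#'   (length `M`, reduced modulo 1).
#' @export
pmcs_pattern <- function(f, M, delta_alpha = numeric(M - 1)) {
  if (f <= 0) stop("'f' must be positive")
  if (M < 1) stop("'M' must be at least 1")
  if (length(delta_alpha) != M - 1) {
    stop(sprintf("'delta_alpha' must have length M - 1 = %d", M - 1))
  }
  alpha <- c(0, cumsum(delta_alpha)) %% 1
  structure(list(f = f, M = as.integer(M), delta_alpha = delta_alpha,
                 alpha = alpha), class = "pmcs_pattern")
}

#' Stimulus onset times of a PMCS pattern
#'
#' Subpopulation `k` receives onsets at `(n + alpha_k) / f` seconds for all
#' integers `n` placing the onset in `[t_start, t_end)`: exactly one onset
#' per subpopulation per cycle.
#'
#' @param pattern A [pmcs_pattern()] object.
#' @param t_start,t_end Window (ms); `t_end > t_start`.
#' @return A list of `M` numeric vectors of onset times (ms), sorted.
#' @export
pmcs_onsets <- function(pattern, t_start, t_end) {
  stopifnot(inherits(pattern, "pmcs_pattern"))
  if (t_end <= t_start) stop("'t_end' must exceed 't_start'")
  T_ms <- 1000 / pattern$f
  lapply(seq_len(pattern$M), function(k) {
    off <- pattern$alpha[k] * T_ms
    n0 <- ceiling((t_start - off) / T_ms)
    n1 <- floor((t_end - off) / T_ms)
    if (n1 < n0) return(numeric(0))
    t <- seq.int(n0, n1) * T_ms + off
    t[t >= t_start & t < t_end]
  })
}

#' Onset times for coordinated reset with rapidly varying sequence
#'
#' CRS RVS assigns, within every cycle of duration `1/f`, the `M` slot
#' phases `0, 1/M, ..., (M-1)/M` to the `M` subpopulations by an independent
#' uniform random permutation, so each subpopulation receives exactly one
#' stimulus per cycle but the delivery order is reshuffled every cycle.
#'
#' @param pattern A [pmcs_pattern()] object (only `f` and `M` are used).
#' @param n_cycles Number of cycles to schedule, starting at time 0.
#' @param seed Integer seed for the per-cycle permutations.
#' @return A list of `M` numeric vectors of onset times (ms), sorted.
#' @export
crs_rvs_onsets <- function(pattern, n_cycles, seed) {
  stopifnot(inherits(pattern, "pmcs_pattern"))
  if (n_cycles < 1) stop("'n_cycles' must be at least 1")
  M <- pattern$M
  T_ms <- 1000 / pattern$f
  set.seed(as.integer(seed))
  slots <- matrix(0L, nrow = n_cycles, ncol = M)
  for (c in seq_len(n_cycles)) slots[c, ] <- sample.int(M)
  # slots[c, k]: slot index (1..M) of subpopulation k in cycle c
  lapply(seq_len(M), function(k) {
    (seq_len(n_cycles) - 1) * T_ms + (slots[, k] - 1L) * T_ms / M
  })
}

#' Phase-shift matrix of a PMCS pattern
#'
#' Entry `(x, y)` is the phase shift between stimulus trains delivered to
#' the postsynaptic subpopulation `y` and the presynaptic subpopulation `x`:
#' the sum of the intermediate phase lags, reduced modulo one (with a sign
#' flip for `y < x`). The diagonal is zero and
#' `Dphi[x, y] + Dphi[y, x] == 0 (mod 1)` for `x != y`.
#'
#' @param delta_alpha Numeric vector of `M - 1` phase lags.
#' @return An `M x M` numeric matrix with entries in `[0, 1)`.
#' @export
phase_shift_matrix <- function(delta_alpha) {
  M <- length(delta_alpha) + 1L
  alpha <- c(0, cumsum(delta_alpha))
  D <- matrix(0, M, M)
  for (x in seq_len(M)) {
    for (y in seq_len(M)) {
      if (y > x) D[x, y] <- (alpha[y] - alpha[x]) %% 1
      if (y < x) D[x, y] <- (-(alpha[x] - alpha[y])) %% 1
    }
  }
  D
}

#' Export a stimulus schedule as a table
#'
#' @param onsets List of per-subpopulation onset time vectors (ms), as
#'   returned by [pmcs_onsets()] or [crs_rvs_onsets()].
#' @param path Optional path; when given, the table is written as
#'   tab-separated text.
#' @return A data.frame with columns `subpopulation`, `onset_ms`,
#'   `stimulus_id`, sorted by onset time.
#' @export
schedule_table <- function(onsets, path = NULL) {
  df <- do.call(rbind, lapply(seq_along(onsets), function(k) {
    if (!length(onsets[[k]])) return(NULL)
    data.frame(subpopulation = k, onset_ms = onsets[[k]],
               stimulus_id = seq_along(onsets[[k]]))
  }))
  df <- df[order(df$onset_ms, df$subpopulation), , drop = FALSE]
  rownames(df) <- NULL
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  df
}
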